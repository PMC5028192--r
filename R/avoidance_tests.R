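#' Mann-Whitney U test
#'
#' Rank-sum test used throughout the avoidance analyses. The p-value is exact
#' (full permutation distribution) when `nx * ny <= 400` and the pooled
#' sample has no ties; otherwise a normal approximation with midrank tie
#' correction and continuity correction is used. Energies capped at 0 create
#' tie masses, so the tie-corrected path matters in practice.
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"` (x stochastically greater than y) or
#'   `"two.sided"`.
#' @return list with `U` (of sample `x`), `p`, and `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("constant pooled sample; p = 1")
    return(list(U = nx * ny / 2, p = 1, method = "degenerate"))
  }
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (nx * ny <= 400 && !ties) {
    # exact distribution of U (no ties): pwilcox enumerates rank configurations
    p <- switch(alternative,
      greater = pwilcox(U - 1, nx, ny, lower.tail = FALSE),
      two.sided = min(1, 2 * min(pwilcox(U, nx, ny),
                                 pwilcox(U - 1, nx, ny, lower.tail = FALSE))))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- nx * ny / 2
  n <- nx + ny
  tt <- table(pooled)
  tiecor <- sum(tt^3 - tt) / (n * (n - 1))
  v <- nx * ny / 12 * ((n + 1) - tiecor)
  if (v <= 0) {
    warning("zero rank variance; p = 1")
    return(list(U = U, p = 1, method = "degenerate"))
  }
  z <- switch(alternative,
    greater = (U - mu - 0.5) / sqrt(v),
    two.sided = (abs(U - mu) - 0.5) / sqrt(v))
  p <- switch(alternative,
    greater = pnorm(z, lower.tail = FALSE),
    two.sided = min(1, 2 * pnorm(z, lower.tail = FALSE)))
  list(U = U, p = p, method = "normal")
}

#' Extrinsic avoidance test for one genome
#'
#' Computes interaction energies for every native mRNA-head x ncRNA pair and
#' for shuffled heads (dinucleotide-preserving) x native ncRNAs, then asks
#' whether native energies are stochastically higher (less stable) than the
#' shuffle null with a one-tailed Mann-Whitney U test. All shuffles' pair
#' energies are pooled into a single null sample; the test returns one
#' p-value per genome.
#'
#' @param bundle a [genome_bundle()].
#' @param params an [energy_params()] object.
#' @param mode energy mode, `"access"` (default) or `"hybrid"`; see
#'   [interaction_energy()].
#' @param n_shuffles dinucleotide-preserving shuffles per head (default 200).
#' @param seed optional seed for the shuffle draw.
#' @param max_site site cap for `"access"` mode.
#' @return object of class `avoidance_result` with the native and null
#'   energy samples, `U` and `p_extrinsic` (`p_intrinsic` and `avoider`
#'   filled by [avoidance_scan()] / [classify_genome()]).
#' @export
extrinsic_avoidance_test <- function(bundle, params = energy_params(),
                                     mode = c("access", "hybrid"),
                                     n_shuffles = 200L, seed = NULL,
                                     max_site = 25L) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "genome_bundle"))
  if (!is.null(seed)) set.seed(seed)
  heads <- bundle$mrna_heads
  shuf <- unlist(lapply(heads, function(h) as.character(dinuc_shuffle(h, n_shuffles))))
  native <- as.vector(interaction_energy_matrix(heads, bundle$ncrnas, params,
                                                mode = mode, max_site = max_site))
  null <- as.vector(interaction_energy_matrix(setNames(shuf, NULL), bundle$ncrnas,
                                              params, mode = mode,
                                              max_site = max_site))
  if (all(native == 0) && all(null == 0)) {
    warning("no-interaction genome ", bundle$genome_id, "; p = 1")
    res <- list(U = length(native) * length(null) / 2, p = 1)
  } else {
    res <- mann_whitney_u(native, null, alternative = "greater")
  }
  structure(list(genome_id = bundle$genome_id, phylum = bundle$phylum,
                 domain = bundle$domain, native_energies = native,
                 null_energies = null, u_statistic = res$U,
                 p_extrinsic = res$p, p_intrinsic = NA_real_,
                 avoider = NA),
            class = "avoidance_result")
}

#' Intrinsic avoidance test for one genome
#'
#' Two-tailed Mann-Whitney U test for a G+C composition difference between a
#' genome's ncRNAs and its mRNA 5' regions. Compositional separation limits
#' the molecules' capacity to interact regardless of sequence order, which
#' the energy-shift (extrinsic) test cannot see.
#'
#' @param bundle a [genome_bundle()].
#' @return two-tailed p-value.
#' @export
intrinsic_avoidance_test <- function(bundle) {
  stopifnot(inherits(bundle, "genome_bundle"))
  if (length(bundle$ncrnas) < 2L || length(bundle$mrna_heads) < 2L) {
    stop("intrinsic test needs >= 2 sequences per class")
  }
  gcn <- gc_content(bundle$ncrnas)
  gcm <- gc_content(bundle$mrna_heads)
  if (sd(c(gcn, gcm)) > 0 && (sd(gcn) == 0 || sd(gcm) == 0)) {
    warning("zero within-class G+C variance in ", bundle$genome_id,
            "; the intrinsic test treats sequences as independent and its ",
            "p-value is unreliable for compositionally degenerate bundles")
  }
  mann_whitney_u(gcn, gcm, alternative = "two.sided")$p
}

#' Classify a genome as an avoider
#'
#' A genome avoids stochastic interactions if either the extrinsic
#' (energy-shift) or the intrinsic (G+C separation) test is significant at
#' `alpha` (strict `<`). No multiple-testing correction is applied across
#' genomes.
#'
#' @param result an `avoidance_result` with both p-values set, or a list with
#'   `p_extrinsic` and `p_intrinsic`.
#' @param alpha significance threshold (default 0.05).
#' @return logical.
#' @export
classify_genome <- function(result, alpha = 0.05) {
  stopifnot(!is.na(result$p_extrinsic), !is.na(result$p_intrinsic))
  (result$p_extrinsic < alpha) || (result$p_intrinsic < alpha)
}

#' Run both avoidance tests over a set of genomes
#'
#' @param bundles list of [genome_bundle()] objects.
#' @inheritParams extrinsic_avoidance_test
#' @param alpha classification threshold.
#' @return data.frame with one row per genome: `genome_id`, `phylum`,
#'   `domain`, `n_pairs`, `mean_native`, `mean_null`, `U`, `p_extrinsic`,
#'   `p_intrinsic`, `avoider`.
#' @export
avoidance_scan <- function(bundles, params = energy_params(),
                           mode = c("access", "hybrid"), n_shuffles = 200L,
                           seed = NULL, alpha = 0.05, max_site = 25L) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(bundles, function(b) {
    ex <- extrinsic_avoidance_test(b, params, mode = mode,
                                   n_shuffles = n_shuffles, max_site = max_site)
    ex$p_intrinsic <- intrinsic_avoidance_test(b)
    data.frame(genome_id = b$genome_id, phylum = b$phylum, domain = b$domain,
               n_pairs = length(ex$native_energies),
               mean_native = mean(ex$native_energies),
               mean_null = mean(ex$null_energies),
               U = ex$u_statistic, p_extrinsic = ex$p_extrinsic,
               p_intrinsic = ex$p_intrinsic,
               avoider = classify_genome(ex, alpha))
  })
  do.call(rbind, rows)
}

#' @export
print.avoidance_result <- function(x, ...) {
  cat(sprintf("<avoidance_result> %s: %d native vs %d null energies\n",
              x$genome_id, length(x$native_energies), length(x$null_energies)))
  cat(sprintf("  mean native %.2f, mean null %.2f kcal/mol\n",
              mean(x$native_energies), mean(x$null_energies)))
  cat(sprintf("  p_extrinsic = %.3g, p_intrinsic = %s, avoider = %s\n",
              x$p_extrinsic,
              ifelse(is.na(x$p_intrinsic), "NA", format(x$p_intrinsic, digits = 3)),
              x$avoider))
  invisible(x)
}

#' Density difference between native and null energy distributions
#'
#' Gaussian-kernel densities (Silverman's rule-of-thumb bandwidth, computed
#' per sample) evaluated on a common grid and subtracted. Positive values
#' mark an excess of native interactions at that energy.
#'
#' @param native,null numeric energy samples.
#' @param n_grid grid size.
#' @param from,to optional grid range (defaults to the pooled range extended
#'   by three bandwidths).
#' @return data.frame of class `density_difference` with `energy` and
#'   `delta_density`.
#' @export
density_difference_curve <- function(native, null, n_grid = 512L,
                                     from = NULL, to = NULL) {
  stopifnot(length(native) >= 2L, length(null) >= 2L)
  bw1 <- stats::bw.nrd0(native)
  bw2 <- stats::bw.nrd0(null)
  if (is.null(from)) from <- min(native, null) - 3 * max(bw1, bw2)
  if (is.null(to)) to <- max(native, null) + 3 * max(bw1, bw2)
  d1 <- density(native, bw = bw1, n = n_grid, from = from, to = to)
  d2 <- density(null, bw = bw2, n = n_grid, from = from, to = to)
  structure(data.frame(energy = d1$x, delta_density = d1$y - d2$y),
            class = c("density_difference", "data.frame"))
}

#' Per-phylum summary of avoidance results
#'
#' Fraction of avoider genomes and quantiles of `-log10(p_extrinsic)` per
#' phylum. Groups with fewer than `min_genomes` genomes are flagged
#' (`small_sample`), mirroring the exclusion of sparsely sequenced phyla
#' from genome-scale summaries.
#'
#' @param results data.frame from [avoidance_scan()].
#' @param min_genomes flag threshold (default 20).
#' @return data.frame with one row per phylum.
#' @export
phylum_summary <- function(results, min_genomes = 20L) {
  stopifnot(nrow(results) >= 1L)
  sp <- split(results, results$phylum)
  rows <- lapply(sp, function(d) {
    lp <- -log10(d$p_extrinsic)
    q <- quantile(lp, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(phylum = d$phylum[1], n_genomes = nrow(d),
               frac_avoider = mean(d$avoider),
               neglog10p_q25 = q[1], neglog10p_median = q[2],
               neglog10p_q75 = q[3],
               small_sample = nrow(d) < min_genomes)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
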