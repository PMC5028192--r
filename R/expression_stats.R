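#' Codon adaptation index
#'
#' Geometric mean over codons of the relative adaptiveness
#' `w = count(codon) / max count among its synonyms`, computed against a
#' reference usage table. Zero usage counts are smoothed to 0.5 before
#' normalisation. Codons of single-codon amino acids (Met, Trp) and stop
#' codons are excluded from the mean, as usual.
#'
#' @param cds RNA coding sequence (length divisible by 3).
#' @param usage named numeric vector of codon counts (RNA codons); see
#'   [codon_usage()].
#' @return CAI in (0, 1].
#' @export
compute_cai <- function(cds, usage) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  ct <- codon_table()
  w <- cai_weights(usage)
  cod <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- ct$code[cod]
  if (anyNA(aa)) stop("invalid codon(s) in CDS")
  keep <- aa != "*" & ct$degeneracy[aa] > 1L
  if (!any(keep)) stop("no multi-codon amino acids in CDS; CAI undefined")
  exp(mean(log(w[cod[keep]])))
}

# relative adaptiveness per codon from a usage count table
cai_weights <- function(usage) {
  ct <- codon_table()
  counts <- setNames(numeric(length(ct$code)), names(ct$code))
  usage <- usage[names(usage) %in% names(counts)]
  counts[names(usage)] <- usage
  counts[counts == 0] <- 0.5
  w <- counts
  for (codons in ct$synonyms) w[codons] <- counts[codons] / max(counts[codons])
  w
}

#' Accumulate codon usage counts from a set of coding sequences
#'
#' @param cds_set character vector of coding sequences (lengths divisible
#'   by 3).
#' @return named numeric vector of counts over the 64 RNA codons.
#' @export
codon_usage <- function(cds_set) {
  ct <- codon_table()
  counts <- setNames(numeric(length(ct$code)), names(ct$code))
  for (cds in cds_set) {
    if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
    cod <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    t <- table(cod)
    counts[names(t)] <- counts[names(t)] + as.numeric(t)
  }
  counts
}

#' Spearman rank correlation
#'
#' Midrank-based rho. For `n <= 8` the p-value is the exact permutation
#' probability (all `n!` orderings enumerated, valid with ties); otherwise
#' the usual t approximation.
#'
#' @param x,y numeric vectors (`n >= 3`).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `rho`, `p`, `method`; `rho` and `p` are NA (with a
#'   warning) for constant input.
#' @export
spearman <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, method = "degenerate"))
  }
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 8L) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(ix) cor(rx, ry[ix]))
    eps <- 1e-12
    p <- switch(alternative,
      two.sided = mean(abs(rhos) >= abs(rho) - eps),
      greater = mean(rhos >= rho - eps),
      less = mean(rhos <= rho + eps))
    return(list(rho = rho, p = p, method = "exact"))
  }
  t <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
  p <- switch(alternative,
    two.sided = 2 * pt(abs(t), n - 2, lower.tail = FALSE),
    greater = pt(t, n - 2, lower.tail = FALSE),
    less = pt(t, n - 2))
  list(rho = rho, p = min(1, p), method = "t")
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

#' Variance partitioning of protein abundance
#'
#' Ordinary least squares of log protein abundance on codon adaptation
#' (`cai`), 5' folding energy (`fold5p`), avoidance (summed interaction
#' energy) and, when present, log mRNA abundance. Reports the R^2 of each
#' single-feature model, of the full model, and of the full model with the
#' avoidance feature removed — the drop measures what avoidance explains over
#' and above the classical predictors.
#'
#' @param records data.frame with `protein_abundance` and the feature
#'   columns; zero/negative protein abundances are dropped with a warning
#'   before the log transform.
#' @param features feature columns to use (default the spec's four, reduced
#'   to those present).
#' @return list with `r2_single` (named), `r2_full`, `r2_minus_avoidance`,
#'   `drop`, `n`.
#' @export
variance_partition <- function(records,
                               features = c("cai", "fold5p", "avoidance",
                                            "log_mrna")) {
  d <- records
  if (!("log_mrna" %in% names(d)) && "mrna_abundance" %in% names(d)) {
    ok <- d$mrna_abundance > 0
    d$log_mrna <- ifelse(ok, log(d$mrna_abundance), NA_real_)
  }
  features <- intersect(features, names(d))
  if (length(features) < 2L) stop("need at least two feature columns")
  keep <- d$protein_abundance > 0
  if (any(!keep)) warning(sum(!keep), " records with non-positive protein abundance dropped")
  d <- d[keep, , drop = FALSE]
  d$y <- log(d$protein_abundance)
  d <- d[complete.cases(d[, c("y", features)]), , drop = FALSE]
  if (nrow(d) <= length(features) + 1L) stop("too few records for the full model")
  X <- as.matrix(d[, features])
  kap <- kappa(cbind(1, scale(X)), exact = TRUE)
  if (kap > 1e6) warning("near-collinear features (condition number ", signif(kap, 3), ")")
  r2 <- function(fml) summary(lm(fml, data = d))$r.squared
  r2_single <- vapply(features, function(f) r2(stats::reformulate(f, "y")),
                      numeric(1))
  r2_full <- r2(stats::reformulate(features, "y"))
  rest <- setdiff(features, "avoidance")
  r2_wo <- if (length(rest)) r2(stats::reformulate(rest, "y")) else 0
  list(r2_single = r2_single, r2_full = r2_full, r2_minus_avoidance = r2_wo,
       drop = r2_full - r2_wo, n = nrow(d))
}

#' Outlier analysis of protein-per-mRNA ratios
#'
#' Ranks genes by translational efficiency (protein / mRNA abundance),
#' z-transforms each metric over all genes, and reports the mean z of the
#' `top_n` most and least productive genes per metric together with a
#' one-sample z test of the group mean against the background (mean 0, sd 1).
#'
#' @param records data.frame with `protein_abundance`, `mrna_abundance` and
#'   metric columns.
#' @param top_n group size (default 10; needs `nrow >= 4 * top_n`).
#' @param metrics metric columns (default cai, fold5p, avoidance).
#' @return data.frame with `group`, `metric`, `mean_z`, `p`.
#' @export
outlier_zscores <- function(records, top_n = 10L,
                            metrics = c("cai", "fold5p", "avoidance")) {
  d <- records
  stopifnot(all(c("protein_abundance", "mrna_abundance") %in% names(d)))
  bad <- d$mrna_abundance == 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with zero mRNA abundance excluded")
    d <- d[!bad, , drop = FALSE]
  }
  if (nrow(d) < 4L * top_n) stop("need at least 4 * top_n genes")
  metrics <- intersect(metrics, names(d))
  ratio <- d$protein_abundance / d$mrna_abundance
  ord <- order(ratio)
  groups <- list(bottom = ord[seq_len(top_n)],
                 top = ord[seq(nrow(d) - top_n + 1L, nrow(d))])
  rows <- list()
  for (m in metrics) {
    s <- sd(d[[m]])
    z <- if (s > 0) (d[[m]] - mean(d[[m]])) / s else rep(0, nrow(d))
    for (g in names(groups)) {
      mz <- mean(z[groups[[g]]])
      p <- 2 * pnorm(abs(mz) * sqrt(top_n), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(group = g, metric = m,
                                              mean_z = mz, p = p)
    }
  }
  do.call(rbind, rows)
}

#' Group comparison of expression values
#'
#' Kruskal-Wallis test across construct categories followed by pairwise
#' one-tailed Mann-Whitney U tests (the group with the larger median taken as
#' the "greater" side), Holm-corrected.
#'
#' @param values numeric expression values.
#' @param groups group labels (>= 2 groups, each with >= 2 values).
#' @return list with `H`, `p` and `pairwise` (data.frame: `group1`, `group2`,
#'   `p_raw`, `p_holm`, with `group1` the higher-median group).
#' @export
group_tests <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 values")
  kw <- kruskal.test(values, groups)
  lev <- levels(groups)
  cmb <- combn(lev, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    g1 <- cmb[1, k]; g2 <- cmb[2, k]
    v1 <- values[groups == g1]; v2 <- values[groups == g2]
    if (median(v2) > median(v1)) { tmp <- g1; g1 <- g2; g2 <- tmp; tv <- v1; v1 <- v2; v2 <- tv }
    data.frame(group1 = g1, group2 = g2,
               p_raw = mann_whitney_u(v1, v2, alternative = "greater")$p)
  })
  pw <- do.call(rbind, rows)
  pw$p_holm <- p.adjust(pw$p_raw, method = "holm")
  list(H = unname(kw$statistic), p = kw$p.value, pairwise = pw)
}
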