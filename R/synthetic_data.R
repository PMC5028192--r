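#' Specification for the synthetic-data generators
#'
#' Defines the study conditions every synthetic fixture is generated under:
#' genome dimensions, compositional targets, the planted extrinsic-avoidance
#' shift, the expression model and the contact concordance. Defaults are the
#' package's standard fixture scale (20 genomes x 50 heads x 10 ncRNAs x 50
#' shuffles) with neutral composition (G+C 0.5) and no planted effect.
#'
#' @param n_genomes number of genomes (default 20).
#' @param n_heads mRNA heads per genome (default 50).
#' @param n_ncrnas ncRNAs per genome (default 10).
#' @param head_len head length (default 21).
#' @param ncrna_len_range ncRNA length range (default 60..100 nt).
#' @param gc_mrna,gc_ncrna target G+C fractions (default 0.5).
#' @param head_sampling `"template_shuffle"` (default): each genome's heads
#'   are dinucleotide-preserving shuffles of one genome-level template, so
#'   all heads share a composition (within-genome homogeneity) and, at
#'   `effect_delta = 0`, native heads are exactly exchangeable with their
#'   shuffle null. `"iid"`: heads are independent draws at `gc_mrna`, giving
#'   the compositional heterogeneity the intrinsic (G+C) test operates on.
#' @param effect_delta planted extrinsic-avoidance shift in kcal/mol: mRNA
#'   heads are rejection-sampled until their mean interaction energy against
#'   the genome's ncRNAs is at least `effect_delta` above (less stable than)
#'   the genome's null mean. 0 disables rejection and yields calibrated
#'   nulls.
#' @param n_shuffles shuffles per head for fixture-level scans (default 50).
#' @param beta_avoid,beta_cai,beta_fold expression-model coefficients on the
#'   z-scaled features.
#' @param sigma expression noise sd (ignored when `target_r2` is given).
#' @param target_r2 optional planned signal fraction; the noise sd is set to
#'   `sqrt(var(signal) * (1 - R2) / R2)`.
#' @param contact_concordance probability that a residue's contact flag is
#'   the complement of its avoidance flag (1 = avoided residues are exactly
#'   the accessible ones, 0.5 = independent).
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genomes = 20L, n_heads = 50L, n_ncrnas = 10L,
                           head_len = 21L, ncrna_len_range = c(60L, 100L),
                           gc_mrna = 0.5, gc_ncrna = 0.5, effect_delta = 0,
                           head_sampling = c("template_shuffle", "iid"),
                           n_shuffles = 50L, beta_avoid = 1, beta_cai = 0.5,
                           beta_fold = 0.5, sigma = 1, target_r2 = NULL,
                           contact_concordance = 0.5, seed = 1L) {
  head_sampling <- match.arg(head_sampling)
  stopifnot(gc_mrna >= 0, gc_mrna <= 1, gc_ncrna >= 0, gc_ncrna <= 1,
            sigma >= 0, contact_concordance >= 0, contact_concordance <= 1,
            effect_delta >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

# random RNA strings with a target G+C fraction
random_rna <- function(n, len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    character(1))
}

#' Generate a synthetic genome bundle
#'
#' ncRNAs are i.i.d. random sequences at the target G+C. Head candidates are
#' drawn per `head_sampling` (by default as dinucleotide shuffles of a
#' genome-level template, so the `effect_delta = 0` null is exactly
#' exchangeable with the shuffle control). With `effect_delta > 0`, avoidance
#' is planted by rejection sampling: the genome's null mean pair energy is
#' estimated from reference draws, and a candidate head is kept only if its
#' mean interaction energy against the ncRNA set is at least `effect_delta`
#' above that null mean, i.e. its interactions are at least `effect_delta`
#' kcal/mol weaker than expected. Rejection (rather than relabelling
#' energies) means the planted effect survives re-analysis under any energy
#' mode.
#'
#' @param spec a [synthetic_spec()].
#' @param genome_id identifier (default `"synth1"`).
#' @param params an [energy_params()] object.
#' @param mode energy mode used for the rejection criterion.
#' @param phylum,domain labels for the bundle.
#' @param n_reference candidate draws used to estimate the null mean
#'   (default 60).
#' @param max_draws rejection-sampling budget; exceeding it is an error
#'   (infeasible spec).
#' @return a [genome_bundle()].
#' @export
synth_genome <- function(spec, genome_id = "synth1", params = energy_params(),
                         mode = c("hybrid", "access"), phylum = "SimPhylum",
                         domain = "BACTERIA", n_reference = 60L,
                         max_draws = 1e5) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "synthetic_spec"))
  lens <- if (spec$ncrna_len_range[1] == spec$ncrna_len_range[2]) {
    rep(spec$ncrna_len_range[1], spec$n_ncrnas)
  } else {
    sample(spec$ncrna_len_range[1]:spec$ncrna_len_range[2], spec$n_ncrnas,
           replace = TRUE)
  }
  ncrnas <- vapply(lens, function(L) random_rna(1, L, spec$gc_ncrna),
                   character(1))
  names(ncrnas) <- sprintf("%s_ncrna%02d", genome_id, seq_along(ncrnas))

  template <- random_rna(1, spec$head_len, spec$gc_mrna)
  draw_heads <- function(k) {
    if (spec$head_sampling == "template_shuffle") {
      as.character(dinuc_shuffle(template, k))
    } else {
      random_rna(k, spec$head_len, spec$gc_mrna)
    }
  }
  if (spec$effect_delta <= 0) {
    heads <- draw_heads(spec$n_heads)
  } else {
    mu0 <- mean(interaction_energy_matrix(
      setNames(draw_heads(n_reference), NULL), ncrnas, params, mode = mode))
    thr <- mu0 + spec$effect_delta
    heads <- character(0)
    drawn <- 0
    batch <- max(20L, spec$n_heads)
    while (length(heads) < spec$n_heads) {
      if (drawn >= max_draws) {
        stop("rejection sampling failed after ", drawn,
             " draws; effect_delta = ", spec$effect_delta, " is infeasible ",
             "for this composition")
      }
      cand <- draw_heads(batch)
      drawn <- drawn + batch
      e <- interaction_energy_matrix(setNames(cand, NULL), ncrnas, params,
                                     mode = mode)
      keep <- rowMeans(e) >= thr
      heads <- c(heads, cand[keep])
    }
    heads <- heads[seq_len(spec$n_heads)]
  }
  names(heads) <- sprintf("%s_head%03d", genome_id, seq_along(heads))
  genome_bundle(genome_id, heads, ncrnas, domain = domain, phylum = phylum,
                head_len = spec$head_len)
}

#' Generate synthetic expression records with known ground truth
#'
#' Random coding sequences are generated and their real metrics computed
#' (CAI against the set's own usage, 5' folding MFE, summed interaction
#' energy of the head against the genome's ncRNAs); log protein abundance is
#' then a linear function of the z-scaled metrics plus Gaussian noise, and
#' mRNA abundance an independent log-normal. The realised coefficients,
#' noise sd and planned R^2 values (computed from the noiseless signal, not
#' from the fitted model) are attached as attribute `truth`.
#'
#' @param spec a [synthetic_spec()].
#' @param ncrnas ncRNA set (defaults to a fresh draw per `spec`).
#' @param n_genes number of genes (default 200).
#' @param cds_len CDS length in nt, multiple of 3 (default 120).
#' @param params an [energy_params()] object.
#' @param mode energy mode for the avoidance metric.
#' @return data.frame with `gene_id`, `mrna_abundance`, `protein_abundance`,
#'   `cai`, `fold5p`, `avoidance`; attribute `truth` holds the planted model.
#' @export
synth_expression <- function(spec, ncrnas = NULL, n_genes = 200L,
                             cds_len = 120L, params = energy_params(),
                             mode = c("hybrid", "access")) {
  mode <- match.arg(mode)
  stopifnot(cds_len %% 3L == 0L, cds_len >= spec$head_len)
  if (is.null(ncrnas)) {
    lens <- sample(spec$ncrna_len_range[1]:spec$ncrna_len_range[2],
                   spec$n_ncrnas, replace = TRUE)
    ncrnas <- vapply(lens, function(L) random_rna(1, L, spec$gc_ncrna),
                     character(1))
    names(ncrnas) <- sprintf("ncrna%02d", seq_along(ncrnas))
  }
  cds <- random_rna(n_genes, cds_len, spec$gc_mrna)
  usage <- codon_usage(cds)
  heads <- substr(cds, 1L, spec$head_len)
  avoid <- rowSums(interaction_energy_matrix(setNames(heads, NULL), ncrnas,
                                             params, mode = mode))
  pc <- .par_cpp(params)
  fold5p <- vapply(cds, function(s) {
    win <- substr(s, 1L, min(37L, nchar(s)))
    v <- .enc(win)
    c_fold(v, pc, rep(FALSE, length(v)), structure = FALSE)$energy
  }, numeric(1), USE.NAMES = FALSE)
  cai <- vapply(cds, compute_cai, numeric(1), usage = usage,
                USE.NAMES = FALSE)

  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  za <- zs(avoid); zc <- zs(cai); zf <- zs(fold5p)
  signal <- spec$beta_avoid * za + spec$beta_cai * zc + spec$beta_fold * zf
  vs <- var(signal)
  sigma <- spec$sigma
  if (!is.null(spec$target_r2) && vs > 0) {
    sigma <- sqrt(vs * (1 - spec$target_r2) / spec$target_r2)
  }
  log_protein <- signal + rnorm(n_genes, 0, sigma)
  # planned quantities from the noiseless signal (independent of the fit)
  vt <- vs + sigma^2
  r2_planned <- if (vt > 0) vs / vt else 0
  others <- if (vs > 0) fitted(lm(signal ~ zc + zf)) else signal
  r2_wo_planned <- if (vt > 0) var(others) / vt else 0
  rec <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    mrna_abundance = exp(rnorm(n_genes, 4, 1)),
    protein_abundance = exp(log_protein),
    cai = cai, fold5p = fold5p, avoidance = avoid,
    stringsAsFactors = FALSE)
  attr(rec, "truth") <- list(
    beta = c(avoid = spec$beta_avoid, cai = spec$beta_cai,
             fold = spec$beta_fold),
    sigma = sigma, r2_planned = r2_planned,
    r2_minus_avoidance_planned = r2_wo_planned,
    drop_planned = r2_planned - r2_wo_planned)
  rec
}

#' Generate a synthetic contact table concordant with an avoidance profile
#'
#' With probability `concordance` a residue's contact flag is the complement
#' of its avoidance flag (avoided => accessible); otherwise it copies the
#' flag. `concordance = 1` gives perfect anti-association, 0.5 independence,
#' 0 perfect co-occurrence.
#'
#' @param profile an [ncrna_window_profile()] result.
#' @param concordance probability in `[0, 1]`.
#' @param seed optional seed.
#' @return data.frame with `position`, `in_contact`.
#' @export
synth_contacts <- function(profile, concordance = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  avoided <- residue_avoidance(profile)
  flip <- runif(length(avoided)) < concordance
  data.frame(position = seq_along(avoided),
             in_contact = ifelse(flip, !avoided, avoided))
}

#' Build a profile fixture with one planted avoided window
#'
#' Constructs an ncRNA with a G+C-rich target window and native mRNA heads
#' rejection-sampled to bind that window only weakly (duplex energy above
#' `native_threshold`). Dinucleotide shuffles of such heads bind the window
#' at composition-typical strength, so the planted window carries a real
#' extrinsic avoidance signal while flanking windows stay null.
#'
#' @param n_heads number of native heads.
#' @param head_len head length (default 21).
#' @param ncrna_len ncRNA length (default 60).
#' @param window_start planted window start (default 26).
#' @param w window length (default 10).
#' @param gc background G+C (default 0.5).
#' @param native_threshold maximum binding strength allowed for native heads
#'   against the planted window, kcal/mol; the default 0 admits only heads
#'   with no favourable binding at all, so the planted contrast is carried by
#'   sequence arrangement (which shuffling destroys) rather than by
#'   composition (which shuffling preserves).
#' @param params an [energy_params()] object.
#' @param seed optional seed.
#' @return list with `ncrna`, `heads`, `window_start`, `w`.
#' @export
synth_avoided_window <- function(n_heads = 40L, head_len = 21L,
                                 ncrna_len = 60L, window_start = 26L, w = 10L,
                                 gc = 0.5, native_threshold = 0,
                                 params = energy_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(window_start >= 1L, window_start + w - 1L <= ncrna_len)
  ncrna <- random_rna(1, ncrna_len, gc)
  # G+C-rich planted window: plenty of binding partners in shuffled space
  win <- random_rna(1, w, 0.8)
  substr(ncrna, window_start, window_start + w - 1L) <- win
  heads <- character(0)
  drawn <- 0
  while (length(heads) < n_heads) {
    if (drawn > 1e5) stop("could not sample weakly binding native heads")
    cand <- random_rna(50L, head_len, gc)
    drawn <- drawn + 50L
    e <- interaction_energy_matrix(setNames(cand, NULL), c(win = win), params,
                                   mode = "hybrid")
    heads <- c(heads, cand[e[, 1] >= native_threshold])
  }
  heads <- heads[seq_len(n_heads)]
  names(heads) <- sprintf("head%03d", seq_along(heads))
  list(ncrna = setNames(ncrna, "planted"), heads = heads,
       window_start = window_start, w = w)
}
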