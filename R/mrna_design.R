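#' Sample synonymous coding sequences for a protein
#'
#' Draws coding sequences uniformly over codons at each site (usage-weighted
#' sampling available via `weights`), so the extremes of CAI, folding energy
#' and avoidance are all reachable. Duplicates are removed from the output.
#'
#' @param protein amino-acid string over the 20 standard residues.
#' @param n number of draws.
#' @param seed optional seed.
#' @param weights optional named codon weight vector for usage-weighted
#'   sampling (e.g. a [codon_usage()] table).
#' @return character vector of distinct RNA coding sequences, each
#'   translating to `protein`.
#' @export
sample_synonymous <- function(protein, n, seed = NULL, weights = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ct <- codon_table()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- !(aa %in% setdiff(names(ct$synonyms), "*"))
  if (any(bad)) stop("unknown residue(s): ", paste(unique(aa[bad]), collapse = ", "))
  cols <- lapply(aa, function(a) {
    syn <- ct$synonyms[[a]]
    wt <- if (is.null(weights)) NULL else {
      v <- weights[syn]; v[is.na(v)] <- 0
      if (sum(v) == 0) NULL else v
    }
    sample(syn, n, replace = TRUE, prob = wt)
  })
  unique(do.call(paste0, cols))
}

#' Enumerate every synonymous coding sequence of a short protein
#'
#' Exhaustive version of [sample_synonymous()] for toy proteins; the pool
#' size is the product of codon degeneracies, so keep it small.
#'
#' @param protein amino-acid string.
#' @return character vector of all coding sequences.
#' @export
enumerate_synonymous <- function(protein) {
  ct <- codon_table()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  pools <- ct$synonyms[aa]
  n <- prod(lengths(pools))
  if (n > 1e6) stop("degeneracy ", n, " too large to enumerate")
  out <- do.call(expand.grid, c(rev(pools), stringsAsFactors = FALSE))
  out <- out[, rev(seq_along(pools)), drop = FALSE]
  do.call(paste0, out)
}

#' Score a candidate coding sequence for the designer
#'
#' Computes the selection metrics: CAI against a reference usage, the 5' end
#' folding MFE (first `fold_len` nucleotides, default 37), the avoidance sum
#' (summed interaction energy of the first `head_len` nucleotides against
#' every ncRNA — ncRNAs are assumed far more abundant than the mRNA, so each
#' site is saturated,
#' so energies add), overall G+C and 5' head G+C. Higher avoidance sums (less
#' negative) mean more avoidance.
#'
#' @param cds RNA coding sequence.
#' @param ncrnas named character vector of ncRNAs.
#' @param usage codon usage reference (see [codon_usage()]).
#' @param params an [energy_params()] object.
#' @param mode energy mode (default `"hybrid"`).
#' @param head_len interaction region length (default 21).
#' @param fold_len folding window (default 37; truncated with a warning for
#'   shorter toy sequences).
#' @return one-row data.frame: `cds`, `cai`, `fold5p`, `avoidance_sum`, `gc`,
#'   `gc5p`.
#' @export
score_candidate <- function(cds, ncrnas, usage, params = energy_params(),
                            mode = c("hybrid", "access"), head_len = 21L,
                            fold_len = 37L) {
  mode <- match.arg(mode)
  out <- score_candidates(cds, ncrnas, usage, params, mode, head_len, fold_len)
  out
}

#' @describeIn score_candidate vectorised scoring of a candidate pool.
#' @param cds_set character vector of coding sequences.
#' @export
score_candidates <- function(cds_set, ncrnas, usage, params = energy_params(),
                             mode = c("hybrid", "access"), head_len = 21L,
                             fold_len = 37L) {
  mode <- match.arg(mode)
  stopifnot(length(ncrnas) >= 1L)
  if (any(nchar(cds_set) < head_len)) stop("CDS shorter than the interaction head")
  if (any(nchar(cds_set) < fold_len)) {
    warning("CDS shorter than fold window; folding first ",
            min(nchar(cds_set)), " nt instead of ", fold_len)
  }
  heads <- substr(cds_set, 1L, head_len)
  e <- interaction_energy_matrix(setNames(heads, NULL), ncrnas, params,
                                 mode = mode)
  avoid <- rowSums(e)
  pc <- .par_cpp(params)
  fold5p <- vapply(cds_set, function(s) {
    win <- substr(s, 1L, min(fold_len, nchar(s)))
    v <- .enc(win)
    c_fold(v, pc, rep(FALSE, length(v)), structure = FALSE)$energy
  }, numeric(1), USE.NAMES = FALSE)
  cai <- vapply(cds_set, compute_cai, numeric(1), usage = usage,
                USE.NAMES = FALSE)
  data.frame(cds = cds_set, cai = cai, fold5p = fold5p, avoidance_sum = avoid,
             gc = gc_content(cds_set), gc5p = gc_content(heads),
             stringsAsFactors = FALSE)
}

#' Design-selection specification
#'
#' Constraints used by [select_extremes()]: the global G+C band, the exact
#' head G+C target (matched as `round(gc5p_target * head_len)` G+C
#' nucleotides, since a 21-nt head only realises multiples of 1/21) and the
#' minimum pairwise Hamming distance between selected constructs.
#'
#' @param n_per_category constructs per extreme category (default 2).
#' @param n_optimal optimal constructs (default 1).
#' @param gc_band closed G+C interval (default `c(0.468, 0.480)`).
#' @param gc5p_target head G+C target (default 0.48).
#' @param min_pairwise_hamming diversity constraint (default 100 nt).
#' @param head_len interaction region length (default 21).
#' @return list of class `design_spec`.
#' @export
design_spec <- function(n_per_category = 2L, n_optimal = 1L,
                        gc_band = c(0.468, 0.480), gc5p_target = 0.48,
                        min_pairwise_hamming = 100L, head_len = 21L) {
  stopifnot(n_per_category >= 0L, n_optimal >= 0L,
            length(gc_band) == 2L, gc_band[1] <= gc_band[2],
            gc_band[1] >= 0, gc_band[2] <= 1)
  structure(list(n_per_category = n_per_category, n_optimal = n_optimal,
                 gc_band = gc_band, gc5p_target = gc5p_target,
                 min_pairwise_hamming = min_pairwise_hamming,
                 head_len = head_len),
            class = "design_spec")
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Select extreme and optimal constructs from a scored pool
#'
#' Filters the pool to the G+C band and the exact head G+C count, then
#' greedily picks, per category in the order MIN_FOLD, MAX_FOLD, MIN_CAI,
#' MAX_CAI, MIN_AVOID, MAX_AVOID, the most extreme candidates that are at
#' least `min_pairwise_hamming` substitutions away from everything already
#' selected; the OPTIMAL construct (high CAI, weak 5' structure, high
#' avoidance) is chosen last among candidates at or above the per-metric
#' medians of the filtered pool, by lexicographic comparison on
#' (cai, fold5p, avoidance_sum) descending. With the default counts
#' (2 per extreme x 2 directions x 3 metrics + 1) this yields 13 constructs.
#'
#' @param candidates scored pool from [score_candidates()].
#' @param spec a [design_spec()].
#' @return `candidates` rows for the selected constructs with an added
#'   `category` column.
#' @export
select_extremes <- function(candidates, spec = design_spec()) {
  stopifnot(nrow(candidates) >= 1L, inherits(spec, "design_spec"))
  gc5p_count <- round(spec$gc5p_target * spec$head_len)
  pool <- candidates[
    candidates$gc >= spec$gc_band[1] & candidates$gc <= spec$gc_band[2] &
    round(candidates$gc5p * spec$head_len) == gc5p_count, , drop = FALSE]
  if (nrow(pool) == 0L) {
    stop("no candidates satisfy the G+C constraints (band [",
         spec$gc_band[1], ", ", spec$gc_band[2], "], head G+C count ",
         gc5p_count, ")")
  }
  cats <- c(MIN_FOLD = "fold5p", MAX_FOLD = "fold5p", MIN_CAI = "cai",
            MAX_CAI = "cai", MIN_AVOID = "avoidance_sum",
            MAX_AVOID = "avoidance_sum")
  decreasing <- c(MIN_FOLD = FALSE, MAX_FOLD = TRUE, MIN_CAI = FALSE,
                  MAX_CAI = TRUE, MIN_AVOID = FALSE, MAX_AVOID = TRUE)
  selected <- integer(0)
  category <- character(0)
  far_enough <- function(idx) {
    all(vapply(selected, function(s)
      hamming(pool$cds[idx], pool$cds[s]) >= spec$min_pairwise_hamming,
      logical(1)))
  }
  for (cat in names(cats)) {
    ord <- order(pool[[cats[cat]]], decreasing = decreasing[cat])
    taken <- 0L
    for (idx in ord) {
      if (taken >= spec$n_per_category) break
      if (idx %in% selected || !far_enough(idx)) next
      selected <- c(selected, idx)
      category <- c(category, cat)
      taken <- taken + 1L
    }
    if (taken < spec$n_per_category) {
      stop("insufficient candidates for category ", cat,
           " under the diversity constraint (needed ", spec$n_per_category,
           ", found ", taken, ")")
    }
  }
  if (spec$n_optimal > 0L) {
    med <- vapply(c("cai", "fold5p", "avoidance_sum"),
                  function(m) median(pool[[m]]), numeric(1))
    opt <- which(pool$cai >= med["cai"] & pool$fold5p >= med["fold5p"] &
                 pool$avoidance_sum >= med["avoidance_sum"])
    opt <- opt[order(-pool$cai[opt], -pool$fold5p[opt],
                     -pool$avoidance_sum[opt])]
    taken <- 0L
    for (idx in opt) {
      if (taken >= spec$n_optimal) break
      if (idx %in% selected || !far_enough(idx)) next
      selected <- c(selected, idx)
      category <- c(category, "OPTIMAL")
      taken <- taken + 1L
    }
    if (taken < spec$n_optimal) {
      stop("insufficient candidates for the OPTIMAL construct ",
           "(above-median filter + diversity constraint)")
    }
  }
  out <- pool[selected, , drop = FALSE]
  out$category <- category
  rownames(out) <- NULL
  out
}
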