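#' Positional avoidance profile along an ncRNA
#'
#' Slides a window (default 10 nt, step 1) along the ncRNA and, for each
#' window, compares the interaction energies of the native mRNA heads against
#' dinucleotide-shuffled heads with a one-tailed Mann-Whitney U test. Windows
#' with `p < alpha` (default 0.001) are flagged as avoided: native mRNAs bind
#' them less than composition predicts. The shuffled head set is drawn once
#' and reused across windows.
#'
#' @param ncrna a single ncRNA string (named or not).
#' @param heads named character vector of mRNA heads.
#' @param params an [energy_params()] object.
#' @param w window length (default 10).
#' @param step step size (default 1).
#' @param n_shuffles shuffles per head (default 200).
#' @param alpha window significance threshold (default 0.001).
#' @param seed optional shuffle seed.
#' @param mode energy mode; windows are short, so the raw duplex energy
#'   (`"hybrid"`) is the default here.
#' @param reference_id identifier stored with the profile.
#' @return data.frame of class `avoidance_profile` with `window_start`,
#'   `p_value`, `avoided`; attributes `reference_id`, `ref_length`, `w`,
#'   `alpha`.
#' @export
ncrna_window_profile <- function(ncrna, heads, params = energy_params(),
                                 w = 10L, step = 1L, n_shuffles = 200L,
                                 alpha = 0.001, seed = NULL,
                                 mode = c("hybrid", "access"),
                                 reference_id = names(ncrna) %||% "ncrna") {
  mode <- match.arg(mode)
  force(reference_id) # default uses names(ncrna); bind before unname()
  ncrna <- unname(ncrna)
  L <- nchar(ncrna)
  if (w > L) stop("window length ", w, " exceeds ncRNA length ", L)
  if (!is.null(seed)) set.seed(seed)
  shuf <- unlist(lapply(heads, function(h) as.character(dinuc_shuffle(h, n_shuffles))))
  starts <- seq(1L, L - w + 1L, by = step)
  p <- vapply(starts, function(s0) {
    win <- substr(ncrna, s0, s0 + w - 1L)
    native <- as.vector(interaction_energy_matrix(heads, c(win = win), params,
                                                  mode = mode))
    null <- as.vector(interaction_energy_matrix(setNames(shuf, NULL),
                                                c(win = win), params, mode = mode))
    if (all(native == 0) && all(null == 0)) return(1)
    mann_whitney_u(native, null, alternative = "greater")$p
  }, numeric(1))
  structure(data.frame(window_start = starts, p_value = p, avoided = p < alpha),
            class = c("avoidance_profile", "data.frame"),
            reference_id = reference_id, ref_length = L, w = as.integer(w),
            alpha = alpha)
}

#' Reduce window-level avoidance flags to residues
#'
#' A residue is avoided if covering windows are significant: under
#' `reduce = "any"` (default) one significant covering window suffices;
#' `"majority"` requires more than half of the covering windows.
#'
#' @param profile an [ncrna_window_profile()] result.
#' @param reduce `"any"` or `"majority"`.
#' @return logical vector over the reference's residues.
#' @export
residue_avoidance <- function(profile, reduce = c("any", "majority")) {
  reduce <- match.arg(reduce)
  L <- attr(profile, "ref_length")
  w <- attr(profile, "w")
  hits <- integer(L)
  cover <- integer(L)
  for (k in seq_len(nrow(profile))) {
    idx <- profile$window_start[k]:(profile$window_start[k] + w - 1L)
    cover[idx] <- cover[idx] + 1L
    if (profile$avoided[k]) hits[idx] <- hits[idx] + 1L
  }
  if (reduce == "any") hits > 0L else hits > cover / 2
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test. The two-sided p-value sums all tables (with the
#' observed margins) whose point probability does not exceed the observed
#' one, the standard convention.
#'
#' @param table 2x2 matrix of non-negative integer counts; all margins must
#'   be positive.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (on the `[1,1]`
#'   cell).
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate margin in 2x2 table")
  }
  a <- table[1, 1]
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); N <- sum(table)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- dhyper(support, c1, N - c1, r1)
  pa <- dhyper(a, c1, N - c1, r1)
  switch(alternative,
    greater = sum(pr[support >= a]),
    less = sum(pr[support <= a]),
    two.sided = min(1, sum(pr[pr <= pa * (1 + 1e-7)])))
}

#' Association between avoided ncRNA regions and structural accessibility
#'
#' Cross-tabulates residues by avoidance (from the window profile) and by
#' structural contact (from a residue contact table derived from a 3D
#' structure: any atom within 3.4 Angstroms of another chain), then applies
#' Fisher's exact test. Avoided regions are predicted to be the accessible
#' (non-contacted) ones.
#'
#' @param profile an [ncrna_window_profile()] result.
#' @param contacts data.frame from [read_contact_table()] covering the
#'   profile's reference length.
#' @param reduce residue reduction rule, see [residue_avoidance()].
#' @param alternative sidedness of the Fisher test (default two-sided).
#' @return list with `table` (2x2: avoided x in_contact), `odds_ratio` (the
#'   odds of an avoided residue being accessible relative to the others;
#'   `Inf`-capped when a denominator cell is empty) and `p`.
#' @export
accessibility_association <- function(profile, contacts,
                                      reduce = c("any", "majority"),
                                      alternative = c("two.sided", "greater",
                                                      "less")) {
  reduce <- match.arg(reduce)
  alternative <- match.arg(alternative)
  L <- attr(profile, "ref_length")
  if (nrow(contacts) != L) {
    stop("contact table covers ", nrow(contacts), " residues, profile reference has ", L)
  }
  avoided <- residue_avoidance(profile, reduce)
  tab <- matrix(c(sum(avoided & contacts$in_contact),
                  sum(avoided & !contacts$in_contact),
                  sum(!avoided & contacts$in_contact),
                  sum(!avoided & !contacts$in_contact)),
                2, 2, byrow = TRUE,
                dimnames = list(avoided = c("TRUE", "FALSE"),
                                in_contact = c("TRUE", "FALSE")))
  num <- tab[1, 2] * tab[2, 1]
  den <- tab[1, 1] * tab[2, 2]
  or <- if (den == 0) Inf else num / den
  list(table = tab, odds_ratio = or,
       p = fisher_exact_2x2(tab, alternative = alternative))
}

#' Positional correlation between window avoidance and expression on mRNAs
#'
#' Slides a window (default 21 nt, step 1) along a set of coding sequences;
#' for each start position the per-CDS avoidance score is the summed
#' interaction energy of that window against the ncRNA set, and Spearman's
#' correlation with the expression values is reported. Localises which part
#' of an mRNA carries the avoidance signal for expression.
#'
#' @param cds_set named character vector of coding sequences (>= 5).
#' @param expression numeric expression value per CDS (same order).
#' @param ncrnas named character vector of ncRNAs.
#' @param params an [energy_params()] object.
#' @param w window length (default 21).
#' @param step step size (default 1).
#' @param mode energy mode (default `"hybrid"`).
#' @return data.frame with `position`, `rho`, `p` (NA when expression is
#'   constant).
#' @export
mrna_window_correlation <- function(cds_set, expression, ncrnas,
                                    params = energy_params(), w = 21L,
                                    step = 1L, mode = c("hybrid", "access")) {
  mode <- match.arg(mode)
  stopifnot(length(cds_set) == length(expression), length(cds_set) >= 5L)
  L <- min(nchar(cds_set))
  if (any(nchar(cds_set) != L)) {
    warning("unequal CDS lengths; windows truncated at ", L, " nt")
  }
  if (L < w) stop("shortest CDS (", L, " nt) shorter than the window")
  starts <- seq(1L, L - w + 1L, by = step)
  rows <- lapply(starts, function(s0) {
    wins <- substr(cds_set, s0, s0 + w - 1L)
    e <- interaction_energy_matrix(setNames(wins, names(cds_set)), ncrnas,
                                   params, mode = mode)
    score <- rowSums(e)
    sp <- spearman(score, expression)
    data.frame(position = s0, rho = sp$rho, p = sp$p)
  })
  do.call(rbind, rows)
}
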