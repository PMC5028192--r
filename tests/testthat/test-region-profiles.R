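toy <- energy_params_toy()
def <- energy_params()

test_that("Fisher 2x2 matches hand-derived hypergeometric values", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)), 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2, byrow = TRUE),
                                alternative = "greater"), 1 / 20)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(3, 0, 4, 0), 2)), "degenerate margin")
})

test_that("Fisher 2x2 equals enumeration and the reference implementation", {
  set.seed(61)
  for (k in 1:60) {
    N <- sample(4:30, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    c_ <- sample(0:(N - a - b), 1); d <- N - a - b - c_
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(fisher_exact_2x2(tab, alt), fisher_oracle(tab, alt),
                   info = paste(c(tab), collapse = ","))
    }
    # independent cross-check against the reference implementation
    expect_equal(fisher_exact_2x2(tab, "two.sided"),
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("window profiles tile the reference and stay null on dead windows", {
  set.seed(62)
  # U-free heads: a poly-A ncRNA offers no pairing partner anywhere
  heads <- setNames(vapply(1:10, function(i)
    paste(sample(c("A", "C", "G"), 21, replace = TRUE), collapse = ""),
    character(1)), paste0("h", 1:10))
  ncrna <- paste(rep("A", 30), collapse = "")
  prof <- ncrna_window_profile(ncrna, heads, toy, w = 10, n_shuffles = 10)
  expect_equal(nrow(prof), 30 - 10 + 1)
  expect_equal(prof$window_start, 1:21)
  expect_true(all(prof$p_value == 1))
  expect_false(any(prof$avoided))
  expect_error(ncrna_window_profile("ACGUA", heads, toy, w = 10), "exceeds")
})

test_that("a planted avoided window is recovered and flanks stay clean", {
  set.seed(63)
  fx <- synth_avoided_window(n_heads = 40, ncrna_len = 60, window_start = 26,
                             w = 10, params = def)
  prof <- ncrna_window_profile(fx$ncrna, fx$heads, def, w = 10,
                               n_shuffles = 50, alpha = 0.001, seed = 64)
  planted <- prof$window_start >= fx$window_start - 9 &
             prof$window_start <= fx$window_start + fx$w - 1
  expect_true(any(prof$avoided[planted]))
  # windows at least w positions away from the planted site carry no signal
  far <- prof$window_start + 10 - 1 < fx$window_start - fx$w |
         prof$window_start > fx$window_start + fx$w - 1 + fx$w
  expect_false(any(prof$avoided[far]))
})

test_that("profile flags are invariant to head order and ncRNA id", {
  set.seed(65)
  heads <- setNames(vapply(1:8, function(i) random_rna_str(21, 0.6),
                           character(1)), paste0("h", 1:8))
  ncrna <- random_rna_str(25, 0.6)
  p1 <- ncrna_window_profile(c(x = ncrna), heads, def, w = 10,
                             n_shuffles = 20, seed = 66)
  p2 <- ncrna_window_profile(c(renamed = ncrna), rev(heads), def, w = 10,
                             n_shuffles = 20, seed = 66)
  expect_equal(p1$avoided, p2$avoided)
  expect_equal(attr(p2, "reference_id"), "renamed")
})

test_that("residue reduction rules and accessibility association behave", {
  prof <- structure(
    data.frame(window_start = 1:11,
               p_value = c(rep(1, 5), 1e-5, rep(1, 5)),
               avoided = c(rep(FALSE, 5), TRUE, rep(FALSE, 5))),
    class = c("avoidance_profile", "data.frame"),
    reference_id = "r", ref_length = 20L, w = 10L, alpha = 0.001)
  av <- residue_avoidance(prof)
  expect_equal(which(av), 6:15)
  av2 <- residue_avoidance(prof, "majority")
  expect_true(all(which(av2) %in% 6:15))

  # perfect concordance on 10+10 residues: one-sided p = 1/C(20,10)
  contacts <- data.frame(position = 1:20, in_contact = !av)
  assoc <- accessibility_association(prof, contacts, alternative = "less")
  expect_equal(assoc$p, 1 / choose(20, 10))
  expect_equal(assoc$odds_ratio, Inf)
  assoc2 <- accessibility_association(prof, contacts)
  expect_equal(assoc2$p, 2 / choose(20, 10))

  # degenerate margin: everything accessible
  c0 <- data.frame(position = 1:20, in_contact = rep(FALSE, 20))
  expect_error(accessibility_association(prof, c0), "degenerate margin")
  expect_error(accessibility_association(prof, contacts[1:5, ]), "covers")
})

test_that("contact concordance calibrates the Fisher association", {
  prof <- structure(
    data.frame(window_start = 1:41,
               p_value = c(rep(1, 10), rep(1e-5, 10), rep(1, 21)),
               avoided = c(rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 21))),
    class = c("avoidance_profile", "data.frame"),
    reference_id = "r", ref_length = 50L, w = 10L, alpha = 0.001)
  set.seed(67)
  p_perfect <- accessibility_association(
    prof, synth_contacts(prof, concordance = 1))$p
  p_indep <- replicate(40, accessibility_association(
    prof, synth_contacts(prof, concordance = 0.5))$p)
  expect_lt(p_perfect, 1e-6)
  expect_gt(mean(p_indep > 0.05), 0.8)
})

test_that("mRNA window correlations localise a monotone expression signal", {
  set.seed(68)
  ncrnas <- setNames(vapply(1:3, function(i) random_rna_str(40, 0.6),
                            character(1)), paste0("n", 1:3))
  cds <- setNames(vapply(1:12, function(i) random_rna_str(45, 0.5),
                         character(1)), paste0("g", 1:12))
  # expression strictly increasing in the window-1 avoidance score
  e1 <- rowSums(interaction_energy_matrix(
    setNames(substr(cds, 1, 21), names(cds)), ncrnas, def, mode = "hybrid"))
  expr <- rank(e1)
  mc <- mrna_window_correlation(cds, expr, ncrnas, def, w = 21)
  expect_equal(nrow(mc), 45 - 21 + 1)
  expect_equal(mc$rho[1], 1)
  # constant expression: undefined correlation flagged NA (with warnings)
  mc0 <- suppressWarnings(
    mrna_window_correlation(cds, rep(1, 12), ncrnas, def, w = 21))
  expect_true(all(is.na(mc0$rho)))
  # unequal lengths: truncated with a warning
  cds2 <- cds; cds2[1] <- paste0(cds2[1], "ACG")
  expect_warning(mrna_window_correlation(cds2, expr, ncrnas, def, w = 21),
                 "truncated")
})
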