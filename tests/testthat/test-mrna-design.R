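toy <- energy_params_toy()
def <- energy_params()

test_that("synonymous sampling respects the genetic code", {
  expect_equal(sample_synonymous("MW", 20), "AUGUGG")
  set.seed(81)
  v <- sample_synonymous("KK", 400)
  expect_setequal(v, c("AAAAAA", "AAAAAG", "AAGAAA", "AAGAAG"))
  prot <- "MLKTRGWSDE"
  s <- sample_synonymous(prot, 50, seed = 82)
  expect_true(all(vapply(s, translate_rna, character(1)) == prot))
  expect_error(sample_synonymous("MB", 5), "unknown residue")
  # usage-weighted sampling shifts codon frequencies towards the heavy codon
  w <- c(AAA = 100, AAG = 1)
  vw <- sample_synonymous("KKKKKKKKKK", 200, seed = 83, weights = w)
  cod <- unlist(lapply(vw, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
  expect_gt(mean(cod == "AAA"), 0.7)
})

test_that("enumeration covers the full synonymous space", {
  e <- enumerate_synonymous("MKC")
  expect_length(e, 1 * 2 * 2)
  expect_true(all(vapply(e, translate_rna, character(1)) == "MKC"))
  expect_equal(length(unique(e)), length(e))
})

test_that("candidate scores decompose into hand-computable terms", {
  set.seed(84)
  # 8-codon toy protein, scores against two short ncRNAs
  cds <- sample_synonymous("MKLVAGFD", 5)
  ncr <- c(n1 = "GGCAUGCAUGGC", n2 = "AAACCCUUUGGG")
  usage <- codon_usage(cds)
  expect_warning(sc <- score_candidates(cds, ncr, usage, def), "fold window")
  for (i in seq_along(cds)) {
    h <- substr(cds[i], 1, 21)
    expect_equal(sc$avoidance_sum[i],
                 duplex_mfe(h, ncr[1], def)$energy +
                 duplex_mfe(h, ncr[2], def)$energy)
    expect_equal(sc$gc5p[i], gc_content(h))
  }
  # an all-A ncRNA contributes nothing
  sc0 <- suppressWarnings(score_candidates(cds[1], c(a = strrep("A", 30)),
                                           usage, def))
  expect_equal(sc0$avoidance_sum, 0)
  # adding the head's reverse complement strictly lowers the sum
  h <- substr(cds[1], 1, 21)
  rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(h, "")[[1]]), collapse = ""))
  sc1 <- suppressWarnings(score_candidates(cds[1], c(ncr, rc = rc), usage, def))
  expect_lt(sc1$avoidance_sum, sc$avoidance_sum[1])
})

test_that("greedy selection matches brute force on an exhaustive toy pool", {
  set.seed(85)
  prot <- "MTKLAVFDEW" # 6144 synonymous variants, exhaustively scored
  pool <- enumerate_synonymous(prot)
  ncr <- c(n1 = "GGCAUGCAUGGCUUACG", n2 = "CCGAUUUGGGCACGCU")
  usage <- codon_usage(pool)
  scored <- suppressWarnings(score_candidates(pool, ncr, usage, def))
  spec <- design_spec(n_per_category = 1L, n_optimal = 1L,
                      gc_band = c(0.30, 0.70), gc5p_target = 0.48,
                      min_pairwise_hamming = 0L, head_len = 21L)
  sel <- select_extremes(scored, spec)
  expect_equal(nrow(sel), 7)
  # brute-force argmax/argmin inside the constraint set
  ok <- scored$gc >= 0.30 & scored$gc <= 0.70 &
        round(scored$gc5p * 21) == round(0.48 * 21)
  sub <- scored[ok, ]
  expect_equal(sel$avoidance_sum[sel$category == "MAX_AVOID"],
               max(sub$avoidance_sum))
  expect_equal(sel$avoidance_sum[sel$category == "MIN_AVOID"],
               min(sub$avoidance_sum))
  expect_equal(sel$fold5p[sel$category == "MIN_FOLD"], min(sub$fold5p))
  expect_equal(sel$cai[sel$category == "MAX_CAI"], max(sub$cai))
  # optimal construct dominates the per-metric medians
  opt <- sel[sel$category == "OPTIMAL", ]
  expect_gte(opt$cai, median(sub$cai))
  expect_gte(opt$fold5p, median(sub$fold5p))
  expect_gte(opt$avoidance_sum, median(sub$avoidance_sum))
})

test_that("diversity constraint and category counts give 13 distant constructs", {
  set.seed(86)
  # synthetic GFP-scale protein (239 aa) so Hamming-100 is meaningful
  aa <- setdiff(names(codon_table()$degeneracy), c("*", "M", "W"))
  prot <- paste(c("M", sample(aa, 238, replace = TRUE)), collapse = "")
  pool <- sample_synonymous(prot, 4000)
  ncr <- setNames(vapply(1:4, function(i) random_rna_str(60, 0.55),
                         character(1)), paste0("n", 1:4))
  usage <- codon_usage(pool)
  scored <- score_candidates(pool, ncr, usage, def)
  spec <- design_spec() # full defaults: G+C band, gc5p 0.48, hamming 100
  sel <- select_extremes(scored, spec)
  expect_equal(nrow(sel), 13)
  expect_equal(sum(sel$category == "OPTIMAL"), 1)
  expect_equal(as.integer(table(sel$category)[c("MIN_FOLD", "MAX_AVOID")]),
               c(2L, 2L))
  expect_true(all(vapply(sel$cds, translate_rna, character(1)) == prot))
  expect_true(all(sel$gc >= 0.468 & sel$gc <= 0.480))
  expect_equal(round(sel$gc5p * 21), rep(10, 13))
  h <- vapply(seq_len(nrow(sel)), function(i)
    min(vapply(seq_len(nrow(sel))[-i], function(j)
      rnavoid:::hamming(sel$cds[i], sel$cds[j]), numeric(1))), numeric(1))
  expect_true(all(h >= 100))
})

test_that("selection is deterministic and fails loudly when infeasible", {
  set.seed(87)
  pool <- enumerate_synonymous("MTKLAV")
  ncr <- c(n1 = "GGCAUGCAUGGCUU")
  scored <- suppressWarnings(score_candidates(pool, ncr, codon_usage(pool), def,
                                              head_len = 18L))
  spec <- design_spec(n_per_category = 1, n_optimal = 1,
                      gc_band = c(0, 1), gc5p_target = 0.5,
                      min_pairwise_hamming = 0, head_len = 18L)
  s1 <- select_extremes(scored, spec)
  s2 <- select_extremes(scored, spec)
  expect_identical(s1, s2)
  # near-degenerate protein: a two-sequence pool cannot fill the categories
  tiny <- enumerate_synonymous("MKMWMW")
  one <- suppressWarnings(score_candidates(tiny, ncr, codon_usage(tiny), def,
                                           head_len = 18L))
  expect_error(select_extremes(one, design_spec(head_len = 18L)),
               "G\\+C|insufficient")
})
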