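test_that("CAI follows the geometric-mean definition", {
  # usage: leucine UUA:3, UUG:1, everything else zero-smoothed
  usage <- c(UUA = 3, UUG = 1)
  expect_equal(compute_cai("UUG", usage), 1 / 3)
  expect_equal(compute_cai("UUA", usage), 1)
  # a CDS built only from most-frequent codons scores 1
  set.seed(71)
  cds <- sample_synonymous("MLKTRGW", 50)
  usage2 <- codon_usage(cds)
  ct <- codon_table()
  best <- vapply(strsplit("MLKTRGW", "")[[1]], function(a) {
    syn <- ct$synonyms[[a]]
    syn[which.max(usage2[syn])]
  }, character(1))
  expect_equal(compute_cai(paste(best, collapse = ""), usage2), 1)
  expect_error(compute_cai("AUGG", usage2), "divisible by 3")
})

test_that("CAI concatenation identity and usage-rescaling invariance hold", {
  set.seed(72)
  cds <- sample_synonymous("MLKTRGWSDE", 30)
  usage <- codon_usage(cds)
  c1 <- cds[1]; c2 <- cds[2]
  ct <- codon_table()
  n_inf <- function(s) {
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    sum(ct$degeneracy[ct$code[cod]] > 1 & ct$code[cod] != "*")
  }
  lhs <- log(compute_cai(paste0(c1, c2), usage))
  rhs <- (n_inf(c1) * log(compute_cai(c1, usage)) +
          n_inf(c2) * log(compute_cai(c2, usage))) / (n_inf(c1) + n_inf(c2))
  expect_equal(lhs, rhs)
  expect_equal(compute_cai(c1, usage * 17), compute_cai(c1, usage))
})

test_that("Spearman handles monotone, reversed and tied inputs", {
  expect_equal(spearman(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman(1:3, c(30, 20, 10))$rho, -1)
  expect_warning(s <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(s$rho))
  # rank invariance: spearman(x, y) == spearman(rank(x), rank(y))
  set.seed(73)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman(x, y)$rho, spearman(rank(x), rank(y))$rho)
  expect_equal(spearman(x, y)$p, spearman(rank(x), rank(y))$p)
})

test_that("exact Spearman p equals permutation enumeration with ties", {
  set.seed(74)
  perm_oracle <- function(x, y, alt) {
    rx <- rank(x); ry <- rank(y)
    obs <- cor(rx, ry)
    perms <- rnavoid:::.permutations(length(x))
    rhos <- apply(perms, 1, function(ix) cor(rx, ry[ix]))
    eps <- 1e-12
    if (alt == "two.sided") mean(abs(rhos) >= abs(obs) - eps)
    else mean(rhos >= obs - eps)
  }
  for (k in 1:10) {
    x <- sample(1:4, 5, replace = TRUE)
    y <- rnorm(5)
    if (length(unique(x)) == 1) next
    s <- spearman(x, y)
    expect_equal(s$method, "exact")
    expect_equal(s$p, perm_oracle(x, y, "two.sided"))
  }
  # no-ties case agrees with the reference implementation's exact p
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman(x, y)$p,
               cor.test(x, y, method = "spearman")$p.value,
               tolerance = 1e-9)
})

test_that("variance partitioning recovers exact and null structure", {
  set.seed(75)
  n <- 200
  d <- data.frame(cai = runif(n, 0.2, 1), fold5p = -rexp(n, 0.2),
                  avoidance = -rexp(n, 0.1))
  # y exactly linear in avoidance only
  d$protein_abundance <- exp(2 + 0.5 * d$avoidance)
  vp <- variance_partition(d, features = c("cai", "fold5p", "avoidance"))
  expect_equal(unname(vp$r2_single["avoidance"]), 1)
  expect_equal(vp$r2_full, 1)
  expect_equal(vp$drop, 1 - vp$r2_minus_avoidance)
  expect_gte(vp$drop, 0)
  # pure noise: everything near zero
  d$protein_abundance <- exp(rnorm(n))
  vp0 <- variance_partition(d, features = c("cai", "fold5p", "avoidance"))
  expect_lt(vp0$r2_full, 0.06)
  expect_true(all(vp0$r2_single < 0.05))
  # full model dominates any subset
  d$protein_abundance <- exp(0.3 * d$cai + 0.2 * d$avoidance + rnorm(n, 0, 0.5))
  vp1 <- variance_partition(d, features = c("cai", "fold5p", "avoidance"))
  expect_gte(vp1$r2_full, max(vp1$r2_single) - 1e-12)
})

test_that("outlier z-scores are centred for flat metrics and shifted by design", {
  set.seed(76)
  n <- 60
  d <- data.frame(protein_abundance = exp(rnorm(n)),
                  mrna_abundance = exp(rnorm(n)),
                  cai = rep(0.5, n), # identical for all genes
                  fold5p = rnorm(n),
                  avoidance = rnorm(n))
  oz <- outlier_zscores(d, top_n = 10)
  expect_equal(oz$mean_z[oz$metric == "cai"], c(0, 0))
  # construct the top group one sd above the mean on avoidance
  ratio <- d$protein_abundance / d$mrna_abundance
  top <- order(ratio, decreasing = TRUE)[1:10]
  d$avoidance <- rnorm(n, 0, 0.01)
  d$avoidance[top] <- 1
  oz2 <- outlier_zscores(d, top_n = 10)
  z_top <- oz2$mean_z[oz2$metric == "avoidance" & oz2$group == "top"]
  expect_gt(z_top, 1.5) # far above background
  expect_lt(oz2$p[oz2$metric == "avoidance" & oz2$group == "top"], 0.01)
  d$mrna_abundance[1] <- 0
  expect_warning(outlier_zscores(d, top_n = 10), "zero mRNA")
})

test_that("group tests detect a shifted construct class and relate to MWU", {
  set.seed(77)
  vals <- c(rnorm(4, 0, 0.5), rnorm(4, 7, 0.5), rnorm(4, 15, 0.5))
  grp <- rep(c("low1", "mid", "high"), each = 4)
  gt <- group_tests(vals, grp)
  expect_lt(gt$p, 0.01)
  expect_equal(nrow(gt$pairwise), 3)
  top <- gt$pairwise[gt$pairwise$group2 %in% c("low1", "mid") &
                     gt$pairwise$group1 == "high", ]
  expect_true(all(top$p_holm < 0.1))
  expect_error(group_tests(vals, rep("one", 12)), "two groups")

  # two groups: H equals the squared MWU normal deviate (asymptotically)
  x <- rnorm(30); y <- rnorm(30, 0.8)
  kw <- kruskal.test(c(x, y), rep(1:2, each = 30))
  U <- mann_whitney_u(x, y, "two.sided")$U
  mu <- 30 * 30 / 2; v <- 30 * 30 * 61 / 12
  expect_equal(unname(kw$statistic), (U - mu)^2 / v, tolerance = 1e-6)
})
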