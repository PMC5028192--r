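toy <- energy_params_toy()
def <- energy_params()

test_that("toy folding matches hand-derived energies", {
  expect_equal(fold_mfe("AAAAAA", toy), list(energy = 0, structure = "......"))
  # two WC stacks at -3 plus a +5 hairpin
  r <- fold_mfe("GGGAAACCC", toy)
  expect_equal(r$energy, -1)
  expect_equal(r$structure, "(((...)))")
})

test_that("toy duplex matches hand-derived energy and sites", {
  r <- duplex_mfe("GGGG", "CCCC", toy)
  expect_equal(r$energy, -5) # 3 stacks at -3 + init 4
  expect_equal(r$site_a, c(1L, 4L))
  expect_equal(r$site_b, c(1L, 4L))
  expect_equal(r$pairing, "((((&))))")
  r0 <- duplex_mfe("AAAA", "AAAA", toy)
  expect_equal(r0$energy, 0)
  expect_true(is.na(r0$site_a[1]))
})

test_that("folding DP equals exhaustive enumeration on short sequences", {
  set.seed(101)
  for (k in 1:60) {
    s <- random_rna_str(sample(5:12, 1), runif(1, 0.3, 0.7))
    expect_equal(fold_mfe(s, def)$energy, fold_oracle(s, def), info = s)
    expect_equal(fold_mfe(s, toy)$energy, fold_oracle(s, toy), info = s)
  }
})

test_that("duplex DP equals exhaustive enumeration on short pairs", {
  set.seed(102)
  for (k in 1:60) {
    a <- random_rna_str(sample(4:8, 1), runif(1, 0.3, 0.8))
    b <- random_rna_str(sample(4:8, 1), runif(1, 0.3, 0.8))
    expect_equal(duplex_mfe(a, b, def)$energy, duplex_oracle(a, b, def),
                 info = paste(a, b))
  }
})

test_that("reported fold structure is consistent with its energy", {
  set.seed(103)
  for (k in 1:25) {
    s <- random_rna_str(sample(8:14, 1), 0.7)
    r <- fold_mfe(s, def)
    db <- strsplit(r$structure, "")[[1]]
    op <- which(db == "("); cl <- which(db == ")")
    expect_equal(length(op), length(cl))
    if (length(op)) {
      # rebuild the pair list from the dot-bracket and rescore it
      stack <- integer(0); pairs <- NULL
      for (i in seq_along(db)) {
        if (db[i] == "(") stack <- c(stack, i)
        if (db[i] == ")") {
          pairs <- rbind(pairs, c(stack[length(stack)], i))
          stack <- stack[-length(stack)]
        }
      }
      expect_equal(score_structure(s, pairs, def), r$energy)
    } else {
      expect_equal(r$energy, 0)
    }
  }
})

test_that("opening energy is the constrained-unconstrained fold difference", {
  expect_equal(opening_energy("AAAAAA", c(2, 4), toy), 0)
  # forcing the hairpin's closing side open costs its full stability
  expect_equal(opening_energy("GGGAAACCC", c(1, 3), toy), 1)
  s <- "GGGAAACCCAAAGGGAAACCC"
  e <- fold_mfe(s, def)$energy
  expect_equal(opening_energy(s, c(1, nchar(s)), def), -e)
  expect_error(opening_energy(s, c(0, 3), def), "invalid site")
  # constrained enumeration agreement
  set.seed(104)
  for (k in 1:15) {
    x <- random_rna_str(10, 0.7)
    expect_equal(opening_energy(x, c(3, 6), def),
                 max(0, fold_oracle(x, def, 3:6) - fold_oracle(x, def)))
  }
})

test_that("access mode equals joint brute-force minimisation and dominates hybrid", {
  set.seed(105)
  for (k in 1:10) {
    a <- random_rna_str(sample(6:8, 1), 0.7)
    b <- random_rna_str(sample(6:8, 1), 0.7)
    acc <- interaction_energy(a, b, def, mode = "access", max_site = 8)
    expect_equal(acc$energy, access_oracle(a, b, def, 8), info = paste(a, b))
    expect_gte(acc$energy, duplex_mfe(a, b, def)$energy - 1e-9)
  }
  # unstructured molecules: opening terms vanish, ACCESS == HYBRID
  a <- "AAAAAGGGGGAAAAA" # no intramolecular pairs possible under toy params
  b <- "AAACCCCCAAA"
  expect_equal(interaction_energy(a, b, toy, mode = "access")$energy,
               duplex_mfe(a, b, toy)$energy)
})

test_that("duplex energy is minimal against the reverse complement", {
  revcomp <- function(s) chartr("ACGU", "UGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  set.seed(106)
  for (k in 1:10) {
    a <- random_rna_str(10, 0.5)
    e_rc <- duplex_mfe(a, revcomp(a), def)$energy
    for (m in 1:10) {
      b <- random_rna_str(10, 0.5)
      expect_lte(e_rc, duplex_mfe(a, b, def)$energy + 1e-9)
    }
  }
})

test_that("A-padding never stabilises a duplex when AU stacks are forbidden", {
  # forbid every stack touching an A:U pair, then pad both molecules with A's
  noau <- toy
  noau$stack[c("AU", "UA"), ] <- Inf
  noau$stack[, c("AU", "UA")] <- Inf
  pad <- function(s) paste0("AAA", s, "AAA")
  set.seed(107)
  for (k in 1:20) {
    a <- random_rna_str(8, 0.8); b <- random_rna_str(8, 0.8)
    expect_gte(duplex_mfe(pad(a), pad(b), noau)$energy,
               duplex_mfe(a, b, noau)$energy - 1e-9)
  }
})

test_that("stabilising one molecule never lowers the ACCESS energy", {
  # appending a self-complementary hairpin arm to b adds intramolecular
  # structure overlapping its binding site
  a <- "GGGGGGGG"
  b_open <- "AAACCCCCCAAA"
  b_closed <- "AAACCCCCCAAAGGGGGG" # the C-run can now pair internally
  e_open <- interaction_energy(a, b_open, def, mode = "access", max_site = 12)$energy
  e_closed <- interaction_energy(a, b_closed, def, mode = "access", max_site = 12)$energy
  expect_gte(e_closed, e_open - 1e-9)
})

test_that("parameter TSVs load with caps, symmetry and validation", {
  expect_s3_class(def, "energy_params")
  expect_equal(def$min_hairpin, 3L)
  expect_equal(def$duplex_max_loop, 6L)
  # thermodynamic symmetry of the shipped WC table: E(p,q) = E(rev q, rev p)
  revp <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  pr <- c("AU", "UA", "CG", "GC")
  for (p in pr) for (q in pr) {
    expect_equal(def$stack[p, q], def$stack[revp(q), revp(p)])
  }
  expect_true(all(def$stack[pr, pr] <= 0))
  expect_true(all(def$hairpin[3:400] > 0))
  # hairpin table grows with loop size in the extrapolated tail
  expect_true(all(diff(def$hairpin[9:400]) > 0))
  expect_true(all(!is.finite(toy$stack[, "GU"])))
})
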