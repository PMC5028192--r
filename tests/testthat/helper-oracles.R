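# Brute-force oracles, independent of the package's dynamic programming.
# Structures are enumerated exhaustively and scored by explicit loop
# decomposition; duplexes are enumerated as pair chains. Only feasible for
# short sequences, which is the point.

.obases <- c("A", "C", "G", "U")

opair <- function(x, y) {
  p <- paste0(x, y)
  if (p %in% c("AU", "UA", "CG", "GC", "GU", "UG")) p else NA_character_
}

# all nested structures (lists of 2-col pair matrices) for a sequence
enumerate_structures <- function(seq, min_hairpin = 3L) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (j - i + 1 < min_hairpin + 2) return(list(NULL))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- gen(i + 1, j) # i unpaired
    for (k in (i + min_hairpin + 1):j) {
      if (is.na(opair(v[i], v[k]))) next
      left <- gen(i + 1, k - 1)
      right <- if (k + 1 <= j) gen(k + 1, j) else list(NULL)
      for (L in left) for (R in right) {
        out[[length(out) + 1]] <- rbind(c(i, k), L, R)
      }
    }
    memo[[key]] <- out
    out
  }
  gen(1, n)
}

# score one nested structure by loop decomposition under `par`
score_structure <- function(seq, pairs, par) {
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  np <- nrow(pairs)
  # parent = tightest enclosing pair
  parent <- rep(0L, np)
  for (k in seq_len(np)) {
    best <- 0L
    for (m in seq_len(np)) {
      if (m == k) next
      if (pairs[m, 1] < pairs[k, 1] && pairs[m, 2] > pairs[k, 2]) {
        if (best == 0L || pairs[m, 1] > pairs[best, 1]) best <- m
      }
    }
    parent[k] <- best
  }
  loop_pen <- function(tab, size) {
    if (size < 1 || size > length(tab)) return(Inf)
    tab[size]
  }
  E <- 0
  for (k in seq_len(np)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    p <- opair(v[i], v[j])
    if (is.na(p)) return(Inf)
    ch <- which(parent == k)
    if (length(ch) == 0) {
      E <- E + loop_pen(par$hairpin, j - i - 1)
    } else if (length(ch) == 1) {
      ki <- pairs[ch, 1]; kj <- pairs[ch, 2]
      d1 <- ki - i - 1; d2 <- j - kj - 1
      q <- opair(v[ki], v[kj])
      if (d1 + d2 > par$max_loop) return(Inf)
      E <- E + if (d1 == 0 && d2 == 0) {
        par$stack[p, q]
      } else if (d1 == 0 || d2 == 0) {
        loop_pen(par$bulge, d1 + d2)
      } else {
        loop_pen(par$internal, d1 + d2)
      }
    } else {
      if (!is.finite(par$multi[1])) return(Inf)
      unp <- (j - i - 1) - sum(pairs[ch, 2] - pairs[ch, 1] + 1)
      E <- E + par$multi[1] + par$multi[2] * (1 + length(ch)) +
        par$multi[3] * unp
    }
  }
  E
}

fold_oracle <- function(seq, par, forced_open = integer(0)) {
  structs <- enumerate_structures(seq, par$min_hairpin)
  best <- 0
  for (s in structs) {
    if (length(forced_open) && !is.null(s) &&
        any(s %in% forced_open)) next
    e <- score_structure(seq, s, par)
    if (e < best) best <- e
  }
  best
}

# all duplex pair chains between a and b (intermolecular only)
duplex_oracle <- function(a, b, par) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(va); nb <- length(vb)
  cap <- par$duplex_max_loop
  auend <- function(p) if (p %in% c("CG", "GC")) 0 else par$au_end
  loop_pen <- function(tab, size) if (size > length(tab)) Inf else tab[size]
  best <- 0
  rec <- function(i, j, e, plast) {
    tot <- e + auend(plast)
    if (tot < best) best <<- tot
    if (i >= na || j <= 1) return()
    for (k in (i + 1):min(na, i + 1 + cap)) {
      d1 <- k - i - 1
      for (l in (j - 1):max(1, j - 1 - (cap - d1))) {
        p <- opair(va[k], vb[l])
        if (is.na(p)) next
        d2 <- j - l - 1
        de <- if (d1 == 0 && d2 == 0) {
          par$stack[plast, p]
        } else if (d1 == 0 || d2 == 0) {
          loop_pen(par$bulge, d1 + d2)
        } else {
          loop_pen(par$internal, d1 + d2)
        }
        if (!is.finite(de)) next
        rec(k, l, e + de, p)
      }
    }
  }
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    p <- opair(va[i], vb[j])
    if (is.na(p)) next
    rec(i, j, par$init + auend(p), p)
  }
  best
}

# joint opening + hybridisation minimum by enumerating site pairs
access_oracle <- function(a, b, par, max_site = 25L) {
  na <- nchar(a); nb <- nchar(b)
  open_all <- function(s, n) {
    base <- fold_oracle(s, par)
    out <- list()
    for (i in seq_len(n)) for (ii in i:min(n, i + max_site - 1)) {
      out[[paste(i, ii)]] <- fold_oracle(s, par, i:ii) - base
    }
    out
  }
  oa <- open_all(a, na)
  ob <- open_all(b, nb)
  best <- 0
  for (i in seq_len(na)) for (ii in i:min(na, i + max_site - 1)) {
    for (j in seq_len(nb)) for (jj in j:min(nb, j + max_site - 1)) {
      d <- duplex_oracle(substr(a, i, ii), substr(b, j, jj), par)
      tot <- oa[[paste(i, ii)]] + ob[[paste(j, jj)]] + d
      if (tot < best) best <- tot
    }
  }
  best
}

# exact Mann-Whitney p by enumerating all label assignments
mwu_oracle <- function(x, y, alternative = "greater") {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  U <- u_of(seq_len(nx))
  sets <- combn(nx + ny, nx)
  us <- apply(sets, 2, u_of)
  eps <- 1e-9
  if (alternative == "greater") {
    mean(us >= U - eps)
  } else {
    min(1, 2 * min(mean(us >= U - eps), mean(us <= U + eps)))
  }
}

# exact Fisher p by direct enumeration over the hypergeometric support
fisher_oracle <- function(tab, alternative = "two.sided") {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- choose(r1, support) * choose(N - r1, c1 - support) / choose(N, c1)
  pa <- pr[support == a]
  switch(alternative,
    greater = sum(pr[support >= a]),
    less = sum(pr[support <= a]),
    two.sided = min(1, sum(pr[pr <= pa * (1 + 1e-7)])))
}

random_rna_str <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.obases, len, replace = TRUE, prob = p), collapse = "")
}
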