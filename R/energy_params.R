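#' Nearest-neighbour energy parameters
#'
#' The engine is a deliberately simplified Turner-style model: Watson-Crick
#' and GU wobble pairs, helix stacking free energies, hairpin/bulge/interior
#' loop penalties indexed by total unpaired length, a linear multibranch
#' penalty, a duplex initiation cost and an AU/GU duplex-end penalty, all at
#' 37 degrees C in kcal/mol. There are no dangling ends, coaxial stacks,
#' special hairpins or loop-asymmetry terms: the analyses need a consistent,
#' comparable energy scale across thousands of sequence pairs, not parity
#' with a particular folding suite.
#'
#' Parameters are stored as a TSV with columns `kind`, `key`,
#' `kcal_per_mol`. Kinds:
#' \describe{
#'   \item{STACK}{key `XY/WZ`: helix stack with top strand 5'-XY-3' over
#'     bottom strand 3'-WZ-5' (pairs X:W and Y:Z). `Inf` forbids a stack.}
#'   \item{HAIRPIN, BULGE, INTERNAL}{key = loop size (total unpaired
#'     nucleotides); sizes not listed are `Inf` unless `META extrapolate` is
#'     1, in which case sizes beyond the largest listed are extended with the
#'     Jacobson-Stockmayer term `E(max) + 1.75 RT log(n/max)`.}
#'   \item{INIT}{duplex initiation cost.}
#'   \item{AU_END}{penalty per AU or GU pair closing a duplex end.}
#'   \item{MULTI}{keys `a`, `b`, `c`: multibranch offset, per-branch and
#'     per-unpaired-nucleotide terms of the linear multiloop penalty.}
#'   \item{META}{keys `max_loop`, `duplex_max_loop`, `min_hairpin`,
#'     `extrapolate`: interior-loop caps (fold / duplex), the minimum hairpin
#'     loop and the extrapolation switch.}
#' }
#'
#' @param path TSV file; the default loads the parameter set shipped with the
#'   package.
#' @return object of class `energy_params`.
#' @export
load_energy_params <- function(path) {
  d <- read.delim(path, comment.char = "#", colClasses = "character")
  stopifnot(all(c("kind", "key", "kcal_per_mol") %in% names(d)))
  val <- suppressWarnings(as.numeric(d$kcal_per_mol))
  if (anyNA(val)) stop("non-numeric kcal_per_mol entries in ", path)

  meta <- c(max_loop = 30, duplex_max_loop = 6, min_hairpin = 3, extrapolate = 1)
  mrows <- d$kind == "META"
  meta[d$key[mrows]] <- val[mrows]

  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- matrix(Inf, 6, 6, dimnames = list(pairs, pairs))
  srows <- which(d$kind == "STACK")
  for (i in srows) {
    key <- d$key[i]
    top <- strsplit(key, "/", fixed = TRUE)[[1]]
    if (length(top) != 2L || nchar(top[1]) != 2L || nchar(top[2]) != 2L) {
      stop("bad STACK key: ", key)
    }
    p1 <- paste0(substr(top[1], 1, 1), substr(top[2], 1, 1))
    p2 <- paste0(substr(top[1], 2, 2), substr(top[2], 2, 2))
    if (!(p1 %in% pairs) || !(p2 %in% pairs)) stop("STACK key is not WC/GU: ", key)
    stack[p1, p2] <- val[i]
  }

  max_len <- 500L
  rt <- 0.6163 # kcal/mol at 37C
  loop_tab <- function(kind, min_size) {
    v <- rep(Inf, max_len)
    rows <- which(d$kind == kind)
    sz <- as.integer(d$key[rows])
    v[sz] <- val[rows]
    if (meta["extrapolate"] > 0 && length(sz) > 0) {
      mx <- max(sz[is.finite(val[rows])])
      beyond <- seq_len(max_len) > mx
      v[beyond] <- v[mx] + 1.75 * rt * log(seq_len(max_len)[beyond] / mx)
    }
    if (min_size > 1) v[seq_len(min_size - 1)] <- Inf
    v
  }

  obj <- structure(list(
    stack = stack,
    hairpin = loop_tab("HAIRPIN", meta["min_hairpin"]),
    bulge = loop_tab("BULGE", 1L),
    internal = loop_tab("INTERNAL", 2L),
    init = val[match("INIT", d$kind)],
    au_end = val[match("AU_END", d$kind)],
    multi = c(a = val[which(d$kind == "MULTI" & d$key == "a")[1]],
              b = val[which(d$kind == "MULTI" & d$key == "b")[1]],
              c = val[which(d$kind == "MULTI" & d$key == "c")[1]]),
    max_loop = as.integer(meta["max_loop"]),
    duplex_max_loop = as.integer(meta["duplex_max_loop"]),
    min_hairpin = as.integer(meta["min_hairpin"])
  ), class = "energy_params")
  if (is.na(obj$init)) obj$init <- 0
  if (is.na(obj$au_end)) obj$au_end <- 0
  obj$multi[is.na(obj$multi)] <- Inf
  validate_energy_params(obj)
  obj
}

#' @describeIn load_energy_params the default parameter set shipped with the
#'   package (Turner-like rounded values).
#' @export
energy_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_energy_params(
        system.file("extdata", "energy_params_default.tsv", package = "rnavoid"))
    }
    cache
  }
})

#' @describeIn load_energy_params the minimal "toy" parameter set used in
#'   tests and worked examples (WC stacks -3, hairpin(3) +5, duplex init +4,
#'   everything else forbidden).
#' @export
energy_params_toy <- function() {
  load_energy_params(
    system.file("extdata", "energy_params_toy.tsv", package = "rnavoid"))
}

validate_energy_params <- function(p) {
  wc <- c("AU", "UA", "CG", "GC")
  st <- p$stack[wc, wc]
  if (any(is.finite(st) & st > 0)) stop("WC/WC stack energies must be <= 0")
  for (nm in c("hairpin", "bulge", "internal")) {
    v <- p[[nm]]
    if (any(is.finite(v) & v < 0)) stop(nm, " penalties must be >= 0")
  }
  if (is.finite(p$au_end) && p$au_end < 0) stop("au_end must be >= 0")
  invisible(p)
}

#' @export
print.energy_params <- function(x, ...) {
  cat("<energy_params> simplified nearest-neighbour model (37C, kcal/mol)\n")
  cat(sprintf("  finite stacks: %d/36, init %.2f, au_end %.2f, multi (%.1f, %.1f, %.1f)\n",
              sum(is.finite(x$stack)), x$init, x$au_end,
              x$multi[1], x$multi[2], x$multi[3]))
  cat(sprintf("  loop caps: fold %d, duplex %d; min hairpin %d\n",
              x$max_loop, x$duplex_max_loop, x$min_hairpin))
  invisible(x)
}

# list passed to the C++ core
.par_cpp <- function(p) {
  list(stack = unname(p$stack), hairpin = p$hairpin, bulge = p$bulge,
       internal = p$internal, init = p$init, au_end = p$au_end,
       multi = unname(p$multi), max_loop = p$max_loop,
       duplex_max_loop = p$duplex_max_loop, min_hairpin = p$min_hairpin)
}
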