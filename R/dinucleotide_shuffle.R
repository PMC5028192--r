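#' Dinucleotide-preserving sequence shuffle
#'
#' Draws uniform random sequences with exactly the source's dinucleotide
#' multiset (hence identical mononucleotide counts, G+C and endpoints). The
#' sequence is treated as an Eulerian path on the dinucleotide multigraph; a
#' uniform Euler path with fixed endpoints is sampled by random-arborescence
#' rejection plus uniform out-edge orderings, so no MCMC burn-in or swap
#' tuning is involved. This is the negative-control generator for the
#' extrinsic avoidance test: stacking (dinucleotide) statistics are what the
#' nearest-neighbour energies are computed over, so the null must preserve
#' them exactly.
#'
#' @param s RNA string of length >= 3.
#' @param n number of shuffles to draw.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param source_id optional identifier of the source sequence, stored as an
#'   attribute.
#' @return object of class `shuffle_batch`: character vector of `n` shuffled
#'   sequences with attributes `source_id` and `seed`.
#' @export
dinuc_shuffle <- function(s, n, seed = NULL, source_id = NULL) {
  stopifnot(length(s) == 1L, n >= 1L)
  if (nchar(s) < 3L) stop("dinucleotide shuffle needs length >= 3")
  if (!is.null(seed)) set.seed(seed)
  out <- c_dinuc_shuffle(.enc(s), as.integer(n))
  structure(out, source_id = source_id, seed = seed, class = "shuffle_batch")
}

#' @export
print.shuffle_batch <- function(x, ...) {
  cat(sprintf("<shuffle_batch> %d dinucleotide-preserving shuffles of %s (%d nt)\n",
              length(x), attr(x, "source_id") %||% "a sequence",
              nchar(x[[1]])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dinucleotide counts of a sequence
#'
#' @param s RNA string.
#' @return named integer vector of the 16 dinucleotide counts.
#' @export
dinuc_counts <- function(s) {
  abc <- c("A", "C", "G", "U")
  keys <- as.vector(outer(abc, abc, paste0))
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  di <- paste0(v[-length(v)], v[-1])
  counts <- setNames(integer(16), keys)
  t <- table(di)
  counts[names(t)] <- as.integer(t)
  counts
}
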