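#' Read RNA sequences from a FASTA file
#'
#' Sequences are normalised to the RNA alphabet (case folded, `T` replaced by
#' `U`). Records that still contain characters outside `{A,C,G,U}` after
#' normalisation (ambiguity codes such as `N`) are skipped with a warning:
#' nearest-neighbour energies are undefined on ambiguous bases, so such
#' records are dropped rather than repaired.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param role role label attached to the returned set: one of `"MRNA_HEAD"`,
#'   `"NCRNA"`, `"CDS"`, `"OTHER"`.
#' @return named character vector of RNA sequences with attribute `role`.
#'   Names are the first whitespace-delimited token of each description line.
#' @export
read_fasta <- function(path, role = c("OTHER", "MRNA_HEAD", "NCRNA", "CDS")) {
  role <- match.arg(role)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_rna(as.character(set))
  ok <- !grepl("[^ACGU]", seqs)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with ambiguity codes skipped: ",
            paste(ids[!ok], collapse = ", "))
  }
  if (any(nchar(seqs[ok]) == 0L)) stop("empty sequence record in ", path)
  structure(setNames(seqs[ok], ids[ok]), role = role)
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  set <- Biostrings::BStringSet(unclass(x))
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Upper-cases and replaces T with U; DNA input is accepted silently because
#' coding sequences are usually distributed as DNA.
#'
#' @param x character vector.
#' @return character vector over the RNA alphabet (plus any residual
#'   ambiguity codes, which downstream functions reject).
#' @export
normalize_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

# encode an RNA string as 0-based integers (A=0, C=1, G=2, U=3)
.enc <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,U}")
  v
}

.enc_list <- function(x) lapply(unname(x), .enc)

#' Extract a region of a coding sequence
#'
#' Coordinates are 1-based and inclusive throughout the package. The default
#' region `(1, 21)` is the mRNA "head", the designated interaction region at
#' the 5' end of the CDS. A 5'UTR-extended convention is expressed by the
#' caller through coordinates on a UTR-extended sequence.
#'
#' @param cds a single RNA string.
#' @param start,end 1-based inclusive bounds; `end` beyond the sequence is an
#'   error (it signals a truncated CDS).
#' @return the subsequence as a character scalar.
#' @export
cds_region <- function(cds, start = 1L, end = 21L) {
  stopifnot(length(cds) == 1L, start >= 1L, end >= start)
  if (end > nchar(cds)) {
    stop("region end ", end, " beyond sequence length ", nchar(cds))
  }
  substr(cds, start, end)
}

#' G+C fraction of sequences
#'
#' @param s character vector of non-empty RNA/DNA strings.
#' @return numeric vector of (#G + #C) / length in `[0, 1]`.
#' @export
gc_content <- function(s) {
  n <- nchar(s)
  if (any(n == 0L)) stop("gc_content undefined for empty sequences")
  gc <- nchar(gsub("[^GCgc]", "", s))
  unname(gc / n)
}

#' A+T/U fraction (complement of [gc_content()])
#' @param s character vector of sequences.
#' @return numeric vector.
#' @export
at_content <- function(s) 1 - gc_content(s)

# ---------------------------------------------------------------- codons ----

#' Codon table utilities
#'
#' Returns the standard genetic code on the RNA alphabet together with the
#' synonym structure used by the codon adaptation index and the synonymous
#' sampler.
#'
#' @return list with `code` (named character: codon -> amino acid, `*` for
#'   stop), `synonyms` (list: amino acid -> codons) and `degeneracy`
#'   (named integer per amino acid).
#' @export
codon_table <- function() {
  code <- Biostrings::RNA_GENETIC_CODE
  syn <- split(names(code), unname(code))
  list(code = code, synonyms = syn,
       degeneracy = vapply(syn, length, integer(1)))
}

#' Translate an RNA coding sequence
#' @param cds RNA string with length divisible by 3.
#' @return amino-acid string (`*` for stop codons).
#' @export
translate_rna <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  code <- codon_table()$code
  cod <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- code[cod]
  if (anyNA(aa)) stop("invalid codon(s): ", paste(cod[is.na(aa)], collapse = ", "))
  paste(aa, collapse = "")
}

#' Count the synonymous mRNA variants of a protein
#'
#' Exact product of standard-genetic-code codon degeneracies, optionally
#' times 3 for the stop codon. The count is returned as an arbitrary
#' precision integer because it overflows doubles' exactness almost
#' immediately (a typical protein has >1e100 variants).
#'
#' @param protein string over the 20 standard amino acids.
#' @param include_stop multiply by 3 for the three stop codons?
#' @return object of class `big_count`; see [format.big_count()].
#' @export
count_synonymous_variants <- function(protein, include_stop = FALSE) {
  deg <- codon_table()$degeneracy
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- !(aa %in% setdiff(names(deg), "*"))
  if (any(bad)) stop("unknown residue(s): ", paste(unique(aa[bad]), collapse = ", "))
  x <- .big_one()
  for (d in deg[aa]) x <- .big_mul_small(x, d)
  if (include_stop) x <- .big_mul_small(x, deg[["*"]])
  x
}

# little-endian base-1e9 arbitrary-precision unsigned integers
.big_one <- function() structure(list(limbs = 1), class = "big_count")

.big_mul_small <- function(x, m) {
  l <- x$limbs * m
  carry <- 0
  for (i in seq_along(l)) {
    v <- l[i] + carry
    carry <- floor(v / 1e9)
    l[i] <- v - carry * 1e9
  }
  while (carry > 0) {
    l <- c(l, carry %% 1e9)
    carry <- floor(carry / 1e9)
  }
  structure(list(limbs = l), class = "big_count")
}

#' @describeIn count_synonymous_variants decimal string of the exact count.
#' @param x a `big_count`.
#' @param ... ignored.
#' @export
format.big_count <- function(x, ...) {
  l <- rev(x$limbs)
  paste0(l[1], paste(sprintf("%09d", l[-1]), collapse = ""))
}

#' @export
print.big_count <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @describeIn count_synonymous_variants scientific notation at `digits`
#'   significant figures (e.g. `"7.62e+111"`).
#' @param digits significant figures.
#' @export
signif_big_count <- function(x, digits = 3L) {
  s <- format(x)
  exp <- nchar(s) - 1L
  mant <- as.numeric(paste0(substr(s, 1, 1), ".", substr(s, 2, min(nchar(s), 16))))
  mant <- signif(mant, digits)
  if (mant >= 10) { mant <- mant / 10; exp <- exp + 1L }
  sprintf("%.*ge+%d", digits, mant, exp)
}

# ------------------------------------------------------------ containers ----

#' Bundle a genome's core mRNA heads and core ncRNAs
#'
#' The unit of the avoidance tests. ncRNAs are deduplicated (identical
#' paralogous copies collapsed); every mRNA head must have the configured
#' head length.
#'
#' @param genome_id genome identifier.
#' @param mrna_heads named character vector of mRNA 5' regions.
#' @param ncrnas named character vector of ncRNA sequences.
#' @param domain `"BACTERIA"` or `"ARCHAEA"`.
#' @param phylum phylum label used by [phylum_summary()].
#' @param head_len required head length (default 21 nt).
#' @return object of class `genome_bundle`.
#' @export
genome_bundle <- function(genome_id, mrna_heads, ncrnas,
                          domain = c("BACTERIA", "ARCHAEA"),
                          phylum = "unknown", head_len = 21L) {
  domain <- match.arg(domain)
  stopifnot(length(mrna_heads) >= 1L, length(ncrnas) >= 1L)
  if (any(nchar(mrna_heads) != head_len)) {
    stop("all mRNA heads must have length ", head_len)
  }
  dup <- duplicated(unname(ncrnas))
  if (any(dup)) ncrnas <- ncrnas[!dup]
  structure(list(genome_id = genome_id, domain = domain, phylum = phylum,
                 mrna_heads = mrna_heads, ncrnas = ncrnas,
                 head_len = head_len),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %s (%s/%s): %d mRNA heads (%d nt), %d ncRNAs\n",
              x$genome_id, x$domain, x$phylum, length(x$mrna_heads),
              x$head_len, length(x$ncrnas)))
  invisible(x)
}

# ------------------------------------------------------- contact tables -----

#' Read a residue contact table
#'
#' Two-column TSV `position<TAB>in_contact{0,1}` with a header, one row per
#' residue of a reference ncRNA. Positions must be contiguous from 1.
#'
#' @param path TSV path.
#' @return data.frame with integer `position` and logical `in_contact`.
#' @export
read_contact_table <- function(path) {
  d <- read.delim(path, comment.char = "#")
  stopifnot(all(c("position", "in_contact") %in% names(d)))
  d <- d[order(d$position), c("position", "in_contact")]
  if (!identical(as.integer(d$position), seq_len(nrow(d)))) {
    stop("contact table positions must be contiguous 1..L")
  }
  if (!all(d$in_contact %in% c(0L, 1L))) stop("in_contact must be 0/1")
  data.frame(position = as.integer(d$position),
             in_contact = as.logical(d$in_contact))
}

#' Write a residue contact table
#' @param contacts data.frame as returned by [read_contact_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(contacts, path) {
  d <- data.frame(position = contacts$position,
                  in_contact = as.integer(contacts$in_contact))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
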