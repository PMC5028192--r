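#' Minimum free energy secondary structure of one RNA
#'
#' Dynamic-programming minimisation over nested structures under the
#' simplified nearest-neighbour model (hairpins, stacks, bulges, interior
#' loops and linear-penalty multibranch loops; minimum hairpin loop 3). The
#' energy is never positive: when no stabilising structure exists the open
#' chain (energy 0) is returned.
#'
#' @param s RNA string.
#' @param params an [energy_params()] object.
#' @param constraint optional integer vector of 1-based positions forced to
#'   stay unpaired.
#' @return list with `energy` (kcal/mol, <= 0) and `structure` (dot-bracket).
#' @export
fold_mfe <- function(s, params = energy_params(), constraint = NULL) {
  v <- .enc(s)
  mask <- rep(FALSE, length(v))
  if (!is.null(constraint)) {
    stopifnot(all(constraint >= 1L), all(constraint <= length(v)))
    mask[constraint] <- TRUE
  }
  r <- c_fold(v, .par_cpp(params), mask, structure = TRUE)
  list(energy = r$energy, structure = r$structure)
}

#' Energy cost of opening a binding site
#'
#' The increase in folding MFE when a contiguous site is forced to stay
#' unpaired: `fold_mfe(s, site unpaired) - fold_mfe(s)`. Non-negative by
#' construction; 0 for unstructured molecules.
#'
#' @param s RNA string.
#' @param site length-2 vector `c(from, to)`, 1-based inclusive.
#' @param params an [energy_params()] object.
#' @return opening energy in kcal/mol (>= 0).
#' @export
opening_energy <- function(s, site, params = energy_params()) {
  n <- nchar(s)
  if (length(site) != 2L || site[1] < 1L || site[2] > n || site[1] > site[2]) {
    stop("invalid site interval")
  }
  v <- .enc(s)
  pc <- .par_cpp(params)
  e0 <- c_fold(v, pc, rep(FALSE, n), structure = FALSE)$energy
  mask <- rep(FALSE, n)
  mask[site[1]:site[2]] <- TRUE
  ec <- c_fold(v, pc, mask, structure = FALSE)$energy
  max(0, ec - e0)
}

#' Opening energies of all short sites of one molecule
#'
#' Precomputes [opening_energy()] for every contiguous interval up to
#' `max_site` nucleotides; row = site start, column = site length. Used to
#' cache the accessibility term when one molecule is screened against many
#' partners.
#'
#' @inheritParams opening_energy
#' @param max_site maximum site length (default 25).
#' @return numeric matrix `nchar(s) x max_site` (NA where the interval runs
#'   off the end).
#' @export
opening_profile <- function(s, params = energy_params(), max_site = 25L) {
  c_opening_profile(.enc(s), .par_cpp(params), as.integer(max_site))
}

#' Intermolecular duplex minimum free energy
#'
#' Best hybridisation between two RNAs allowing only intermolecular pairs
#' (stacks, bulges and interior loops along the duplex), plus the duplex
#' initiation cost and AU/GU end penalties. A positive optimum is reported as
#' 0 with empty sites ("no favourable interaction"), which avoids sign-flip
#' artifacts in the downstream rank tests. Energy ties are broken towards the
#' lexicographically smallest site pair.
#'
#' @param a,b RNA strings.
#' @param params an [energy_params()] object.
#' @return object of class `duplex_result`: `energy` (kcal/mol, <= 0),
#'   `site_a`, `site_b` (1-based inclusive intervals, NA when no
#'   interaction) and `pairing` (dot-bracket duplex string `"...&..."`).
#' @export
duplex_mfe <- function(a, b, params = energy_params()) {
  r <- c_duplex(.enc(a), .enc(b), .par_cpp(params))
  structure(r, class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  if (is.na(x$site_a[1])) {
    cat("<duplex_result> no favourable interaction (0 kcal/mol)\n")
  } else {
    cat(sprintf("<duplex_result> %.2f kcal/mol  a[%d..%d] : b[%d..%d]  %s\n",
                x$energy, x$site_a[1], x$site_a[2], x$site_b[1], x$site_b[2],
                x$pairing))
    if (!is.null(x$open_a)) {
      cat(sprintf("  duplex %.2f + open_a %.2f + open_b %.2f\n",
                  x$duplex, x$open_a, x$open_b))
    }
  }
  invisible(x)
}

#' Intermolecular interaction energy
#'
#' The pipeline's central quantity. Mode `"hybrid"` is the raw duplex MFE
#' ([duplex_mfe()]). Mode `"access"` additionally charges the intramolecular
#' cost of opening the binding site on each molecule: it minimises
#' `opening_energy(a, site_a) + opening_energy(b, site_b) + duplex energy`
#' over all contiguous site pairs of length `<= max_site`. Because opening a
#' larger site never costs less, the optimal sites equal the duplex span, so
#' the search runs over anchored duplexes rather than all interval pairs.
#' `"access"` is the pipeline default; `"hybrid"` is retained for
#' model-comparison experiments and large calibration runs.
#'
#' @inheritParams duplex_mfe
#' @param mode `"access"` (opening + hybridisation) or `"hybrid"`.
#' @param max_site maximum binding-site length per molecule (default 25).
#' @param open_a,open_b optional precomputed [opening_profile()] matrices.
#' @return a `duplex_result`; in `"access"` mode with extra fields `open_a`,
#'   `open_b`, `duplex` decomposing the total.
#' @export
interaction_energy <- function(a, b, params = energy_params(),
                               mode = c("access", "hybrid"), max_site = 25L,
                               open_a = NULL, open_b = NULL) {
  mode <- match.arg(mode)
  if (mode == "hybrid") return(duplex_mfe(a, b, params))
  stopifnot(max_site >= 4L)
  if (is.null(open_a)) open_a <- opening_profile(a, params, max_site)
  if (is.null(open_b)) open_b <- opening_profile(b, params, max_site)
  r <- c_access(.enc(a), .enc(b), .par_cpp(params), as.integer(max_site),
                open_a, open_b)
  structure(r, class = "duplex_result")
}

#' Interaction energies for all pairs of two sequence sets
#'
#' Batch version of [interaction_energy()] returning only energies; the
#' workhorse of the genome scans (one call per genome per head set).
#'
#' @param a_set,b_set named character vectors of RNA sequences.
#' @inheritParams interaction_energy
#' @return numeric matrix `length(a_set) x length(b_set)` of energies
#'   (kcal/mol, <= 0).
#' @export
interaction_energy_matrix <- function(a_set, b_set, params = energy_params(),
                                      mode = c("access", "hybrid"),
                                      max_site = 25L) {
  mode <- match.arg(mode)
  ea <- .enc_list(a_set)
  eb <- .enc_list(b_set)
  pc <- .par_cpp(params)
  m <- if (mode == "hybrid") {
    c_duplex_batch(ea, eb, pc)
  } else {
    oa <- lapply(a_set, opening_profile, params = params, max_site = max_site)
    ob <- lapply(b_set, opening_profile, params = params, max_site = max_site)
    c_access_batch(ea, eb, pc, as.integer(max_site), unname(oa), unname(ob))
  }
  dimnames(m) <- list(names(a_set), names(b_set))
  m
}
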