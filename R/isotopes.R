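# Natural isotope abundances (CHNOS), indexed by neutron-number shift
# relative to the lightest isotope. Values: IUPAC/NIST representative.
.isotope_abundances <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))

# convolution of two shift-indexed abundance vectors, truncated at nmax
.conv <- function(a, b, nmax) {
  out <- numeric(nmax)
  for (i in seq_along(a)) {
    jmax <- min(length(b), nmax - i + 1L)
    if (jmax >= 1L)
      out[i:(i + jmax - 1L)] <- out[i:(i + jmax - 1L)] + a[i] * b[1:jmax]
  }
  out
}

# distribution of `count` atoms of one element (fast exponentiation)
.element_power <- function(p, count, nmax) {
  result <- c(1, numeric(nmax - 1L))
  base <- c(p, numeric(max(0L, nmax - length(p))))[1:nmax]
  while (count > 0L) {
    if (count %% 2L == 1L) result <- .conv(result, base, nmax)
    base <- .conv(base, base, nmax)
    count <- count %/% 2L
  }
  result
}

#' Aggregated isotopologue envelope
#'
#' Computes the relative abundances of the M, M+1, ..., M+(n_peaks-1)
#' aggregated isotopologues of a molecule from its CHNOS elemental
#' composition, by convolving the natural isotope distributions of its
#' atoms. Peptides and glycopeptides are mapped to formulas with
#' [molecular_formula()]. Abundances are normalized to the most intense
#' peak (base peak = 1).
#'
#' @param x A formula (named numeric vector with any of C,H,N,O,S), an
#'   `fcg_peptide`/`fcg_glycopeptide`, or a sequence string.
#' @param n_peaks Number of isotopologue peaks to return (>= 1).
#' @return Numeric vector of length `n_peaks`.
#' @examples
#' isotope_envelope("EEQYNSTYR", n_peaks = 4)
#' @export
isotope_envelope <- function(x, n_peaks = 6L) {
  stopifnot(n_peaks >= 1L)
  if (!is.numeric(x)) x <- molecular_formula(x)
  if (is.null(names(x)) || !all(names(x) %in% names(.isotope_abundances)))
    stop("formula must be named with elements among C, H, N, O, S")
  if (any(x < 0)) stop("negative atom counts")
  dist <- c(1, numeric(n_peaks - 1L))
  for (el in names(x)) {
    if (x[[el]] == 0) next
    dist <- .conv(dist, .element_power(.isotope_abundances[[el]], x[[el]], n_peaks),
                  n_peaks)
  }
  dist / max(dist)
}
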