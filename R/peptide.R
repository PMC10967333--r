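#' Peptide with protein coordinates and modifications
#'
#' @param sequence Amino-acid string (20-letter alphabet).
#' @param start,end 1-based inclusive coordinates on the parent protein.
#' @param mods Data frame with columns `position` (1-based within the
#'   peptide) and `name` (a key of `mass_constants()$modifications`), or
#'   `NULL`.
#' @param missed_cleavages Number of internal cleavage sites retained.
#' @return An object of class `fcg_peptide`.
#' @examples
#' p <- peptide("EEQYNSTYR", start = 293, end = 301)
#' peptide_mass(p)
#' @export
peptide <- function(sequence, start = 1L, end = start + nchar(sequence) - 1L,
                    mods = NULL, missed_cleavages = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("peptide sequence must be non-empty")
  letters <- strsplit(sequence, "")[[1]]
  known <- names(.element_table()$residues)
  bad <- which(!(letters %in% known))
  if (length(bad))
    stop(sprintf("unknown residue letter '%s' at position %d", letters[bad[1]], bad[1]))
  if (start > end || end - start + 1L != nchar(sequence))
    stop("coordinates inconsistent with sequence length")
  if (is.null(mods))
    mods <- data.frame(position = integer(), name = character())
  stopifnot(all(c("position", "name") %in% names(mods)))
  if (nrow(mods) && (any(mods$position < 1L) || any(mods$position > nchar(sequence))))
    stop("modification position outside the peptide")
  structure(list(sequence = sequence, start = as.integer(start),
                 end = as.integer(end), mods = mods,
                 missed_cleavages = as.integer(missed_cleavages)),
            class = "fcg_peptide")
}

#' @export
print.fcg_peptide <- function(x, ...) {
  cat(sprintf("<peptide> %d-%s-%d", x$start, x$sequence, x$end))
  if (nrow(x$mods))
    cat("  [", paste(x$mods$name, "@", x$mods$position, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus modification deltas plus one water.
#'
#' @param pep An [peptide()] object or a plain sequence string.
#' @param constants Mass table, see [mass_constants()].
#' @return Mass in Da.
#' @export
peptide_mass <- function(pep, constants = mass_constants()) {
  if (is.character(pep)) pep <- peptide(pep)
  stopifnot(inherits(pep, "fcg_peptide"))
  res <- constants$residues[strsplit(pep$sequence, "")[[1]]]
  m <- sum(res) + constants$water
  if (nrow(pep$mods)) {
    delta <- constants$modifications[pep$mods$name]
    if (anyNA(delta)) stop("unknown modification: ",
                           paste(pep$mods$name[is.na(delta)], collapse = ", "))
    m <- m + sum(delta)
  }
  m
}

#' Glycopeptide: a peptide carrying one glycan at a sequon asparagine
#'
#' The site must fall on the Asn of a valid N-glycosylation sequon
#' (N-X-S/T, X != P) readable within the peptide.
#'
#' @param pep An [peptide()] object.
#' @param site 1-based position within the peptide (an N), or `NA` for a
#'   bare peptide (empty glycan only).
#' @param glycan A [glycan_composition()].
#' @return An object of class `fcg_glycopeptide`.
#' @examples
#' gp <- glycopeptide(peptide("EEQYNSTYR", 293, 301), site = 5,
#'                    glycan = glycan_composition(4, 3))
#' glycopeptide_mz(gp, charge = 2)  # 1244.4976
#' @export
glycopeptide <- function(pep, site, glycan) {
  stopifnot(inherits(pep, "fcg_peptide"), inherits(glycan, "glycan_composition"))
  if (sum(glycan) == 0) {
    site <- NA_integer_
  } else {
    n <- nchar(pep$sequence)
    if (is.na(site) || site < 1L || site > n)
      stop("glycosylation site outside the peptide")
    s <- strsplit(pep$sequence, "")[[1]]
    ok <- site + 2L <= n && s[site] == "N" && s[site + 1L] != "P" &&
      s[site + 2L] %in% c("S", "T")
    if (!ok) stop("site ", site, " is not the Asn of an N-X-S/T (X != P) sequon")
  }
  structure(list(peptide = pep, site = as.integer(site), glycan = glycan),
            class = "fcg_glycopeptide")
}

#' @export
print.fcg_glycopeptide <- function(x, ...) {
  cat(sprintf("<glycopeptide> %s + %s", x$peptide$sequence, format(x$glycan)))
  if (!is.na(x$site)) cat(sprintf(" @ site %d (N%d)", x$site, x$peptide$start + x$site - 1L))
  cat("\n")
  invisible(x)
}

#' Neutral glycopeptide mass and protonated m/z
#'
#' The neutral mass is exactly `peptide_mass + glycan_mass` (attachment is
#' anhydrous); the m/z of the `[M + zH]z+` species is
#' `(M + z * proton) / z`.
#'
#' @param gp An [glycopeptide()] object.
#' @param charge Positive integer charge state.
#' @inheritParams peptide_mass
#' @return Mass in Da / m/z.
#' @export
glycopeptide_mass <- function(gp, constants = mass_constants()) {
  stopifnot(inherits(gp, "fcg_glycopeptide"))
  peptide_mass(gp$peptide, constants) + glycan_mass(gp$glycan, constants)
}

#' @rdname glycopeptide_mass
#' @export
glycopeptide_mz <- function(gp, charge, constants = mass_constants()) {
  if (length(charge) != 1L || is.na(charge) || charge < 1 || charge != round(charge))
    stop("charge must be a positive integer")
  (glycopeptide_mass(gp, constants) + charge * constants$proton) / charge
}

#' CHNOS elemental composition of a peptide or glycopeptide
#'
#' Used by [isotope_envelope()]. Modifications contribute their formulas;
#' the 18O of `deamidation_18O` is treated as the deamidation formula (the
#' heavy atom is modelled as a fixed mass shift, not a natural-abundance
#' oxygen).
#'
#' @param x An `fcg_peptide`, `fcg_glycopeptide`, or sequence string.
#' @return Named integer vector with elements C, H, N, O, S.
#' @export
molecular_formula <- function(x) {
  et <- .element_table()
  if (is.character(x)) x <- peptide(x)
  if (inherits(x, "fcg_glycopeptide")) {
    fg <- Reduce(`+`, Map(function(unit, k) et$monosaccharides[[unit]] * k,
                          c("HexNAc", "Hex", "Fuc", "NeuAc"), as.list(unclass(x$glycan))),
                 c(C = 0, H = 0, N = 0, O = 0, S = 0))
    return(molecular_formula(x$peptide) + fg)
  }
  stopifnot(inherits(x, "fcg_peptide"))
  res <- strsplit(x$sequence, "")[[1]]
  out <- Reduce(`+`, et$residues[res]) + et$water
  if (nrow(x$mods))
    out <- out + Reduce(`+`, et$modifications[x$mods$name], c(C = 0, H = 0, N = 0, O = 0, S = 0))
  out
}
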