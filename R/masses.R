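#' @importFrom jsonlite fromJSON
NULL

.fcg <- new.env(parent = emptyenv())

#' Monoisotopic mass constants
#'
#' Returns the table of monoisotopic masses used throughout the package:
#' amino-acid residue masses, monosaccharide residue masses (dehydrated,
#' i.e. the mass a unit contributes inside a glycan), modification deltas,
#' and the water/proton constants. The table ships as a versioned JSON
#' resource and can be replaced wholesale with [load_mass_table()], e.g. to
#' study alternative mass conventions.
#'
#' The modification deltas include `deamidation` (+0.98402 Da, Asn to Asp)
#' and `deamidation_18O` (+2.98826 Da, Asn to Asp with incorporation of one
#' heavy oxygen), the signature left by PNGase F deglycosylation performed
#' in H2(18)O.
#'
#' @return A list with components `residues`, `monosaccharides`,
#'   `modifications` (named numeric vectors, Da), and scalars `water`,
#'   `proton`, `electron`, `o18_minus_o16` (Da).
#' @examples
#' mc <- mass_constants()
#' mc$monosaccharides[["HexNAc"]]
#' @export
mass_constants <- function() {
  if (is.null(.fcg$mass_table))
    load_mass_table(system.file("extdata", "mass_table.json",
                                package = "fcglycoscope", mustWork = TRUE))
  .fcg$mass_table
}

#' Replace the active mass table
#'
#' @param path Path to a JSON mass table with the same shape as the
#'   packaged `inst/extdata/mass_table.json`.
#' @return The loaded table, invisibly.
#' @export
load_mass_table <- function(path) {
  raw <- jsonlite::fromJSON(path)
  tab <- list(
    version = raw$version,
    residues = unlist(raw$residues),
    monosaccharides = unlist(raw$monosaccharides),
    modifications = unlist(raw$modifications),
    water = raw$water, proton = raw$proton, electron = raw$electron,
    o18_minus_o16 = raw$o18_minus_o16)
  stopifnot(all(tab$residues > 0), all(tab$monosaccharides > 0),
            tab$water > 0, tab$proton > 0)
  .fcg$mass_table <- tab
  invisible(tab)
}

#' Elemental compositions (CHNOS) of residues and glycan units
#'
#' Atom counts used by [isotope_envelope()]. Kept in code (not the JSON
#' resource) because isotope modelling needs integers, not masses.
#' @keywords internal
.element_table <- function() {
  m <- function(C = 0, H = 0, N = 0, O = 0, S = 0) c(C = C, H = H, N = N, O = O, S = S)
  list(
    residues = list(
      G = m(2, 3, 1, 1),  A = m(3, 5, 1, 1),  S = m(3, 5, 1, 2),
      P = m(5, 7, 1, 1),  V = m(5, 9, 1, 1),  T = m(4, 7, 1, 2),
      C = m(3, 5, 1, 1, 1), L = m(6, 11, 1, 1), I = m(6, 11, 1, 1),
      N = m(4, 6, 2, 2),  D = m(4, 5, 1, 3),  Q = m(5, 8, 2, 2),
      K = m(6, 12, 2, 1), E = m(5, 7, 1, 3),  M = m(5, 9, 1, 1, 1),
      H = m(6, 7, 3, 1),  F = m(9, 9, 1, 1),  R = m(6, 12, 4, 1),
      Y = m(9, 9, 1, 2),  W = m(11, 10, 2, 1)),
    monosaccharides = list(
      HexNAc = m(8, 13, 1, 5), Hex = m(6, 10, 0, 5),
      Fuc = m(6, 10, 0, 4), NeuAc = m(11, 17, 1, 8)),
    modifications = list(
      carbamidomethyl = m(2, 3, 1, 1), oxidation = m(O = 1),
      acetyl = m(2, 2, 0, 1), deamidation = m(0, -1, -1, 1),
      # 18O handled as a mass shift, not a natural-abundance atom
      deamidation_18O = m(0, -1, -1, 1)),
    water = m(H = 2, O = 1))
}
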