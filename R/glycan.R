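#' Glycan composition
#'
#' An N-glycan composition counts the four monosaccharide classes relevant
#' to (human or glyco-engineered plant) IgG Fc glycans: N-acetylhexosamine
#' (HexNAc), hexose (Hex), deoxyhexose (Fuc), and N-acetylneuraminic acid
#' (NeuAc). Compositions carry no topology: isomers (e.g. bisecting GlcNAc
#' versus an antenna GlcNAc) are indistinguishable at this level.
#'
#' @param hexnac,hex,fuc,neuac Non-negative integer counts.
#' @return An object of class `glycan_composition` (named integer vector).
#' @examples
#' g0 <- glycan_composition(hexnac = 4, hex = 3)
#' glycan_mass(g0)
#' @export
glycan_composition <- function(hexnac = 0, hex = 0, fuc = 0, neuac = 0) {
  x <- c(hexnac = hexnac, hex = hex, fuc = fuc, neuac = neuac)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("monosaccharide counts must be non-negative integers")
  structure(as.integer(x), names = names(x), class = "glycan_composition")
}

#' @export
format.glycan_composition <- function(x, ...) {
  if (sum(x) == 0) return("bare")
  lab <- c("HexNAc", "Hex", "Fuc", "NeuAc")
  keep <- x > 0
  paste0(lab[keep], unclass(x)[keep], collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", format(x), "  (",
      sprintf("%.4f", glycan_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' @export
as.character.glycan_composition <- function(x, ...) format(x)

#' Parse a composition string such as "HexNAc4Hex3Fuc1"
#'
#' @param x Character scalar; the empty string or "bare" gives the empty
#'   composition.
#' @return A [glycan_composition()].
#' @export
parse_glycan_composition <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x %in% c("", "bare")) return(glycan_composition())
  m <- gregexpr("(HexNAc|Hex|Fuc|NeuAc)(\\d+)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (length(parts) == 0L || sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse glycan composition: ", x)
  counts <- c(HexNAc = 0L, Hex = 0L, Fuc = 0L, NeuAc = 0L)
  for (p in parts) {
    unit <- sub("\\d+$", "", p)
    counts[unit] <- counts[unit] + as.integer(sub("^\\D+", "", p))
  }
  glycan_composition(counts[["HexNAc"]], counts[["Hex"]],
                     counts[["Fuc"]], counts[["NeuAc"]])
}

#' Neutral monoisotopic mass of a glycan composition
#'
#' Monosaccharides contribute their dehydrated residue mass; attaching the
#' glycan to an Asn side chain adds no water. The empty composition has
#' mass zero.
#'
#' @param glycan A [glycan_composition()].
#' @param constants Mass table, see [mass_constants()].
#' @return Mass in Da.
#' @export
glycan_mass <- function(glycan, constants = mass_constants()) {
  stopifnot(inherits(glycan, "glycan_composition"))
  ms <- constants$monosaccharides
  sum(unclass(glycan) * ms[c("HexNAc", "Hex", "Fuc", "NeuAc")])
}

#' Oxonium (B-type) ion m/z for a glycan fragment
#'
#' Singly protonated carbohydrate fragment: the summed residue masses plus
#' one proton. Water-loss satellites are obtained with `water_loss`.
#'
#' @param glycan A non-empty [glycan_composition()].
#' @param water_loss Number of water molecules lost (0, 1 or 2).
#' @inheritParams glycan_mass
#' @return m/z of the singly charged oxonium ion.
#' @examples
#' oxonium_mz(glycan_composition(hexnac = 1))                 # ~204.0867
#' oxonium_mz(glycan_composition(hexnac = 1), water_loss = 1) # ~186.0760
#' @export
oxonium_mz <- function(glycan, water_loss = 0, constants = mass_constants()) {
  stopifnot(inherits(glycan, "glycan_composition"))
  if (sum(glycan) == 0) stop("oxonium ion of an empty composition is undefined")
  glycan_mass(glycan, constants) + constants$proton - water_loss * constants$water
}
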