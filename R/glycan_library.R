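#' Classify a glycan composition
#'
#' Assigns one of the three mature N-glycan classes — oligomannose,
#' complex, hybrid — or "other", from monosaccharide counts alone:
#'
#' * HexNAc = 2 and Hex >= 5: oligomannose (Man5 and larger);
#' * HexNAc = 3, Hex >= 5, no NeuAc: hybrid (one processed antenna, one
#'   unsubstituted mannose arm);
#' * any other HexNAc >= 3: complex;
#' * HexNAc = 1 with no Hex: "other" (the single-GlcNAc remnant left by
#'   lysosomal degradation, seen on Fc sequons as "monoHexNAc");
#' * remaining compositions (e.g. the HexNAc2Hex3 paucimannose core):
#'   "other".
#'
#' This is a stated heuristic on counts: composition data cannot separate
#' isomers (a bisecting GlcNAc is counted like an antenna GlcNAc), and
#' reports flag the classification as composition-based.
#'
#' @param glycan A non-empty [glycan_composition()].
#' @return One of `"oligomannose"`, `"hybrid"`, `"complex"`, `"other"`.
#' @examples
#' classify_glycan(glycan_composition(2, 5))      # oligomannose (Man5)
#' classify_glycan(glycan_composition(4, 3, 1))   # complex (G0F)
#' @export
classify_glycan <- function(glycan) {
  stopifnot(inherits(glycan, "glycan_composition"))
  if (sum(glycan) == 0) stop("cannot classify an empty composition")
  hn <- glycan[["hexnac"]]; hx <- glycan[["hex"]]; na <- glycan[["neuac"]]
  if (hn == 2L && hx >= 5L) return("oligomannose")
  if (hn == 3L && hx >= 5L && na == 0L) return("hybrid")
  if (hn >= 3L) return("complex")
  "other"
}

.library_cache <- new.env(parent = emptyenv())

#' Load a glycan composition library
#'
#' Libraries are TSV files with columns `shorthand` (may be empty),
#' `hexnac`, `hex`, `fuc`, `neuac` and an optional `class_override`.
#' Compositions must be unique; shorthands, where present, must map to
#' compositions bijectively. The glycan class is computed with
#' [classify_glycan()] unless overridden.
#'
#' @param path TSV path; defaults to the packaged ~30-entry library that
#'   covers IgG Fc glycoforms reported for human and glyco-engineered
#'   plant expression (G-series complex glycans, Man5-Man9, hybrids,
#'   bisected/truncated species, and the monoHexNAc remnant). The packaged
#'   library is a documented stand-in for proprietary search-engine
#'   libraries, not a copy of one.
#' @return Data frame with columns `shorthand`, `hexnac`, `hex`, `fuc`,
#'   `neuac`, `class`, `mass`, `composition` (canonical string form).
#' @export
glycan_library <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.library_cache$default)) return(.library_cache$default)
    path <- system.file("extdata", "glycan_library.tsv",
                        package = "fcglycoscope", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = c(shorthand = "character"))
  stopifnot(all(c("shorthand", "hexnac", "hex", "fuc", "neuac") %in% names(df)))
  comps <- lapply(seq_len(nrow(df)), function(i)
    glycan_composition(df$hexnac[i], df$hex[i], df$fuc[i], df$neuac[i]))
  df$composition <- vapply(comps, format, "")
  if (anyDuplicated(df$composition))
    stop("library compositions are not unique")
  sh <- df$shorthand[df$shorthand != ""]
  if (anyDuplicated(sh)) stop("library shorthands are not unique")
  df$class <- vapply(comps, classify_glycan, "")
  if ("class_override" %in% names(df)) {
    ov <- !is.na(df$class_override) & df$class_override != ""
    df$class[ov] <- df$class_override[ov]
    df$class_override <- NULL
  }
  df$mass <- vapply(comps, glycan_mass, 0)
  stopifnot(all(df$mass > 0))
  df <- df[order(df$mass), c("shorthand", "hexnac", "hex", "fuc", "neuac",
                             "class", "mass", "composition")]
  rownames(df) <- NULL
  if (cache) .library_cache$default <- df
  df
}

#' Shorthand name to composition, and back
#'
#' Standard IgG shorthand: Gn(F) are biantennary complex glycans with n
#' galactoses (HexNAc4 Hex 3+n) and optional core fucose; S counts NeuAc;
#' Man5-Man9 are the oligomannose series HexNAc2 Hex k.
#'
#' @param name Shorthand string, e.g. `"G0F"`, `"Man5"`.
#' @param library A [glycan_library()] data frame.
#' @return `shorthand_to_composition`: a [glycan_composition()].
#'   `composition_to_shorthand`: the shorthand, or the canonical
#'   composition string when no shorthand exists.
#' @examples
#' shorthand_to_composition("G0")   # HexNAc4Hex3
#' @export
shorthand_to_composition <- function(name, library = glycan_library()) {
  i <- match(name, library$shorthand)
  if (is.na(i))
    stop("unknown glycan shorthand '", name, "'; known: ",
         paste(setdiff(library$shorthand, ""), collapse = ", "))
  glycan_composition(library$hexnac[i], library$hex[i],
                     library$fuc[i], library$neuac[i])
}

#' @rdname shorthand_to_composition
#' @param glycan A [glycan_composition()].
#' @export
composition_to_shorthand <- function(glycan, library = glycan_library()) {
  key <- format(glycan)
  i <- match(key, library$composition)
  if (is.na(i) || library$shorthand[i] == "") return(key)
  library$shorthand[i]
}
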