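#' A single mass spectrum (centroided)
#'
#' Peak lists are stored as parallel numeric vectors sorted by m/z.
#' Duplicate m/z values are merged by summing intensities. MS2 spectra
#' must carry a precursor descriptor.
#'
#' @param mz,intensity Parallel numeric vectors; intensities must be
#'   non-negative.
#' @param scan_id Unique scan identifier (string or integer).
#' @param ms_level 1 or 2.
#' @param precursor_mz,precursor_charge Precursor descriptor (MS2).
#' @param rt Retention time in seconds (optional).
#' @param metadata Named list of extra header fields.
#' @return An object of class `fcg_spectrum`.
#' @export
spectrum <- function(mz, intensity, scan_id, ms_level = 2L,
                     precursor_mz = NA_real_, precursor_charge = NA_integer_,
                     rt = NA_real_, metadata = list()) {
  stopifnot(length(mz) == length(intensity), !anyNA(mz))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!ms_level %in% c(1L, 2L)) stop("ms_level must be 1 or 2")
  if (ms_level == 2L && is.na(precursor_mz))
    stop("an MS2 spectrum requires a precursor m/z")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(scan_id = as.character(scan_id), ms_level = as.integer(ms_level),
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 rt = as.numeric(rt), metadata = metadata),
            class = "fcg_spectrum")
}

#' @export
print.fcg_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> MS%d, %d peaks", x$scan_id, x$ms_level, length(x$mz)))
  if (x$ms_level == 2L)
    cat(sprintf(", precursor %.4f (%s+)", x$precursor_mz,
                ifelse(is.na(x$precursor_charge), "?", x$precursor_charge)))
  if (!is.na(x$rt)) cat(sprintf(", rt %.1f s", x$rt))
  cat("\n")
  invisible(x)
}

#' An ordered collection of spectra from one acquisition
#'
#' @param spectra List of [spectrum()] objects with unique scan ids.
#' @param source Source path or label.
#' @param metadata Named list.
#' @return An object of class `fcg_run`.
#' @export
ms_run <- function(spectra, source = NA_character_, metadata = list()) {
  stopifnot(all(vapply(spectra, inherits, TRUE, "fcg_spectrum")))
  ids <- vapply(spectra, `[[`, "", "scan_id")
  if (anyDuplicated(ids)) stop("scan ids must be unique within a run")
  structure(list(spectra = spectra, source = source, metadata = metadata),
            class = "fcg_run")
}

#' @export
print.fcg_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, 1L, "ms_level")
  cat(sprintf("<run> %d spectra (%d MS1, %d MS2)",
              length(x$spectra), sum(lv == 1L), sum(lv == 2L)))
  if (!is.na(x$source)) cat(" from", x$source)
  cat("\n")
  invisible(x)
}

#' @export
length.fcg_run <- function(x) length(x$spectra)

#' Write a run to Mascot Generic Format
#'
#' One BEGIN IONS/END IONS block per spectrum. MS1 spectra (MGF has no
#' native MS1 concept) are written with an `MSLEVEL=1` header and no
#' PEPMASS line; the package reader understands this convention. m/z are
#' written to 5 decimals and intensities to 4, so a round trip preserves
#' peaks to well within 1e-4 m/z and 0.1% intensity.
#'
#' @param run An [ms_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(run, path) {
  stopifnot(inherits(run, "fcg_run"))
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in run$spectra) {
    lines <- c("BEGIN IONS", paste0("TITLE=", sp$scan_id))
    if (sp$ms_level == 1L) lines <- c(lines, "MSLEVEL=1")
    if (!is.na(sp$rt)) lines <- c(lines, sprintf("RTINSECONDS=%.3f", sp$rt))
    if (sp$ms_level == 2L) {
      lines <- c(lines, sprintf("PEPMASS=%.5f", sp$precursor_mz))
      if (!is.na(sp$precursor_charge))
        lines <- c(lines, sprintf("CHARGE=%d+", sp$precursor_charge))
    }
    for (key in names(sp$metadata))
      lines <- c(lines, paste0(key, "=", sp$metadata[[key]]))
    lines <- c(lines, sprintf("%.5f %.4f", sp$mz, sp$intensity), "END IONS")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a Mascot Generic Format file
#'
#' Accepts standard MGF plus the package's `MSLEVEL=1` convention for MS1
#' scans. Unknown headers are preserved in each spectrum's `metadata`.
#' Malformed blocks are reported with their line number.
#'
#' @param path MGF path.
#' @return An [ms_run()].
#' @export
read_mgf <- function(path) {
  raw <- readLines(path)
  spectra <- list()
  i <- 1L; n <- length(raw); auto <- 0L
  while (i <= n) {
    line <- trimws(raw[i])
    if (line == "") { i <- i + 1L; next }
    if (line != "BEGIN IONS")
      stop("malformed MGF at line ", i, ": expected BEGIN IONS, got '", line, "'")
    begin_line <- i
    i <- i + 1L
    headers <- character(); mz <- numeric(); int <- numeric()
    while (i <= n && trimws(raw[i]) != "END IONS") {
      l <- trimws(raw[i])
      if (l != "") {
        if (grepl("=", l, fixed = TRUE)) headers <- c(headers, l)
        else {
          parts <- strsplit(l, "[ \t]+")[[1]]
          v <- suppressWarnings(as.numeric(parts))
          if (length(v) < 2 || anyNA(v[1:2]))
            stop("malformed MGF peak at line ", i, ": '", l, "'")
          mz <- c(mz, v[1]); int <- c(int, v[2])
        }
      }
      i <- i + 1L
    }
    if (i > n) stop("malformed MGF: block at line ", begin_line, " lacks END IONS")
    i <- i + 1L
    key <- toupper(sub("=.*", "", headers))
    val <- sub("^[^=]*=", "", headers)
    h <- function(k) if (k %in% key) val[match(k, key)] else NA_character_
    ms_level <- if (!is.na(h("MSLEVEL"))) as.integer(h("MSLEVEL")) else 2L
    pm <- NA_real_; pc <- NA_integer_
    if (ms_level == 2L) {
      if (is.na(h("PEPMASS")))
        stop("malformed MGF: MS2 block at line ", begin_line, " lacks PEPMASS")
      pm <- as.numeric(strsplit(h("PEPMASS"), "[ \t]+")[[1]][1])
      if (!is.na(h("CHARGE")))
        pc <- as.integer(sub("\\+$", "", h("CHARGE")))
    }
    auto <- auto + 1L
    known <- c("TITLE", "MSLEVEL", "PEPMASS", "CHARGE", "RTINSECONDS")
    extra <- as.list(val[!(key %in% known)])
    names(extra) <- sub("=.*", "", headers)[!(key %in% known)]
    spectra[[auto]] <- spectrum(
      mz, int,
      scan_id = if (!is.na(h("TITLE"))) h("TITLE") else paste0("scan_", auto),
      ms_level = ms_level, precursor_mz = pm, precursor_charge = pc,
      rt = if (!is.na(h("RTINSECONDS"))) as.numeric(h("RTINSECONDS")) else NA_real_,
      metadata = extra)
  }
  ms_run(spectra, source = path)
}

#' Read a (subset of) mzML file
#'
#' Minimal reader for centroided mzML: 64-bit or 32-bit little-endian
#' binary arrays, zlib-compressed or uncompressed. Anything else (profile
#' spectra declared in CV terms are not detected; numpress or other
#' compressions are) raises an unsupported-feature error. MGF remains the
#' canonical interchange format.
#'
#' @param path mzML path.
#' @return An [ms_run()].
#' @export
read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrum")
  decode <- function(bda) {
    acc <- xml2::xml_attr(xml2::xml_find_all(bda, ".//cvParam"), "accession")
    txt <- xml2::xml_text(xml2::xml_find_first(bda, ".//binary"))
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if ("MS:1000574" %in% acc) {
      raw <- memDecompress(raw, type = "gzip")
    } else if (any(acc %in% c("MS:1002312", "MS:1002313", "MS:1002314")))
      stop("unsupported mzML binary compression (only zlib or none)")
    size <- if ("MS:1000521" %in% acc) 4L else 8L
    readBin(raw, "double", n = length(raw) %/% size, size = size, endian = "little")
  }
  spectra <- lapply(seq_along(nodes), function(k) {
    nd <- nodes[[k]]
    cvs <- xml2::xml_find_all(nd, "./cvParam")
    acc <- xml2::xml_attr(cvs, "accession")
    lev <- xml2::xml_attr(cvs, "value")[acc == "MS:1000511"]
    ms_level <- if (length(lev)) as.integer(lev[1]) else 1L
    bdas <- xml2::xml_find_all(nd, ".//binaryDataArray")
    mzv <- intv <- numeric()
    for (b in bdas) {
      bacc <- xml2::xml_attr(xml2::xml_find_all(b, ".//cvParam"), "accession")
      if ("MS:1000514" %in% bacc) mzv <- decode(b)
      if ("MS:1000515" %in% bacc) intv <- decode(b)
    }
    sel <- xml2::xml_find_first(nd, ".//selectedIon")
    pm <- NA_real_; pc <- NA_integer_
    if (!inherits(sel, "xml_missing")) {
      scv <- xml2::xml_find_all(sel, ".//cvParam")
      sacc <- xml2::xml_attr(scv, "accession"); sval <- xml2::xml_attr(scv, "value")
      if ("MS:1000744" %in% sacc) pm <- as.numeric(sval[sacc == "MS:1000744"][1])
      if ("MS:1000041" %in% sacc) pc <- as.integer(sval[sacc == "MS:1000041"][1])
    }
    rtn <- xml2::xml_find_first(nd, ".//scan/cvParam[@accession='MS:1000016']")
    rt <- NA_real_
    if (!inherits(rtn, "xml_missing")) {
      rt <- as.numeric(xml2::xml_attr(rtn, "value"))
      if (grepl("minute", xml2::xml_attr(rtn, "unitName") %||% "")) rt <- rt * 60
    }
    id <- xml2::xml_attr(nd, "id")
    spectrum(mzv, intv, scan_id = if (is.na(id)) paste0("scan_", k) else id,
             ms_level = ms_level, precursor_mz = pm, precursor_charge = pc, rt = rt)
  })
  ms_run(spectra, source = path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Match a peak within a ppm tolerance
#'
#' Returns the most intense peak within `tol_ppm` of the target m/z; ties
#' on intensity are broken by smaller |delta ppm|.
#'
#' @param spec An [spectrum()].
#' @param target_mz Target m/z.
#' @param tol_ppm Tolerance in parts per million (> 0).
#' @return A list with `mz`, `intensity`, `ppm`, or `NULL` when no peak
#'   lies within tolerance.
#' @export
match_peak <- function(spec, target_mz, tol_ppm) {
  stopifnot(inherits(spec, "fcg_spectrum"), tol_ppm > 0)
  if (!length(spec$mz)) return(NULL)
  ppm <- (spec$mz - target_mz) / target_mz * 1e6
  hit <- which(abs(ppm) <= tol_ppm)
  if (!length(hit)) return(NULL)
  best <- hit[order(-spec$intensity[hit], abs(ppm[hit]))][1]
  list(mz = spec$mz[best], intensity = spec$intensity[best], ppm = ppm[best])
}
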