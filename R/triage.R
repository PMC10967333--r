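#' Diagnostic oxonium-ion panel
#'
#' The low-mass carbohydrate B-type fragments used to recognise
#' glycopeptide HCD spectra. The default panel is the seven-ion set used
#' to trigger glycopeptide MS2 acquisition on the instrument this package
#' emulates offline: HexNAc (m/z 204.0867) and its water-loss and
#' cross-ring satellites, HexNAcHex, and the NeuAc pair. The reference m/z
#' values are the published trigger values; they agree with first
#' principles ([oxonium_mz()]) to within 0.001 Da.
#'
#' @param tol_ppm Matching tolerance, ppm.
#' @param min_hits Minimum number of distinct panel ions that must match.
#' @return Data frame (`label`, `mz`) with attributes `tol_ppm`,
#'   `min_hits`.
#' @export
oxonium_panel <- function(tol_ppm = 15, min_hits = 2L) {
  stopifnot(tol_ppm > 0, min_hits >= 1L)
  df <- data.frame(
    label = c("HexNAc", "HexNAc-CH6O3", "HexNAcHex", "HexNAc-2H2O",
              "HexNAc-H2O", "NeuAc", "NeuAc-H2O"),
    mz = c(204.0867, 138.0545, 366.1396, 168.0653, 186.0760,
           292.1031, 274.0927),
    stringsAsFactors = FALSE)
  attr(df, "tol_ppm") <- tol_ppm
  attr(df, "min_hits") <- as.integer(min_hits)
  df
}

#' Is this MS2 spectrum glycopeptide-derived?
#'
#' Applies the oxonium-ion rule: the spectrum is called glycopeptide-
#' derived when at least `min_hits` distinct panel ions each match a peak
#' within `tol_ppm`. This reproduces, as an offline filter, the
#' two-of-panel / 15 ppm acquisition trigger. An optional relative
#' intensity floor (fraction of the base peak) can be imposed; by default
#' none is (the trigger used none).
#'
#' @param spec An MS2 [spectrum()].
#' @param panel An [oxonium_panel()].
#' @param min_intensity_frac Minimum oxonium peak intensity as a fraction
#'   of the base peak (default 0 = off).
#' @return List with `decision` (logical) and `matched` (character vector
#'   of matched panel labels).
#' @export
is_glyco_spectrum <- function(spec, panel = oxonium_panel(),
                              min_intensity_frac = 0) {
  stopifnot(inherits(spec, "fcg_spectrum"))
  if (spec$ms_level != 2L) stop("oxonium triage applies to MS2 spectra only")
  tol <- attr(panel, "tol_ppm") %||% 15
  min_hits <- attr(panel, "min_hits") %||% 2L
  floor_i <- if (length(spec$intensity)) min_intensity_frac * max(spec$intensity) else 0
  matched <- character()
  for (i in seq_len(nrow(panel))) {
    hit <- match_peak(spec, panel$mz[i], tol)
    if (!is.null(hit) && hit$intensity >= floor_i)
      matched <- c(matched, panel$label[i])
  }
  list(decision = length(matched) >= min_hits, matched = matched)
}

#' Triage every MS2 spectrum in a run
#'
#' @param run An [ms_run()].
#' @inheritParams is_glyco_spectrum
#' @return Data frame with columns `scan_id`, `decision`, `n_matched`,
#'   `matched` (comma-separated labels); one row per MS2 spectrum.
#' @export
triage_run <- function(run, panel = oxonium_panel(), min_intensity_frac = 0) {
  stopifnot(inherits(run, "fcg_run"))
  ms2 <- Filter(function(s) s$ms_level == 2L, run$spectra)
  res <- lapply(ms2, is_glyco_spectrum, panel = panel,
                min_intensity_frac = min_intensity_frac)
  data.frame(
    scan_id = vapply(ms2, `[[`, "", "scan_id"),
    decision = vapply(res, `[[`, TRUE, "decision"),
    n_matched = vapply(res, function(r) length(r$matched), 0L),
    matched = vapply(res, function(r) paste(r$matched, collapse = ","), ""),
    stringsAsFactors = FALSE)
}
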