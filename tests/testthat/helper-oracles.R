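# Independent oracles used across the suite. These deliberately do not
# share code with the package: masses are summed from a literal CHNOS
# atom-count table and NIST atomic masses, and isotope envelopes are
# convolved one atom at a time.

.or_atomic <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                O = 15.9949146196, S = 31.97207100)

.or_formulas <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

.or_sugars <- list(HexNAc = c(8, 13, 1, 5, 0), Hex = c(6, 10, 0, 5, 0),
                   Fuc = c(6, 10, 0, 4, 0), NeuAc = c(11, 17, 1, 8, 0))

# neutral monoisotopic mass by elemental summation
oracle_peptide_mass <- function(seq) {
  atoms <- Reduce(`+`, .or_formulas[strsplit(seq, "")[[1]]]) + c(0, 2, 0, 1, 0)
  sum(atoms * .or_atomic)
}

oracle_glycan_mass <- function(hexnac, hex, fuc, neuac) {
  atoms <- hexnac * .or_sugars$HexNAc + hex * .or_sugars$Hex +
    fuc * .or_sugars$Fuc + neuac * .or_sugars$NeuAc
  sum(atoms * .or_atomic)
}

# isotope envelope by one-atom-at-a-time polynomial multiplication
oracle_envelope <- function(formula, n_peaks) {
  ab <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
             N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
             S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
  dist <- 1
  for (el in names(formula)) {
    for (k in seq_len(formula[[el]])) {
      new <- numeric(min(n_peaks, length(dist) + length(ab[[el]]) - 1))
      for (i in seq_along(dist)) for (j in seq_along(ab[[el]])) {
        idx <- i + j - 1
        if (idx <= length(new)) new[idx] <- new[idx] + dist[i] * ab[[el]][j]
      }
      dist <- new
    }
  }
  dist <- c(dist, numeric(max(0, n_peaks - length(dist))))[seq_len(n_peaks)]
  dist / max(dist)
}

# per-residue boolean-mask coverage
oracle_coverage <- function(intervals, len) {
  mask <- logical(len)
  for (i in seq_len(nrow(intervals)))
    mask[intervals$start[i]:intervals$end[i]] <- TRUE
  100 * sum(mask) / len
}

random_peptide <- function(n) paste(sample(names(.or_formulas), n, TRUE), collapse = "")

# minimal mzML document for reader tests
make_mzml <- function(path, spectra, compress = TRUE, size = 8L) {
  enc <- function(x) {
    raw <- writeBin(as.numeric(x), raw(), size = size, endian = "little")
    if (compress) raw <- memCompress(raw, type = "gzip")
    jsonlite::base64_enc(raw)
  }
  comp_cv <- if (compress)
    '<cvParam accession="MS:1000574" name="zlib compression"/>'
  else '<cvParam accession="MS:1000576" name="no compression"/>'
  size_cv <- if (size == 8L)
    '<cvParam accession="MS:1000523" name="64-bit float"/>'
  else '<cvParam accession="MS:1000521" name="32-bit float"/>'
  blocks <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    prec <- if (!is.null(s$precursor_mz)) sprintf(
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>
         <cvParam accession="MS:1000744" name="selected ion m/z" value="%.5f"/>
         <cvParam accession="MS:1000041" name="charge state" value="%d"/>
       </selectedIon></selectedIonList></precursor></precursorList>',
      s$precursor_mz, s$charge) else ""
    sprintf('<spectrum id="%s" index="%d" defaultArrayLength="%d">
      <cvParam accession="MS:1000511" name="ms level" value="%d"/>
      <scanList count="1"><scan>
        <cvParam accession="MS:1000016" name="scan start time" value="%.4f" unitName="minute"/>
      </scan></scanList>%s
      <binaryDataArrayList count="2">
        <binaryDataArray>%s%s<cvParam accession="MS:1000514" name="m/z array"/>
          <binary>%s</binary></binaryDataArray>
        <binaryDataArray>%s%s<cvParam accession="MS:1000515" name="intensity array"/>
          <binary>%s</binary></binaryDataArray>
      </binaryDataArrayList></spectrum>',
      s$id, i - 1L, length(s$mz), s$ms_level, s$rt / 60, prec,
      size_cv, comp_cv, enc(s$mz), size_cv, comp_cv, enc(s$intensity))
  }, "")
  xml <- paste0('<?xml version="1.0" encoding="utf-8"?>\n<mzML>\n<run id="r">\n',
                '<spectrumList count="', length(spectra), '">\n',
                paste(blocks, collapse = "\n"), '\n</spectrumList>\n</run>\n</mzML>\n')
  writeLines(xml, path)
  path
}

# a fast low-noise config for search tests
quiet_config <- function(seed, preset = "hca-n", ...)
  synth_config(preset, seed = seed, noise_peaks = 0L, decoy_rate = 0,
               mz_jitter_ppm = 0, intensity_cv = 0, ...)
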