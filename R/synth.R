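#' Synthetic protein context
#'
#' A synthetic heavy-chain fragment: the universal human IgG1 CH2-domain
#' context carrying the conserved Fc sequon within the tryptic/Glu-C
#' peptide EEQYNSTYR. It stands in for the (unpublished) antibody heavy
#' chain in simulations and examples; it is constructed, not measured.
#'
#' @return Named character vector of length 1.
#' @export
synthetic_protein <- function() {
  c(synthetic_IgG1_heavy_CH2 = paste0(
    "APELLGGPSVFLFPPKPKDTLMISRTPEVTCVVVDVSHEDPEVKFNWYVDGVEVHNAKTKPR",
    "EEQYNSTYRVVSVLTVLHQDWLNGKEYKCKVSNKALPAPIEK"))
}

#' Platform glycoform presets
#'
#' Two stated glycosylation states of the same IgG1 produced on different
#' platforms:
#'
#' * `"hca-n"` (glyco-engineered tobacco plant): 13 glycoforms, tight
#'   distribution dominated by G0, all three glycan classes represented,
#'   ~1% fucosylated, site occupancy 49.1%.
#' * `"hca-mrna"` (mRNA expression in human vaginal epithelial cells): 11
#'   glycoforms, fairly even distribution biased to fucosylated complex
#'   types with G0F/G1F/G2F most abundant, a sialylated species (G2S1F)
#'   present, site occupancy 96.0%.
#'
#' The glycoform counts, dominant species, fucosylation and occupancy
#' values are the stated platform characteristics; the individual filler
#' weights are documented package constants chosen to respect them.
#'
#' @param name `"hca-n"` or `"hca-mrna"`.
#' @return List with `name`, `glycoforms` (data frame `composition`,
#'   `shorthand`, `weight`), `occupancy`, `n_glycoforms`.
#' @export
platform_preset <- function(name = c("hca-n", "hca-mrna")) {
  name <- match.arg(name)
  lib <- glycan_library()
  spec <- switch(name,
    "hca-n" = list(
      occupancy = 0.491,
      w = c(G0 = 0.40, G1 = 0.06, G2 = 0.02,
            Man5 = 0.08, Man6 = 0.05, Man7 = 0.04, Man8 = 0.04, Man9 = 0.03,
            HexNAc3Hex5 = 0.08, HexNAc3Hex6 = 0.05, HexNAc3Hex3 = 0.06,
            G0F = 0.01, monoHexNAc = 0.08)),
    "hca-mrna" = list(
      occupancy = 0.960,
      w = c(G0F = 0.18, G1F = 0.17, G2F = 0.15, G2S1F = 0.09,
            G0 = 0.07, G1 = 0.06, Man5 = 0.07, Man6 = 0.05,
            HexNAc3Hex5 = 0.06, HexNAc5Hex4Fuc1 = 0.04, monoHexNAc = 0.06)))
  comp <- vapply(names(spec$w), function(key) {
    if (key %in% lib$shorthand) format(shorthand_to_composition(key, lib))
    else format(parse_glycan_composition(key))
  }, "")
  gf <- data.frame(composition = unname(comp),
                   shorthand = vapply(comp, function(cc)
                     composition_to_shorthand(parse_glycan_composition(cc), lib), ""),
                   weight = unname(spec$w), stringsAsFactors = FALSE)
  stopifnot(abs(sum(gf$weight) - 1) < 1e-9, !anyDuplicated(gf$composition))
  list(name = name, glycoforms = gf, occupancy = spec$occupancy,
       n_glycoforms = nrow(gf))
}

#' Synthetic-run configuration
#'
#' Defaults encode the emulated acquisition: resolving power 120,000 at
#' m/z 200 scaling as 1/sqrt(m/z), precursor charges 2-3, 97% isotopic
#' purity of the heavy-oxygen water, centroided output with 2 ppm
#' Gaussian m/z jitter, 10% multiplicative intensity noise, 30 random
#' noise peaks per spectrum and a 5% rate of non-glycopeptide decoy MS2
#' scans.
#'
#' @param preset A [platform_preset()] name or list; ignored for custom
#'   `glycoforms`.
#' @param seed Integer seed fixing all randomness.
#' @param glycoforms Optional custom data frame (`composition`/`shorthand`,
#'   `weight`).
#' @param occupancy Optional occupancy override in \[0, 1\].
#' @param protein Protein context (named character vector).
#' @param glycopeptide_seq,glyco_site The sequon-bearing peptide and its
#'   Asn position used for all glycoforms.
#' @param charges Precursor charge states simulated.
#' @param spectra_per_glycoform MS1+MS2 pairs per glycoform per charge.
#' @param resolving_power,rp_ref_mz Instrument resolution model.
#' @param mz_jitter_ppm Gaussian m/z error (s.d., ppm).
#' @param intensity_cv Lognormal intensity coefficient of variation.
#' @param noise_peaks Random noise peaks added per spectrum.
#' @param decoy_rate Fraction of additional peptide-only MS2 decoys.
#' @param label_purity 18O purity of the water in deglyco runs.
#' @param n_ms1_scans MS1 scans in a deglyco run.
#' @param ms2_completeness Probability each theoretical fragment ion is
#'   present in a synthetic MS2 spectrum.
#' @param ms1_n_peaks Isotopologue peaks simulated per envelope.
#' @return List of class `fcg_synth_config`.
#' @export
synth_config <- function(preset = "hca-n", seed = 1L, glycoforms = NULL,
                         occupancy = NULL, protein = synthetic_protein(),
                         glycopeptide_seq = "EEQYNSTYR", glyco_site = 5L,
                         charges = c(2L, 3L), spectra_per_glycoform = 3L,
                         resolving_power = 120000, rp_ref_mz = 200,
                         mz_jitter_ppm = 2, intensity_cv = 0.1,
                         noise_peaks = 30L, decoy_rate = 0.05,
                         label_purity = 0.97, n_ms1_scans = 10L,
                         ms2_completeness = 1.0, ms1_n_peaks = 6L) {
  if (is.character(preset)) preset <- platform_preset(preset)
  if (is.null(glycoforms)) glycoforms <- preset$glycoforms
  if (is.null(occupancy)) occupancy <- preset$occupancy
  if (abs(sum(glycoforms$weight) - 1) > 1e-9)
    stop("glycoform weights must sum to 1")
  stopifnot(occupancy >= 0, occupancy <= 1, resolving_power > 0,
            label_purity > 0, label_purity <= 1)
  structure(list(preset_name = preset$name %||% "custom",
                 glycoforms = glycoforms, occupancy = occupancy,
                 protein = protein, glycopeptide_seq = glycopeptide_seq,
                 glyco_site = as.integer(glyco_site),
                 charges = as.integer(charges),
                 spectra_per_glycoform = as.integer(spectra_per_glycoform),
                 resolving_power = resolving_power, rp_ref_mz = rp_ref_mz,
                 mz_jitter_ppm = mz_jitter_ppm, intensity_cv = intensity_cv,
                 noise_peaks = as.integer(noise_peaks), decoy_rate = decoy_rate,
                 label_purity = label_purity,
                 n_ms1_scans = as.integer(n_ms1_scans),
                 ms2_completeness = ms2_completeness,
                 ms1_n_peaks = as.integer(ms1_n_peaks), seed = as.integer(seed)),
            class = "fcg_synth_config")
}

# predicted FWHM at a given m/z for a resolution defined at a reference m/z
# and scaling as 1/sqrt(m/z) (Orbitrap-like)
.fwhm <- function(mz, rp, ref) mz / (rp * sqrt(ref / mz))

# merge centroids closer than k * FWHM (intensity-weighted m/z, summed
# intensity) - emulates the loss of resolution that makes the unlabeled
# M+3 isotopologue coalesce with the 18O-labeled monoisotopic peak
.centroid_merge <- function(mz, int, rp, ref, k = 1.5) {
  if (length(mz) < 2L) return(list(mz = mz, intensity = int))
  o <- order(mz); mz <- mz[o]; int <- int[o]
  grp <- cumsum(c(1, diff(mz) > k * .fwhm(mz[-length(mz)], rp, ref)))
  list(mz = as.numeric(tapply(mz * int, grp, sum) / tapply(int, grp, sum)),
       intensity = as.numeric(tapply(int, grp, sum)))
}

.jitter_mz <- function(mz, ppm_sd) mz * (1 + stats::rnorm(length(mz), 0, ppm_sd * 1e-6))

.lognoise <- function(n, cv) if (cv <= 0) rep(1, n) else
  stats::rlnorm(n, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2)))

# assemble one centroided synthetic spectrum
.make_spectrum <- function(mz, int, cfg, scan_id, ms_level, precursor_mz = NA,
                           precursor_charge = NA, rt = NA,
                           mz_range = c(100, 2000)) {
  if (cfg$noise_peaks > 0L) {
    nmz <- stats::runif(cfg$noise_peaks, mz_range[1], mz_range[2])
    nint <- stats::rexp(cfg$noise_peaks, rate = 1) * 0.002 * max(int, 1)
    mz <- c(mz, nmz); int <- c(int, nint)
  }
  mz <- .jitter_mz(mz, cfg$mz_jitter_ppm)
  m <- .centroid_merge(mz, int, cfg$resolving_power, cfg$rp_ref_mz)
  spectrum(m$mz, m$intensity, scan_id = scan_id, ms_level = ms_level,
           precursor_mz = precursor_mz, precursor_charge = precursor_charge,
           rt = rt)
}

#' Generate a synthetic glycopeptide MS run with ground truth
#'
#' For every glycoform in the configured profile, at each charge state and
#' replicate, the generator emits an MS1 scan holding the glycopeptide's
#' isotope envelope (monoisotopic height proportional to the glycoform
#' weight, isotopologue shape from [isotope_envelope()]) and a paired HCD
#' MS2 scan holding the full theoretical fragment set
#' ([theoretical_fragments()]: oxonium, Y series, b/y, site-localizing
#' glycosylated b/y), plus noise peaks, intensity noise and m/z jitter.
#' Peptide-only decoy MS2 scans (backbone ions only, no oxonium) are added
#' at `decoy_rate`.
#'
#' @param config A [synth_config()].
#' @return List with `run` (an [ms_run()]), `truth` (data frame: MS2
#'   `scan_id`, `peptide`, `site`, `composition`, `shorthand`, `charge`,
#'   `weight`, `is_decoy`), and `config`.
#' @export
generate_glyco_run <- function(config = synth_config()) {
  stopifnot(inherits(config, "fcg_synth_config"))
  set.seed(config$seed)
  cfg <- config
  prot <- cfg$protein[[1]]
  pstart <- as.integer(regexpr(cfg$glycopeptide_seq, prot, fixed = TRUE))
  if (pstart < 1L) stop("glycopeptide sequence not found in the protein context")
  pep <- peptide(cfg$glycopeptide_seq, pstart,
                 pstart + nchar(cfg$glycopeptide_seq) - 1L)
  spectra <- list(); truth <- list()
  rt <- 0; scan <- 0L
  base_int <- 1e6
  for (i in seq_len(nrow(cfg$glycoforms))) {
    glycan <- parse_glycan_composition(cfg$glycoforms$composition[i])
    gp <- glycopeptide(pep, cfg$glyco_site, glycan)
    env <- isotope_envelope(gp, cfg$ms1_n_peaks)
    env <- env / env[1]
    for (rep in seq_len(cfg$spectra_per_glycoform)) for (z in cfg$charges) {
      rt <- rt + 3
      mono <- glycopeptide_mz(gp, z)
      h <- base_int * cfg$glycoforms$weight[i] * .lognoise(1, cfg$intensity_cv)
      scan <- scan + 1L
      ms1 <- .make_spectrum(mono + (seq_len(cfg$ms1_n_peaks) - 1L) * .neutron / z,
                            h * env, cfg, sprintf("MS1_%04d", scan), 1L,
                            rt = rt, mz_range = c(370, 2000))
      spectra[[length(spectra) + 1L]] <- ms1
      obs_prec <- match_peak(ms1, mono, 20)
      frag <- theoretical_fragments(gp, charges = unique(c(1L, min(2L, z))))
      keep <- stats::runif(nrow(frag)) <= cfg$ms2_completeness
      frag <- frag[keep, , drop = FALSE]
      fint <- c(b = 2e4, y = 2e4, Y = 4e4, B = 8e4)[frag$series]
      fint[frag$series %in% c("b", "y") & frag$remnant != ""] <- 1e4
      fint <- fint * .lognoise(nrow(frag), cfg$intensity_cv)
      scan <- scan + 1L
      spectra[[length(spectra) + 1L]] <- .make_spectrum(
        frag$mz, fint, cfg, sprintf("MS2_%04d", scan), 2L,
        precursor_mz = if (is.null(obs_prec)) mono else obs_prec$mz,
        precursor_charge = z, rt = rt + 1)
      truth[[length(truth) + 1L]] <- data.frame(
        scan_id = sprintf("MS2_%04d", scan), peptide = cfg$glycopeptide_seq,
        site = cfg$glyco_site, composition = cfg$glycoforms$composition[i],
        shorthand = cfg$glycoforms$shorthand[i], charge = z,
        weight = cfg$glycoforms$weight[i], is_decoy = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  # peptide-only decoys: backbone fragments of another digest product
  n_decoy <- round(cfg$decoy_rate * length(truth))
  if (n_decoy > 0) {
    dpep <- peptide("VVSVLTVLHQDWLNGK")
    dgp <- glycopeptide(dpep, NA, glycan_composition())
    dfrag <- theoretical_fragments(dgp, charges = 1L)
    dfrag <- dfrag[dfrag$series %in% c("b", "y"), , drop = FALSE]
    for (d in seq_len(n_decoy)) {
      rt <- rt + 3; scan <- scan + 1L
      z <- sample(cfg$charges, 1L)
      spectra[[length(spectra) + 1L]] <- .make_spectrum(
        dfrag$mz, 2e4 * .lognoise(nrow(dfrag), cfg$intensity_cv), cfg,
        sprintf("MS2_%04d", scan), 2L,
        precursor_mz = (peptide_mass(dpep) + z * mass_constants()$proton) / z,
        precursor_charge = z, rt = rt)
      truth[[length(truth) + 1L]] <- data.frame(
        scan_id = sprintf("MS2_%04d", scan), peptide = dpep$sequence,
        site = NA_integer_, composition = "bare", shorthand = "",
        charge = z, weight = 0, is_decoy = TRUE, stringsAsFactors = FALSE)
    }
  }
  list(run = ms_run(spectra, source = sprintf("synthetic:%s", cfg$preset_name)),
       truth = do.call(rbind, truth), config = cfg)
}

#' Generate a synthetic 18O deglycosylation MS1 run
#'
#' Emulates the MS1 survey of a PNGase-F-in-H2(18)O-treated digest: each
#' scan holds, per charge state, the unlabeled (Asn) peptide envelope at
#' weight (1 - occupancy) and the 18O-labeled (Asp + 18O, +2.98826 Da)
#' envelope at weight occupancy x purity, with the purity remainder
#' leaking to the 16O-deamidation position (+0.98402 Da). Centroids
#' closer than the resolution limit coalesce, reproducing the overlap of
#' the labeled monoisotopic peak with the unlabeled M+3 isotopologue.
#'
#' @param config A [synth_config()]; `occupancy` and `label_purity` are
#'   the governing parameters.
#' @return List with `run` (MS1-only [ms_run()]), `occupancy` (the
#'   generating truth), and `config`.
#' @export
generate_deglyco_run <- function(config = synth_config()) {
  stopifnot(inherits(config, "fcg_synth_config"))
  set.seed(config$seed + 1L)
  cfg <- config
  pep <- peptide(cfg$glycopeptide_seq)
  m <- peptide_mass(pep)
  mc <- mass_constants()
  env_u <- isotope_envelope(pep, cfg$ms1_n_peaks)
  env_u <- env_u / env_u[1]
  dmods <- data.frame(position = cfg$glyco_site, name = "deamidation")
  env_l <- isotope_envelope(peptide(cfg$glycopeptide_seq, mods = dmods),
                            cfg$ms1_n_peaks)
  env_l <- env_l / env_l[1]
  shift_l <- mc$modifications[["deamidation_18O"]]
  shift_d <- mc$modifications[["deamidation"]]
  o <- cfg$occupancy; pur <- cfg$label_purity
  base_int <- 1e6
  spectra <- vector("list", cfg$n_ms1_scans)
  for (k in seq_len(cfg$n_ms1_scans)) {
    mz <- numeric(); int <- numeric()
    for (z in cfg$charges) {
      mz_u <- (m + z * mc$proton) / z
      lad <- (seq_len(cfg$ms1_n_peaks) - 1L) * .neutron / z
      h <- base_int * .lognoise(1, cfg$intensity_cv)
      if (o < 1) { mz <- c(mz, mz_u + lad); int <- c(int, h * (1 - o) * env_u) }
      if (o > 0) {
        hl <- base_int * .lognoise(1, cfg$intensity_cv)
        mz <- c(mz, mz_u + shift_l / z + lad)
        int <- c(int, hl * o * pur * env_l)
        if (pur < 1) {
          mz <- c(mz, mz_u + shift_d / z + lad)
          int <- c(int, hl * o * (1 - pur) * env_l)
        }
      }
    }
    spectra[[k]] <- .make_spectrum(mz, int, cfg, sprintf("MS1_%04d", k), 1L,
                                   rt = 3 * k, mz_range = c(370, 2000))
  }
  list(run = ms_run(spectra, source = sprintf("synthetic-deglyco:%s", cfg$preset_name)),
       occupancy = o, config = cfg)
}
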