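test_that("platform presets encode the stated glycosylation states", {
  n <- platform_preset("hca-n")
  m <- platform_preset("hca-mrna")
  expect_equal(n$n_glycoforms, 13L)
  expect_equal(m$n_glycoforms, 11L)
  expect_equal(n$occupancy, 0.491)
  expect_equal(m$occupancy, 0.960)
  expect_equal(sum(n$glycoforms$weight), 1)
  expect_equal(sum(m$glycoforms$weight), 1)
  # plant product: G0 dominant, ~1% fucosylated, all three classes present
  expect_identical(n$glycoforms$shorthand[which.max(n$glycoforms$weight)], "G0")
  lib <- glycan_library()
  cls <- lib$class[match(n$glycoforms$composition, lib$composition)]
  expect_true(all(c("oligomannose", "hybrid", "complex") %in% cls))
  fuc <- grepl("Fuc", n$glycoforms$composition)
  expect_lte(sum(n$glycoforms$weight[fuc]), 0.02)
  # mRNA product: fucosylated complex bias, G0F/G1F/G2F on top, G2S1F present
  top3 <- m$glycoforms$shorthand[order(-m$glycoforms$weight)][1:3]
  expect_setequal(top3, c("G0F", "G1F", "G2F"))
  expect_true("G2S1F" %in% m$glycoforms$shorthand)
  expect_true("monoHexNAc" %in% m$glycoforms$shorthand)
})

test_that("generation is deterministic given a seed, byte for byte", {
  t1 <- tempfile(fileext = ".mgf"); t2 <- tempfile(fileext = ".mgf")
  write_mgf(generate_glyco_run(synth_config("hca-n", seed = 7,
                                            spectra_per_glycoform = 1L))$run, t1)
  write_mgf(generate_glyco_run(synth_config("hca-n", seed = 7,
                                            spectra_per_glycoform = 1L))$run, t2)
  expect_identical(readLines(t1), readLines(t2))
  d1 <- generate_deglyco_run(synth_config("hca-mrna", seed = 7))
  d2 <- generate_deglyco_run(synth_config("hca-mrna", seed = 7))
  write_mgf(d1$run, t1); write_mgf(d2$run, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("ground truth accompanies every generated MS2 spectrum", {
  g <- generate_glyco_run(synth_config("hca-n", seed = 8,
                                       spectra_per_glycoform = 1L))
  ms2_ids <- vapply(Filter(function(s) s$ms_level == 2L, g$run$spectra),
                    `[[`, "", "scan_id")
  expect_setequal(g$truth$scan_id, ms2_ids)
  expect_equal(length(unique(g$truth$composition[!g$truth$is_decoy])), 13L)
})

test_that("invalid generator configurations are rejected", {
  bad <- data.frame(composition = c("HexNAc4Hex3", "HexNAc2Hex5"),
                    shorthand = c("G0", "Man5"), weight = c(0.6, 0.3))
  expect_error(synth_config("hca-n", glycoforms = bad), "sum to 1")
  expect_error(synth_config("hca-n", occupancy = 1.2), "occupancy")
})

test_that("MS1 envelope shapes agree with the isotope model", {
  q <- generate_glyco_run(quiet_config(10, spectra_per_glycoform = 1L,
                                       charges = 2L))
  gp <- glycopeptide(peptide("EEQYNSTYR"), 5,
                     parse_glycan_composition(q$truth$composition[1]))
  env <- isotope_envelope(gp, 4)
  ms1 <- q$run$spectra[[1]]
  mono <- glycopeptide_mz(gp, 2L)
  h <- vapply(0:3, function(k)
    match_peak(ms1, mono + k * 1.0033548 / 2, 10)$intensity, 0)
  expect_equal(h / h[1], env / env[1], tolerance = 1e-6)
})

test_that("deglyco runs respect the occupancy extremes", {
  mc <- mass_constants()
  m <- peptide_mass("EEQYNSTYR")
  d0 <- generate_deglyco_run(synth_config("hca-n", seed = 11, occupancy = 0,
                                          noise_peaks = 0L))
  d1 <- generate_deglyco_run(synth_config("hca-n", seed = 11, occupancy = 1,
                                          noise_peaks = 0L))
  for (z in c(2L, 3L)) {
    mz_u <- (m + z * mc$proton) / z
    mz_l <- mz_u + mc$modifications[["deamidation_18O"]] / z
    s0 <- d0$run$spectra[[1]]; s1 <- d1$run$spectra[[1]]
    expect_false(is.null(match_peak(s0, mz_u, 10)))
    expect_true(is.null(match_peak(s0, mz_l, 10)))   # no label at occupancy 0
    expect_true(is.null(match_peak(s1, mz_u, 10)))   # no unlabeled at occupancy 1
    expect_false(is.null(match_peak(s1, mz_l, 10)))
  }
})
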