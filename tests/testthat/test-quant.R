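test_that("isotope envelopes match the brute-force convolution oracle", {
  expect_lte(abs(isotope_envelope("G", 2)[2] - 0.025), 0.005)
  expect_identical(isotope_envelope("G", 1), 1)
  for (seq in c("EEQYNSTYR", "VVSVLTVLHQDWLNGK", "MCW")) {
    f <- molecular_formula(seq)
    expect_equal(isotope_envelope(seq, 5), oracle_envelope(f, 5),
                 tolerance = 1e-3)
  }
  gp <- glycopeptide(peptide("EEQYNSTYR"), 5, glycan_composition(4, 3))
  expect_equal(isotope_envelope(gp, 4), oracle_envelope(molecular_formula(gp), 4),
               tolerance = 1e-3)
  expect_error(isotope_envelope("B"), "unknown residue")
})

# an idealised deglyco MS1 scan with specified mono heights per species
deglyco_scan <- function(unlab, lab, z = 2L, id = "m1") {
  mc <- mass_constants()
  m <- peptide_mass("EEQYNSTYR")
  mz_u <- (m + z * mc$proton) / z
  mz_l <- mz_u + mc$modifications[["deamidation_18O"]] / z
  spectrum(c(mz_u, mz_l)[c(unlab, lab) > 0], c(unlab, lab)[c(unlab, lab) > 0],
           id, 1L)
}

test_that("occupancy reduces to labeled / (labeled + unlabeled) heights", {
  run <- ms_run(list(deglyco_scan(100, 100)))
  occ <- occupancy_18O(run, "EEQYNSTYR", 5, charges = 2L,
                       correct_isotope = FALSE)
  expect_equal(occ$occupied, 0.5)
  occ2 <- occupancy_18O(ms_run(list(deglyco_scan(0, 50))), "EEQYNSTYR", 5,
                        charges = 2L, correct_isotope = FALSE)
  expect_equal(occ2$occupied, 1.0)
  occ3 <- occupancy_18O(ms_run(list(deglyco_scan(0, 0, id = "m0"))),
                        "EEQYNSTYR", 5, charges = 2L)
  expect_false(occ3$quantifiable)
  expect_true(is.na(occ3$occupied))
})

test_that("occupancy input contracts are enforced", {
  run <- ms_run(list(deglyco_scan(10, 10)))
  expect_error(occupancy_18O(run, "EEQYNSTYR", 2), "Asn")
  ms2only <- ms_run(list(spectrum(1, 1, "x", 2L, precursor_mz = 5)))
  expect_error(occupancy_18O(ms2only, "EEQYNSTYR", 5), "MS1")
})

test_that("the M+3 isotopologue correction removes the zero-occupancy bias", {
  occs <- sapply(1:5, function(s) {
    d <- generate_deglyco_run(synth_config("hca-n", seed = s, occupancy = 0))
    c(on = occupancy_18O(d$run, "EEQYNSTYR", 5)$occupied,
      off = occupancy_18O(d$run, "EEQYNSTYR", 5, correct_isotope = FALSE)$occupied)
  })
  expect_true(all(occs["on", ] <= 0.01))
  expect_true(all(occs["off", ] > occs["on", ]))
})

test_that("occupancy recovery is unbiased across the curve", {
  for (o in c(0.1, 0.25, 0.491, 0.75, 0.96)) {
    rec <- sapply(1:6, function(s) {
      d <- generate_deglyco_run(synth_config("hca-n", seed = 100 * s,
                                             occupancy = o))
      occupancy_18O(d$run, "EEQYNSTYR", 5)$occupied
    })
    expect_lte(abs(mean(rec) - o), 0.02)
  }
})

test_that("occupancy is invariant to uniform intensity scaling", {
  d <- generate_deglyco_run(synth_config("hca-mrna", seed = 9))
  o1 <- occupancy_18O(d$run, "EEQYNSTYR", 5)$occupied
  scaled <- ms_run(lapply(d$run$spectra, function(s)
    spectrum(s$mz, s$intensity * 1e3, s$scan_id, s$ms_level, rt = s$rt)))
  expect_equal(occupancy_18O(scaled, "EEQYNSTYR", 5)$occupied, o1,
               tolerance = 1e-12)
})

test_that("glycoform profiles normalize to one and renormalize on removal", {
  q <- generate_glyco_run(synth_config("hca-n", seed = 51,
                                       spectra_per_glycoform = 2L))
  res <- search_run(q$run, synthetic_protein())
  glyco <- res[res$composition != "bare", ]
  prof <- glycoform_profile(glyco, q$run)
  expect_equal(sum(prof$fraction), 1, tolerance = 1e-9)
  drop1 <- glycoform_profile(glyco[glyco$composition != prof$composition[1], ],
                             q$run)
  keep <- prof[-1, ]
  expect_equal(drop1$fraction[match(keep$composition, drop1$composition)],
               keep$fraction / sum(keep$fraction), tolerance = 1e-9)
})

test_that("profile fractions recover the generating weights", {
  gf <- data.frame(composition = c("HexNAc4Hex3", "HexNAc4Hex3Fuc1", "HexNAc2Hex5"),
                   shorthand = c("G0", "G0F", "Man5"),
                   weight = c(0.6, 0.3, 0.1))
  g <- generate_glyco_run(synth_config("hca-n", seed = 52, glycoforms = gf,
                                       spectra_per_glycoform = 3L))
  res <- search_run(g$run, synthetic_protein())
  prof <- glycoform_profile(res[res$composition != "bare", ], g$run)
  expect_equal(nrow(prof), 3L)
  got <- prof$fraction[match(gf$composition, prof$composition)]
  expect_true(all(abs(got - gf$weight) <= 0.05))
})

test_that("degenerate profile inputs are handled", {
  q <- generate_glyco_run(quiet_config(53, spectra_per_glycoform = 1L))
  res <- search_run(q$run, synthetic_protein())
  one <- res[res$composition == res$composition[res$composition != "bare"][1], ]
  prof1 <- glycoform_profile(one, q$run)
  expect_equal(prof1$fraction, 1.0)
  empty <- glycoform_profile(res[0, ], q$run)
  expect_equal(nrow(empty), 0L)
})
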