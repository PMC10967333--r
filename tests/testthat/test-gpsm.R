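# a noiseless spectrum holding exactly the theoretical ions of gp
perfect_spectrum <- function(gp, z = 2L, scan = "perfect") {
  frag <- theoretical_fragments(gp, charges = c(1L, 2L))
  spectrum(frag$mz, rep(100, nrow(frag)), scan, 2L,
           precursor_mz = glycopeptide_mz(gp, z), precursor_charge = z)
}

fc_peptides <- digest(synthetic_protein()[[1]], max_missed = 2)

test_that("candidate generation matches precursors within tolerance", {
  fc_peptides$protein <- "hc"
  cand <- generate_candidates(1244.4976, 2L, fc_peptides)
  expect_true(any(cand$sequence == "EEQYNSTYR" & cand$site == 5 &
                    cand$composition == "HexNAc4Hex3"))
  bare <- generate_candidates(595.2596, 2L, fc_peptides)
  expect_true(any(bare$sequence == "EEQYNSTYR" & bare$composition == "bare"))
  expect_equal(nrow(generate_candidates(4999.99, 2L, fc_peptides)), 0L)
})

test_that("theoretical fragments include the site-defining ions", {
  gp <- glycopeptide(peptide("EEQYNSTYR", 293, 301), 5, glycan_composition(4, 3))
  frag <- theoretical_fragments(gp)
  expect_true(any(frag$series == "y" & frag$index == 5 & frag$remnant == "HexNAc1"))
  expect_true(any(frag$series == "y" & frag$index == 5 & frag$remnant == "HexNAc2"))
  expect_true(any(frag$series == "b" & frag$index == 5 & frag$remnant == "HexNAc1"))
  y0 <- frag$mz[frag$series == "Y" & frag$index == 0 & frag$charge == 1]
  expect_equal(y0, 1189.5120, tolerance = 1e-4)
  # full b/y ladders at each charge
  expect_equal(sum(frag$series == "b" & frag$remnant == "" & frag$charge == 1), 8L)
  expect_equal(sum(frag$series == "y" & frag$remnant == "" & frag$charge == 1), 8L)
  # length-1 peptide: no backbone ions
  gp1 <- glycopeptide(peptide("G"), NA, glycan_composition())
  expect_false(any(theoretical_fragments(gp1)$series %in% c("b", "y")))
})

test_that("self-match scores high with site localization; empty scores zero", {
  gp <- glycopeptide(peptide("EEQYNSTYR", 293, 301), 5, glycan_composition(4, 3))
  g <- score_gpsm(perfect_spectrum(gp), gp)
  expect_gte(g$score, 90)
  expect_true(g$site_localized)
  empty <- spectrum(numeric(), numeric(), "e", 2L, precursor_mz = 1244.4976,
                    precursor_charge = 2L)
  expect_equal(score_gpsm(empty, gp)$score, 0)
})

test_that("the wrong glycan scores strictly below the generating one", {
  pep <- peptide("EEQYNSTYR", 293, 301)
  true_gp <- glycopeptide(pep, 5, glycan_composition(4, 3))
  sp <- perfect_spectrum(true_gp)
  wrong <- glycopeptide(pep, 5, glycan_composition(4, 4))
  expect_lt(score_gpsm(sp, wrong)$score, score_gpsm(sp, true_gp)$score)
})

test_that("the score is invariant to peak order and intensity rescaling", {
  gp <- glycopeptide(peptide("EEQYNSTYR", 293, 301), 5, glycan_composition(4, 3))
  sp <- perfect_spectrum(gp)
  s0 <- score_gpsm(sp, gp)$score
  set.seed(3)
  perm <- sample(length(sp$mz))
  sp2 <- spectrum(sp$mz[perm], sp$intensity[perm] * 17.5, "p", 2L,
                  precursor_mz = sp$precursor_mz, precursor_charge = 2L)
  expect_equal(score_gpsm(sp2, gp)$score, s0)
})

test_that("matched fragments re-verify within tolerance when recomputed", {
  gp <- glycopeptide(peptide("EEQYNSTYR", 293, 301), 5, glycan_composition(4, 3))
  g <- score_gpsm(perfect_spectrum(gp), gp, tol_ppm = 20)
  frag <- theoretical_fragments(gp, charges = c(1L, 2L))
  for (i in seq_len(nrow(g$matched))) {
    th <- frag$mz[frag$label == g$matched$label[i]]
    expect_lte(abs(g$matched$obs_mz[i] - th) / th * 1e6, 20)
  }
})

test_that("search identifies every spectrum on a noiseless run", {
  q <- generate_glyco_run(quiet_config(41, spectra_per_glycoform = 1L))
  res <- search_run(q$run, synthetic_protein())
  m <- merge(res, q$truth, by = "scan_id", suffixes = c("", ".t"))
  expect_equal(nrow(m), nrow(q$truth))
  expect_identical(m$composition, m$composition.t)
  expect_true(all(m$site == m$site.t))
  # rich glycans leave a deep Y ladder; the single-rung monoHexNAc caps lower
  sugars <- vapply(m$composition, function(cc)
    sum(parse_glycan_composition(cc)), 0L)
  expect_true(all(m$score[sugars >= 4] >= 90))
  expect_true(all(m$score >= 70))
})

test_that("search accuracy stays above 95% at default noise", {
  g <- generate_glyco_run(synth_config("hca-n", seed = 42,
                                       spectra_per_glycoform = 2L))
  res <- search_run(g$run, synthetic_protein())
  m <- merge(res, g$truth, by = "scan_id", suffixes = c("", ".t"))
  m <- m[!m$is_decoy, ]
  expect_gte(mean(m$composition == m$composition.t), 0.95)
})

test_that("a run of plain peptide spectra yields no glycopeptide matches", {
  q <- generate_glyco_run(synth_config("hca-n", seed = 43, noise_peaks = 0L,
                                       mz_jitter_ppm = 0, intensity_cv = 0,
                                       spectra_per_glycoform = 1L,
                                       decoy_rate = 0.5))
  decoy_ids <- q$truth$scan_id[q$truth$is_decoy]
  keep <- Filter(function(s) s$ms_level == 2L && s$scan_id %in% decoy_ids,
                 q$run$spectra)
  res <- search_run(ms_run(keep), synthetic_protein())
  expect_equal(sum(res$composition != "bare"), 0L)
})

test_that("search output ordering and ties are deterministic", {
  g <- generate_glyco_run(synth_config("hca-mrna", seed = 44,
                                       spectra_per_glycoform = 1L))
  r1 <- search_run(g$run, synthetic_protein())
  r2 <- search_run(g$run, synthetic_protein())
  expect_identical(r1, r2)
})
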