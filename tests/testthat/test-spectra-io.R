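test_that("MGF round trip preserves a small run", {
  run <- ms_run(list(
    spectrum(c(100.1, 200.2), c(10, 20), "s1", 2L, precursor_mz = 500.25,
             precursor_charge = 2L, rt = 12.5,
             metadata = list(COLLISION = "HCD30")),
    spectrum(c(371.1, 800.8, 1200.0), c(5, 1, 3), "s2", 1L, rt = 13)))
  tmp <- tempfile(fileext = ".mgf")
  write_mgf(run, tmp)
  back <- read_mgf(tmp)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    expect_equal(back$spectra[[i]]$mz, run$spectra[[i]]$mz, tolerance = 1e-4)
    expect_equal(back$spectra[[i]]$intensity, run$spectra[[i]]$intensity,
                 tolerance = 1e-3)
    expect_identical(back$spectra[[i]]$ms_level, run$spectra[[i]]$ms_level)
    expect_identical(back$spectra[[i]]$scan_id, run$spectra[[i]]$scan_id)
  }
  expect_equal(back$spectra[[1]]$precursor_mz, 500.25, tolerance = 1e-4)
  expect_identical(back$spectra[[1]]$metadata$COLLISION, "HCD30")
})

test_that("MGF edge cases behave by contract", {
  tmp <- tempfile(fileext = ".mgf")
  writeLines(character(), tmp)
  expect_equal(length(read_mgf(tmp)), 0L)
  writeLines(c("BEGIN IONS", "TITLE=x", "100.0 1.0", "END IONS"), tmp)
  expect_error(read_mgf(tmp), "PEPMASS")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=500.1"), tmp)
  expect_error(read_mgf(tmp), "END IONS")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=500.1", "abc def", "END IONS"), tmp)
  expect_error(read_mgf(tmp), "line 4")
})

test_that("MGF round trip is idempotent over random runs", {
  set.seed(5)
  spectra <- lapply(1:300, function(i) {
    n <- sample(5:40, 1)
    spectrum(sort(runif(n, 100, 2000)) + seq_len(n) * 1e-3, rexp(n) * 1e4,
             paste0("r", i), 2L, precursor_mz = runif(1, 400, 1500),
             precursor_charge = sample(2:4, 1), rt = i)
  })
  t1 <- tempfile(fileext = ".mgf"); t2 <- tempfile(fileext = ".mgf")
  write_mgf(ms_run(spectra), t1)
  write_mgf(read_mgf(t1), t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(1, 2), c(-1, 1), "a", 2L, precursor_mz = 5), "non-negative")
  expect_error(spectrum(1, 1, "a", 2L), "precursor")
  s <- spectrum(c(3, 1, 2, 2), c(1, 1, 1, 1), "a", 1L)  # sorts, merges duplicates
  expect_identical(s$mz, c(1, 2, 3))
  expect_identical(s$intensity, c(1, 2, 1))
  expect_error(ms_run(list(spectrum(1, 1, "a", 1L), spectrum(2, 1, "a", 1L))),
               "unique")
})

test_that("ppm peak matching picks the most intense in-tolerance peak", {
  s <- spectrum(c(204.0867, 204.0960, 500), c(10, 50, 1), "a", 1L)
  hit <- match_peak(s, 204.0867, 15)
  expect_equal(hit$mz, 204.0867)  # the intense peak at +46 ppm is ignored
  s2 <- spectrum(c(204.0867, 204.0869), c(10, 50), "a", 1L)
  expect_equal(match_peak(s2, 204.0867, 15)$mz, 204.0869)  # intensity wins
  expect_null(match_peak(spectrum(204.0898, 1, "a", 1L), 204.0867, 15))
  expect_null(match_peak(spectrum(numeric(), numeric(), "a", 1L), 204.0867, 15))
})

test_that("peak matching is invariant under uniform m/z rescaling", {
  set.seed(8)
  s <- spectrum(sort(runif(30, 100, 2000)), rexp(30), "a", 1L)
  for (target in sample(s$mz, 5)) {
    h1 <- match_peak(s, target, 12)
    s2 <- spectrum(s$mz * 1.5, s$intensity, "a", 1L)
    h2 <- match_peak(s2, target * 1.5, 12)
    expect_equal(h1$intensity, h2$intensity)
    expect_equal(h1$ppm, h2$ppm, tolerance = 1e-6)
  }
})

test_that("the minimal mzML reader handles centroided spectra", {
  spectra <- list(
    list(id = "scan=1", ms_level = 1L, rt = 60, mz = c(400.12345, 500.5),
         intensity = c(1e5, 2e5)),
    list(id = "scan=2", ms_level = 2L, rt = 61, mz = c(204.0867, 366.1396),
         intensity = c(10, 20), precursor_mz = 1244.4976, charge = 2L))
  for (compress in c(TRUE, FALSE)) {
    tmp <- tempfile(fileext = ".mzML")
    make_mzml(tmp, spectra, compress = compress)
    run <- read_mzml(tmp)
    expect_equal(length(run), 2L)
    expect_equal(run$spectra[[1]]$mz, spectra[[1]]$mz, tolerance = 1e-6)
    expect_equal(run$spectra[[1]]$rt, 60)
    expect_identical(run$spectra[[2]]$ms_level, 2L)
    expect_equal(run$spectra[[2]]$precursor_mz, 1244.4976)
    expect_identical(run$spectra[[2]]$precursor_charge, 2L)
  }
  # 32-bit arrays
  tmp <- tempfile(fileext = ".mzML")
  make_mzml(tmp, spectra[1], size = 4L)
  expect_equal(read_mzml(tmp)$spectra[[1]]$mz, spectra[[1]]$mz, tolerance = 1e-3)
})
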