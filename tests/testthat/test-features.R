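test_that("peak counting follows the local-max-above-standard rule", {
  spec <- spectrum_bcg(1:7, c(0, 1, 4, 1, 0, 2, 0), df = 1)
  half <- find_peaks(spec, 0.5)     # theta = 2: the 2-bin is not > theta
  expect_equal(half$count, 1L)
  expect_equal(half$peaks$peak_freq, 3)
  quarter <- find_peaks(spec, 0.25) # theta = 1: both local maxima qualify
  expect_equal(quarter$count, 2L)
  expect_equal(oracle_count(spec$power, 0.5 * 4), 1L)
  expect_equal(oracle_count(spec$power, 0.25 * 4), 2L)

  # two equal maxima both count
  spec2 <- spectrum_bcg(1:5, c(0, 3, 0, 3, 0), df = 1)
  expect_equal(find_peaks(spec2, 0.5)$count, 2L)

  # a flat-topped plateau is credited once, to its leftmost bin
  spec3 <- spectrum_bcg(1:6, c(0, 4, 4, 4, 1, 0), df = 1)
  ps <- find_peaks(spec3, 0.5)
  expect_equal(ps$count, 1L)
  expect_equal(ps$peaks$peak_freq, 2)

  # the band-edge global maximum is countable (one-sided test)
  spec4 <- spectrum_bcg(1:4, c(5, 3, 1, 0), df = 1)
  expect_equal(find_peaks(spec4, 0.5)$count, 1L)
})

test_that("the triangular toy spectrum reproduces the worked areas", {
  spec <- spectrum_bcg(0:2, c(0, 4, 0), df = 1)
  half <- find_peaks(spec, 0.5)
  expect_equal(half$total_area, 1.0, tolerance = 1e-12)
  expect_equal(half$peaks$region_lo, 0.5)
  expect_equal(half$peaks$region_hi, 1.5)
  quarter <- find_peaks(spec, 0.25)
  expect_equal(quarter$total_area, 2.25, tolerance = 1e-12)

  f <- extract_features(spec)
  expect_equal(f$n_peaks, 1)
  expect_equal(f$sharpness, 1 / 3.25, tolerance = 1e-12)

  # and the independent refined-grid oracle agrees
  expect_equal(oracle_area(spec$freqs, spec$power, 2), 1.0, tolerance = 1e-6)
  expect_equal(oracle_area(spec$freqs, spec$power, 1), 2.25, tolerance = 1e-6)
})

test_that("merged regions are counted once in area but per-maximum in count", {
  # two local maxima above theta sharing one above-threshold excursion
  spec <- spectrum_bcg(1:7, c(0, 4, 3.5, 4, 0, 0, 0), df = 1)
  ps <- find_peaks(spec, 0.5)
  expect_equal(ps$count, 2L)
  expect_equal(nrow(ps$regions), 1L)
  expect_equal(ps$total_area, oracle_area(spec$freqs, spec$power, 2),
               tolerance = 1e-9)
})

test_that("widening a peak at constant height halves the sharpness", {
  narrow <- spectrum_bcg(0:2, c(0, 4, 0), df = 1)
  wide <- spectrum_bcg(0:4, c(0, 2, 4, 2, 0), df = 1)
  fn <- extract_features(narrow)
  fw <- extract_features(wide)
  expect_equal(fn$n_peaks, fw$n_peaks)
  expect_equal(fw$sharpness, fn$sharpness / 2, tolerance = 1e-12)
})

test_that("counts and areas match the brute-force oracle on random spectra", {
  set.seed(12)
  for (i in 1:60) {
    spec <- random_spectrum()
    for (fr in c(0.5, 0.25)) {
      ps <- find_peaks(spec, fr)
      oc <- oracle_peaks(spec, fr)
      expect_identical(ps$count, oc$count)
      expect_equal(ps$total_area, oc$total_area,
                   tolerance = 1e-6 * max(oc$total_area, 1e-12))
    }
  }
})

test_that("the quarter standard admits at least the half-standard peaks", {
  set.seed(13)
  for (i in 1:50) {
    spec <- random_spectrum()
    f <- extract_features(spec)
    expect_gte(f$n_quarter, f$n_half)
    expect_gte(f$n_half, 1L)
    expect_true(is.finite(f$sharpness) && f$sharpness > 0)
  }
})

test_that("degenerate spectra are rejected", {
  expect_error(find_peaks(spectrum_bcg(1:2, c(1, 2), df = 1)), "3 bins")
  expect_error(find_peaks(spectrum_bcg(1:3, c(0, 0, 0), df = 1)), "zero maximum")
})
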