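# Mean residue ellipticity, helicity, melt fits and isodichroic detection.

test_that("MRE conversion follows the 3300 M dA / (l c n) rule and its
           linearity", {
  wl <- seq(190, 260, by = 1)
  zero <- cd_spectrum(wl, rep(0, length(wl)), "deltaA",
                      meta = list(l = 0.1, c = 0.1, M = 15922, n = 143))
  expect_true(all(to_mre(zero)$signal == 0))
  one <- cd_spectrum(wl, rep(1e-3, length(wl)), "deltaA",
                     meta = list(l = 0.1, c = 0.1, M = 15922, n = 143))
  expect_equal(to_mre(one)$signal[1],
               3300 * 15922 * 1e-3 / (0.1 * 0.1 * 143))
  # linear in dA, inverse-linear in l, c and n
  expect_equal(to_mre(one, c = 0.2)$signal, to_mre(one)$signal / 2)
  expect_equal(to_mre(one, l = 0.05)$signal, to_mre(one)$signal * 2)
  two <- cd_spectrum(wl, rep(2e-3, length(wl)), "deltaA", meta = one$meta)
  expect_equal(to_mre(two)$signal, 2 * to_mre(one)$signal)
  nometa <- cd_spectrum(wl, rep(1e-3, length(wl)), "deltaA")
  expect_error(to_mre(nometa), "metadata")
})

test_that("helicity fraction hits its endpoints and asymptote", {
  n <- 143
  hmax <- -40000 * (1 - 2.5 / n)
  expect_equal(as.numeric(helicity_fraction(hmax, n)), 1)
  expect_equal(as.numeric(helicity_fraction(0, n)), 0)
  expect_equal(as.numeric(helicity_fraction(hmax / 2, n)), 0.5)
  expect_warning(f <- helicity_fraction(hmax * 1.2, n), "clipped")
  expect_equal(as.numeric(f), 1)
  # infinite-chain limit
  expect_equal(as.numeric(helicity_fraction(-20000, 1e6)), 0.5,
               tolerance = 1e-4)
  expect_error(helicity_fraction(-1000, 2), "exceed")
})

test_that("double-wavelength classification assigns centroids and flags
           the boundary", {
  expect_identical(classify_rc_pmg(-18900, -1700)$class, "RC-like")
  expect_identical(classify_rc_pmg(-10700, -3900)$class, "PMG-like")
  # any point is boundary when the tolerance is made extreme
  expect_identical(classify_rc_pmg(-15000, -2800, boundary_tol = 10)$class,
                   "boundary")
})

test_that("noiseless melts are recovered exactly and degenerate ones
           rejected", {
  m <- gen_melt(Tm = 51, slope = 5, noise_frac = 0)
  f <- melt_fit(m$temperature, m$signal)
  expect_equal(f$Tm, 51, tolerance = 1e-6)
  expect_equal(f$slope, 5, tolerance = 1e-6)
  expect_identical(f$quality, "good")
  expect_error(melt_fit(20:60, rep(1, 41)), "flat")
  expect_error(melt_fit(1:5, 1:5), "8")
})

test_that("melt midpoint recovery is unbiased at 5% noise", {
  tms <- sapply(1:50, function(s) {
    m <- gen_melt(Tm = 51, noise_frac = 0.05, seed = s)
    melt_fit(m$temperature, m$signal)$Tm
  })
  expect_lt(abs(mean(tms) - 51), 0.5)
})

test_that("a transition outside the measured range is flagged as poor", {
  m <- gen_melt(Tm = 95, slope = 5, noise_frac = 0.01, seed = 2,
                temperature = seq(20, 80, 1))
  f <- suppressWarnings(melt_fit(m$temperature, m$signal))
  expect_identical(f$quality, "poor")
})

test_that("isodichroic detection finds the constructed crossing and
           rejects crossing-free families", {
  fam <- gen_cd_family(crossing = 205, snr = 100, seed = 4)
  ip <- isodichroic_point(fam)
  expect_true(ip$detected)
  expect_equal(ip$wavelength, 205, tolerance = 1)
  # parallel spectra never cross
  wl <- fam[[1]]$wavelength
  base <- fam[[1]]$signal
  parallel <- lapply(c(0, 4000, -4000), function(off)
    cd_spectrum(wl, base + off, "mre"))
  ip2 <- isodichroic_point(parallel)
  expect_false(ip2$detected)
  # identical spectra are degenerate, not a detection
  ip3 <- isodichroic_point(rep(list(fam[[1]]), 3))
  expect_false(ip3$detected)
  expect_match(ip3$note, "degenerate")
  short <- cd_spectrum(wl[-1], base[-1], "mre")
  expect_error(isodichroic_point(list(fam[[1]], fam[[2]], short)), "grid")
})
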