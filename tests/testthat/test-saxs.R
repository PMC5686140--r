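# Guinier analysis, indirect Fourier transform, shape diagnostics and
# expected-size calculators.

test_that("Guinier fit recovers analytic model radii without noise", {
  q <- dense_q()
  sph <- gen_saxs(q, "sphere", list(R = 50), snr = Inf)
  g <- guinier_fit(sph)
  expect_equal(g$Rg, 50 * sqrt(3 / 5), tolerance = 0.01)
  coil <- gen_saxs(q, "debye_coil", list(Rg = 35), snr = Inf)
  g2 <- guinier_fit(coil)
  expect_equal(g2$Rg, 35, tolerance = 0.01)
  expect_lte(g$qRg_max_used, 1.3 + 1e-6)
})

test_that("Guinier refit of a pure Gaussian is idempotent", {
  q <- dense_q(200)
  rg0 <- 30
  I <- exp(-q^2 * rg0^2 / 3)
  cv <- scattering_curve(q, I, I * 1e-6)
  expect_equal(guinier_fit(cv)$Rg, rg0, tolerance = 1e-6)
  # and the back-transform of the fit itself refits identically
  g <- guinier_fit(cv)
  I2 <- g$I0 * exp(-q^2 * g$Rg^2 / 3)
  g2 <- guinier_fit(scattering_curve(q, I2, I2 * 1e-6))
  expect_equal(g2$Rg, g$Rg, tolerance = 1e-6)
})

test_that("noisy coil curves are recovered without bias", {
  q <- dense_q()
  rel <- sapply(1:20, function(s)
    guinier_fit(gen_saxs(q, "debye_coil", list(Rg = 35), snr = 50,
                         seed = s))$Rg / 35 - 1)
  expect_lt(abs(mean(rel)), 0.02)
})

test_that("flat and underdetermined curves are rejected", {
  q <- dense_q(50)
  flat <- scattering_curve(q, rep(2, 50), rep(0.01, 50))
  expect_error(guinier_fit(flat), "non-Guinier")
  tiny <- scattering_curve(q[1:4], exp(-q[1:4]^2 * 100), rep(0.01, 4))
  expect_error(guinier_fit(tiny), "5")
})

test_that("indirect transform recovers the sphere distance distribution", {
  q <- dense_q()
  cv <- gen_saxs(q, "sphere", list(R = 30), snr = Inf, seed = 2)
  pr <- suppressWarnings(auto_dmax(cv))
  expect_equal(pr$Dmax, 60, tolerance = 0.05)
  expect_equal(pr$Rg, 30 * sqrt(3 / 5), tolerance = 0.01)
  # analytic sphere distance distribution, normalized rms < 0.05
  x <- pr$r / 30
  pan <- ifelse(pr$r <= 60, pr$r^2 * (1 - 3 * x / 4 + x^3 / 16), 0)
  sc <- sum(pr$pr * pan) / sum(pan^2)
  expect_lt(sqrt(mean((pr$pr - sc * pan)^2)) / max(sc * pan), 0.05)
})

test_that("transform of the fitted P(r) reproduces the curve (identity)", {
  q <- dense_q(300)
  cv <- gen_saxs(q, "sphere", list(R = 30), snr = Inf, seed = 2)
  f <- ift_pr(cv, 60)
  expect_lt(f$chi2, 0.1)
  expect_lt(max(abs(f$I_fit - cv$I)) / max(cv$I), 1e-3)
})

test_that("coil P(r) radius agrees with the Guinier radius", {
  q <- dense_q()
  cv <- gen_saxs(q, "debye_coil", list(Rg = 35), snr = 200, seed = 3)
  g <- guinier_fit(cv)
  pr <- suppressWarnings(auto_dmax(cv, g))
  expect_equal(pr$Rg, g$Rg, tolerance = 0.02 * g$Rg)
})

test_that("Porod diagnostics separate spheres from coils", {
  q <- dense_q()
  sph <- gen_saxs(q, "sphere", list(R = 30), snr = Inf)
  ps <- porod_loglog(sph)
  expect_identical(ps$classification, "globular-like")
  expect_lte(ps$min_slope, -3.5)
  qc <- seq(0.003, 0.6, length.out = 500)
  coil <- gen_saxs(qc, "debye_coil", list(Rg = 35), snr = Inf)
  pc <- porod_loglog(coil)
  expect_identical(pc$classification, "no sharp interface")
  expect_equal(min(pc$slopes$slope), -2, tolerance = 0.15)
})

test_that("Kratky transform rises monotonically for a Gaussian in its
           Guinier regime", {
  q <- dense_q(200)
  rg0 <- 30
  I <- exp(-q^2 * rg0^2 / 3)
  k <- kratky(scattering_curve(q, I, I * 0.01))
  low <- q * rg0 < 1.3
  expect_true(all(diff(k$q2I[low]) > 0))
  expect_equal(k$q2I, q^2 * I)
})

test_that("forward-intensity mass calibration is a ratio rule", {
  expect_equal(mm_from_i0(10, 2, 10, 2, 66500), 66500)
  expect_equal(mm_from_i0(5, 2, 10, 2, 66500), 33250)
  # BSA-referenced arithmetic: I0/c ratio of 12.8/66.5 gives 12.8 kDa
  expect_equal(mm_from_i0(12.8 / 66.5 * 3, 1, 3, 1, 66500), 12800)
  expect_error(mm_from_i0(1, 0, 1, 1, 1), "positive")
})

test_that("expected-size models keep their ordering and closed forms", {
  for (n in c(50, 100, 143, 300)) {
    expect_lt(expected_rg(n, "globular"), expected_rg(n, "IDP_flory"))
    expect_lt(expected_rg(n, "IDP_flory"), expected_rg(n, "unfolded"))
  }
  expect_equal(expected_rg(NULL, "from_Rs", Rs = 25), sqrt(0.6) * 25)
  sph <- expected_rg(143, "sphere_from_volume")
  expect_equal(unname(sph["radius"]), (3 * 143 * 134 / (4 * pi))^(1 / 3))
  expect_equal(unname(sph["Rg"]), unname(sph["radius"]) * sqrt(0.6))
  expect_error(expected_rg(143, "nope"))
})

test_that("q unit conversion round-trips losslessly", {
  cv <- scattering_curve(dense_q(50), exp(-dense_q(50)), rep(0.01, 50))
  back <- convert_q_units(convert_q_units(cv, "A", "nm"), "nm", "A")
  expect_equal(back$q, cv$q)
})

test_that("generator truths match their analytic models", {
  q <- dense_q(100)
  sph <- gen_saxs(q, "sphere", list(R = 30), snr = Inf)
  expect_equal(attr(sph, "truth")$Rg, 30 * sqrt(0.6))
  expect_equal(sph$I, sphere_intensity(q, 30))
  coil <- gen_saxs(q, "debye_coil", list(Rg = 40), snr = Inf)
  expect_equal(coil$I, debye_coil_intensity(q, 40))
  noisy1 <- gen_saxs(q, "sphere", list(R = 30), snr = 20, seed = 5)
  noisy2 <- gen_saxs(q, "sphere", list(R = 30), snr = 20, seed = 5)
  expect_identical(noisy1$I, noisy2$I)   # deterministic under seed
})
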