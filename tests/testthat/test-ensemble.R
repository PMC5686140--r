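# Conformer pools, Debye curves, chi-square and GA sub-ensemble selection.
# Pool sizes here are small; the full-scale planted-recovery experiment
# lives in the acceptance tests.

test_that("pool generation is deterministic and respects chain geometry", {
  p1 <- generate_pool(40, 20, seed = 7)
  p2 <- generate_pool(40, 20, seed = 7)
  expect_identical(p1[[5]]$xyz, p2[[5]]$xyz)
  p3 <- generate_pool(40, 20, seed = 8)
  expect_false(identical(p1[[1]]$xyz, p3[[1]]$xyz))
  for (cf in p1[1:5]) {
    bonds <- sqrt(rowSums(diff(cf$xyz)^2))
    expect_true(all(abs(bonds - 3.8) < 0.01))
    d <- as.matrix(stats::dist(cf$xyz))
    n <- nrow(d)
    far <- abs(row(d) - col(d)) >= 3
    expect_true(all(d[far] >= 4.0 - 1e-9))
  }
})

test_that("minimal chains are valid and the boundary holds", {
  p <- generate_pool(10, 5, seed = 1)
  expect_identical(length(p), 5L)
  expect_true(all(pool_rg(p) > 0))
  expect_error(generate_pool(5, 2), "at least 10")
})

test_that("default pool dimensions are Flory-like for an IDP of 143
           residues", {
  p <- generate_pool(143, 120, seed = 2)
  flory <- expected_rg(143, "IDP_flory")
  expect_lt(abs(mean(pool_rg(p)) - flory) / flory, 0.25)
})

test_that("Debye curve matches closed forms and the brute-force sum", {
  q <- seq(0.02, 0.4, length.out = 30)
  ff <- exp(-q^2 * 9 / 2)^2     # Gaussian dummy-residue form factor squared
  single <- debye_curve(matrix(0, 1, 3), q, sigma_f = 3)
  expect_equal(single, ff * 1)
  two <- debye_curve(rbind(c(0, 0, 0), c(7, 0, 0)), q, sigma_f = 3,
                     bin_width = 0)
  expect_equal(two, ff * 2 * (1 + sin(7 * q) / (7 * q)))
  # straight 50-bead chain: binned histogram vs exact double sum
  chain <- cbind(3.8 * (0:49), 0, 0)
  exact <- debye_curve(chain, q, bin_width = 0)
  binned <- debye_curve(chain, q, bin_width = 0.5)
  expect_lt(max(abs(binned - exact)) / max(exact), 1e-3)
  # independent O(N^2) oracle
  oracle <- sapply(seq_along(q), function(k) {
    qq <- q[k]; s <- 0
    for (i in 1:50) for (j in 1:50) {
      r <- abs(i - j) * 3.8
      s <- s + if (r == 0) 1 else sin(qq * r) / (qq * r)
    }
    ff[k] * s
  })
  expect_equal(exact, oracle, tolerance = 1e-9)
})

test_that("conformer curves satisfy Guinier: fitted vs coordinate Rg", {
  p <- generate_pool(80, 4, seed = 3)
  q <- seq(0.004, 0.25, length.out = 250)
  for (cf in p) {
    I <- debye_curve(cf, q)
    g <- guinier_fit(scattering_curve(q, I, I * 1e-4))
    # coordinate Rg vs scattering Rg differ by the form-factor width
    rg_eff <- sqrt(cf$Rg^2 + 9)   # Gaussian bead of sd 3 A adds sigma_f^2
    expect_equal(g$Rg, rg_eff, tolerance = 0.03 * rg_eff)
  }
})

test_that("chi-square is zero for proportional curves and ~1 for 1-sigma
           noise", {
  q <- seq(0.01, 0.3, length.out = 100)
  I <- debye_coil_intensity(q, 30)
  target <- scattering_curve(q, I, 0.02 * I)
  expect_equal(chi2_curve(5 * I, target)$chi2, 0, tolerance = 1e-20)
  expect_equal(chi2_curve(5 * I, target)$mu, 0.2)
  set.seed(9)
  chis <- replicate(100, {
    noisy <- I + rnorm(length(I), 0, 0.02 * I)
    chi2_curve(I, scattering_curve(q, noisy, 0.02 * I))$chi2
  })
  expect_equal(mean(chis), 1, tolerance = 0.1)
  expect_error(chi2_curve(I[1:10], target), "grids")
})

test_that("GA finds a planted conformer and never fits worse than the best
           single", {
  p <- generate_pool(60, 300, seed = 21)
  q <- seq(0.01, 0.3, length.out = 50)
  curves <- pool_curves(p, q)
  planted <- 123L
  target <- scattering_curve(q, curves[, planted], 0.02 * curves[, planted])
  fit <- ga_select(curves, target, max_ensemble = 20, generations = 120,
                   population = 60, pool_rg = pool_rg(p), seed = 5)
  expect_lt(fit$chi2, 0.01)
  expect_lte(fit$chi2, fit$chi2_best_single + 1e-12)
  expect_lt(stats::sd(fit$selected_rg) / mean(fit$selected_rg), 0.05)
  # identical seed, identical result; chi2 <= best single across seeds
  fit2 <- ga_select(curves, target, max_ensemble = 20, generations = 120,
                    population = 60, pool_rg = pool_rg(p), seed = 5)
  expect_identical(fit$selected, fit2$selected)
  for (s in c(6, 7)) {
    f <- ga_select(curves, target, max_ensemble = 20, generations = 40,
                   population = 40, pool_rg = pool_rg(p), seed = s)
    expect_lte(f$chi2, f$chi2_best_single + 1e-12)
  }
})

test_that("the pool-average curve is fit essentially perfectly", {
  p <- generate_pool(60, 100, seed = 22)
  q <- seq(0.01, 0.3, length.out = 50)
  curves <- pool_curves(p, q)
  avg <- rowMeans(curves)
  target <- scattering_curve(q, avg, 0.02 * avg)
  fit <- suppressWarnings(
    ga_select(curves, target, max_ensemble = 20, generations = 150,
              population = 60, pool_rg = pool_rg(p), seed = 1))
  expect_lt(fit$chi2, 0.05)
})

test_that("bimodality detection flags two well-separated modes only", {
  set.seed(33)
  uni <- rnorm(500, 35, 4)
  two <- c(rnorm(250, 25, 2.5), rnorm(250, 55, 3))
  fake_fit <- function(sel) structure(
    list(pool_rg = c(uni, two), selected_rg = sel), class = "ensemble_fit")
  rd_uni <- rg_distribution(fake_fit(uni))
  expect_false(rd_uni$bimodal)
  rd_two <- rg_distribution(fake_fit(two))
  expect_true(rd_two$bimodal)
  expect_equal(sort(rd_two$peaks), c(25, 55), tolerance = 0.15)
})

test_that("histogram overlap is 1 for identical and small for disjoint
           shapes", {
  expect_equal(histogram_overlap(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(histogram_overlap(c(5, 0, 0), c(0, 0, 5)), 0)
})

test_that("conformer pools round-trip through multi-model PDB", {
  p <- generate_pool(15, 3, seed = 2)
  path <- tempfile(fileext = ".pdb")
  write_pool_pdb(p, path)
  back <- read_pool_pdb(path)
  expect_identical(length(back), 3L)
  expect_equal(back[[2]]$xyz, p[[2]]$xyz, tolerance = 1e-3)
  expect_equal(pool_rg(back), pool_rg(p), tolerance = 1e-3)
})
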