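# Stokes-radius laws, compaction index and SEC calibration.

test_that("calibration-standard law inverts in closed form", {
  mm_unit <- 10^(0.254 / 0.369)      # mass at which Rs = 1 A
  expect_equal(rs_standard(mm_unit), 1, tolerance = 1e-12)
  expect_equal(rs_standard(66000), 10^(0.369 * log10(66000) - 0.254))
  expect_equal(rs_standard(2e5) / rs_standard(1e5), 2^0.369)
  expect_error(rs_standard(-1), "positive")
})

test_that("state radii keep their order over the working mass range", {
  mm <- 10^seq(log10(5e3), log10(1e5), length.out = 40)
  nf <- expected_rs(mm[1], "NF")   # vectorized check via loop
  for (m in mm) {
    r <- sapply(c("NF", "MG", "PMG", "U"), expected_rs, MM = m)
    expect_true(all(diff(r) > 0))
  }
  expect_error(expected_rs(15922, "XX"))
})

test_that("dimer law equals the folded law at twice the mass", {
  for (m in c(8e3, 15922, 6e4))
    expect_equal(expected_rs(m, "DimNF"), expected_rs(2 * m, "NF"))
})

test_that("compaction index hits its endpoints and decreases with Rs_obs", {
  mm <- 15922
  expect_equal(compaction_index(expected_rs(mm, "NF"), mm), 1)
  expect_equal(compaction_index(expected_rs(mm, "U"), mm), 0)
  rs <- seq(20, 34, by = 1)
  ci <- sapply(rs, compaction_index, MM = mm)
  expect_true(all(diff(ci) < 0))
  expect_warning(compaction_index(10, mm), "outside")
})

test_that("nearest-state call picks the ratio closest to 1 and breaks ties
           toward compactness", {
  rep <- hydro_report(15922, expected_rs(15922, "PMG"), 143)
  expect_identical(rep$nearest_state, "PMG")
  # exact tie between two states: broken toward the more compact one
  fake <- list(ratios = c(A = 1.08, B = 0.92), expected = c(A = 20, B = 30))
  pick <- classify_state(fake)
  expect_identical(as.character(pick), "A")
  expect_true(isTRUE(attr(pick, "tie")))
})

test_that("hydro report echoes the construct length and exposes all ratios", {
  rep <- hydro_report(15922, 24.7, 143, id = "demo")
  expect_identical(rep$N, 143)
  expect_setequal(names(rep$ratios),
                  c("NF", "MG", "PMG", "U", "DimNF", "IDP"))
  df <- as.data.frame(rep)
  expect_identical(nrow(df), 1L)
  expect_equal(df$ratio_U, 24.7 / expected_rs(15922, "U"))
})

test_that("SEC calibration recovers an exact line and its standards", {
  gen <- gen_sec_calibration(n_standards = 6, noise = 0, seed = 1)
  cal <- suppressWarnings(calibrate_sec(gen$standards))
  expect_equal(cal$coefficients[[2]], 1 / gen$truth$b, tolerance = 1e-9)
  for (i in seq_len(nrow(gen$standards)))
    expect_equal(rs_from_elution(cal, gen$standards$Ve[i]),
                 rs_standard(gen$standards$MM[i]), tolerance = 1e-9)
  expect_error(calibrate_sec(gen$standards[1:2, ]), "3")
  expect_warning(rs_from_elution(cal, max(gen$standards$Ve) + 5),
                 "extrapolat")
})

test_that("1% elution noise leaves mean recovered Rs within 2% over
           replicates", {
  target_mm <- 5e4
  rel <- sapply(1:100, function(s) {
    gen <- gen_sec_calibration(n_standards = 6, noise = 0.01, seed = s)
    cal <- calibrate_sec(gen$standards)
    ve_true <- gen$truth$a + gen$truth$b * log10(rs_standard(target_mm))
    suppressWarnings(rs_from_elution(cal, ve_true)) / rs_standard(target_mm) - 1
  })
  expect_lt(abs(mean(rel)), 0.02)
})
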