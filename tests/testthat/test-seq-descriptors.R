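# Charge patterning, diagram-of-states and compositional descriptors.

test_that("charged fractions count Lys/Arg and Asp/Glu, His neutral at pH 7", {
  expect_equal(unname(charged_fractions(poly_seq("G", 20))), c(0, 0))
  expect_equal(unname(charged_fractions(poly_seq("E", 10))), c(0, 1))
  s <- protein_sequence("KKRRDDEEHH")
  expect_equal(unname(charged_fractions(s)), c(0.4, 0.4))
  expect_equal(unname(charged_fractions(s, his_charged = TRUE)), c(0.6, 0.4))
  expect_error(protein_sequence(""), "empty")
})

test_that("NCPR and FCR follow from the fractions and validate inputs", {
  expect_equal(unname(ncpr_fcr(0.136, 0.201)),
               c(0.136 - 0.201, 0.136 + 0.201))
  expect_equal(unname(ncpr_fcr(0, 0)), c(0, 0))
  expect_equal(unname(ncpr_fcr(0.5, 0.5)), c(0, 1))
  expect_error(ncpr_fcr(-0.1, 0.2), "0,1")
  expect_error(ncpr_fcr(0.7, 0.5), "sum")
})

test_that("kappa is 1 for charge blocks and near 0 for strict alternation", {
  block <- paste0(strrep("E", 25), strrep("K", 25))
  expect_equal(kappa_patterning(block), 1)
  alt <- strrep("EK", 25)
  k_alt <- kappa_patterning(alt)
  expect_lt(k_alt, 0.05)
  # alternation is (near-)minimal: no random permutation of the same
  # composition should score much lower
  set.seed(11)
  chars <- strsplit(alt, "")[[1]]
  k_perm <- replicate(200, kappa_patterning(
    paste(sample(chars), collapse = "")))
  expect_true(all(k_perm >= k_alt - 1e-12))
})

test_that("kappa is invariant under reversal and charge-identity swaps", {
  set.seed(42)
  for (i in 1:5) {
    s <- random_protein(60, seed = 100 + i)
    k <- kappa_patterning(s)
    rev_s <- paste(rev(strsplit(s$residues, "")[[1]]), collapse = "")
    expect_equal(kappa_patterning(rev_s), k, tolerance = 1e-12)
    swapped <- chartr("KRDE", "RKED", s$residues)
    expect_equal(kappa_patterning(swapped), k, tolerance = 1e-12)
  }
})

test_that("kappa stays in [0,1] and errors on degenerate input", {
  for (i in 1:20) {
    s <- random_protein(30, seed = 300 + i)
    f <- charged_fractions(s)
    if (sum(f) == 0) next
    k <- kappa_patterning(s)
    expect_gte(k, 0); expect_lte(k, 1)
  }
  expect_error(kappa_patterning(poly_seq("G", 30)), "undefined")
  expect_error(kappa_patterning("EK"), "shorter")
})

test_that("segregated-block normalizer dominates random arrangements of
           ASR1-like compositions", {
  # the normalizer is the conventional segregated construction; for
  # realistic mixed compositions it should not be beaten by chance
  set.seed(7)
  comp_seq <- gen_sequence(80, asr1_like_composition(), seed = 9)
  charges <- ifelse(strsplit(comp_seq$residues, "")[[1]] %in% c("K", "R"), 1L,
                    ifelse(strsplit(comp_seq$residues, "")[[1]] %in%
                             c("D", "E"), -1L, 0L))
  for (g in c(5L, 6L)) {
    dmax <- idpchar:::delta_max_g(charges, g)
    d_rand <- replicate(1000, idpchar:::delta_g(sample(charges), g))
    expect_true(all(d_rand <= dmax + 1e-12))
  }
})

test_that("diagram-of-states regions follow the FCR/NCPR bands", {
  expect_identical(phase_diagram_region(0.136, 0.201), 2L)
  expect_identical(phase_diagram_region(0.131, 0.204), 2L)
  expect_identical(phase_diagram_region(0.05, 0.05), 1L)
  expect_identical(phase_diagram_region(0.30, 0.30), 3L)
  expect_identical(phase_diagram_region(0.02, 0.40), 4L)
  expect_identical(phase_diagram_region(0.40, 0.02), 5L)
})

test_that("charge-hydropathy places hydrophobic homopolymers on the
           ordered side", {
  ch <- charge_hydropathy(poly_seq("I", 30))
  expect_false(ch$is_disordered)
  expect_equal(ch$CH_H, 1)                      # KD(I) rescales to 1
  expect_equal(ch$CH_distance, ch$CH_boundary - ch$CH_H)
  che <- charge_hydropathy(poly_seq("E", 30))   # charged, hydrophilic
  expect_true(che$is_disordered)
  expect_error(charge_hydropathy("IVL"), "shorter")
})

test_that("hydropathy mean sits on the rescaled 0-9 Kyte-Doolittle scale", {
  expect_equal(hydropathy_mean(poly_seq("G", 10)), 4.1)
  expect_equal(hydropathy_mean(poly_seq("I", 10)), 9.0)
  expect_equal(hydropathy_mean(poly_seq("R", 10)), 0.0)
})

test_that("composition deviation is zero at the reference and scales
           linearly", {
  s <- protein_sequence("AAEEKKGGWW")
  ref_self <- structure(rep(0, 20), names = idpchar:::AA_STANDARD)
  ref_self[c("A", "E", "K", "G", "W")] <- 0.2
  dev <- composition_deviation(s, ref_self)
  expect_true(all(abs(dev$deviation[dev$csp > 0]) < 1e-12))
  # doubling: E at 2x reference
  ref2 <- ref_self; ref2["E"] <- 0.1; ref2["A"] <- 0.3
  dev2 <- composition_deviation(s, ref2)
  expect_equal(dev2$deviation[dev2$residue == "E"], 1)
  # identity sum: sum CSP * (1 + D) = 1 for the shipped reference
  dev3 <- composition_deviation(s)
  expect_equal(sum(dev3$csp * (1 + dev3$deviation)), 1, tolerance = 1e-9)
  expect_setequal(
    dev3$residue[dev3$class == "disorder-promoting"],
    c("A", "G", "R", "D", "H", "Q", "K", "S", "E", "P"))
})

test_that("sequence report has the standard columns in order", {
  rep <- seq_report(list(poly_seq("E", 20), random_protein(40, 5)))
  expect_identical(
    names(rep),
    c("id", "N", "f_plus", "f_minus", "NCPR", "FCR", "kappa", "PDR",
      "hydropathy", "CH_R", "CH_H", "CH_distance"))
  expect_identical(nrow(rep), 2L)
  expect_true(all(abs(rep$NCPR) <= rep$FCR + 1e-12))
})

test_that("pI estimate orders acidic below basic homopolymers", {
  expect_lt(isoelectric_point(poly_seq("E", 20)), 5)
  expect_gt(isoelectric_point(poly_seq("K", 20)), 9)
})
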