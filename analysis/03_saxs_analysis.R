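#!/usr/bin/env Rscript
# Stage 3 - small-angle X-ray scattering analysis.
#
# The experimental BM29 curves are not deposited, so the pipeline runs on
# synthetic curves with known ground truth: a compact sphere (the control a
# folded protein would give) and a Gaussian coil with an IDP-like radius.
# Each curve passes through Guinier analysis, automatic Dmax selection with
# the regularized indirect Fourier transform, and the Kratky/Porod shape
# diagnostics. The expected-size calculators give the reference values an
# experimental Rg would be compared against.

suppressPackageStartupMessages(library(idpchar))
dir.create("results", showWarnings = FALSE)

q <- seq(0.003, 0.45, length.out = 500)   # Angstrom^-1, synchrotron-like

analyze <- function(curve, label, true_rg) {
  g <- guinier_fit(curve)
  pr <- suppressWarnings(auto_dmax(curve, g))
  po <- porod_loglog(curve)
  message(sprintf(
    "%s: Guinier Rg %.2f A (true %.2f), P(r) Rg %.2f A, Dmax %.1f A, %s",
    label, g$Rg, true_rg, pr$Rg, pr$Dmax, po$classification))
  data.frame(curve = label, Rg_true = true_rg, Rg_guinier = g$Rg,
             I0 = g$I0, Rg_pr = pr$Rg, Dmax = pr$Dmax,
             porod_min_slope = po$min_slope,
             classification = po$classification)
}

sphere <- gen_saxs(q, "sphere", list(R = 30), snr = 100, seed = 31)
coil <- gen_saxs(q, "debye_coil", list(Rg = 35), snr = 100, seed = 32)
tab <- rbind(analyze(sphere, "sphere_R30", 30 * sqrt(3 / 5)),
             analyze(coil, "coil_Rg35", 35))
write.csv(tab, "results/saxs_analysis.csv", row.names = FALSE)
message("The coil shows no Porod q^-4 region (no sharp solvent interface) ",
        "while the sphere does - the scattering signature separating ",
        "disordered chains from globular particles.")

# reference sizes for the two ASR1 construct lengths
sizes <- do.call(rbind, lapply(c(143, 141), function(n) {
  sph <- expected_rg(n, "sphere_from_volume")
  data.frame(N = n,
             Rg_idp_flory = expected_rg(n, "IDP_flory"),
             Rg_globular = expected_rg(n, "globular"),
             Rg_unfolded = expected_rg(n, "unfolded"),
             sphere_radius = unname(sph["radius"]),
             sphere_Rg = unname(sph["Rg"]))
}))
write.csv(sizes, "results/expected_sizes.csv", row.names = FALSE)
print(round(sizes, 1))
message("A measured Rg of ~35 A for a 141-143 residue chain matches the ",
        "IDP expectation (33.6-33.9 A), not the globular (~15.5 A) or ",
        "fully unfolded (~110 A) ones.")

# example of forward-intensity mass calibration against a BSA-like standard
mm <- mm_from_i0(I0 = 12.8 / 66.5 * 3.0, c = 1.0,
                 reference_I0 = 3.0, reference_c = 1.0,
                 reference_MM = 66500)
message(sprintf("I(0)-calibrated mass example: %.1f kDa", mm / 1000))
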