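#!/usr/bin/env Rscript
# Stage 5 - circular dichroism analyses.
#
# Thermal-melt sigmoid fitting (the temperature-induced folding typical of
# IDPs), isodichroic-point detection for two-state transitions, the
# double-wavelength RC/PMG classification, and the helicity ladder are run
# on synthetic data with embedded truth.

suppressPackageStartupMessages(library(idpchar))
dir.create("results", showWarnings = FALSE)

# melt recovery: 50 noisy replicates of a Tm = 51 C Boltzmann transition
tms <- sapply(1:50, function(s) {
  m <- gen_melt(Tm = 51, slope = 5, noise_frac = 0.05, seed = s)
  melt_fit(m$temperature, m$signal)$Tm
})
message(sprintf("Melt fits at 5%% noise: mean Tm %.1f C (sd %.1f; truth 51)",
                mean(tms), sd(tms)))
one <- gen_melt(Tm = 51, slope = 5, noise_frac = 0.05, seed = 1)
fit1 <- melt_fit(one$temperature, one$signal)
print(fit1)
write.csv(data.frame(replicate = seq_along(tms), Tm = tms),
          "results/melt_replicates.csv", row.names = FALSE)

# isodichroic point of a two-state glycerol-like titration family
fam <- gen_cd_family(fractions = seq(0, 1, length.out = 6), crossing = 205,
                     snr = 100, seed = 5)
ip <- isodichroic_point(fam)
message(sprintf("Isodichroic point: %.1f nm (constructed at 205 nm) - %s",
                ip$wavelength, ip$note))

# double-wavelength classification of representative points
pts <- data.frame(id = c("RC_example", "PMG_example"),
                  MRE_200 = c(-18500, -11000), MRE_222 = c(-1800, -3800))
pts$class <- vapply(seq_len(nrow(pts)), function(i)
  classify_rc_pmg(pts$MRE_200[i], pts$MRE_222[i])$class, character(1))
print(pts)

# helicity ladder for a 143-residue chain
mre <- seq(0, -40000 * (1 - 2.5 / 143), length.out = 5)
ladder <- data.frame(MRE_220 = mre,
                     helicity = vapply(mre, function(m)
                       as.numeric(helicity_fraction(m, 143)), numeric(1)))
write.csv(ladder, "results/helicity_ladder.csv", row.names = FALSE)
print(ladder)
message("All CD utilities recover their constructed truths; with real ",
        "spectra the same calls quantify additive-induced folding.")
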