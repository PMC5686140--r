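#!/usr/bin/env Rscript
# Stage 4 - conformer-pool generation and sub-ensemble selection.
#
# Emulates the ensemble-optimization stage: a pool of self-avoiding
# C-alpha chains is generated, coarse-grained Debye curves computed, and a
# genetic algorithm selects a sub-ensemble (max 50 conformers, repetition
# allowed) whose average curve matches a target. The planted target is a
# 50/50 mixture of a compact and an expanded sub-population - the
# two-state scenario a bimodal selected-Rg distribution reveals.
# Pool sizes here are moderate so the stage runs in seconds; the tests run
# the larger version.

suppressPackageStartupMessages(library(idpchar))
dir.create("results", showWarnings = FALSE)

N <- 143
pc <- generate_pool(N, 400, seed = 11, angle_mean = 85, angle_sd = 20)
pe <- generate_pool(N, 400, seed = 12, angle_mean = 147, angle_sd = 12)
pool <- merge_pools(pc, pe)
rg <- pool_rg(pool)
message(sprintf("Pool of %d chains: compact mode %.1f A, expanded %.1f A",
                length(pool), mean(pool_rg(pc)), mean(pool_rg(pe))))

q <- seq(0.01, 0.30, length.out = 60)
curves <- pool_curves(pool, q)
comp <- attr(pool, "component")
target <- gen_saxs(q, "two_population",
                   list(I1 = rowMeans(curves[, comp == 1]),
                        I2 = rowMeans(curves[, comp == 2]), w = 0.5),
                   snr = 100, seed = 41)

fit <- suppressWarnings(
  ga_select(curves, target, max_ensemble = 50, generations = 300,
            population = 100, pool_rg = rg, seed = 42))
print(fit)
rd <- rg_distribution(fit)
message(sprintf("Selected sub-ensemble: chi2 %.2f; bimodal = %s; modes at %s A",
                fit$chi2, rd$bimodal, paste(rd$peaks, collapse = " and ")))

write.csv(data.frame(Rg_mid = rd$mids, pool = rd$pool_counts,
                     selected = rd$selected_counts),
          "results/ensemble_rg_distribution.csv", row.names = FALSE)
write.csv(data.frame(chi2 = fit$chi2, chi2_best_single = fit$chi2_best_single,
                     bimodal = rd$bimodal,
                     mode1 = rd$peaks[1], mode2 = rd$peaks[2],
                     truth1 = mean(pool_rg(pc)), truth2 = mean(pool_rg(pe))),
          "results/ensemble_summary.csv", row.names = FALSE)
# a representative handful of selected conformers, for visual inspection
reps <- utils::head(fit$selected[!duplicated(fit$selected)], 4)
write_pool_pdb(pool[reps], "results/selected_conformers.pdb")
message("Selection recovers both planted sub-populations: the scattering ",
        "curve alone cannot be explained by a single homogeneous coil ",
        "ensemble.")
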