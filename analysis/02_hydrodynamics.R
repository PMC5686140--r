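#!/usr/bin/env Rscript
# Stage 2 - hydrodynamic classification from size-exclusion chromatography.
#
# From each protein's mass and observed Stokes radius, compute the radii
# expected for the reference conformational states (natively folded, molten
# globule, premolten globule, urea-unfolded, folded dimer, IDP power law),
# the observed/expected ratios, the compaction index, and the nearest-state
# call. A synthetic SEC calibration demonstrates the elution-volume route
# to the observed radius.

suppressPackageStartupMessages(library(idpchar))
dir.create("results", showWarnings = FALSE)

inputs <- data.frame(
  id = c("HvASR1", "TtASR1"),
  MM = c(15922, 15645),      # Da, recombinant constructs
  Rs_obs = c(24.7, 25.2),    # Angstrom, analytical SEC
  N = c(143, 141))           # residues incl. vector-encoded extension

rows <- lapply(seq_len(nrow(inputs)), function(i)
  as.data.frame(hydro_report(inputs$MM[i], inputs$Rs_obs[i], inputs$N[i],
                             id = inputs$id[i])))
tab <- do.call(rbind, rows)
write.csv(tab, "results/hydro_table.csv", row.names = FALSE)
print(tab, digits = 3)
message("Observed radii fall between the molten-globule and premolten-",
        "globule expectations (CI ~ ", paste(round(tab$CI, 2), collapse = "/"),
        "): far too expanded for a folded monomer, too compact for a ",
        "urea-unfolded chain. The folded-dimer ratio is also near 1 - ",
        "SEC alone cannot exclude a dimer; that requires an independent ",
        "mass measurement (native MS or the SAXS I(0) mass).")

cal_gen <- gen_sec_calibration(n_standards = 6, noise = 0.005, seed = 11)
cal <- calibrate_sec(cal_gen$standards)
print(cal)
ve_query <- cal_gen$truth$a + cal_gen$truth$b * log10(24.7)
message(sprintf(
  "Synthetic calibration check: elution volume %.2f mL -> Rs %.1f A",
  ve_query, rs_from_elution(cal, ve_query)))
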