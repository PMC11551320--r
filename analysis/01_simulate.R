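#!/usr/bin/env Rscript
# Stage 0: generate every synthetic dataset the analysis consumes.
#
# The fixtures encode the study conditions: a 40->20 C temperature jump with
# interconversion rates 0.09/0.36 per hour (0.24/0.98 with the prolyl
# isomerase CypA present and a 1.25-fold brighter spectrum), 15N CEST of a
# linear Enigma <-> Ground <-> PD exchange at 20 C and 4 C, methyl 13C CEST
# of the Ground <-> Enigma process (k_ex 173 /s, p_b 7%), a slow two-state
# process at k_ex 6.4 /s, constant-time CPMG at two temperatures, and a
# multi-state peak-volume table at 4 C where the partially disordered state
# dominates.

library(confex)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
fx <- default_fixtures()
seed <- 20260926L

write_one <- function(tab, name) {
  path <- file.path(out, paste0(name, ".tsv"))
  write_peak_table(tab, path)
  cat(sprintf("  %-22s %6d rows\n", name, nrow(tab)))
}

cat("simulating fixture datasets (seed", seed, ")\n")
write_one(simulate_realtime_dataset(fx$tjump20C, seed = seed + 1L), "tjump20C")
write_one(simulate_realtime_dataset(fx$tjump20C_cypa, seed = seed + 2L), "tjump20C_cypa")
write_one(simulate_cest_dataset(fx$cestMethyl_20C, seed = seed + 3L), "cestMethyl_20C")
write_one(simulate_cest_dataset(fx$cest15N_20C, seed = seed + 4L), "cest15N_20C")
write_one(simulate_cest_dataset(fx$cest15N_4C, seed = seed + 5L), "cest15N_4C")
write_one(simulate_cest_dataset(fx$cest15N_beta1_20C, seed = seed + 6L), "cest15N_beta1_20C")
write_one(simulate_cpmg_dataset(fx$cpmg15N_25C, seed = seed + 7L), "cpmg15N_25C")
write_one(simulate_cpmg_dataset(fx$cpmg15N_35C, seed = seed + 8L), "cpmg15N_35C")
write_one(simulate_volume_table(fx$volumes_4C, seed = seed + 9L), "volumes_4C")
cat("done; tables under", out, "\n")
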