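#!/usr/bin/env Rscript
# Stage 2: CEST model fitting. Two-state fits for the methyl data and the
# slow beta1-strand process; linear three-state (Enigma <-> Ground <-> PD)
# fits at 20 C and 4 C with the Enigma R2 tied to the Ground R2; reduced
# chi-squared comparison of alternative topologies at 20 C. Fits restrict
# the initialization to the known exchange regime of each process to keep
# the driver quick; the offset grids are fit in full because they are
# matched to the dip linewidths.

library(confex)

dir.create("results", showWarnings = FALSE)
fx <- default_fixtures()

rows <- list()
note_fit <- function(label, fit, extra = "") {
  cat(sprintf("%s: %s; populations %s; reduced chi2 %.3f %s\n", label,
              paste(sprintf("k(%s) = %.3g /s", names(fit$rates), fit$rates),
                    collapse = ", "),
              paste(sprintf("%s = %.3f", names(fit$populations),
                            fit$populations), collapse = ", "),
              fit$chi2_red, extra))
}

## methyl 13C CEST: Ground <-> Enigma two-state
tab_me <- read_peak_table("results/data/cestMethyl_20C.tsv")
fit_me <- fit_exchange_model(tab_me, "two_state", fx$cestMethyl_20C$scheme,
                             tie_r2 = "B", starts = 1, deep_minor = "B",
                             seed = 401L, maxit = 150,
                             regimes = c("fast", "anchored"), carry = 1)
kex_me <- unname(fit_me$rates[["G->B"]]) / fit_me$populations[["B"]]
note_fit("methyl 2-state", fit_me, sprintf("(k_ex = %.0f /s)", kex_me))
rows$methyl <- data.frame(dataset = "cestMethyl_20C", topology = "two_state",
                          kex_per_s = kex_me,
                          p_minor = fit_me$populations[["B"]],
                          chi2_red = fit_me$chi2_red)

## beta1 strand: slow two-state process at both B1 fields
tab_b1 <- read_peak_table("results/data/cest15N_beta1_20C.tsv")
fit_b1 <- fit_exchange_model(tab_b1, "two_state", fx$cest15N_beta1_20C$scheme,
                             tie_r2 = "B", starts = 1, deep_minor = "B",
                             seed = 402L, maxit = 150,
                             regimes = "slow", carry = 1)
kex_b1 <- unname(fit_b1$rates[["G->B"]]) / fit_b1$populations[["B"]]
note_fit("beta1 2-state", fit_b1, sprintf("(k_ex = %.2f /s)", kex_b1))
rows$beta1 <- data.frame(dataset = "cest15N_beta1_20C", topology = "two_state",
                         kex_per_s = kex_b1,
                         p_minor = fit_b1$populations[["B"]],
                         chi2_red = fit_b1$chi2_red)

## 15N three-state fits
fit3 <- function(file, scheme, deep_minor, seed, regimes) {
  tab <- read_peak_table(file)
  fit_exchange_model(tab, "linear_three_state", scheme, tie_r2 = "E",
                     starts = 1, deep_minor = deep_minor, seed = seed,
                     maxit = 150, regimes = regimes, carry = 1)
}
f20 <- fit3("results/data/cest15N_20C.tsv", fx$cest15N_20C$scheme, "E", 403L,
            c("fast", "anchored"))
note_fit("15N 20C linear 3-state", f20)
f4 <- fit3("results/data/cest15N_4C.tsv", fx$cest15N_4C$scheme, "PD", 404L,
           c("slow", "anchored"))
note_fit("15N 4C linear 3-state", f4)

cest_pops <- data.frame(
  temperature_C = c(rep(20, 3), rep(4, 3)),
  state = rep(c("Enigma", "Ground", "PD"), 2),
  population = c(unname(f20$populations[c("E", "G", "PD")]),
                 unname(f4$populations[c("E", "G", "PD")])),
  k_from_ground_per_s = c(NA, NA, NA, NA, NA, NA)
)
cest_pops$k_from_ground_per_s[c(1, 3)] <- unname(f20$rates[c("G->E", "G->PD")])
cest_pops$k_from_ground_per_s[c(4, 6)] <- unname(f4$rates[c("G->E", "G->PD")])
write.table(cest_pops, "results/cest_populations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

two_state_tab <- rbind(rows$methyl, rows$beta1)
write.table(two_state_tab, "results/cest_two_state.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## topology comparison at 20 C: is the Ground-PD edge needed?
cmp_fits <- list(f20)
for (tp in c("fully_connected_three_state", "no_g_pd_three_state")) {
  tab <- read_peak_table("results/data/cest15N_20C.tsv")
  cmp_fits[[length(cmp_fits) + 1]] <-
    fit_exchange_model(tab, tp, fx$cest15N_20C$scheme, tie_r2 = "E",
                       starts = 1, deep_minor = "E", seed = 405L,
                       maxit = 100, regimes = c("fast", "anchored"),
                       carry = 1)
}
cmp <- compare_models(cmp_fits)
print(cmp)
write.table(cmp, "results/cest_model_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/cest_populations.tsv, cest_two_state.tsv, cest_model_comparison.tsv\n")
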