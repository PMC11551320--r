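# Seeded generators: fixture parameter values, determinism, noise calibration
# and round trips against the forward models.

fx <- default_fixtures()

test_that("fixture kinetic parameters encode the study conditions", {
  expect_equal(unname(fx$tjump20C$realtime_rates), c(0.09, 0.36))
  expect_equal(unname(fx$tjump20C_cypa$realtime_rates), c(0.24, 0.98))
  expect_equal(unname(fx$tjump20C$eq_pops), c(0.8, 0.2))
  m <- fx$cestMethyl_20C$model_fn(fx$cestMethyl_20C$residues[1, ])
  expect_equal(unname(kex_pb(m)), c(173, 0.07))
  m3 <- fx$cest15N_20C$model_fn(fx$cest15N_20C$residues[1, ])
  expect_equal(m3$populations[match(c("E", "PD"), m3$labels)], c(0.08, 0.03))
  m4 <- fx$cest15N_4C$model_fn(fx$cest15N_4C$residues[1, ])
  expect_equal(m4$populations[match("PD", m4$labels)], 0.75)
  expect_equal(unname(fx$volumes_4C$populations["PD"]), 0.75)
  mb <- fx$cest15N_beta1_20C$model_fn(fx$cest15N_beta1_20C$residues[1, ])
  expect_equal(unname(kex_pb(mb)), c(6.4, 0.05))
})

test_that("noiseless temperature-jump peaks decay with the summed rate", {
  tab <- simulate_realtime_dataset(fx$tjump20C, noise_sigma = 0)
  g1 <- tab[tab$peak_id == "G1", ]
  fit <- fit_single_exponential(g1)
  expect_rel(fit$k, 0.45, 1e-6)
  f1 <- tab[tab$peak_id == "F1", ]
  expect_rel(fit_single_exponential(f1)$k, 0.45, 1e-6)
  ## Ground grows toward equilibrium (negative amplitude), FS decays
  expect_lt(fit$b, 0)
})

test_that("generators are deterministic in the seed and the seed only moves noise", {
  a <- simulate_realtime_dataset(fx$tjump20C, seed = 11)
  b <- simulate_realtime_dataset(fx$tjump20C, seed = 11)
  expect_identical(a, b)
  c0 <- simulate_realtime_dataset(fx$tjump20C, seed = 11, noise_sigma = 0)
  c1 <- simulate_realtime_dataset(fx$tjump20C, seed = 99, noise_sigma = 0)
  expect_identical(c0, c1) # noiseless signal independent of the noise seed
  d <- simulate_realtime_dataset(fx$tjump20C, seed = 99)
  expect_false(identical(a$volume, d$volume))

  e1 <- simulate_cest_dataset(fx$cestMethyl_20C, seed = 5)
  e2 <- simulate_cest_dataset(fx$cestMethyl_20C, seed = 5)
  expect_identical(e1, e2)
})

test_that("realtime noise has the stated standard deviation", {
  noiseless <- simulate_realtime_dataset(fx$tjump20C, noise_sigma = 0)
  noisy <- simulate_realtime_dataset(fx$tjump20C, seed = 3, noise_sigma = 0.02)
  resid <- noisy$volume - noiseless$volume
  expect_rel(stats::sd(resid), 0.02 * max(noiseless$volume), 0.05)
})

test_that("CEST tables equal the forward model without noise and saturate below reference", {
  tab <- simulate_cest_dataset(fx$cestMethyl_20C, noise_sigma = 0)
  fr <- fx$cestMethyl_20C
  res1 <- fr$residues[1, ]
  sub <- tab[tab$residue == res1$residue, ]
  model <- fr$model_fn(res1)
  prof <- cest_profile(model, fr$scheme, "G")
  ref <- sub$volume[is.na(sub$offset_ppm)]
  expect_equal(sub$volume[!is.na(sub$offset_ppm)] / ref, prof$intensity,
               tolerance = 1e-12)
  expect_true(all(ref > sub$volume[!is.na(sub$offset_ppm)]))
})

test_that("the 20C Ground-state CEST profile dips at both the PD and Enigma offsets", {
  tab <- simulate_cest_dataset(fx$cest15N_20C, noise_sigma = 0)
  fr <- fx$cest15N_20C
  res1 <- fr$residues[1, ]
  prof <- cest_profiles_from_table(tab[tab$residue == res1$residue, ])[[1]]
  at <- function(ppm) prof$intensity[which.min(abs(prof$offset_ppm - ppm))]
  base <- stats::quantile(prof$intensity, 0.9, names = FALSE)
  expect_gt(base - at(res1$pos_E), 0.02)
  expect_gt(base - at(res1$pos_PD), 0.005)
})

test_that("CPMG volumes round-trip through R2eff and duplicates differ only by noise", {
  tab0 <- simulate_cpmg_dataset(fx$cpmg15N_25C, noise_sigma = 0)
  fr <- fx$cpmg15N_25C
  sub <- tab0[tab0$residue == fr$residues$residue[1], ]
  prof <- compute_r2eff_profile(sub, fr$scheme)
  res <- fr$residues[1, ]
  model <- two_state_model(kex = res$k_leave / res$pb, pb = res$pb,
                           labels = c("G", "E"),
                           delta_omega = c(res$pos_G, res$pos_G + res$dw),
                           r1 = c(1.5, 1.5), r2 = rep(res$r2_G, 2))
  direct <- cpmg_r2eff(model, fr$scheme, "G")
  expect_equal(prof$r2eff, direct$r2eff, tolerance = 1e-10)

  tab <- simulate_cpmg_dataset(fx$cpmg15N_25C, seed = 4)
  sub <- tab[tab$residue == fr$residues$residue[1], ]
  dup <- sub[sub$ncyc == 30, ]
  expect_equal(nrow(dup), 2)
  expect_false(dup$volume[1] == dup$volume[2])
  expect_lt(abs(diff(dup$volume)), 6 * dup$volume_sd[1])
})

test_that("volume tables are population times response, PD dominant at 4C", {
  tab <- simulate_volume_table(fx$volumes_4C, noise_sigma = 0)
  for (res in unique(tab$residue)) {
    sub <- tab[tab$residue == res, ]
    expect_equal(sub$state[which.max(sub$volume)], "PD")
    expect_equal(sub$volume / sum(sub$volume),
                 unname(fx$volumes_4C$populations[sub$state]),
                 tolerance = 1e-12)
  }
  pops <- populations_from_volumes(tab)
  expect_equal(unname(pops$mean), unname(fx$volumes_4C$populations),
               tolerance = 1e-12)
})

test_that("generated tables survive the write/read round trip unchanged", {
  tab <- simulate_cest_dataset(fx$cestMethyl_20C, seed = 8)
  path <- tempfile(fileext = ".tsv")
  expect_no_warning(write_peak_table(tab, path))
  back <- expect_no_warning(read_peak_table(path))
  expect_equal(back$volume, tab$volume, tolerance = 1e-12)
  expect_equal(back$offset_ppm, tab$offset_ppm, tolerance = 1e-12)
  expect_identical(back$peak_id, tab$peak_id)
  ## acquisition metadata come back numeric, so a re-read table is fittable
  expect_type(back$b1_hz, "double")
  expect_equal(back$t_relax, tab$t_relax)
})
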