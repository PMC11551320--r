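# Dip detection, the global exchange-model fit and reduced-chi-squared model
# comparison. Heavier parameter-recovery checks on the full fixtures live in
# test-acceptance.R; here small datasets exercise correctness.

fx <- default_fixtures()

test_that("dips are located within one grid step on clean profiles", {
  m <- exchange_model(c("G", "B"), c(0.8, 0.2), c("G->B" = 15),
                      delta_omega = c(117.0, 122.3), r1 = c(1.5, 1.5),
                      r2 = c(10, 10))
  sch <- n15_cest_scheme(b1 = 20, lo = 110, hi = 130, by = 0.3)
  p <- cest_profile(m, sch, "G")
  d <- initialize_from_dips(p)
  expect_gte(nrow(d), 2)
  expect_lt(abs(d$offset_ppm[1] - 117.0), 0.3 + 1e-9)
  expect_lt(min(abs(d$offset_ppm[-1] - 122.3)), 0.3 + 1e-9)
})

test_that("flat profiles yield only the trivial minimum and shallow dips are suppressed", {
  off <- seq(110, 130, 0.3)
  set.seed(1)
  flat <- list(offset_ppm = off, intensity = 0.5 + rnorm(length(off), 0, 0.005))
  d <- initialize_from_dips(flat)
  expect_lte(nrow(d), 1)
  ## a dip shallower than the stated threshold is not reported
  dipped <- flat
  i <- which.min(abs(off - 122))
  dipped$intensity[i] <- dipped$intensity[i] - 0.01
  d2 <- initialize_from_dips(dipped, depth_threshold = 0.05)
  expect_true(all(abs(d2$offset_ppm - 122) > 0.3 | d2$depth > 0.05))
})

## small fast-to-fit two-state dataset used by the correctness checks below
small_two_state_table <- function(noise = 0, seed = 1) {
  sch <- n15_cest_scheme(b1 = 20, t_relax = 0.4, lo = 112, hi = 126, by = 0.35)
  residues <- data.frame(residue = 1:3, pos_G = c(116, 119, 121.5),
                         dw = c(4.2, -3.6, 3.0), r1 = c(1.4, 1.6, 1.5),
                         r2 = c(9, 11, 10))
  rows <- lapply(seq_len(3), function(i) {
    r <- residues[i, ]
    m <- two_state_model(kex = 60, pb = 0.10, labels = c("G", "B"),
                         delta_omega = c(r$pos_G, r$pos_G + r$dw),
                         r1 = rep(r$r1, 2), r2 = rep(r$r2, 2))
    prof <- cest_profile(m, sch, "G")
    data.frame(peak_id = paste0("R", i), residue = i, state = "G",
               plane = c(0L, seq_along(prof$offset_ppm)),
               offset_ppm = c(NA, prof$offset_ppm),
               volume = c(1, prof$intensity), volume_sd = 0.008)
  })
  tab <- do.call(rbind, rows)
  if (noise > 0) {
    set.seed(seed)
    tab$volume <- tab$volume + rnorm(nrow(tab), 0, noise)
    tab$volume_sd <- noise
  }
  list(table = tab, scheme = sch)
}

test_that("fitting the generating two-state topology on clean data recovers it near-exactly", {
  d <- small_two_state_table()
  fit <- fit_exchange_model(d$table, "two_state", d$scheme, tie_r2 = "B",
                            starts = 1, seed = 3, maxit = 200)
  expect_rel(unname(fit$rates["G->B"]), 6, 0.02)   # pb * kex
  expect_rel(unname(fit$populations["B"]), 0.10, 0.02)
  expect_lt(fit$chi2_red, 0.01) # noiseless: essentially zero misfit
  ## tied minor-state R2 equals the observed state's bit-exactly
  expect_identical(fit$residues$r2_B, fit$residues$r2_G)
})

test_that("model comparison penalizes a missing exchange edge and tolerates a superset", {
  ## linear three-state data at a 4C-like condition, small grid for speed
  sch <- n15_cest_scheme(b1 = 20, t_relax = 0.4, lo = 110, hi = 130, by = 0.5)
  residues <- data.frame(residue = 1:2, pos_G = c(115, 121),
                         pos_E = c(120.5, 126.5), pos_PD = c(111.5, 117.5))
  pops <- c(E = 0.06, G = 0.74, PD = 0.20)
  rows <- lapply(1:2, function(i) {
    r <- residues[i, ]
    m <- exchange_model(c("E", "G", "PD"), unname(pops),
                        c("G->E" = 10, "G->PD" = 3),
                        delta_omega = c(r$pos_E, r$pos_G, r$pos_PD),
                        r1 = rep(1.5, 3), r2 = c(10, 10, 5))
    prof <- cest_profile(m, sch, "G")
    set.seed(100 + i)
    data.frame(peak_id = paste0("R", i), residue = i, state = "G",
               plane = c(0L, seq_along(prof$offset_ppm)),
               offset_ppm = c(NA, prof$offset_ppm),
               volume = c(1, prof$intensity) + rnorm(nrow(prof) + 1, 0, 0.005),
               volume_sd = 0.005)
  })
  tab <- do.call(rbind, rows)

  init_for <- function(topology) {
    list(k_edges = switch(topology,
           linear_three_state = c(10, 3),
           fully_connected_three_state = c(10, 3, 0.01),
           no_g_pd_three_state = c(10, 3)),
         pops = c(E = 0.06, PD = 0.20, G = 0.74),
         residues = data.frame(
           pos_obs = residues$pos_G,
           d_E = residues$pos_E - residues$pos_G,
           d_PD = residues$pos_PD - residues$pos_G,
           r1 = 1.5, r2_obs = 10, r2_PD = 5
         ))
  }
  fits <- lapply(c("linear_three_state", "fully_connected_three_state",
                   "no_g_pd_three_state"), function(tp) {
    fit_exchange_model(tab, tp, sch, tie_r2 = "E", init = init_for(tp),
                       seed = 5, maxit = 150)
  })
  cmp <- compare_models(fits)
  expect_equal(cmp$topology[1] %in% c("linear_three_state",
                                      "fully_connected_three_state"), TRUE)
  lin <- cmp[cmp$topology == "linear_three_state", ]
  full <- cmp[cmp$topology == "fully_connected_three_state", ]
  nogpd <- cmp[cmp$topology == "no_g_pd_three_state", ]
  ## dropping the true G-PD edge is notably worse than the generating model
  expect_gt(nogpd$chi2_red, lin$chi2_red * 1.10)
  ## the fully connected superset is comparable to the generating model
  expect_true(full$comparable_to_best || lin$comparable_to_best)
  expect_lt(full$chi2_red, lin$chi2_red * 1.10 + 0.05)
})

test_that("model comparison ties break stably and near-zero edges are flagged", {
  mk <- function(topology, chi2_red, rates) {
    structure(list(topology = topology, chi2_red = chi2_red, rates = rates,
                   n_points = 100, n_params = 10), class = "cest_fit")
  }
  a <- mk("two_state", 1.00, c("G->B" = 5))
  b <- mk("linear_three_state", 1.00, c("G->E" = 5, "G->PD" = 1e-6))
  cmp <- compare_models(list(b, a))
  expect_equal(cmp$topology, c("linear_three_state", "two_state"))
  expect_true(all(cmp$comparable_to_best))
  expect_match(cmp$flagged_edges[cmp$topology == "linear_three_state"], "G->PD")
  expect_error(compare_models(list()), "length")
})
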