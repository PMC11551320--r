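# Rate-matrix algebra, Bloch-McConnell propagation and the closed-form limit
# expressions.

test_that("rate matrix has zero column sums and the stated stationary state", {
  m <- exchange_model(c("A", "B"), c(0.8, 0.2), c("A->B" = 1, "B->A" = 4))
  K <- build_rate_matrix(m)
  expect_equal(colSums(K), c(A = 0, B = 0))
  expect_equal(as.numeric(K %*% c(0.8, 0.2)), c(0, 0), tolerance = 1e-12)

  ## three-state chain with all rates equal: uniform stationary distribution
  m3 <- exchange_model(c("E", "G", "PD"), rep(1 / 3, 3),
                       c("E->G" = 5, "G->E" = 5, "G->PD" = 5, "PD->G" = 5))
  K3 <- build_rate_matrix(m3)
  expect_equal(as.numeric(K3 %*% rep(1 / 3, 3)), rep(0, 3), tolerance = 1e-12)
})

test_that("the stationary vector from eigendecomposition matches the model populations", {
  ## Enigma-like fixture: k_(G->E) chosen so p_E = 0.08 at equilibrium
  pops <- c(E = 0.08, G = 0.89, PD = 0.03)
  m <- exchange_model(names(pops), as.numeric(pops),
                      c("G->E" = 12, "G->PD" = 2))
  K <- build_rate_matrix(m)
  expect_equal(colSums(K), c(E = 0, G = 0, PD = 0), tolerance = 1e-12)
  ev <- eigen(K)
  i0 <- which.min(abs(ev$values))
  expect_lt(abs(ev$values[i0]), 1e-10)
  v <- Re(ev$vectors[, i0])
  v <- v / sum(v)
  expect_equal(v, as.numeric(pops), tolerance = 1e-8)
})

test_that("detailed balance violations and unknown states are rejected", {
  expect_error(
    exchange_model(c("A", "B"), c(0.8, 0.2), c("A->B" = 1, "B->A" = 1)),
    "detailed balance"
  )
  expect_error(
    exchange_model(c("A", "B"), c(0.8, 0.2), c("A->C" = 1)),
    "unknown state"
  )
  expect_error(exchange_model(c("A", "B"), c(0.7, 0.2)), "sum to 1")
})

test_that("model and scheme configs round-trip through YAML", {
  m <- two_state_n15(kex = 173, pb = 0.07, dw_ppm = 4.1)
  m2 <- model_from_config(model_to_config(m))
  expect_equal(m2$populations, m$populations)
  expect_equal(m2$k, m$k)
  expect_equal(m2$delta_omega, m$delta_omega)
  expect_equal(m2$r1, m$r1)
  expect_equal(m2$r2, m$r2)

  sch <- n15_cest_scheme()
  sch2 <- scheme_from_config(scheme_to_config(sch))
  expect_equal(sch2$offsets_ppm, sch$offsets_ppm)
  expect_equal(sch2$b1_hz, sch$b1_hz)
  cp <- n15_cpmg_scheme()
  cp2 <- scheme_from_config(scheme_to_config(cp))
  expect_equal(cp2$ncyc_values, cp$ncyc_values)
})

test_that("a depopulated minor state reduces the CEST profile to the single-state case", {
  sch <- n15_cest_scheme()
  m0 <- exchange_model("A", 1, NULL, delta_omega = 118, r1 = 1.5, r2 = 10)
  m <- exchange_model(c("A", "B"), c(1, 0), NULL,
                      delta_omega = c(118, 123), r1 = c(1.5, 1.5), r2 = c(10, 10))
  expect_equal(cest_profile(m, sch, "A")$intensity,
               cest_profile(m0, sch, "A")$intensity, tolerance = 1e-12)
})

test_that("slow-exchange CEST dips sit at the state resonances", {
  m <- two_state_n15(kex = 20, pb = 0.3, dw_ppm = 5, pos = 117)
  sch <- n15_cest_scheme(b1 = 20, lo = 110, hi = 130, by = 0.2)
  p <- cest_profile(m, sch, "A")
  expect_true(all(p$intensity > -0.05 & p$intensity < 1.05))
  ord <- order(p$intensity)
  ## deepest point at the observed resonance, and a second dip at the minor
  ## state's resonance, each within one grid step
  expect_lt(abs(p$offset_ppm[ord[1]] - 117), 0.2 + 1e-9)
  away <- p[abs(p$offset_ppm - 117) > 2, ]
  expect_lt(abs(away$offset_ppm[which.min(away$intensity)] - 122), 0.2 + 1e-9)
})

test_that("zero saturation time returns the all-ones reference profile", {
  m <- two_state_n15(kex = 100, pb = 0.05, dw_ppm = 3)
  sch <- cest_scheme("N15", 800, b1_hz = 20, t_relax = 0,
                     offsets_ppm = seq(110, 125, 0.5))
  expect_true(all(cest_profile(m, sch, "A")$intensity == 1))
  expect_error(cest_scheme("N15", 800, b1_hz = -5, t_relax = 0.4,
                           offsets_ppm = 110:120), "b1_hz")
})

test_that("matrix-exponential and Euler propagation agree on the Enigma fixture", {
  fx <- default_fixtures()
  fr <- fx$cest15N_20C
  model <- fr$model_fn(fr$residues[1, ])
  sch <- fr$scheme
  sch$offsets_ppm <- sch$offsets_ppm[seq(1, length(sch$offsets_ppm), by = 10)]
  a <- cest_profile(model, sch, "G")
  b <- cest_profile_euler(model, sch, "G")
  expect_lt(max(abs(a$intensity - b$intensity)), 1e-3)
})

test_that("zero saturation field preserves population proportions up to R1 decay", {
  pops <- c(E = 0.08, G = 0.89, PD = 0.03)
  m <- exchange_model(names(pops), as.numeric(pops),
                      c("G->E" = 12, "G->PD" = 2),
                      delta_omega = c(125.2, 119.5, 122.3),
                      r1 = rep(1.3, 3), r2 = c(12, 12, 5))
  sch <- cest_scheme("N15", 800, b1_hz = 0, t_relax = 0.5,
                     offsets_ppm = c(110, 119.5, 128))
  for (s in names(pops)) {
    p <- cest_profile(m, sch, s)
    ## z-magnetization stays proportional to populations, scaled by exp(-R1 t)
    expect_equal(p$intensity, rep(exp(-1.3 * 0.5), 3), tolerance = 1e-8)
  }
})

test_that("CPMG without exchange is flat at the intrinsic R2", {
  m <- two_state_n15(kex = 0, pb = 0.05, dw_ppm = 4, r2 = 9)
  d <- cpmg_r2eff(m, n15_cpmg_scheme(), "A")
  expect_equal(d$r2eff, rep(9, nrow(d)), tolerance = 1e-8)
})

test_that("Bloch-McConnell R2eff matches Carver-Richards within 2% of Rex across regimes", {
  sch <- n15_cpmg_scheme()
  dw_ppm <- 4
  dw_rad <- 2 * pi * dw_ppm * nucleus_freq_mhz("N15", 800)
  for (ratio in c(0.2, 1, 5)) {
    for (pb in c(0.03, 0.08, 0.15)) {
      m <- two_state_n15(kex = ratio * dw_rad, pb = pb, dw_ppm = dw_ppm)
      bm <- cpmg_r2eff(m, sch, "A")
      cr <- carver_richards_r2eff(m, sch, "A")
      rex <- max(bm$r2eff) - min(bm$r2eff)
      expect_lt(max(abs(bm$r2eff - cr$r2eff)), 0.02 * rex)
    }
  }
})

test_that("fast-exchange R2eff approaches the closed-form exchange contribution", {
  dw_rad <- 500 # rad/s
  dw_ppm <- dw_rad / (2 * pi * nucleus_freq_mhz("N15", 800))
  m <- two_state_n15(kex = 10 * dw_rad, pb = 0.1, dw_ppm = dw_ppm, r2 = 8)
  d <- cpmg_r2eff(m, n15_cpmg_scheme(), "A")
  rex_num <- d$r2eff[1] - 8 # low-frequency point minus population-weighted R2
  expect_rel(rex_num, rex_fast_limit(m, dw_rad), 0.05)
})

test_that("slow-exchange numerical Rex approaches the rate of leaving the observed state", {
  ## k_ex <= dw/10 and nu_cpmg <= k_ex/10
  dw_rad <- 2 * pi * 5 * nucleus_freq_mhz("N15", 800) # ~2546 rad/s
  m <- two_state_n15(kex = 250, pb = 0.05, dw_ppm = 5, r2 = 10)
  sch <- cpmg_scheme("N15", 800, t_ct = 0.12, ncyc_values = c(1, 48, 60))
  d <- cpmg_r2eff(m, sch, "A") # nu = 8.3, 400, 500 Hz
  rex_num <- d$r2eff[1] - 10
  expect_rel(rex_num, 0.05 * 250, tol = 0.10) # k_AB = pb * kex = 12.5 /s
})

test_that("fast-limit formula evaluates the stated closed form", {
  m <- two_state_model(kex = 10000, pb = 0.05)
  expect_equal(rex_fast_limit(m, 1000), 0.95 * 0.05 * 1e6 / 1e4)
  expect_equal(rex_fast_limit(m, 0), 0)
  m2 <- two_state_model(kex = 20000, pb = 0.05)
  expect_equal(rex_fast_limit(m2, 1000), rex_fast_limit(m, 1000) / 2)
  ## optional dR2 correction shrinks the numerator
  m3 <- two_state_model(kex = 10000, pb = 0.05, r2 = c(10, 30))
  expect_lt(rex_fast_limit(m3, 1000, include_dr2 = TRUE),
            rex_fast_limit(m3, 1000))
  expect_error(rex_fast_limit(exchange_model("A", 1), 100), "two-state")
})

test_that("slow-limit Rex is the rate of leaving the observed state", {
  m <- exchange_model(c("Ground", "E"), c(0.92, 0.08), c("Ground->E" = 12))
  expect_equal(rex_slow_limit(m, "Ground"), 12)
  expect_equal(rex_slow_limit(m, "E"), 12 * 0.92 / 0.08)
  m0 <- exchange_model(c("A", "B"), c(1, 0), NULL)
  expect_equal(rex_slow_limit(m0, "A"), 0)
})

test_that("three-state chain CEST exchange is reciprocated where an edge exists", {
  ## low-temperature-like chain: PD dominant and slowly returning, so the
  ## two-step relay PD -> G -> E is weak
  pops <- c(E = 0.02, G = 0.23, PD = 0.75)
  m <- exchange_model(names(pops), as.numeric(pops),
                      c("G->E" = 4, "G->PD" = 2),
                      delta_omega = c(125.2, 119.5, 122.3),
                      r1 = rep(1.2, 3), r2 = c(12, 12, 5))
  sch <- n15_cest_scheme(b1 = 10, t_relax = 0.5, lo = 112, hi = 130, by = 0.15)
  at <- function(p, ppm) p$intensity[which.min(abs(p$offset_ppm - ppm))]
  base <- function(p) stats::quantile(p$intensity, 0.9, names = FALSE)
  pg <- cest_profile(m, sch, "G")
  ## observed from G: dips at both the E and PD offsets
  dip_g_at_e <- base(pg) - at(pg, 125.2)
  expect_gt(dip_g_at_e, 0.1)
  expect_gt(base(pg) - at(pg, 122.3), 0.1)
  ## observed from PD: the G dip is reciprocated (direct edge) ...
  ppd <- cest_profile(m, sch, "PD")
  dip_pd_at_g <- base(ppd) - at(ppd, 119.5)
  expect_gt(dip_pd_at_g, 0.05)
  ## ... while the E offset, with no E-PD edge, shows at most a faint
  ## second-order relay shadow, far weaker than the direct dips
  dip_pd_at_e <- base(ppd) - at(ppd, 125.2)
  expect_lt(dip_pd_at_e, 0.4 * dip_g_at_e)
  expect_lt(dip_pd_at_e, 0.4 * dip_pd_at_g)
})
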