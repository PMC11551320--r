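# Populations from volumes, CEST/realtime population merging, Boltzmann free
# energies, Eyring barriers and the cross-temperature offset.

test_that("volume normalization gives per-residue populations and averages", {
  tab <- data.frame(
    peak_id = paste0("R1_", c("G", "F", "P")), residue = 1,
    state = c("Ground", "FS", "PD"), plane = 1,
    volume = c(75, 15, 10), volume_sd = 1
  )
  p <- populations_from_volumes(tab)
  expect_equal(unname(p$mean), c(0.75, 0.15, 0.10))
  ## doubling every volume changes nothing
  tab2 <- tab
  tab2$volume <- tab2$volume * 2
  expect_equal(populations_from_volumes(tab2)$mean, p$mean)
  ## residues missing a state are excluded from that average
  tab3 <- rbind(tab, data.frame(peak_id = c("R2_G", "R2_F"), residue = 2,
                                state = c("Ground", "FS"), plane = 1,
                                volume = c(60, 40), volume_sd = 1))
  p3 <- suppressMessages(populations_from_volumes(tab3,
                                                  states = c("Ground", "FS", "PD")))
  expect_equal(unname(p3$n_residues), c(2, 2, 1))
})

test_that("population merging rescales CEST states into the realtime anchor mass", {
  merged <- merge_populations(c(Ground = 0.92, Enigma = 0.08),
                              c(Ground = 0.80, FS = 0.20),
                              anchor_state = "Ground")
  expect_equal(unname(merged[c("Ground", "Enigma", "FS")]),
               c(0.736, 0.064, 0.20), tolerance = 1e-12)
  expect_equal(sum(merged), 1)
  ## with no extra realtime states the CEST populations pass through
  same <- merge_populations(c(Ground = 0.92, Enigma = 0.08),
                            c(Ground = 1), anchor_state = "Ground")
  expect_equal(unname(same), c(0.92, 0.08))
  ## merged populations always sum to 1
  set.seed(7)
  for (i in 1:25) {
    cp <- runif(3); cp <- cp / sum(cp); names(cp) <- c("Ground", "E", "PD")
    rp <- runif(2); rp <- rp / sum(rp); names(rp) <- c("Ground", "FS")
    expect_equal(sum(merge_populations(cp, rp, "Ground")), 1, tolerance = 1e-12)
  }
  expect_error(merge_populations(c(Ground = 0.9, E = 0.1),
                                 c(Ground = 0, FS = 1), "Ground"), "zero")
})

test_that("Boltzmann inversion gives the stated free energies", {
  dg <- state_free_energies(c(A = 0.8, B = 0.2), 293.15, reference = "A")
  expect_equal(unname(dg["A"]), 0)
  expect_equal(unname(dg["B"]), -1.98720425e-3 * 293.15 * log(0.25),
               tolerance = 1e-12)
  expect_equal(unname(round(dg["B"], 3)), 0.808)
  ## ordering of dG reverses the ordering of populations
  p <- c(X = 0.5, Y = 0.3, Z = 0.2)
  dg3 <- state_free_energies(p, 300)
  expect_equal(order(dg3), order(-p))
  expect_error(state_free_energies(c(A = 1, B = 0), 300), "zero population")
})

test_that("Eyring barrier matches the closed form and round-trips to machine precision", {
  k <- 0.09 / 3600 # 1/h in 1/s
  dg <- eyring_barrier(k, 293.15)
  expect_equal(round(dg, 1), 23.3)
  ## prefactor identity: k = kB T / h gives a zero barrier
  pref <- 1.380649e-23 * 293.15 / 6.62607015e-34
  expect_equal(eyring_barrier(pref, 293.15), 0, tolerance = 1e-12)
  ## round trip
  for (kk in c(1e-6, 2.5e-5, 12, 1e4)) {
    expect_rel(eyring_rate(eyring_barrier(kk, 310), 310), kk, 1e-12)
  }
  expect_error(eyring_barrier(0, 300), "> 0")
})

test_that("assembled landscapes respect barrier dominance and the cold offset", {
  pops20 <- c(Ground = 0.736, Enigma = 0.064, FS = 0.20)
  rates20 <- c("Ground->FS" = 0.09 / 3600, "Ground->Enigma" = 12)
  l20 <- build_landscape(pops20, rates20, 293.15, reference = "Ground")
  b <- l20$barriers
  ## the hours-long fold switch towers over the millisecond Enigma exchange
  expect_gt(b$dg_abs[b$to == "FS"], b$dg_abs[b$to == "Enigma"])
  ## every barrier sits at or above both connected states
  expect_true(all(b$dg_abs >= pmax(l20$dg[b$from], l20$dg[b$to]) - 1e-9))

  pops4 <- c(Ground = 0.23, Enigma = 0.02, PD = 0.75)
  rates4 <- c("Ground->FS" = 0.02 / 3600, "Ground->Enigma" = 4)
  pops4 <- c(pops4, FS = 1e-6)
  pops4 <- pops4 / sum(pops4)
  l4 <- build_landscape(pops4, rates4, 277.15, reference = "Ground")
  shifted <- apply_temperature_offset(l4, l20, offset = 2,
                                      transition = c("Ground", "FS"))
  expect_equal(unname(shifted$dg - l4$dg), rep(2, length(l4$dg)))
  expect_equal(shifted$offset_applied, 2)
  ## zero offset leaves the landscape unchanged (modulo a possible warning)
  same <- suppressWarnings(apply_temperature_offset(l4, l20, offset = 0,
                                                    transition = c("Ground", "FS")))
  expect_equal(same$dg, l4$dg)
  ## the minimal compliant offset produces barrier equality
  i4 <- which(l4$barriers$to == "FS")
  i20 <- which(l20$barriers$to == "FS")
  minimal <- l20$barriers$dg_abs[i20] - l4$barriers$dg_abs[i4]
  if (minimal > 0) {
    eq <- apply_temperature_offset(l4, l20, offset = minimal,
                                   transition = c("Ground", "FS"))
    expect_equal(eq$barriers$dg_abs[i4], l20$barriers$dg_abs[i20],
                 tolerance = 1e-9)
    expect_warning(
      apply_temperature_offset(l4, l20, offset = minimal / 2,
                               transition = c("Ground", "FS")),
      "minimal compliant offset"
    )
  }
})
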