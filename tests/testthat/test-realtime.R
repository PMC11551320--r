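# Per-peak exponential fits, amplitude filtering, the shared-rate global fit,
# bootstrap uncertainty and the cross-experiment scale factor.

fx <- default_fixtures()

test_that("single-exponential fit recovers exact parameters on clean data", {
  t <- seq(0.12, 16, by = 0.33)
  series <- data.frame(time_h = t, volume = 2e5 + 8e5 * exp(-0.45 * t),
                       volume_sd = 1)
  f <- fit_single_exponential(series)
  expect_rel(f$a, 2e5, 1e-6)
  expect_rel(f$b, 8e5, 1e-6)
  expect_rel(f$k, 0.45, 1e-6)
  expect_true(f$converged)
})

test_that("a constant series fits with rate indistinguishable from zero", {
  t <- seq(0.12, 16, by = 0.33)
  f <- fit_single_exponential(data.frame(time_h = t, volume = rep(5e5, length(t))))
  expect_equal(f$k, 0)
  expect_lt(abs(f$b), 1)
})

test_that("median recovered rate over noisy peaks is within 5% of truth", {
  ## the median over 50 peaks at 2% noise scatters by a few percent per
  ## realization, so the property is checked on the mean over four seeds
  meds <- vapply(1:4, function(s) {
    tab <- simulate_realtime_dataset(fx$tjump20C, seed = 20L + s)
    ks <- vapply(unique(tab$peak_id)[1:50], function(id) {
      fit_single_exponential(tab[tab$peak_id == id, ])$k
    }, numeric(1))
    stats::median(ks)
  }, numeric(1))
  expect_rel(mean(meds), 0.45, 0.05)
})

test_that("amplitude filter drops weak peaks and keeps the fixture's 45+37", {
  tab <- simulate_realtime_dataset(fx$tjump20C)
  ## a synthetic weak peak below the 4e5 amplitude cut
  t <- sort(unique(tab$time_h))
  weak <- data.frame(peak_id = "W1", residue = 999, state = "Ground",
                     plane = seq_along(t), time_h = t,
                     volume = 1e5 + 3e5 * exp(-0.45 * t),
                     volume_sd = tab$volume_sd[1])
  filt <- suppressMessages(filter_peaks(rbind(tab, weak)))
  expect_false("W1" %in% filt$fits$peak_id)
  expect_equal(unname(filt$counts[c("Ground", "FS")]), c(45, 37))
  ## threshold zero retains every converged peak
  all_in <- suppressMessages(filter_peaks(rbind(tab, weak), threshold = 0))
  expect_true("W1" %in% all_in$fits$peak_id)
})

test_that("global fit recovers the generating rates exactly on noiseless data", {
  tab <- simulate_realtime_dataset(fx$tjump20C, noise_sigma = 0)
  fit <- global_fit_rates(tab)
  expect_rel(fit$k_fwd, 0.09, 1e-6)
  expect_rel(fit$k_rev, 0.36, 1e-6)
  expect_equal(fit$k_obs, fit$k_fwd + fit$k_rev, tolerance = 1e-12)
  expect_equal(unname(fit$populations["Ground"]),
               unname(fit$k_rev / fit$k_obs), tolerance = 1e-12)
  expect_equal(fit$lifetimes_h, 1 / c(fit$k_fwd, fit$k_rev))
})

test_that("global rates are invariant to rescaling one peak's volumes and uncertainty", {
  tab <- simulate_realtime_dataset(fx$tjump20C, seed = 5)
  fit1 <- global_fit_rates(tab)
  tab2 <- tab
  i <- tab2$peak_id == "G7"
  tab2$volume[i] <- tab2$volume[i] * 50
  tab2$volume_sd[i] <- tab2$volume_sd[i] * 50
  fit2 <- global_fit_rates(tab2)
  expect_equal(fit2$k_obs, fit1$k_obs, tolerance = 1e-9)
})

test_that("the shared-rate fit obeys the nested-model inequalities", {
  tab <- simulate_realtime_dataset(fx$tjump20C, seed = 9)
  fit <- global_fit_rates(tab)
  rss_at <- function(k) {
    sum(vapply(split(tab, tab$peak_id), function(s) {
      x <- exp(-k * s$time_h)
      r <- stats::lm.fit(cbind(1, x), s$volume)$residuals
      sum(r^2) / s$volume_sd[1]^2
    }, numeric(1)))
  }
  ## optimal shared k beats any other common k ...
  expect_lte(fit$rss, rss_at(0.5) + 1e-6)
  expect_lte(fit$rss, rss_at(0.3) + 1e-6)
  ## ... and cannot beat per-peak free rates
  free <- sum(vapply(split(tab, tab$peak_id), function(s) {
    fit_single_exponential(s)$rss
  }, numeric(1)))
  expect_gte(fit$rss, free - 1e-6)
})

test_that("bootstrap collapses without noise and is seed-deterministic", {
  tab <- simulate_realtime_dataset(fx$tjump20C, noise_sigma = 0)
  tab$volume_sd <- 1e-9
  b0 <- bootstrap_uncertainty(tab, n_boot = 60, seed = 1, resample_peaks = FALSE)
  expect_lt(diff(b0$intervals[, "k_fwd"]), 1e-6)

  tabn <- simulate_realtime_dataset(fx$tjump20C, seed = 2)
  b1 <- bootstrap_uncertainty(tabn, n_boot = 60, seed = 42)
  b2 <- bootstrap_uncertainty(tabn, n_boot = 60, seed = 42)
  expect_identical(b1$intervals, b2$intervals)
  expect_warning(bootstrap_uncertainty(tabn, n_boot = 20, seed = 1), "n_boot")
  expect_error(bootstrap_uncertainty(tabn, n_boot = 60), "seed")
})

test_that("scale factor recovers exact multiplicative offsets and resists outliers", {
  tab <- simulate_realtime_dataset(fx$tjump20C, seed = 13)
  tab_b <- tab
  tab_b$volume <- tab_b$volume * 1.25
  expect_equal(estimate_scale_factor(tab, tab_b), 1.25, tolerance = 1e-9)
  expect_equal(estimate_scale_factor(tab, tab), 1, tolerance = 1e-12)
  ## one wild peak does not move the median materially
  tab_c <- tab_b
  i <- tab_c$peak_id == "G3"
  tab_c$volume[i] <- tab_c$volume[i] * 100
  expect_rel(estimate_scale_factor(tab, tab_c), 1.25, 0.01)
})
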