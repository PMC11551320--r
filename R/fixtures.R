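## Seeded synthetic-data generator: fixtures encode the study conditions
## (rates, populations, acquisition parameters) and every dataset the pipeline
## consumes is simulated from them. Structural draws (response factors,
## per-residue shifts and relaxation rates) are fixed by the fixture seed;
## the seed passed to a simulate_*() call controls only the noise, so
## changing it changes the noise realization but never the noiseless signal.

default_n15_offsets <- function() {
  ## 104-135 ppm in 25 Hz increments at an 800 MHz 1H field
  step <- hz_to_ppm(25, "N15", 800)
  seq(104, 135, by = step)
}

default_cpmg_ncyc <- function() {
  ## 14 dispersion points over T_CT = 60 ms plus reference, with repeat
  ## planes at ncyc 0, 30 and 60 for duplicate-based uncertainties
  c(0L, 1L, 2L, 3L, 4L, 6L, 8L, 10L, 14L, 18L, 24L, 30L, 38L, 48L, 60L,
    0L, 30L, 60L)
}

new_fixture <- function(name, kind, seed, ...) {
  structure(c(list(name = name, kind = kind, seed = seed), list(...)),
            class = "confex_fixture")
}

#' @export
print.confex_fixture <- function(x, ...) {
  cat(sprintf("<fixture '%s'> kind = %s, seed = %d, noise_sigma = %g\n",
              x$name, x$kind, x$seed, x$noise_sigma))
  invisible(x)
}

## deterministic per-fixture draws in a private RNG scope
with_fixture_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

make_realtime_fixture <- function(name, k_fwd, k_rev, seed, scale,
                                  noise_sigma = 0.02,
                                  n_peaks = c(Ground = 45, FS = 37),
                                  init_pops = c(Ground = 0.6, FS = 0.4),
                                  response_seed = seed) {
  k_obs <- k_fwd + k_rev
  eq <- c(Ground = k_rev / k_obs, FS = k_fwd / k_obs)
  peaks <- with_fixture_rng(response_seed, {
    ground_res <- seq_len(n_peaks[["Ground"]])
    fs_res <- seq_len(n_peaks[["FS"]])
    data.frame(
      peak_id = c(paste0("G", ground_res), paste0("F", fs_res)),
      residue = c(ground_res, fs_res),
      state = c(rep("Ground", n_peaks[["Ground"]]), rep("FS", n_peaks[["FS"]])),
      response = exp(rnorm(n_peaks[["Ground"]] + n_peaks[["FS"]], 0, 0.3))
    )
  })
  new_fixture(
    name, "realtime", seed,
    realtime_rates = c(k_fwd = k_fwd, k_rev = k_rev),
    init_pops = init_pops, eq_pops = eq,
    n_peaks = n_peaks, peaks = peaks,
    times_h = seq(0.12, 16, by = 0.33),
    scale = scale, noise_sigma = noise_sigma
  )
}

make_cest_fixture <- function(name, model_fn, scheme, n_res, seed,
                              noise_sigma = 0.01, observed = "G",
                              draw_residue) {
  schemes <- if (inherits(scheme, "acq_scheme")) list(scheme) else scheme
  residues <- with_fixture_rng(seed, draw_residue(n_res))
  new_fixture(
    name, "cest", seed,
    model_fn = model_fn, scheme = schemes[[1]], schemes = schemes,
    observed = observed,
    residues = residues, scale = 1e6, noise_sigma = noise_sigma
  )
}

#' Built-in fixtures encoding the study conditions
#'
#' Returns the named collection of synthetic-data fixtures used throughout the
#' package. Kinetic parameters are the study's reported values: temperature
#' jump rates 0.09/0.36 1/h at 20 degrees C (0.24/0.98 1/h with the
#' prolyl-isomerase CypA present and a 1.25-fold higher intensity scale),
#' methyl CEST exchange k_ex = 173 1/s with p_b = 7 percent, a linear
#' Enigma <-> Ground <-> PD three-state model with the Enigma state at 8
#' percent (20 degrees C) or 2 percent (4 degrees C) and the partially
#' disordered (PD) state at 3 percent (20 degrees C) or 75 percent (4 degrees
#' C), a slow two-state process at k_ex = 6.4 1/s, p_b = 5 percent, and CPMG
#' fixtures whose rate of leaving the Ground state rises with temperature.
#'
#' @return Named list of fixture objects consumed by the `simulate_*()`
#'   generators.
#' @export
default_fixtures <- function() {
  fx <- list()

  fx$tjump20C <- make_realtime_fixture("tjump20C", 0.09, 0.36, seed = 101L,
                                       scale = 1e7)
  ## same sample and peaks as the uncatalyzed jump (identical per-peak
  ## response factors), but a 1.25-fold higher overall intensity scale and
  ## 2.5-fold faster interconversion
  fx$tjump20C_cypa <- make_realtime_fixture("tjump20C_cypa", 0.24, 0.98,
                                            seed = 102L, scale = 1.25e7,
                                            response_seed = 101L)

  ## linear three-state chain E <-> G <-> PD; per-residue draw of the Ground
  ## position, the minor-state shift separations and relaxation rates. The
  ## Enigma state's R2 equals the Ground state's (the constraint used when
  ## fitting is true in the generator).
  draw_n15_3state <- function(r2_g_range, r1_val) {
    force(r2_g_range); force(r1_val)
    function(n_res) {
      pos_g <- runif(n_res, 112, 126)
      sgn_pd <- sample(c(-1, 1), n_res, replace = TRUE)
      sgn_e <- sample(c(-1, 1), n_res, replace = TRUE)
      r2_g <- runif(n_res, r2_g_range[1], r2_g_range[2])
      data.frame(
        residue = sort(sample(52:90, n_res)),
        pos_G = pos_g,
        pos_PD = pos_g + sgn_pd * runif(n_res, 2.5, 4),
        pos_E = pos_g + sgn_e * runif(n_res, 4.5, 6.5),
        r1 = rep(r1_val, n_res),
        r2_G = r2_g, r2_E = r2_g,
        r2_PD = runif(n_res, 4, 7),
        response = exp(rnorm(n_res, 0, 0.3))
      )
    }
  }

  model_3state <- function(p_e, p_pd, k_ge, k_gpd) {
    force(p_e); force(p_pd); force(k_ge); force(k_gpd)
    function(res_row) {
      exchange_model(
        labels = c("E", "G", "PD"),
        populations = c(p_e, 1 - p_e - p_pd, p_pd),
        rates = c("G->E" = k_ge, "G->PD" = k_gpd),
        delta_omega = c(res_row$pos_E, res_row$pos_G, res_row$pos_PD),
        r1 = rep(res_row$r1, 3),
        r2 = c(res_row$r2_E, res_row$r2_G, res_row$r2_PD)
      )
    }
  }

  ## at 4 C both the Ground and the (dominant) PD peaks are observable, and
  ## their profiles are fit jointly; the reciprocated PD-observed dips pin the
  ## Ground/PD population balance
  fx$cest15N_4C <- make_cest_fixture(
    "cest15N_4C",
    model_fn = model_3state(p_e = 0.02, p_pd = 0.75, k_ge = 4, k_gpd = 2),
    scheme = cest_scheme("N15", 800, b1_hz = 10, t_relax = 0.5,
                         offsets_ppm = default_n15_offsets()),
    n_res = 11, seed = 201L, observed = c("G", "PD"),
    draw_residue = draw_n15_3state(c(12, 20), r1_val = 1.2)
  )

  fx$cest15N_20C <- make_cest_fixture(
    "cest15N_20C",
    model_fn = model_3state(p_e = 0.08, p_pd = 0.03, k_ge = 12, k_gpd = 2),
    scheme = cest_scheme("N15", 800, b1_hz = 20, t_relax = 0.4,
                         offsets_ppm = default_n15_offsets()),
    n_res = 5, seed = 202L,
    draw_residue = draw_n15_3state(c(10, 16), r1_val = 1.5)
  )

  ## methyl 13C CEST: two-state Ground <-> Enigma, k_ex = 173 /s, p_b = 7 %;
  ## one methyl (L82-like) with a large shift separation, the rest moderate
  ## to small as in the observed methyl profiles
  fx$cestMethyl_20C <- make_cest_fixture(
    "cestMethyl_20C",
    model_fn = function(res_row) {
      two_state_model(
        kex = 173, pb = 0.07, labels = c("G", "E"),
        delta_omega = c(res_row$pos_G, res_row$pos_G + res_row$dw),
        r1 = rep(res_row$r1, 2), r2 = rep(res_row$r2_G, 2)
      )
    },
    scheme = cest_scheme("C13", 800, b1_hz = 20, t_relax = 0.4,
                         offsets_ppm = seq(8, 25, length.out = 97)),
    n_res = 6, seed = 203L,
    draw_residue = function(n_res) {
      data.frame(
        residue = c(54, 57, 60, 72, 82, 85),
        pos_G = runif(n_res, 12, 22),
        dw = c(-2.8, 1.9, -1.2, 0.7, 4.1, 0.9),
        r1 = runif(n_res, 0.8, 1.2),
        r2_G = runif(n_res, 8, 14),
        response = exp(rnorm(n_res, 0, 0.3))
      )
    }
  )

  ## slow two-state process seen for residues 39-42 (k_ex = 6.4 /s, p = 5 %);
  ## recorded at both B1 fields, which is what separates k_ex from p_b for a
  ## process this slow
  fx$cest15N_beta1_20C <- make_cest_fixture(
    "cest15N_beta1_20C",
    model_fn = function(res_row) {
      two_state_model(
        kex = 6.4, pb = 0.05, labels = c("G", "B"),
        delta_omega = c(res_row$pos_G, res_row$pos_G + res_row$dw),
        r1 = rep(res_row$r1, 2), r2 = rep(res_row$r2_G, 2)
      )
    },
    scheme = list(
      cest_scheme("N15", 800, b1_hz = 10, t_relax = 0.5,
                  offsets_ppm = default_n15_offsets()),
      cest_scheme("N15", 800, b1_hz = 20, t_relax = 0.4,
                  offsets_ppm = default_n15_offsets())
    ),
    n_res = 4, seed = 204L,
    draw_residue = function(n_res) {
      data.frame(
        residue = 39:42,
        pos_G = runif(n_res, 114, 124),
        dw = sample(c(-1, 1), n_res, replace = TRUE) * runif(n_res, 3, 5),
        r1 = rep(1.5, n_res),
        r2_G = runif(n_res, 10, 16),
        response = exp(rnorm(n_res, 0, 0.3))
      )
    }
  )

  ## multi-state volume table at 4 C: PD is the dominant species (75 %)
  fx$volumes_4C <- with_fixture_rng(301L, {
    n_res <- 11
    new_fixture(
      "volumes_4C", "volumes", 301L,
      populations = c(Ground = 0.15, FS = 0.10, PD = 0.75),
      residues = data.frame(
        residue = sort(sample(5:90, n_res)),
        response = exp(rnorm(n_res, 0, 0.3))
      ),
      scale = 1e6, noise_sigma = 0.02
    )
  })

  ## CPMG fixtures at two temperatures: rates of leaving the Ground state
  ## roughly double from 25 C to 35 C (slow-intermediate regime), two groups
  ## of residues (large Rex ~ 12 /s, small Rex ~ 2 /s). Residue-level
  ## structure is shared between the two temperatures.
  cpmg_res <- with_fixture_rng(401L, {
    n_large <- 12
    n_small <- 8
    data.frame(
      residue = sort(sample(5:90, n_large + n_small)),
      group = c(rep("large", n_large), rep("small", n_small)),
      dw = c(sample(c(-1, 1), n_large, TRUE) * runif(n_large, 3, 6),
             sample(c(-1, 1), n_small, TRUE) * runif(n_small, 2, 4)),
      pb = c(rep(0.08, n_large), rep(0.05, n_small)),
      pos_G = runif(n_large + n_small, 110, 128),
      r2_G = runif(n_large + n_small, 8, 14),
      response = exp(rnorm(n_large + n_small, 0, 0.3))
    )
  })
  cpmg_scheme_std <- cpmg_scheme("N15", 600, t_ct = 0.06,
                                 ncyc_values = default_cpmg_ncyc())
  make_cpmg_fixture <- function(name, seed, k_leave_large, k_leave_small) {
    res <- cpmg_res
    res$k_leave <- ifelse(res$group == "large", k_leave_large, k_leave_small)
    new_fixture(
      name, "cpmg", seed,
      scheme = cpmg_scheme_std, residues = res,
      scale = 1e6, noise_sigma = 0.01
    )
  }
  fx$cpmg15N_25C <- make_cpmg_fixture("cpmg15N_25C", 402L,
                                      k_leave_large = 12, k_leave_small = 2)
  fx$cpmg15N_35C <- make_cpmg_fixture("cpmg15N_35C", 403L,
                                      k_leave_large = 24, k_leave_small = 4)

  fx
}

#' Simulate a real-time temperature-jump intensity series
#'
#' Each peak's volume follows `a_i + b_i * exp(-k_obs * t)` where `k_obs` is
#' the sum of the forward and reverse interconversion rates, the plateau and
#' amplitude are set by the state populations before and after the jump times
#' a per-peak response factor, and additive Gaussian noise of sd
#' `noise_sigma * max(amplitude)` is applied. The time grid emulates ~20 min
#' spectra over 16 h starting after a 7 min deadtime.
#'
#' @param fixture A realtime fixture from [default_fixtures()].
#' @param seed Noise seed; defaults to the fixture seed. Changing it changes
#'   only the noise realization.
#' @param noise_sigma Noise level as a fraction of the maximum noiseless
#'   volume; defaults to the fixture's value.
#' @return A peak table data frame with columns `peak_id`, `residue`, `state`,
#'   `plane`, `time_h`, `volume`, `volume_sd`.
#' @export
simulate_realtime_dataset <- function(fixture, seed = fixture$seed,
                                      noise_sigma = fixture$noise_sigma) {
  stopifnot(inherits(fixture, "confex_fixture"), fixture$kind == "realtime")
  k_obs <- sum(fixture$realtime_rates)
  if (max(abs(fixture$init_pops - fixture$eq_pops)) < 1e-12) {
    warning("initial populations equal equilibrium populations: no observable decay")
  }
  times <- fixture$times_h
  pk <- fixture$peaks
  p_eq <- fixture$eq_pops[pk$state]
  p_0 <- fixture$init_pops[pk$state]
  ## volume_i(t) = scale * resp_i * (p_eq + (p_0 - p_eq) exp(-k_obs t))
  decay <- exp(-k_obs * times)
  noiseless <- do.call(rbind, lapply(seq_len(nrow(pk)), function(i) {
    v <- fixture$scale * pk$response[i] * (p_eq[i] + (p_0[i] - p_eq[i]) * decay)
    data.frame(
      peak_id = pk$peak_id[i], residue = pk$residue[i], state = pk$state[i],
      plane = seq_along(times), time_h = times, volume = v
    )
  }))
  sd_abs <- noise_sigma * max(noiseless$volume)
  with_fixture_rng(seed, {
    noiseless$volume <- noiseless$volume + rnorm(nrow(noiseless), 0, sd_abs)
  })
  noiseless$volume_sd <- max(sd_abs, .Machine$double.eps)
  noiseless
}

## per-residue exchange model of a CEST fixture
fixture_residue_model <- function(fixture, i) {
  fixture$model_fn(fixture$residues[i, , drop = FALSE])
}

#' Simulate a CEST peak-volume dataset
#'
#' Per residue and observed state, saturated-plane volumes equal the
#' Bloch-McConnell forward profile of the fixture's exchange model times the
#' peak's reference volume (per-residue response factor times the observed
#' state's population), plus Gaussian noise of fixed absolute spectral level;
#' a `t_relax = 0` reference plane (plane 0, `offset_ppm = NA`) is included
#' per peak. Fixtures may declare several observable states (e.g. Ground and
#' the dominant PD state at 4 degrees C), one peak per state.
#'
#' @inheritParams simulate_realtime_dataset
#' @param fixture A CEST fixture from [default_fixtures()].
#' @return Peak table with columns `peak_id`, `residue`, `state` (the observed
#'   state), `plane`, `offset_ppm`, `volume`, `volume_sd`.
#' @export
simulate_cest_dataset <- function(fixture, seed = fixture$seed,
                                  noise_sigma = fixture$noise_sigma) {
  stopifnot(inherits(fixture, "confex_fixture"), fixture$kind == "cest")
  schemes <- fixture$schemes %||% list(fixture$scheme)
  rows <- lapply(seq_len(nrow(fixture$residues)), function(i) {
    res <- fixture$residues[i, ]
    model <- fixture_residue_model(fixture, i)
    sd_abs <- noise_sigma * fixture$scale * res$response # spectral noise level
    do.call(rbind, lapply(seq_along(schemes), function(si) {
      sch <- schemes[[si]]
      do.call(rbind, lapply(fixture$observed, function(obs) {
        prof <- cest_profile(model, sch, obs)
        ref <- fixture$scale * res$response *
          model$populations[match(obs, model$labels)]
        data.frame(
          peak_id = paste0("R", res$residue, "_", obs),
          residue = res$residue, state = obs,
          plane = (si - 1L) * 10000L + c(0L, seq_along(prof$offset_ppm)),
          offset_ppm = c(NA_real_, prof$offset_ppm),
          b1_hz = sch$b1_hz, t_relax = sch$t_relax,
          volume = c(ref, ref * prof$intensity),
          volume_sd = sd_abs
        )
      }))
    }))
  })
  tab <- do.call(rbind, rows)
  with_fixture_rng(seed, {
    tab$volume <- tab$volume + rnorm(nrow(tab), 0, tab$volume_sd)
  })
  tab$volume_sd <- pmax(tab$volume_sd, .Machine$double.eps)
  tab
}

#' Simulate a constant-time CPMG peak-volume dataset
#'
#' Volumes are `reference * exp(-R2eff * T_CT)` plus Gaussian noise, with the
#' reference (`ncyc = 0`) and duplicate planes of the fixture's scheme
#' included for uncertainty estimation.
#'
#' @inheritParams simulate_realtime_dataset
#' @param fixture A CPMG fixture from [default_fixtures()].
#' @return Peak table with columns `peak_id`, `residue`, `state`, `plane`,
#'   `ncyc`, `volume`, `volume_sd`.
#' @export
simulate_cpmg_dataset <- function(fixture, seed = fixture$seed,
                                  noise_sigma = fixture$noise_sigma) {
  stopifnot(inherits(fixture, "confex_fixture"), fixture$kind == "cpmg")
  sch <- fixture$scheme
  rows <- lapply(seq_len(nrow(fixture$residues)), function(i) {
    res <- fixture$residues[i, ]
    model <- two_state_model(
      kex = res$k_leave / res$pb, pb = res$pb, labels = c("G", "E"),
      delta_omega = c(res$pos_G, res$pos_G + res$dw),
      r1 = c(1.5, 1.5), r2 = rep(res$r2_G, 2)
    )
    disp <- cpmg_r2eff(model, sch, "G")
    r2eff <- disp$r2eff[match(sch$ncyc_values, disp$ncyc)]
    ref <- fixture$scale * res$response
    vol <- ifelse(sch$ncyc_values == 0, ref, ref * exp(-r2eff * sch$t_ct))
    data.frame(
      peak_id = paste0("R", res$residue),
      residue = res$residue, state = "G",
      plane = seq_along(sch$ncyc_values),
      ncyc = sch$ncyc_values, volume = vol,
      volume_sd = noise_sigma * ref
    )
  })
  tab <- do.call(rbind, rows)
  with_fixture_rng(seed, {
    tab$volume <- tab$volume + rnorm(nrow(tab), 0, tab$volume_sd)
  })
  tab$volume_sd <- pmax(tab$volume_sd, .Machine$double.eps)
  tab
}

#' Simulate a multi-state HSQC peak-volume table
#'
#' For every residue, one volume per assigned state proportional to
#' population times a per-residue response factor, plus Gaussian noise.
#'
#' @inheritParams simulate_realtime_dataset
#' @param fixture A volumes fixture from [default_fixtures()].
#' @return Peak table with columns `peak_id`, `residue`, `state`, `plane`,
#'   `volume`, `volume_sd`.
#' @export
simulate_volume_table <- function(fixture, seed = fixture$seed,
                                  noise_sigma = fixture$noise_sigma) {
  stopifnot(inherits(fixture, "confex_fixture"), fixture$kind == "volumes")
  states <- names(fixture$populations)
  res <- fixture$residues
  tab <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    data.frame(
      peak_id = paste0("R", res$residue[i], "_", states),
      residue = res$residue[i], state = states, plane = 1L,
      volume = fixture$scale * res$response[i] * as.numeric(fixture$populations)
    )
  }))
  sd_abs <- noise_sigma * max(tab$volume)
  with_fixture_rng(seed, {
    tab$volume <- tab$volume + rnorm(nrow(tab), 0, sd_abs)
  })
  tab$volume_sd <- max(sd_abs, .Machine$double.eps)
  tab
}
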