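## Forward models: CEST profiles, CPMG dispersion, and the closed-form limit
## expressions used as initializers and cross-checks.

state_index <- function(model, observed_state) {
  i <- match(observed_state, model$labels)
  if (is.na(i)) {
    stop("observed_state '", observed_state, "' not among model labels: ",
         paste(model$labels, collapse = ", "))
  }
  i
}

#' Simulate a CEST profile by Bloch-McConnell propagation
#'
#' The 3N-dimensional magnetization (x, y, z per state) is propagated under
#' exchange + relaxation + B1 nutation for the saturation period `t_relax`,
#' starting from z-magnetization proportional to the stationary populations.
#' The observed state's z-component is read out and normalized by the
#' no-saturation (`t_relax = 0`) reference, i.e. by the observed population.
#'
#' @param model An [exchange_model()]; `delta_omega` holds each state's
#'   resonance position in ppm.
#' @param scheme A [cest_scheme()].
#' @param observed_state Label of the state whose peak is integrated.
#' @return A data frame with columns `offset_ppm` and `intensity` (I/I0), one
#'   row per saturation offset.
#' @seealso [cest_profile_euler()] for the brute-force integrator.
#' @export
cest_profile <- function(model, scheme, observed_state) {
  stopifnot(inherits(model, "exchange_model"), inherits(scheme, "cest_scheme"))
  obs <- state_index(model, observed_state)
  if (scheme$t_relax == 0) {
    return(data.frame(offset_ppm = scheme$offsets_ppm, intensity = 1))
  }
  freq <- nucleus_freq_mhz(scheme$nucleus, scheme$h1_freq_mhz)
  keep <- model$populations > 0
  if (!keep[obs]) stop("observed state has zero population")
  sub <- prune_states(model, keep)
  inten <- bm_cest_cpp(
    K = build_rate_matrix(sub),
    omega_rad = 2 * pi * sub$delta_omega * freq,
    r1 = sub$r1, r2 = sub$r2, pops = sub$populations,
    w1 = 2 * pi * scheme$b1_hz, t_relax = scheme$t_relax,
    offsets_rad = 2 * pi * scheme$offsets_ppm * freq,
    obs = match(observed_state, sub$labels) - 1L
  )
  data.frame(offset_ppm = scheme$offsets_ppm, intensity = as.numeric(inten))
}

## drop zero-population states (their rows/columns of the generator are only
## reachable through zero rates anyway, but removing them keeps the
## propagation well-conditioned and makes the p_b = 0 degenerate case exact)
prune_states <- function(model, keep) {
  if (all(keep)) return(model)
  k <- model$k[keep, keep, drop = FALSE]
  rates <- c()
  labs <- model$labels[keep]
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (k[i, j] > 0) rates[paste0(labs[i], "->", labs[j])] <- k[i, j]
  }
  exchange_model(
    labels = labs,
    populations = model$populations[keep] / sum(model$populations[keep]),
    rates = if (length(rates)) rates else NULL,
    delta_omega = model$delta_omega[keep],
    r1 = model$r1[keep], r2 = model$r2[keep]
  )
}

#' Brute-force CEST profile by explicit small-step Euler integration
#'
#' Integrates the same magnetization ODE as [cest_profile()] with a fixed-step
#' Euler scheme; used as an independent numerical cross-check of the
#' matrix-exponential propagation. Forward Euler applied to an oscillatory
#' system is stable only while `omega^2 * dt / 2` stays below the relaxation
#' damping, so the default step of 0.1 microseconds covers offsets tens of
#' ppm from resonance; increase `dt` only for near-resonance comparisons.
#'
#' @inheritParams cest_profile
#' @param dt Integration step in seconds (default 1e-7).
#' @return Data frame as in [cest_profile()].
#' @export
cest_profile_euler <- function(model, scheme, observed_state, dt = 1e-7) {
  stopifnot(inherits(model, "exchange_model"), inherits(scheme, "cest_scheme"))
  if (scheme$t_relax == 0) {
    return(data.frame(offset_ppm = scheme$offsets_ppm, intensity = 1))
  }
  obs <- state_index(model, observed_state)
  keep <- model$populations > 0
  sub <- prune_states(model, keep)
  freq <- nucleus_freq_mhz(scheme$nucleus, scheme$h1_freq_mhz)
  inten <- bm_cest_euler_cpp(
    K = build_rate_matrix(sub),
    omega_rad = 2 * pi * sub$delta_omega * freq,
    r1 = sub$r1, r2 = sub$r2, pops = sub$populations,
    w1 = 2 * pi * scheme$b1_hz, t_relax = scheme$t_relax,
    offsets_rad = 2 * pi * scheme$offsets_ppm * freq,
    obs = match(observed_state, sub$labels) - 1L, dt = dt
  )
  data.frame(offset_ppm = scheme$offsets_ppm, intensity = as.numeric(inten))
}

#' Effective transverse relaxation over a constant-time CPMG train
#'
#' Propagates transverse magnetization through `ncyc` ideal
#' tau-180-2tau-180-tau cycles spanning the constant-time period and returns
#' `R2,eff = -(1/T_CT) * log(I/I0)` per CPMG frequency `nu = ncyc/t_ct`.
#' Reference planes (`ncyc = 0`) are excluded from the output.
#'
#' @param model An [exchange_model()].
#' @param scheme A [cpmg_scheme()].
#' @param observed_state Label of the observed state.
#' @return Data frame with columns `ncyc`, `nu_cpmg` (Hz) and `r2eff` (1/s),
#'   one row per unique non-zero `ncyc`, ordered by `nu_cpmg`.
#' @export
cpmg_r2eff <- function(model, scheme, observed_state) {
  stopifnot(inherits(model, "exchange_model"), inherits(scheme, "cpmg_scheme"))
  obs <- state_index(model, observed_state)
  keep <- model$populations > 0
  sub <- prune_states(model, keep)
  freq <- nucleus_freq_mhz(scheme$nucleus, scheme$h1_freq_mhz)
  ncyc <- sort(unique(scheme$ncyc_values[scheme$ncyc_values > 0]))
  r2eff <- bm_cpmg_cpp(
    K = build_rate_matrix(sub),
    omega_rad = 2 * pi * (sub$delta_omega - scheme$carrier_ppm) * freq,
    r2 = sub$r2, pops = sub$populations,
    t_ct = scheme$t_ct, ncyc = as.integer(ncyc),
    obs = match(observed_state, sub$labels) - 1L
  )
  data.frame(ncyc = ncyc, nu_cpmg = ncyc / scheme$t_ct,
             r2eff = as.numeric(r2eff))
}

#' Fast-exchange limit of the exchange contribution to R2
#'
#' Standard Swift-Connick form `p_A * p_B * delta_omega^2 / k_ex` for a
#' two-state model. An optional correction subtracts `delta_R2^2` (the squared
#' difference of the intrinsic transverse relaxation rates) from
#' `delta_omega^2`; it is off by default because `delta_R2` is normally small
#' compared to `delta_omega`.
#'
#' @param model A two-state [exchange_model()].
#' @param delta_omega_rad Chemical-shift difference between the two states in
#'   rad/s.
#' @param include_dr2 Apply the `delta_R2^2` correction (default `FALSE`).
#' @return R_ex in 1/s.
#' @export
rex_fast_limit <- function(model, delta_omega_rad, include_dr2 = FALSE) {
  stopifnot(inherits(model, "exchange_model"))
  if (model$n_states != 2) stop("rex_fast_limit() requires a two-state model")
  kex <- model$k[1, 2] + model$k[2, 1]
  pa <- model$populations[1]
  pb <- model$populations[2]
  num <- delta_omega_rad^2
  if (include_dr2) num <- num - diff(model$r2)^2
  pa * pb * num / kex
}

#' Slow-exchange limit of R_ex: the rate of leaving the observed state
#'
#' @param model A two-state [exchange_model()].
#' @param observed_state Observed state's label.
#' @return R_ex in 1/s (equal to the first-order rate out of the observed
#'   state).
#' @export
rex_slow_limit <- function(model, observed_state) {
  stopifnot(inherits(model, "exchange_model"))
  if (model$n_states != 2) stop("rex_slow_limit() requires a two-state model")
  i <- state_index(model, observed_state)
  j <- setdiff(1:2, i)
  model$k[i, j]
}

#' Carver-Richards closed-form R2,eff for two-state CPMG
#'
#' Closed-form expression for the effective transverse relaxation rate of the
#' observed state under a CPMG train, valid across exchange regimes for ideal
#' pulses. Used in this package purely as an independent cross-check of the
#' numerical Bloch-McConnell propagation, never as a fitting model.
#'
#' @inheritParams cpmg_r2eff
#' @return Data frame with columns `ncyc`, `nu_cpmg`, `r2eff`.
#' @export
carver_richards_r2eff <- function(model, scheme, observed_state) {
  stopifnot(inherits(model, "exchange_model"), inherits(scheme, "cpmg_scheme"))
  if (model$n_states != 2) stop("Carver-Richards requires a two-state model")
  obs <- state_index(model, observed_state)
  oth <- setdiff(1:2, obs)
  pa <- model$populations[obs]
  pb <- model$populations[oth]
  kex <- model$k[1, 2] + model$k[2, 1]
  r2a <- model$r2[obs]
  r2b <- model$r2[oth]
  freq <- nucleus_freq_mhz(scheme$nucleus, scheme$h1_freq_mhz)
  dw <- 2 * pi * (model$delta_omega[oth] - model$delta_omega[obs]) * freq

  ncyc <- sort(unique(scheme$ncyc_values[scheme$ncyc_values > 0]))
  nu <- ncyc / scheme$t_ct

  dR <- r2a - r2b - pa * kex + pb * kex
  psi <- dR^2 - dw^2 + 4 * pa * pb * kex^2
  zeta <- 2 * dw * dR
  root <- sqrt(psi^2 + zeta^2)
  Dp <- 0.5 * (1 + (psi + 2 * dw^2) / root)
  Dm <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  etap <- sqrt(pmax(psi + root, 0) / 2) / (2 * nu)
  etam <- sqrt(pmax(-psi + root, 0) / 2) / (2 * nu)
  arg <- Dp * cosh(etap) - Dm * cos(etam)
  r2eff <- 0.5 * (r2a + r2b + kex) - nu * acosh(pmax(arg, 1))
  data.frame(ncyc = ncyc, nu_cpmg = nu, r2eff = r2eff)
}
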