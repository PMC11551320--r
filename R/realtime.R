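## Stage 1: per-peak exponential fits, the global two-state rate fit, the
## cross-experiment intensity rescaling, and bootstrap uncertainty.
##
## All exponential fits profile the linear parameters (plateau a, amplitude b)
## exactly for a trial rate k and minimize the profiled weighted residual sum
## of squares over k with a 1-D bounded search. This needs no starting values
## and cannot diverge; k >= 0 is enforced by the search interval.

## weighted LS of volume ~ a + b exp(-k t) at fixed k; returns list(a, b, rss)
profile_ab <- function(times, volumes, w, k) {
  x <- exp(-k * times)
  X <- cbind(1, x)
  fit <- stats::lm.wfit(X, volumes, w)
  list(a = fit$coefficients[1], b = fit$coefficients[2],
       rss = sum(w * fit$residuals^2))
}

#' Fit a single-exponential decay to one peak's intensity series
#'
#' Least-squares fit of `volume = a + b * exp(-k * time)` with `k >= 0`.
#' Standard errors come from the linearized Jacobian at the optimum.
#'
#' @param series Data frame with columns `time_h`, `volume` and optionally
#'   `volume_sd` (used as weights); at least 4 points, strictly increasing
#'   times.
#' @param k_max Upper bound of the rate search interval (1/h).
#' @return List with `a`, `b`, `k`, standard errors `a_se`, `b_se`, `k_se`,
#'   the residual sum of squares `rss` and a `converged` flag.
#' @export
fit_single_exponential <- function(series, k_max = 50) {
  stopifnot(all(c("time_h", "volume") %in% names(series)))
  t <- series$time_h
  y <- series$volume
  if (length(t) < 4) stop("need at least 4 points to fit a + b*exp(-k t)")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  w <- if ("volume_sd" %in% names(series)) 1 / series$volume_sd^2 else rep(1, length(t))

  obj <- function(k) profile_ab(t, y, w, k)$rss
  opt <- stats::optimize(obj, interval = c(0, k_max), tol = 1e-10)
  ## a boundary solution at k_max means the model class does not describe the
  ## series; flag it rather than report a pinned rate
  converged <- opt$minimum < k_max * (1 - 1e-6)
  ## constant series: prefer k = 0 when it fits (numerically) as well as the
  ## optimum; the threshold is scaled to the data so exact-zero residuals on
  ## both sides resolve to the parsimonious rate
  if (obj(0) <= opt$objective * (1 + 1e-9) + 1e-12 * sum(w * y^2)) {
    opt$minimum <- 0
    opt$objective <- obj(0)
    converged <- TRUE
  }
  k <- opt$minimum
  ab <- profile_ab(t, y, w, k)
  a <- unname(ab$a); b <- unname(ab$b)
  if (is.na(b)) b <- 0 # k = 0 makes the design collinear: no decaying part

  ## linearized covariance
  e <- exp(-k * t)
  J <- cbind(1, e, -b * t * e)
  dof <- max(length(t) - 3, 1)
  s2 <- ab$rss / dof
  cv <- tryCatch(s2 * solve(crossprod(J * sqrt(w))), error = function(e) NULL)
  se <- if (is.null(cv)) rep(NA_real_, 3) else sqrt(pmax(diag(cv), 0))

  list(a = a, b = b, k = k, a_se = se[1], b_se = se[2], k_se = se[3],
       rss = ab$rss, converged = converged)
}

## per-peak single-exponential fits over a realtime peak table
fit_all_peaks <- function(table) {
  ids <- unique(table$peak_id)
  rows <- lapply(ids, function(id) {
    sub <- table[table$peak_id == id, ]
    f <- tryCatch(fit_single_exponential(sub), error = function(e) NULL)
    if (is.null(f)) {
      f <- list(a = NA_real_, b = NA_real_, k = NA_real_, converged = FALSE)
    }
    data.frame(
      peak_id = id, residue = sub$residue[1], state = sub$state[1],
      a = f$a, b = f$b, k = f$k, converged = isTRUE(f$converged)
    )
  })
  do.call(rbind, rows)
}

#' Amplitude filter for the global fit
#'
#' Retains peaks whose fitted exponential amplitude satisfies
#' `|b| > threshold` (and whose per-peak fit converged), reporting retained
#' counts per state. The default threshold of 4e5 is in the fixture volume
#' units.
#'
#' @param table Realtime peak table (see [simulate_realtime_dataset()]).
#' @param threshold Amplitude threshold; peaks at or below it are dropped.
#' @param fits Optional precomputed per-peak fit table from internal per-peak
#'   fits; computed if missing.
#' @return List with the filtered `table`, the per-peak `fits` of retained
#'   peaks, and `counts` (retained peaks per state).
#' @export
filter_peaks <- function(table, threshold = 4e5, fits = NULL) {
  if (is.null(fits)) fits <- fit_all_peaks(table)
  dropped <- fits[!fits$converged | !(abs(fits$b) > threshold), ]
  if (nrow(dropped)) {
    message("filter_peaks: dropped ", nrow(dropped), " peak(s): ",
            paste(utils::head(dropped$peak_id, 10), collapse = ", "),
            if (nrow(dropped) > 10) ", ..." else "")
  }
  keep <- fits[fits$converged & abs(fits$b) > threshold, ]
  if (nrow(keep) == 0) stop("filter_peaks: no peaks pass the amplitude filter")
  list(
    table = table[table$peak_id %in% keep$peak_id, ],
    fits = keep,
    counts = c(table(keep$state))
  )
}

#' Global two-state rate fit across peaks
#'
#' Fits one shared observable rate `k_obs` across all peaks (both state
#' families jointly), with per-peak plateau and amplitude profiled exactly.
#' The observable rate is then decomposed into directional rates using the
#' equilibrium populations estimated from the amplitude/plateau fractions:
#' within a state family every peak shares
#' `b_i / a_i = (p_0 - p_eq) / p_eq` regardless of its response factor, so
#' the medians of the two families determine the equilibrium populations
#' exactly (`p_major = r_minor / (r_minor - r_major)`). Then
#' `k_(G->FS) = k_obs * p_FS` and `k_(FS->G) = k_obs * p_G`.
#'
#' @param table Realtime peak table (typically after [filter_peaks()]).
#' @param states Two state labels, major first (default `c("Ground", "FS")`).
#' @param fallback_p_minor Minor-state equilibrium population used if no
#'   residue has peaks in both states (default `NULL`: error in that case).
#' @param k_max Upper bound of the rate search (1/h).
#' @return List of class `global_fit` with `k_obs`, `k_fwd` (major -> minor),
#'   `k_rev`, `populations`, `lifetimes_h`, per-peak coefficients `coefs`,
#'   `counts` and the weighted `rss`.
#' @export
global_fit_rates <- function(table, states = c("Ground", "FS"),
                             fallback_p_minor = NULL, k_max = 50) {
  ids <- unique(table$peak_id)
  if (length(ids) < 2) stop("global fit needs at least 2 peaks")
  split_tab <- split(table, table$peak_id)[ids]

  times0 <- split_tab[[1]]$time_h
  common_grid <- all(vapply(split_tab, function(s) {
    length(s$time_h) == length(times0) && all(s$time_h == times0)
  }, logical(1)))

  if (common_grid) {
    Y <- vapply(split_tab, function(s) s$volume, numeric(length(times0)))
    wpk <- vapply(split_tab, function(s) 1 / s$volume_sd[1]^2, numeric(1))
    obj <- function(k) {
      X <- cbind(1, exp(-k * times0))
      qr_x <- qr(X)
      res <- qr.resid(qr_x, Y)
      sum(colSums(res^2) * wpk)
    }
  } else {
    obj <- function(k) {
      sum(vapply(split_tab, function(s) {
        w <- 1 / s$volume_sd^2
        profile_ab(s$time_h, s$volume, w, k)$rss
      }, numeric(1)))
    }
  }

  opt <- stats::optimize(obj, interval = c(0, k_max), tol = 1e-10)
  k_obs <- opt$minimum

  coefs <- do.call(rbind, lapply(split_tab, function(s) {
    w <- 1 / s$volume_sd^2
    ab <- profile_ab(s$time_h, s$volume, w, k_obs)
    data.frame(peak_id = s$peak_id[1], residue = s$residue[1],
               state = s$state[1], a = unname(ab$a), b = unname(ab$b))
  }))
  rownames(coefs) <- NULL

  ## directional decomposition via amplitude/plateau fractions: within each
  ## state family, b_i / a_i = (p_0 - p_eq) / p_eq is independent of the
  ## per-peak response factor, so with r_major and r_minor the medians of the
  ## two families and a common initial condition,
  ## p_major = r_minor / (r_minor - r_major) exactly
  major <- coefs[coefs$state == states[1], ]
  minor <- coefs[coefs$state == states[2], ]
  r_of <- function(cf) {
    ok <- is.finite(cf$a) & cf$a > 0
    if (!any(ok)) return(NA_real_)
    stats::median(cf$b[ok] / cf$a[ok])
  }
  r_maj <- r_of(major)
  r_min <- r_of(minor)
  if (is.finite(r_maj) && is.finite(r_min) &&
      abs(r_min - r_maj) > 1e-8 && r_min * r_maj <= 0) {
    p_minor <- 1 - r_min / (r_min - r_maj)
    p_minor <- min(max(p_minor, 0), 1)
  } else if (!is.null(fallback_p_minor)) {
    p_minor <- fallback_p_minor
  } else if (nrow(major) == 0 || nrow(minor) == 0) {
    warning("global_fit_rates: peaks for only one state; directional split unavailable")
    p_minor <- NA_real_
  } else {
    stop("directional split is undetermined (no opposing amplitude fractions); supply fallback_p_minor")
  }

  pops <- c(1 - p_minor, p_minor)
  names(pops) <- states
  k_fwd <- k_obs * p_minor     # major -> minor, e.g. k_(G->FS)
  k_rev <- k_obs * (1 - p_minor)

  structure(
    list(
      k_obs = k_obs, k_fwd = k_fwd, k_rev = k_rev,
      populations = pops,
      lifetimes_h = c(1 / k_fwd, 1 / k_rev),
      coefs = coefs, counts = c(table(coefs$state)), rss = opt$objective
    ),
    class = "global_fit"
  )
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("<global_fit> k_obs = %.4g /h; k_fwd = %.4g /h, k_rev = %.4g /h\n",
              x$k_obs, x$k_fwd, x$k_rev))
  cat("equilibrium populations:",
      paste(sprintf("%s = %.3f", names(x$populations), x$populations),
            collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap uncertainty of the global rates
#'
#' Each replicate (i) re-draws Gaussian noise per data point at its stated
#' uncertainty and (ii) resamples peaks with replacement within each state,
#' then repeats the global fit. Returns percentile intervals (2.5/97.5) and
#' standard deviations for the three rates.
#'
#' @inheritParams global_fit_rates
#' @param n_boot Number of replicates (warning below 50).
#' @param seed Required integer seed.
#' @param resample_peaks Resample peaks with replacement within each state
#'   (default `TRUE`).
#' @param resample_noise Re-draw per-point noise (default `TRUE`).
#' @return List with a `replicates` data frame (`k_fwd`, `k_rev`, `k_obs` per
#'   replicate), an `intervals` matrix and `sd` vector.
#' @export
bootstrap_uncertainty <- function(table, n_boot = 1000, seed,
                                  states = c("Ground", "FS"),
                                  resample_peaks = TRUE,
                                  resample_noise = TRUE) {
  if (missing(seed)) stop("bootstrap_uncertainty: a seed is required")
  if (n_boot < 50) warning("n_boot < 50: intervals will be unstable")
  peaks <- unique(table[, c("peak_id", "state")])
  split_tab <- split(table, table$peak_id)
  reps <- with_fixture_rng(seed, {
    do.call(rbind, lapply(seq_len(n_boot), function(b) {
      if (resample_peaks) {
        sel <- unlist(lapply(states, function(s) {
          ids <- peaks$peak_id[peaks$state == s]
          sample(ids, length(ids), replace = TRUE)
        }))
      } else {
        sel <- peaks$peak_id
      }
      tab_b <- do.call(rbind, lapply(seq_along(sel), function(j) {
        s <- split_tab[[sel[j]]]
        s$peak_id <- paste0("bs", j) # resampled copies count as distinct peaks
        if (resample_noise) s$volume <- s$volume + stats::rnorm(nrow(s), 0, s$volume_sd)
        s
      }))
      fit <- global_fit_rates(tab_b, states = states)
      data.frame(k_fwd = fit$k_fwd, k_rev = fit$k_rev, k_obs = fit$k_obs)
    }))
  })
  qs <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  rownames(qs) <- c("2.5%", "97.5%")
  list(replicates = reps, intervals = qs, sd = apply(reps, 2, stats::sd))
}

#' Cross-experiment intensity scale factor
#'
#' Robust (median) ratio of matched peak amplitudes between two experiments
#' sharing peaks of a given state; e.g. a higher signal-to-noise repeat
#' experiment can be put on the scale of the first by dividing its volumes by
#' the returned factor. For time series the per-peak amplitude is the fitted
#' exponential plateau, which cancels both the kinetic time course and the
#' point noise; tables without a time axis compare per-peak median volumes.
#'
#' @param table_a,table_b Realtime peak tables sharing peak ids.
#' @param state State whose peaks anchor the comparison (default `"Ground"`).
#' @return Scalar factor such that `table_b`'s matched-peak amplitudes are
#'   `factor` times those of `table_a`.
#' @export
estimate_scale_factor <- function(table_a, table_b, state = "Ground") {
  a <- table_a[table_a$state == state, ]
  b <- table_b[table_b$state == state, ]
  ids <- intersect(unique(a$peak_id), unique(b$peak_id))
  if (length(ids) == 0) stop("no shared peaks of state '", state, "'")
  if (length(ids) < 5) warning("fewer than 5 shared peaks; factor unstable")
  amp_fun <- if ("time_h" %in% names(a) && "time_h" %in% names(b)) {
    function(tab, id) {
      f <- tryCatch(fit_single_exponential(tab[tab$peak_id == id, ]),
                    error = function(e) NULL)
      if (is.null(f) || !is.finite(f$a) || f$a <= 0) NA_real_ else f$a
    }
  } else {
    function(tab, id) stats::median(tab$volume[tab$peak_id == id])
  }
  ratios <- vapply(ids, function(id) amp_fun(b, id) / amp_fun(a, id),
                   numeric(1))
  stats::median(ratios, na.rm = TRUE)
}
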