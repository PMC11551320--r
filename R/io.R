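## Shared readers/writers and the end-to-end pipeline driver.

peak_core_cols <- c("peak_id", "residue", "state", "plane", "volume", "volume_sd")

#' Write / read a peak table as tab-separated text
#'
#' Tables are written with a one-line header; `read_peak_table()` validates
#' the core columns (`peak_id`, `residue`, `state`, `plane`, `volume`,
#' `volume_sd`), carries unknown extra columns through, and reports malformed
#' numeric fields with their line number.
#'
#' @param table A peak table data frame.
#' @param path Output/input path.
#' @return `read_peak_table()` returns the data frame; `write_peak_table()`
#'   returns `path` invisibly.
#' @export
write_peak_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  miss <- setdiff(peak_core_cols, header)
  if (length(miss)) {
    stop("peak table ", path, " missing column(s): ", paste(miss, collapse = ", "))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  num_cols <- intersect(c("residue", "plane", "volume", "volume_sd",
                          "time_h", "offset_ppm", "ncyc", "b1_hz", "t_relax"),
                        names(tab))
  for (cn in num_cols) {
    raw <- tab[[cn]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | raw %in% c("NA", "")))
    if (length(bad)) {
      stop("peak table ", path, ": malformed numeric in column '", cn,
           "' at line ", bad[1] + 1) # +1 for the header line
    }
    tab[[cn]] <- val
  }
  tab
}

#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file with stage blocks. Every stochastic stage
#' must name an explicit seed; unknown top-level keys are rejected.
#'
#' @param path Path to a YAML config.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Configuration list (as from `yaml::read_yaml`).
#' @export
validate_run_config <- function(cfg) {
  known <- c("out_dir", "simulate", "realtime", "cest", "cpmg", "landscape")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$out_dir)) stop("config requires out_dir")
  if (!is.null(cfg$simulate) && is.null(cfg$simulate$seed)) {
    stop("simulate stage requires an explicit seed")
  }
  if (!is.null(cfg$realtime)) {
    if (is.null(cfg$realtime$n_boot)) cfg$realtime$n_boot <- 200
    if (cfg$realtime$n_boot > 0 && is.null(cfg$realtime$seed)) {
      stop("realtime bootstrap requires an explicit seed")
    }
    if (is.null(cfg$realtime$threshold)) cfg$realtime$threshold <- 4e5
  }
  if (!is.null(cfg$cest)) {
    if (is.null(cfg$cest$seed)) {
      stop("cest stage requires an explicit seed (multi-start jitter)")
    }
    if (is.null(cfg$cest$thin)) cfg$cest$thin <- 1
  }
  if (!is.null(cfg$cpmg)) {
    if (is.null(cfg$cpmg$seed)) stop("cpmg stage requires an explicit seed")
    if (is.null(cfg$cpmg$alpha)) cfg$cpmg$alpha <- 0.05
    if (is.null(cfg$cpmg$nu_low)) cfg$cpmg$nu_low <- 50
  }
  if (!is.null(cfg$landscape)) {
    if (is.null(cfg$landscape$temperature)) cfg$landscape$temperature <- 293.15
    if (is.null(cfg$landscape$offset_cold)) cfg$landscape$offset_cold <- 2
  }
  cfg
}

#' Default demonstration configuration
#'
#' Runs every stage on the built-in fixtures at reduced fitting effort.
#'
#' @param out_dir Output directory.
#' @param seed Base seed.
#' @return Configuration list accepted by [run_pipeline()].
#' @export
default_run_config <- function(out_dir, seed = 1L) {
  validate_run_config(list(
    out_dir = out_dir,
    simulate = list(seed = seed),
    realtime = list(threshold = 4e5, n_boot = 100, seed = seed + 1L),
    cest = list(seed = seed + 2L, starts = 1, maxit = 200),
    cpmg = list(seed = seed + 3L, alpha = 0.05, nu_low = 50),
    landscape = list(temperature = 293.15, offset_cold = 2)
  ))
}

log_stage <- function(log_path, stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  cat(msg, "\n", file = log_path, append = TRUE)
  invisible(msg)
}

#' Run the full analysis pipeline on fixture data
#'
#' Chains simulate -> realtime fit -> CEST fit -> CPMG Rex/classification ->
#' landscape, logging every stage's seeds and parameters, and writes each
#' stage's report (YAML) plus the input tables under the configured output
#' directory. Input files are never modified; rerunning with the same config
#' reproduces the same outputs.
#'
#' @param config Configuration list (see [read_run_config()] /
#'   [default_run_config()]).
#' @return List with the stage results: `realtime`, `cest`, `cpmg`,
#'   `landscape`, and `paths` of written artifacts.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  cat("", file = log_path)
  paths <- list(log = log_path)
  fx <- default_fixtures()
  results <- list()

  ## --- simulate -----------------------------------------------------------
  seed <- config$simulate$seed
  log_stage(log_path, "simulate", "seed = ", seed)
  tab_rt <- simulate_realtime_dataset(fx$tjump20C, seed = seed)
  tab_cest <- simulate_cest_dataset(fx$cest15N_20C, seed = seed + 10L)
  tab_cpmg1 <- simulate_cpmg_dataset(fx$cpmg15N_25C, seed = seed + 20L)
  tab_cpmg2 <- simulate_cpmg_dataset(fx$cpmg15N_35C, seed = seed + 21L)
  for (nm in c("tab_rt", "tab_cest", "tab_cpmg1", "tab_cpmg2")) {
    p <- file.path(out, paste0(nm, ".tsv"))
    write_peak_table(get(nm), p)
    paths[[nm]] <- p
  }

  ## --- realtime -----------------------------------------------------------
  rt_cfg <- config$realtime
  log_stage(log_path, "realtime", "threshold = ", rt_cfg$threshold,
            ", n_boot = ", rt_cfg$n_boot, ", seed = ", rt_cfg$seed)
  filt <- filter_peaks(tab_rt, threshold = rt_cfg$threshold)
  rt_fit <- global_fit_rates(filt$table)
  rt_boot <- if (rt_cfg$n_boot > 0) {
    bootstrap_uncertainty(filt$table, n_boot = rt_cfg$n_boot, seed = rt_cfg$seed)
  } else NULL
  results$realtime <- list(fit = rt_fit, bootstrap = rt_boot, counts = filt$counts)
  report <- list(
    k_fwd_per_h = rt_fit$k_fwd, k_rev_per_h = rt_fit$k_rev,
    k_obs_per_h = rt_fit$k_obs,
    lifetimes_h = as.list(rt_fit$lifetimes_h),
    populations = as.list(rt_fit$populations),
    peaks_used = as.list(filt$counts)
  )
  if (!is.null(rt_boot)) report$rate_sd <- as.list(rt_boot$sd)
  paths$realtime_report <- file.path(out, "realtime_report.yaml")
  yaml::write_yaml(report, paths$realtime_report)

  ## --- cest ---------------------------------------------------------------
  log_stage(log_path, "cest", "topology = linear_three_state, seed = ",
            config$cest$seed)
  tab_cest_fit <- tab_cest
  thin <- config$cest$thin %||% 1
  if (thin > 1) {
    ## keep reference planes and every thin-th saturated offset per peak
    keep <- is.na(tab_cest_fit$offset_ppm) | (tab_cest_fit$plane %% thin == 0)
    tab_cest_fit <- tab_cest_fit[keep, ]
  }
  cest_fit <- fit_exchange_model(
    tab_cest_fit, "linear_three_state", fx$cest15N_20C$scheme,
    tie_r2 = "E", starts = config$cest$starts %||% 1,
    deep_minor = "E", seed = config$cest$seed,
    maxit = config$cest$maxit %||% 400,
    regimes = config$cest$regimes %||% c("slow", "mid", "fast", "anchored"),
    carry = config$cest$carry %||% 2
  )
  results$cest <- cest_fit
  paths$cest_report <- file.path(out, "cest_report.yaml")
  yaml::write_yaml(list(
    topology = cest_fit$topology, rates = as.list(cest_fit$rates),
    populations = as.list(cest_fit$populations),
    chi2_red = cest_fit$chi2_red
  ), paths$cest_report)

  ## --- cpmg ---------------------------------------------------------------
  log_stage(log_path, "cpmg", "nu_low = ", config$cpmg$nu_low,
            ", alpha = ", config$cpmg$alpha)
  rex1 <- rex_table(tab_cpmg1, fx$cpmg15N_25C$scheme, nu_low = config$cpmg$nu_low)
  rex2 <- rex_table(tab_cpmg2, fx$cpmg15N_35C$scheme, nu_low = config$cpmg$nu_low)
  cls <- classify_regime(rex1, rex2, alpha = config$cpmg$alpha,
                         seed = config$cpmg$seed)
  results$cpmg <- cls
  paths$cpmg_report <- file.path(out, "cpmg_report.tsv")
  utils::write.table(cls, paths$cpmg_report, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- landscape ----------------------------------------------------------
  temp <- config$landscape$temperature
  log_stage(log_path, "landscape", "T = ", temp, " K")
  cest_pops <- cest_fit$populations[c("E", "G", "PD")]
  names(cest_pops) <- c("Enigma", "Ground", "PD")
  merged <- merge_populations(cest_pops, rt_fit$populations,
                              anchor_state = "Ground")
  rates <- c(
    "Ground->FS" = unname(rt_fit$k_fwd) / 3600,
    "Ground->Enigma" = unname(cest_fit$rates[["G->E"]]),
    "Ground->PD" = unname(cest_fit$rates[["G->PD"]])
  )
  land <- build_landscape(merged, rates, temperature = temp,
                          reference = "Ground")
  results$landscape <- land
  paths$landscape_report <- file.path(out, "landscape_report.yaml")
  yaml::write_yaml(list(
    temperature_K = temp,
    populations = as.list(merged),
    dG_kcal = as.list(land$dg),
    barriers = land$barriers
  ), paths$landscape_report)

  results$paths <- paths
  log_stage(log_path, "done", "all stages complete")
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a
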