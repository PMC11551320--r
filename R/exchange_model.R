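## Multi-state exchange models: constructor, validation, rate-matrix algebra,
## and plain-text (YAML) serialization.

#' Construct a multi-state chemical exchange model
#'
#' An exchange model holds `n` conformational states with first-order
#' interconversion rates on a set of directed edges, stationary populations,
#' and per-state chemical-shift offsets and relaxation rates. Populations and
#' rates must satisfy detailed balance on every edge
#' (`p_i * k_ij == p_j * k_ji`), which also makes the population vector the
#' stationary vector of the assembled rate matrix.
#'
#' Rates are supplied as a named numeric vector with names of the form
#' `"A->B"` giving the forward rate from state `A` to state `B` in 1/s. For
#' every edge either direction may be given; the reverse rate is filled in
#' from detailed balance if missing.
#'
#' @param labels Character vector of state names (length >= 1).
#' @param populations Stationary fractions, summing to 1.
#' @param rates Named numeric vector of first-order rates in 1/s, names like
#'   `"G->E"`. May be `NULL` for a single-state model.
#' @param delta_omega Chemical shift per state in ppm (absolute position
#'   relative to a stated carrier convention; one value per state).
#' @param r1 Longitudinal relaxation rate per state (1/s).
#' @param r2 Transverse relaxation rate per state (1/s).
#' @return An object of class `exchange_model`.
#' @examples
#' m <- exchange_model(
#'   labels = c("G", "E"), populations = c(0.92, 0.08),
#'   rates = c("G->E" = 12), delta_omega = c(119.5, 125.2),
#'   r1 = c(1.5, 1.5), r2 = c(12, 12)
#' )
#' build_rate_matrix(m)
#' @export
exchange_model <- function(labels, populations, rates = NULL,
                           delta_omega = NULL, r1 = NULL, r2 = NULL) {
  n <- length(labels)
  stopifnot(n >= 1, !anyDuplicated(labels))
  populations <- as.numeric(populations)
  if (length(populations) != n) stop("populations must have one entry per state")
  if (abs(sum(populations) - 1) > 1e-9) stop("populations must sum to 1 (within 1e-9)")
  if (any(populations < 0)) stop("populations must be non-negative")
  if (is.null(delta_omega)) delta_omega <- rep(0, n)
  if (is.null(r1)) r1 <- rep(0, n)
  if (is.null(r2)) r2 <- rep(0, n)
  stopifnot(length(delta_omega) == n, length(r1) == n, length(r2) == n)
  if (any(r1 < 0) || any(r2 < 0)) stop("relaxation rates must be >= 0")

  k <- matrix(0, n, n, dimnames = list(labels, labels)) # k[i, j] = rate i -> j
  if (!is.null(rates) && length(rates)) {
    if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
      stop("rates must be a named vector with names like 'A->B'")
    }
    for (nm in names(rates)) {
      ends <- strsplit(nm, "->", fixed = TRUE)[[1]]
      if (length(ends) != 2 || !all(ends %in% labels)) {
        stop("rate '", nm, "' references an unknown state (labels: ",
             paste(labels, collapse = ", "), ")")
      }
      if (rates[[nm]] < 0) stop("rate '", nm, "' must be >= 0")
      k[ends[1], ends[2]] <- rates[[nm]]
    }
    ## fill reverse rates from detailed balance where only one direction given
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && xor(k[i, j] > 0, k[j, i] > 0)) {
        if (k[i, j] > 0) {
          if (populations[j] <= 0) stop("cannot infer reverse rate into zero-population state")
          k[j, i] <- k[i, j] * populations[i] / populations[j]
        } else {
          if (populations[i] <= 0) stop("cannot infer reverse rate into zero-population state")
          k[i, j] <- k[j, i] * populations[j] / populations[i]
        }
      }
    }
    ## detailed balance on every edge
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && (k[i, j] > 0 || k[j, i] > 0)) {
        db <- populations[i] * k[i, j] - populations[j] * k[j, i]
        scale <- max(populations[i] * k[i, j], populations[j] * k[j, i], 1)
        if (abs(db) / scale > 1e-8) {
          stop("detailed balance violated on edge ", labels[i], "<->", labels[j])
        }
      }
    }
  }

  structure(
    list(
      n_states = n, labels = labels, populations = populations,
      k = k, delta_omega = as.numeric(delta_omega),
      r1 = as.numeric(r1), r2 = as.numeric(r2)
    ),
    class = "exchange_model"
  )
}

#' Convenience constructor for a two-state model from (k_ex, p_b)
#'
#' Standard CEST/CPMG parameterization: total exchange rate
#' `k_ex = k_AB + k_BA` and minor-state population `p_b`, with
#' `k_AB = p_b * k_ex` and `k_BA = (1 - p_b) * k_ex`.
#'
#' @param kex Total exchange rate (1/s).
#' @param pb Minor-state population (fraction).
#' @param labels Two state names, major first.
#' @param delta_omega,r1,r2 Per-state values as in [exchange_model()].
#' @return An `exchange_model` with two states.
#' @export
two_state_model <- function(kex, pb, labels = c("A", "B"),
                            delta_omega = c(0, 0), r1 = c(1.5, 1.5),
                            r2 = c(10, 10)) {
  stopifnot(kex >= 0, pb >= 0, pb < 1)
  rates <- c(pb * kex, (1 - pb) * kex)
  names(rates) <- c(
    paste0(labels[1], "->", labels[2]),
    paste0(labels[2], "->", labels[1])
  )
  exchange_model(labels, c(1 - pb, pb), rates, delta_omega, r1, r2)
}

#' @export
print.exchange_model <- function(x, ...) {
  cat("<exchange_model> ", x$n_states, " state(s): ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  cat("populations:", paste(signif(x$populations, 4), collapse = ", "), "\n")
  edges <- which(x$k > 0, arr.ind = TRUE)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      cat(sprintf("  k %s->%s = %g /s\n", x$labels[edges[r, 1]],
                  x$labels[edges[r, 2]], x$k[edges[r, 1], edges[r, 2]]))
    }
  }
  invisible(x)
}

#' Assemble the first-order rate matrix of an exchange model
#'
#' Returns the generator `K` with off-diagonal entry `K[j, i] = k_(i->j)` and
#' diagonal entries set so every column sums to zero; the population vector is
#' then a right null vector (`K %*% p = 0`), i.e. the stationary state of
#' `dM/dt = K %*% M`.
#'
#' @param model An [exchange_model()].
#' @return Square numeric matrix (1/s) with state labels as dimnames.
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "exchange_model"))
  K <- t(model$k) # K[j, i] = k_(i->j)
  diag(K) <- 0
  diag(K) <- -colSums(K)
  K
}

#' Total exchange rate and minor population of a two-state model
#'
#' @param model A two-state [exchange_model()].
#' @return Named vector `c(kex = , pb = )` where `pb` is the smaller
#'   population.
#' @export
kex_pb <- function(model) {
  stopifnot(inherits(model, "exchange_model"))
  if (model$n_states != 2) stop("kex_pb() requires a two-state model")
  c(kex = model$k[1, 2] + model$k[2, 1], pb = min(model$populations))
}

#' Serialize an exchange model (or acquisition scheme) to a YAML config block
#'
#' Round-trip guaranteed: `model_from_config(model_to_config(m))` reproduces
#' `m` exactly for all stored fields.
#'
#' @param model An [exchange_model()].
#' @param path Optional file path; if given the YAML text is written there.
#' @return YAML text (invisibly, if `path` given).
#' @export
model_to_config <- function(model, path = NULL) {
  stopifnot(inherits(model, "exchange_model"))
  edges <- which(model$k > 0, arr.ind = TRUE)
  rate_list <- list()
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      nm <- paste0(model$labels[edges[r, 1]], "->", model$labels[edges[r, 2]])
      rate_list[[nm]] <- model$k[edges[r, 1], edges[r, 2]]
    }
  }
  obj <- list(
    labels = as.list(model$labels),
    populations = as.list(model$populations),
    rates = rate_list,
    delta_omega = as.list(model$delta_omega),
    r1 = as.list(model$r1),
    r2 = as.list(model$r2)
  )
  txt <- yaml::as.yaml(obj, precision = 17)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname model_to_config
#' @param text YAML text as produced by [model_to_config()]; alternatively use
#'   `file` to read from disk.
#' @param file Path to a YAML config file.
#' @export
model_from_config <- function(text = NULL, file = NULL) {
  obj <- if (!is.null(file)) yaml::read_yaml(file) else yaml::yaml.load(text)
  rates <- unlist(obj$rates)
  exchange_model(
    labels = unlist(obj$labels),
    populations = unlist(obj$populations),
    rates = if (length(rates)) rates else NULL,
    delta_omega = unlist(obj$delta_omega),
    r1 = unlist(obj$r1),
    r2 = unlist(obj$r2)
  )
}
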