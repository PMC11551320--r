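## Stage 4: populations from peak volumes, merging of CEST and real-time
## population estimates, Boltzmann state free energies, Eyring barriers, and
## the cross-temperature offset.

#' Per-state populations from a multi-state peak-volume table
#'
#' Per residue, each assigned state's population is its volume divided by the
#' residue's total over assigned states; populations are then averaged across
#' residues per state. Residues missing a state are excluded from that
#' state's average (logged).
#'
#' @param table Volume peak table with columns `residue`, `state`, `volume`.
#' @param states Optional state subset/ordering; defaults to all states
#'   present.
#' @return List with `mean` (named average population per state, renormalized
#'   to sum to 1), `per_residue` (wide data frame of per-residue populations)
#'   and `n_residues` used per state.
#' @export
populations_from_volumes <- function(table, states = NULL) {
  if (is.null(states)) states <- unique(table$state)
  per_res <- lapply(split(table, table$residue), function(sub) {
    sub <- sub[sub$state %in% states, ]
    if (nrow(sub) < 2) return(NULL) # need >= 2 assigned states
    v <- tapply(sub$volume, factor(sub$state, levels = states), mean)
    p <- v / sum(v, na.rm = TRUE)
    c(residue = sub$residue[1], p)
  })
  dropped <- names(per_res)[vapply(per_res, is.null, TRUE)]
  if (length(dropped)) {
    message("populations_from_volumes: excluded residue(s) with < 2 assigned states: ",
            paste(dropped, collapse = ", "))
  }
  per_res <- do.call(rbind, per_res)
  if (is.null(per_res)) stop("no residue with >= 2 assigned state volumes")
  per_res <- as.data.frame(per_res)
  incomplete <- apply(per_res[, states, drop = FALSE], 1, function(x) any(is.na(x)))
  if (any(incomplete)) {
    message("populations_from_volumes: ", sum(incomplete),
            " residue(s) missing a state excluded from that state's average")
  }
  mean_p <- colMeans(per_res[, states, drop = FALSE], na.rm = TRUE)
  mean_p <- mean_p / sum(mean_p)
  list(mean = mean_p, per_residue = per_res,
       n_residues = colSums(!is.na(per_res[, states, drop = FALSE])))
}

#' Merge CEST-derived and real-time-derived populations
#'
#' States quantified by CEST (e.g. Ground, Enigma, PD) are invisible or
#' unresolved in the real-time HSQC series, where their combined intensity
#' appears as the anchor state's peak. The CEST populations (which sum to 1
#' over the CEST-visible states) are therefore rescaled so their total equals
#' the anchor state's real-time population; states observed only in the
#' real-time data (e.g. FS) pass through, so the merged set sums to 1.
#'
#' @param cest_pops Named populations over the CEST-visible states (sum to 1).
#' @param realtime_pops Named populations from the real-time experiment,
#'   containing `anchor_state`.
#' @param anchor_state The real-time state that carries the CEST-visible mass
#'   (default `"Ground"`).
#' @return Named population vector over all states, summing to 1.
#' @export
merge_populations <- function(cest_pops, realtime_pops, anchor_state = "Ground") {
  if (!(anchor_state %in% names(realtime_pops))) {
    stop("anchor state '", anchor_state, "' missing from realtime populations")
  }
  if (realtime_pops[[anchor_state]] <= 0) stop("anchor population is zero in realtime input")
  if (sum(cest_pops) <= 0) stop("anchor population is zero in CEST input")
  scaled <- cest_pops * realtime_pops[[anchor_state]] / sum(cest_pops)
  rest <- realtime_pops[setdiff(names(realtime_pops), anchor_state)]
  out <- c(scaled, rest)
  out / sum(out)
}

#' Boltzmann state free energies from populations
#'
#' `dG_i = -R T log(p_i / p_ref)` in kcal/mol with
#' `R = 1.98720425e-3 kcal/(mol K)`; the reference state has `dG = 0`.
#'
#' @param pops Named population vector (> 0).
#' @param temperature Temperature in K.
#' @param reference Reference state name (default the most populated state).
#' @return Named vector of free energies (kcal/mol).
#' @export
state_free_energies <- function(pops, temperature, reference = NULL) {
  if (any(pops <= 0)) {
    stop("zero population for state(s): ",
         paste(names(pops)[pops <= 0], collapse = ", "))
  }
  if (is.null(reference)) reference <- names(pops)[which.max(pops)]
  if (!(reference %in% names(pops))) stop("unknown reference state: ", reference)
  -nmr_constants$R_kcal * temperature * log(pops / pops[[reference]])
}

#' Eyring barrier from a rate constant
#'
#' `dG_act = -R T log(k h / (kappa kB T))` in kcal/mol, with the transmission
#' coefficient `kappa = 1` by default. [eyring_rate()] is the exact inverse.
#'
#' @param k Rate constant in 1/s (> 0).
#' @param temperature Temperature in K.
#' @param kappa Transmission coefficient (default 1).
#' @return Barrier height in kcal/mol.
#' @export
eyring_barrier <- function(k, temperature, kappa = 1) {
  if (any(k <= 0)) stop("rate must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  pref <- kappa * nmr_constants$kB * temperature / nmr_constants$h
  -nmr_constants$R_kcal * temperature * log(k / pref)
}

#' @rdname eyring_barrier
#' @param dg Barrier height in kcal/mol.
#' @export
eyring_rate <- function(dg, temperature, kappa = 1) {
  pref <- kappa * nmr_constants$kB * temperature / nmr_constants$h
  pref * exp(-dg / (nmr_constants$R_kcal * temperature))
}

#' Assemble a free-energy landscape from populations and rates
#'
#' State free energies come from Boltzmann inversion of the (merged)
#' populations relative to the reference state; each transition's barrier is
#' the Eyring barrier of the rate leaving the reference-side state plus that
#' state's own free energy, so barriers sit above both connected states.
#'
#' @param pops Named populations over all states (sum to 1).
#' @param rates Named rate vector like `c("Ground->FS" = 2.5e-5)` in 1/s
#'   (rates out of the state whose free energy anchors the barrier).
#' @param temperature Temperature in K.
#' @param reference Reference state (default most populated).
#' @return Object of class `landscape`: `temperature`, `populations`, `dg`
#'   (kcal/mol per state), `barriers` (data frame: `from`, `to`, `dg_act`
#'   relative barrier, `dg_abs` absolute barrier above the reference) and
#'   `offset_applied` (0 until [apply_temperature_offset()]).
#' @export
build_landscape <- function(pops, rates, temperature, reference = NULL) {
  dg <- state_free_energies(pops, temperature, reference)
  barriers <- NULL
  if (length(rates)) {
    ends <- strsplit(names(rates), "->", fixed = TRUE)
    barriers <- data.frame(
      from = vapply(ends, `[`, "", 1),
      to = vapply(ends, `[`, "", 2),
      k = as.numeric(rates)
    )
    if (!all(barriers$from %in% names(pops)) || !all(barriers$to %in% names(pops))) {
      stop("rate names reference unknown states")
    }
    barriers$dg_act <- eyring_barrier(barriers$k, temperature)
    barriers$dg_abs <- dg[barriers$from] + barriers$dg_act
  }
  structure(
    list(temperature = temperature, populations = pops, dg = dg,
         barriers = barriers, offset_applied = 0),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> T = %.2f K (offset applied: %g kcal/mol)\n",
              x$temperature, x$offset_applied))
  print(data.frame(state = names(x$dg), p = as.numeric(x$populations[names(x$dg)]),
                   dG_kcal = as.numeric(x$dg)), row.names = FALSE)
  if (!is.null(x$barriers)) {
    cat("barriers:\n")
    print(x$barriers[, c("from", "to", "k", "dg_act", "dg_abs")], row.names = FALSE)
  }
  invisible(x)
}

#' Shift a cold-temperature landscape by a constant free-energy offset
#'
#' State free energies at two temperatures are each defined relative to their
#' own reference, so an absolute offset between the two diagrams is
#' unidentified. Assuming the absolute height of the shared rate-limiting
#' barrier cannot decrease with temperature bounds the offset from below;
#' a constant (default 2 kcal/mol) is added to every cold-temperature state
#' and barrier value. If the chosen offset still leaves the cold barrier below
#' the warm one, a warning reports the minimal compliant offset.
#'
#' @param landscape_cold,landscape_warm `landscape` objects sharing the
#'   rate-limiting transition.
#' @param offset Constant added to all cold-temperature free energies
#'   (kcal/mol, default 2).
#' @param transition Length-2 character vector naming the shared transition
#'   (default: the cold landscape's highest absolute barrier).
#' @return The adjusted cold `landscape`.
#' @export
apply_temperature_offset <- function(landscape_cold, landscape_warm, offset = 2,
                                     transition = NULL) {
  stopifnot(inherits(landscape_cold, "landscape"),
            inherits(landscape_warm, "landscape"))
  bc <- landscape_cold$barriers
  bw <- landscape_warm$barriers
  if (is.null(bc) || is.null(bw)) stop("both landscapes need barriers")
  if (is.null(transition)) {
    i <- which.max(bc$dg_abs)
    transition <- c(bc$from[i], bc$to[i])
  }
  ic <- which(bc$from == transition[1] & bc$to == transition[2])
  iw <- which(bw$from == transition[1] & bw$to == transition[2])
  if (length(ic) != 1 || length(iw) != 1) {
    stop("shared transition ", paste(transition, collapse = "->"),
         " not present in both landscapes")
  }
  out <- landscape_cold
  out$dg <- out$dg + offset
  out$barriers$dg_abs <- out$barriers$dg_abs + offset
  out$offset_applied <- landscape_cold$offset_applied + offset
  if (out$barriers$dg_abs[ic] < bw$dg_abs[iw]) {
    minimal <- bw$dg_abs[iw] - landscape_cold$barriers$dg_abs[ic]
    warning(sprintf(
      "offset %.3g kcal/mol leaves the cold barrier below the warm one; minimal compliant offset is %.3g kcal/mol",
      offset, minimal
    ))
  }
  out
}
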