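## Acquisition schemes for CEST and CPMG experiments.

#' CEST acquisition scheme
#'
#' Describes a saturation-transfer experiment: a weak B1 field of strength
#' `b1_hz` applied for `t_relax` seconds at each offset in `offsets_ppm`,
#' plus one reference plane recorded with `t_relax = 0`.
#'
#' @param nucleus Saturated nucleus, `"N15"` or `"C13"`.
#' @param h1_freq_mhz Spectrometer 1H frequency in MHz.
#' @param b1_hz Saturation field strength in Hz (> 0).
#' @param t_relax Saturation period in seconds (> 0).
#' @param offsets_ppm Saturation offsets in ppm.
#' @param carrier_ppm Carrier position in ppm (offsets are absolute ppm; the
#'   carrier is retained for bookkeeping).
#' @return Object of class `cest_scheme`.
#' @export
cest_scheme <- function(nucleus, h1_freq_mhz, b1_hz, t_relax, offsets_ppm,
                        carrier_ppm = mean(range(offsets_ppm))) {
  nucleus <- match.arg(nucleus, c("N15", "C13", "H1"))
  if (b1_hz < 0) stop("b1_hz must be >= 0")
  if (t_relax < 0) stop("t_relax must be >= 0")
  if (length(offsets_ppm) < 1) stop("offsets_ppm must be non-empty")
  structure(
    list(
      kind = "cest", nucleus = nucleus, h1_freq_mhz = h1_freq_mhz,
      b1_hz = b1_hz, t_relax = t_relax,
      offsets_ppm = as.numeric(offsets_ppm), carrier_ppm = carrier_ppm
    ),
    class = c("cest_scheme", "acq_scheme")
  )
}

#' CPMG acquisition scheme
#'
#' Constant-time relaxation dispersion: `ncyc` refocusing cycles within a
#' fixed period `t_ct`, giving CPMG frequencies `nu = ncyc / t_ct`. `ncyc = 0`
#' denotes the reference plane (no relaxation period).
#'
#' @inheritParams cest_scheme
#' @param t_ct Constant-time relaxation period in seconds (> 0).
#' @param ncyc_values Integer cycle counts; may include 0 (reference) and
#'   duplicates (repeat planes for uncertainty estimation).
#' @return Object of class `cpmg_scheme`.
#' @export
cpmg_scheme <- function(nucleus, h1_freq_mhz, t_ct, ncyc_values,
                        carrier_ppm = 119) {
  nucleus <- match.arg(nucleus, c("N15", "C13", "H1"))
  if (t_ct <= 0) stop("t_ct must be > 0")
  if (any(ncyc_values < 0)) stop("ncyc_values must be >= 0")
  structure(
    list(
      kind = "cpmg", nucleus = nucleus, h1_freq_mhz = h1_freq_mhz,
      t_ct = t_ct, ncyc_values = as.integer(ncyc_values),
      carrier_ppm = carrier_ppm
    ),
    class = c("cpmg_scheme", "acq_scheme")
  )
}

#' CPMG frequencies of a scheme
#'
#' @param scheme A [cpmg_scheme()].
#' @param drop_reference Drop `ncyc = 0` planes (default `TRUE`).
#' @return Numeric vector `ncyc / t_ct` in Hz.
#' @export
nu_cpmg <- function(scheme, drop_reference = TRUE) {
  stopifnot(inherits(scheme, "cpmg_scheme"))
  nc <- scheme$ncyc_values
  if (drop_reference) nc <- nc[nc > 0]
  nc / scheme$t_ct
}

#' @export
print.acq_scheme <- function(x, ...) {
  if (x$kind == "cest") {
    cat(sprintf("<cest_scheme> %s @ %g MHz 1H, B1 = %g Hz, T_relax = %g s, %d offsets (%g..%g ppm)\n",
                x$nucleus, x$h1_freq_mhz, x$b1_hz, x$t_relax,
                length(x$offsets_ppm), min(x$offsets_ppm), max(x$offsets_ppm)))
  } else {
    cat(sprintf("<cpmg_scheme> %s @ %g MHz 1H, T_CT = %g s, ncyc: %s\n",
                x$nucleus, x$h1_freq_mhz, x$t_ct,
                paste(x$ncyc_values, collapse = ",")))
  }
  invisible(x)
}

#' Serialize / deserialize an acquisition scheme as YAML
#'
#' @param scheme A `cest_scheme` or `cpmg_scheme`.
#' @param path Optional output file.
#' @return YAML text, or a scheme object for `scheme_from_config()`.
#' @export
scheme_to_config <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "acq_scheme"))
  txt <- yaml::as.yaml(unclass(scheme), precision = 17)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname scheme_to_config
#' @param text,file YAML text or path.
#' @export
scheme_from_config <- function(text = NULL, file = NULL) {
  obj <- if (!is.null(file)) yaml::read_yaml(file) else yaml::yaml.load(text)
  if (identical(obj$kind, "cest")) {
    cest_scheme(obj$nucleus, obj$h1_freq_mhz, obj$b1_hz, obj$t_relax,
                unlist(obj$offsets_ppm), obj$carrier_ppm)
  } else if (identical(obj$kind, "cpmg")) {
    cpmg_scheme(obj$nucleus, obj$h1_freq_mhz, obj$t_ct,
                unlist(obj$ncyc_values), obj$carrier_ppm)
  } else {
    stop("unknown scheme kind: ", obj$kind)
  }
}
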