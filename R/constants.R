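## Physical constants and ppm <-> Hz conversion, collected in one place.

#' Physical constants used throughout the package
#'
#' Gas constant in kcal/(mol K), Boltzmann constant in J/K and Planck constant
#' in J s (CODATA 2018 exact values), plus the gyromagnetic-ratio fractions
#' used to convert a spectrometer's 1H Larmor frequency to the Larmor
#' frequency of other nuclei.
#'
#' @format A named list with elements `R_kcal` (kcal mol-1 K-1), `kB` (J/K),
#'   `h` (J s) and `gamma_frac` (named vector: fraction of the 1H frequency
#'   for N15, C13 and H1; magnitudes, sign ignored).
#' @export
nmr_constants <- list(
  R_kcal = 1.98720425e-3,
  kB = 1.380649e-23,
  h = 6.62607015e-34,
  gamma_frac = c(N15 = 0.101329, C13 = 0.251450, H1 = 1.0)
)

#' Larmor frequency of a nucleus at a given spectrometer field
#'
#' @param nucleus One of `"N15"`, `"C13"`, `"H1"`.
#' @param h1_freq_mhz Spectrometer 1H Larmor frequency in MHz (e.g. 800).
#' @return Larmor frequency of `nucleus` in MHz.
#' @export
nucleus_freq_mhz <- function(nucleus, h1_freq_mhz) {
  nucleus <- match.arg(nucleus, names(nmr_constants$gamma_frac))
  h1_freq_mhz * nmr_constants$gamma_frac[[nucleus]]
}

#' Convert an offset in ppm to Hz (or back) for a nucleus
#'
#' @inheritParams nucleus_freq_mhz
#' @param ppm,hz Values to convert.
#' @return Numeric vector in the other unit.
#' @export
ppm_to_hz <- function(ppm, nucleus, h1_freq_mhz) {
  ppm * nucleus_freq_mhz(nucleus, h1_freq_mhz)
}

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(hz, nucleus, h1_freq_mhz) {
  hz / nucleus_freq_mhz(nucleus, h1_freq_mhz)
}
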