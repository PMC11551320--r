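# Shared builders for small exchange systems used across test files.

two_state_n15 <- function(kex, pb, dw_ppm, pos = 118, r1 = 1.5, r2 = 10,
                          h1 = 800) {
  two_state_model(kex = kex, pb = pb, labels = c("A", "B"),
                  delta_omega = c(pos, pos + dw_ppm),
                  r1 = c(r1, r1), r2 = c(r2, r2))
}

n15_cpmg_scheme <- function(h1 = 800, t_ct = 0.06,
                            ncyc = c(1, 2, 3, 4, 6, 8, 10, 14, 18, 24, 30, 38, 48, 60)) {
  cpmg_scheme("N15", h1, t_ct = t_ct, ncyc_values = ncyc)
}

n15_cest_scheme <- function(b1 = 20, t_relax = 0.4, lo = 108, hi = 130,
                            by = 0.2, h1 = 800) {
  cest_scheme("N15", h1, b1_hz = b1, t_relax = t_relax,
              offsets_ppm = seq(lo, hi, by = by))
}

## thin a CEST peak table to every k-th saturated offset (reference planes
## kept); used to keep global fits fast in tests
thin_cest_table <- function(tab, k = 2) {
  keep <- is.na(tab$offset_ppm)
  sat_idx <- which(!keep)
  per_peak <- split(sat_idx, paste(tab$peak_id[sat_idx], tab$plane[sat_idx] %/% 10000))
  sel <- unlist(lapply(per_peak, function(ix) ix[seq(1, length(ix), by = k)]))
  tab[sort(c(which(keep), sel)), ]
}

expect_rel <- function(value, target, tol) {
  expect_lt(abs(value - target) / abs(target), tol)
}
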