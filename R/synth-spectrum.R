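#' Synthesise an absorbance spectrum from Gaussian bands
#'
#' @param bands list of length-3 numeric vectors (or a 3-column matrix):
#'   centre (nm), Gaussian sigma (nm), peak absorbance. An empty list gives
#'   an all-zero spectrum.
#' @param grid wavelength grid (nm); must cover at least 380--780 nm.
#' @return an [absorbance_spectrum()].
#' @export
make_spectrum <- function(bands = list(), grid = seq(360, 800, by = 1)) {
  if (min(grid) > 380 || max(grid) < 780)
    stopf("wavelength grid must cover the visible range 380-780 nm")
  if (is.matrix(bands)) bands <- split(bands, row(bands))
  a <- rep(0, length(grid))
  for (b in bands) {
    stopifnot(length(b) == 3)
    a <- a + b[3] * exp(-0.5 * ((grid - b[1]) / b[2])^2)
  }
  absorbance_spectrum(grid, a)
}

#' Synthesise a molecular-weight distribution
#'
#' Log-normal number-weighted abundance over a mass grid, the usual shape of
#' a low-mass synthetic polymer population.
#'
#' @param mode_mass mass (Da) at the abundance mode.
#' @param sigma_log log-space standard deviation.
#' @param grid mass grid (Da).
#' @return data.frame with `mass_da`, `abundance` (number-weighted).
#' @export
make_mwd <- function(mode_mass = 1500, sigma_log = 0.35,
                     grid = seq(200, 12000, by = 25)) {
  mu <- log(mode_mass) + sigma_log^2
  ab <- exp(-0.5 * ((log(grid) - mu) / sigma_log)^2) / grid
  data.frame(mass_da = grid, abundance = ab / max(ab))
}
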