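#' Physical constants (CODATA 2018)
#'
#' Named list of the physical constants used throughout the package:
#' `h` (Planck constant, J s), `c` (speed of light, m/s), `N_A` (Avogadro
#' constant, 1/mol), and `sigma_per_eps` (conversion from a molar extinction
#' coefficient in M^-1 cm^-1 to an absorption cross section in cm^2,
#' `sigma = 1000 * ln(10) / N_A * eps = 3.8235e-21 * eps`).
#'
#' @return A named list of constants.
#' @examples
#' resolft_constants()$sigma_per_eps * 48700 # off-state cross section, cm^2
#' @export
resolft_constants <- function() {
  h <- 6.62607015e-34
  c <- 2.99792458e8
  N_A <- 6.02214076e23
  list(
    h = h,
    c = c,
    N_A = N_A,
    sigma_per_eps = 1000 * log(10) / N_A
  )
}

#' Absorption cross section from a molar extinction coefficient
#'
#' @param eps Extinction coefficient in M^-1 cm^-1 (vectorized).
#' @return Cross section in cm^2.
#' @export
cross_section <- function(eps) {
  stopifnot(all(eps >= 0, na.rm = TRUE))
  resolft_constants()$sigma_per_eps * eps
}

#' Photon flux from an intensity
#'
#' Converts an irradiance to a photon flux, `Phi = I * lambda / (h c)`.
#'
#' @param intensity Irradiance in kW/cm^2 (vector or matrix).
#' @param wavelength Wavelength in nm.
#' @return Photon flux in photons cm^-2 s^-1, same shape as `intensity`.
#' @examples
#' photon_flux(1, 405) # about 2.04e21
#' @export
photon_flux <- function(intensity, wavelength) {
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("intensity must be non-negative")
  }
  const <- resolft_constants()
  intensity * 1000 * (wavelength * 1e-9) / (const$h * const$c)
}
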