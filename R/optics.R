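#' Optical system configuration
#'
#' Parameters of the confocal RESOLFT optical system: a high-NA oil
#' immersion objective and a pinhole specified in Airy units at the
#' detection wavelength.
#'
#' @param numerical_aperture Objective NA (default 1.4).
#' @param immersion_index Immersion/sample refractive index (default 1.518,
#'   oil). Must exceed the NA.
#' @param excitation_wavelengths Excitation wavelengths in nm.
#' @param detection_wavelength Detection wavelength in nm (default 516).
#' @param pinhole Pinhole diameter in Airy units (1 AU = `1.22 lambda / NA`
#'   at the detection wavelength); default 1.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(numerical_aperture = 1.4,
                           immersion_index = 1.518,
                           excitation_wavelengths = c(405, 488),
                           detection_wavelength = 516,
                           pinhole = 1) {
  if (numerical_aperture <= 0 || numerical_aperture >= immersion_index) {
    stop("need 0 < NA < immersion_index")
  }
  if (pinhole <= 0) stop("pinhole must be > 0 Airy units")
  structure(list(numerical_aperture = numerical_aperture,
                 immersion_index = immersion_index,
                 excitation_wavelengths = excitation_wavelengths,
                 detection_wavelength = detection_wavelength,
                 pinhole = pinhole),
            class = "optical_config")
}

#' Focal-plane sampling grid
#'
#' A square lateral grid in the focal plane (z = 0), symmetric about the
#' focus with an odd point count per axis so that the origin is sampled.
#'
#' @param spacing Grid spacing in nm (default 5).
#' @param half_extent Half-width of the grid in nm (default 1000).
#' @return An object of class `focal_grid` with coordinate vectors `x`, `y`.
#' @export
focal_grid <- function(spacing = 5, half_extent = 1000) {
  if (spacing <= 0) stop("spacing must be > 0")
  n_half <- ceiling(half_extent / spacing)
  x <- seq(-n_half, n_half) * spacing
  structure(list(spacing = spacing, half_extent = n_half * spacing,
                 x = x, y = x),
            class = "focal_grid")
}

grid_compatible <- function(a, b) {
  isTRUE(all.equal(a$spacing, b$spacing)) && length(a$x) == length(b$x)
}

#' Radial focal intensity profile (vectorial Debye-Wolf)
#'
#' Focal-plane (z = 0) intensity of a tightly focused, circularly polarized
#' beam with a uniformly filled aplanatic pupil, from the Richards-Wolf
#' diffraction integrals. For `beam_kind = "doughnut"` a 0-2pi vortex phase
#' ramp (charge 1, co-rotating with the circular polarization) is applied,
#' which shifts every Bessel order up by one and enforces an exact on-axis
#' zero. Returned intensities are unnormalized (relative units).
#'
#' @param wavelength Vacuum wavelength in nm.
#' @param numerical_aperture Objective NA.
#' @param immersion_index Refractive index of the focusing medium.
#' @param beam_kind `"gaussian"` (regularly focused), `"doughnut"`, or
#'   `"detection"` (same field as gaussian, at the detection wavelength).
#' @param r Radii in nm at which to evaluate the profile.
#' @param n_nodes Number of Gauss-Legendre nodes for the aperture integral.
#' @return Numeric vector of relative intensities, one per radius.
#' @export
focal_radial_profile <- function(wavelength, numerical_aperture,
                                 immersion_index, beam_kind, r,
                                 n_nodes = 96) {
  beam_kind <- match.arg(beam_kind, c("gaussian", "doughnut", "detection"))
  alpha <- asin(numerical_aperture / immersion_index)
  gl <- pracma::gaussLegendre(n_nodes, 0, alpha)
  th <- gl$x
  w <- gl$w
  k <- 2 * pi * immersion_index / wavelength # nm^-1 in the medium
  st <- sin(th)
  ct <- cos(th)
  apod <- sqrt(ct) # aplanatic energy projection
  w0 <- w * apod * st * (1 + ct)
  wz <- w * apod * st^2
  w2 <- w * apod * st * (1 - ct)
  X <- k * outer(st, r) # nodes x radii
  shift <- if (beam_kind == "doughnut") 1L else 0L
  i0 <- colSums(w0 * besselJ(X, 0 + shift))
  iz <- colSums(wz * besselJ(X, 1 + shift))
  i2 <- colSums(w2 * besselJ(X, 2 + shift))
  i0^2 + 2 * iz^2 + i2^2
}

#' Focal-plane intensity map
#'
#' Evaluates the vectorial focal field of [focal_radial_profile()] on a 2-D
#' grid and normalizes it so that the integral of the intensity over the
#' focal plane equals the stated beam power.
#'
#' @param config An [optical_config()].
#' @param wavelength Wavelength in nm.
#' @param beam_kind `"gaussian"` or `"doughnut"`.
#' @param power Beam power in microwatt, `>= 0`.
#' @param grid A [focal_grid()].
#' @return An object of class `intensity_map` with `values` in kW/cm^2.
#' @examples
#' g <- focal_grid(10, 600)
#' m <- focal_intensity_map(optical_config(), 488, "gaussian", 1, g)
#' map_fwhm(m)
#' @export
focal_intensity_map <- function(config, wavelength, beam_kind, power, grid) {
  beam_kind <- match.arg(beam_kind, c("gaussian", "doughnut", "detection"))
  if (power < 0) stop("power must be >= 0")
  if (grid$spacing > wavelength / 8 / config$numerical_aperture) {
    warning("grid spacing coarser than lambda/(8 NA); FWHM estimates may be biased")
  }
  r_max <- sqrt(2) * grid$half_extent + 2 * grid$spacing
  r_fine <- seq(0, r_max, by = min(1, grid$spacing / 4))
  prof <- focal_radial_profile(wavelength, config$numerical_aperture,
                               config$immersion_index, beam_kind, r_fine)
  rr <- sqrt(outer(grid$x^2, grid$y^2, `+`))
  vals <- matrix(stats::approx(r_fine, prof, xout = rr, rule = 2)$y,
                 nrow = length(grid$x))
  cell_cm2 <- (grid$spacing * 1e-7)^2
  total <- sum(vals) * cell_cm2 # relative power
  scale <- if (total > 0 && power > 0) (power * 1e-6) / total / 1000 else 0
  intensity_map(grid, wavelength, vals * scale, beam_kind, power)
}

#' Intensity map container
#'
#' @param grid A [focal_grid()].
#' @param wavelength Wavelength in nm.
#' @param values Matrix of intensities (kW/cm^2) or efficiencies, indexed
#'   `[x, y]`, all `>= 0`.
#' @param beam_kind One of `"gaussian"`, `"doughnut"`, `"detection"`.
#' @param total_power Beam power in microwatt (`NA` for efficiency maps).
#' @return An object of class `intensity_map`.
#' @export
intensity_map <- function(grid, wavelength, values, beam_kind,
                          total_power = NA_real_) {
  stopifnot(inherits(grid, "focal_grid"),
            nrow(values) == length(grid$x),
            ncol(values) == length(grid$y))
  if (any(values < 0)) stop("intensities must be >= 0")
  if (beam_kind == "doughnut") {
    origin <- values[(nrow(values) + 1) / 2, (ncol(values) + 1) / 2]
    if (origin >= 1e-6 * max(values)) {
      stop("doughnut central zero violated (origin >= 1e-6 x crest)")
    }
  }
  structure(list(grid = grid, wavelength = wavelength, values = values,
                 beam_kind = beam_kind, total_power = total_power),
            class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("<intensity_map> %s, %g nm, %dx%d @ %g nm spacing, max %.4g\n",
              x$beam_kind, x$wavelength, nrow(x$values), ncol(x$values),
              x$grid$spacing, max(x$values)))
  invisible(x)
}

# linear 2-D convolution of a with kernel k (same size output, centred),
# via zero-padded FFT
conv2_same <- function(a, k) {
  na <- dim(a)
  nk <- dim(k)
  n1 <- stats::nextn(na[1] + nk[1] - 1, 2)
  n2 <- stats::nextn(na[2] + nk[2] - 1, 2)
  pa <- matrix(0, n1, n2)
  pk <- matrix(0, n1, n2)
  pa[seq_len(na[1]), seq_len(na[2])] <- a
  pk[seq_len(nk[1]), seq_len(nk[2])] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    (n1 * n2)
  off1 <- (nk[1] - 1) / 2
  off2 <- (nk[2] - 1) / 2
  full[off1 + seq_len(na[1]), off2 + seq_len(na[2])]
}

#' Confocal detection efficiency map
#'
#' Detection probability as a function of the emitter's lateral position:
#' the detection-wavelength PSF convolved with the back-projected pinhole
#' (a disc of diameter `pinhole x 1.22 lambda_det / NA`), peak-normalized.
#'
#' @param config An [optical_config()].
#' @param grid A [focal_grid()].
#' @return An `intensity_map` with unitless efficiency values (max 1).
#' @export
detection_efficiency_map <- function(config, grid) {
  psf <- focal_intensity_map(config, config$detection_wavelength,
                             "detection", 1, grid)
  d_airy <- 1.22 * config$detection_wavelength / config$numerical_aperture
  radius <- config$pinhole * d_airy / 2
  rr <- sqrt(outer(grid$x^2, grid$y^2, `+`))
  # disc indicator with half-cell edge smoothing to reduce pixelation
  kern <- pmin(pmax((radius - rr) / grid$spacing + 0.5, 0), 1)
  eff <- conv2_same(psf$values, kern)
  eff[eff < 0] <- 0
  eff <- eff / max(eff)
  intensity_map(grid, config$detection_wavelength, eff, "detection")
}

#' Pinhole diameter in nm
#'
#' @param config An [optical_config()].
#' @return Back-projected pinhole diameter in nm,
#'   `pinhole x 1.22 lambda_det / NA`.
#' @export
pinhole_diameter <- function(config) {
  config$pinhole * 1.22 * config$detection_wavelength /
    config$numerical_aperture
}

fwhm_1d <- function(x, y) {
  i_max <- which.max(y)
  if (i_max == 1L || i_max == length(y)) {
    stop("no interior maximum: FWHM undefined")
  }
  half <- y[i_max] / 2
  left <- y[seq_len(i_max)]
  right <- y[i_max:length(y)]
  if (min(left) > half || min(right) > half) {
    stop("profile does not fall below half maximum: FWHM undefined")
  }
  il <- max(which(left <= half))
  xl <- x[il] + (x[il + 1] - x[il]) * (half - y[il]) / (y[il + 1] - y[il])
  ir0 <- i_max - 1 + min(which(right <= half))
  xr <- x[ir0 - 1] + (x[ir0] - x[ir0 - 1]) * (half - y[ir0 - 1]) /
    (y[ir0] - y[ir0 - 1])
  xr - xl
}

#' Full width at half maximum
#'
#' Linear-interpolated half-maximum crossings. For a 2-D map the width is
#' measured along the x and y cuts through the maximum and averaged; for a
#' 1-D profile supply `positions` and `values` (or a two-column object).
#' Degenerate (monotone or flat) profiles are an error.
#'
#' @param map An `intensity_map`, `effective_psf`, matrix, or numeric vector
#'   of profile values.
#' @param positions Positions (nm) when `map` is a vector of values.
#' @param spacing Grid spacing in nm when `map` is a bare matrix.
#' @return FWHM in nm.
#' @examples
#' x <- seq(-500, 500, 5)
#' map_fwhm(exp(-x^2 / (2 * 100^2)), positions = x) # ~235.5 nm
#' @export
map_fwhm <- function(map, positions = NULL, spacing = NULL) {
  if (inherits(map, c("intensity_map", "effective_psf"))) {
    v <- map$values
    x <- map$grid$x
  } else if (is.matrix(map)) {
    if (is.null(spacing)) stop("spacing required for a bare matrix")
    v <- map
    x <- (seq_len(nrow(map)) - (nrow(map) + 1) / 2) * spacing
  } else {
    if (is.null(positions)) stop("positions required for a 1-D profile")
    if (max(map) == min(map)) stop("flat profile: FWHM undefined")
    return(fwhm_1d(positions, map))
  }
  idx <- which(v == max(v), arr.ind = TRUE)[1, ]
  fx <- fwhm_1d(x, v[, idx[2]])
  fy <- fwhm_1d(x, v[idx[1], ])
  (fx + fy) / 2
}

#' FWHM-area intensity estimate
#'
#' The experimental convention of estimating a focal intensity from a
#' measured beam power and spot FWHM, assuming the power falls on a circular
#' area with the FWHM as diameter: `I = P / (pi (FWHM/2)^2)`.
#'
#' @param power Beam power in microwatt.
#' @param fwhm Spot FWHM in nm.
#' @return Intensity in kW/cm^2.
#' @export
fwhm_area_intensity <- function(power, fwhm) {
  (power * 1e-6) / (pi * (fwhm / 2 * 1e-7)^2) / 1000
}
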