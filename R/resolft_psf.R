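#' Pulse scheme for sequential RESOLFT
#'
#' An ordered sequence of illumination steps. Each step has a role
#' (`activation`, `off_switching` or `readout`), a duration and one or more
#' beams, a beam being `(beam_kind, wavelength, power)`.
#'
#' @param steps List of steps; each step a list with `role`,
#'   `duration` (microseconds, > 0) and `beams` (list of
#'   `list(beam_kind=, wavelength=, power=)`, power in microwatt).
#' @return An object of class `pulse_scheme`.
#' @seealso [sequential_scheme()]
#' @export
pulse_scheme <- function(steps) {
  roles <- vapply(steps, `[[`, "", "role")
  ok <- roles %in% c("activation", "off_switching", "readout")
  if (!all(ok)) stop("unknown step role: ", paste(roles[!ok], collapse = ", "))
  for (s in steps) {
    if (s$duration <= 0) stop("step durations must be > 0")
  }
  structure(list(steps = steps), class = "pulse_scheme")
}

#' Default sequential RESOLFT pulse scheme
#'
#' The pulse sequence used for sequential-mode imaging: a 70 us regularly
#' focused 488 nm activation pulse (7.6 uW), a 350 us doughnut-shaped
#' 405 nm off-switching pulse (1.16 uW) and a 120 us regularly focused
#' 488 nm readout pulse (0.51 uW).
#'
#' @param activation_us,activation_uW Activation pulse duration and power.
#' @param off_us,off_uW Off-switching pulse duration and power.
#' @param readout_us,readout_uW Readout pulse duration and power.
#' @return A [pulse_scheme()].
#' @export
sequential_scheme <- function(activation_us = 70, activation_uW = 7.6,
                              off_us = 350, off_uW = 1.16,
                              readout_us = 120, readout_uW = 0.51) {
  pulse_scheme(list(
    list(role = "activation", duration = activation_us,
         beams = list(list(beam_kind = "gaussian", wavelength = 488,
                           power = activation_uW))),
    list(role = "off_switching", duration = off_us,
         beams = list(list(beam_kind = "doughnut", wavelength = 405,
                           power = off_uW))),
    list(role = "readout", duration = readout_us,
         beams = list(list(beam_kind = "gaussian", wavelength = 488,
                           power = readout_uW)))
  ))
}

new_effective_psf <- function(grid, raw_values, scheme, brightness_unit) {
  peak <- max(raw_values)
  if (peak <= 0) stop("effective PSF has zero signal everywhere")
  vals <- raw_values / peak
  psf <- structure(list(grid = grid, values = vals, scheme = scheme,
                        peak_brightness = peak,
                        brightness_unit = brightness_unit,
                        fwhm = NA_real_),
                   class = "effective_psf")
  psf$fwhm <- map_fwhm(psf)
  psf
}

#' @export
print.effective_psf <- function(x, ...) {
  cat(sprintf("<effective_psf> %s scheme, FWHM %.1f nm, peak %.4g %s\n",
              x$scheme, x$fwhm, x$peak_brightness, x$brightness_unit))
  invisible(x)
}

# per-grid-point rates for a set of beams at one optical configuration;
# returns kon/koff/kemit matrices (1/s)
beam_rate_fields <- function(model, config, beams, grid,
                             cross_activation_488_off = FALSE) {
  n <- length(grid$x)
  kon <- koff <- kemit <- matrix(0, n, n)
  for (b in beams) {
    map <- focal_intensity_map(config, b$wavelength, b$beam_kind,
                               b$power, grid)
    co <- rate_coefficients(model, b$wavelength,
                            cross_activation_488_off = cross_activation_488_off)
    kon <- kon + co$k_on * map$values
    koff <- koff + co$k_off * map$values
    kemit <- kemit + co$k_emit * map$values
  }
  list(k_on = kon, k_off = koff, k_emit = kemit)
}

evolve_field <- function(p, kon, koff, t_s) {
  ktot <- kon + koff
  pss <- ifelse(ktot > 0, kon / ktot, p)
  pss + (p - pss) * exp(-ktot * t_s)
}

# time integral of p(t) over [0, t_s] under constant rates
integrate_field <- function(p, kon, koff, t_s) {
  ktot <- kon + koff
  pss <- ifelse(ktot > 0, kon / ktot, p)
  decay <- ifelse(ktot > 0, (1 - exp(-ktot * t_s)) / ktot, t_s)
  pss * t_s + (p - pss) * decay
}

#' Effective PSF of the sequential RESOLFT scheme
#'
#' Evolves the on-state population at every focal-plane position through
#' the activation and off-switching pulses of a [pulse_scheme()] and forms
#' the expected fluorescence signal of the readout pulse: on-state
#' population x readout excitation rate x confocal detection efficiency,
#' integrated over the readout duration. On-switching driven by the 405 nm
#' off-switching beam (through the off-state's 405 nm absorption) is
#' included; re-activation by the weak readout beam is excluded by default.
#'
#' @param model An [rsfp_model()].
#' @param config An [optical_config()].
#' @param scheme A [pulse_scheme()] containing activation, off_switching
#'   and readout steps.
#' @param grid A [focal_grid()].
#' @param p0 On-fraction at the start of the sequence (default 0: the
#'   off-switching of the previous cycle leaves the ensemble dark).
#' @param include_readout_activation If `TRUE`, the on-state population
#'   continues to evolve during readout and the time-dependent population
#'   is integrated; by default the population is frozen at its pre-readout
#'   value.
#' @return An `effective_psf` (peak-normalized, FWHM attached,
#'   `peak_brightness` in photons per pulse cycle per molecule).
#' @export
effective_psf_sequential <- function(model, config, scheme = sequential_scheme(),
                                     grid = focal_grid(), p0 = 0,
                                     include_readout_activation = FALSE) {
  roles <- vapply(scheme$steps, `[[`, "", "role")
  for (need in c("activation", "off_switching", "readout")) {
    if (!need %in% roles) stop("scheme is missing a ", need, " step")
  }
  n <- length(grid$x)
  p <- matrix(p0, n, n)
  signal <- matrix(0, n, n)
  det <- detection_efficiency_map(config, grid)$values
  for (s in scheme$steps) {
    rf <- beam_rate_fields(model, config, s$beams, grid)
    t_s <- s$duration * 1e-6
    if (s$role == "readout") {
      p_int <- if (include_readout_activation) {
        integrate_field(p, rf$k_on, rf$k_off, t_s)
      } else {
        p * t_s
      }
      signal <- signal + p_int * rf$k_emit * det
      if (include_readout_activation) {
        p <- evolve_field(p, rf$k_on, rf$k_off, t_s)
      }
    } else {
      p <- evolve_field(p, rf$k_on, rf$k_off, t_s)
    }
  }
  new_effective_psf(grid, signal, "sequential", "photons/cycle")
}

#' Effective PSF of the one-step RESOLFT scheme
#'
#' Steady-state on-fraction under the superimposed regularly focused
#' 488 nm excitation beam and doughnut-shaped 405 nm off-switching beam,
#' multiplied by the excitation rate and the confocal detection efficiency.
#'
#' @param model An [rsfp_model()].
#' @param config An [optical_config()].
#' @param p488 488 nm beam power in microwatt.
#' @param p405 405 nm (doughnut) beam power in microwatt.
#' @param grid A [focal_grid()].
#' @return An `effective_psf` (`peak_brightness` in photons/s per molecule).
#' @examples
#' \donttest{
#' psf <- effective_psf_onestep(padron2_model(), optical_config(),
#'                              0.6, 1.19, focal_grid(10, 800))
#' psf$fwhm
#' }
#' @export
effective_psf_onestep <- function(model, config, p488 = 0.6, p405 = 1.19,
                                  grid = focal_grid()) {
  if (p488 < 0 || p405 < 0) stop("powers must be >= 0")
  if (p488 == 0 && p405 == 0) stop("at least one beam power must be > 0")
  beams <- list(list(beam_kind = "gaussian", wavelength = 488, power = p488))
  if (p405 > 0) {
    beams <- c(beams, list(list(beam_kind = "doughnut", wavelength = 405,
                                power = p405)))
  }
  rf <- beam_rate_fields(model, config, beams, grid)
  ktot <- rf$k_on + rf$k_off
  pss <- ifelse(ktot > 0, rf$k_on / ktot, 0)
  det <- detection_efficiency_map(config, grid)$values
  new_effective_psf(grid, pss * rf$k_emit * det, "onestep", "photons/s")
}

#' Confocal effective PSF
#'
#' The diffraction-limited reference: excitation map times detection
#' efficiency, with all photoswitching disabled (every molecule on).
#'
#' @param model An [rsfp_model()] (sets the emission rate scale).
#' @param config An [optical_config()].
#' @param p488 Excitation power in microwatt.
#' @param grid A [focal_grid()].
#' @return An `effective_psf` (`peak_brightness` in photons/s per molecule).
#' @export
effective_psf_confocal <- function(model, config, p488 = 0.6,
                                   grid = focal_grid()) {
  exc <- focal_intensity_map(config, 488, "gaussian", p488, grid)
  co <- rate_coefficients(model, 488)
  det <- detection_efficiency_map(config, grid)$values
  new_effective_psf(grid, co$k_emit * exc$values * det, "confocal",
                    "photons/s")
}

#' Fluorophore phantom
#'
#' A 2-D map of fluorophore surface density on a focal-grid raster.
#'
#' @param grid A [focal_grid()].
#' @param density Matrix of densities (molecules/nm^2), `>= 0`.
#' @return An object of class `phantom`.
#' @export
phantom <- function(grid, density) {
  stopifnot(inherits(grid, "focal_grid"),
            nrow(density) == length(grid$x),
            ncol(density) == length(grid$y))
  if (any(density < 0)) stop("densities must be >= 0")
  structure(list(grid = grid, density = density), class = "phantom")
}

#' Scan configuration
#'
#' @param pixel_size Scan pixel size in nm (default 25).
#' @param dwell_time Pixel dwell time in microseconds (default 300).
#' @param photon_noise Apply Poisson sampling to the expected counts?
#' @param rng_seed Seed for the Poisson sampling.
#' @param mode `"frozen"` (convolution with the effective PSF) or
#'   `"kinetic"` (the on-state field is evolved pixel-to-pixel as the beams
#'   move).
#' @param substeps Sub-dwell time steps per pixel in kinetic mode.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(pixel_size = 25, dwell_time = 300,
                        photon_noise = FALSE, rng_seed = 1L,
                        mode = c("frozen", "kinetic"), substeps = 1L) {
  if (pixel_size <= 0 || dwell_time <= 0) {
    stop("pixel_size and dwell_time must be > 0")
  }
  structure(list(pixel_size = pixel_size, dwell_time = dwell_time,
                 photon_noise = photon_noise, rng_seed = as.integer(rng_seed),
                 mode = match.arg(mode), substeps = as.integer(substeps)),
            class = "scan_config")
}

shift_matrix <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  src_i <- seq_len(n1) - di
  src_j <- seq_len(n2) - dj
  ok_i <- src_i >= 1 & src_i <= n1
  ok_j <- src_j >= 1 & src_j <= n2
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

#' Simulate a raster scan of a phantom
#'
#' Scans the superimposed beams over a fluorophore [phantom()] and returns
#' the image of expected (or Poisson-sampled) photon counts per pixel.
#' In the default frozen-kinetics mode the image is the phantom convolved
#' with the scheme's effective PSF, scaled by the dwell time (sequential
#' scheme: by the pulse cycle). In kinetic mode (one-step and confocal
#' schemes) the on-state population field is evolved as the beams move,
#' pixel to pixel, and the time-averaged population during each dwell
#' contributes to the signal.
#'
#' @param phantom A [phantom()].
#' @param scheme `"sequential"`, `"onestep"` or `"confocal"`.
#' @param model An [rsfp_model()].
#' @param config An [optical_config()].
#' @param scan A [scan_config()].
#' @param psf Optionally a precomputed `effective_psf` on the phantom's
#'   grid spacing (frozen mode).
#' @param p488,p405 Beam powers in microwatt (one-step/confocal).
#' @param pulse A [pulse_scheme()] (sequential).
#' @return A list with `image` (matrix of counts), `pixel_size`, `scheme`
#'   and `mode`.
#' @export
simulate_scan <- function(phantom, scheme = c("onestep", "sequential", "confocal"),
                          model, config, scan = scan_config(),
                          psf = NULL, p488 = 0.6, p405 = 1.19,
                          pulse = sequential_scheme()) {
  scheme <- match.arg(scheme)
  g <- phantom$grid
  stride <- round(scan$pixel_size / g$spacing)
  if (stride < 1 || abs(stride * g$spacing - scan$pixel_size) > 1e-9) {
    stop("phantom raster must divide the scan pixel size")
  }
  dwell_s <- scan$dwell_time * 1e-6
  pix_i <- seq(1, length(g$x), by = stride)
  if (scan$mode == "frozen" || scheme == "sequential") {
    if (is.null(psf)) {
      psf <- switch(scheme,
        onestep = effective_psf_onestep(model, config, p488, p405, g),
        confocal = effective_psf_confocal(model, config, p488, g),
        sequential = effective_psf_sequential(model, config, pulse, g))
    }
    if (!grid_compatible(psf$grid, g)) {
      stop("effective PSF grid does not match the phantom raster")
    }
    t_scale <- if (identical(psf$brightness_unit, "photons/s")) dwell_s else 1
    raw <- psf$values * psf$peak_brightness
    full <- conv2_same(phantom$density, raw) * g$spacing^2 * t_scale
    img <- full[pix_i, pix_i]
  } else {
    beams <- list(list(beam_kind = "gaussian", wavelength = 488, power = p488))
    if (scheme == "onestep" && p405 > 0) {
      beams <- c(beams, list(list(beam_kind = "doughnut", wavelength = 405,
                                  power = p405)))
    }
    rf <- beam_rate_fields(model, config, beams, g)
    if (scheme == "confocal") {
      rf$k_on <- rf$k_on * 0 + 1e12 # photoswitching disabled: always on
      rf$k_off <- rf$k_off * 0
    }
    det <- detection_efficiency_map(config, g)$values
    ctr <- (length(g$x) + 1) / 2
    p <- matrix(0, length(g$x), length(g$y))
    img <- matrix(0, length(pix_i), length(pix_i))
    dt <- dwell_s / scan$substeps
    for (jj in seq_along(pix_i)) {
      for (ii in seq_along(pix_i)) {
        di <- pix_i[ii] - ctr
        dj <- pix_i[jj] - ctr
        kon <- shift_matrix(rf$k_on, di, dj)
        koff <- shift_matrix(rf$k_off, di, dj)
        kemit <- shift_matrix(rf$k_emit * det, di, dj)
        counts <- 0
        for (s in seq_len(scan$substeps)) {
          p_int <- integrate_field(p, kon, koff, dt)
          counts <- counts + sum(phantom$density * p_int * kemit)
          p <- evolve_field(p, kon, koff, dt)
        }
        img[ii, jj] <- counts * g$spacing^2
      }
    }
  }
  if (scan$photon_noise) {
    set.seed(scan$rng_seed)
    img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                  nrow = nrow(img))
  }
  list(image = img, pixel_size = stride * g$spacing, scheme = scheme,
       mode = if (scheme == "sequential") "frozen" else scan$mode)
}

#' Lorentzian line-profile fit
#'
#' Least-squares fit of `y = offset + amplitude * gamma^2 /
#' ((x - center)^2 + gamma^2)`, the model used for intensity line profiles
#' across filament images. The fitted FWHM is `2 gamma`.
#'
#' @param positions Positions in nm (>= 5 points).
#' @param values Profile values.
#' @return A list with `center`, `fwhm`, `amplitude`, `offset`, the `fit`
#'   object and `converged`.
#' @export
lorentzian_profile_fit <- function(positions, values) {
  if (length(positions) < 5) stop("need at least 5 profile points")
  if (max(values) == min(values)) {
    stop("constant profile: Lorentzian fit is unidentifiable")
  }
  ord <- order(positions)
  x <- positions[ord]
  y <- values[ord]
  off0 <- min(y)
  amp0 <- max(y) - off0
  x00 <- x[which.max(y)]
  above <- x[y - off0 > amp0 / 2]
  g0 <- max((max(above) - min(above)) / 2, diff(range(x)) / 20)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + amplitude * gamma^2 / ((x - center)^2 + gamma^2),
      start = list(offset = off0, amplitude = amp0, center = x00, gamma = g0),
      lower = c(-Inf, 0, min(x), 1e-9 * diff(range(x))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Lorentzian fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  list(center = unname(cf["center"]), fwhm = 2 * unname(cf["gamma"]),
       amplitude = unname(cf["amplitude"]), offset = unname(cf["offset"]),
       fit = fit, converged = TRUE)
}
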