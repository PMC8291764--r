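#' Generator specification
#'
#' Common options of the seeded synthetic-data generators. With a fixed
#' seed every generator is a deterministic function of its parameters.
#'
#' @param rng_seed Integer seed.
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Standard deviation of Gaussian noise (relative to the
#'   signal scale for spectra/titrations).
#' @param poisson_scale Expected counts at unit signal for Poisson noise.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(rng_seed = 1L,
                           noise_model = c("none", "gaussian", "poisson"),
                           noise_sd = 0.02, poisson_scale = 1000) {
  structure(list(rng_seed = as.integer(rng_seed),
                 noise_model = match.arg(noise_model),
                 noise_sd = noise_sd, poisson_scale = poisson_scale),
            class = "generator_spec")
}

apply_noise <- function(values, spec, scale = max(abs(values))) {
  switch(spec$noise_model,
         none = values,
         gaussian = values + stats::rnorm(length(values), 0,
                                          spec$noise_sd * scale),
         poisson = {
           lam <- pmax(values / scale, 0) * spec$poisson_scale
           stats::rpois(length(values), lam) * scale / spec$poisson_scale
         })
}

#' Synthetic pH titration curve
#'
#' Evaluates the mono- or biphasic dose-response family of
#' [fit_ph_response()] on a pH grid (the titration buffers span pH 3-10.5
#' in 0.5 steps) and adds optional noise.
#'
#' @param mode `"monophasic"` or `"biphasic"`.
#' @param pka Transition constant(s): one value (monophasic) or two
#'   (biphasic, ascending).
#' @param amplitudes `c(A0, A1)` or `c(A0, A1, A2)`.
#' @param ph Vector of pH values within `[3, 11]`.
#' @param spec A [generator_spec()].
#' @return A data frame (`titration_curve`) with columns `pH`, `intensity`,
#'   plus attributes `truth` (generating parameters).
#' @examples
#' tc <- gen_titration_curve("biphasic", c(6.6, 9.1))
#' fit_ph_response(tc, "biphasic")
#' @export
gen_titration_curve <- function(mode = c("monophasic", "biphasic"),
                                pka, amplitudes = NULL,
                                ph = seq(3, 10.5, by = 0.5),
                                spec = generator_spec()) {
  mode <- match.arg(mode)
  if (any(ph < 3 | ph > 11)) stop("pH grid must lie within [3, 11]")
  n_pka <- if (mode == "monophasic") 1L else 2L
  stopifnot(length(pka) == n_pka)
  if (is.null(amplitudes)) {
    amplitudes <- if (mode == "monophasic") c(0, 1) else c(0, 0.55, 0.45)
  }
  pars <- if (mode == "monophasic") {
    c(A0 = amplitudes[1], A1 = amplitudes[2], pKa = pka)
  } else {
    pka <- sort(pka)
    c(A0 = amplitudes[1], A1 = amplitudes[2], A2 = amplitudes[3],
      pKa1 = pka[1], pKa2 = pka[2])
  }
  f <- ph_response(ph, mode, pars)
  set.seed(spec$rng_seed)
  out <- data.frame(pH = ph, intensity = pmax(apply_noise(f, spec), 0))
  attr(out, "truth") <- pars
  class(out) <- c("titration_curve", class(out))
  out
}

#' Synthetic timed absorption-spectrum series
#'
#' Wraps [forward_cuvette_switching()] and applies optional noise to each
#' spectrum, for switching-quantum-yield recovery tests. The default
#' exposure ladders follow the characterization protocol: off-switching
#' 1-60 s at 405 nm, on-switching 1-180 s at 500 nm.
#'
#' @param model An [rsfp_model()].
#' @param irradiation An [irradiation_record()].
#' @param durations Cumulative exposure times in seconds.
#' @param p0 Initial on-fraction.
#' @param spec A [generator_spec()].
#' @return A `spectrum_series` (see [forward_cuvette_switching()]).
#' @export
gen_spectrum_series <- function(model,
                                irradiation = irradiation_record(405, 6.02),
                                durations = c(1, 2, 3, 4, 5, 10, 20, 30, 60),
                                p0 = 1, spec = generator_spec()) {
  series <- forward_cuvette_switching(model, irradiation, durations, p0 = p0)
  if (spec$noise_model != "none") {
    set.seed(spec$rng_seed)
    scale <- max(vapply(series$spectra, function(s) max(s$absorbance), 0))
    series$spectra <- lapply(series$spectra, function(s) {
      s$absorbance <- pmax(apply_noise(s$absorbance, spec, scale), 0)
      s
    })
  }
  series
}

draw_gaussian_line <- function(density, gx, gy, px, py, sigma, amplitude) {
  # accumulate a Gaussian-profile line segment chain onto the raster
  for (k in seq_len(length(px) - 1)) {
    x0 <- px[k]; y0 <- py[k]; x1 <- px[k + 1]; y1 <- py[k + 1]
    seg_len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    n_sub <- max(2L, ceiling(seg_len / (sigma / 2)))
    xs <- seq(x0, x1, length.out = n_sub)
    ys <- seq(y0, y1, length.out = n_sub)
    for (m in seq_len(n_sub)) {
      ix <- which(abs(gx - xs[m]) <= 3 * sigma)
      iy <- which(abs(gy - ys[m]) <= 3 * sigma)
      if (length(ix) == 0 || length(iy) == 0) next
      gadd <- outer(exp(-(gx[ix] - xs[m])^2 / (2 * sigma^2)),
                    exp(-(gy[iy] - ys[m])^2 / (2 * sigma^2)))
      density[ix, iy] <- pmax(density[ix, iy],
                              amplitude * gadd)
    }
  }
  density
}

#' Random filament phantom
#'
#' Smooth random curvilinear filaments of sub-resolution thickness on a
#' focal grid, emulating cytoskeletal structures for scan simulation.
#'
#' @param n_filaments Number of filaments.
#' @param grid A [focal_grid()].
#' @param thickness_sd Gaussian cross-section sd of a filament in nm
#'   (default 15 nm, well below the diffraction limit).
#' @param density_peak Peak fluorophore surface density (molecules/nm^2).
#' @param spec A [generator_spec()].
#' @return A [phantom()].
#' @export
gen_filament_phantom <- function(n_filaments = 3, grid = focal_grid(25, 1000),
                                 thickness_sd = 15, density_peak = 0.01,
                                 spec = generator_spec()) {
  if (grid$spacing > thickness_sd * 2) {
    stop("raster must be finer than the filament thickness")
  }
  set.seed(spec$rng_seed)
  dens <- matrix(0, length(grid$x), length(grid$y))
  L <- grid$half_extent
  for (i in seq_len(n_filaments)) {
    # random smooth path: heading is a random walk in angle
    n_step <- 40L
    step <- 2.4 * L / n_step
    ang <- stats::runif(1, 0, 2 * pi)
    x <- stats::runif(1, -L, L)
    y <- stats::runif(1, -L, L)
    px <- numeric(n_step)
    py <- numeric(n_step)
    for (s in seq_len(n_step)) {
      px[s] <- x
      py[s] <- y
      ang <- ang + stats::rnorm(1, 0, 0.25)
      x <- x + step * cos(ang)
      y <- y + step * sin(ang)
    }
    dens <- draw_gaussian_line(dens, grid$x, grid$y, px, py,
                               thickness_sd, density_peak)
  }
  phantom(grid, dens)
}

#' Two parallel line phantom
#'
#' The canonical resolution target: two straight parallel lines of
#' sub-resolution thickness separated by a given distance, centred on the
#' grid.
#'
#' @param separation Line separation in nm.
#' @param grid A [focal_grid()].
#' @param thickness_sd Gaussian cross-section sd in nm.
#' @param density_peak Peak density (molecules/nm^2).
#' @return A [phantom()] with two vertical density ridges at
#'   `x = +/- separation/2`.
#' @export
two_line_phantom <- function(separation = 140, grid = focal_grid(25, 500),
                             thickness_sd = 15, density_peak = 0.01) {
  prof <- density_peak * (
    exp(-(grid$x - separation / 2)^2 / (2 * thickness_sd^2)) +
    exp(-(grid$x + separation / 2)^2 / (2 * thickness_sd^2)))
  phantom(grid, matrix(prof, nrow = length(grid$x), ncol = length(grid$y)))
}
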