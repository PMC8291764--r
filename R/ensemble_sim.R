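#' Illumination program
#'
#' An ordered sequence of illumination segments for ensemble (bacterial
#' colony) switching experiments. Each segment has a duration in ms and a
#' set of simultaneous [illumination()] fields.
#'
#' @param segments List of segments, each
#'   `list(duration = ms, fields = list(illumination(...), ...))`.
#' @return An object of class `illumination_program`.
#' @examples
#' prog <- illumination_program(list(
#'   list(duration = 10, fields = list(illumination(405, 4.1))),
#'   list(duration = 50, fields = list(illumination(488, 17.4)))))
#' @export
illumination_program <- function(segments) {
  if (length(segments) == 0) stop("program must contain at least one segment")
  for (s in segments) {
    if (s$duration <= 0) stop("segment durations must be > 0")
  }
  structure(list(segments = segments), class = "illumination_program")
}

#' Simulate an ensemble switching trace
#'
#' Evolves the on-state population and the surviving (unbleached) fraction
#' of a protein ensemble through an [illumination_program()], using the
#' two-state rates of the photophysics model with the lumped bleaching
#' channel. The reported signal is
#' `surviving x p_on x k_emit`; segments containing only sub-450 nm light
#' yield no fluorescence (emission is not excited by the off-switching
#' wavelength).
#'
#' @param model An [rsfp_model()].
#' @param program An [illumination_program()].
#' @param p0 Initial on-fraction.
#' @param dt Sampling interval in ms.
#' @param intensity_scale Effective-intensity scale factor applied to all
#'   fields (colony optical thickness is otherwise ignored).
#' @return A data frame (`switching_trace`) with columns `time` (ms),
#'   `signal` (photons/s per initial molecule), `p_on`, `surviving`.
#' @export
simulate_colony_trace <- function(model, program, p0 = 0, dt = 0.5,
                                  intensity_scale = 1) {
  stopifnot(inherits(program, "illumination_program"))
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  t_ms <- 0
  p <- p0
  surv <- 1
  rows <- list(data.frame(time = 0, signal = NA_real_, p_on = p,
                          surviving = surv))
  first_kemit <- NA_real_
  for (seg in program$segments) {
    fields <- lapply(seg$fields, function(f) {
      illumination(f$wavelength, f$intensity * intensity_scale)
    })
    rates <- switching_rates(model, fields)
    if (is.na(first_kemit)) first_kemit <- rates$k_emit
    tt <- seq(dt, seg$duration, by = dt)
    if (length(tt) == 0 || tt[length(tt)] < seg$duration) {
      tt <- c(tt, seg$duration)
    }
    p_t <- evolve_on_fraction(p, rates, tt * 1e-3)
    surv_t <- surv * exp(-rates$k_bleach * tt * 1e-3)
    rows[[length(rows) + 1]] <- data.frame(
      time = t_ms + tt,
      signal = surv_t * p_t * rates$k_emit,
      p_on = p_t, surviving = surv_t)
    p <- p_t[length(p_t)]
    surv <- surv_t[length(surv_t)]
    t_ms <- t_ms + seg$duration
  }
  out <- do.call(rbind, rows)
  out$signal[1] <- p0 * first_kemit # emission under the first segment's light
  class(out) <- c("switching_trace", class(out))
  out
}

#' Half-time of an on-switching trace
#'
#' Time at which a rising, saturating trace crosses 50% of its plateau
#' (relative to its starting level), by linear interpolation. Invariant to
#' positive scaling of the signal.
#'
#' @param trace A data frame with columns `time` (ms) and `signal`.
#' @return Half-time in ms.
#' @export
switching_half_time <- function(trace) {
  t <- trace$time
  s <- trace$signal
  keep <- !is.na(s)
  t <- t[keep]
  s <- s[keep]
  n <- length(s)
  plateau <- mean(s[t >= t[n] * 0.9])
  s0 <- s[1]
  if (plateau <= s0 || (plateau - s[n]) > 0.05 * (plateau - s0)) {
    stop("trace does not rise to a plateau: half-time undefined")
  }
  half <- s0 + 0.5 * (plateau - s0)
  i <- min(which(s >= half))
  if (i == 1) return(t[1])
  t[i - 1] + (t[i] - t[i - 1]) * (half - s[i - 1]) / (s[i] - s[i - 1])
}

#' Residual off-state level from a consecutive on-switching curve
#'
#' The residual fluorescence in the ensemble off-state is probed by the
#' subsequent on-switching response: the rising curve is fitted with a
#' saturating exponential and extrapolated to `t = 0`; the starting level
#' is reported as a percentage of the full on-state amplitude.
#'
#' @param trace A rising `switching_trace` (columns `time`, `signal`).
#' @param reference_max Full on-state signal amplitude (same units).
#' @return Residual level in percent.
#' @export
residual_from_onswitch_curve <- function(trace, reference_max) {
  if (reference_max <= 0) stop("reference amplitude must be > 0")
  keep <- !is.na(trace$signal)
  x <- trace$time[keep]
  y <- trace$signal[keep]
  dat <- data.frame(x = x, y = y)
  # tau start from the 63% crossing of the observed rise
  y63 <- y[1] + 0.632 * (max(y) - y[1])
  i63 <- which(y >= y63)
  tau0 <- if (length(i63) > 0) max(x[i63[1]] - x[1], diff(range(x)) / 1e4)
          else diff(range(x)) / 5
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ plateau - (plateau - s0) * exp(-x / tau),
                      data = dat,
                      start = list(plateau = max(y), s0 = y[1], tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("on-switching curve fit failed: ",
                             conditionMessage(e)))
  100 * unname(stats::coef(fit)["s0"]) / reference_max
}

#' Simulate a switching-fatigue cycling protocol
#'
#' Repeatedly cycles the ensemble between a low (off) and a high (on)
#' fluorescence target, computing for each cycle the 405 nm and 488 nm
#' illumination durations that reach the targets given the current rates,
#' applying bleaching per absorbed photon, and recording the cycle's
#' maximum signal. `cycles_to_half` is the first (interpolated) cycle at
#' which the maximum falls below 50% of the first cycle's.
#'
#' @param model An [rsfp_model()] (set `qy_bleach > 0` for finite fatigue).
#' @param off_target,on_target Off/on targets in percent of the full
#'   on-state (`0 < off < on < 100`).
#' @param i405,i488 Illumination intensities in kW/cm^2.
#' @param n_cycles Number of cycles to simulate.
#' @return A list with `maxima` (data frame `cycle`, `max_signal`,
#'   `surviving`), `cycles_to_half` (`Inf` if never reached) and the
#'   per-cycle durations `t_off_ms`, `t_on_ms`.
#' @export
simulate_fatigue_protocol <- function(model, off_target = 5, on_target = 95,
                                      i405 = 3.6, i488 = 2.6,
                                      n_cycles = 100) {
  if (!(off_target > 0 && off_target < on_target && on_target < 100)) {
    stop("need 0 < off_target < on_target < 100")
  }
  r405 <- switching_rates(model, list(illumination(405, i405)))
  r488 <- switching_rates(model, list(illumination(488, i488)))
  p_lo <- off_target / 100
  p_hi <- on_target / 100
  k405 <- r405$k_on + r405$k_off
  k488 <- r488$k_on + r488$k_off
  if (k405 <= 0 || k488 <= 0) stop("targets unreachable: switching rates are zero")
  pss405 <- r405$k_on / k405
  pss488 <- r488$k_on / k488
  if (pss405 >= p_lo || pss488 <= p_hi) {
    stop("targets unreachable at these intensities")
  }
  t_off <- log((p_hi - pss405) / (p_lo - pss405)) / k405
  t_on <- log((pss488 - p_lo) / (pss488 - p_hi)) / k488
  surv <- 1
  per_cycle_loss <- exp(-(r405$k_bleach * t_off + r488$k_bleach * t_on))
  maxima <- numeric(n_cycles)
  surviving <- numeric(n_cycles)
  for (i in seq_len(n_cycles)) {
    surv <- surv * per_cycle_loss
    surviving[i] <- surv
    maxima[i] <- surv * p_hi * r488$k_emit
  }
  cycles_to_half <- Inf
  if (per_cycle_loss < 1) {
    below <- which(maxima < 0.5 * maxima[1])
    if (length(below) > 0) {
      i <- below[1]
      cycles_to_half <- if (i == 1) 1 else {
        (i - 1) + (maxima[i - 1] - 0.5 * maxima[1]) /
          (maxima[i - 1] - maxima[i])
      }
    }
  }
  list(maxima = data.frame(cycle = seq_len(n_cycles), max_signal = maxima,
                           surviving = surviving),
       cycles_to_half = cycles_to_half,
       t_off_ms = t_off * 1e3, t_on_ms = t_on * 1e3)
}

#' Simulate dual (simultaneous) illumination off-switching
#'
#' Irradiates the ensemble with 405 and 488 nm light simultaneously from
#' the full on-state, as in one-step RESOLFT's periphery, and reports the
#' residual fluorescence: the steady-state signal as a percentage of the
#' full-on signal at the same 488 nm intensity.
#'
#' @param model An [rsfp_model()].
#' @param i405,i488 Intensities in kW/cm^2 (not both zero).
#' @param duration Trace duration in ms.
#' @param p0 Initial on-fraction (default 1).
#' @param dt Sampling interval in ms.
#' @return A list with `trace` (a `switching_trace`), `residual_percent`
#'   and `time_constant_ms` (`1/(k_on + k_off)`).
#' @export
simulate_dual_illumination <- function(model, i405, i488, duration = 100,
                                       p0 = 1, dt = 0.1) {
  if (i405 < 0 || i488 < 0) stop("intensities must be >= 0")
  if (i405 == 0 && i488 == 0) stop("at least one intensity must be > 0")
  prog <- illumination_program(list(list(
    duration = duration,
    fields = list(illumination(405, i405), illumination(488, i488)))))
  trace <- simulate_colony_trace(model, prog, p0 = p0, dt = dt)
  rates <- switching_rates(model, list(illumination(405, i405),
                                       illumination(488, i488)))
  p_ss <- steady_state_on_fraction(rates)
  list(trace = trace,
       residual_percent = 100 * p_ss,
       time_constant_ms = 1e3 / (rates$k_on + rates$k_off))
}
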