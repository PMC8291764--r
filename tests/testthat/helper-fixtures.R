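# shared small fixtures; grids kept coarse for speed, acceptance tests use
# the full-resolution defaults
test_model <- function(...) padron2_model(...)
test_optics <- function() optical_config()
coarse_grid <- function() focal_grid(10, 600)

# independent Runge-Kutta oracle for the two-state kinetics
ode_on_fraction <- function(p0, k_on, k_off, t) {
  deriv <- function(tt, y, parms) list(k_on * (1 - y[1]) - k_off * y[1])
  sol <- deSolve::ode(c(p = p0), c(0, t), deriv, parms = NULL,
                      method = "ode45", rtol = 1e-10, atol = 1e-12)
  unname(sol[nrow(sol), "p"])
}
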