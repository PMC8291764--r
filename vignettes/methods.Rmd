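---
title: "Methods: photophysics, focal fields and effective PSFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photophysics, focal fields and effective PSFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the physical model, the parameter conventions and
the numerical choices behind `resolftsim`, and states the limitations of
each approximation.

## Two-state photoswitching model

A reversibly switchable fluorescent protein (RSFP) is reduced to a
two-state system: a fluorescent *on*-state and a dark *off*-state. Under
constant illumination the on-fraction `p(t)` obeys

    dp/dt = k_on (1 - p) - k_off p,

with the closed-form solution

    p(t) = p_ss + (p0 - p_ss) exp(-(k_on + k_off) t),
    p_ss = k_on / (k_on + k_off).

Every rate is a product of an absorption cross-section, a photon flux and
a quantum yield, `k = sigma(lambda) Phi(I, lambda) QY`, with

  - `sigma = (1000 ln 10 / N_A) eps` (so `sigma [cm^2] = 3.8235e-21 eps`),
  - `Phi = I lambda / (h c)` (photons cm^-2 s^-1 per incident intensity),
  - CODATA 2018 values of `h`, `c`, `N_A` (see `resolft_constants()`).

The model is linear in intensity: no triplet shelving, no intermediate
dark states, no intensity-dependent quantum yields. This is adequate for
the continuous-wave, low-intensity (W/cm^2 to kW/cm^2) regime the package
targets, and is a stated limitation for pulsed or saturating excitation.

### Chromophore species and role flags

Each protein is described by three absorbing species — the neutral and
anionic forms of the on-state chromophore and the off-state chromophore —
with per-species extinction spectra on a 1 nm grid from 240 to 700 nm.
Role flags on the species decide where absorbed photons go:

  - the **neutral on-state** species drives on-to-off switching
    (positive-switching phenotype: the off-switching light at 405 nm is
    absorbed by the neutral form),
  - the **off-state** species drives off-to-on switching (and its short
    wavelength tail gives a weak 405 nm cross-activation, which the PSF
    calculations include),
  - the **anionic on-state** species emits fluorescence; emission is only
    excited at wavelengths of at least 450 nm
    (`emission_min_wavelength`), so pure 405 nm segments yield no signal.

### The apparent-extinction convention

Tabulated extinction coefficients of the on-state bands are treated as
*apparent* (equilibrium-weighted) values: they already contain the
neutral/anionic equilibrium of the on-state ensemble at the measurement
pH. Consequently the rate formulas do **not** multiply by the anionic
fraction `f_anionic` again — neither in the emission rate nor in the
off-switching rate. The supporting observation is that dividing the
tabulated anionic-band extinctions by the tabulated anionic fractions
reproduces the intrinsic extinction of the GFP-type anionic chromophore
(about 6e4 M^-1 cm^-1), which would not hold if the tabulated values
were intrinsic. `f_anionic` is kept on the model object as descriptive
metadata and for the denaturation-based extinction work-flow.

### Band stand-ins

Full extinction spectra of the three species are not tabulated anywhere;
only peak positions and peak extinctions are. The built-in protein models
(`padron2_model()`, `padron_model()`, `kohinoor_model()`) therefore build
each species spectrum as a Gaussian band (30 nm standard deviation)
through the tabulated peak. The absolute rates at the exact peaks are
faithful; rates at wavelengths far from a peak (e.g. 405 nm, which sits
on the flanks of all bands) inherit the band-shape assumption. The
effective-PSF predictions reproduce the reference resolution figures
within their tolerance under this stand-in, and `read_protein_model()`
accepts user-supplied measured spectra wherever better data exist.

## Vectorial focal fields

Focal intensity distributions are computed with the Richards-Wolf
(vectorial Debye) diffraction integrals for an aplanatic objective,
assuming circular input polarization:

  - the regularly focused (gaussian) beam uses the standard three
    integrals `I0, I1, I2` with apodization `sqrt(cos theta)` and angular
    weights `sin theta (1 + cos theta)`, `sin^2 theta`,
    `sin theta (1 - cos theta)`, summed as `|I0|^2 + 2|I1|^2 + |I2|^2`;
  - the doughnut is a charge-1 vortex beam with circular polarization
    co-rotating with the vortex, which shifts the Bessel orders to 1, 2, 3
    and yields a mathematically exact on-axis null (the null is asserted
    at construction time, `< 1e-6` of the crest).

The circular-polarization assumption is a deliberate design decision: it
is the standard choice for doughnut-based nanoscopy (a counter-rotating
or linear polarization partially fills the null) and it makes the fields
radially symmetric, so a 1-D radial integral plus interpolation gives the
2-D map. The integrals are evaluated with Gauss-Legendre quadrature
(96 nodes over the aperture angle `alpha = asin(NA/n)`); maps are
normalized so that the focal-plane integral equals the stated beam power
(checked to 1% in the test-suite) and intensities are reported in
kW/cm^2.

Only the focal plane (`z = 0`) is modelled; axial confinement and
aberrations are out of scope.

## Confocal detection

The detection point spread function at the emission wavelength (516 nm)
is convolved with the pinhole disc (1 Airy unit diameter,
`1.22 lambda / NA` = 449.7 nm at 516 nm/NA 1.4) and peak-normalized. The
product of excitation map and detection efficiency is the confocal
reference PSF; with the default 5 nm grid its width comes out near
187 nm.

## Effective RESOLFT PSFs

**Sequential scheme.** The pulse sequence (defaults: 70 us activation at
7.6 uW gaussian 488 nm; 350 us off-switching at 1.16 uW doughnut 405 nm;
120 us readout at 0.51 uW gaussian 488 nm) is applied pointwise to the
on-fraction field, using the closed-form propagator per step. The signal
is the readout excitation rate times the on-fraction integrated over the
readout window times the detection efficiency. By default the population
is *frozen* during readout (`include_readout_activation = FALSE`): the
weak readout beam re-activates slowly compared with the readout window,
and freezing makes the scheme's resolution attributable to the preceding
pulses alone; the flag turns the full kinetics back on.

**One-step scheme.** Both beams are on simultaneously (defaults 0.6 uW
gaussian 488 nm + 1.19 uW doughnut 405 nm) and the on-fraction field is
taken at its steady state, `k_on/(k_on + k_off)` pointwise; the signal is
the steady-state population times excitation rate times detection. At the
doughnut crest the competition leaves only a few percent of molecules on,
which is what confines the effective PSF.

All effective PSFs are peak-normalized with the peak brightness
(photons/s, or photons per pulse cycle for the sequential scheme) kept as
an attribute, and their FWHM is read off the interpolated half-maximum
crossings of the central line cuts.

## Scan simulation

Frozen mode treats the image as phantom (*) effective-PSF times dwell
time (FFT convolution with zero padding). Kinetic mode propagates the
on-state field from pixel to pixel as the beams move, using the exact
time-average of `p(t)` during each dwell, and reduces to the frozen
convolution at long dwell times (a 1% agreement is part of the
acceptance suite). Optional photon noise is Poisson with a seeded RNG.

## Spectroscopic estimation procedures

  - **Relative fluorescence quantum yield**: ratio of integrated emission
    over absorbance against a reference of known yield (trapezoidal
    integration).
  - **pKa fits**: mono- and biphasic sigmoidal dose-response fits in pH
    with Levenberg-Marquardt (`minpack.lm`), multi-start over the pKa
    grid to avoid local minima; biphasic constants are reported in
    ascending order. Constant curves are flagged unidentifiable instead
    of fitted.
  - **Extinction by alkaline denaturation**: anchored to the denatured
    GFP chromophore (44,000 M^-1 cm^-1 at 447 nm).
  - **Switching quantum yields**: a forward cuvette model integrates the
    two-state kinetics with the photokinetic factor
    `(1 - 10^-A)/(A ln 10)` (volume-averaged absorbed flux at finite
    absorbance; `deSolve::lsoda`, rtol 1e-10), produces timed absorption
    spectra, which are unmixed into state populations by non-negative
    least squares; the single free quantum yield is then found by 1-D
    optimization on the population trajectory. Noiseless round-trips
    recover generating values to well under 1%.
  - **ExpDec2**: biexponential decay fits with the `t1 <= t2` convention,
    multi-start.

## Ensemble simulations

Colony-scale switching experiments are simulated with the same rate
model: programmable illumination segments, half-times by interpolation,
residual off-state levels by saturating-exponential extrapolation to
`t = 0`, fatigue cycling with analytically computed per-cycle switching
durations and a lumped per-absorbed-photon bleaching channel, and dual
(simultaneous 405+488) illumination whose residual equals the
steady-state competition. Bleaching yields are free parameters (no
tabulated values exist for them), so fatigue outputs are qualitative
unless the user supplies a yield.

## Numerical choices and problem sizes

  - Default focal grid: 5 nm spacing, 1000 nm half-extent (401 x 401) —
    seconds per PSF because the field is radial; coarser 10 nm grids are
    used in the fast test fixtures. A warning is raised when the spacing
    undersamples `lambda / (8 NA)`.
  - ODE tolerances: rtol 1e-10/atol 1e-12 (cuvette model), closed forms
    wherever rates are piecewise constant.
  - Quadrature: 96-node Gauss-Legendre over the aperture.
  - All file formats are delimited text or TIFF+YAML sidecars with exact
    (17 significant digit) numeric round-trips.

## Limitations

  - Two states only; no triplets, no spectral heterogeneity, no pH
    dependence of the switching rates themselves.
  - Focal plane only; no axial sectioning, no aberrations, no refractive
    index mismatch.
  - Gaussian band stand-ins for species spectra away from tabulated
    peaks.
  - Bleaching is a single lumped channel with a user-chosen yield.
  - The scan simulator moves the beams on the phantom raster; sub-raster
    scan positions are not interpolated.

## A worked example

```{r example}
library(resolftsim)
m <- padron2_model()
cfg <- optical_config()
g <- focal_grid(5, 1000)

effective_psf_confocal(m, cfg, 0.6, g)$fwhm    # ~186.8 nm
effective_psf_sequential(m, cfg, grid = g)$fwhm # ~51 nm
effective_psf_onestep(m, cfg, 0.6, 1.19, g)$fwhm # ~55 nm
```
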