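#' Gaussian-band stand-in state spectra
#'
#' Builds per-state extinction spectra as sums of Gaussian bands on the
#' common 240-700 nm grid. True protein band shapes are not tabulated, so
#' Gaussian bands centred at the reported absorption maxima with the
#' reported peak extinctions serve as stand-ins; the default band width is
#' a 30 nm standard deviation.
#'
#' @param peaks A list with one element per species name (`on_neutral`,
#'   `on_anionic`, `off`); each element is a list of bands, a band being
#'   `c(center_nm, eps_peak, width_nm)` (width = Gaussian sd). A single band
#'   may be given as a bare numeric triple.
#' @return Named list of [chromophore_species()].
#' @examples
#' sp <- gen_state_spectra(list(
#'   on_neutral = c(384, 23500, 30),
#'   on_anionic = c(495, 13250, 30),
#'   off        = c(498, 48700, 30)))
#' species_extinction(sp$off, 488)
#' @export
gen_state_spectra <- function(peaks) {
  stopifnot(is.list(peaks))
  nms <- names(peaks)
  if (!setequal(nms, c("on_neutral", "on_anionic", "off"))) {
    stop("peaks must name on_neutral, on_anionic and off")
  }
  grid <- spectral_grid()
  out <- lapply(nms, function(nm) {
    bands <- peaks[[nm]]
    if (is.numeric(bands)) bands <- list(bands)
    eps <- numeric(length(grid))
    for (b in bands) {
      stopifnot(length(b) == 3)
      if (b[3] <= 0) stop("band widths must be > 0")
      eps <- eps + b[2] * exp(-(grid - b[1])^2 / (2 * b[3]^2))
    }
    chromophore_species(nm, grid, eps)
  })
  names(out) <- nms
  out
}

band_defaults <- list(
  padron2 = list(
    peaks = list(on_neutral = c(384, 23500, 30),
                 on_anionic = c(495, 13250, 30),
                 off        = c(498, 48700, 30)),
    qy_off = 0.115, qy_on = 0.005, qy_fl = 0.49, f_anionic = 0.222,
    pka = c(6.6, 9.1)
  ),
  padron = list(
    peaks = list(on_neutral = c(398, 19200, 30),
                 on_anionic = c(504, 32700, 30),
                 off        = c(505, 57700, 30)),
    qy_off = NA_real_, qy_on = NA_real_, qy_fl = 0.64, f_anionic = 0.582,
    pka = 5.9
  ),
  kohinoor = list(
    peaks = list(on_neutral = c(388, 24800, 30),
                 on_anionic = c(496, 12400, 30),
                 off        = c(496, 39500, 30)),
    qy_off = 0.088, qy_on = 0.015, qy_fl = 0.73, f_anionic = 0.180,
    pka = c(5.3, 8.6)
  )
)

make_protein_model <- function(key, qy_bleach = 0) {
  d <- band_defaults[[key]]
  rsfp_model(gen_state_spectra(d$peaks),
             qy_off = d$qy_off, qy_on = d$qy_on, qy_fl = d$qy_fl,
             qy_bleach = qy_bleach, f_anionic = d$f_anionic, name = key)
}

#' Built-in protein photophysics models
#'
#' Default [rsfp_model()] parameter sets for Padron2, Padron and Kohinoor
#' (switching and fluorescence quantum yields, anionic on-state fraction,
#' and Gaussian-band stand-in state spectra at the reported absorption
#' maxima). Extinction coefficients at the working wavelengths 405/488 nm
#' are evaluated from these band stand-ins and should be treated as
#' placeholders where per-wavelength measurements exist; see
#' [gen_state_spectra()]. Padron's switching quantum yields were not
#' determined and are `NA`: rate construction for Padron requires the user
#' to supply them.
#'
#' @param qy_bleach Lumped photobleaching quantum yield (default 0).
#' @return An [rsfp_model()].
#' @examples
#' m <- padron2_model()
#' switching_rates(m, list(illumination(405, 4.1)))$k_off
#' @export
padron2_model <- function(qy_bleach = 0) make_protein_model("padron2", qy_bleach)

#' @rdname padron2_model
#' @export
padron_model <- function(qy_bleach = 0) make_protein_model("padron", qy_bleach)

#' @rdname padron2_model
#' @export
kohinoor_model <- function(qy_bleach = 0) make_protein_model("kohinoor", qy_bleach)

#' Read or write a protein parameter file
#'
#' Protein photophysics parameters are stored as structured YAML: one block
#' per protein with quantum yields, the anionic fraction and per-species
#' extinction samples on the 1 nm 240-700 nm grid (linear interpolation
#' between samples).
#'
#' @param path File path.
#' @param model An [rsfp_model()] (for writing).
#' @return `read_protein_model()` returns an [rsfp_model()];
#'   `write_protein_model()` returns `path` invisibly.
#' @export
read_protein_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  sp <- lapply(names(cfg$species), function(nm) {
    s <- cfg$species[[nm]]
    chromophore_species(nm, as.numeric(s$wavelengths), as.numeric(s$extinction))
  })
  rsfp_model(sp, qy_off = cfg$qy_off, qy_on = cfg$qy_on, qy_fl = cfg$qy_fl,
             qy_bleach = cfg$qy_bleach %||% 0,
             f_anionic = cfg$f_anionic %||% 0.222,
             name = cfg$name %||% "rsfp")
}

#' @rdname read_protein_model
#' @export
write_protein_model <- function(model, path) {
  cfg <- list(
    name = model$name,
    qy_off = model$qy_off, qy_on = model$qy_on, qy_fl = model$qy_fl,
    qy_bleach = model$qy_bleach, f_anionic = model$f_anionic,
    species = lapply(model$species, function(s) {
      list(wavelengths = s$wavelengths, extinction = s$extinction)
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
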