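#' Read a delimited table against a schema
#'
#' Reads a comma-separated file whose header must match the schema's
#' column names exactly; columns are converted to the declared types and
#' malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @param schema Named character vector mapping column names to types
#'   (`"numeric"` or `"character"`).
#' @return A data frame with the typed columns.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(wavelength_nm = 1:3, value = 0.5), f,
#'           row.names = FALSE)
#' read_table_checked(f, c(wavelength_nm = "numeric", value = "numeric"))
#' @export
read_table_checked <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  header <- trimws(gsub('"', "", header))
  if (!identical(header, names(schema))) {
    stop("header mismatch in ", path, ": expected columns [",
         paste(names(schema), collapse = ", "), "], found [",
         paste(header, collapse = ", "), "]")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & nzchar(trimws(df[[col]])))
      if (length(bad) > 0) {
        stop("malformed numeric values in ", path, ", column '", col,
             "', line(s) ", paste(bad + 1, collapse = ", "))
      }
      df[[col]] <- v
    }
  }
  df
}

#' Spectrum, titration and trace file I/O
#'
#' CSV readers/writers for the package's delimited-text formats: spectra
#' (`wavelength_nm`, `value`), titrations (`pH`, `intensity`) and
#' switching traces (`time_ms`, `signal`). Values round-trip at 17
#' significant digits.
#'
#' @param path File path.
#' @param x The object to write (two-column data frame).
#' @return Readers return a data frame; writers return `path` invisibly.
#' @export
read_spectrum <- function(path) {
  df <- read_table_checked(path, c(wavelength_nm = "numeric",
                                   value = "numeric"))
  stats::setNames(df, c("wavelength", "value"))
}

write_csv17 <- function(df, path) {
  out <- df
  for (i in seq_along(out)) {
    if (is.numeric(out[[i]])) out[[i]] <- sprintf("%.17g", out[[i]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(x, path) {
  write_csv17(data.frame(wavelength_nm = x[[1]], value = x[[2]]), path)
}

#' @rdname read_spectrum
#' @export
read_titration <- function(path) {
  read_table_checked(path, c(pH = "numeric", intensity = "numeric"))
}

#' @rdname read_spectrum
#' @export
write_titration <- function(x, path) {
  write_csv17(data.frame(pH = x$pH, intensity = x$intensity), path)
}

#' @rdname read_spectrum
#' @export
read_trace <- function(path) {
  df <- read_table_checked(path, c(time_ms = "numeric", signal = "numeric"))
  stats::setNames(df, c("time", "signal"))
}

#' @rdname read_spectrum
#' @export
write_trace <- function(x, path) {
  write_csv17(data.frame(time_ms = x$time, signal = x$signal), path)
}

#' Intensity map I/O
#'
#' Writes an [intensity_map()] (or effective PSF) as a single-plane 32-bit
#' float TIFF plus a YAML sidecar header (`<path>.yml`) carrying the grid
#' spacing, wavelength, beam kind and power; `read_intensity_map()`
#' reconstructs the object.
#'
#' @param map An `intensity_map`.
#' @param path TIFF file path.
#' @return `write_intensity_map()` returns `path` invisibly.
#' @export
write_intensity_map <- function(map, path) {
  vmax <- max(map$values)
  scale <- if (vmax > 0) vmax else 1
  tiff::writeTIFF(map$values / scale, path, bits.per.sample = 32L,
                  reduce = TRUE)
  yaml::write_yaml(list(spacing_nm = map$grid$spacing,
                        half_extent_nm = map$grid$half_extent,
                        wavelength_nm = map$wavelength,
                        beam_kind = map$beam_kind,
                        total_power_uW = map$total_power,
                        value_scale = scale),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_intensity_map
#' @export
read_intensity_map <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  vals <- tiff::readTIFF(path, as.is = FALSE) * meta$value_scale
  g <- focal_grid(meta$spacing_nm, meta$half_extent_nm)
  intensity_map(g, meta$wavelength_nm, vals, meta$beam_kind,
                meta$total_power_uW %||% NA_real_)
}

#' Spectrum-series I/O
#'
#' Writes a `spectrum_series` as one spectrum CSV per time point plus a
#' YAML manifest listing the times and the irradiation parameters.
#'
#' @param series A `spectrum_series`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @param path Manifest path (for reading).
#' @return `write_spectrum_series()` returns the manifest path invisibly.
#' @export
write_spectrum_series <- function(series, dir, stem = "spectrum") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(series$times))
  for (i in seq_along(series$times)) {
    files[i] <- sprintf("%s_%03d.csv", stem, i)
    write_spectrum(stats::setNames(series$spectra[[i]],
                                   c("wavelength", "value")),
                   file.path(dir, files[i]))
  }
  manifest <- file.path(dir, paste0(stem, "_manifest.yml"))
  yaml::write_yaml(list(times_s = series$times, files = files,
                        irradiation = unclass(series$irradiation)),
                   manifest)
  invisible(manifest)
}

#' @rdname write_spectrum_series
#' @export
read_spectrum_series <- function(path) {
  m <- yaml::read_yaml(path)
  dir <- dirname(path)
  spectra <- lapply(m$files, function(f) {
    s <- read_spectrum(file.path(dir, f))
    stats::setNames(s, c("wavelength", "absorbance"))
  })
  irr <- irradiation_record(m$irradiation$wavelength,
                            m$irradiation$intensity,
                            m$irradiation$path_length,
                            m$irradiation$concentration)
  structure(list(times = as.numeric(m$times_s), p_on = NULL,
                 spectra = spectra, irradiation = irr),
            class = "spectrum_series")
}
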