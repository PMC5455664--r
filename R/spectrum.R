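#' Raman spectrum
#'
#' A single Raman spectrum: a strictly increasing wavenumber axis (cm^-1,
#' within 0--4000) paired with intensities in counts per second.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   increasing, all within `[0, 4000]`.
#' @param intensity Numeric vector of intensities (cps), same length as
#'   `wavenumber`, all finite.
#' @param name Optional character label (e.g. the reference material).
#'
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity` and `name`.
#' @examples
#' s <- raman_spectrum(seq(400, 1200, by = 2), dnorm(seq(400, 1200, by = 2), 961, 8))
#' @export
raman_spectrum <- function(wavenumber, intensity, name = NULL) {
  check_wavenumber_axis(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(wavenumber)) {
    abort("`wavenumber` and `intensity` must have equal lengths.")
  }
  if (!all(is.finite(intensity))) {
    abort("`intensity` must be finite everywhere.")
  }
  structure(
    list(wavenumber = as.numeric(wavenumber), intensity = intensity,
         name = name),
    class = "raman_spectrum"
  )
}

check_wavenumber_axis <- function(wavenumber) {
  if (length(wavenumber) < 2 || anyNA(wavenumber)) {
    abort("Wavenumber axis must have at least two finite values.")
  }
  if (any(diff(wavenumber) <= 0)) {
    abort("Wavenumber axis must be strictly increasing.")
  }
  if (min(wavenumber) < 0 || max(wavenumber) > 4000) {
    abort("Wavenumber axis must lie within [0, 4000] cm^-1.")
  }
  invisible(wavenumber)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumber)
  cat(sprintf("<raman_spectrum%s: %d points, %.0f-%.0f cm^-1>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$wavenumber), rng[1], rng[2]))
  invisible(x)
}

#' @export
as_tibble.raman_spectrum <- function(x, ...) {
  tibble(wavenumber = x$wavenumber, intensity = x$intensity)
}

# Index of the axis sample nearest to a wavenumber position.
nearest_axis_index <- function(wavenumber, position) {
  if (position < min(wavenumber) || position > max(wavenumber)) {
    abort(sprintf("Position %.1f cm^-1 lies outside the axis range [%.1f, %.1f].",
                  position, min(wavenumber), max(wavenumber)))
  }
  which.min(abs(wavenumber - position))
}

#' Resample a spectrum onto a new wavenumber axis
#'
#' Linear interpolation; values outside the source axis are extrapolated as
#' the nearest endpoint (`rule = 2`), which only matters when reference
#' spectra were recorded on a slightly wider grating range than the map.
#'
#' @param s A [raman_spectrum].
#' @param wavenumber Target axis (strictly increasing).
#' @return A [raman_spectrum] on the target axis.
#' @export
resample_spectrum <- function(s, wavenumber) {
  stopifnot(inherits(s, "raman_spectrum"))
  check_wavenumber_axis(wavenumber)
  if (length(s$wavenumber) == length(wavenumber) &&
      all(s$wavenumber == wavenumber)) {
    return(s)
  }
  y <- approx(s$wavenumber, s$intensity, xout = wavenumber, rule = 2)$y
  raman_spectrum(wavenumber, y, name = s$name)
}
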