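#' Bone-relevant Raman bands and display windows
#'
#' The default set of Raman bands used to build band images of bone and
#' graft material: the phosphate mineral modes (nu2/nu4/nu1 PO4 at 438, 589
#' and 961 cm^-1), the B-type carbonate substitution at 1075 cm^-1, the
#' amide III/I matrix bands (1256, 1677 cm^-1) and the C-H bending and
#' stretching bands (1457, 2937 cm^-1), each with the intensity window (cps)
#' giving optimum image contrast for a typical bone measurement.
#'
#' @return A tibble with columns `band`, `position` (cm^-1), `window_lo` and
#'   `window_hi` (cps) and `group` (mineral / matrix marker).
#' @export
raman_bands <- function() {
  tibble(
    band = c("nu2PO4", "nu4PO4", "nu1PO4", "carbonate",
             "amideIII", "amideI", "CH_bend", "CH_stretch"),
    position = c(438, 589, 961, 1075, 1256, 1677, 1457, 2937),
    window_lo = rep(0, 8),
    window_hi = c(200, 200, 400, 200, 150, 150, 150, 500),
    group = c("mineral", "mineral", "mineral", "mineral",
              "matrix", "matrix", "matrix", "matrix")
  )
}

new_feature_layer <- function(values, raw, kind, name, meta, valid_mask) {
  structure(
    list(values = values, raw = raw, kind = kind, name = name,
         meta = meta, valid_mask = valid_mask),
    class = "feature_layer"
  )
}

#' @export
print.feature_layer <- function(x, ...) {
  cat(sprintf("<feature_layer '%s' (%s): %d x %d, values 0-255>\n",
              x$name, x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_layer <- function(x) dim(x$values)

#' @export
as_tibble.feature_layer <- function(x, ...) {
  g <- pixel_grid(nrow(x$values), ncol(x$values))
  dplyr::mutate(g,
                value = flatten_image(x$values),
                raw = flatten_image(x$raw),
                layer = x$name, kind = x$kind)
}

#' Raman band image
#'
#' Builds the 8-bit single-channel image of intensities at one wavenumber
#' position across a map: per pixel, the intensity at the axis sample
#' nearest `position` is clipped to `window` and linearly mapped so that
#' `window[1]` becomes 0 and `window[2]` becomes 255 (round half up).
#' Narrow windows enhance the contrast of weak bands. The map is expected
#' to be baseline corrected first (see [baseline_correct()]).
#'
#' @param m A [raman_map].
#' @param position Band position in cm^-1, inside the axis range.
#' @param window Length-2 numeric `c(lo, hi)` intensity window in cps,
#'   `lo < hi`.
#' @param name Layer name; defaults to `"band_<position>"`.
#' @return A `feature_layer` of kind `"band_image"`; `$raw` holds the
#'   clipped cps values, `$values` the 0--255 integers.
#' @export
band_image <- function(m, position, window, name = NULL) {
  stopifnot(inherits(m, "raman_map"))
  if (length(window) != 2 || !all(is.finite(window)) || window[1] >= window[2]) {
    abort("`window` must be c(lo, hi) with lo < hi.")
  }
  i <- nearest_axis_index(m$wavenumber, position)
  v <- m$spectra[, i]
  clipped <- pmin(pmax(v, window[1]), window[2])
  scaled <- round_half_up((clipped - window[1]) / (window[2] - window[1]) * 255)
  new_feature_layer(
    values = unflatten_image(as.integer(scaled), m$rows, m$cols),
    raw = unflatten_image(clipped, m$rows, m$cols),
    kind = "band_image",
    name = name %||% sprintf("band_%g", position),
    meta = list(position = position, window = window,
                axis_sample = m$wavenumber[i]),
    valid_mask = m$valid_mask
  )
}

#' Raman correlation map against a reference spectrum
#'
#' Computes, per pixel, the Pearson coefficient of correlation (COC) between
#' the pixel spectrum and a reference spectrum of a candidate material,
#' by default over the entire recorded spectral range. The raw signed COC is
#' retained (it is what coefficient-of-determination attribution squares);
#' the 8-bit display values clip negative COC to 0 and scale so COC 1 maps
#' to 255.
#'
#' @param m A [raman_map].
#' @param ref A [raman_spectrum]; resampled onto the map axis by linear
#'   interpolation if needed.
#' @param range Optional `c(lo, hi)` wavenumber range restricting the
#'   correlation; default `NULL` uses the full axis.
#' @param name Layer name; defaults to the reference name.
#' @return A `feature_layer` of kind `"correlation_map"`; `$raw` holds the
#'   signed COC. Pixels whose spectrum has zero variance over the range get
#'   COC 0 and are flagged `FALSE` in the layer's `valid_mask`.
#' @export
correlation_map <- function(m, ref, range = NULL, name = NULL) {
  stopifnot(inherits(m, "raman_map"), inherits(ref, "raman_spectrum"))
  ref <- resample_spectrum(ref, m$wavenumber)
  idx <- seq_along(m$wavenumber)
  if (!is.null(range)) {
    if (length(range) != 2 || range[1] >= range[2]) {
      abort("`range` must be c(lo, hi) with lo < hi.")
    }
    idx <- which(m$wavenumber >= range[1] & m$wavenumber <= range[2])
    if (length(idx) < 3) abort("`range` must contain at least 3 axis samples.")
  }
  r <- ref$intensity[idx]
  if (stats::sd(r) == 0) abort("Reference spectrum has zero variance over the range.")
  X <- m$spectra[, idx, drop = FALSE]
  n <- ncol(X)
  px_var <- (rowSums(X^2) - n * rowMeans(X)^2) / (n - 1)
  coc <- rep(0, nrow(X))
  ok <- px_var > 0
  if (any(ok)) {
    suppressWarnings(
      coc[ok] <- as.vector(cor(t(X[ok, , drop = FALSE]), r))
    )
  }
  # zero-variance pixels (exactly, or to rounding) carry no correlation
  ok[!is.finite(coc)] <- FALSE
  coc[!is.finite(coc)] <- 0
  mask <- m$valid_mask & unflatten_image(ok, m$rows, m$cols)
  new_feature_layer(
    values = unflatten_image(as.integer(round_half_up(pmax(coc, 0) * 255)),
                             m$rows, m$cols),
    raw = unflatten_image(coc, m$rows, m$cols),
    kind = "correlation_map",
    name = name %||% ref$name %||% "reference",
    meta = list(reference = ref$name, range = range),
    valid_mask = mask
  )
}

#' Signal-to-noise ratio of a band across a map
#'
#' SNR at a wavenumber position, computed as the ratio between the averaged
#' Raman intensities at the axis sample nearest `position` (over valid
#' pixels) and the root mean square of the background noise in a peak-free
#' window, pooled over pixels. The noise RMS is taken about each pixel's
#' mean level over the window, so the figure measures the noise fluctuation
#' itself and is insensitive to the small residual offset a baseline
#'-correction convention may leave under the noise floor.
#'
#' @param m A [raman_map] (baseline corrected).
#' @param position Band position (cm^-1).
#' @param noise_range `c(lo, hi)` wavenumber window containing no bands and
#'   at least 8 axis samples.
#' @return A single number. For a noiseless map (zero RMS) the SNR is not
#'   defined; `Inf` is returned with attribute `noiseless = TRUE`.
#' @export
snr <- function(m, position, noise_range) {
  stopifnot(inherits(m, "raman_map"))
  i <- nearest_axis_index(m$wavenumber, position)
  if (length(noise_range) != 2 || noise_range[1] >= noise_range[2]) {
    abort("`noise_range` must be c(lo, hi) with lo < hi.")
  }
  idx <- which(m$wavenumber >= noise_range[1] & m$wavenumber <= noise_range[2])
  if (length(idx) == 0) abort("Empty noise window.")
  if (length(idx) < 8) abort("Noise window must contain at least 8 axis samples.")
  ok <- flatten_image(m$valid_mask)
  signal <- mean(m$spectra[ok, i])
  noise <- m$spectra[ok, idx, drop = FALSE]
  rms <- sqrt(mean((noise - rowMeans(noise))^2))
  if (rms == 0) {
    return(structure(Inf, noiseless = TRUE))
  }
  signal / rms
}
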