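#' Automatic baseline correction by asymmetric least squares
#'
#' Removes a smooth fluorescence/luminescence background from Raman spectra
#' using asymmetric least squares (ALS): a second-difference-penalized
#' smoother whose weights are iteratively reweighted so that points above
#' the current baseline estimate (the peaks) get weight `asymmetry` and
#' points below get weight `1 - asymmetry`. The estimated baseline is
#' subtracted from the spectrum.
#'
#' The penalized system is pentadiagonal and is solved by a banded Cholesky
#' factorization in compiled code, so correcting a full map is cheap.
#'
#' @param x A [raman_spectrum] or [raman_map].
#' @param smoothness Penalty weight on the squared second differences of the
#'   baseline, in (sample^4) units of the axis grid. Larger values give a
#'   stiffer baseline. The default `1e6` keeps a polynomial-grade
#'   fluorescence background while leaving bands a few samples wide intact.
#' @param asymmetry Weight assigned to points above the running baseline, in
#'   (0, 1); small values force the baseline under the peaks. Default 0.01.
#' @param max_iter Maximum reweighting iterations (default 10; the weights
#'   typically fix after 4--6).
#' @param ... Passed between methods.
#'
#' @return An object of the same class as `x` with the baseline subtracted.
#' @examples
#' wn <- seq(400, 1800, by = 2)
#' s <- raman_spectrum(wn, 300 * exp(-((wn - 961) / 8)^2 / 2) + 0.05 * wn)
#' flat <- baseline_correct(s)
#' @export
baseline_correct <- function(x, smoothness = 1e6, asymmetry = 0.01,
                             max_iter = 10L, ...) {
  UseMethod("baseline_correct")
}

#' @rdname baseline_correct
#' @export
baseline_correct.raman_spectrum <- function(x, smoothness = 1e6,
                                            asymmetry = 0.01,
                                            max_iter = 10L, ...) {
  z <- als_fit(matrix(x$intensity, ncol = 1), smoothness, asymmetry, max_iter)
  raman_spectrum(x$wavenumber, x$intensity - z[, 1], name = x$name)
}

#' @rdname baseline_correct
#' @export
baseline_correct.raman_map <- function(x, smoothness = 1e6, asymmetry = 0.01,
                                       max_iter = 10L, ...) {
  # spectra are rows of the pixel matrix; the solver wants them as columns
  z <- als_fit(t(x$spectra), smoothness, asymmetry, max_iter)
  out <- x
  out$spectra <- x$spectra - t(z)
  out
}

als_fit <- function(Y, smoothness, asymmetry, max_iter) {
  if (!is.numeric(smoothness) || smoothness <= 0) {
    abort("`smoothness` must be a positive number.")
  }
  if (asymmetry <= 0 || asymmetry >= 1) {
    abort("`asymmetry` must lie strictly between 0 and 1.")
  }
  if (!all(is.finite(Y))) abort("Spectra must be finite for baseline correction.")
  if (nrow(Y) < 4) abort("Baseline correction needs at least 4 axis samples.")
  als_baseline_cpp(Y, smoothness, asymmetry, as.integer(max_iter))
}
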