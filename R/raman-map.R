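#' Hyperspectral Raman map
#'
#' A rectangular XY grid of Raman spectra sharing one wavenumber axis, the
#' result of point-by-point mapping over a region of interest. Pixel spectra
#' are stored as the rows of a matrix in row-major pixel order (pixel
#' `(r, c)` is row `(r - 1) * cols + c`), which is also the vectorization
#' order used when feature layers are assembled into the raw data matrix for
#' clustering.
#'
#' @param spectra Numeric matrix, `rows * cols` by `length(wavenumber)`;
#'   finite.
#' @param rows,cols Grid dimensions.
#' @param wavenumber Shared wavenumber axis (cm^-1, strictly increasing).
#' @param step_um Grid step size in micrometres (default 50, a typical
#'   mapping step for millimetre-scale bone regions).
#' @param valid_mask Logical `rows x cols` matrix; `FALSE` marks pixels that
#'   downstream statistics should treat as unusable (e.g. zero-variance
#'   spectra). Defaults to all `TRUE`.
#'
#' @return An object of class `raman_map`.
#' @export
raman_map <- function(spectra, rows, cols, wavenumber, step_um = 50,
                      valid_mask = NULL) {
  check_wavenumber_axis(wavenumber)
  spectra <- as.matrix(spectra)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1 || cols < 1) abort("`rows` and `cols` must be positive.")
  if (step_um <= 0) abort("`step_um` must be positive.")
  if (nrow(spectra) != rows * cols) {
    abort(sprintf("`spectra` has %d rows; expected rows * cols = %d.",
                  nrow(spectra), rows * cols))
  }
  if (ncol(spectra) != length(wavenumber)) {
    abort("`spectra` columns must match the wavenumber axis length.")
  }
  if (!all(is.finite(spectra))) abort("Map intensities must be finite.")
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, rows, cols)
  }
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == c(rows, cols)))
  structure(
    list(spectra = spectra, rows = rows, cols = cols,
         wavenumber = as.numeric(wavenumber), step_um = step_um,
         valid_mask = valid_mask),
    class = "raman_map"
  )
}

#' @export
print.raman_map <- function(x, ...) {
  cat(sprintf("<raman_map: %d x %d pixels, %d channels (%.0f-%.0f cm^-1), step %.0f um>\n",
              x$rows, x$cols, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber), x$step_um))
  invisible(x)
}

#' @export
dim.raman_map <- function(x) c(x$rows, x$cols, length(x$wavenumber))

#' Extract one pixel spectrum from a map
#'
#' @param m A [raman_map].
#' @param row,col 1-based grid indices.
#' @return A [raman_spectrum].
#' @export
pixel_spectrum <- function(m, row, col) {
  stopifnot(inherits(m, "raman_map"))
  if (row < 1 || row > m$rows || col < 1 || col > m$cols) {
    abort("Pixel index out of range.")
  }
  raman_spectrum(m$wavenumber, m$spectra[(row - 1L) * m$cols + col, ])
}

#' @export
as_tibble.raman_map <- function(x, ...) {
  px <- pixel_grid(x$rows, x$cols)
  tibble(
    row = rep(px$row, each = length(x$wavenumber)),
    col = rep(px$col, each = length(x$wavenumber)),
    wavenumber = rep(x$wavenumber, times = nrow(px)),
    intensity = as.vector(t(x$spectra))
  )
}

# Row-major pixel order shared by maps, layers and the feature matrix.
pixel_grid <- function(rows, cols) {
  tibble(row = rep(seq_len(rows), each = cols),
         col = rep(seq_len(cols), times = rows))
}

# rows x cols matrix -> row-major vector and back.
flatten_image <- function(img) as.vector(t(img))
unflatten_image <- function(v, rows, cols) matrix(v, nrow = rows, byrow = TRUE)

#' Read / write the columnar Raman map text format
#'
#' Plain-text exchange format for Raman maps: UTF-8, tab-separated, header
#' lines `# rows R`, `# cols C`, `# step_um S`, then a matrix whose first
#' column is the wavenumber axis (cm^-1, increasing) followed by one column
#' per pixel in row-major pixel order.
#'
#' @param path File path.
#' @return `read_raman_map()` returns a [raman_map]; `write_raman_map()`
#'   returns `path` invisibly.
#' @export
read_raman_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 4) abort("Malformed Raman map file: too short.")
  hdr <- function(i, key) {
    m <- regmatches(lines[i], regexec(paste0("^# ", key, " ([0-9.eE+-]+)$"), lines[i]))[[1]]
    if (length(m) != 2) {
      abort(sprintf("Malformed header at line %d: expected '# %s <value>'.", i, key))
    }
    as.numeric(m[2])
  }
  rows <- hdr(1, "rows"); cols <- hdr(2, "cols"); step <- hdr(3, "step_um")
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  n_pix <- rows * cols
  vals <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(vals)
  bad <- which(widths != n_pix + 1)
  if (length(bad)) {
    abort(sprintf("Ragged row at line %d: %d fields, expected %d.",
                  bad[1] + 3L, widths[bad[1]], n_pix + 1L))
  }
  num <- matrix(as.numeric(unlist(vals, use.names = FALSE)),
                nrow = length(body), byrow = TRUE)
  if (anyNA(num)) abort("Non-numeric value in Raman map body.")
  wn <- num[, 1]
  check_wavenumber_axis(wn)
  raman_map(t(num[, -1, drop = FALSE]), rows, cols, wn, step_um = step)
}

#' @param m A [raman_map].
#' @rdname read_raman_map
#' @export
write_raman_map <- function(m, path) {
  stopifnot(inherits(m, "raman_map"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# rows %d", m$rows),
               sprintf("# cols %d", m$cols),
               sprintf("# step_um %g", m$step_um)), con)
  utils::write.table(cbind(m$wavenumber, t(m$spectra)), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
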