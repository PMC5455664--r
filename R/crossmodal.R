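#' Micro-CT density image
#'
#' A single-channel grayscale slice from X-ray micro computed tomography.
#' Gray values are a density proxy (X-ray absorption); industrial CT values
#' are not calibrated absorption coefficients.
#'
#' @param values Integer matrix of gray values within the declared bit
#'   depth.
#' @param bit_depth 8 or 16.
#' @param voxel_size_um Voxel size in micrometres (default 9.79).
#' @return An object of class `density_image`.
#' @export
density_image <- function(values, bit_depth = 16, voxel_size_um = 9.79) {
  values <- as.matrix(values)
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  if (voxel_size_um <= 0) abort("`voxel_size_um` must be positive.")
  lim <- 2^bit_depth - 1
  if (anyNA(values) || min(values) < 0 || max(values) > lim) {
    abort(sprintf("Gray values must lie within [0, %d].", lim))
  }
  structure(list(values = values, bit_depth = as.integer(bit_depth),
                 voxel_size_um = voxel_size_um),
            class = "density_image")
}

#' @export
print.density_image <- function(x, ...) {
  cat(sprintf("<density_image: %d x %d, %d bit, voxel %.2f um>\n",
              nrow(x$values), ncol(x$values), x$bit_depth, x$voxel_size_um))
  invisible(x)
}

#' @export
dim.density_image <- function(x) dim(x$values)

#' Map a 16-bit CT image to 8 bit
#'
#' Full-range linear mapping `round(value / 257)`: monotone, with 0 mapping
#' to 0 and 65535 to 255, so the endpoints of the 16-bit scale are
#' preserved exactly.
#'
#' @param img A [density_image] with `bit_depth = 16`. An image that is
#'   already 8 bit is returned unchanged with a warning.
#' @return An 8-bit [density_image].
#' @export
map_16bit_to_8bit <- function(img) {
  stopifnot(inherits(img, "density_image"))
  if (img$bit_depth == 8) {
    warn("Image is already 8 bit; returning it unchanged.")
    return(img)
  }
  density_image(round_half_up(img$values / 257), bit_depth = 8,
                voxel_size_um = img$voxel_size_um)
}

#' Affine registration between the Raman grid and the CT image
#'
#' A 2D affine transform mapping Raman grid indices `(row, col)` to CT
#' pixel coordinates: `ct = A %*% c(row, col) + offset`. In practice the
#' transform is derived from fiducial landmarks such as saw kerfs; for
#' phantoms it is the identity.
#'
#' @param A 2 x 2 matrix with non-zero determinant.
#' @param offset Length-2 numeric.
#' @return An object of class `registration_transform`.
#' @export
registration_transform <- function(A = diag(2), offset = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  if (!all(is.finite(A)) || abs(det(A)) < 1e-12) {
    abort("The linear part of the transform must be invertible.")
  }
  if (length(offset) != 2 || !all(is.finite(offset))) {
    abort("`offset` must be two finite numbers.")
  }
  structure(list(A = A, offset = as.numeric(offset)),
            class = "registration_transform")
}

#' Resample a CT image onto the Raman grid
#'
#' Adapts the digital resolution of the CT image to the (coarser) Raman
#' grid: each Raman pixel is mapped through the registration transform and
#' the CT gray value at the transformed coordinate is picked by
#' nearest-neighbor (default) or bilinear interpolation. Coordinates
#' falling outside the CT image are masked (`NA`) and excluded from the
#' downstream statistics.
#'
#' @param ct An 8-bit [density_image].
#' @param transform A [registration_transform].
#' @param grid `c(rows, cols)` of the Raman map.
#' @param method `"nearest"` or `"bilinear"`.
#' @return A numeric `rows x cols` matrix of gray values with `NA` for
#'   out-of-bounds pixels.
#' @export
resample_ct <- function(ct, transform = registration_transform(),
                        grid, method = c("nearest", "bilinear")) {
  stopifnot(inherits(ct, "density_image"),
            inherits(transform, "registration_transform"))
  if (ct$bit_depth != 8) abort("Resampling expects an 8-bit image; run map_16bit_to_8bit() first.")
  method <- match.arg(method)
  rows <- grid[1]; cols <- grid[2]
  px <- pixel_grid(rows, cols)
  tc <- cbind(px$row, px$col) %*% t(transform$A) +
    matrix(transform$offset, nrow(px), 2, byrow = TRUE)
  r <- tc[, 1]; c <- tc[, 2]
  nr <- nrow(ct$values); nc <- ncol(ct$values)
  out <- rep(NA_real_, nrow(px))
  if (method == "nearest") {
    ri <- round_half_up(r); ci <- round_half_up(c)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out[ok] <- ct$values[cbind(ri[ok], ci[ok])]
  } else {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    # clamp the cell so points on the last row/column interpolate inside it
    r0 <- pmin(pmax(floor(r), 1), nr - 1)
    c0 <- pmin(pmax(floor(c), 1), nc - 1)
    fr <- (r - r0)[ok]; fc <- (c - c0)[ok]
    v00 <- ct$values[cbind(r0[ok], c0[ok])]
    v01 <- ct$values[cbind(r0[ok], c0[ok] + 1)]
    v10 <- ct$values[cbind(r0[ok] + 1, c0[ok])]
    v11 <- ct$values[cbind(r0[ok] + 1, c0[ok] + 1)]
    out[ok] <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
      v10 * fr * (1 - fc) + v11 * fr * fc
  }
  unflatten_image(out, rows, cols)
}

seg_gray_frame <- function(gray, seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  gray <- as.matrix(gray)
  if (!all(dim(gray) == dim(seg$labels))) {
    abort("`gray` and the segmentation must share one grid.")
  }
  tibble(gray = flatten_image(gray),
         segment = flatten_image(seg$labels)) |>
    dplyr::filter(!is.na(.data$gray))
}

#' One-way ANOVA of CT gray values across segments
#'
#' Standard fixed-effects one-way decomposition of the resampled CT gray
#' values over the Raman-based segments:
#' `F = (SS_between / df_between) / (SS_within / df_within)`, with the
#' p-value from the F distribution. Degenerate inputs are handled
#' explicitly: zero within-segment variance with distinct means gives
#' `F = Inf`, `p = 0`; completely constant data gives `F = 0`, `p = 1`.
#'
#' @param gray Numeric `rows x cols` matrix (masked pixels `NA`).
#' @param seg A [segmentation_result] on the same grid.
#' @return A one-row tibble with columns `f`, `df_between`, `df_within`,
#'   `p`, `n`.
#' @export
anova_by_segment <- function(gray, seg) {
  d <- seg_gray_frame(gray, seg)
  counts <- table(d$segment)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("Need at least 2 segments with at least 2 pixels each.")
  }
  df_b <- length(counts) - 1L
  df_w <- nrow(d) - length(counts)
  fit <- lm(gray ~ factor(segment), data = d)
  tab <- suppressWarnings(anova(fit))  # perfect-fit warning; handled below
  ss_b <- tab$`Sum Sq`[1]; ss_w <- tab$`Sum Sq`[2]
  tot <- ss_b + ss_w
  if (tot <= 0 || ss_b / max(tot, 1e-300) < 1e-14) {
    f <- 0; p <- 1
  } else if (ss_w / tot < 1e-14) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  }
  tibble(f = f, df_between = df_b, df_within = df_w, p = p, n = nrow(d))
}

#' Per-segment box statistics of CT gray values
#'
#' Box-plot statistics in the usual convention: the central mark is the
#' median, box edges are the 25th and 75th percentiles (linear
#' interpolation of order statistics), whiskers extend to the most extreme
#' data points not considered outliers, and outliers are points beyond 1.5
#' times the interquartile range from the box.
#'
#' @inheritParams anova_by_segment
#' @return A tibble with one row per segment: `segment`, `n`, `median`,
#'   `q25`, `q75`, `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
boxplot_stats <- function(gray, seg) {
  d <- seg_gray_frame(gray, seg)
  d |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$gray),
      q25 = quantile(.data$gray, 0.25, type = 7, names = FALSE),
      q75 = quantile(.data$gray, 0.75, type = 7, names = FALSE),
      whisker_lo = min(.data$gray[.data$gray >= q25 - 1.5 * (q75 - q25)]),
      whisker_hi = max(.data$gray[.data$gray <= q75 + 1.5 * (q75 - q25)]),
      n_outliers = sum(.data$gray < whisker_lo | .data$gray > whisker_hi),
      .groups = "drop"
    )
}

#' Normalized per-segment gray-value histograms
#'
#' Relative frequencies of the 8-bit gray values within each segment over
#' `n_bins` integer bins (default 256, i.e. one bin per gray level). Each
#' segment's frequencies sum to 1; empty bins are 0.
#'
#' @inheritParams anova_by_segment
#' @param n_bins Number of bins covering 0--255 (default 256).
#' @return A tibble in long form: `segment`, `gray` (bin center), `count`,
#'   `prop`.
#' @export
segment_histograms <- function(gray, seg, n_bins = 256) {
  d <- seg_gray_frame(gray, seg)
  if (min(d$gray) < 0 || max(d$gray) > 255) {
    abort("Gray values must lie within 0-255; run map_16bit_to_8bit() first.")
  }
  width <- 256 / n_bins
  segs <- seq_len(seg$n_segments)
  purrr::map_dfr(segs, function(s) {
    v <- d$gray[d$segment == s]
    bin <- pmin(floor(v / width), n_bins - 1)
    counts <- tabulate(bin + 1, nbins = n_bins)
    # bin lower edge; with the default one-bin-per-gray-level this is the
    # gray value itself
    tibble(segment = s,
           gray = (seq_len(n_bins) - 1) * width,
           count = counts,
           prop = if (length(v)) counts / length(v) else rep(0, n_bins),
           empty_segment = length(v) == 0)
  })
}

#' Coefficient-of-determination table and material attribution
#'
#' For each (material, segment) pair the coefficient of determination (COD)
#' is the square of the mean raw Pearson COC of the segment's pixels in the
#' material's correlation map. The highest COD in a row attributes the
#' material to a segment. An alternative aggregation — the mean of the
#' per-pixel squared COC — is available via `method = "mean_cod"`.
#'
#' @param correlation_layers List of `feature_layer`s of kind
#'   `"correlation_map"` (carrying raw COC), or a [layer_stack] from which
#'   they are extracted.
#' @param seg A [segmentation_result] on the same grid.
#' @param method `"sq_mean_coc"` (default: square of the segment-mean COC)
#'   or `"mean_cod"` (mean per-pixel squared COC).
#' @return An object of class `cod_table`: a list with `cod` (tibble,
#'   one row per material, one `segment_<i>` column per segment),
#'   `attribution` (tibble `material`, `segment`, `cod`) and `method`.
#' @export
cod_table <- function(correlation_layers, seg,
                      method = c("sq_mean_coc", "mean_cod")) {
  method <- match.arg(method)
  if (inherits(correlation_layers, "layer_stack")) {
    correlation_layers <- purrr::keep(correlation_layers$layers,
                                      ~ .x$kind == "correlation_map")
  }
  if (!length(correlation_layers)) abort("No correlation layers supplied.")
  stopifnot(inherits(seg, "segmentation_result"))
  segs <- seq_len(seg$n_segments)
  seg_vec <- flatten_image(seg$labels)
  rows <- purrr::map_dfr(correlation_layers, function(l) {
    if (!identical(dim(l$raw), dim(seg$labels))) {
      abort("Correlation layers and segmentation must share one grid.")
    }
    coc <- flatten_image(l$raw)
    ok <- flatten_image(l$valid_mask)
    cod <- vapply(segs, function(s) {
      sel <- seg_vec == s & ok
      if (!any(sel)) return(NA_real_)
      if (method == "sq_mean_coc") mean(coc[sel])^2 else mean(coc[sel]^2)
    }, numeric(1))
    tibble(material = l$name, segment = segs, cod = cod)
  })
  wide <- tidyr::pivot_wider(rows, names_from = "segment",
                             values_from = "cod", names_prefix = "segment_")
  attribution <- rows |>
    dplyr::group_by(.data$material) |>
    dplyr::slice_max(.data$cod, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("material", "segment", "cod")
  structure(list(cod = wide, attribution = attribution, method = method),
            class = "cod_table")
}

#' @export
print.cod_table <- function(x, ...) {
  cat("<cod_table> (", x$method, ")\n", sep = "")
  print(x$cod)
  cat("attribution:\n")
  print(x$attribution)
  invisible(x)
}

#' @export
tidy.cod_table <- function(x, ...) {
  tidyr::pivot_longer(x$cod, dplyr::starts_with("segment_"),
                      names_to = "segment", names_prefix = "segment_",
                      values_to = "cod") |>
    dplyr::mutate(segment = as.integer(.data$segment))
}

#' Cross-modal report: segments vs CT gray values
#'
#' Bundles the one-way ANOVA, per-segment box statistics, normalized
#' gray-value histograms and (optionally) the COD attribution table for a
#' segmentation overlaid on a co-registered 8-bit CT image.
#'
#' @inheritParams anova_by_segment
#' @param correlation_layers Optional list of correlation-map layers (or a
#'   [layer_stack]) for the COD table.
#' @param cod_method Passed to [cod_table()].
#' @return An object of class `crossmodal_report` with elements `anova`,
#'   `box_stats`, `histograms` and `cod` (`NULL` when no correlation
#'   layers are given).
#' @export
crossmodal_report <- function(gray, seg, correlation_layers = NULL,
                              cod_method = "sq_mean_coc") {
  rep <- list(
    anova = anova_by_segment(gray, seg),
    box_stats = boxplot_stats(gray, seg),
    histograms = segment_histograms(gray, seg),
    cod = if (!is.null(correlation_layers)) {
      cod_table(correlation_layers, seg, method = cod_method)
    }
  )
  structure(rep, class = "crossmodal_report")
}

#' @export
print.crossmodal_report <- function(x, ...) {
  cat("<crossmodal_report>\n")
  cat(sprintf("  ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$f, x$anova$p))
  cat(sprintf("  %d segments; COD table %s\n", nrow(x$box_stats),
              if (is.null(x$cod)) "absent" else "present"))
  invisible(x)
}

#' @export
glance.crossmodal_report <- function(x, ...) {
  tibble(f = x$anova$f, p = x$anova$p,
         df_between = x$anova$df_between, df_within = x$anova$df_within,
         n_segments = nrow(x$box_stats),
         n_pixels = x$anova$n)
}
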