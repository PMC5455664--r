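#' Default pipeline configuration
#'
#' The tunable parameters of the fusion pipeline with their defaults: the
#' band list of [raman_bands()], a redundancy threshold of 0.9 absolute
#' COC, a dendrogram cut at 57% of the total distance, a minimum segment
#' size of 20 pixels, asymmetric-least-squares baseline parameters, an
#' identity registration transform and the phantom simulation settings.
#'
#' @return A nested list; see the entries' names. Can be written to / read
#'   from YAML with [yaml::write_yaml()] / [read_pipeline_config()].
#' @export
default_config <- function() {
  list(
    bands = as.data.frame(raman_bands()[, c("band", "position",
                                            "window_lo", "window_hi")]),
    baseline = list(smoothness = 1e6, asymmetry = 0.01),
    coc_threshold = 0.9,
    # tuned for the default phantom to avoid over-/under-segmentation (the
    # tissue measurements this emulates used 0.57/0.55; the cut is a
    # per-dataset choice)
    cut_fraction = 0.45,
    min_segment_size = 20,
    cod_method = "sq_mean_coc",
    registration = list(A = c(1, 0, 0, 1), offset = c(0, 0)),
    phantom = list(shape = c(60, 80), baseline_amp = 100, noise_sd = 8,
                   faulty_fraction = 0.01, kerf = TRUE,
                   shared_density = FALSE),
    inputs = list(raman_map = NULL, ct = NULL, references = NULL)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]: entries absent
#' from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  if (is.list(cfg$bands) && !is.data.frame(cfg$bands)) {
    cfg$bands <- as.data.frame(do.call(rbind.data.frame, cfg$bands))
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$coc_threshold <= 0 || cfg$coc_threshold >= 1) {
    abort("`coc_threshold` must be in (0, 1).")
  }
  if (cfg$cut_fraction <= 0 || cfg$cut_fraction >= 1) {
    abort("`cut_fraction` must be in (0, 1).")
  }
  if (any(cfg$bands$window_lo >= cfg$bands$window_hi)) {
    abort("Every band window needs window_lo < window_hi.")
  }
  cfg
}

#' Build the feature-layer stack of a map
#'
#' Baseline-corrects the map, then builds one correlation map per reference
#' spectrum followed by one band image per configured band. Order matters:
#' the redundancy filter keeps the earlier member of a correlated pair, and
#' reference-correlation maps carry the most specific material information,
#' so they are placed first and redundant band images are the ones dropped.
#'
#' @param map A [raman_map] (raw; baseline correction is applied here).
#' @param refs Named list of [raman_spectrum] references.
#' @param bands Data frame with columns `band`, `position`, `window_lo`,
#'   `window_hi` (default [raman_bands()]).
#' @param baseline List with `smoothness` and `asymmetry` for
#'   [baseline_correct()].
#' @return A list with `stack` (the [layer_stack]) and `corrected_map`.
#' @export
build_feature_stack <- function(map, refs, bands = raman_bands(),
                                baseline = list(smoothness = 1e6,
                                                asymmetry = 0.01)) {
  corrected <- baseline_correct(map, smoothness = baseline$smoothness,
                                asymmetry = baseline$asymmetry)
  band_layers <- purrr::pmap(
    list(bands$band, bands$position, bands$window_lo, bands$window_hi),
    function(nm, pos, lo, hi) band_image(corrected, pos, c(lo, hi), name = nm)
  )
  corr_layers <- purrr::imap(refs, function(r, nm) {
    correlation_map(corrected, r, name = nm)
  })
  list(stack = layer_stack(c(unname(corr_layers), band_layers)),
       corrected_map = corrected)
}

#' Run the full fusion pipeline
#'
#' End-to-end run: obtain inputs (either the supplied `map`/`ct`/`refs` or
#' a simulated phantom), build and filter the feature stack, segment the
#' map, co-register the CT slice and produce the cross-modal report. When
#' `out_dir` is given, artifacts are written: feature layers as gray and
#' rainbow pseudo-color PNGs, the removal log as CSV, the segmentation as
#' PNG + JSON, the dendrogram merge heights as JSON, the cross-modal
#' report as JSON plus CSV tables, and a structured log of every threshold
#' applied.
#'
#' @param config Configuration list (see [default_config()]) or a YAML
#'   path.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param seed Integer seed for the phantom simulation.
#' @param map,ct,refs Optional explicit inputs overriding the config; `ct`
#'   may be 16 bit (it is mapped to 8 bit) and is resampled onto the map
#'   grid through the configured registration transform.
#' @param truth Optional [phantom_truth] carried into the result for
#'   validation.
#' @return An object of class `fusion_result`: a list with `stack`,
#'   `removal_log`, `dendrogram`, `segmentation`, `gray8`, `report`,
#'   `config`, `seed` and (if simulated or supplied) `truth`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         seed = 1L, map = NULL, ct = NULL, refs = NULL,
                         truth = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_config(config)
  if (is.null(map)) {
    if (!is.null(config$inputs$raman_map)) {
      map <- read_raman_map(config$inputs$raman_map)
      if (!is.null(config$inputs$ct)) ct <- read_ct_image(config$inputs$ct)
      if (!is.null(config$inputs$references)) {
        refs <- read_reference_spectra(config$inputs$references)
      }
    } else {
      ph <- simulate_phantom(
        shape = config$phantom$shape,
        materials = bone_graft_materials(config$phantom$shared_density),
        baseline_amp = config$phantom$baseline_amp,
        noise_sd = config$phantom$noise_sd,
        faulty_fraction = config$phantom$faulty_fraction,
        kerf = config$phantom$kerf,
        seed = seed
      )
      map <- ph$map; ct <- ph$ct; refs <- ph$refs; truth <- ph$truth
    }
  }
  if (is.null(ct) || is.null(refs)) {
    abort("`ct` and `refs` are required when a map is supplied.")
  }

  fs <- build_feature_stack(map, refs, bands = as_tibble(config$bands),
                            baseline = config$baseline)
  filt <- remove_redundant(fs$stack, threshold = config$coc_threshold)
  sg <- segment_map(filt$stack, cut_fraction = config$cut_fraction,
                    min_segment_size = config$min_segment_size)

  if (ct$bit_depth == 16) ct <- map_16bit_to_8bit(ct)
  tr <- registration_transform(matrix(config$registration$A, 2, 2),
                               config$registration$offset)
  gray8 <- resample_ct(ct, tr, grid = c(map$rows, map$cols))

  # attribution uses every reference correlation map; the redundancy filter
  # governs only the clustering data set
  corr_layers <- purrr::keep(fs$stack$layers, ~ .x$kind == "correlation_map")
  report <- crossmodal_report(gray8, sg$segmentation,
                              correlation_layers = if (length(corr_layers)) corr_layers,
                              cod_method = config$cod_method)

  res <- structure(
    list(stack = filt$stack, removal_log = filt$removal_log,
         dendrogram = sg$dendrogram, segmentation = sg$segmentation,
         gray8 = gray8, report = report, config = config, seed = seed,
         truth = truth),
    class = "fusion_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result>\n")
  cat(sprintf("  %d layers kept (%d removed), %d segments, ANOVA F = %.3g (p = %.3g)\n",
              length(x$stack), nrow(x$removal_log),
              x$segmentation$n_segments, x$report$anova$f, x$report$anova$p))
  invisible(x)
}

#' @export
glance.fusion_result <- function(x, ...) {
  tibble(n_layers = length(x$stack),
         n_removed = nrow(x$removal_log),
         n_segments = x$segmentation$n_segments,
         cut_fraction = x$segmentation$cut_fraction,
         cut_height = x$segmentation$cut_height,
         f = x$report$anova$f, p = x$report$anova$p)
}

# ---- artifact writing --------------------------------------------------

rainbow_rgb <- function(values255) {
  # blue (low) -> green (medium) -> red (high), the usual rainbow order of
  # chemical-imaging software
  pal <- grDevices::colorRampPalette(c("blue", "cyan", "green", "yellow",
                                       "red"))(256)
  col <- grDevices::col2rgb(pal[values255 + 1L]) / 255
  array(c(col[1, ], col[2, ], col[3, ]),
        dim = c(dim(values255), 3))
}

write_layer_pngs <- function(stack, dir) {
  for (l in stack$layers) {
    png::writePNG(l$values / 255, file.path(dir, paste0(l$name, "_gray.png")))
    png::writePNG(rainbow_rgb(l$values), file.path(dir, paste0(l$name, "_rainbow.png")))
  }
}

segment_palette <- function(n) {
  grDevices::hcl.colors(max(n, 2), palette = "Dark 3")[seq_len(n)]
}

write_segmentation_png <- function(seg, path) {
  cols <- grDevices::col2rgb(segment_palette(seg$n_segments)) / 255
  lab <- seg$labels
  img <- array(0, dim = c(dim(lab), 3))
  for (ch in 1:3) img[, , ch] <- matrix(cols[ch, lab], nrow(lab), ncol(lab))
  png::writePNG(img, path)
}

#' Write a CT image as TIFF
#'
#' 16-bit images use the full 0--65535 range; 8-bit images 0--255.
#'
#' @param img A [density_image].
#' @param path Output path (.tiff).
#' @return `path`, invisibly.
#' @export
write_ct_image <- function(img, path) {
  stopifnot(inherits(img, "density_image"))
  bps <- img$bit_depth
  tiff::writeTIFF(img$values / (2^bps - 1), path, bits.per.sample = bps)
  invisible(path)
}

#' Read a CT image from TIFF or PNG
#'
#' @param path File path (.tif/.tiff/.png).
#' @param bit_depth Declared bit depth of the stored image (default 16 for
#'   TIFF, 8 for PNG).
#' @return A [density_image].
#' @export
read_ct_image <- function(path, bit_depth = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path)
    bit_depth <- bit_depth %||% 16
  } else if (ext == "png") {
    v <- png::readPNG(path)
    bit_depth <- bit_depth %||% 8
  } else {
    abort("CT images must be TIFF or PNG.")
  }
  if (length(dim(v)) == 3) v <- v[, , 1]
  density_image(round_half_up(v * (2^bit_depth - 1)), bit_depth = bit_depth)
}

read_reference_spectra <- function(paths) {
  refs <- lapply(paths, function(p) {
    d <- utils::read.table(p, header = TRUE, sep = "\t")
    raman_spectrum(d[[1]], d[[2]],
                   name = tools::file_path_sans_ext(basename(p)))
  })
  names(refs) <- vapply(refs, function(r) r$name, character(1))
  refs
}

# Serializes every tabular artifact with fixed numeric formatting so a
# rerun on the same seed is byte-identical.
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layers_dir <- file.path(out_dir, "layers")
  dir.create(layers_dir, showWarnings = FALSE)
  write_layer_pngs(res$stack, layers_dir)
  utils::write.csv(res$removal_log, file.path(out_dir, "removal_log.csv"),
                   row.names = FALSE)
  write_segmentation_png(res$segmentation, file.path(out_dir, "segmentation.png"))
  seg_json <- list(
    n_segments = res$segmentation$n_segments,
    cut_fraction = res$segmentation$cut_fraction,
    cut_height = res$segmentation$cut_height,
    segment_sizes = res$segmentation$segment_sizes,
    small_segment = res$segmentation$small_segment,
    labels = apply(res$segmentation$labels, 1, paste, collapse = ",")
  )
  jsonlite::write_json(seg_json, file.path(out_dir, "segmentation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(merge = res$dendrogram$merge, height = res$dendrogram$height),
    file.path(out_dir, "dendrogram.json"), digits = NA, pretty = TRUE
  )
  report <- list(
    anova = as.list(res$report$anova),
    box_stats = res$report$box_stats,
    histograms = res$report$histograms[res$report$histograms$count > 0, ],
    cod = if (!is.null(res$report$cod)) {
      list(table = res$report$cod$cod,
           attribution = res$report$cod$attribution,
           method = res$report$cod$method)
    }
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(res$report$box_stats, file.path(out_dir, "box_stats.csv"),
                   row.names = FALSE)
  if (!is.null(res$report$cod)) {
    utils::write.csv(res$report$cod$cod, file.path(out_dir, "cod_table.csv"),
                     row.names = FALSE)
  }
  log <- list(
    seed = res$seed,
    coc_threshold = res$config$coc_threshold,
    cut_fraction = res$config$cut_fraction,
    cut_height = res$segmentation$cut_height,
    min_segment_size = res$config$min_segment_size,
    baseline = res$config$baseline,
    n_layers_in = length(res$stack) + nrow(res$removal_log),
    n_layers_kept = length(res$stack),
    removed = res$removal_log$removed
  )
  jsonlite::write_json(log, file.path(out_dir, "pipeline_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write phantom ground-truth artifacts
#'
#' Writes the Raman map (columnar text), the CT slice (16-bit TIFF), the
#' label image and faulty mask (8-bit PNG) and the truth metadata (JSON).
#'
#' @param phantom A list as returned by [simulate_phantom()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_phantom <- function(phantom, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_raman_map(phantom$map, file.path(out_dir, "raman_map.tsv"))
  write_ct_image(phantom$ct, file.path(out_dir, "ct.tiff"))
  png::writePNG(phantom$truth$labels / 255, file.path(out_dir, "labels.png"))
  png::writePNG(phantom$truth$faulty_mask * 1, file.path(out_dir, "faulty_mask.png"))
  for (r in phantom$refs) {
    utils::write.table(
      data.frame(wavenumber = r$wavenumber, intensity = r$intensity),
      file.path(out_dir, paste0("ref_", r$name, ".tsv")),
      sep = "\t", row.names = FALSE
    )
  }
  meta <- list(
    seed = phantom$truth$seed,
    materials = names(phantom$truth$materials),
    n_faulty = sum(phantom$truth$faulty_mask),
    shape = dim(phantom$truth$labels)
  )
  jsonlite::write_json(meta, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
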