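# Shared fixtures, built in code. Full phantom pipeline runs are cached per
# configuration so the integration tests can share them.

.pipeline_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(seed, shared_density = FALSE, kerf = TRUE) {
  key <- sprintf("s%d_%d_%d", seed, shared_density, kerf)
  if (is.null(.pipeline_cache[[key]])) {
    cfg <- default_config()
    cfg$phantom$shared_density <- shared_density
    cfg$phantom$kerf <- kerf
    .pipeline_cache[[key]] <- run_pipeline(cfg, seed = seed)
  }
  .pipeline_cache[[key]]
}

truth_vec <- function(res) as.vector(t(res$truth$labels))
seg_vec <- function(res) as.vector(t(res$segmentation$labels))

# The segment that covers the majority of a material's true pixels.
majority_segment <- function(res, material) {
  i <- match(material, names(res$truth$materials))
  tv <- truth_vec(res); sv <- seg_vec(res)
  as.integer(names(which.max(table(sv[tv == i]))))
}

# A small flat map whose pixel spectra are given as rows.
make_test_map <- function(spectra, rows, cols, wavenumber) {
  raman_map(spectra, rows, cols, wavenumber)
}

# Feature layer straight from a value matrix (tests of the stack module).
make_test_layer <- function(values, name, kind = "band_image") {
  values <- round(values)
  ramanfuse:::new_feature_layer(
    values = matrix(as.integer(values), nrow(values), ncol(values)),
    raw = values, kind = kind, name = name, meta = list(),
    valid_mask = matrix(TRUE, nrow(values), ncol(values))
  )
}

# Layers with a prescribed correlation structure: columns of an exact
# Gram-factor construction, discretized to 0-255.
correlated_layers <- function(R, n = 400, seed = 42) {
  set.seed(seed)
  L <- chol(R)
  basis <- qr.Q(qr(matrix(rnorm(n * nrow(R)), n)))  # orthonormal columns
  X <- basis %*% L
  X <- apply(X, 2, function(v) (v - min(v)) / (max(v) - min(v)) * 255)
  lapply(seq_len(ncol(X)), function(j) {
    make_test_layer(matrix(X[, j], 20), name = paste0("L", j))
  })
}

# Gaussian peak helper for spectral tests.
gaussian_peak <- function(wn, center, height, width) {
  height * exp(-((wn - center) / width)^2 / 2)
}
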