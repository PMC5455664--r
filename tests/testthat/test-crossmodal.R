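seg_from <- function(labels, rows, cols, min_segment_size = 1) {
  labels_to_image(labels, c(rows, cols), min_segment_size = min_segment_size)
}

test_that("16-to-8-bit mapping is endpoint-exact", {
  img <- density_image(matrix(c(0L, 65535L, 32896L, 257L), 2), bit_depth = 16)
  out <- map_16bit_to_8bit(img)
  expect_identical(out$bit_depth, 8L)
  expect_equal(as.vector(out$values), c(0, 255, 128, 1))

  img8 <- density_image(matrix(5L, 2, 2), bit_depth = 8)
  expect_warning(out <- map_16bit_to_8bit(img8), "already 8 bit")
  expect_identical(out$values, img8$values)

  expect_error(density_image(matrix(70000, 1), bit_depth = 16), "within")
})

test_that("CT resampling honors the affine transform and masks out-of-bounds", {
  v <- matrix(sample(0:255, 36, replace = TRUE), 6)
  ct <- density_image(v, bit_depth = 8)
  # identity on equal grids is the identity
  out <- resample_ct(ct, registration_transform(), c(6, 6))
  expect_equal(out, v, ignore_attr = TRUE)

  # constant image stays constant under scaling
  ct_const <- density_image(matrix(7L, 8, 8), bit_depth = 8)
  out <- resample_ct(ct_const, registration_transform(2 * diag(2), c(-1, -1)),
                     c(4, 4))
  expect_true(all(out == 7))

  # coordinates outside the CT are NA-masked
  out <- resample_ct(ct, registration_transform(diag(2), c(3, 0)), c(6, 6))
  expect_true(all(is.na(out[4:6, ])))
  expect_true(all(!is.na(out[1:3, ])))

  # 2x upsampled CT of a label image maps back onto the truth exactly
  lab <- make_label_image(c(20, 24), 3, kerf = FALSE, seed = 2)
  ct2 <- density_image(kronecker(lab * 50L, matrix(1L, 2, 2)), bit_depth = 8)
  out <- resample_ct(ct2, registration_transform(2 * diag(2), c(-0.5, -0.5)),
                     c(20, 24))
  expect_gte(mean(out == lab * 50), 0.99)

  expect_error(registration_transform(matrix(0, 2, 2)), "invertible")

  # bilinear interpolation averages neighbors
  ct_lin <- density_image(matrix(c(0L, 10L, 0L, 10L), 2), bit_depth = 8)
  out <- resample_ct(ct_lin, registration_transform(diag(2), c(0.5, 0)),
                     c(1, 2), method = "bilinear")
  expect_equal(as.vector(out), c(5, 5))
})

test_that("one-way ANOVA matches the textbook decomposition", {
  # identical groups: no between-group variance
  g <- matrix(c(1, 2, 3, 1, 2, 3), 2, byrow = TRUE)
  seg <- seg_from(c(1, 1, 1, 2, 2, 2), 2, 3)
  out <- anova_by_segment(g, seg)
  expect_equal(out$f, 0)
  expect_equal(out$p, 1)

  # zero within-group variance: F = Inf sentinel, p = 0
  g <- matrix(c(5, 5, 5, 9, 9, 9), 2, byrow = TRUE)
  out <- anova_by_segment(g, seg)
  expect_identical(out$f, Inf)
  expect_identical(out$p, 0)

  # hand-computed closed form
  g <- matrix(c(1, 2, 3, 2, 3, 4, 5, 6, 7), 3, byrow = TRUE)
  seg3 <- seg_from(rep(1:3, each = 3), 3, 3)
  out <- anova_by_segment(g, seg3)
  oracle <- anova_oracle(as.vector(t(g)), rep(1:3, each = 3))
  expect_equal(out$f, oracle$f, tolerance = 1e-10)
  expect_equal(out$p, oracle$p, tolerance = 1e-10)
  expect_identical(out$df_between, 2L)
  expect_identical(out$df_within, 6L)

  # random instances
  for (seed in 1:20) {
    set.seed(seed)
    n <- 24
    vals <- matrix(round(runif(n, 0, 255)), 4)
    labs <- sample(1:3, n, replace = TRUE)
    labs[1:6] <- rep(1:3, 2)  # keep every group populated with >= 2 pixels
    seg_r <- seg_from(labs, 4, 6)
    out <- anova_by_segment(vals, seg_r)
    # renumbering by size does not change the decomposition
    oracle <- anova_oracle(as.vector(t(vals)), labs)
    expect_equal(out$f, oracle$f, tolerance = 1e-10)
  }

  expect_error(anova_by_segment(matrix(1, 2, 2), seg_from(rep(1, 4), 2, 2)),
               "at least 2 segments")
})

test_that("box statistics follow the linear-interpolation convention", {
  g <- matrix(1:100, 10, byrow = TRUE)
  seg <- seg_from(rep(1, 100), 10, 10)
  out <- boxplot_stats(g, seg)
  expect_equal(out$median, 50.5)
  expect_equal(out$q25, 25.75)
  expect_equal(out$q75, 75.25)
  expect_identical(out$n_outliers, 0L)

  # constant segment: zero IQR, no outliers
  g <- matrix(4, 3, 3)
  out <- boxplot_stats(g, seg_from(rep(1, 9), 3, 3))
  expect_equal(out$median, 4)
  expect_equal(out$q75 - out$q25, 0)
  expect_identical(out$n_outliers, 0L)
  expect_equal(out$whisker_lo, 4)

  # one far point beyond 1.5 IQR is the single outlier
  v <- c(10, 11, 12, 13, 14, 15, 16, 17, 200)
  out <- boxplot_stats(matrix(v, 3, byrow = TRUE), seg_from(rep(1, 9), 3, 3))
  expect_identical(out$n_outliers, 1L)
  expect_equal(out$whisker_hi, 17)

  # random segments against the oracle
  for (seed in 1:20) {
    set.seed(seed)
    v <- round(runif(30, 0, 255))
    out <- boxplot_stats(matrix(v, 5, byrow = TRUE), seg_from(rep(1, 30), 5, 6))
    o <- box_oracle(v)
    expect_equal(out$median, o$median, tolerance = 1e-10)
    expect_equal(out$q25, o$q25, tolerance = 1e-10)
    expect_equal(out$q75, o$q75, tolerance = 1e-10)
    expect_equal(out$whisker_lo, o$whisker_lo)
    expect_equal(out$whisker_hi, o$whisker_hi)
    expect_identical(out$n_outliers, as.integer(o$n_outliers))
  }
})

test_that("segment histograms are normalized relative frequencies", {
  g <- matrix(7, 2, 2)
  seg <- seg_from(rep(1, 4), 2, 2)
  h <- segment_histograms(g, seg)
  expect_equal(sum(h$prop), 1)
  expect_equal(h$prop[h$gray == 7], 1)
  expect_true(all(h$prop[h$gray != 7] == 0))

  # per-segment masses are 1 within 1e-9
  set.seed(2)
  g <- matrix(sample(0:255, 200, replace = TRUE), 10)
  seg <- seg_from(rep(1:2, each = 100), 10, 20)
  h <- segment_histograms(g, seg)
  sums <- tapply(h$prop, h$segment, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # a large uniform segment concentrates nowhere
  set.seed(3)
  g <- matrix(sample(0:255, 10000, replace = TRUE), 100)
  h <- segment_histograms(g, seg_from(rep(1, 10000), 100, 100))
  expect_lt(max(h$prop), 3 / 256)
})

test_that("COD squares the segment-mean COC and attributes by row max", {
  seg <- seg_from(rep(1:2, each = 8), 4, 4)
  perfect <- make_test_layer(matrix(0, 4, 4), "m1", kind = "correlation_map")
  perfect$raw <- matrix(c(rep(1, 8), rep(0.1, 8)), 4, 4, byrow = TRUE)
  half <- perfect; half$name <- "m2"
  half$raw <- matrix(c(rep(0.5, 8), rep(0.9, 8)), 4, 4, byrow = TRUE)
  ct <- cod_table(list(perfect, half), seg)
  tab <- tidy(ct)
  expect_equal(tab$cod[tab$material == "m1" & tab$segment == 1], 1)
  expect_equal(tab$cod[tab$material == "m2" & tab$segment == 1], 0.25)
  expect_equal(tab$cod[tab$material == "m2" & tab$segment == 2], 0.81)
  expect_identical(ct$attribution$segment[ct$attribution$material == "m1"], 1L)
  expect_identical(ct$attribution$segment[ct$attribution$material == "m2"], 2L)
  expect_true(all(tab$cod >= 0 & tab$cod <= 1))

  # mean-of-squares alternative
  ct2 <- cod_table(list(half), seg, method = "mean_cod")
  tab2 <- tidy(ct2)
  expect_equal(tab2$cod[tab2$segment == 1], 0.25)

  # attribution is invariant to relabeling of the same partition
  seg_a <- seg_from(rep(c(1, 2), c(6, 10)), 4, 4)
  seg_b <- seg_from(rep(c(5, 3), c(6, 10)), 4, 4)
  expect_identical(seg_a$labels, seg_b$labels)
  ct_a <- cod_table(list(perfect, half), seg_a)
  ct_b <- cod_table(list(perfect, half), seg_b)
  expect_identical(ct_a$attribution, ct_b$attribution)
})

test_that("crossmodal_report bundles the four analyses", {
  res <- cached_pipeline(1)
  rep <- res$report
  expect_s3_class(rep, "crossmodal_report")
  expect_true(all(c("f", "p") %in% names(rep$anova)))
  expect_identical(nrow(rep$box_stats), res$segmentation$n_segments)
  expect_s3_class(rep$cod, "cod_table")
  g <- glance(rep)
  expect_identical(g$n_segments, res$segmentation$n_segments)
})
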