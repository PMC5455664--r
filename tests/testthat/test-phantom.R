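axis <- seq(50, 3300, by = 4)

test_that("material specs validate their invariants", {
  expect_error(material_spec("x", data.frame(center = 1, height = 1, width = 0),
                             ct_gray_modes = data.frame(mean = 1, sd = 1, weight = 1)),
               "width")
  expect_error(material_spec("x", data.frame(center = 1, height = 1, width = 1),
                             ct_gray_modes = data.frame(mean = 1, sd = 1, weight = 0.5)),
               "sum to 1")
  expect_error(material_spec("x", data.frame(center = 1, height = 1, width = 1),
                             luminescence = c(2000, 1200, 5),
                             ct_gray_modes = data.frame(mean = 1, sd = 1, weight = 1)),
               "lo < hi")
})

test_that("reference spectra peak where the bands are placed", {
  bone_like <- material_spec(
    "bonelike", data.frame(center = 961, height = 400, width = 8),
    ct_gray_modes = data.frame(mean = 100, sd = 5, weight = 1)
  )
  refs <- make_reference_spectra(list(bone_like), axis)
  s <- refs$bonelike
  expect_equal(which.max(s$intensity), which.min(abs(axis - 961)))
  expect_true(all(s$intensity >= 0))

  empty <- material_spec("void", data.frame(center = numeric(),
                                            height = numeric(),
                                            width = numeric()),
                         ct_gray_modes = data.frame(mean = 1, sd = 1, weight = 1))
  expect_true(all(make_reference_spectra(list(empty), axis)$void$intensity == 0))

  # same inputs, same seed -> identical spectra
  r1 <- make_reference_spectra(list(bone_like), axis, noise_sd = 2, seed = 5)
  r2 <- make_reference_spectra(list(bone_like), axis, noise_sd = 2, seed = 5)
  expect_identical(r1$bonelike$intensity, r2$bonelike$intensity)

  off_axis <- material_spec("bad", data.frame(center = 3500, height = 1, width = 1),
                            ct_gray_modes = data.frame(mean = 1, sd = 1, weight = 1))
  expect_error(make_reference_spectra(list(off_axis), axis), "outside the axis")
})

test_that("luminescent materials light up between 1200 and 2000 only", {
  mats <- bone_graft_materials()
  refs <- make_reference_spectra(list(mats$biooss), axis)
  s <- refs$biooss$intensity
  mid <- axis > 1350 & axis < 1850
  expect_true(all(s[mid] > 10))          # luminescence floor inside the bump
  outside <- axis > 2200 & axis < 2700
  expect_true(all(s[outside] < 1))
})

test_that("label images have contiguous well-sized regions and a kerf", {
  lab <- make_label_image(c(60, 80), 4, kerf = TRUE, seed = 1)
  expect_identical(dim(lab), c(60L, 80L))
  expect_setequal(sort(unique(as.vector(lab))), 0:4)
  counts <- tabulate(as.vector(lab), nbins = 4)
  expect_true(all(counts >= 48))

  one <- make_label_image(c(20, 20), 1, kerf = FALSE, seed = 1)
  expect_identical(sort(unique(as.vector(one))), 1L)

  expect_identical(make_label_image(c(30, 30), 3, seed = 9),
                   make_label_image(c(30, 30), 3, seed = 9))
  expect_error(make_label_image(c(10, 10), 50, seed = 1), "n_regions")
  expect_error(make_label_image(c(4, 80), 2, seed = 1), "at least 8")
})

test_that("the noiseless unmixed map equals the references pixel for pixel", {
  mats <- bone_graft_materials()
  placed <- mats[setdiff(names(mats), "background")]
  labels <- make_label_image(c(16, 20), 4, kerf = FALSE, seed = 2)
  truth <- phantom_truth(labels, placed, mats$background, seed = 2)
  refs <- make_reference_spectra(unname(placed), axis)
  out <- synthesize_map(truth, refs, baseline_amp = 0, noise_sd = 0,
                        faulty_fraction = 0, border_mix = FALSE, seed = 2)
  lab <- as.vector(t(labels))
  for (k in c(1, 77, 320)) {
    expect_equal(out$map$spectra[k, ], refs[[lab[k]]]$intensity)
  }
  # pure-region correlation with own reference is exactly 1
  cm <- correlation_map(out$map, refs$bone)
  expect_true(all(abs(cm$raw[labels == match("bone", names(placed))] - 1) < 1e-12))
})

test_that("faulty pixels are recorded and contain only noise", {
  mats <- bone_graft_materials()
  placed <- mats[setdiff(names(mats), "background")]
  labels <- make_label_image(c(60, 80), 4, kerf = FALSE, seed = 3)
  truth <- phantom_truth(labels, placed, mats$background, seed = 3)
  refs <- make_reference_spectra(unname(placed), axis)
  out <- synthesize_map(truth, refs, baseline_amp = 0, noise_sd = 0,
                        faulty_fraction = 0.02, seed = 3)
  n_faulty <- sum(out$truth$faulty_mask)
  expect_gt(n_faulty, 0)
  # with zero noise, faulty pixels are exactly zero spectra
  fl <- as.vector(t(out$truth$faulty_mask))
  expect_true(all(out$map$spectra[fl, ] == 0))
  expect_true(all(rowSums(abs(out$map$spectra[!fl, , drop = FALSE])) > 0))
  # binomial draw at p = 0.02 over 4800 pixels stays in a sane range
  expect_gt(n_faulty, 4800 * 0.02 * 0.4)
  expect_lt(n_faulty, 4800 * 0.02 * 2.5)
})

test_that("the phantom hits its configured band SNR", {
  # single-material phantom: nu1PO4 height 400 cps over noise_sd 8 -> ~50
  m <- material_spec("apatite", data.frame(center = 961, height = 400, width = 8),
                     ct_gray_modes = data.frame(mean = 100, sd = 5, weight = 1))
  labels <- matrix(1L, 40, 40)
  truth <- phantom_truth(labels, list(apatite = m),
                         bone_graft_materials()$background, seed = 4)
  refs <- make_reference_spectra(list(m), axis)
  out <- synthesize_map(truth, refs, baseline_amp = 100, noise_sd = 8,
                        faulty_fraction = 0, seed = 4)
  corrected <- baseline_correct(out$map)
  measured <- snr(corrected, 961, c(2200, 2700))
  expect_gt(measured, 50 * 0.8)
  expect_lt(measured, 50 * 1.2)
})

test_that("synthetic CT draws from the configured mixtures", {
  mats <- bone_graft_materials()
  placed <- mats[setdiff(names(mats), "background")]

  # degenerate mixture: sd 0 maps every pixel to exactly its mean
  deg <- material_spec("flat", data.frame(center = 961, height = 1, width = 1),
                       ct_gray_modes = data.frame(mean = 60, sd = 0, weight = 1))
  truth <- phantom_truth(matrix(1L, 10, 10), list(flat = deg),
                         mats$background, seed = 5)
  ct <- synthesize_ct(truth, seed = 5)
  expect_identical(ct$bit_depth, 16L)
  ct8 <- map_16bit_to_8bit(ct)
  expect_true(all(ct8$values == 60))
  # the 16-bit image is exactly 257x its 8-bit intent
  expect_true(all(ct$values == ct8$values * 257))

  expect_identical(synthesize_ct(truth, seed = 8)$values,
                   synthesize_ct(truth, seed = 8)$values)

  # marginals match the mixture: KS distance < 0.05 at >= 5000 pixels
  big_truth <- phantom_truth(matrix(2L, 72, 80), placed, mats$background, seed = 6)
  gray <- as.vector(map_16bit_to_8bit(synthesize_ct(big_truth, seed = 6))$values)
  modes <- placed$bone$ct_gray_modes
  mix_cdf <- function(x) {
    rowSums(vapply(seq_len(nrow(modes)), function(k) {
      modes$weight[k] * stats::pnorm(x, modes$mean[k], modes$sd[k])
    }, numeric(length(x))))
  }
  grid <- 0:255
  emp <- stats::ecdf(gray)
  # half-step shift accounts for the integer rounding of stored gray values
  ks <- max(abs(emp(grid) - mix_cdf(grid + 0.5)))
  expect_lt(ks, 0.05)
})

test_that("per-segment gray histograms of bimodal materials show both modes", {
  mats <- bone_graft_materials()
  truth <- phantom_truth(matrix(1L, 60, 80), list(bone = mats$bone),
                         mats$background, seed = 7)
  gray <- map_16bit_to_8bit(synthesize_ct(truth, seed = 7))$values
  h <- tabulate(as.vector(gray) + 1, nbins = 256)
  sm <- as.numeric(stats::filter(h, rep(1 / 5, 5), sides = 2))
  loc <- which(diff(sign(diff(sm))) < 0) + 1
  loc <- loc[sm[loc] > 0.002 * length(gray)]
  peaks <- loc - 1  # gray value of each local maximum
  expect_true(any(abs(peaks - 60) <= 3))
  expect_true(any(abs(peaks - 115) <= 3))
})

test_that("simulate_phantom is deterministic in its seed", {
  a <- simulate_phantom(shape = c(16, 16), seed = 11)
  b <- simulate_phantom(shape = c(16, 16), seed = 11)
  expect_identical(a$map$spectra, b$map$spectra)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$truth$labels, b$truth$labels)
  c_ <- simulate_phantom(shape = c(16, 16), seed = 12)
  expect_false(identical(a$map$spectra, c_$map$spectra))
})
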