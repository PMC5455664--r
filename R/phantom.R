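#' Material specification for the synthetic phantom
#'
#' Describes one material of the phantom: its Raman signature as a sum of
#' Gaussian bands (plus, optionally, a broad luminescence bump such as the
#' one the inorganic components of deproteinized bovine bone produce
#' between 1200 and 2000 cm^-1), and its micro-CT gray-value distribution
#' as a Gaussian mixture on the 8-bit scale.
#'
#' @param name Material label.
#' @param peaks Tibble / data frame with columns `center` (cm^-1), `height`
#'   (cps) and `width` (Gaussian sigma, cm^-1, > 0); may have zero rows.
#' @param luminescence `NULL`, or `c(lo, hi, amplitude)`: a raised-cosine
#'   bump spanning `[lo, hi]` cm^-1 with peak amplitude in cps.
#' @param ct_gray_modes Tibble / data frame with columns `mean` (0--255),
#'   `sd` and `weight`; weights must sum to 1.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, peaks, luminescence = NULL, ct_gray_modes) {
  peaks <- as_tibble(as.data.frame(peaks))
  if (nrow(peaks) && (!all(c("center", "height", "width") %in% names(peaks)) ||
                      any(peaks$width <= 0))) {
    abort("`peaks` needs columns center/height/width with width > 0.")
  }
  if (!is.null(luminescence)) {
    if (length(luminescence) != 3 || luminescence[1] >= luminescence[2]) {
      abort("`luminescence` must be c(lo, hi, amplitude) with lo < hi.")
    }
  }
  ct_gray_modes <- as_tibble(as.data.frame(ct_gray_modes))
  if (!all(c("mean", "sd", "weight") %in% names(ct_gray_modes)) ||
      nrow(ct_gray_modes) < 1) {
    abort("`ct_gray_modes` needs columns mean/sd/weight.")
  }
  if (abs(sum(ct_gray_modes$weight) - 1) > 1e-8) {
    abort("`ct_gray_modes$weight` must sum to 1.")
  }
  structure(list(name = name, peaks = peaks, luminescence = luminescence,
                 ct_gray_modes = ct_gray_modes),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec '%s': %d bands%s, %d CT mode(s)>\n",
              x$name, nrow(x$peaks),
              if (is.null(x$luminescence)) "" else " + luminescence",
              nrow(x$ct_gray_modes)))
  invisible(x)
}

peak_tbl <- function(center, height, width) {
  tibble(center = center, height = height, width = width)
}
mode_tbl <- function(mean, sd, weight) {
  tibble(mean = mean, sd = sd, weight = weight)
}

#' Default materials of the bone-graft phantom
#'
#' Four materials emulating a grafted bone section — a deproteinized
#' bovine bone mineral granulate ("biooss"), natural bone ("bone"),
#' tricalcium phosphate ("tcp") and fat ("fat") — plus an air/alcohol
#' background used for the saw-kerf stripe. Band positions and heights
#' follow the bone-relevant bands of [raman_bands()] (phosphate nu1 at
#' 961 cm^-1 peaking at 400 cps, C-H stretching at 2937 cm^-1 up to
#' 500 cps); the granulate carries a luminescence bump over 1200--2000
#' cm^-1 that bleeds into the amide-region band images, and its CT gray
#' level (mode 140) exceeds bone. Bone's gray values are an even mixture
#' of modes 60 and 115 (soft callus vs dense lamellar regions), and fat
#' shows two close modes at 55 and 62.
#'
#' @param shared_density If `TRUE`, tricalcium phosphate is given exactly
#'   the bone gray-value mixture, producing a phantom in which two
#'   chemically distinct materials are indistinguishable by density alone.
#' @return A named list of [material_spec] objects, including the
#'   `background` spec for label 0.
#' @export
bone_graft_materials <- function(shared_density = FALSE) {
  # unequal weights keep the mixture median on the dominant-mode shoulder,
  # where the gray-value CDF is steep and the sample median is stable,
  # while preserving the bimodality
  bone_modes <- mode_tbl(c(60, 115), c(4, 6), c(0.85, 0.15))
  mats <- list(
    biooss = material_spec(
      "biooss",
      peak_tbl(c(438, 589, 961, 1075, 2937),
               c(150, 120, 400, 180, 60),
               c(6, 6, 8, 6, 12)),
      luminescence = c(1200, 2000, 60),
      ct_gray_modes = mode_tbl(140, 10, 1)
    ),
    bone = material_spec(
      "bone",
      peak_tbl(c(438, 589, 961, 1075, 1256, 1457, 1677, 2937),
               c(120, 100, 380, 60, 70, 90, 110, 280),
               c(6, 6, 8, 6, 8, 8, 8, 12)),
      ct_gray_modes = bone_modes
    ),
    tcp = material_spec(
      "tcp",
      peak_tbl(c(438, 589, 949, 970),
               c(160, 130, 300, 200),
               c(6, 6, 8, 8)),
      ct_gray_modes = if (shared_density) bone_modes else mode_tbl(115, 8, 1)
    ),
    fat = material_spec(
      "fat",
      peak_tbl(c(1302, 1445, 1657, 1745, 2855, 2895),
               c(150, 200, 80, 90, 350, 250),
               c(10, 10, 10, 8, 14, 14)),
      ct_gray_modes = mode_tbl(c(55, 62), c(5, 5), c(0.6, 0.4))
    ),
    background = material_spec(
      "background", peak_tbl(numeric(), numeric(), numeric()),
      ct_gray_modes = mode_tbl(18, 6, 1)
    )
  )
  mats
}

#' Collagen-membrane reference material
#'
#' A purified collagen membrane used as an additional reference spectrum
#' (it is not placed in the phantom). Its spectrum shares the organic
#' amide/C-H bands of bone matrix, so its correlation map is typically
#' filtered out as redundant.
#'
#' @return A [material_spec].
#' @export
collagen_membrane_material <- function() {
  material_spec(
    "collagen_membrane",
    peak_tbl(c(1256, 1457, 1677, 2937),
             c(90, 100, 130, 320),
             c(8, 8, 8, 12)),
    ct_gray_modes = mode_tbl(70, 10, 1)
  )
}

#' Ground truth of a synthetic phantom
#'
#' @param labels Integer `rows x cols` matrix; 0 is background, positive
#'   values index `materials`.
#' @param materials Named list of [material_spec] (placed materials, label
#'   order).
#' @param background [material_spec] for label 0.
#' @param faulty_mask Logical matrix of the same shape (poor-SNR pixels);
#'   default all `FALSE`.
#' @param seed The seed the phantom was generated from.
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(labels, materials, background,
                          faulty_mask = NULL, seed = NA_integer_) {
  labels <- as.matrix(labels)
  if (is.null(faulty_mask)) {
    faulty_mask <- matrix(FALSE, nrow(labels), ncol(labels))
  }
  if (!all(dim(faulty_mask) == dim(labels))) {
    abort("`labels` and `faulty_mask` must share one shape.")
  }
  if (max(labels) > length(materials) || min(labels) < 0) {
    abort("Every label must index a material or the background (0).")
  }
  structure(list(labels = labels, materials = materials,
                 background = background, faulty_mask = faulty_mask,
                 seed = seed),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth: %d x %d, %d materials, %d faulty pixels>\n",
              nrow(x$labels), ncol(x$labels), length(x$materials),
              sum(x$faulty_mask)))
  invisible(x)
}

material_intensity <- function(mat, wavenumber) {
  y <- rep(0, length(wavenumber))
  if (nrow(mat$peaks)) {
    if (any(mat$peaks$center < min(wavenumber) |
            mat$peaks$center > max(wavenumber))) {
      abort(sprintf("Material '%s' has a peak center outside the axis range.",
                    mat$name))
    }
    for (k in seq_len(nrow(mat$peaks))) {
      y <- y + mat$peaks$height[k] *
        exp(-((wavenumber - mat$peaks$center[k]) / mat$peaks$width[k])^2 / 2)
    }
  }
  if (!is.null(mat$luminescence)) {
    lo <- mat$luminescence[1]; hi <- mat$luminescence[2]
    amp <- mat$luminescence[3]
    inside <- wavenumber >= lo & wavenumber <= hi
    t <- (wavenumber[inside] - lo) / (hi - lo)
    y[inside] <- y[inside] + amp * (1 - cos(2 * pi * t)) / 2
  }
  y
}

#' Synthesize reference spectra for phantom materials
#'
#' Each reference is the sum of the material's Gaussian bands plus its
#' luminescence ramp, evaluated on the given axis; optional i.i.d. Gaussian
#' measurement noise can be added. Non-negative everywhere when
#' `noise_sd = 0`.
#'
#' @param materials A list of [material_spec].
#' @param wavenumber Strictly increasing axis (cm^-1).
#' @param noise_sd Measurement noise added to the references (cps; default
#'   0, i.e. ideal references).
#' @param seed Integer seed (only consulted when `noise_sd > 0`).
#' @return A named list of [raman_spectrum].
#' @export
make_reference_spectra <- function(materials, wavenumber, noise_sd = 0,
                                   seed = 1L) {
  check_wavenumber_axis(wavenumber)
  if (inherits(materials, "material_spec")) materials <- list(materials)
  nm <- vapply(materials, function(m) m$name, character(1))
  refs <- lapply(materials, function(m) {
    y <- material_intensity(m, wavenumber)
    raman_spectrum(wavenumber, y, name = m$name)
  })
  names(refs) <- nm
  if (noise_sd > 0) {
    refs <- with_seed(seed, lapply(refs, function(s) {
      s$intensity <- pmax(s$intensity + rnorm(length(s$intensity), 0, noise_sd), 0)
      s
    }))
  }
  refs
}

# Seeded RNG scope: all phantom randomness flows from one integer seed
# without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic label image with contiguous material regions
#'
#' Draws `n_regions` seed points and assigns every pixel to its nearest
#' seed (a Voronoi partition), giving contiguous blobs; optionally a thin
#' background stripe — the saw kerf used as an orientation mark — is cut
#' across the image (label 0). Seed sets in which any material would
#' occupy less than 1% of the pixels are redrawn.
#'
#' @param shape `c(rows, cols)`, both at least 8.
#' @param n_regions Number of materials (labels `1..n_regions`).
#' @param kerf Add the background stripe (default `TRUE`).
#' @param seed Integer seed.
#' @return Integer `rows x cols` matrix of labels in `0..n_regions`.
#' @export
make_label_image <- function(shape, n_regions, kerf = TRUE, seed = 1L) {
  rows <- shape[1]; cols <- shape[2]
  if (rows < 8 || cols < 8) abort("`shape` must be at least 8 x 8.")
  # each blob needs room for a contiguous region covering >= 1% of pixels
  if (n_regions < 1 || n_regions > min(100, rows * cols / 8)) {
    abort("`n_regions` exceeds the pixel budget (each material needs >= 1% of pixels).")
  }
  px <- pixel_grid(rows, cols)
  with_seed(seed, {
    for (attempt in 1:100) {
      sr <- runif(n_regions, 1, rows)
      sc <- runif(n_regions, 1, cols)
      d2 <- outer(px$row, sr, `-`)^2 + outer(px$col, sc, `-`)^2
      lab <- max.col(-d2, ties.method = "first")
      if (kerf) {
        theta <- runif(1, 0, pi)
        # stripe through a random interior point, ~2 px wide
        pr <- runif(1, rows * 0.3, rows * 0.7)
        pc <- runif(1, cols * 0.3, cols * 0.7)
        # ~3 px wide (a 150 um kerf at 50 um step) so its core survives
        # 3x3 partial-volume mixing
        dline <- abs(cos(theta) * (px$row - pr) + sin(theta) * (px$col - pc))
        lab[dline <= 1.5] <- 0L
      }
      counts <- tabulate(lab, nbins = n_regions)
      if (all(counts >= ceiling(0.01 * rows * cols))) {
        return(unflatten_image(as.integer(lab), rows, cols))
      }
    }
    abort("Could not place regions with >= 1% coverage each; enlarge the grid.")
  })
}

# 3x3 label-fraction smoothing: per pixel, the fraction of each label among
# itself and its neighbors. Creates partial-volume mixing at region borders.
label_fractions <- function(labels, n_materials) {
  rows <- nrow(labels); cols <- ncol(labels)
  w <- matrix(0, rows * cols, n_materials + 1L)  # col 1 = background
  for (dr in -1:1) for (dc in -1:1) {
    rr <- pmin(pmax(seq_len(rows) + dr, 1), rows)
    cc <- pmin(pmax(seq_len(cols) + dc, 1), cols)
    neigh <- labels[rr, cc, drop = FALSE]
    idx <- cbind(seq_len(rows * cols), flatten_image(neigh) + 1L)
    w[idx] <- w[idx] + 1
  }
  w / rowSums(w)
}

#' Synthesize the hyperspectral Raman map of a phantom
#'
#' Each pixel spectrum is the reference spectrum of its material — mixed
#' with neighboring materials at region borders through 3x3 label-fraction
#' smoothing — plus a smooth low-order polynomial fluorescence baseline
#' scaled by `baseline_amp`, plus i.i.d. Gaussian noise. A random subset of
#' pixels (fraction `faulty_fraction`) is replaced by noise-only spectra,
#' emulating arbitrarily distributed faulty measurements with poor SNR.
#'
#' @param truth A [phantom_truth].
#' @param refs Named list of [raman_spectrum] on one axis, containing one
#'   entry per material of `truth`.
#' @param baseline_amp Baseline scale in cps (0 disables).
#' @param noise_sd Noise standard deviation in cps (0 disables).
#' @param faulty_fraction Proportion of faulty pixels, in `[0, 0.2)`.
#' @param seed Integer seed.
#' @param border_mix Mix neighboring materials at borders (default `TRUE`);
#'   `FALSE` gives the idealized phantom whose interior and border pixels
#'   all equal their reference exactly in the noiseless limit.
#' @param step_um Grid step recorded in the map (default 50).
#' @return A list with elements `map` (a [raman_map]) and `truth` (the
#'   input truth with `faulty_mask` recorded).
#' @export
synthesize_map <- function(truth, refs, baseline_amp = 100, noise_sd = 8,
                           faulty_fraction = 0.01, seed = 1L,
                           border_mix = TRUE, step_um = 50) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (faulty_fraction < 0 || faulty_fraction >= 0.2) {
    abort("`faulty_fraction` must be in [0, 0.2).")
  }
  nm <- vapply(truth$materials, function(m) m$name, character(1))
  if (!all(nm %in% names(refs))) {
    abort("`refs` must contain one spectrum per phantom material.")
  }
  wn <- refs[[1]]$wavenumber
  for (r in refs) {
    if (!identical(r$wavenumber, wn)) abort("All references must share one axis.")
  }
  rows <- nrow(truth$labels); cols <- ncol(truth$labels)
  n_pix <- rows * cols
  n_wn <- length(wn)
  # reference matrix indexed by label + 1 (background row = zeros)
  R <- rbind(rep(0, n_wn),
             t(vapply(nm, function(x) refs[[x]]$intensity, numeric(n_wn))))
  if (border_mix) {
    W <- label_fractions(truth$labels, length(truth$materials))
    S <- W %*% R
  } else {
    S <- R[flatten_image(truth$labels) + 1L, , drop = FALSE]
  }
  faulty <- rep(FALSE, n_pix)
  with_seed(seed, {
    if (baseline_amp > 0) {
      t01 <- (wn - wn[n_wn] * 0) # placeholder
      t01 <- (wn - wn[1]) / (wn[n_wn] - wn[1])
      basis <- cbind(1, 1 - t01, (1 - t01)^2)
      coefs <- matrix(runif(n_pix * 3, 0.2, 1), n_pix, 3)
      S <- S + baseline_amp * (coefs %*% t(basis))
    }
    if (faulty_fraction > 0) {
      faulty <- runif(n_pix) < faulty_fraction
      S[faulty, ] <- 0
    }
    if (noise_sd > 0) {
      S <- S + matrix(rnorm(n_pix * n_wn, 0, noise_sd), n_pix, n_wn)
    }
  })
  truth$faulty_mask <- unflatten_image(faulty, rows, cols)
  list(
    map = raman_map(S, rows, cols, wn, step_um = step_um),
    truth = truth
  )
}

#' Synthesize the co-registered micro-CT slice of a phantom
#'
#' Per-pixel gray values are drawn from the material's Gaussian mixture on
#' the 8-bit (0--255) scale, rounded, then scaled by 257 to 16 bit and
#' clipped to `[0, 65535]` — so the 16-to-8-bit mapping round-trips
#' exactly. Materials may share overlapping modes, in which case gray value
#' alone cannot separate them.
#'
#' @param truth A [phantom_truth].
#' @param seed Integer seed.
#' @return A [density_image] with `bit_depth = 16`.
#' @export
synthesize_ct <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  lab <- flatten_image(truth$labels)
  gray <- numeric(length(lab))
  specs <- c(list(truth$background), truth$materials)
  with_seed(seed, {
    for (li in seq_along(specs)) {
      sel <- which(lab == li - 1L)
      if (!length(sel)) next
      modes <- specs[[li]]$ct_gray_modes
      comp <- sample(nrow(modes), length(sel), replace = TRUE,
                     prob = modes$weight)
      gray[sel] <- rnorm(length(sel), modes$mean[comp], modes$sd[comp])
    }
  })
  g8 <- pmin(pmax(round_half_up(gray), 0), 255)
  density_image(unflatten_image(as.integer(g8 * 257L), nrow(truth$labels),
                                ncol(truth$labels)),
                bit_depth = 16)
}

#' Simulate a complete co-registered phantom
#'
#' One call generating the full synthetic study: ground-truth label image
#' (with saw kerf), reference spectra, hyperspectral Raman map and
#' co-registered 16-bit CT slice. Defaults emulate a 60 x 80 pixel map at
#' 50 um step over 50--3300 cm^-1 (4 cm^-1 spacing), four materials plus
#' kerf, band SNR near 50 at 961 cm^-1 (noise_sd 8 against a 400 cps
#' peak), a 100 cps fluorescence baseline and 1% faulty pixels.
#'
#' @param shape `c(rows, cols)` (default `c(60, 80)`).
#' @param materials Named list of [material_spec] including a `background`
#'   entry (default [bone_graft_materials()]).
#' @param wavenumber Axis (default `seq(50, 3300, by = 4)`).
#' @param baseline_amp,noise_sd,faulty_fraction,border_mix Passed to
#'   [synthesize_map()].
#' @param kerf Passed to [make_label_image()].
#' @param extra_reference_materials Additional [material_spec]s whose
#'   reference spectra are produced without placing them in the phantom
#'   (default: the collagen membrane).
#' @param seed Integer seed driving all randomness.
#' @return A list with elements `map`, `ct`, `truth` and `refs`.
#' @export
simulate_phantom <- function(shape = c(60, 80),
                             materials = bone_graft_materials(),
                             wavenumber = seq(50, 3300, by = 4),
                             baseline_amp = 100, noise_sd = 8,
                             faulty_fraction = 0.01, kerf = TRUE,
                             border_mix = TRUE,
                             extra_reference_materials = list(collagen_membrane_material()),
                             seed = 1L) {
  if (!"background" %in% names(materials)) {
    abort("`materials` must include a 'background' entry.")
  }
  placed <- materials[setdiff(names(materials), "background")]
  labels <- make_label_image(shape, length(placed), kerf = kerf, seed = seed)
  truth <- phantom_truth(labels, placed, materials$background, seed = seed)
  refs <- make_reference_spectra(c(unname(placed), extra_reference_materials),
                                 wavenumber)
  sm <- synthesize_map(truth, refs, baseline_amp = baseline_amp,
                       noise_sd = noise_sd, faulty_fraction = faulty_fraction,
                       seed = seed + 1L, border_mix = border_mix)
  ct <- synthesize_ct(sm$truth, seed = seed + 2L)
  list(map = sm$map, ct = ct, truth = sm$truth, refs = refs)
}
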