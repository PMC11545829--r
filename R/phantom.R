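#' Synthetic chest phantom specification
#'
#' Describes a seeded synthetic CT slice: two lung-field ellipses embedded in
#' a soft-tissue body on an air background, vessel-like bright line segments
#' inside the lungs, and quasi-spherical nodules with ground-truth masks.
#' The default intensity palette follows real CT contrast ordering: air
#' -1000 HU, lung parenchyma -850 HU, vessels -100 HU, soft tissue +40 HU,
#' nodules around +30 HU.
#'
#' @param shape image dims `c(ny, nx)` in pixels.
#' @param spacing_mm pixel spacing (y, x) in mm.
#' @param lung_ellipses list of lungs, each `list(center = c(y, x) px,
#'   axes = c(ry, rx) px, intensity = HU)`.  Default: two lungs filling the
#'   grid.
#' @param vessels `list(count =, width_px =, intensity =)` vessel segments
#'   drawn inside the lungs.
#' @param nodules list of nodules, each `list(center = c(y, x) px,
#'   diameter_mm =, intensity = HU, solid = TRUE)`.  Diameters must lie in
#'   (0, 30] mm (pulmonary nodules are lesions of diameter <= 3 cm) and
#'   centers inside a lung ellipse.
#' @param background_hu air background intensity.
#' @param body_hu soft-tissue body intensity.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256, 256), spacing_mm = c(1, 1),
                         lung_ellipses = NULL,
                         vessels = list(count = 6, width_px = 2, intensity = .HU_VESSEL),
                         nodules = list(),
                         background_hu = .HU_AIR, body_hu = .HU_TISSUE) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 16))
    .stop_typed("lungscreen_parameter_error", "shape must be two dims >= 16")
  if (is.null(lung_ellipses)) {
    cy <- shape[1] / 2
    lung_ellipses <- list(
      list(center = c(cy, shape[2] * 0.30), axes = c(shape[1] * 0.32, shape[2] * 0.17),
           intensity = .HU_LUNG),
      list(center = c(cy, shape[2] * 0.70), axes = c(shape[1] * 0.32, shape[2] * 0.17),
           intensity = .HU_LUNG))
  }
  spec <- structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                         lung_ellipses = lung_ellipses, vessels = vessels,
                         nodules = nodules, background_hu = background_hu,
                         body_hu = body_hu),
                    class = "phantom_spec")
  for (nd in nodules) {
    d <- nd$diameter_mm
    if (!is.numeric(d) || d <= 0 || d > 30)
      .stop_typed("lungscreen_spec_error", "nodule diameter must be in (0, 30] mm, got %s", d)
    if (!.inside_lung(nd$center, lung_ellipses))
      .stop_typed("lungscreen_spec_error", "nodule center (%.1f, %.1f) lies outside every lung ellipse",
                  nd$center[1], nd$center[2])
  }
  spec
}

.inside_lung <- function(center, lungs, shrink = 1) {
  any(vapply(lungs, function(l) {
    sum(((center - l$center) / (l$axes * shrink))^2) <= 1
  }, TRUE))
}

.ellipse_mask <- function(shape, center, axes) {
  y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  x <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((y - center[1]) / axes[1])^2 + ((x - center[2]) / axes[2])^2 <= 1
}

#' Noise model for phantom corruption
#'
#' @param gaussian_sigma additive Gaussian noise standard deviation (HU).
#' @param speckle_sigma multiplicative speckle standard deviation (unitless,
#'   applied as `x * (1 + N(0, sigma))` on the positive-shifted intensity).
#' @param salt_pepper_fraction fraction of pixels replaced by the image min
#'   or max, at most 0.2.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sigma = 0, speckle_sigma = 0,
                        salt_pepper_fraction = 0) {
  if (gaussian_sigma < 0 || speckle_sigma < 0 || salt_pepper_fraction < 0)
    .stop_typed("lungscreen_parameter_error", "noise parameters must be non-negative")
  if (salt_pepper_fraction > 0.2)
    .stop_typed("lungscreen_parameter_error", "salt_pepper_fraction must be <= 0.2")
  structure(list(gaussian_sigma = gaussian_sigma, speckle_sigma = speckle_sigma,
                 salt_pepper_fraction = salt_pepper_fraction),
            class = "noise_model")
}

#' Generate one phantom slice with ground truth
#'
#' Deterministic given `(spec, seed)`.  Vessels are random line segments
#' confined to the lung interiors; nodules are rasterized discs of the
#' requested physical diameter.
#'
#' @param spec a [phantom_spec].
#' @param seed integer RNG seed.
#' @return list with `clean` (a [ct_image] in HU), `nodule_truth` and
#'   `lung_truth` (binary matrices).
#' @export
generate_slice <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sh <- spec$shape
  img <- matrix(spec$background_hu, sh[1], sh[2])
  # soft-tissue body: ellipse bounding the lungs with margin
  ctrs <- vapply(spec$lung_ellipses, function(l) l$center, c(0, 0))
  axs <- vapply(spec$lung_ellipses, function(l) l$axes, c(0, 0))
  body_c <- rowMeans(ctrs)
  body_a <- c(max(abs(ctrs[1, ] - body_c[1]) + axs[1, ]) + 0.06 * sh[1],
              max(abs(ctrs[2, ] - body_c[2]) + axs[2, ]) + 0.06 * sh[2])
  img[.ellipse_mask(sh, body_c, body_a)] <- spec$body_hu
  lung_truth <- matrix(FALSE, sh[1], sh[2])
  for (l in spec$lung_ellipses) {
    m <- .ellipse_mask(sh, l$center, l$axes)
    img[m] <- l$intensity
    lung_truth <- lung_truth | m
  }
  # vessels: short bright segments starting inside a lung
  v <- spec$vessels
  if (!is.null(v) && v$count > 0) {
    for (i in seq_len(v$count)) {
      l <- spec$lung_ellipses[[sample.int(length(spec$lung_ellipses), 1)]]
      t0 <- runif(2, -0.6, 0.6)
      p0 <- l$center + t0 * l$axes
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 0.2, 0.7) * min(l$axes)
      npts <- max(2L, ceiling(len))
      ts <- seq(0, len, length.out = npts)
      ys <- round(p0[1] + ts * sin(ang)); xs <- round(p0[2] + ts * cos(ang))
      hw <- max(0L, floor(v$width_px / 2))
      for (dy in -hw:hw) for (dx in -hw:hw) {
        yy <- ys + dy; xx <- xs + dx
        ok <- yy >= 1 & yy <= sh[1] & xx >= 1 & xx <= sh[2]
        idx <- cbind(yy[ok], xx[ok])
        inl <- lung_truth[idx]
        if (any(inl)) img[idx[inl, , drop = FALSE]] <- v$intensity
      }
    }
  }
  nodule_truth <- matrix(FALSE, sh[1], sh[2])
  for (nd in spec$nodules) {
    r_px <- (nd$diameter_mm / 2) / mean(spec$spacing_mm)
    y <- matrix(seq_len(sh[1]), sh[1], sh[2])
    x <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
    m <- ((y - nd$center[1]) * spec$spacing_mm[1])^2 +
         ((x - nd$center[2]) * spec$spacing_mm[2])^2 <=
         (r_px * mean(spec$spacing_mm))^2
    inten <- nd$intensity %||% 30
    img[m] <- inten
    nodule_truth <- nodule_truth | m
  }
  list(clean = ct_image(img, spacing_mm = spec$spacing_mm, is_hu = TRUE),
       nodule_truth = nodule_truth * 1L,
       lung_truth = lung_truth * 1L)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Corrupt an image with the phantom noise model
#'
#' Applies, in order: additive Gaussian noise, multiplicative speckle (on the
#' intensity shifted to a positive scale so speckle amplitude tracks tissue
#' brightness), then salt-and-pepper replacement with the image min/max.
#' Deterministic given `seed`.
#'
#' @param img a [ct_image] or numeric array.
#' @param nm a [noise_model].
#' @param seed integer RNG seed.
#' @return object of the same type as `img` with noisy pixels.
#' @export
corrupt <- function(img, nm, seed = 1) {
  stopifnot(inherits(nm, "noise_model"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  px <- .as_pixels(img)
  n <- length(px)
  if (nm$gaussian_sigma > 0) px <- px + rnorm(n, 0, nm$gaussian_sigma)
  if (nm$speckle_sigma > 0) {
    shift <- min(px)
    px <- (px - shift) * (1 + rnorm(n, 0, nm$speckle_sigma)) + shift
  }
  if (nm$salt_pepper_fraction > 0) {
    k <- round(nm$salt_pepper_fraction * n)
    if (k > 0) {
      idx <- sample.int(n, k)
      salt <- runif(k) < 0.5
      lo <- min(px); hi <- max(px)
      px[idx] <- ifelse(salt, hi, lo)
    }
  }
  if (inherits(img, "ct_image")) { img$pixels <- px; img } else px
}

#' Generate a synthetic screening cohort with known risk structure
#'
#' Draws patient covariates from documented distributions — age uniform on
#' 55..74 years, smoking intensity log-normal (median 20 cigarettes/day,
#' log-sd 0.4) for ever-smokers, binary histories Bernoulli — and computes
#' each row's latent risk with [risk_probability] under `coefficients`, so
#' parameter-recovery tests close the loop against the risk module itself.
#'
#' @param n number of patients (>= 1).
#' @param coefficients a [risk_coefficients] object.
#' @param seed integer RNG seed.
#' @param threshold stratification threshold used for the latent stratum.
#' @return list with `covariates` (data frame, one row per patient including
#'   `patient_id`) and `risk` (latent probability vector) and `stratum`
#'   (latent "high"/"low" under `threshold`).
#' @export
generate_cohort <- function(n, coefficients, seed = 1, threshold = 0.0151) {
  if (n < 1) .stop_typed("lungscreen_parameter_error", "n must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  status <- sample(c("never", "former", "current"), n, replace = TRUE,
                   prob = c(0.25, 0.40, 0.35))
  ever <- status != "never"
  cov <- data.frame(
    patient_id = seq_len(n),
    age = runif(n, 55, 74),
    smoking_status = status,
    intensity = ifelse(ever, rlnorm(n, log(20), 0.4), 0),
    duration = ifelse(ever, runif(n, 10, 50), 0),
    quit_years = ifelse(status == "former", runif(n, 1, 15), 0),
    family_history_lung_cancer = runif(n) < 0.15,
    copd = runif(n) < 0.20,
    personal_cancer_history = runif(n) < 0.05,
    bmi = pmin(pmax(rnorm(n, 27, 4), 15), 50),
    education = sample.int(6, n, replace = TRUE),
    stringsAsFactors = FALSE)
  cov$is_current_smoker <- status == "current"
  cov$is_former_smoker <- status == "former"
  p <- risk_probability(cov, coefficients)
  list(covariates = cov, risk = p,
       stratum = ifelse(p >= threshold, "high", "low"))
}

#' Single-nodule phantom with the nodule fully inside a lung
#'
#' Samples a nodule center uniformly inside a lung ellipse shrunk by the
#' nodule radius, so the whole lesion is intrapulmonary (juxtapleural
#' lesions that merge with the chest wall are a documented limitation of
#' threshold-based detection and are not part of the recovery study).
#'
#' @param diameter_mm nodule diameter.
#' @param seed integer RNG seed.
#' @param shape,intensity passed through to [phantom_spec].
#' @return a [phantom_spec] with one nodule and attribute `nodule_center`.
#' @export
single_nodule_spec <- function(diameter_mm, seed = 1, shape = c(256, 256),
                               intensity = 30) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  base <- phantom_spec(shape = shape)
  r_px <- diameter_mm / 2 + 2
  l <- base$lung_ellipses[[sample.int(length(base$lung_ellipses), 1)]]
  repeat {
    u <- runif(2, -1, 1)
    if (sum(u^2) <= 1) break
  }
  center <- l$center + u * pmax(l$axes - r_px, 1)
  phantom_spec(shape = shape,
               nodules = list(list(center = center, diameter_mm = diameter_mm,
                                   intensity = intensity, solid = TRUE)))
}

#' Seeded nodule-detection recovery study
#'
#' Generates `n` single-nodule phantoms (diameters uniform in
#' `diameter_range`), corrupts each with Gaussian noise of `noise_sigma` HU,
#' runs RWICWM denoising and [detect_nodules] under the default
#' configuration, and scores a hit when a surviving candidate centroid lies
#' within one nodule radius (+2 mm rasterization slack) of the truth.
#'
#' @param n number of phantoms.
#' @param diameter_range nodule diameter range in mm.
#' @param noise_sigma additive Gaussian noise (HU).
#' @param seed integer RNG seed.
#' @param shape slice dims.
#' @return list with `sensitivity`, `fp_per_slice`, and the per-slice
#'   `results` data frame.
#' @export
run_detection_study <- function(n = 50, diameter_range = c(6, 20),
                                noise_sigma = 15, seed = 1,
                                shape = c(256, 256)) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  diameters <- runif(n, diameter_range[1], diameter_range[2])
  rows <- lapply(seq_len(n), function(i) {
    s <- seed * 1000 + i
    sp <- single_nodule_spec(diameters[i], seed = s, shape = shape)
    nd <- sp$nodules[[1]]
    sl <- generate_slice(sp, seed = s)
    noisy <- corrupt(sl$clean, noise_model(gaussian_sigma = noise_sigma),
                     seed = s + 1)
    den <- rwicwm_denoise(noisy)
    det <- detect_nodules(den, seed = s)
    cd <- det$candidates
    dist <- if (nrow(cd)) sqrt((cd$y_mm - (nd$center[1] - 1))^2 +
                               (cd$x_mm - (nd$center[2] - 1))^2) else numeric()
    hits <- dist <= diameters[i] / 2 + 2
    data.frame(slice = i, diameter_mm = diameters[i],
               hit = any(hits), n_candidates = nrow(cd),
               false_positives = nrow(cd) - sum(hits))
  })
  results <- do.call(rbind, rows)
  list(sensitivity = mean(results$hit),
       fp_per_slice = mean(results$false_positives),
       results = results)
}

#' Sample labeled image patches from phantoms for classifier experiments
#'
#' Draws `n_per_class` patches of each class from seeded phantom slices:
#' `"normal"` patches of lung parenchyma, `"nodule"` patches centered on an
#' inserted nodule.  Patches are windowed to `[0, 1]` with the lung display
#' window.
#'
#' @param n_per_class patches per class.
#' @param size patch side length in pixels.
#' @param noise_sigma additive Gaussian noise level (HU).
#' @param seed integer RNG seed.
#' @return list with `x` (array `n x size x size`) and `y` (character labels).
#' @export
phantom_patches <- function(n_per_class = 30, size = 16, noise_sigma = 15, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(0, dim = c(n, size, size))
  y <- character(n)
  nm <- noise_model(gaussian_sigma = noise_sigma)
  half <- size / 2
  for (i in seq_len(n)) {
    has_nodule <- i > n_per_class
    sh <- c(96, 96)
    ctr <- c(48 + runif(1, -4, 4), 48 + runif(1, -4, 4))
    lungs <- list(list(center = c(48, 48), axes = c(34, 30), intensity = .HU_LUNG))
    nods <- if (has_nodule)
      list(list(center = ctr, diameter_mm = runif(1, 6, 12), intensity = 30, solid = TRUE))
    else list()
    sp <- phantom_spec(shape = sh, lung_ellipses = lungs, nodules = nods,
                       vessels = list(count = 2, width_px = 1, intensity = .HU_VESSEL))
    sl <- generate_slice(sp, seed = seed * 10000 + i)
    noisy <- corrupt(sl$clean, nm, seed = seed * 10000 + i + 1)
    win <- rescale_for_display(noisy) / 255
    rows <- round(ctr[1] - half + 1):round(ctr[1] + half)
    cols <- round(ctr[2] - half + 1):round(ctr[2] + half)
    x[i, , ] <- win[rows, cols]
    y[i] <- if (has_nodule) "nodule" else "normal"
  }
  ord <- sample.int(n)
  list(x = x[ord, , , drop = FALSE], y = y[ord])
}
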