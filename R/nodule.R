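# WDSI-LSO candidate detection: sliding-window parenchyma extraction,
# Weibull-scale-factor Light Spectrum Optimizer multilevel thresholding,
# ROI labelling and shape-feature filtering.

#' Extract lung parenchyma with a sliding window
#'
#' Slides a `window x window` box with step `stride` over the image and marks
#' a window as lung when its mean intensity falls inside `hu_range` and at
#' least `min_fraction` of its pixels do individually (the coverage test
#' rejects boundary windows whose air/soft-tissue mix merely averages into
#' the band).  The union of accepted windows is cleaned up by keeping the
#' two largest 8-connected components (the two lung fields), filling each
#' component's convex hull (lung fields are convex here, and large solid
#' nodules otherwise carve unfillable bays into the window union) and
#' filling holes, so vessels and nodules inside the lung stay part of the
#' mask.
#'
#' @param img 2D [ct_image] or matrix in HU.
#' @param window window side in pixels, `window >= stride >= 1`.
#' @param stride step in pixels.
#' @param hu_range `c(low, high)` acceptance band; the default (-950, -500)
#'   HU brackets aerated lung parenchyma.
#' @param min_fraction minimum fraction of in-band pixels per accepted
#'   window.
#' @return binary lung mask matrix.
#' @export
extract_parenchyma <- function(img, window = 16, stride = 8,
                               hu_range = c(-950, -500), min_fraction = 0.6) {
  px <- .as_pixels(img)
  if (length(dim(px)) != 2)
    .stop_typed("lungscreen_format_error", "extract_parenchyma requires a 2D image")
  if (stride < 1 || window < stride)
    .stop_typed("lungscreen_parameter_error", "need window >= stride >= 1")
  nr <- nrow(px); nc <- ncol(px)
  if (window > min(nr, nc))
    .stop_typed("lungscreen_parameter_error", "window (%d) larger than image", window)
  # integral images for O(1) window sums and in-band pixel counts
  integral <- function(z) {
    S <- apply(apply(z, 2, cumsum), 1, cumsum)  # transposed cumulative sums
    rbind(0, cbind(0, t(S)))
  }
  S <- integral(px)
  B <- integral((px >= hu_range[1] & px <= hu_range[2]) * 1)
  win_sum <- function(S, y0, x0) {
    S[y0 + window, x0 + window] - S[y0, x0 + window] -
      S[y0 + window, x0] + S[y0, x0]
  }
  ys <- unique(c(seq(1, nr - window + 1, stride), nr - window + 1))
  xs <- unique(c(seq(1, nc - window + 1, stride), nc - window + 1))
  mask <- matrix(FALSE, nr, nc)
  area <- window * window
  for (y0 in ys) for (x0 in xs) {
    m <- win_sum(S, y0, x0) / area
    frac <- win_sum(B, y0, x0) / area
    if (m >= hu_range[1] && m <= hu_range[2] && frac >= min_fraction)
      mask[y0:(y0 + window - 1), x0:(x0 + window - 1)] <- TRUE
  }
  if (!any(mask)) return(mask * 1L)
  lab <- label_components(mask * 1L)
  n <- attr(lab, "n_components")
  if (n > 2) {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    keep <- order(sizes, decreasing = TRUE)[1:2]
  } else keep <- seq_len(n)
  out <- matrix(FALSE, nr, nc)
  for (id in keep) out <- out | .convex_fill(lab == id)
  filled <- EBImage::fillHull(out * 1L)
  (filled > 0) * 1L
}

# fill the convex hull of a binary component (scanline rasterization).
# Lung fields are convex, so this closes boundary bays (e.g. carved by a
# large nodule) that topological hole-filling cannot reach.
.convex_fill <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) return(mask)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  vx <- pts[h, 2]; vy <- pts[h, 1]
  nv <- length(h)
  out <- mask
  for (y in seq(min(vy), max(vy))) {
    xs <- numeric()
    for (e in seq_len(nv)) {
      y1 <- vy[e]; y2 <- vy[if (e == nv) 1 else e + 1]
      x1 <- vx[e]; x2 <- vx[if (e == nv) 1 else e + 1]
      if ((y1 <= y && y < y2) || (y2 <= y && y < y1))
        xs <- c(xs, x1 + (y - y1) * (x2 - x1) / (y2 - y1))
    }
    if (length(xs) >= 2) {
      xs <- sort(xs)
      out[y, ceiling(xs[1]):floor(xs[length(xs)])] <- TRUE
    }
  }
  out
}

#' Connected-component labelling (8-connectivity 2D, 26-connectivity 3D)
#' @param mask binary matrix or 3D array.
#' @return integer array of labels `0, 1..n` with attribute `n_components`.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  lab <- .label_components_cpp(as.integer(mask != 0), as.integer(d))
  n <- attr(lab, "n_components")
  dim(lab) <- d
  attr(lab, "n_components") <- n
  lab
}

#' Histogram of image intensities for threshold optimization
#' @param values numeric vector (or image) of intensities.
#' @param n_bins number of equal-width bins.
#' @param range optional `c(lo, hi)`; defaults to the value range.
#' @return normalized probability vector with attribute `mids` (bin centers).
#' @export
intensity_histogram <- function(values, n_bins = 256, range = NULL) {
  v <- as.numeric(.as_pixels(values))
  if (is.null(range)) range <- base::range(v)
  if (range[2] <= range[1]) range[2] <- range[1] + 1
  br <- seq(range[1], range[2], length.out = n_bins + 1)
  cnt <- tabulate(pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L),
                       n_bins), nbins = n_bins)
  p <- cnt / sum(cnt)
  attr(p, "mids") <- (br[-1] + br[-length(br)]) / 2
  p
}

.hist_values <- function(hist) {
  attr(hist, "mids") %||% (seq_along(hist) - 1)
}

#' Otsu between-class variance of a thresholded histogram
#'
#' For thresholds `t` splitting the gray levels into classes, returns
#' `sum_c w_c (mu_c - mu)^2` — the between-class variance whose maximization
#' picks the threshold most likely to separate the class probability masses.
#' Empty classes contribute zero.
#'
#' @param hist normalized histogram (probability vector summing to 1),
#'   optionally with a `mids` attribute giving bin values; bin index - 1 is
#'   used otherwise.
#' @param t numeric thresholds on the bin-value scale.
#' @return the between-class variance (>= 0).
#' @export
class_probability_objective <- function(hist, t) {
  p <- as.numeric(hist)
  if (abs(sum(p) - 1) > 1e-6)
    .stop_typed("lungscreen_parameter_error", "hist must be normalized to sum 1")
  vals <- .hist_values(hist)
  t <- sort(as.numeric(t))
  cls <- findInterval(vals, t, left.open = TRUE) + 1L  # vals <= t1 -> class 1
  mu <- sum(p * vals)
  obj <- 0
  for (c in unique(cls)) {
    w <- sum(p[cls == c])
    if (w <= 0) next
    muc <- sum(p[cls == c] * vals[cls == c]) / w
    obj <- obj + w * (muc - mu)^2
  }
  obj
}

#' Weibull-distributed scale factor draws
#'
#' Inverse-transform sampling `lambda * (-log U)^(1/k)`; with `k = 1` this is
#' the exponential distribution with mean `lambda`.  These draws multiply
#' every stochastic step size of [lso_optimize].
#'
#' @param n number of draws.
#' @param shape Weibull shape `k > 0`.
#' @param scale Weibull scale `lambda > 0`.
#' @param u optional uniforms in (0, 1) to force (for testing closed forms).
#' @return positive numeric vector of length `n`.
#' @export
weibull_scale <- function(n = 1, shape = 1.5, scale = 1, u = NULL) {
  if (shape <= 0 || scale <= 0)
    .stop_typed("lungscreen_parameter_error", "Weibull shape and scale must be > 0")
  if (is.null(u)) u <- runif(n)
  scale * (-log(u))^(1 / shape)
}

#' Multilevel thresholding by a Weibull-scaled Light Spectrum Optimizer
#'
#' Evolves a population of threshold vectors with three light-spectrum-style
#' operators — refraction toward the best-known solution, dispersion around
#' the population mean, and reflection (random restart) — with every
#' stochastic step size multiplied by a fresh [weibull_scale] draw.
#' Selection is greedy per individual and the best-ever solution is retained
#' (elitism), so the best-objective trace is non-decreasing.  The objective
#' is [class_probability_objective].
#'
#' @param hist normalized histogram (see [intensity_histogram]).
#' @param n_thresholds number of thresholds (>= 1, fewer than the number of
#'   occupied bins).
#' @param pop_size population size (>= 4).
#' @param n_iters iterations.
#' @param weibull_shape,weibull_scale_par Weibull step-size parameters.
#' @param seed integer RNG seed.
#' @return an object of class `threshold_set`: `levels` (strictly increasing,
#'   on the histogram's bin-value scale), `objective_value`, `trace`
#'   (best objective per iteration), and the population.
#' @export
lso_optimize <- function(hist, n_thresholds = 2, pop_size = 20, n_iters = 100,
                         weibull_shape = 1.5, weibull_scale_par = 1, seed = 1) {
  p <- as.numeric(hist)
  occupied <- sum(p > 0)
  if (n_thresholds < 1)
    .stop_typed("lungscreen_parameter_error", "n_thresholds must be >= 1")
  if (pop_size < 4)
    .stop_typed("lungscreen_parameter_error", "pop_size must be >= 4")
  if (n_thresholds >= occupied)
    .stop_typed("lungscreen_parameter_error",
                "n_thresholds (%d) must be below the %d occupied bins",
                n_thresholds, occupied)
  vals <- .hist_values(hist)
  lo <- min(vals[p > 0]); hi <- max(vals[p > 0])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- n_thresholds
  fix <- function(x) sort(pmin(pmax(x, lo), hi))
  pop <- lapply(seq_len(pop_size), function(i) fix(runif(d, lo, hi)))
  f <- vapply(pop, function(x) class_probability_objective(hist, x), 0)
  best_i <- which.max(f)
  best <- pop[[best_i]]; best_f <- f[best_i]
  trace <- numeric(n_iters)
  for (it in seq_len(n_iters)) {
    pmean <- Reduce(`+`, pop) / pop_size
    psd <- sqrt(Reduce(`+`, lapply(pop, function(x) (x - pmean)^2)) / pop_size)
    for (i in seq_len(pop_size)) {
      x <- pop[[i]]
      w <- weibull_scale(d, weibull_shape, weibull_scale_par)
      r <- runif(1)
      cand <- if (r < 0.5) {            # refraction toward the incumbent best
        x + w * runif(d) * (best - x)
      } else if (r < 0.8) {             # dispersion around the population mean
        pmean + w * rnorm(d) * pmax(psd, 1e-3 * (hi - lo))
      } else {                          # reflection: random restart
        runif(d, lo, hi) * w / max(w)
      }
      cand <- fix(cand)
      fc <- class_probability_objective(hist, cand)
      if (fc >= f[i]) { pop[[i]] <- cand; f[i] <- fc }
      if (fc > best_f) { best <- cand; best_f <- fc }
    }
    trace[it] <- best_f
  }
  structure(list(levels = best, objective_value = best_f, trace = trace,
                 population = pop, weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale_par, seed = seed),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> levels [%s], objective %.4f\n",
              paste(format(x$levels, digits = 5), collapse = ", "),
              x$objective_value))
  invisible(x)
}

#' Label regions of interest above the detection threshold
#'
#' Pixels are partitioned into the multilevel intensity classes induced by
#' the thresholds; every class above the lowest threshold is
#' connected-component labelled (8-connectivity in 2D, 26 in 3D) separately,
#' so structures of different intensity (vessels vs nodules vs soft tissue)
#' stay distinct regions.  Only regions intersecting the lung mask are kept
#' — the mask conceals everything else — but each region keeps its full
#' extent so that the overlap feature of [measure_candidates] can penalize
#' regions hanging outside the lung.
#'
#' @param img [ct_image] or array on the same intensity scale as `t`.
#' @param t a `threshold_set` or numeric thresholds.
#' @param lung binary lung mask of the same shape.
#' @param open_radius optional morphological opening radius (px) applied to
#'   every class mask before labelling (2D only); detaches and removes
#'   vessel-width structures while leaving nodule-sized blobs intact.  0
#'   disables.
#' @return integer label array (consecutive labels) with attribute
#'   `n_components`.
#' @export
extract_rois <- function(img, t, lung, open_radius = 0) {
  px <- .as_pixels(img)
  levels <- if (inherits(t, "threshold_set")) t$levels else sort(as.numeric(t))
  lung <- .as_pixels(lung)
  if (!all(dim(px) == dim(lung)))
    .stop_typed("lungscreen_parameter_error", "image and lung mask shapes differ")
  out <- array(0L, dim = dim(px))
  if (sum(lung != 0) == 0) {
    warning("empty lung mask: no regions of interest")
    attr(out, "n_components") <- 0L
    return(out)
  }
  cls <- array(findInterval(px, levels, left.open = TRUE) + 1L, dim = dim(px))
  nxt <- 0L
  brush <- if (open_radius > 0 && length(dim(px)) == 2)
    EBImage::makeBrush(2 * open_radius + 1, "disc") else NULL
  for (c in 2L:(length(levels) + 1L)) {
    m <- (cls == c) * 1L
    if (!is.null(brush)) m <- EBImage::opening(m, brush)
    lab <- label_components(m)
    n <- attr(lab, "n_components")
    if (n == 0) next
    touches <- unique(lab[lab > 0 & lung != 0])
    for (id in touches) {
      nxt <- nxt + 1L
      out[lab == id] <- nxt
    }
  }
  attr(out, "n_components") <- nxt
  out
}

#' Measure nodule-candidate features of labelled regions
#'
#' For every labelled region: physical centroid (mm, 0-based index times
#' spacing), area (largest axial cross-section for volumes), volume (0 for
#' 2D), elongation (major/minor axis ratio from second moments, with the
#' pixel-extent term `s^2/12` added so a single pixel has elongation 1),
#' overlap (fraction of the region inside the lung mask), mean intensity,
#' solidity flag (`mean_intensity >= solid_hu`), and a compactness score
#' `overlap / elongation` used for ranking.
#'
#' @param labels integer label array from [extract_rois].
#' @param img intensity image (HU) of the same shape.
#' @param lung binary lung mask.
#' @param spacing_mm per-axis spacing in mm, ordered y, x and (for volumes) z.
#' @param solid_hu solidity threshold on mean intensity (default -300 HU).
#' @return data frame of candidates, one row per region.
#' @export
measure_candidates <- function(labels, img, lung, spacing_mm = NULL,
                               solid_hu = -300) {
  px <- .as_pixels(img)
  if (is.null(spacing_mm))
    spacing_mm <- if (inherits(img, "ct_image")) img$spacing_mm else rep(1, length(dim(px)))
  lung <- .as_pixels(lung)
  nd <- length(dim(labels))
  n <- attr(labels, "n_components") %||% max(labels)
  rows <- vector("list", n)
  for (id in seq_len(n)) {
    idx <- which(labels == id)
    ai <- arrayInd(idx, dim(labels))
    npix <- length(idx)
    # physical coordinates, 0-based
    phys <- sweep(ai - 1, 2, spacing_mm[seq_len(nd)], `*`)
    ctr <- colMeans(phys)
    cov <- if (npix > 1) stats::cov(phys) * (npix - 1) / npix else
      matrix(0, nd, nd)
    diag(cov) <- diag(cov) + spacing_mm[seq_len(nd)]^2 / 12  # pixel extent
    ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    elong <- sqrt(max(ev[1], 0) / max(ev[nd], .Machine$double.eps))
    if (nd == 2) {
      area <- npix * spacing_mm[1] * spacing_mm[2]
      vol <- 0
      z_mm <- 0
    } else {
      slice_counts <- tabulate(ai[, 3], nbins = dim(labels)[3])
      area <- max(slice_counts) * spacing_mm[1] * spacing_mm[2]
      vol <- npix * prod(spacing_mm[1:3])
      z_mm <- ctr[3]
    }
    ol <- sum(lung[idx] != 0) / npix
    mi <- mean(px[idx])
    rows[[id]] <- data.frame(
      id = id, x_mm = ctr[2], y_mm = ctr[1], z_mm = z_mm,
      area_mm2 = area, volume_mm3 = vol, elongation = elong,
      overlap = ol, mean_intensity = mi, solid = mi >= solid_hu,
      score = ol / elong)
  }
  if (n == 0) {
    return(data.frame(id = integer(), x_mm = numeric(), y_mm = numeric(),
                      z_mm = numeric(), area_mm2 = numeric(),
                      volume_mm3 = numeric(), elongation = numeric(),
                      overlap = numeric(), mean_intensity = numeric(),
                      solid = logical(), score = numeric()))
  }
  do.call(rbind, rows)
}

#' Default candidate acceptance ranges
#'
#' Area bounds are the disc areas of 3 mm and 30 mm diameters — the pulmonary
#' nodule size range — elongation at most 3 (nodules are quasi-spherical;
#' vessels are elongated), and at least half of each region inside the lung.
#'
#' @param area_range `c(min, max)` area in mm^2.
#' @param volume_range optional `c(min, max)` volume in mm^3 (3D only).
#' @param el_max maximum elongation.
#' @param ol_min minimum lung-overlap fraction.
#' @return a named list usable as `config` of [filter_candidates].
#' @export
candidate_filter_config <- function(area_range = pi * c(3 / 2, 30 / 2)^2,
                                    volume_range = NULL, el_max = 3,
                                    ol_min = 0.5) {
  list(area_range = area_range, volume_range = volume_range,
       el_max = el_max, ol_min = ol_min)
}

#' Filter nodule candidates by feature ranges
#'
#' Keeps candidates whose features fall inside every configured range and
#' returns them in stable descending-score order.
#'
#' @param cands candidate data frame from [measure_candidates].
#' @param config a [candidate_filter_config] list.
#' @return the surviving rows, ordered by `score` descending.
#' @export
filter_candidates <- function(cands, config = candidate_filter_config()) {
  if (nrow(cands) == 0) return(cands)
  keep <- cands$area_mm2 >= config$area_range[1] &
          cands$area_mm2 <= config$area_range[2] &
          cands$elongation <= config$el_max &
          cands$overlap >= config$ol_min
  if (!is.null(config$volume_range) && any(cands$volume_mm3 > 0)) {
    keep <- keep & cands$volume_mm3 >= config$volume_range[1] &
                   cands$volume_mm3 <= config$volume_range[2]
  }
  out <- cands[keep, , drop = FALSE]
  out[order(-out$score), , drop = FALSE]
}

#' Detect nodule candidates in a denoised slice
#'
#' Convenience wrapper chaining the detection stage: in-lung intensity
#' histogram, [lso_optimize] multilevel thresholding, [extract_rois],
#' [measure_candidates] and [filter_candidates].
#'
#' @param img denoised 2D [ct_image] in HU.
#' @param lung binary lung mask (computed with [extract_parenchyma] when
#'   `NULL`).
#' @param n_thresholds thresholds for the multilevel split.
#' @param seed integer RNG seed for the optimizer.
#' @param filter_config a [candidate_filter_config].
#' @param solid_hu solidity threshold (HU).
#' @param n_bins histogram bins.
#' @param open_radius opening radius passed to [extract_rois] (default 2 px,
#'   which suppresses vessel-width structures).
#' @return list with `candidates` (filtered data frame), `all_candidates`,
#'   `thresholds` (the `threshold_set`), `lung` (mask) and `labels`.
#' @export
detect_nodules <- function(img, lung = NULL, n_thresholds = 2, seed = 1,
                           filter_config = candidate_filter_config(),
                           solid_hu = -300, n_bins = 128, open_radius = 2) {
  px <- .as_pixels(img)
  if (is.null(lung)) lung <- extract_parenchyma(img)
  vals <- px[lung != 0]
  if (length(vals) == 0)
    .stop_typed("lungscreen_degenerate_error",
                "lung mask is empty; nothing to threshold (is the image in HU?)")
  hist <- intensity_histogram(vals, n_bins = n_bins)
  ts <- lso_optimize(hist, n_thresholds = n_thresholds, seed = seed)
  labels <- extract_rois(px, ts, lung, open_radius = open_radius)
  spacing <- if (inherits(img, "ct_image")) img$spacing_mm else NULL
  cands <- measure_candidates(labels, img, lung, spacing_mm = spacing,
                              solid_hu = solid_hu)
  list(candidates = filter_candidates(cands, filter_config),
       all_candidates = cands, thresholds = ts, lung = lung, labels = labels)
}
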