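# RWICWM denoising: undecimated Ricker (Mexican-hat) band decomposition,
# iterative center-weighted-median smoothing of the per-scale variance field,
# variance-gated shrinkage, exact additive reconstruction.

.gauss_kernel <- function(sigma, h) {
  if (sigma <= 0) {           # delta
    k <- matrix(0, 2 * h + 1, 2 * h + 1)
    k[h + 1, h + 1] <- 1
    return(k)
  }
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Discrete Mexican-hat (Ricker) band-pass kernel at dyadic scale j, realized
# as the difference of adjacent-scale Gaussians G_{j-1} - G_j (G_0 = delta):
# zero-sum center-surround kernels that telescope, so the scale-J Gaussian
# smooth plus all details reconstructs the image exactly.
.ricker_kernel <- function(j, h) {
  s_lo <- if (j == 1) 0 else 2^(j - 2)
  s_hi <- 2^(j - 1)
  .gauss_kernel(s_lo, h) - .gauss_kernel(s_hi, h)
}

.box_mean <- function(x, w) {
  EBImage::filter2(x, matrix(1 / (w * w), w, w), boundary = "replicate")
}

.local_variance <- function(x, w) {
  pmax(.box_mean(x^2, w) - .box_mean(x, w)^2, 0)
}

#' RWICWM filter parameters
#'
#' @param n_scales number of Ricker band-pass scales (dyadic widths), >= 1.
#' @param center_weight odd positive center replication count of the
#'   center-weighted median (CWM) smoother.
#' @param window odd CWM/variance window side, >= 3.
#' @param max_iters maximum CWM smoothing passes per scale.
#' @param tol relative-change stopping tolerance of the iteration.
#' @param shrink_mode `"variance-gated"` (Wiener-style gain `v / (v + sn^2)`)
#'   or `"soft"` (soft-threshold at `sn * sqrt(2 * log n)`).
#' @return an object of class `rwicwm_params`.
#' @export
rwicwm_params <- function(n_scales = 3, center_weight = 3, window = 5,
                          max_iters = 10, tol = 1e-3,
                          shrink_mode = c("variance-gated", "soft")) {
  shrink_mode <- match.arg(shrink_mode)
  if (n_scales < 1) .stop_typed("lungscreen_parameter_error", "n_scales must be >= 1")
  if (window < 3 || window %% 2 == 0)
    .stop_typed("lungscreen_parameter_error", "window must be an odd integer >= 3")
  if (center_weight < 1 || center_weight %% 2 == 0)
    .stop_typed("lungscreen_parameter_error", "center_weight must be an odd positive integer")
  if (max_iters < 1 || tol <= 0)
    .stop_typed("lungscreen_parameter_error", "max_iters >= 1 and tol > 0 required")
  structure(list(n_scales = n_scales, center_weight = center_weight,
                 window = window, max_iters = max_iters, tol = tol,
                 shrink_mode = shrink_mode), class = "rwicwm_params")
}

#' Undecimated Ricker wavelet decomposition
#'
#' A-trous band-pass decomposition with discrete Mexican-hat (Ricker)
#' kernels: detail band j is the image convolved with the zero-sum
#' center-surround kernel `G_{j-1} - G_j` (Gaussians of dyadic sigma
#' `2^(j-1)`, `G_0` the delta), and the approximation is the coarsest
#' Gaussian smooth.  Every band has the image's shape and the kernels
#' telescope, so `approx + sum(details)` reconstructs the input exactly.
#'
#' @param img 2D [ct_image] or matrix.
#' @param n_scales number of scales, >= 1.
#' @return object of class `wavelet_field`: list with `details` (finest ->
#'   coarsest), `approx`, and `variance` (filled by [iterative_cwm_smooth]).
#' @export
ricker_decompose <- function(img, n_scales = 3) {
  px <- .as_pixels(img)
  if (length(dim(px)) != 2)
    .stop_typed("lungscreen_format_error", "ricker_decompose requires a 2D image")
  if (n_scales < 1) .stop_typed("lungscreen_parameter_error", "n_scales must be >= 1")
  kmax <- 2 * ceiling(4 * 2^(n_scales - 1)) + 1
  if (kmax > min(dim(px)))
    .stop_typed("lungscreen_parameter_error",
                "n_scales = %d needs a %d-px kernel exceeding the %dx%d image",
                n_scales, kmax, dim(px)[1], dim(px)[2])
  h <- ceiling(4 * 2^(n_scales - 1))
  details <- vector("list", n_scales)
  norms <- numeric(n_scales)
  for (j in seq_len(n_scales)) {
    k <- .ricker_kernel(j, h)
    norms[j] <- sqrt(sum(k^2))
    details[[j]] <- EBImage::filter2(px, k, boundary = "replicate")
  }
  approx <- EBImage::filter2(px, .gauss_kernel(2^(n_scales - 1), h),
                             boundary = "replicate")
  structure(list(details = details, approx = approx, variance = NULL,
                 kernel_norms = norms),
            class = "wavelet_field")
}

#' Reconstruct an image from a wavelet field
#' @param field a `wavelet_field`.
#' @return numeric matrix `approx + sum(details)`.
#' @export
wavelet_reconstruct <- function(field) {
  field$approx + Reduce(`+`, field$details)
}

# one CWM pass over a 2D field
.cwm_pass <- function(x, window, center_weight) {
  .cwm_filter_cpp(x, as.integer(window), as.integer(center_weight))
}

#' Iteratively smooth the wavelet coefficient variance field
#'
#' Estimates the local variance of each detail band in a `window`-sized
#' neighborhood, then smooths every variance field with a center-weighted
#' median filter until the maximum relative change drops below `tol` or
#' `max_iters` passes.  Inter-scale dependence is then applied by averaging
#' each band's smoothed variance with its parent (next-coarser) band's,
#' weight 0.5.  Detail coefficients are left untouched.
#'
#' @param field a `wavelet_field` from [ricker_decompose].
#' @param p an [rwicwm_params].
#' @return the field with `variance` filled with smoothed per-scale fields.
#' @export
iterative_cwm_smooth <- function(field, p = rwicwm_params()) {
  stopifnot(inherits(field, "wavelet_field"))
  vs <- lapply(field$details, .local_variance, w = p$window)
  vs <- lapply(vs, function(v) {
    for (it in seq_len(p$max_iters)) {
      v_new <- .cwm_pass(v, p$window, p$center_weight)
      rel <- max(abs(v_new - v)) / (max(v) + .Machine$double.eps)
      v <- v_new
      if (rel < p$tol) break
    }
    v
  })
  J <- length(vs)
  if (J > 1) for (j in seq_len(J - 1)) vs[[j]] <- 0.5 * (vs[[j]] + vs[[j + 1]])
  field$variance <- vs
  field
}

#' Ricker Wavelet Iterative Center-Weighted Median (RWICWM) denoising
#'
#' Decomposes the image into undecimated Ricker bands, smooths each band's
#' local-variance field iteratively with a center-weighted median filter,
#' shrinks every detail coefficient by the variance-gated gain
#' `v / (v + sn^2)` — `v` the smoothed local variance, `sn` a robust global
#' noise scale (median absolute deviation of the finest band / 0.6745) — and
#' reconstructs.  Large-magnitude (edge) coefficients carry large local
#' variance and pass nearly unchanged; flat-region coefficients are crushed.
#'
#' @param img 2D [ct_image] or matrix.
#' @param p an [rwicwm_params].
#' @return denoised image of the same type and shape as `img`.
#' @export
rwicwm_denoise <- function(img, p = rwicwm_params()) {
  px <- .as_pixels(img)
  field <- ricker_decompose(px, p$n_scales)
  field <- iterative_cwm_smooth(field, p)
  # robust global noise scale from the finest band, propagated to coarser
  # bands through the band kernels' L2 norms
  sn1 <- median(abs(field$details[[1]])) / 0.6745
  sn <- sn1 * field$kernel_norms / field$kernel_norms[1]
  out <- field$approx
  for (j in seq_along(field$details)) {
    d <- field$details[[j]]
    if (p$shrink_mode == "variance-gated") {
      v <- pmax(field$variance[[j]] - sn[j]^2, 0)   # signal part of the variance
      gain <- v / (v + sn[j]^2)
      out <- out + gain * d
    } else {
      thr <- sn[j] * sqrt(2 * log(length(d)))
      out <- out + sign(d) * pmax(abs(d) - thr, 0)
    }
  }
  if (inherits(img, "ct_image")) { img$pixels <- out; img } else out
}

#' Seeded denoising-gain study on phantom slices
#'
#' For each noise level, corrupts a default phantom slice with additive
#' Gaussian noise and reports display-window PSNR of the noisy and the
#' RWICWM-denoised image against the clean slice.
#'
#' @param sigmas Gaussian noise levels in HU.
#' @param seed integer RNG seed.
#' @param shape slice dims.
#' @return data frame with `sigma`, `psnr_noisy_db`, `psnr_denoised_db`,
#'   `gain_db`, `ssim_noisy`, `ssim_denoised`.
#' @export
run_denoise_study <- function(sigmas = c(10, 15, 25), seed = 1,
                              shape = c(256, 256)) {
  sp <- phantom_spec(shape = shape)
  sl <- generate_slice(sp, seed = seed)
  ref <- rescale_for_display(sl$clean)
  rows <- lapply(sigmas, function(s) {
    noisy <- corrupt(sl$clean, noise_model(gaussian_sigma = s),
                     seed = seed + round(s))
    den <- rwicwm_denoise(noisy)
    rn <- rescale_for_display(noisy); rd <- rescale_for_display(den)
    data.frame(sigma = s, psnr_noisy_db = psnr(rn, ref),
               psnr_denoised_db = psnr(rd, ref),
               gain_db = psnr(rd, ref) - psnr(rn, ref),
               ssim_noisy = ssim(rn, ref), ssim_denoised = ssim(rd, ref))
  })
  do.call(rbind, rows)
}

#' Baseline denoising filters
#'
#' Standard comparators for RWICWM: a Gaussian filter, an adaptive (local
#' Wiener) filter, and a guided filter using the image itself as guidance.
#'
#' @param img 2D [ct_image] or matrix.
#' @param method one of `"gaussian"`, `"wiener"`, `"guided"`.
#' @param params method parameters: `sigma` (gaussian, default 1), `window`
#'   (wiener, default 5), `radius` and `eps` (guided, defaults 4 and
#'   `(0.02 * range)^2`).
#' @return denoised image, same type and shape as `img`.
#' @export
baseline_denoise <- function(img, method = c("gaussian", "wiener", "guided"),
                             params = list()) {
  if (!is.character(method) || !method[1] %in% c("gaussian", "wiener", "guided"))
    .stop_typed("lungscreen_parameter_error", "unknown denoise method: %s",
                paste(method[1], collapse = ""))
  method <- method[1]
  px <- .as_pixels(img)
  out <- switch(method,
    gaussian = {
      sigma <- params$sigma %||% 1
      h <- max(1L, ceiling(4 * sigma))
      g <- exp(-(seq(-h, h))^2 / (2 * max(sigma, 1e-8)^2))
      k <- outer(g, g); k <- k / sum(k)
      EBImage::filter2(px, k, boundary = "replicate")
    },
    wiener = {
      w <- params$window %||% 5
      mu <- .box_mean(px, w)
      v <- .local_variance(px, w)
      nu <- mean(v)
      mu + pmax(v - nu, 0) / pmax(v, nu) * (px - mu)
    },
    guided = {
      r <- params$radius %||% 4
      w <- 2 * r + 1
      eps <- params$eps %||% (0.02 * diff(range(px)))^2
      mu <- .box_mean(px, w)
      v <- .local_variance(px, w)
      a <- v / (v + eps)
      b <- (1 - a) * mu
      .box_mean(a, w) * px + .box_mean(b, w)
    })
  if (inherits(img, "ct_image")) { img$pixels <- out; img } else out
}

#' Histogram equalization contrast enhancement
#'
#' Classic cumulative-distribution mapping: the image is rescaled to
#' `n_bins` gray levels over its own range, and each level is remapped to
#' `round(CDF * (n_bins - 1))`.  The mapping is monotone non-decreasing; a
#' constant image is returned unchanged with a warning.
#'
#' @param img 2D [ct_image] or matrix.
#' @param n_bins number of gray levels (256 for 8-bit behaviour).
#' @return equalized image on the `0..n_bins-1` scale (a [ct_image] with
#'   `is_hu = FALSE` when the input was a `ct_image`).
#' @export
histogram_equalize <- function(img, n_bins = 256) {
  px <- .as_pixels(img)
  if (length(dim(px)) != 2)
    .stop_typed("lungscreen_format_error", "histogram_equalize requires a 2D image")
  mn <- min(px); mx <- max(px)
  if (mx == mn) {
    warning("constant image: histogram equalization is a no-op")
    return(img)
  }
  q <- round((px - mn) / (mx - mn) * (n_bins - 1))
  counts <- tabulate(q + 1L, nbins = n_bins)
  cdf <- cumsum(counts) / length(px)
  lut <- round(cdf * (n_bins - 1))
  out <- matrix(lut[q + 1L], nrow(px), ncol(px))
  if (inherits(img, "ct_image")) {
    ct_image(out, spacing_mm = img$spacing_mm, is_hu = FALSE)
  } else out
}
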