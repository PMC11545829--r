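test_that("a-trous decomposition reconstructs exactly and has zero-mean bands", {
  set.seed(11)
  img <- matrix(rnorm(96 * 96, -500, 200), 96, 96)
  f <- ricker_decompose(img, 3)
  expect_lt(max(abs(wavelet_reconstruct(f) - img)), 1e-9)
  # constant image: zero-sum kernels give (numerically) zero details
  fc <- ricker_decompose(matrix(42, 64, 64), 2)
  for (d in fc$details) expect_lt(max(abs(d)), 1e-9)
  expect_error(ricker_decompose(matrix(0, 20, 20), 4),
               class = "lungscreen_parameter_error")
})

test_that("an impulse reproduces the band kernel (direct convolution oracle)", {
  im <- matrix(0, 41, 41); im[21, 21] <- 1
  f <- ricker_decompose(im, 2)
  h <- ceiling(4 * 2)
  k1 <- lungscreen:::.ricker_kernel(1, h)
  oracle <- direct_conv(im, k1)
  expect_equal(f$details[[1]], oracle, tolerance = 1e-12)
})

test_that("center-weighted median smoothing behaves like its hand oracle", {
  # lone spike in a 1-row field is removed by one plain-median pass
  x <- matrix(c(0, 0, 9, 0, 0), 1, 5)
  expect_equal(lungscreen:::.cwm_filter_cpp(x, 3L, 1L),
               matrix(0, 1, 5))
  # center weight >= window^2 makes the filter an identity
  set.seed(12)
  v <- matrix(runif(49), 7, 7)
  expect_equal(lungscreen:::.cwm_filter_cpp(v, 3L, 9L), v)
  # constant variance field is unchanged by the full iteration
  img <- matrix(rnorm(64 * 64), 64, 64)
  f <- ricker_decompose(img, 2)
  f$details[[1]][] <- 1  # constant coefficients -> constant variance field
  sm <- iterative_cwm_smooth(ricker_decompose(matrix(3, 64, 64), 2))
  for (v2 in sm$variance) expect_lt(max(abs(v2)), 1e-9)
})

test_that("RWICWM is an identity on clean flat images and improves noisy PSNR", {
  img <- matrix(-850, 64, 64)
  out <- rwicwm_denoise(img)
  expect_lt(max(abs(out - img)), 1e-6)

  st <- run_denoise_study(sigmas = c(15), seed = 3, shape = c(128, 128))
  expect_gt(st$psnr_denoised_db, st$psnr_noisy_db)
  expect_false(any(is.na(st)))
})

test_that("RWICWM preserves edges better than a flat-matched Gaussian", {
  set.seed(21)
  clean <- cbind(matrix(-850, 128, 64), matrix(40, 128, 64))
  noisy <- clean + rnorm(length(clean), 0, 15)
  den <- rwicwm_denoise(noisy)
  flat_cols <- c(3:60, 69:126)
  edge_cols <- 63:66
  mse_flat <- function(x) mean((x[, flat_cols] - clean[, flat_cols])^2)
  mae_edge <- function(x) mean(abs(x[, edge_cols] - clean[, edge_cols]))
  # Gaussian sigma matched to equal smoothing of the flat regions
  sig <- c(0.8, 1, 1.3, 1.6, 2, 2.5)
  gm <- lapply(sig, function(s) baseline_denoise(noisy, "gaussian", list(sigma = s)))
  match_i <- which.min(abs(vapply(gm, mse_flat, 0) - mse_flat(den)))
  expect_lt(mae_edge(den), mae_edge(gm[[match_i]]))
})

test_that("baseline filters satisfy their closed-form limits", {
  set.seed(4)
  z <- matrix(runif(900), 30, 30)
  expect_equal(baseline_denoise(z, "gaussian", list(sigma = 1e-4)), z,
               tolerance = 1e-10)
  # wiener reduces the variance of pure white noise
  wn <- matrix(rnorm(128^2), 128, 128)
  expect_lt(var(as.vector(baseline_denoise(wn, "wiener", list(window = 5)))),
            var(as.vector(wn)))
  # guided filter with huge eps degenerates to the double box mean
  g <- baseline_denoise(z, "guided", list(radius = 3, eps = 1e12))
  bb <- lungscreen:::.box_mean(lungscreen:::.box_mean(z, 7), 7)
  expect_equal(g, bb, tolerance = 1e-8)
  expect_error(baseline_denoise(z, "nlm"), class = "lungscreen_parameter_error")
})

test_that("filters keep shape and produce no NaN on finite inputs", {
  set.seed(30)
  img <- matrix(runif(40 * 56, -1000, 400), 40, 56)
  for (m in c("gaussian", "wiener", "guided")) {
    out <- baseline_denoise(img, m)
    expect_equal(dim(out), dim(img))
    expect_true(all(is.finite(out)))
  }
  out <- rwicwm_denoise(img)
  expect_equal(dim(out), dim(img))
  expect_true(all(is.finite(out)))
})

test_that("histogram equalization follows the CDF mapping and flattens", {
  # two-value image: 90% at 10, 10% at 200 -> CDF * 255 = {229.5, 255}
  set.seed(2)
  img <- matrix(10, 100, 10)
  img[sample(1000, 100)] <- 200
  he <- histogram_equalize(img)
  lv <- sort(unique(as.vector(he)))
  expect_equal(lv[1], 0.9 * 255, tolerance = 1)
  expect_equal(lv[2], 255)
  # already-uniform histogram: identity within one bin
  u <- matrix(rep(0:255, length.out = 256 * 4), 256, 4)
  heu <- histogram_equalize(u)
  expect_lte(max(abs(heu - u)), 1)
  # mapping is monotone non-decreasing
  set.seed(13)
  r <- matrix(round(stats::rbeta(500, 2, 5) * 255), 25, 20)
  hr <- histogram_equalize(r)
  o <- order(as.vector(r))
  expect_true(all(diff(as.vector(hr)[o]) >= 0))
  # flatter histogram than the (already 8-bit) input: chi-square to uniform
  # over coarse bins (discrete equalization redistributes levels, it cannot
  # split them, so flatness is a coarse-grain property)
  chisq_u <- function(x) {
    p <- tabulate(findInterval(x, seq(0, 256, 16), rightmost.closed = TRUE),
                  16) / length(x)
    sum((p - 1 / 16)^2)
  }
  expect_lt(chisq_u(hr), chisq_u(r))
  expect_warning(histogram_equalize(matrix(5, 4, 4)), "constant")
})
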