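test_that("sliding-window parenchyma extraction matches its brute-force oracle", {
  air <- matrix(-1000, 64, 64)
  expect_true(all(extract_parenchyma(air, window = 8, stride = 8) == 0))
  expect_error(extract_parenchyma(air, window = 128),
               class = "lungscreen_parameter_error")
  expect_error(extract_parenchyma(air, window = 4, stride = 8),
               class = "lungscreen_parameter_error")

  # stride == window: accepted-block count equals exhaustive window evaluation
  set.seed(41)
  img <- matrix(sample(c(-1000, -850, 40), 64 * 64, TRUE, c(0.4, 0.4, 0.2)), 64, 64)
  w <- 8
  accepted <- 0
  for (y0 in seq(1, 64 - w + 1, w)) for (x0 in seq(1, 64 - w + 1, w)) {
    blk <- img[y0:(y0 + w - 1), x0:(x0 + w - 1)]
    if (mean(blk) >= -950 && mean(blk) <= -500 &&
        mean(blk >= -950 & blk <= -500) >= 0.6) accepted <- accepted + 1
  }
  # count accepted blocks in the raw union (before component cleanup) by
  # re-deriving from the mask: each accepted block is fully marked
  mask_union <- matrix(FALSE, 64, 64)
  for (y0 in seq(1, 64 - w + 1, w)) for (x0 in seq(1, 64 - w + 1, w)) {
    blk <- img[y0:(y0 + w - 1), x0:(x0 + w - 1)]
    if (mean(blk) >= -950 && mean(blk) <= -500 &&
        mean(blk >= -950 & blk <= -500) >= 0.6)
      mask_union[y0:(y0 + w - 1), x0:(x0 + w - 1)] <- TRUE
  }
  expect_equal(sum(mask_union) / w^2, accepted)
})

test_that("parenchyma mask covers the phantom lungs tightly", {
  sl <- test_slice(seed = 42)
  den <- rwicwm_denoise(sl$noisy)
  lung <- extract_parenchyma(den)
  cover <- sum(lung * sl$lung_truth) / sum(sl$lung_truth)
  spill <- sum(lung * (1 - sl$lung_truth)) / sum(1 - sl$lung_truth)
  expect_gte(cover, 0.9)
  expect_lte(spill, 0.1)
})

test_that("between-class variance objective reproduces hand Otsu values", {
  # two equal deltas at bin values 50 and 200: omega1*omega2*(mu1-mu2)^2
  p <- numeric(256); p[51] <- 0.5; p[201] <- 0.5
  h <- p; attr(h, "mids") <- 0:255
  for (t in c(60, 125, 199))
    expect_equal(class_probability_objective(h, t), 0.25 * 150^2)
  # any threshold strictly between the deltas attains the maximum
  expect_lt(class_probability_objective(h, 210), 0.25 * 150^2)
  # degenerate one-bin histogram: objective 0 everywhere
  q <- numeric(16); q[4] <- 1
  expect_equal(class_probability_objective(q, 7), 0)
  # invariance under bin refinement of the same two-delta mass
  p2 <- numeric(512); p2[101] <- 0.5; p2[401] <- 0.5
  h2 <- p2; attr(h2, "mids") <- seq(0, 255.5, by = 0.5)
  expect_equal(class_probability_objective(h2, 125), 0.25 * 150^2)
  expect_error(class_probability_objective(p * 2, 10),
               class = "lungscreen_parameter_error")
})

test_that("Weibull scale-factor draws follow the closed form", {
  expect_error(weibull_scale(1, shape = 0, scale = 1),
               class = "lungscreen_parameter_error")
  expect_equal(weibull_scale(1, shape = 2, scale = 3, u = exp(-1)), 3)
  set.seed(51)
  draws <- weibull_scale(1e5, shape = 1, scale = 2)
  expect_equal(mean(draws), 2, tolerance = 0.02)
  set.seed(7); a <- weibull_scale(10, 1.5, 1)
  set.seed(7); b <- weibull_scale(10, 1.5, 1)
  expect_identical(a, b)
})

test_that("LSO thresholding matches exhaustive search on small histograms", {
  # single threshold on a two-delta histogram: exact optimum
  p <- numeric(64); p[11] <- 0.5; p[51] <- 0.5
  h <- p; attr(h, "mids") <- 0:63
  ts <- lso_optimize(h, n_thresholds = 1, pop_size = 10, n_iters = 50, seed = 2)
  expect_equal(ts$objective_value, 0.25 * 40^2, tolerance = 1e-9)
  expect_true(all(diff(ts$trace) >= 0))

  hits <- 0
  for (s in 1:20) {
    set.seed(s + 500)
    p <- runif(64); p <- p / sum(p)
    ph <- p; attr(ph, "mids") <- 0:63
    opt <- exhaustive_otsu(p, 0:63, 2)
    got <- lso_optimize(ph, n_thresholds = 2, pop_size = 20, n_iters = 100,
                        seed = s)$objective_value
    if (got >= 0.99 * opt) hits <- hits + 1
  }
  expect_gte(hits, 18)

  expect_error(lso_optimize(h, n_thresholds = 2, pop_size = 2),
               class = "lungscreen_parameter_error")
  expect_error(lso_optimize(h, n_thresholds = 2),
               class = "lungscreen_parameter_error")  # >= occupied bins
})

test_that("ROI extraction respects the lung mask and labels consecutively", {
  img <- matrix(-850, 32, 32)
  img[5:8, 5:8] <- 40      # inside lung
  img[20:23, 25:28] <- 40  # outside lung
  lung <- matrix(0L, 32, 32); lung[2:16, 2:16] <- 1L
  lab <- extract_rois(img, c(-500), lung)
  expect_equal(attr(lab, "n_components"), 1)
  expect_true(all(lab[5:8, 5:8] == 1))
  expect_true(all(lab[20:23, 25:28] == 0))
  expect_identical(sort(unique(as.vector(lab))), c(0L, 1L))
  expect_warning(lab0 <- extract_rois(img, c(-500), matrix(0L, 32, 32)),
                 "empty lung mask")
  expect_equal(attr(lab0, "n_components"), 0)
})

test_that("candidate features match geometry oracles", {
  lab <- array(0L, c(40, 40)); lab[11:20, 11:20] <- 1L
  attr(lab, "n_components") <- 1L
  img <- matrix(-850, 40, 40); img[11:20, 11:20] <- 40
  lung <- matrix(1L, 40, 40)
  cf <- measure_candidates(lab, img, lung, spacing_mm = c(1, 1))
  expect_equal(cf$area_mm2, 100)
  expect_equal(cf$elongation, 1)
  expect_equal(cf$overlap, 1)
  expect_true(cf$solid)

  # 20 x 5 rectangle: elongation ~ 4 from second moments
  lab2 <- array(0L, c(40, 40)); lab2[11:15, 11:30] <- 1L
  attr(lab2, "n_components") <- 1L
  cf2 <- measure_candidates(lab2, img, lung)
  expect_equal(cf2$elongation, 4, tolerance = 0.1)

  # translation invariance and spacing^2 area scaling
  lab3 <- array(0L, c(40, 40)); lab3[21:25, 16:35] <- 1L
  attr(lab3, "n_components") <- 1L
  cf3 <- measure_candidates(lab3, img, lung)
  expect_equal(cf3$elongation, cf2$elongation)
  expect_equal(cf3$area_mm2, cf2$area_mm2)
  cf4 <- measure_candidates(lab2, img, lung, spacing_mm = c(2, 2))
  expect_equal(cf4$area_mm2, 4 * cf2$area_mm2)

  # single pixel: elongation defined as 1
  lab5 <- array(0L, c(10, 10)); lab5[5, 5] <- 1L
  attr(lab5, "n_components") <- 1L
  cf5 <- measure_candidates(lab5, matrix(0, 10, 10), matrix(1L, 10, 10))
  expect_equal(cf5$elongation, 1)

  # partial lung overlap
  lung6 <- matrix(0L, 40, 40); lung6[1:40, 1:20] <- 1L
  cf6 <- measure_candidates(lab2, img, lung6)
  expect_equal(cf6$overlap, 0.5)
})

test_that("candidate filtering applies every configured rule in score order", {
  expect_equal(nrow(filter_candidates(measure_candidates(
    structure(array(0L, c(4, 4)), n_components = 0L),
    matrix(0, 4, 4), matrix(1, 4, 4)))), 0)
  cands <- data.frame(
    id = 1:5,
    x_mm = 1:5, y_mm = 1:5, z_mm = 0,
    area_mm2 = c(50, 3, 900, 60, 80),
    volume_mm3 = 0,
    elongation = c(1.2, 1.0, 1.1, 3.5, 2.0),
    overlap = c(0.9, 1, 1, 1, 0.3),
    mean_intensity = 0, solid = TRUE,
    score = c(0.75, 1, 0.9, 0.29, 0.15))
  kept <- filter_candidates(cands, candidate_filter_config())
  # hand application of the rules: area in [7.07, 706.9], el <= 3, ol >= 0.5
  expect_equal(kept$id, c(1))
  cands$overlap[5] <- 0.8
  kept2 <- filter_candidates(cands, candidate_filter_config())
  expect_equal(kept2$id, c(1, 5))  # stable descending score
})

test_that("the detection stage finds a phantom nodule where it was inserted", {
  sl <- test_slice(seed = 52, diameter_mm = 10)
  den <- rwicwm_denoise(sl$noisy)
  det <- detect_nodules(den, seed = 52)
  expect_gte(nrow(det$candidates), 1)
  d <- sqrt((det$candidates$y_mm - 127)^2 + (det$candidates$x_mm - 87)^2)
  expect_lte(min(d), 5 + 2)
})
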