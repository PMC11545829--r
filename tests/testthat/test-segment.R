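test_that("Dice index forms agree with hand arithmetic and each other", {
  expect_equal(dice_sets(5, 5, 5), 1)
  expect_equal(dice_sets(3, 4, 0), 0)
  expect_equal(dice_sets(4, 6, 3), 0.6)
  expect_message(expect_equal(dice_sets(0, 0, 0), 1), "empty")
  expect_error(dice_sets(2, 2, 3), class = "lungscreen_parameter_error")

  expect_equal(dice_counts(7, 0, 0), 1)
  expect_equal(dice_counts(0, 3, 2), 0)
  expect_equal(dice_counts(2, 1, 1), 2 / 3)
  expect_error(dice_counts(0, 0, 0), class = "lungscreen_undefined_error")

  expect_equal(dice_vectors(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(dice_vectors(c(1, 0), c(0, 1)), 0)
  expect_equal(dice_vectors(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(dice_vectors(c(0, 0), c(0, 0)), class = "lungscreen_undefined_error")
  expect_error(dice_vectors(1, c(1, 2)), class = "lungscreen_parameter_error")
})

test_that("Dice operations are symmetric, bounded, and set/vector-consistent", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    a <- sample(c(0, 1), n, TRUE)
    b <- sample(c(0, 1), n, TRUE)
    if (sum(a) + sum(b) == 0) next
    dv <- dice_vectors(a, b)
    expect_equal(dv, dice_vectors(b, a))
    expect_gte(dv, 0); expect_lte(dv, 1)
    # Eq. 8 on binary vectors equals the set form
    expect_equal(dv, dice_sets(sum(a), sum(b), sum(a * b)))
    # and the confusion-count form
    tp <- sum(a * b); fp <- sum((1 - a) * b); fn <- sum(a * (1 - b))
    if (tp + fp + fn > 0) expect_equal(dv, dice_counts(tp, fp, fn))
  }
  # non-negative real vectors stay bounded
  for (i in 1:20) {
    a <- runif(8); b <- runif(8)
    expect_gte(dice_vectors(a, b), 0)
    expect_lte(dice_vectors(a, b), 1)
  }
})

test_that("Dice K-means recovers separable structure deterministically", {
  img <- cbind(matrix(0.1, 16, 8), matrix(0.9, 16, 8))
  st <- dice_kmeans(img, k = 2, patch_radius = 0, seed = 1)
  m <- foreground_mask(st, img)
  expect_true(all(m[, 9:16] == 1))
  expect_true(all(m[, 1:8] == 0))
  expect_true(all(m %in% c(0, 1)))

  st2 <- dice_kmeans(img, k = 2, patch_radius = 0, seed = 1)
  expect_identical(st$assignments, st2$assignments)

  expect_error(dice_kmeans(img, k = 1), class = "lungscreen_parameter_error")
  expect_error(dice_kmeans(matrix(0.5, 8, 8), k = 2),
               class = "lungscreen_degenerate_error")
})

test_that("K-means objective trace is non-decreasing and centroids in [0,1]", {
  set.seed(19)
  img <- matrix(runif(24 * 24), 24, 24)
  st <- dice_kmeans(img, k = 3, seed = 2)
  expect_true(all(diff(st$objective_trace) >= -1e-12))
  expect_true(all(st$centroids >= 0 & st$centroids <= 1))
  expect_true(all(st$assignments %in% 1:3))
})

test_that("tiny-image clustering agrees with the exhaustive partition oracle", {
  # brute force over all 2-partitions: centroid = mean feature, objective =
  # mean soft-Dice similarity of pixels to their centroid
  oracle_best <- function(v) {
    n <- length(v)
    best <- -Inf; best_lab <- NULL
    for (mask in 1:(2^n - 2)) {
      lab <- as.integer(intToBits(mask))[1:n] + 1L
      ob <- 0
      for (g in 1:2) {
        sel <- lab == g
        if (!any(sel)) { ob <- NA; break }
        cen <- mean(v[sel])
        ob <- ob + sum(2 * v[sel] * cen / (v[sel]^2 + cen^2))
      }
      if (!is.na(ob) && ob / n > best) { best <- ob / n; best_lab <- lab }
    }
    list(objective = best, labels = best_lab)
  }
  set.seed(23)
  for (rep in 1:5) {
    v <- c(runif(5, 0.05, 0.25), runif(5, 0.7, 0.95))[sample(10)]
    img <- matrix(v, 2, 5)
    st <- dice_kmeans(img, k = 2, patch_radius = 0, seed = rep, max_iter = 50)
    ours <- mean(vapply(seq_along(v), function(i)
      dice_vectors(v[i], st$centroids[st$assignments[i], ]), 0))
    orc <- oracle_best(v)
    expect_equal(ours, orc$objective, tolerance = 1e-6)
    same <- st$assignments == st$assignments[1]
    osame <- orc$labels == orc$labels[1]
    expect_true(all(same == osame) || all(same == !osame))
  }
})

test_that("foreground mask isolates a bright nodule on the phantom", {
  sl <- test_slice(seed = 31, diameter_mm = 12, vessels = FALSE)
  den <- rwicwm_denoise(sl$noisy)
  # cluster the calibrated in-lung intensities: non-lung pixels are set to
  # the in-lung median so the two clusters split parenchyma vs nodule
  px <- den$pixels
  px[sl$lung_truth == 0] <- median(px[sl$lung_truth == 1])
  st <- dice_kmeans(px, k = 2, seed = 5, max_iter = 25)
  fg <- foreground_mask(st, px, lung_mask = sl$lung_truth)
  fg_in_lung <- fg * sl$lung_truth
  tp <- sum(fg_in_lung * sl$nodule_truth)
  d <- dice_counts(tp, sum(fg_in_lung) - tp, sum(sl$nodule_truth) - tp)
  expect_gte(d, 0.7)
})
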