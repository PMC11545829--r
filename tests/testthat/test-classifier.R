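test_that("triplet loss follows the margin rule exactly", {
  expect_equal(triplet_loss(0.2, 0.9, 0.5), 0)
  expect_equal(triplet_loss(0.4, 0.4, 0), 0)
  expect_equal(triplet_loss(0.8, 0.3, 0.2), 0.7)
  expect_error(triplet_loss(-1, 0, 0), class = "lungscreen_parameter_error")
  # monotonicity: non-increasing in dAN, non-decreasing in dAP and m
  set.seed(71)
  for (i in 1:25) {
    dap <- runif(1, 0, 2); dan <- runif(1, 0, 2); m <- runif(1, 0, 1)
    eps <- runif(1, 0.01, 0.5)
    l <- triplet_loss(dap, dan, m)
    expect_gte(l, 0)
    expect_lte(triplet_loss(dap, dan + eps, m), l)
    expect_gte(triplet_loss(dap + eps, dan, m), l)
    expect_gte(triplet_loss(dap, dan, m + eps), l)
  }
})

test_that("augmentation pairs are seeded, weakly shifted, and cut out", {
  set.seed(72)
  img <- matrix(runif(24 * 24, 0.2, 1), 24, 24)
  a <- augment_pair(img, seed = 5)
  b <- augment_pair(img, seed = 5)
  expect_identical(a, b)
  # the weak view is a flip and/or an integer translation of at most 2 px
  found <- FALSE
  for (fl in c(FALSE, TRUE)) for (dy in -2:2) for (dx in -2:2) {
    base <- if (fl) img[, rev(seq_len(24))] else img
    ys <- pmin(pmax(seq_len(24) - dy, 1), 24)
    xs <- pmin(pmax(seq_len(24) - dx, 1), 24)
    if (isTRUE(all.equal(base[ys, xs], a$weak))) found <- TRUE
  }
  expect_true(found)
  # exactly one zeroed 8x8 block in the strong view (input is positive)
  zeros <- which(a$strong == 0, arr.ind = TRUE)
  expect_equal(nrow(zeros), 64)
  expect_equal(diff(range(zeros[, 1])), 7)
  expect_equal(diff(range(zeros[, 2])), 7)
})

test_that("embeddings are unit-norm and deterministic at inference", {
  pp <- phantom_patches(8, size = 16, seed = 3)
  cfg <- sscl_config(epochs = 2, seed = 4)
  mod <- train_sscl(pp$x, pp$y, cfg = cfg)
  z1 <- embed(pp$x, mod)
  z2 <- embed(pp$x, mod)
  expect_identical(z1, z2)
  expect_equal(unname(sqrt(rowSums(z1^2))), rep(1, nrow(z1)), tolerance = 1e-6)
  expect_error(embed(array(0, c(1, 8, 8)), mod), class = "lungscreen_shape_error")
})

test_that("pseudo-labelling accepts by prototype confidence", {
  protos <- rbind(a = c(1, 0), b = c(0, 1))
  pl <- pseudo_label(rbind(c(1, 0)), protos, confidence = 0.9)
  expect_equal(pl$labels, "a")
  expect_true(pl$accepted)
  # equidistant embedding is rejected at any confidence > 1/2
  pl2 <- pseudo_label(rbind(c(1, 1) / sqrt(2)), protos, confidence = 0.51)
  expect_false(pl2$accepted)
  expect_equal(pl2$confidence, 0.5, tolerance = 1e-9)
  # Gaussian toy: accepted labels agree with the Bayes (sign) rule
  set.seed(73)
  n <- 10000
  cls <- sample(c(-1, 1), n, TRUE)
  E <- cbind(cls + rnorm(n), rnorm(n))
  protos2 <- rbind(neg = c(-1, 0), pos = c(1, 0))
  pl3 <- pseudo_label(E, protos2, confidence = 0.7, temperature = 0.5)
  bayes <- ifelse(E[, 1] > 0, "pos", "neg")
  expect_gte(mean((pl3$labels == bayes)[pl3$accepted]), 0.98)
})

test_that("training overfits a small two-class phantom set deterministically", {
  pp <- phantom_patches(30, size = 16, seed = 5)
  cfg <- sscl_config(epochs = 30, seed = 7)
  mod <- train_sscl(pp$x, pp$y, cfg = cfg)
  expect_gte(mod$train_accuracy, 0.95)
  expect_lt(tail(mod$history, 1), mod$history[1])
  mod2 <- train_sscl(pp$x, pp$y, cfg = cfg)
  expect_identical(mod$par$W1, mod2$par$W1)
  expect_identical(mod$head_W, mod2$head_W)
  # split realized within one sample of (0.7, 0.2, 0.1) and disjoint
  n <- dim(pp$x)[1]
  sp <- mod$split
  expect_equal(length(sp$train), round(0.7 * n), tolerance = 1)
  expect_equal(length(sp$val), round(0.2 * n), tolerance = 1)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), seq_len(n))
  # class structure is reflected in the embedding space
  z <- embed(pp$x, mod)
  S <- z %*% t(z)
  same <- outer(pp$y, pp$y, "==")
  diag(same) <- NA
  expect_gt(mean(S[same & !is.na(same)]), mean(S[!same & !is.na(same)]))
  expect_error(train_sscl(pp$x, rep("one", n), cfg = cfg),
               class = "lungscreen_degenerate_error")
})

test_that("disabling the contrastive weight reduces to supervised training", {
  pp <- phantom_patches(10, size = 16, seed = 9)
  mA <- train_sscl(pp$x, pp$y, cfg = sscl_config(epochs = 1, seed = 11, alpha = 0))
  mB <- train_sscl(pp$x, pp$y, cfg = sscl_config(epochs = 1, seed = 11,
                                                 contrastive = FALSE))
  expect_equal(mA$history[1], mB$history[1], tolerance = 1e-6)
})

test_that("classification outputs proper probabilities and flags", {
  pp <- phantom_patches(30, size = 16, seed = 5)
  cfg <- sscl_config(epochs = 30, seed = 7)
  mod <- train_sscl(pp$x, pp$y, cfg = cfg)
  te <- c(mod$split$val, mod$split$test)
  pr <- classify(pp$x[te, , , drop = FALSE], mod)
  expect_equal(unname(rowSums(as.matrix(pr[, mod$classes]))), rep(1, length(te)),
               tolerance = 1e-6)
  expect_equal(pr$flag, ifelse(pr$class == "normal", "Normal", "Abnormal"))
  # held-out accuracy above chance for 2 classes
  expect_gt(mean(pr$class == pp$y[te]), 0.6)
  expect_identical(predict(mod, pp$x[te, , , drop = FALSE], type = "class"),
                   pr$class)
})

test_that("pseudo-labelled unlabeled data is consumed during training", {
  pp <- phantom_patches(16, size = 16, seed = 15)
  lab <- seq_len(16); unlab <- 17:32
  cfg <- sscl_config(epochs = 8, seed = 21, pseudo_warmup = 2, split = c(0.8, 0.1, 0.1))
  mod <- train_sscl(pp$x[lab, , ], pp$y[lab], unlabeled_x = pp$x[unlab, , ],
                    cfg = cfg)
  expect_equal(length(mod$history), 8)
  expect_true(all(is.finite(mod$history)))
  expect_s3_class(mod, "sscl_model")
})
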