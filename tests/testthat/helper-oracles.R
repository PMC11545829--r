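# Independent oracles used across the suite.  These deliberately re-derive
# quantities with plain loops / closed forms rather than calling the package
# code paths they check.

# exhaustive multilevel between-class variance optimum over all bin cut
# combinations (thresholds placed at bin values)
exhaustive_otsu <- function(p, mids, k) {
  n <- length(p)
  mu <- sum(p * mids)
  best <- -Inf
  combs <- utils::combn(n - 1, k)
  for (ci in seq_len(ncol(combs))) {
    cut <- mids[combs[, ci]]
    cls <- findInterval(mids, cut, left.open = TRUE) + 1
    ob <- 0
    for (cc in unique(cls)) {
      w <- sum(p[cls == cc])
      if (w > 0) {
        m <- sum(p[cls == cc] * mids[cls == cc]) / w
        ob <- ob + w * (m - mu)^2
      }
    }
    if (ob > best) best <- ob
  }
  best
}

# plain double-loop MSE
naive_mse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  s / (nrow(a) * ncol(a))
}

# plain loop confusion counts
naive_confusion <- function(truth, pred, positive) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == positive && pred[i] == positive) tp <- tp + 1
    else if (truth[i] != positive && pred[i] == positive) fp <- fp + 1
    else if (truth[i] == positive && pred[i] != positive) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# direct O(n^2 k^2) convolution with replicate padding (small inputs only)
direct_conv <- function(img, kern) {
  h <- (nrow(kern) - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- min(max(i + di, 1), nr); jj <- min(max(j + dj, 1), nc)
      s <- s + img[ii, jj] * kern[di + h + 1, dj + h + 1]
    }
    out[i, j] <- s
  }
  out
}

# default single-nodule test slice used by several suites
test_slice <- function(seed = 42, diameter_mm = 10, noise_sigma = 15,
                       vessels = TRUE) {
  sp <- phantom_spec(
    vessels = if (vessels) list(count = 6, width_px = 2, intensity = -100)
              else list(count = 0, width_px = 2, intensity = -100),
    nodules = list(list(center = c(128, 88), diameter_mm = diameter_mm,
                        intensity = 30, solid = TRUE)))
  sl <- generate_slice(sp, seed = seed)
  sl$noisy <- corrupt(sl$clean, noise_model(gaussian_sigma = noise_sigma),
                      seed = seed + 1)
  sl
}
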