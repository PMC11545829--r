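# Sorensen-Dice similarity and Dice-based K-means segmentation.

#' Sorensen-Dice index of two sets given their cardinalities
#'
#' `2 |X intersect Y| / (|X| + |Y|)`.  Two empty sets are defined as
#' identical (index 1), with a message.
#'
#' @param x_size,y_size set cardinalities (non-negative counts).
#' @param intersection size of the intersection, at most `min(x_size, y_size)`.
#' @return Dice index in `[0, 1]`.
#' @export
dice_sets <- function(x_size, y_size, intersection) {
  if (x_size < 0 || y_size < 0 || intersection < 0)
    .stop_typed("lungscreen_parameter_error", "set sizes must be non-negative")
  if (intersection > min(x_size, y_size))
    .stop_typed("lungscreen_parameter_error",
                "intersection (%s) exceeds min(|X|, |Y|)", intersection)
  if (x_size + y_size == 0) {
    message("both sets empty: Dice defined as 1")
    return(1)
  }
  2 * intersection / (x_size + y_size)
}

#' Sorensen-Dice index from boolean confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`.
#'
#' @param tp,fp,fn non-negative counts, not all zero.
#' @return Dice index in `[0, 1]`.
#' @export
dice_counts <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0)
    .stop_typed("lungscreen_parameter_error", "counts must be non-negative")
  if (tp + fp + fn == 0)
    .stop_typed("lungscreen_undefined_error", "Dice undefined for tp = fp = fn = 0")
  2 * tp / (2 * tp + fp + fn)
}

#' Soft Sorensen-Dice similarity of two non-negative vectors
#'
#' `2 (a . b) / (||a||^2 + ||b||^2)`; on binary vectors this equals the
#' set form [dice_sets].
#'
#' @param a,b equal-length non-negative numeric vectors, not both zero.
#' @return similarity in `[0, 1]`.
#' @export
dice_vectors <- function(a, b) {
  if (length(a) != length(b))
    .stop_typed("lungscreen_parameter_error", "vectors must have equal length")
  if (any(a < 0) || any(b < 0))
    .stop_typed("lungscreen_parameter_error", "vectors must be non-negative")
  den <- sum(a * a) + sum(b * b)
  if (den == 0)
    .stop_typed("lungscreen_undefined_error", "Dice undefined for two zero vectors")
  2 * sum(a * b) / den
}

# per-pixel neighborhood feature matrix (n_pixels x (2r+1)^2), replicate pad
.patch_features <- function(px, radius) {
  nr <- nrow(px); nc <- ncol(px)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  F <- matrix(0, nr * nc, nrow(offs))
  for (i in seq_len(nrow(offs))) {
    ys <- pmin(pmax(seq_len(nr) + offs$dy[i], 1), nr)
    xs <- pmin(pmax(seq_len(nc) + offs$dx[i], 1), nc)
    F[, i] <- px[ys, xs]
  }
  F
}

# argmax over columns with ties broken toward the lowest index
.argmax_rows <- function(S) {
  best <- rep(1L, nrow(S)); bv <- S[, 1]
  for (j in seq_len(ncol(S))[-1]) {
    hit <- S[, j] > bv
    best[hit] <- j; bv[hit] <- S[hit, j]
  }
  best
}

.dice_sim_matrix <- function(F, C, rsF = rowSums(F * F)) {
  # S[i, c] = 2 F_i . C_c / (||F_i||^2 + ||C_c||^2)
  num <- 2 * (F %*% t(C))
  den <- outer(rsF, rowSums(C * C), `+`)
  num / pmax(den, .Machine$double.eps)
}

#' K-means clustering under the Sorensen-Dice similarity
#'
#' Clusters per-pixel neighborhood intensity vectors (radius `patch_radius`,
#' values normalized to `[0, 1]`) into `k` groups, assigning each pixel to
#' the centroid of highest soft-Dice similarity ([dice_vectors]) and updating
#' centroids as assigned-feature means.  A centroid update is only accepted
#' while the mean assigned similarity does not decrease, so the objective
#' trace is non-decreasing.  Ties in assignment break toward the lowest
#' cluster index; the run is deterministic given `seed`.
#'
#' @param img 2D [ct_image] or matrix; intensities outside `[0, 1]` are
#'   min-max normalized first.
#' @param k number of clusters, >= 2 (default 2: foreground/background).
#' @param patch_radius neighborhood radius in pixels (default 1: 3x3 patch).
#' @param init `"kpp"` (k-means++-style seeding in similarity space) or
#'   `"random"`.
#' @param max_iter,tol stop when the changed-assignment fraction drops below
#'   `tol` or after `max_iter` sweeps.
#' @param seed integer RNG seed.
#' @return an object of class `cluster_state`: `k`, `centroids` (k x d),
#'   `assignments` (label matrix, 1..k), `n_iter`, `converged`,
#'   `objective_trace`.
#' @export
dice_kmeans <- function(img, k = 2, patch_radius = 1, init = c("kpp", "random"),
                        max_iter = 50, tol = 1e-3, seed = 1) {
  init <- match.arg(init)
  if (k < 2) .stop_typed("lungscreen_parameter_error", "k must be >= 2")
  px <- .as_pixels(img)
  if (length(dim(px)) != 2)
    .stop_typed("lungscreen_format_error", "dice_kmeans requires a 2D image")
  rng <- range(px)
  if (rng[1] < 0 || rng[2] > 1) {
    px <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
  }
  F <- .patch_features(px, patch_radius)
  n <- nrow(F)
  if (nrow(unique(F)) < k)
    .stop_typed("lungscreen_degenerate_error",
                "fewer than k = %d distinct neighborhood features", k)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rsF <- rowSums(F * F)
  C <- if (init == "random") {
    F[sample.int(n, k), , drop = FALSE]
  } else {
    idx <- sample.int(n, 1)
    for (j in seq_len(k - 1)) {
      S <- .dice_sim_matrix(F, F[idx, , drop = FALSE], rsF)
      d <- pmax(1 - apply(S, 1, max), 0)   # guard float overshoot of sim == 1
      d[idx] <- 0
      p <- if (sum(d) > 0) d / sum(d) else rep(1 / n, n)
      idx <- c(idx, sample.int(n, 1, prob = p))
    }
    F[idx, , drop = FALSE]
  }
  assign_step <- function(C) {
    S <- .dice_sim_matrix(F, C, rsF)
    a <- .argmax_rows(S)
    list(a = a, obj = mean(S[cbind(seq_len(n), a)]))
  }
  st <- assign_step(C)
  trace <- st$obj
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    C_new <- C
    for (j in seq_len(k)) {
      sel <- st$a == j
      if (any(sel)) C_new[j, ] <- colMeans(F[sel, , drop = FALSE])
      else C_new[j, ] <- F[which.min(apply(.dice_sim_matrix(F, C, rsF), 1, max)), ]
    }
    st_new <- assign_step(C_new)
    if (st_new$obj < st$obj) { converged <- TRUE; break }  # mean update would hurt: stop
    changed <- mean(st_new$a != st$a)
    C <- C_new
    st <- st_new
    trace <- c(trace, st$obj)
    if (changed < tol) { converged <- TRUE; break }
  }
  structure(list(k = k, centroids = C,
                 assignments = matrix(st$a, nrow(px), ncol(px)),
                 n_iter = n_iter, converged = converged,
                 objective_trace = trace, patch_radius = patch_radius),
            class = "cluster_state")
}

#' @export
print.cluster_state <- function(x, ...) {
  cat(sprintf("<cluster_state> k = %d, %d iterations (%s), objective %.4f\n",
              x$k, x$n_iter, if (x$converged) "converged" else "max_iter",
              tail(x$objective_trace, 1)))
  invisible(x)
}

#' Binary foreground mask from a cluster state
#'
#' The cluster with the highest mean image intensity (restricted to
#' `lung_mask` when given) becomes label 1; everything else 0.  In the
#' nodule pipeline the bright in-lung cluster is the nodule-region class.
#'
#' @param state a `cluster_state` from [dice_kmeans].
#' @param img the image that was clustered.
#' @param lung_mask optional binary mask restricting where cluster means are
#'   measured.
#' @return a binary matrix (`segmentation mask`) of the image's shape.
#' @export
foreground_mask <- function(state, img, lung_mask = NULL) {
  stopifnot(inherits(state, "cluster_state"))
  px <- .as_pixels(img)
  a <- state$assignments
  w <- if (!is.null(lung_mask) && sum(lung_mask) > 0) as.logical(lung_mask)
       else rep(TRUE, length(px))
  means <- vapply(seq_len(state$k), function(j) {
    sel <- (a == j) & w
    if (any(sel)) mean(px[sel]) else -Inf
  }, 0)
  (a == which.max(means)) * 1L
}
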