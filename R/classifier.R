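# SSCL-DNN: a small convolutional backbone (logistic activation, 2x2 max
# pooling, residual fully-connected layer), a projection head trained with a
# triplet contrastive loss over weak/strong augmented views, and pseudo-label
# propagation from class prototypes.  Forward and backward passes are written
# out explicitly; training is plain Adam, single-threaded and seeded.

#' Triplet contrastive loss
#'
#' `max(0, d(A,P) - d(A,N) + m)`: zero when the negative is at least the
#' margin `m` farther from the anchor than the positive.
#'
#' @param dAP anchor-positive distance(s), >= 0.
#' @param dAN anchor-negative distance(s), >= 0.
#' @param m margin, >= 0.
#' @return non-negative loss, vectorized.
#' @export
triplet_loss <- function(dAP, dAN, m) {
  if (any(dAP < 0) || any(dAN < 0) || any(m < 0))
    .stop_typed("lungscreen_parameter_error", "distances and margin must be >= 0")
  pmax(0, dAP - dAN + m)
}

#' SSCL training configuration
#'
#' @param classes ordered label set; when the training labels are not a
#'   subset, the observed labels are used instead.  The default is the
#'   3-class scheme (normal / large-cell carcinoma / squamous cell
#'   carcinoma); alternative schemes are configured here.
#' @param proj_dim projection-head dimension.
#' @param margin triplet margin.
#' @param pseudo_label_confidence acceptance confidence for pseudo-labels.
#' @param split train/validation/test fractions summing to 1.
#' @param epochs,batch,lr training schedule (Adam).
#' @param alpha,beta weights of the triplet and pseudo-label loss terms.
#' @param contrastive enable the contrastive term (FALSE is the plain
#'   supervised ablation).
#' @param pseudo_warmup epochs before pseudo-labeling starts.
#' @param temperature softmax temperature over prototype similarities.
#' @param conv_channels channels of the two convolution blocks.
#' @param normal_class label treated as Normal by [classify]; all other
#'   classes flag Abnormal.
#' @param seed integer RNG seed controlling initialization, splits,
#'   augmentation and batching.
#' @return an object of class `sscl_config`.
#' @export
sscl_config <- function(classes = c("normal", "large_cell_carcinoma",
                                    "squamous_cell_carcinoma"),
                        proj_dim = 16, margin = 0.5,
                        pseudo_label_confidence = 0.9,
                        split = c(0.7, 0.2, 0.1), epochs = 30, batch = 16,
                        lr = 0.01, alpha = 0.5, beta = 0.5,
                        contrastive = TRUE, pseudo_warmup = 5,
                        temperature = 0.1, conv_channels = c(8, 8),
                        normal_class = "normal", seed = 1) {
  if (abs(sum(split) - 1) > 1e-8 || length(split) != 3 || any(split < 0))
    .stop_typed("lungscreen_parameter_error", "split must be 3 non-negative fractions summing to 1")
  if (margin < 0) .stop_typed("lungscreen_parameter_error", "margin must be >= 0")
  structure(list(classes = classes, proj_dim = proj_dim, margin = margin,
                 pseudo_label_confidence = pseudo_label_confidence,
                 split = split, epochs = epochs, batch = batch, lr = lr,
                 alpha = alpha, beta = beta, contrastive = contrastive,
                 pseudo_warmup = pseudo_warmup, temperature = temperature,
                 conv_channels = conv_channels, normal_class = normal_class,
                 seed = seed),
            class = "sscl_config")
}

#' Weak/strong augmentation pair
#'
#' Weak view: horizontal flip with probability 1/2 plus an integer
#' translation of at most 2 px per axis (replicate padding).  Strong view:
#' the weak view additionally rotated by up to +/-15 degrees (nearest
#' neighbor), intensity-jittered by up to +/-10%, and with one 8x8 block
#' zeroed (cutout).  Deterministic given `seed`.
#'
#' @param img 2D matrix with values in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return list with `weak` and `strong` matrices of the input shape.
#' @export
augment_pair <- function(img, seed = 1) {
  px <- .as_pixels(img)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- nrow(px); w <- ncol(px)
  weak <- px
  if (runif(1) < 0.5) weak <- weak[, rev(seq_len(w))]
  dy <- sample(-2:2, 1); dx <- sample(-2:2, 1)
  ys <- pmin(pmax(seq_len(h) - dy, 1), h)
  xs <- pmin(pmax(seq_len(w) - dx, 1), w)
  weak <- weak[ys, xs]
  # strong: rotate (nearest neighbor, clamped sampling), jitter, cutout
  th <- runif(1, -15, 15) * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sy <- pmin(pmax(round(cy + cos(th) * yy - sin(th) * xx), 1), h)
  sx <- pmin(pmax(round(cx + sin(th) * yy + cos(th) * xx), 1), w)
  strong <- matrix(weak[cbind(as.vector(sy), as.vector(sx))], h, w)
  strong <- pmin(pmax(strong * runif(1, 0.9, 1.1), 0), 1)
  cs <- min(8L, h, w)
  y0 <- sample.int(h - cs + 1, 1); x0 <- sample.int(w - cs + 1, 1)
  strong[y0:(y0 + cs - 1), x0:(x0 + cs - 1)] <- 0
  list(weak = weak, strong = strong)
}

## ---- network internals -------------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

.im2col_idx <- function(h, w, cin, kh = 3, kw = 3) {
  h1 <- h - kh + 1; w1 <- w - kw + 1
  i <- rep(seq_len(h1), times = w1)
  j <- rep(seq_len(w1), each = h1)
  cols <- list()
  for (ch in seq_len(cin)) for (dx in 0:(kw - 1)) for (dy in 0:(kh - 1))
    cols[[length(cols) + 1]] <- (i + dy) + (j + dx - 1) * h + (ch - 1) * h * w
  idx <- do.call(cbind, cols)
  attr(idx, "out_dim") <- c(h1, w1)
  idx
}

# X: (n, h, w, cin) -> list(out = (n, h1, w1, cout), P = list of im2col mats)
.conv_forward <- function(X, W, b, idx) {
  n <- dim(X)[1]
  od <- attr(idx, "out_dim")
  cout <- nrow(W)
  out <- array(0, c(n, od[1], od[2], cout))
  P <- vector("list", n)
  for (m in seq_len(n)) {
    xf <- as.vector(X[m, , , ])
    Pm <- matrix(xf[idx], nrow(idx), ncol(idx))
    P[[m]] <- Pm
    out[m, , , ] <- Pm %*% t(W) + matrix(b, nrow(idx), cout, byrow = TRUE)
  }
  list(out = out, P = P)
}

.conv_backward <- function(dout, P, W, idx, in_dim) {
  n <- dim(dout)[1]
  rows <- nrow(idx); K <- ncol(idx); cout <- nrow(W)
  dW <- matrix(0, cout, K); db <- numeric(cout)
  dX <- array(0, c(n, in_dim))
  len <- prod(in_dim)
  for (m in seq_len(n)) {
    dm <- matrix(dout[m, , , ], rows, cout)
    dW <- dW + t(dm) %*% P[[m]]
    db <- db + colSums(dm)
    dP <- dm %*% W
    dxf <- numeric(len)
    for (k in seq_len(K)) dxf[idx[, k]] <- dxf[idx[, k]] + dP[, k]
    dX[m, , , ] <- array(dxf, in_dim)
  }
  list(dW = dW, db = db, dX = dX)
}

.pool_forward <- function(A) {
  d <- dim(A)
  h2 <- d[2] %/% 2; w2 <- d[3] %/% 2
  ys <- seq(1, 2 * h2, 2); xs <- seq(1, 2 * w2, 2)
  subs <- list(A[, ys, xs, , drop = FALSE], A[, ys + 1, xs, , drop = FALSE],
               A[, ys, xs + 1, , drop = FALSE], A[, ys + 1, xs + 1, , drop = FALSE])
  best <- subs[[1]]; choice <- array(1L, dim(best))
  for (t in 2:4) {
    upd <- subs[[t]] > best
    best[upd] <- subs[[t]][upd]
    choice[upd] <- t
  }
  list(out = best, choice = choice, in_dim = d[-1])
}

.pool_backward <- function(dout, pool) {
  d <- pool$in_dim
  n <- dim(dout)[1]
  h2 <- dim(dout)[2]; w2 <- dim(dout)[3]
  ys <- seq(1, 2 * h2, 2); xs <- seq(1, 2 * w2, 2)
  dA <- array(0, c(n, d))
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (t in 1:4) {
    sub <- array(0, dim(dout))
    sel <- pool$choice == t
    sub[sel] <- dout[sel]
    dA[, ys + offs[[t]][1], xs + offs[[t]][2], ] <-
      dA[, ys + offs[[t]][1], xs + offs[[t]][2], ] + sub
  }
  dA
}

.init_weights <- function(h, w, cfg) {
  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  h1 <- h - 2; w1 <- w - 2
  h1p <- h1 %/% 2; w1p <- w1 %/% 2
  h2 <- h1p - 2; w2 <- w1p - 2
  if (h2 < 2 || w2 < 2)
    .stop_typed("lungscreen_parameter_error", "patch %dx%d too small for the backbone", h, w)
  h2p <- h2 %/% 2; w2p <- w2 %/% 2
  D <- h2p * w2p * c2
  wi <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  list(W1 = wi(c1, 9), b1 = numeric(c1),
       W2 = wi(c2, 9 * c1), b2 = numeric(c2),
       Wf = wi(D, D) * 0.3, bf = numeric(D),
       Wp = wi(D, cfg$proj_dim),
       dims = list(h = h, w = w, c1 = c1, c2 = c2, D = D,
                   in1 = c(h, w, 1), in2 = c(h1p, w1p, c1)))
}

# full forward pass; X is (n, h, w) in [0, 1].  Inputs are centered to
# [-0.5, 0.5] so the logistic pre-activations start in their linear range
# (uncentered inputs saturate the first block and stall training on a
# sizeable fraction of initializations).
.net_forward <- function(X, par, head_W, head_b, cache = FALSE) {
  n <- dim(X)[1]
  dm <- par$dims
  X4 <- array(X - 0.5, c(n, dm$h, dm$w, 1))
  idx1 <- par$idx1; idx2 <- par$idx2
  cv1 <- .conv_forward(X4, par$W1, par$b1, idx1)
  a1 <- .sigmoid(cv1$out)
  p1 <- .pool_forward(a1)
  cv2 <- .conv_forward(p1$out, par$W2, par$b2, idx2)
  a2 <- .sigmoid(cv2$out)
  p2 <- .pool_forward(a2)
  f <- matrix(p2$out, n, dm$D)          # pollyr
  fp <- f %*% par$Wf + matrix(par$bf, n, dm$D, byrow = TRUE)
  sfp <- .sigmoid(fp)
  full <- sfp + f                        # fulllyr = mu(pollyr . w) + pollyr
  logits <- full %*% head_W + matrix(head_b, n, ncol(head_W), byrow = TRUE)
  zpre <- full %*% par$Wp
  r <- sqrt(pmax(rowSums(zpre^2), 1e-12))
  z <- zpre / r
  res <- list(logits = logits, z = z, full = full)
  if (cache) res$cache <- list(X4 = X4, cv1 = cv1, a1 = a1, p1 = p1,
                               cv2 = cv2, a2 = a2, p2 = p2, f = f,
                               sfp = sfp, zpre = zpre, r = r, n = n)
  res
}

# backward from dlogits (n x C) and dz (n x P); returns parameter gradients
.net_backward <- function(fwd, par, head_W, dlogits = NULL, dz = NULL) {
  ca <- fwd$cache; dm <- par$dims; n <- ca$n
  D <- dm$D
  dfull <- matrix(0, n, D)
  g <- list(W1 = 0, b1 = 0, W2 = 0, b2 = 0, Wf = 0, bf = 0, Wp = 0,
            head_W = 0, head_b = 0)
  if (!is.null(dlogits)) {
    g$head_W <- t(fwd$full) %*% dlogits
    g$head_b <- colSums(dlogits)
    dfull <- dfull + dlogits %*% t(head_W)
  }
  if (!is.null(dz)) {
    # through z = zpre / ||zpre||
    dot <- rowSums(dz * fwd$z)
    dzpre <- (dz - fwd$z * dot) / ca$r
    g$Wp <- t(fwd$full) %*% dzpre
    dfull <- dfull + dzpre %*% t(par$Wp)
  }
  dsfp <- dfull * ca$sfp * (1 - ca$sfp)
  g$Wf <- t(ca$f) %*% dsfp
  g$bf <- colSums(dsfp)
  df <- dsfp %*% t(par$Wf) + dfull       # residual path
  dp2 <- array(df, dim(ca$p2$out))
  da2 <- .pool_backward(dp2, ca$p2)
  dcv2 <- da2 * ca$a2 * (1 - ca$a2)
  bk2 <- .conv_backward(dcv2, ca$cv2$P, par$W2, par$idx2, dm$in2)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  da1p <- .pool_backward(bk2$dX, ca$p1)
  dcv1 <- da1p * ca$a1 * (1 - ca$a1)
  bk1 <- .conv_backward(dcv1, ca$cv1$P, par$W1, par$idx1, dm$in1)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  g
}

.softmax <- function(l) {
  e <- exp(l - apply(l, 1, max))
  e / rowSums(e)
}

## ---- public training / inference --------------------------------------

#' Train the semi-supervised contrastive classifier
#'
#' Optimizes, with Adam, the total loss `CE + alpha * triplet + beta *
#' pseudo-CE`: supervised cross-entropy of the classification head on weak
#' views; a triplet term over projection embeddings with strong views as
#' anchors, the same sample's weak view as positive and a different-class
#' weak view as negative; and, after a warmup, cross-entropy on unlabeled
#' samples that [pseudo_label] accepts against the class prototypes.
#' Deterministic given `cfg$seed` (single-threaded).
#'
#' @param x labeled patches, array `n x h x w` with values in `[0, 1]`.
#' @param y character labels, at least 2 classes.
#' @param unlabeled_x optional unlabeled patch array.
#' @param cfg an [sscl_config].
#' @return an object of class `sscl_model` with weights, `classes`,
#'   `history` (per-epoch loss), `split` (train/val/test indices) and
#'   training accuracy.
#' @export
train_sscl <- function(x, y, unlabeled_x = NULL, cfg = sscl_config()) {
  if (length(dim(x)) != 3)
    .stop_typed("lungscreen_format_error", "x must be an n x h x w array")
  y <- as.character(y)
  if (length(unique(y)) < 2)
    .stop_typed("lungscreen_degenerate_error", "labeled data must contain >= 2 classes")
  classes <- if (all(y %in% cfg$classes)) cfg$classes else sort(unique(y))
  classes <- classes[classes %in% y]
  C <- length(classes)
  n <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  par <- .init_weights(h, w, cfg)
  par$idx1 <- .im2col_idx(h, w, 1)
  dmi <- par$dims
  par$idx2 <- .im2col_idx(dmi$in2[1], dmi$in2[2], dmi$c1)
  head_W <- matrix(rnorm(dmi$D * C, 0, sqrt(1 / dmi$D)), dmi$D, C)
  head_b <- numeric(C)
  # train / val / test split
  perm <- sample.int(n)
  n_tr <- max(2L, round(cfg$split[1] * n))
  n_va <- round(cfg$split[2] * n)
  idx_tr <- perm[seq_len(n_tr)]
  idx_va <- if (n_va > 0) perm[n_tr + seq_len(min(n_va, n - n_tr))] else integer()
  idx_te <- setdiff(perm, c(idx_tr, idx_va))
  yi <- match(y, classes)
  param_names <- c("W1", "b1", "W2", "b2", "Wf", "bf", "Wp")
  adam <- new.env()
  for (nm in c(param_names, "head_W", "head_b")) {
    adam[[paste0("m_", nm)]] <- 0; adam[[paste0("v_", nm)]] <- 0
  }
  tstep <- 0
  apply_grads <- function(g) {
    tstep <<- tstep + 1
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    upd <- function(val, gr, nm) {
      m <- adam[[paste0("m_", nm)]] * b1 + (1 - b1) * gr
      v <- adam[[paste0("v_", nm)]] * b2 + (1 - b2) * gr^2
      adam[[paste0("m_", nm)]] <- m; adam[[paste0("v_", nm)]] <- v
      mh <- m / (1 - b1^tstep); vh <- v / (1 - b2^tstep)
      val - cfg$lr * mh / (sqrt(vh) + eps)
    }
    for (nm in param_names) par[[nm]] <<- upd(par[[nm]], g[[nm]], nm)
    head_W <<- upd(head_W, g$head_W, "head_W")
    head_b <<- upd(head_b, g$head_b, "head_b")
  }
  history <- numeric(cfg$epochs)
  n_un <- if (is.null(unlabeled_x)) 0 else dim(unlabeled_x)[1]
  for (ep in seq_len(cfg$epochs)) {
    ord <- idx_tr[sample.int(length(idx_tr))]
    ep_loss <- 0; n_terms <- 0
    for (b0 in seq(1, length(ord), cfg$batch)) {
      bidx <- ord[b0:min(b0 + cfg$batch - 1, length(ord))]
      nb <- length(bidx)
      Xw <- array(0, c(nb, h, w)); Xs <- array(0, c(nb, h, w))
      for (m in seq_len(nb)) {
        av <- augment_pair(x[bidx[m], , ], seed = sample.int(2^30, 1))
        Xw[m, , ] <- av$weak; Xs[m, , ] <- av$strong
      }
      yb <- yi[bidx]
      fw <- .net_forward(Xw, par, head_W, head_b, cache = TRUE)
      probs <- .softmax(fw$logits)
      Y <- matrix(0, nb, C); Y[cbind(seq_len(nb), yb)] <- 1
      ce <- -mean(log(pmax(probs[cbind(seq_len(nb), yb)], 1e-12)))
      dlogits <- (probs - Y) / nb
      loss <- ce
      dz_w <- NULL; g_s <- NULL
      if (cfg$contrastive && cfg$alpha > 0) {
        fs <- .net_forward(Xs, par, head_W, head_b, cache = TRUE)
        negs <- vapply(seq_len(nb), function(m) {
          pool <- which(yb != yb[m])
          if (length(pool)) pool[sample.int(length(pool), 1)] else NA_integer_
        }, 0L)
        ok <- which(!is.na(negs))
        dz_w <- matrix(0, nb, cfg$proj_dim)
        dz_s <- matrix(0, nb, cfg$proj_dim)
        tl <- 0
        for (m in ok) {
          za <- fs$z[m, ]; zp <- fw$z[m, ]; zn <- fw$z[negs[m], ]
          dAP <- sqrt(sum((za - zp)^2)); dAN <- sqrt(sum((za - zn)^2))
          l <- triplet_loss(dAP, dAN, cfg$margin)
          tl <- tl + l
          if (l > 0 && dAP > 1e-9 && dAN > 1e-9) {
            sc <- cfg$alpha / length(ok)
            dz_s[m, ] <- dz_s[m, ] + sc * ((za - zp) / dAP - (za - zn) / dAN)
            dz_w[m, ] <- dz_w[m, ] - sc * (za - zp) / dAP
            dz_w[negs[m], ] <- dz_w[negs[m], ] + sc * (za - zn) / dAN
          }
        }
        tl <- if (length(ok)) tl / length(ok) else 0
        loss <- loss + cfg$alpha * tl
        g_s <- .net_backward(fs, par, head_W, dlogits = NULL, dz = dz_s)
      }
      g <- .net_backward(fw, par, head_W, dlogits = dlogits, dz = dz_w)
      if (!is.null(g_s)) for (nm in names(g)) g[[nm]] <- g[[nm]] + g_s[[nm]]
      # pseudo-label term on a batch of unlabeled samples
      if (n_un > 0 && cfg$beta > 0 && ep > cfg$pseudo_warmup) {
        fl <- .net_forward(array(x[idx_tr, , ], c(length(idx_tr), h, w)),
                           par, head_W, head_b)
        protos <- class_prototypes(fl$z, y[idx_tr])
        usel <- sample.int(n_un, min(cfg$batch, n_un))
        fu <- .net_forward(array(unlabeled_x[usel, , ],
                                 c(length(usel), h, w)),
                           par, head_W, head_b, cache = TRUE)
        pl <- pseudo_label(fu$z, protos, cfg$pseudo_label_confidence,
                           temperature = cfg$temperature)
        acc <- which(pl$accepted)
        if (length(acc)) {
          pu <- .softmax(fu$logits)
          ui <- match(pl$labels[acc], classes)
          keep <- which(!is.na(ui))
          if (length(keep)) {
            acc <- acc[keep]; ui <- ui[keep]
            pce <- -mean(log(pmax(pu[cbind(acc, ui)], 1e-12)))
            loss <- loss + cfg$beta * pce
            dlo <- matrix(0, length(usel), C)
            Yu <- matrix(0, length(usel), C)
            Yu[cbind(acc, ui)] <- 1
            mask <- rowSums(Yu) > 0
            dlo[mask, ] <- cfg$beta * (pu[mask, , drop = FALSE] -
                                       Yu[mask, , drop = FALSE]) / length(acc)
            gu <- .net_backward(fu, par, head_W, dlogits = dlo, dz = NULL)
            for (nm in names(g)) g[[nm]] <- g[[nm]] + gu[[nm]]
          }
        }
      }
      apply_grads(g)
      ep_loss <- ep_loss + loss; n_terms <- n_terms + 1
    }
    history[ep] <- ep_loss / n_terms
  }
  model <- structure(list(par = par[c(param_names, "idx1", "idx2", "dims")],
                          head_W = head_W, head_b = head_b,
                          classes = classes, cfg = cfg, history = history,
                          split = list(train = idx_tr, val = idx_va,
                                       test = idx_te)),
                     class = "sscl_model")
  fl <- .net_forward(array(x[idx_tr, , ], c(length(idx_tr), h, w)),
                     par, head_W, head_b)
  model$prototypes <- class_prototypes(fl$z, y[idx_tr])
  pred <- classes[apply(fl$logits, 1, which.max)]
  model$train_accuracy <- mean(pred == y[idx_tr])
  model
}

#' @export
print.sscl_model <- function(x, ...) {
  cat(sprintf("<sscl_model> classes [%s], %d epochs, final loss %.4f, train acc %.3f\n",
              paste(x$classes, collapse = ", "), length(x$history),
              tail(x$history, 1), x$train_accuracy))
  invisible(x)
}

.model_forward <- function(model, x) {
  if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
  dm <- model$par$dims
  if (dim(x)[2] != dm$h || dim(x)[3] != dm$w)
    .stop_typed("lungscreen_shape_error", "patch shape %dx%d does not match model (%dx%d)",
                dim(x)[2], dim(x)[3], dm$h, dm$w)
  .net_forward(x, model$par, model$head_W, model$head_b)
}

#' Projection embeddings of image patches
#'
#' Unit-normalized projection vectors; deterministic (the network has no
#' stochastic layers at inference).
#'
#' @param x patch array `n x h x w` (or a single `h x w` matrix).
#' @param model a trained [train_sscl] model.
#' @return matrix `n x proj_dim` of unit vectors.
#' @export
embed <- function(x, model) {
  stopifnot(inherits(model, "sscl_model"))
  .model_forward(model, x)$z
}

#' Class prototypes from labeled embeddings
#' @param embeddings matrix `n x d`.
#' @param labels character labels, every class non-empty.
#' @return matrix (classes x d) of unit-normalized per-class means, with
#'   row names.
#' @export
class_prototypes <- function(embeddings, labels) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  P <- t(vapply(cls, function(cl) {
    m <- colMeans(embeddings[labels == cl, , drop = FALSE])
    m / max(sqrt(sum(m^2)), 1e-12)
  }, numeric(ncol(embeddings))))
  rownames(P) <- cls
  P
}

#' Pseudo-label embeddings against class prototypes
#'
#' Labels each embedding with its nearest prototype by cosine similarity and
#' accepts it iff the softmax (temperature `temperature`) over the
#' similarities puts at least `confidence` mass on the winner.
#'
#' @param embeddings matrix `n x d`.
#' @param prototypes matrix (classes x d) with row names, e.g. from
#'   [class_prototypes].
#' @param confidence acceptance threshold in `[0, 1]`.
#' @param temperature softmax temperature.
#' @return list with `labels`, `accepted` (logical), `confidence` (winner
#'   probability per sample).
#' @export
pseudo_label <- function(embeddings, prototypes, confidence = 0.9,
                         temperature = 0.1) {
  if (is.null(rownames(prototypes)))
    .stop_typed("lungscreen_parameter_error", "prototypes need class row names")
  E <- embeddings / pmax(sqrt(rowSums(embeddings^2)), 1e-12)
  Pn <- prototypes / pmax(sqrt(rowSums(prototypes^2)), 1e-12)
  sims <- E %*% t(Pn)
  sm <- .softmax(sims / temperature)
  win <- apply(sm, 1, which.max)
  conf <- sm[cbind(seq_len(nrow(sm)), win)]
  list(labels = rownames(prototypes)[win], accepted = conf >= confidence,
       confidence = conf)
}

#' Classify patches as Normal or Abnormal
#'
#' @param x patch array or single patch matrix.
#' @param model a trained [train_sscl] model.
#' @return data frame with per-class probability columns, `class`, and
#'   `flag` (`"Normal"` iff the argmax class is the configured normal class,
#'   else `"Abnormal"`).
#' @export
classify <- function(x, model) {
  stopifnot(inherits(model, "sscl_model"))
  fw <- .model_forward(model, x)
  probs <- .softmax(fw$logits)
  colnames(probs) <- model$classes
  cl <- model$classes[apply(probs, 1, which.max)]
  flag <- ifelse(cl == model$cfg$normal_class, "Normal", "Abnormal")
  cbind(as.data.frame(probs), class = cl, flag = flag,
        stringsAsFactors = FALSE)
}

#' @export
predict.sscl_model <- function(object, newdata,
                               type = c("prob", "class", "embedding"), ...) {
  type <- match.arg(type)
  switch(type,
    prob = classify(newdata, object),
    class = classify(newdata, object)$class,
    embedding = embed(newdata, object))
}
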