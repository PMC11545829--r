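# Image-quality (MSE / PSNR / SSIM) and confusion-matrix metrics.

.check_same_shape <- function(a, b) {
  a <- .as_pixels(a); b <- .as_pixels(b)
  if (!identical(dim(a), dim(b)))
    .stop_typed("lungscreen_parameter_error", "image shapes differ: %s vs %s",
                paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  list(a = a, b = b)
}

#' Mean squared error between two images
#' @param a,b images of identical shape.
#' @return mean of squared pixel differences (>= 0).
#' @export
mse <- function(a, b) {
  x <- .check_same_shape(a, b)
  mean((x$a - x$b)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(max_value^2 / MSE)`; `Inf` when the images are identical.
#'
#' @param a,b images of identical shape.
#' @param max_value highest possible pixel value (255 for 8-bit).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(a, b, max_value = 255) {
  if (max_value <= 0) .stop_typed("lungscreen_parameter_error", "max_value must be > 0")
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Structural similarity index (mean local SSIM)
#'
#' Gaussian-weighted local means/variances/covariance (window 11, sigma 1.5)
#' with the standard stabilizers `C1 = (k1 max)^2`, `C2 = (k2 max)^2`.
#'
#' @param a,b images of identical shape.
#' @param window odd window side, at most the image size.
#' @param k1,k2 stabilizer constants.
#' @param max_value dynamic range of the pixel values.
#' @return mean SSIM in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssim <- function(a, b, window = 11, k1 = 0.01, k2 = 0.03, max_value = 255) {
  x <- .check_same_shape(a, b)
  if (window %% 2 == 0 || window > min(dim(x$a)))
    .stop_typed("lungscreen_parameter_error",
                "window must be odd and no larger than the image")
  h <- (window - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * 1.5^2))
  kern <- outer(g, g); kern <- kern / sum(kern)
  f <- function(z) EBImage::filter2(z, kern, boundary = "replicate")
  C1 <- (k1 * max_value)^2; C2 <- (k2 * max_value)^2
  mu_a <- f(x$a); mu_b <- f(x$b)
  va <- f(x$a^2) - mu_a^2
  vb <- f(x$b^2) - mu_b^2
  vab <- f(x$a * x$b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Quality report comparing a processed image with a reference
#' @param processed,reference images of identical shape.
#' @param max_value dynamic range used by PSNR/SSIM.
#' @return object of class `quality_report` with `mse`, `psnr_db`, `ssim`,
#'   `max_value`.
#' @export
quality_report <- function(processed, reference, max_value = 255) {
  structure(list(mse = mse(processed, reference),
                 psnr_db = psnr(processed, reference, max_value),
                 ssim = ssim(processed, reference, max_value = max_value),
                 max_value = max_value),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> MSE %.4g, PSNR %s dB, SSIM %.4f\n",
              x$mse, if (is.infinite(x$psnr_db)) "inf" else sprintf("%.2f", x$psnr_db),
              x$ssim))
  invisible(x)
}

#' Confusion matrix from label vectors
#' @param truth,predicted equal-length label vectors.
#' @param positive the positive-class label.
#' @return object of class `confusion_matrix` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(truth, predicted, positive = TRUE) {
  if (length(truth) != length(predicted))
    .stop_typed("lungscreen_parameter_error", "label vectors must have equal length")
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  confusion_matrix(tp, fp, fn, tn)
}

#' Confusion matrix from counts
#' @param tp,fp,fn,tn non-negative counts, total > 0.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0) || tp + fp + fn + tn == 0)
    .stop_typed("lungscreen_parameter_error",
                "counts must be non-negative with positive total")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d FP %d / FN %d TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @rdname classification_metrics
#' @export
accuracy <- function(cm) {
  (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn)
}

#' Classification metrics from a confusion matrix
#'
#' `accuracy = (TP + TN) / total`, `recall = TP / (TP + FN)` (the fraction of
#' actual positives identified), `precision = TP / (TP + FP)` (the fraction
#' of predicted positives that are real).  A zero denominator raises a typed
#' undefined-metric error.
#'
#' @param cm a `confusion_matrix`.
#' @return a number in `[0, 1]`.
#' @name classification_metrics
#' @export
recall <- function(cm) {
  if (cm$tp + cm$fn == 0)
    .stop_typed("lungscreen_undefined_error", "recall undefined: no actual positives")
  cm$tp / (cm$tp + cm$fn)
}

#' @rdname classification_metrics
#' @export
precision <- function(cm) {
  if (cm$tp + cm$fp == 0)
    .stop_typed("lungscreen_undefined_error", "precision undefined: no predicted positives")
  cm$tp / (cm$tp + cm$fp)
}
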