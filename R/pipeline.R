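# End-to-end orchestration: preprocessing -> segmentation -> nodule
# detection -> risk scoring -> (optional) classification -> evaluation.

.pipeline_defaults <- function() list(
  input = list(image = NULL, phantom = NULL, clean_reference = NULL,
               lung_mask = NULL, covariates = NULL),
  denoise = list(method = "rwicwm", n_scales = 3, window = 5,
                 center_weight = 3, max_iters = 10, tol = 1e-3,
                 equalize = TRUE),
  segment = list(k = 2, patch_radius = 1, max_iter = 25, tol = 1e-3),
  nodule = list(n_thresholds = 2, pop_size = 20, n_iters = 60,
                window = 16, stride = 8, hu_range = c(-950, -500),
                area_range = c(pi * (3 / 2)^2, pi * (30 / 2)^2),
                el_max = 3, ol_min = 0.5, solid_hu = -300, n_bins = 128),
  risk = list(coefficients = NULL, threshold = 0.0151),
  classifier = list(model = NULL),
  metrics = list(max_value = 255),
  seed = 1,
  out_dir = NULL,
  verbosity = "info")

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults for every omitted block, rejects unknown keys by name, and
#' checks the input block before any compute: exactly one of `input$image`
#' (a readable file) or `input$phantom` (a phantom description) must be set.
#' A dumped validated config revalidates identically.
#'
#' @param config a path to a YAML file or a nested list.
#' @return the resolved config list (classed `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      .stop_typed("lungscreen_io_error", "config file does not exist: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  defaults <- .pipeline_defaults()
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top))
    .stop_typed("lungscreen_config_error", "unknown config key(s): %s",
                paste(unknown_top, collapse = ", "))
  for (blk in names(defaults)) {
    if (is.list(defaults[[blk]]) && !is.null(config[[blk]])) {
      unknown <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
      if (length(unknown))
        .stop_typed("lungscreen_config_error", "unknown key(s) in block '%s': %s",
                    blk, paste(unknown, collapse = ", "))
    }
  }
  # merge keeping NULL-valued defaults in place (a dumped config drops them,
  # so a modifyList merge would not round-trip)
  merge_block <- function(def, got) {
    for (k in names(got)) if (!is.null(got[[k]])) def[k] <- got[k]
    def
  }
  cfg <- defaults
  for (blk in names(config)) {
    if (is.list(defaults[[blk]]) && !is.null(config[[blk]]))
      cfg[[blk]] <- merge_block(defaults[[blk]], config[[blk]])
    else if (!is.null(config[[blk]]))
      cfg[blk] <- config[blk]
  }
  has_img <- !is.null(cfg$input$image)
  has_ph <- !is.null(cfg$input$phantom)
  if (!has_img && !has_ph)
    .stop_typed("lungscreen_config_error",
                "config must set input$image or input$phantom")
  if (has_img && !file.exists(cfg$input$image))
    .stop_typed("lungscreen_config_error", "input image does not exist: %s",
                cfg$input$image)
  if (!is.numeric(cfg$seed))
    .stop_typed("lungscreen_config_error", "seed must be numeric")
  structure(cfg, class = "pipeline_config")
}

.log_stage <- function(cfg, fmt, ...) {
  if (identical(cfg$verbosity, "info")) message(sprintf(fmt, ...))
}

.phantom_from_config <- function(ph, seed) {
  nodules <- lapply(ph$nodules %||% list(), function(nd)
    list(center = nd$center, diameter_mm = nd$diameter_mm,
         intensity = nd$intensity %||% 30, solid = nd$solid %||% TRUE))
  spec <- phantom_spec(shape = ph$shape %||% c(256, 256),
                       spacing_mm = ph$spacing_mm %||% c(1, 1),
                       nodules = nodules)
  sl <- generate_slice(spec, seed = seed)
  nm <- noise_model(gaussian_sigma = ph$gaussian_sigma %||% 15,
                    speckle_sigma = ph$speckle_sigma %||% 0,
                    salt_pepper_fraction = ph$salt_pepper_fraction %||% 0)
  noisy <- corrupt(sl$clean, nm, seed = seed + 1)
  list(noisy = noisy, clean = sl$clean, nodule_truth = sl$nodule_truth,
       lung_truth = sl$lung_truth)
}

#' Run the full detection pipeline
#'
#' Executes the fixed stage order: load (or generate) the slice -> denoise ->
#' histogram-equalize -> sliding-window lung parenchyma -> Dice K-means
#' foreground -> LSO multilevel thresholding -> ROI features and filtering ->
#' risk screening (when covariates are supplied) -> classification (when a
#' trained model is supplied) -> evaluation (when ground truth is available).
#' Every stage is logged with its duration; artifacts and a consolidated
#' JSON report (embedding the resolved config and seed) are written under
#' `out_dir` when set.
#'
#' @param config a path, list, or validated `pipeline_config`.
#' @return the run report, invisibly also written to
#'   `file.path(out_dir, "report.json")` when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  t_all <- proc.time()[3]
  durations <- list()
  tic <- function() proc.time()[3]
  report <- list(config = unclass(cfg), seed = cfg$seed)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  run_stage <- function(name, fn) {
    t0 <- tic()
    res <- tryCatch(fn(), error = function(e)
      .stop_typed("lungscreen_stage_error", "stage '%s' failed: %s",
                  name, conditionMessage(e)))
    durations[[name]] <<- round(tic() - t0, 3)
    .log_stage(cfg, "[%s] done in %.2fs", name, durations[[name]])
    res
  }

  inp <- run_stage("input", function() {
    if (!is.null(cfg$input$phantom)) .phantom_from_config(cfg$input$phantom, cfg$seed)
    else {
      img <- read_image2d(cfg$input$image)
      clean <- if (!is.null(cfg$input$clean_reference))
        read_image2d(cfg$input$clean_reference) else NULL
      list(noisy = img, clean = clean, nodule_truth = NULL, lung_truth = NULL)
    }
  })

  dn <- cfg$denoise
  denoised <- run_stage("denoise", function() {
    if (dn$method == "rwicwm") {
      rwicwm_denoise(inp$noisy, rwicwm_params(n_scales = dn$n_scales,
                                              center_weight = dn$center_weight,
                                              window = dn$window,
                                              max_iters = dn$max_iters,
                                              tol = dn$tol))
    } else baseline_denoise(inp$noisy, dn$method)
  })
  equalized <- run_stage("equalize", function() {
    if (isTRUE(dn$equalize)) suppressWarnings(histogram_equalize(denoised))
    else denoised
  })

  lung <- run_stage("parenchyma", function() {
    if (!is.null(cfg$input$lung_mask)) {
      (.as_pixels(read_image2d(cfg$input$lung_mask)) > 127) * 1L
    } else {
      extract_parenchyma(denoised, window = cfg$nodule$window,
                         stride = cfg$nodule$stride,
                         hu_range = cfg$nodule$hu_range)
    }
  })

  seg <- run_stage("segment", function() {
    # cluster the denoised calibrated intensities; outside-lung pixels are
    # set to the in-lung median so k = 2 separates parenchyma from the
    # bright nodule-region class rather than air from body
    px <- .as_pixels(denoised)
    if (sum(lung) > 0) px[lung == 0] <- median(px[lung == 1])
    st <- dice_kmeans(px, k = cfg$segment$k,
                      patch_radius = cfg$segment$patch_radius,
                      max_iter = cfg$segment$max_iter, tol = cfg$segment$tol,
                      seed = cfg$seed)
    list(state = st, foreground = foreground_mask(st, px, lung_mask = lung))
  })

  det <- run_stage("detect", function() {
    fc <- candidate_filter_config(area_range = cfg$nodule$area_range,
                                  el_max = cfg$nodule$el_max,
                                  ol_min = cfg$nodule$ol_min)
    detect_nodules(denoised, lung = lung,
                   n_thresholds = cfg$nodule$n_thresholds, seed = cfg$seed,
                   filter_config = fc, solid_hu = cfg$nodule$solid_hu,
                   n_bins = cfg$nodule$n_bins)
  })
  cands <- det$candidates
  if (!is.null(out_dir)) {
    write_candidates_csv(cands, file.path(out_dir, "candidates.csv"))
    write_image2d(rescale_for_display(denoised), file.path(out_dir, "denoised.png"))
    write_image2d(det$lung * 255, file.path(out_dir, "lung_mask.png"))
  }
  report$n_candidates <- nrow(cands)

  if (!is.null(cfg$input$covariates)) {
    risk_res <- run_stage("risk", function() {
      cov <- read.csv(cfg$input$covariates, stringsAsFactors = FALSE)
      coef <- if (!is.null(cfg$risk$coefficients))
        read_risk_coefficients(cfg$risk$coefficients)
      else read_risk_coefficients(system.file("extdata",
                                              "example_risk_coefficients.yaml",
                                              package = "lungscreen"))
      cd <- cands
      cd$patient_id <- if (nrow(cd)) cov$patient_id[1] else integer()
      screen_cohort(cd, cov, coef, threshold = cfg$risk$threshold)
    })
    report$risk <- list(n_patients = nrow(risk_res),
                        fraction_low = mean(risk_res$stratum == "low"),
                        n_triggered = sum(risk_res$triggered))
    if (!is.null(out_dir))
      write.csv(risk_res, file.path(out_dir, "risk.csv"), row.names = FALSE)
  }

  if (!is.null(cfg$classifier$model)) {
    cls <- run_stage("classify", function() {
      model <- readRDS(cfg$classifier$model)
      dm <- model$par$dims
      px <- .as_pixels(equalized) / max(.as_pixels(equalized))
      patches <- lapply(seq_len(nrow(cands)), function(i) {
        cy <- round(cands$y_mm[i] / denoised$spacing_mm[1]) + 1
        cx <- round(cands$x_mm[i] / denoised$spacing_mm[2]) + 1
        ys <- pmin(pmax(cy - dm$h %/% 2 + seq_len(dm$h) - 1, 1), nrow(px))
        xs <- pmin(pmax(cx - dm$w %/% 2 + seq_len(dm$w) - 1, 1), ncol(px))
        px[ys, xs]
      })
      if (length(patches)) {
        xb <- array(0, c(length(patches), dm$h, dm$w))
        for (i in seq_along(patches)) xb[i, , ] <- patches[[i]]
        classify(xb, model)
      } else NULL
    })
    if (!is.null(cls)) report$classification <-
      list(n_abnormal = sum(cls$flag == "Abnormal"), n = nrow(cls))
  }

  eval_blk <- run_stage("evaluate", function() {
    out <- list()
    if (!is.null(inp$clean)) {
      ref <- rescale_for_display(inp$clean)
      got <- rescale_for_display(denoised)
      noisy <- rescale_for_display(inp$noisy)
      qr <- quality_report(got, ref, max_value = cfg$metrics$max_value)
      out$quality <- list(mse = qr$mse,
                          psnr_db = if (is.infinite(qr$psnr_db)) "inf" else qr$psnr_db,
                          ssim = qr$ssim,
                          psnr_noisy_db = psnr(noisy, ref, cfg$metrics$max_value))
    }
    if (!is.null(inp$nodule_truth)) {
      pred_mask <- (det$labels > 0) * 1L
      keep_ids <- cands$id
      pred_mask[!(det$labels %in% keep_ids)] <- 0L
      cm <- confusion(as.vector(inp$nodule_truth) > 0, as.vector(pred_mask) > 0)
      out$confusion <- list(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
                            accuracy = accuracy(cm),
                            dice = dice_counts(cm$tp, cm$fp, cm$fn))
    }
    out
  })
  if (length(eval_blk)) report <- c(report, eval_blk)

  report$durations <- durations
  report$total_seconds <- round(tic() - t_all, 3)
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(report)
}
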