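landmark_df_to_array <- function(x) {
  # lists of landmark_set or a data frame with wide landmark columns -> K x n x 2
  if (is.data.frame(x)) {
    n <- nrow(x)
    out <- array(0, c(4, n, 2))
    kp <- keypoint_names()
    for (k in seq_along(kp)) {
      out[k, , 1] <- x[[paste0(kp[k], "_x")]]
      out[k, , 2] <- x[[paste0(kp[k], "_y")]]
    }
    return(out)
  }
  n <- length(x)
  out <- array(0, c(4, n, 2))
  for (i in seq_len(n)) out[, i, ] <- unclass(x[[i]])[, c(1, 2)]
  out
}

check_aligned <- function(preds, gts) {
  np <- if (is.data.frame(preds)) nrow(preds) else length(preds)
  ng <- if (is.data.frame(gts)) nrow(gts) else length(gts)
  if (np != ng) {
    rlang::abort("prediction and ground-truth sets differ in length",
                 class = "cephan_error_alignment")
  }
  if (is.data.frame(preds) && is.data.frame(gts) &&
      "id" %in% names(preds) && "id" %in% names(gts) &&
      !identical(preds$id, gts$id)) {
    rlang::abort("prediction and ground-truth ids are not aligned",
                 class = "cephan_error_alignment")
  }
  invisible(np)
}

#' Per-keypoint localization error
#'
#' Mean Euclidean distance between predicted and ground-truth positions, per
#' keypoint and averaged across the four keypoints.
#'
#' @param preds,gts Aligned lists of [landmark_set()] objects, or data frames
#'   with wide landmark columns (and optionally matching `id` columns).
#' @return Tibble with columns `keypoint` (`Ar`, `Ba`, `PNS`, `Aprime`,
#'   `average`) and `error_px`.
#' @export
localization_errors <- function(preds, gts) {
  n <- check_aligned(preds, gts)
  p <- landmark_df_to_array(preds)
  g <- landmark_df_to_array(gts)
  err <- sqrt((p[, , 1, drop = FALSE] - g[, , 1, drop = FALSE])^2 +
                (p[, , 2, drop = FALSE] - g[, , 2, drop = FALSE])^2)[, , 1]
  err <- matrix(err, nrow = 4)
  per <- rowMeans(err)
  names(per) <- keypoint_names()
  ord <- c("Ar", "Ba", "PNS", "Aprime")
  tibble::tibble(keypoint = c(ord, "average"),
                 error_px = unname(c(per[ord], mean(per))))
}

#' PCK-style average precision and recall of keypoint detection
#'
#' A predicted keypoint is correct at threshold `t` when its Euclidean error
#' is at most `t` pixels. With exactly one prediction per ground-truth
#' keypoint, precision and recall both equal the fraction of correct
#' keypoints; AP and AR are their means over the threshold list.
#'
#' @inheritParams localization_errors
#' @param thresholds Pixel thresholds (default `1:10`).
#' @return List with `ap`, `ar` and a `per_threshold` tibble.
#' @export
keypoint_ap_ar <- function(preds, gts, thresholds = 1:10) {
  if (length(thresholds) == 0) {
    rlang::abort("threshold list must be non-empty",
                 class = "cephan_error_config")
  }
  check_aligned(preds, gts)
  p <- landmark_df_to_array(preds)
  g <- landmark_df_to_array(gts)
  err <- sqrt((p[, , 1] - g[, , 1])^2 + (p[, , 2] - g[, , 2])^2)
  frac <- vapply(thresholds, function(t) mean(err <= t), numeric(1))
  list(ap = mean(frac), ar = mean(frac),
       per_threshold = tibble::tibble(threshold = thresholds,
                                      precision = frac, recall = frac))
}

#' Mean absolute A/N ratio error
#'
#' Both landmark sets are passed through [compute_an()]; the error is the
#' mean over samples of the absolute ratio difference. Samples whose
#' geometry is degenerate on either side are excluded with a warning.
#'
#' @inheritParams localization_errors
#' @return List with `mae`, `n_used` and `n_excluded`.
#' @export
an_ratio_error <- function(preds, gts) {
  n <- check_aligned(preds, gts)
  p <- landmark_df_to_array(preds)
  g <- landmark_df_to_array(gts)
  errs <- vapply(seq_len(n), function(i) {
    tryCatch(abs(compute_an(coords_to_landmarks(p[, i, ]))$ratio -
                   compute_an(coords_to_landmarks(g[, i, ]))$ratio),
             error = function(e) NA_real_)
  }, numeric(1))
  n_exc <- sum(is.na(errs))
  if (n_exc > 0) {
    warning(sprintf("%d sample(s) with degenerate geometry excluded", n_exc))
  }
  list(mae = mean(errs, na.rm = TRUE), n_used = n - n_exc,
       n_excluded = n_exc)
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Diagnostic confusion metrics with Wilson confidence intervals
#'
#' Counts the confusion matrix with `hypertrophic` as the positive class and
#' reports sensitivity, specificity, accuracy, precision, recall, F1 and the
#' likelihood ratios LR+ = sens/(1-spec) and LR- = (1-sens)/spec. 95%
#' confidence intervals for the proportions use the Wilson score method.
#'
#' @param pred_labels,gt_labels Aligned character vectors
#'   (`"normal"`/`"hypertrophic"`).
#' @param positive Positive-class label (default `"hypertrophic"`).
#' @param conf Confidence level (default 0.95).
#' @return A list of class `diagnostic_report`: `counts` (TP, FP, TN, FN)
#'   and `metrics` (tibble with `metric`, `estimate`, `ci_low`, `ci_high`).
#' @export
diagnostic_metrics <- function(pred_labels, gt_labels,
                               positive = "hypertrophic", conf = 0.95) {
  if (length(pred_labels) != length(gt_labels)) {
    rlang::abort("label vectors differ in length",
                 class = "cephan_error_alignment")
  }
  gp <- gt_labels == positive
  if (all(gp) || all(!gp)) {
    rlang::abort("sensitivity and specificity are undefined for single-class ground truth",
                 class = "cephan_error_undefined_metric")
  }
  pp <- pred_labels == positive
  tp <- sum(pp & gp); fp <- sum(pp & !gp)
  tn <- sum(!pp & !gp); fn <- sum(!pp & gp)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && prec + sens > 0) 2 * prec * sens / (prec + sens)
        else NA_real_
  lrp <- if (spec < 1) sens / (1 - spec) else Inf
  lrn <- if (spec > 0) (1 - sens) / spec else NA_real_
  ci <- function(k, n) wilson_ci(k, n, conf)
  met <- tibble::tribble(
    ~metric, ~estimate, ~ci,
    "sensitivity", sens, ci(tp, tp + fn),
    "specificity", spec, ci(tn, tn + fp),
    "accuracy", acc, ci(tp + tn, tp + tn + fp + fn),
    "precision", prec, if (tp + fp > 0) ci(tp, tp + fp) else c(NA, NA),
    "recall", sens, ci(tp, tp + fn),
    "F1", f1, c(NA_real_, NA_real_),
    "LR_positive", lrp, c(NA_real_, NA_real_),
    "LR_negative", lrn, c(NA_real_, NA_real_))
  metrics <- tibble::tibble(metric = met$metric, estimate = met$estimate,
                            ci_low = vapply(met$ci, `[`, numeric(1), 1),
                            ci_high = vapply(met$ci, `[`, numeric(1), 2))
  structure(list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 metrics = metrics, conf = conf, positive = positive),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("diagnostic report (positive = %s): TP %d FP %d TN %d FN %d\n",
              x$positive, x$counts["TP"], x$counts["FP"], x$counts["TN"],
              x$counts["FN"]))
  print(x$metrics, n = Inf)
  invisible(x)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' Uses the predicted A/N ratio as a continuous diagnostic score. The curve
#' sweeps all distinct score thresholds; the AUC equals the Mann-Whitney
#' statistic (ties counted 1/2). The 95% CI comes from a stratified bootstrap
#' over samples.
#'
#' @param scores Numeric vector of predicted A/N ratios.
#' @param gt_labels Aligned ground-truth labels.
#' @param n_boot Bootstrap replicates for the CI (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param positive Positive-class label.
#' @return A list of class `roc_result`: `curve` (tibble of `threshold`,
#'   `fpr`, `tpr`), `auc`, `ci_low`, `ci_high`, `n_boot`.
#' @export
roc_auc <- function(scores, gt_labels, n_boot = 2000, seed = 1L,
                    positive = "hypertrophic") {
  if (length(scores) != length(gt_labels)) {
    rlang::abort("scores and labels differ in length",
                 class = "cephan_error_alignment")
  }
  gp <- gt_labels == positive
  if (all(gp) || all(!gp)) {
    rlang::abort("AUC is undefined for single-class ground truth",
                 class = "cephan_error_undefined_metric")
  }
  r <- pROC::roc(response = factor(gp, levels = c(FALSE, TRUE)),
                 predictor = scores, direction = "<", quiet = TRUE)
  set.seed(seed)
  ci <- suppressWarnings(pROC::ci.auc(r, method = "bootstrap",
                                      boot.n = n_boot,
                                      boot.stratified = TRUE,
                                      progress = "none"))
  curve <- tibble::tibble(threshold = r$thresholds,
                          fpr = 1 - r$specificities,
                          tpr = r$sensitivities) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  structure(list(curve = curve, auc = as.numeric(pROC::auc(r)),
                 ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
                 n_boot = n_boot),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f (95%% CI %.4f-%.4f, %d bootstrap reps)\n",
              x$auc, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Full metric suite for a set of predictions
#'
#' Combines localization error, AP/AR, A/N ratio error, confusion metrics
#' and ROC/AUC into one report.
#'
#' @param pred_df Predictions: data frame with wide landmark columns (e.g.
#'   from [predict_landmarks()]).
#' @param gt_df Ground truth in the same layout (e.g. a manifest); its
#'   `true_ratio`/`true_label` columns, when present, define the reference
#'   labels, otherwise labels are derived from the ground-truth landmarks.
#' @param threshold Decision threshold on the ratio (default 0.6).
#' @param ap_thresholds Pixel thresholds for AP/AR.
#' @param n_boot,seed Bootstrap settings for the AUC CI.
#' @return A list of class `metrics_report`.
#' @export
evaluate_predictions <- function(pred_df, gt_df, threshold = 0.6,
                                 ap_thresholds = 1:10, n_boot = 2000,
                                 seed = 1L) {
  check_aligned(pred_df, gt_df)
  if (!"ratio" %in% names(pred_df)) pred_df <- an_ratio(pred_df, threshold)
  if ("true_ratio" %in% names(gt_df)) {
    gt_ratio <- gt_df$true_ratio
  } else {
    gt_ratio <- an_ratio(gt_df, threshold)$ratio
  }
  gt_labels <- classify_ah(gt_ratio, threshold)
  loc <- localization_errors(pred_df, gt_df)
  apar <- keypoint_ap_ar(pred_df, gt_df, ap_thresholds)
  an_err <- list(mae = mean(abs(pred_df$ratio - gt_ratio)),
                 n_used = nrow(pred_df), n_excluded = 0L)
  # confusion metrics and ROC need both classes in the ground truth;
  # on a degenerate (single-class) evaluation set they are omitted
  diag <- tryCatch(diagnostic_metrics(classify_ah(pred_df$ratio, threshold),
                                      gt_labels),
                   cephan_error_undefined_metric = function(e) NULL)
  roc <- tryCatch(roc_auc(pred_df$ratio, gt_labels, n_boot = n_boot,
                          seed = seed),
                  cephan_error_undefined_metric = function(e) NULL)
  f1 <- if (apar$ap + apar$ar > 0) {
    2 * apar$ap * apar$ar / (apar$ap + apar$ar)   # keypoint-detection F1
  } else 0
  structure(list(localization = loc, ap = apar$ap, ar = apar$ar, f1 = f1,
                 per_threshold = apar$per_threshold,
                 an_error = an_err, diagnostics = diag, roc = roc,
                 threshold = threshold, n = nrow(pred_df)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics report over %d samples (threshold %.2f)\n",
              x$n, x$threshold))
  cat(sprintf("  mean localization error: %.3f px\n",
              x$localization$error_px[x$localization$keypoint == "average"]))
  cat(sprintf("  AP %.4f  AR %.4f  F1 %.4f  A/N MAE %.4f\n", x$ap, x$ar,
              x$f1, x$an_error$mae))
  if (!is.null(x$diagnostics)) {
    m <- x$diagnostics$metrics
    est <- function(nm) m$estimate[m$metric == nm]
    cat(sprintf("  sensitivity %.4f  specificity %.4f  accuracy %.4f\n",
                est("sensitivity"), est("specificity"), est("accuracy")))
  }
  if (!is.null(x$roc)) {
    cat(sprintf("  AUC %.4f (95%% CI %.4f-%.4f)\n", x$roc$auc,
                x$roc$ci_low, x$roc$ci_high))
  }
  invisible(x)
}
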