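#' Plot an ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC for adenoid-hypertrophy detection (AUC %.3f)",
                      object$auc),
      subtitle = sprintf("95%% CI %.3f-%.3f, stratified bootstrap",
                         object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' Validation curves over epochs: localization error, AP/AR and A/N ratio
#' error, faceted by metric.
#'
#' @param object A `cephan_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cephan_fit
#' @export
autoplot.cephan_fit <- function(object, ...) {
  long <- object$history |>
    dplyr::select("epoch", "train_total", "val_loc_error", "val_ap",
                  "val_an_error") |>
    tidyr_pivot()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL,
                  title = "Training and validation curves") +
    ggplot2::theme_minimal()
}

# Minimal long-format pivot (avoids a tidyr dependency for one call).
tidyr_pivot <- function(df) {
  metrics <- setdiff(names(df), "epoch")
  purrr::map_dfr(metrics, function(m) {
    tibble::tibble(epoch = df$epoch, metric = m, value = df[[m]])
  })
}

#' Plot a cephalogram sample with its landmarks
#'
#' Ground-truth landmarks are drawn in green; predicted ones, when supplied,
#' in red, with the A and N measurement segments overlaid.
#'
#' @param sample A `ceph_sample`.
#' @param pred Optional predicted [landmark_set()] (or 4x2 matrix).
#' @return A ggplot.
#' @export
plot_sample <- function(sample, pred = NULL) {
  img <- sample$image
  df <- tibble::tibble(
    x = rep(0:(ncol(img) - 1), each = nrow(img)),
    y = rep(0:(nrow(img) - 1), times = ncol(img)),
    value = as.vector(img))
  lm_df <- function(lm, which) {
    m <- unclass(lm)
    tibble::tibble(x = m[, 1], y = m[, 2],
                   keypoint = rownames(m), which = which)
  }
  pts <- lm_df(sample$landmarks, "truth")
  if (!is.null(pred)) pts <- dplyr::bind_rows(pts, lm_df(pred, "prediction"))
  an <- compute_an(sample$landmarks)
  seg <- tibble::tibble(
    x = c(unclass(sample$landmarks)["Aprime", 1], an$foot[1]),
    y = c(unclass(sample$landmarks)["Aprime", 2], an$foot[2]),
    xend = c(an$foot[1], unclass(sample$landmarks)["PNS", 1]),
    yend = c(an$foot[2], unclass(sample$landmarks)["PNS", 2]),
    segment = c("A", "N"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend,
                                       linetype = .data$segment),
                          colour = "#fee090", linewidth = 0.6) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(colour = .data$which), size = 2) +
    ggplot2::scale_colour_manual(values = c(truth = "#1a9850",
                                            prediction = "#d73027")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s: true A/N = %.3f (%s)", sample$id,
                                  sample$true_ratio, sample$true_label),
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_void()
}
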