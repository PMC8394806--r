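#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained model: the per-epoch history
#'
#' @param x A `cephan_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: learning rate, loss breakdown and
#'   the four validation metrics.
#' @method tidy cephan_fit
#' @export
tidy.cephan_fit <- function(x, ...) x$history

#' One-row summary of a trained model
#'
#' @param x A `cephan_fit`.
#' @param ... Unused.
#' @return One-row tibble: epochs, best epoch and the validation metrics at
#'   the best epoch.
#' @method glance cephan_fit
#' @export
glance.cephan_fit <- function(x, ...) {
  h <- x$history[x$best_epoch, ]
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 n_parameters = n_parameters(x$model$params),
                 val_loc_error = h$val_loc_error, val_ap = h$val_ap,
                 val_ar = h$val_ar, val_an_error = h$val_an_error)
}

#' Tidy a diagnostic report
#'
#' @param x A `diagnostic_report`.
#' @param ... Unused.
#' @return The metric tibble (`metric`, `estimate`, `ci_low`, `ci_high`).
#' @method tidy diagnostic_report
#' @export
tidy.diagnostic_report <- function(x, ...) x$metrics

#' @method glance diagnostic_report
#' @export
glance.diagnostic_report <- function(x, ...) {
  wide <- stats::setNames(as.list(x$metrics$estimate), x$metrics$metric)
  dplyr::bind_cols(tibble::as_tibble(wide),
                   tibble::as_tibble(as.list(x$counts)))
}

#' Tidy an ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return The curve tibble (`threshold`, `fpr`, `tpr`).
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_boot = x$n_boot)
}

#' Tidy a full metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Long tibble of `metric`, `estimate` pairs covering localization,
#'   AP/AR, A/N error, confusion metrics and AUC.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  loc <- tibble::tibble(
    metric = paste0("loc_", x$localization$keypoint),
    estimate = x$localization$error_px)
  diag <- if (!is.null(x$diagnostics)) {
    dplyr::select(x$diagnostics$metrics, metric = "metric",
                  estimate = "estimate")
  }
  extra <- tibble::tibble(
    metric = c("ap", "ar", "f1", "an_ratio_mae",
               if (!is.null(x$roc)) "auc"),
    estimate = c(x$ap, x$ar, x$f1, x$an_error$mae,
                 if (!is.null(x$roc)) x$roc$auc))
  dplyr::bind_rows(loc, extra, diag)
}

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  est <- function(nm) {
    if (is.null(x$diagnostics)) return(NA_real_)
    m <- x$diagnostics$metrics
    m$estimate[m$metric == nm]
  }
  tibble::tibble(
    n = x$n,
    loc_error = x$localization$error_px[x$localization$keypoint == "average"],
    ap = x$ap, ar = x$ar, f1 = x$f1, an_ratio_mae = x$an_error$mae,
    sensitivity = est("sensitivity"), specificity = est("specificity"),
    accuracy = est("accuracy"),
    auc = if (!is.null(x$roc)) x$roc$auc else NA_real_)
}
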