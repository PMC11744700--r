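#' Regression metrics: R-squared, MAE, MSE
#'
#' Standard definitions: `r2 = 1 - SS_res / SS_tot` (can be negative for a
#' predictor worse than the mean; `NA` with a warning for zero-variance
#' targets), `mae = mean(|y - yhat|)`, `mse = mean((y - yhat)^2)`. When the
#' targets are transition energies the units are eV (MAE) and eV^2 (MSE).
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return A list of class `"regression_metrics"` with `r2`, `mae`, `mse`.
#' @examples
#' evaluate_regression(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
evaluate_regression <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  res <- y_true - y_pred
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero-variance targets: R^2 undefined")
    NA_real_
  } else 1 - sum(res^2) / ss_tot
  structure(list(r2 = r2, mae = mean(abs(res)), mse = mean(res^2)),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.4f  MAE = %.4f  MSE = %.4f\n", x$r2, x$mae, x$mse))
  invisible(x)
}

#' Classification metrics: accuracy, weighted F1, confusion matrix
#'
#' `accuracy` is the fraction of exact label matches; `weighted_f1` weights
#' each class's F1 score by its support in `y_true` (classes with zero
#' support contribute nothing); `confusion` is the K x K count matrix with
#' true classes on rows, and `confusion_normalized` divides each row by its
#' sum (rows of classes that occur sum to 1).
#'
#' @param y_true,y_pred Character/factor vectors of equal length.
#' @param labels Optional label set fixing the confusion-matrix order;
#'   defaults to the sorted union of observed labels.
#' @return A list of class `"classification_metrics"` with `accuracy`,
#'   `weighted_f1`, `per_class` (precision/recall/F1/support), `confusion`,
#'   `confusion_normalized`.
#' @examples
#' evaluate_classification(c("A", "B", "A", "B"), c("A", "A", "B", "B"))
#' @export
evaluate_classification <- function(y_true, y_pred, labels = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  stopifnot(all(y_true %in% labels), all(y_pred %in% labels))
  K <- length(labels)
  conf <- matrix(0, K, K, dimnames = list(true = labels, pred = labels))
  for (i in seq_along(y_true)) {
    conf[y_true[i], y_pred[i]] <- conf[y_true[i], y_pred[i]] + 1
  }
  support <- rowSums(conf)
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  norm <- conf
  nz <- support > 0
  norm[nz, ] <- conf[nz, , drop = FALSE] / support[nz]
  structure(list(
    accuracy = mean(y_true == y_pred),
    weighted_f1 = sum(f1 * support) / sum(support),
    per_class = data.frame(label = labels, precision = unname(prec),
                           recall = unname(rec), f1 = unname(f1),
                           support = unname(support)),
    confusion = conf,
    confusion_normalized = norm
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy = %.4f  weighted F1 = %.4f\n",
              x$accuracy, x$weighted_f1))
  invisible(x)
}
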