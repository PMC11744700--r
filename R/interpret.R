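#' Configuration for integrated-gradient attribution
#'
#' @param baseline Numeric vector (length = model input dimension; default
#'   the all-zero fingerprint) — the reference configuration the attribution
#'   is measured against. Non-integer baselines (e.g. `s10 = 0.5`) are
#'   deliberately allowed: hypothetical fingerprints are legitimate model
#'   inputs.
#' @param n_steps Number of path points sampled at uniform intervals on the
#'   straight line from baseline to input, endpoints included (default 100).
#'   The integral is approximated with the trapezoidal rule over these
#'   points.
#' @param variant `"normalized_eq3"` (attribution of feature i is
#'   `(s_i - sbar_i) * integral of dF/ds_i`; summing over i recovers
#'   `F(x) - F(baseline)` for exact integrals), `"unnormalized_eq4"` (the
#'   path-averaged gradient itself, useful for smooth sweeps), or
#'   `"fraction_of_total"` (the normalized attributions divided by their
#'   total, so reported contributions sum to exactly 1).
#' @param target For classification models: class label (or index) whose
#'   output is attributed. Ignored for regression.
#' @param of For classification: differentiate the softmax `"prob"` (default)
#'   or the raw `"logit"`.
#' @return A list of class `"ig_config"`.
#' @export
ig_config <- function(baseline = rep(0, 46), n_steps = 100L,
                      variant = c("normalized_eq3", "unnormalized_eq4",
                                  "fraction_of_total"),
                      target = NULL, of = c("prob", "logit")) {
  variant <- match.arg(variant)
  of <- match.arg(of)
  stopifnot(n_steps >= 2, all(is.finite(baseline)))
  structure(list(baseline = baseline, n_steps = as.integer(n_steps),
                 variant = variant, target = target, of = of),
            class = "ig_config")
}

#' Points on the straight path from baseline to input
#'
#' `s_i(alpha) = sbar_i + alpha * (s_i - sbar_i)` at `n_steps` uniformly
#' spaced `alpha` in `[0, 1]`, both endpoints included.
#'
#' @param x,baseline Numeric vectors of equal length.
#' @param n_steps Number of points (>= 2).
#' @return Matrix `n_steps x length(x)`; first row is the baseline, last is
#'   `x`.
#' @export
path_points <- function(x, baseline, n_steps = 100L) {
  stopifnot(length(x) == length(baseline), n_steps >= 2)
  alpha <- seq(0, 1, length.out = n_steps)
  outer(alpha, x - baseline) + matrix(baseline, n_steps, length(x),
                                      byrow = TRUE)
}

# model output F used by IG: regression prediction, or the prob/logit of the
# target class
.ig_output <- function(model, X, k, of) {
  if (model$spec$task == "regression") return(predict(model, X))
  if (of == "logit") {
    if (model$spec$family != "fcnn") {
      stop("logit attribution is only available for fcnn models")
    }
    Xs <- .apply_scaler(model$scaler, as.matrix(X))
    return(.mlp_out(model$fit, Xs)[, k])
  }
  predict(model, X, type = "prob")[, k]
}

#' Integrated-gradient attribution of a model prediction
#'
#' Approximates, for every input feature, the path integral of the model's
#' input gradient along the straight line from the baseline to `x`
#' (trapezoidal rule over `n_steps` uniformly spaced points), and scales it
#' according to the chosen variant (see [ig_config()]). For a linear model
#' the normalized attributions are exact: feature i receives
#' `w_i * (x_i - baseline_i)` and their sum is `F(x) - F(baseline)`.
#'
#' @param model A `"pofp_model"` exposing the gradient contract
#'   ([model_gradient()]).
#' @param x Input vector on the raw fingerprint scale.
#' @param config An [ig_config()].
#' @return A list of class `"ig_result"`: `attributions` (named numeric
#'   vector, same length as `x`), `config`, `model_output_at_x`,
#'   `model_output_at_baseline`.
#' @export
integrated_gradient <- function(model, x, config = ig_config()) {
  stopifnot(inherits(config, "ig_config"))
  x <- as.numeric(x)
  stopifnot(length(x) == model$input_dim,
            length(config$baseline) == model$input_dim)
  if (model$spec$task == "classification" && is.null(config$target)) {
    stop("classification attribution needs config$target")
  }
  k <- if (model$spec$task == "classification") {
    if (is.character(config$target)) match(config$target, model$classes)
    else as.integer(config$target)
  } else 1L
  pts <- path_points(x, config$baseline, config$n_steps)
  grads <- model_gradient(model, pts, target = config$target, of = config$of)
  w <- rep(1, config$n_steps)
  w[c(1, config$n_steps)] <- 0.5
  w <- w / (config$n_steps - 1)
  avg <- colSums(grads * w)
  attr_vec <- switch(config$variant,
    unnormalized_eq4 = avg,
    normalized_eq3 = (x - config$baseline) * avg,
    fraction_of_total = {
      a <- (x - config$baseline) * avg
      tot <- sum(a)
      if (abs(tot) < 1e-12) {
        stop("fraction_of_total undefined: attributions sum to 0")
      }
      a / tot
    })
  names(attr_vec) <- if (length(x) == 46) pofp_digit_names() else
    paste0("x", seq_along(x))
  structure(list(
    attributions = attr_vec,
    config = config,
    model_output_at_x = .ig_output(model, matrix(x, 1), k, config$of),
    model_output_at_baseline = .ig_output(model, matrix(config$baseline, 1),
                                          k, config$of)
  ), class = "ig_result")
}

#' @export
print.ig_result <- function(x, ...) {
  cat("integrated gradients (", x$config$variant, "), F(x) = ",
      signif(x$model_output_at_x, 6), ", F(baseline) = ",
      signif(x$model_output_at_baseline, 6), "\n", sep = "")
  act <- x$attributions[x$attributions != 0]
  if (length(act) > 0) {
    for (nm in names(act)) cat(sprintf("  %-4s %+0.5f\n", nm, act[nm]))
  }
  invisible(x)
}

#' Sweep one feature and record integrated-gradient attributions
#'
#' For each value in `values`, sets `template[sweep_feature] = value`,
#' computes the integrated gradient of the model at that hypothetical
#' fingerprint, and records the attributions of `record_features`. This is
#' the machinery behind attribution-versus-conjugation-scale curves: sweep
#' the aromatic-atom digit (46) and watch how the importance of a donor or
#' acceptor digit changes.
#'
#' @param model A `"pofp_model"`.
#' @param template Numeric vector, the fingerprint template (raw scale).
#' @param sweep_feature Index of the swept feature.
#' @param values Numeric vector of values the swept feature takes (output
#'   rows follow this order).
#' @param config An [ig_config()].
#' @param record_features Indices of features whose attributions are
#'   reported (default: the swept feature plus all non-zero template
#'   features).
#' @return A data.frame with one row per value: `value`, then one column per
#'   recorded feature (named `s<i>`).
#' @export
ig_sweep <- function(model, template, sweep_feature, values,
                     config = ig_config(), record_features = NULL) {
  stopifnot(sweep_feature >= 1, sweep_feature <= length(template),
            all(is.finite(values)))
  if (is.null(record_features)) {
    record_features <- sort(unique(c(which(template != 0), sweep_feature)))
  }
  rows <- lapply(values, function(v) {
    x <- template
    x[sweep_feature] <- v
    ig <- integrated_gradient(model, x, config)
    c(value = v, ig$attributions[record_features])
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("value", paste0("s", record_features))
  out
}

#' Classify a molecule and attribute the prediction
#'
#' Computes the POFP(num) of `smiles`, predicts its class with the model,
#' and runs integrated gradients for the *predicted* class. The printed
#' result mirrors the usual report format: active digit names with signed
#' contributions.
#'
#' @param model A classification `"pofp_model"` trained on 46-digit
#'   fingerprints.
#' @param smiles A SMILES string.
#' @param config An [ig_config()]; its `target` is overridden by the
#'   predicted class.
#' @return A list with `predicted_class`, `fingerprint` and `ig` (an
#'   `"ig_result"`).
#' @export
classify_and_attribute <- function(model, smiles, config = ig_config()) {
  stopifnot(model$spec$task == "classification", model$input_dim == 46)
  fp <- compute_pofp(smiles, mode = "num")
  cls <- predict(model, matrix(as.numeric(fp), 1))
  config$target <- cls
  ig <- integrated_gradient(model, as.numeric(fp), config)
  list(predicted_class = cls, fingerprint = fp, ig = ig)
}

#' Write an attribution result to CSV
#'
#' One row per feature: index, digit name, human label, attribution.
#'
#' @param ig An `"ig_result"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ig_csv <- function(ig, path) {
  stopifnot(inherits(ig, "ig_result"))
  a <- ig$attributions
  df <- data.frame(index = seq_along(a), digit = names(a),
                   label = if (length(a) == 46) pofp_digit_labels() else
                     names(a),
                   attribution = as.numeric(a))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
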