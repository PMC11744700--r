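#' Specify a regression or classification model
#'
#' The model families benchmarked on POFP matrices: ordinary linear
#' regression, support-vector machines (SVR/SVM), k-nearest neighbours,
#' decision trees, random forests, gradient boosting, and the built-in
#' four-layer fully connected neural network ([mlp]). Classical learners are
#' delegated to their established implementations (`stats::lm` least squares,
#' `e1071::svm`, `caret::knnreg`/`caret::knn3`, `rpart`, `randomForest`,
#' `xgboost`); the FCNN is the package's own engine.
#'
#' @param family One of `"linear"`, `"svr_or_svm"`, `"knn"`,
#'   `"decision_tree"`, `"random_forest"`, `"gradient_boosting"`, `"fcnn"`.
#' @param task `"regression"` or `"classification"`. `"linear"` supports
#'   regression only.
#' @param hyperparameters Named list overriding family defaults (e.g. `k` for
#'   knn, `ntree` for random_forest, `nrounds` for gradient_boosting,
#'   `hidden`, `lr`, `batch`, `epochs`, `patience` for fcnn).
#' @param seed Integer seed threaded through every stochastic family.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(family = c("linear", "svr_or_svm", "knn",
                                  "decision_tree", "random_forest",
                                  "gradient_boosting", "fcnn"),
                       task = c("regression", "classification"),
                       hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  task <- match.arg(task)
  if (family == "linear" && task == "classification") {
    stop("family 'linear' supports regression only")
  }
  structure(list(family = family, task = task,
                 hyperparameters = hyperparameters, seed = as.integer(seed)),
            class = "model_spec")
}

.hp <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

# per-column standardization fitted on the training data only; constant
# columns get scale 1 so they pass through unchanged
.fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}
.apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' Build an untrained FCNN scaffold
#'
#' Four fully connected weight layers with ReLU after each hidden layer and a
#' linear output (one unit for regression, one score per class for
#' classification), He-initialized from `seed`.
#'
#' @param input_dim Number of input features (46 for POFP).
#' @param task `"regression"` or `"classification"`.
#' @param hidden_sizes Integer vector of length 3, the hidden-layer widths.
#' @param output_dim Output units (ignored for regression; for
#'   classification set automatically at fit time from the labels if `NULL`).
#' @param seed Integer seed for weight initialization.
#' @return An untrained network (list as used by the internal [mlp] engine).
#' @export
build_fcnn <- function(input_dim = 46L, task = c("regression",
                                                 "classification"),
                       hidden_sizes = c(128L, 64L, 32L), output_dim = NULL,
                       seed = 1L) {
  task <- match.arg(task)
  if (length(hidden_sizes) != 3) {
    stop("hidden_sizes must have length 3 (four weight layers total)")
  }
  if (is.null(output_dim)) output_dim <- if (task == "regression") 1L else 2L
  .mlp_new(input_dim, hidden_sizes, output_dim, seed)
}

#' Fit a model to a feature matrix
#'
#' Standardizes every feature column on the training data (the scaler is
#' stored with the model and reapplied at prediction time), then fits the
#' family requested by the spec. Fitting is reproducible under the spec's
#' seed for every stochastic family.
#'
#' @param spec A `"model_spec"`.
#' @param X Numeric matrix, `n x p` (rows = molecules, columns = fingerprint
#'   digits).
#' @param y Numeric targets (regression) or character/factor labels
#'   (classification); no missing values.
#' @return A `"pofp_model"`: list with `spec`, `scaler`, the fitted object,
#'   `classes` (classification) and, for fcnn, the training `trace`.
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, !anyNA(X), !anyNA(y), length(y) == nrow(X))
  scaler <- .fit_scaler(X)
  Xs <- .apply_scaler(scaler, X)
  classes <- NULL
  if (spec$task == "classification") {
    y <- as.character(y)
    classes <- sort(unique(y))
    yf <- factor(y, levels = classes)
  } else {
    y <- as.numeric(y)
    if (stats::var(y) == 0) warning("zero-variance targets")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  y_scaler <- NULL
  fitted <- switch(spec$family,
    linear = {
      f <- stats::lm.fit(cbind(`(Intercept)` = 1, Xs), y)
      # rank-deficient designs (constant fingerprint columns) give NA
      # coefficients; those features carry no information, so drop them
      f$coefficients[is.na(f$coefficients)] <- 0
      f
    },
    svr_or_svm = {
      if (spec$task == "regression") {
        e1071::svm(x = Xs, y = y, scale = FALSE,
                   cost = .hp(spec, "cost", 1),
                   kernel = .hp(spec, "kernel", "radial"))
      } else {
        e1071::svm(x = Xs, y = yf, scale = FALSE,
                   cost = .hp(spec, "cost", 1),
                   kernel = .hp(spec, "kernel", "radial"))
      }
    },
    knn = {
      k <- .hp(spec, "k", 5L)
      if (spec$task == "regression") caret::knnreg(Xs, y, k = k)
      else caret::knn3(Xs, yf, k = k)
    },
    decision_tree = {
      df <- data.frame(.y = if (spec$task == "regression") y else yf, Xs)
      rpart::rpart(.y ~ ., data = df,
                   method = if (spec$task == "regression") "anova" else "class",
                   control = rpart::rpart.control(
                     cp = .hp(spec, "cp", 0.01),
                     minsplit = .hp(spec, "minsplit", 20L)))
    },
    random_forest = {
      randomForest::randomForest(
        x = Xs, y = if (spec$task == "regression") y else yf,
        ntree = .hp(spec, "ntree", 500L))
    },
    gradient_boosting = {
      params <- list(max_depth = .hp(spec, "max_depth", 6L),
                     eta = .hp(spec, "eta", 0.3), nthread = 1,
                     seed = spec$seed)
      if (spec$task == "regression") {
        params$objective <- "reg:squarederror"
        dtrain <- xgboost::xgb.DMatrix(Xs, label = y)
      } else {
        params$objective <- "multi:softprob"
        params$num_class <- length(classes)
        dtrain <- xgboost::xgb.DMatrix(Xs, label = as.integer(yf) - 1L)
      }
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = .hp(spec, "nrounds", 100L))
    },
    fcnn = {
      hidden <- .hp(spec, "hidden", c(128L, 64L, 32L))
      outdim <- if (spec$task == "regression") 1L else length(classes)
      net <- .mlp_new(ncol(Xs), hidden, outdim, spec$seed)
      Y <- if (spec$task == "regression") {
        # standardized targets keep the loss well conditioned at the default
        # learning rate; the scaler is stored and inverted at prediction time
        y_scaler <- list(center = mean(y), scale = max(stats::sd(y), 1e-12))
        matrix((y - y_scaler$center) / y_scaler$scale, ncol = 1)
      } else {
        oh <- matrix(0, length(yf), length(classes))
        oh[cbind(seq_along(yf), as.integer(yf))] <- 1
        oh
      }
      .mlp_fit(net, Xs, Y, task = spec$task,
               lr = .hp(spec, "lr", 1e-3),
               batch = .hp(spec, "batch", 32L),
               epochs = .hp(spec, "epochs", 500L),
               patience = .hp(spec, "patience", 25L),
               val_frac = .hp(spec, "val_frac", 0.1),
               seed = spec$seed)
    }
  )
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(spec = spec, scaler = scaler, y_scaler = y_scaler,
                 fit = if (spec$family == "fcnn") fitted$net else fitted,
                 trace = if (spec$family == "fcnn") fitted$trace else NULL,
                 classes = classes, input_dim = ncol(X)),
            class = "pofp_model")
}

#' @export
print.pofp_model <- function(x, ...) {
  cat("pofp_model:", x$spec$family, "/", x$spec$task,
      "(", x$input_dim, "features )\n")
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object A `"pofp_model"` from [fit_model()].
#' @param newdata Numeric matrix (or vector for one molecule) on the raw
#'   fingerprint scale; the stored scaler is applied internally.
#' @param type `"response"` (numeric prediction / class label) or `"prob"`
#'   (class-probability matrix; classification only — exact softmax for
#'   fcnn, the learner's probability estimate otherwise).
#' @param ... Unused.
#' @return Numeric vector, character vector of labels, or probability matrix.
#' @export
predict.pofp_model <- function(object, newdata, type = c("response", "prob"),
                               ...) {
  type <- match.arg(type)
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  stopifnot(ncol(X) == object$input_dim)
  Xs <- .apply_scaler(object$scaler, X)
  spec <- object$spec
  if (spec$task == "regression") {
    stopifnot(type == "response")
    return(switch(spec$family,
      linear = as.numeric(cbind(1, Xs) %*% object$fit$coefficients),
      svr_or_svm = as.numeric(stats::predict(object$fit, Xs)),
      knn = as.numeric(stats::predict(object$fit, Xs)),
      decision_tree = as.numeric(stats::predict(object$fit,
                                                data.frame(Xs))),
      random_forest = as.numeric(stats::predict(object$fit, Xs)),
      gradient_boosting = as.numeric(stats::predict(object$fit,
                                                    xgboost::xgb.DMatrix(Xs))),
      fcnn = as.numeric(.mlp_out(object$fit, Xs)) * object$y_scaler$scale +
        object$y_scaler$center
    ))
  }
  # classification
  prob <- switch(spec$family,
    svr_or_svm = NULL,
    knn = stats::predict(object$fit, Xs, type = "prob"),
    decision_tree = stats::predict(object$fit, data.frame(Xs),
                                   type = "prob"),
    random_forest = stats::predict(object$fit, Xs, type = "prob"),
    gradient_boosting = {
      p <- stats::predict(object$fit, xgboost::xgb.DMatrix(Xs))
      matrix(p, ncol = length(object$classes))
    },
    fcnn = .softmax(.mlp_out(object$fit, Xs))
  )
  if (!is.null(prob)) colnames(prob) <- object$classes
  if (type == "prob") {
    if (is.null(prob)) stop("probability output not available for family ",
                            spec$family)
    return(prob)
  }
  if (!is.null(prob)) {
    object$classes[max.col(prob, ties.method = "first")]
  } else {
    as.character(stats::predict(object$fit, Xs))
  }
}

#' Gradient of the model output with respect to the input fingerprint
#'
#' The input-gradient contract used by integrated gradients: for each row of
#' `newdata`, the derivative of the model output (regression prediction, or
#' for classification the softmax probability — or raw score — of a target
#' class) with respect to each of the input features, on the *raw* input
#' scale. Analytic for `fcnn` (exact backpropagation through the stored
#' scaler) and `linear`; central finite differences (step `1e-3` on the
#' standardized scale) for other differentiable-enough families.
#'
#' @param model A `"pofp_model"`.
#' @param newdata Matrix (or single vector) of inputs, raw scale.
#' @param target For classification, the class label or index whose output is
#'   differentiated; ignored for regression.
#' @param of For classification: `"prob"` (softmax probability, default) or
#'   `"logit"` (raw class score). Ignored for regression.
#' @return Matrix `nrow(newdata) x input_dim` of gradients.
#' @export
model_gradient <- function(model, newdata, target = NULL,
                           of = c("prob", "logit")) {
  of <- match.arg(of)
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  spec <- model$spec
  k <- 1L
  if (spec$task == "classification") {
    stopifnot(!is.null(target))
    k <- if (is.character(target)) match(target, model$classes) else
      as.integer(target)
    if (is.na(k) || k < 1 || k > length(model$classes)) {
      stop("unknown target class: ", target)
    }
  }
  if (spec$family == "fcnn") {
    Xs <- .apply_scaler(model$scaler, X)
    gof <- if (spec$task == "regression") "value" else
      if (of == "prob") "prob" else "logit"
    g <- .mlp_input_gradient(model$fit, Xs, on = k, of = gof)
    if (spec$task == "regression") g <- g * model$y_scaler$scale
    return(sweep(g, 2, model$scaler$scale, "/"))
  }
  if (spec$family == "linear") {
    co <- model$fit$coefficients[-1] / model$scaler$scale
    return(matrix(co, nrow = nrow(X), ncol = length(co), byrow = TRUE))
  }
  # finite differences on the standardized scale for the rest
  h <- 1e-3 * model$scaler$scale
  eval_out <- function(M) {
    if (spec$task == "regression") predict(model, M) else
      predict(model, M, type = "prob")[, k]
  }
  g <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    Xp <- X; Xp[, j] <- Xp[, j] + h[j]
    Xm <- X; Xm[, j] <- Xm[, j] - h[j]
    g[, j] <- (eval_out(Xp) - eval_out(Xm)) / (2 * h[j])
  }
  g
}

#' Cross-validate a model spec
#'
#' Splits the data into `folds` folds by seeded shuffling (stratified by
#' label for classification; stratification is relaxed with a warning when a
#' class has fewer members than folds), fits on each training portion and
#' evaluates on the held-out fold. Fold assignment is a pure function of
#' `seed`, `folds` and the data size, so repeated calls are identical.
#'
#' @param spec A `"model_spec"`.
#' @param X Feature matrix.
#' @param y Targets or labels.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @return A list of class `"cv_result"`: `per_fold` (data.frame of metrics
#'   by fold), `mean` (named list of fold-averaged metrics), `folds`
#'   (the fold assignment vector), `confusion` (summed over folds,
#'   classification only).
#' @export
cross_validate <- function(spec, X, y, folds = 5L, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= folds)
  fold_id <- .make_folds(y, n, folds, seed,
                         stratify = spec$task == "classification")
  per_fold <- NULL
  conf_sum <- NULL
  labels <- if (spec$task == "classification") sort(unique(as.character(y)))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    m <- fit_model(spec, X[tr, , drop = FALSE], y[tr])
    pred <- predict(m, X[!tr, , drop = FALSE])
    if (spec$task == "regression") {
      met <- evaluate_regression(y[!tr], pred)
      per_fold <- rbind(per_fold, data.frame(fold = f, r2 = met$r2,
                                             mae = met$mae, mse = met$mse))
    } else {
      met <- evaluate_classification(as.character(y[!tr]), pred,
                                     labels = labels)
      per_fold <- rbind(per_fold,
                        data.frame(fold = f, accuracy = met$accuracy,
                                   weighted_f1 = met$weighted_f1))
      conf_sum <- if (is.null(conf_sum)) met$confusion else
        conf_sum + met$confusion
    }
  }
  means <- as.list(colMeans(per_fold[, -1, drop = FALSE]))
  structure(list(per_fold = per_fold, mean = means, folds = fold_id,
                 confusion = conf_sum, spec = spec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result (", x$spec$family, "/", x$spec$task, "), ",
      max(x$per_fold$fold), " folds; mean: ",
      paste(names(x$mean), round(unlist(x$mean), 4), sep = "=",
            collapse = "  "), "\n", sep = "")
  invisible(x)
}

.make_folds <- function(y, n, folds, seed, stratify) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  fold_id <- integer(n)
  if (stratify) {
    y <- as.character(y)
    small <- names(which(table(y) < folds))
    if (length(small) > 0) {
      warning("class(es) with fewer members than folds: ",
              paste(small, collapse = ", "), "; stratification relaxed")
    }
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    fold_id[sample.int(n)] <- rep_len(seq_len(folds), n)
  }
  fold_id
}
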