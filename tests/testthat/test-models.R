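test_that("regression metrics match their definitions", {
  y <- c(1, 2, 3, 4)
  m <- evaluate_regression(y, y)
  expect_equal(m$r2, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$mse, 0)
  # independent recomputation on random data
  set.seed(3)
  yt <- rnorm(50); yp <- yt + rnorm(50, 0, 0.3)
  m2 <- evaluate_regression(yt, yp)
  expect_equal(m2$mae, mean(abs(yt - yp)), tolerance = 1e-12)
  expect_equal(m2$mse, mean((yt - yp)^2), tolerance = 1e-12)
  expect_equal(m2$r2, 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2),
               tolerance = 1e-12)
  # a constant predictor can never beat the mean
  expect_lte(evaluate_regression(yt, rep(0.2, 50))$r2, 0)
  expect_warning(evaluate_regression(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("classification metrics match a hand-computed fixture", {
  m <- evaluate_classification(c("A", "B", "A", "B"), c("A", "A", "B", "B"))
  expect_equal(m$accuracy, 0.5)
  # 3-class, 10 samples, worked by hand:
  # A: P=3/4 R=3/4 F1=0.75; B: P=2/3 R=2/3 F1=2/3; C: P=2/3 R=2/3 F1=2/3
  # weighted F1 = (4*0.75 + 3*2/3 + 3*2/3)/10 = 0.7
  yt <- c("A", "A", "A", "A", "B", "B", "B", "C", "C", "C")
  yp <- c("A", "A", "B", "A", "B", "B", "C", "C", "C", "A")
  m3 <- evaluate_classification(yt, yp)
  expect_equal(m3$accuracy, 0.7)
  expect_equal(m3$weighted_f1, 0.7)
  expect_equal(m3$per_class$f1, c(0.75, 2 / 3, 2 / 3))
  # occupied rows of the normalized confusion matrix sum to 1
  expect_equal(unname(rowSums(m3$confusion_normalized)), rep(1, 3),
               tolerance = 1e-9)
  expect_equal(sum(m3$confusion), 10)
})

test_that("fcnn scaffold respects architecture and seeding", {
  n1 <- build_fcnn(46, "regression", c(128, 64, 32), seed = 5)
  expect_equal(ncol(n1$W[[4]]), 1)
  expect_equal(vapply(n1$W, nrow, integer(1)), c(46L, 128L, 64L, 32L))
  n2 <- build_fcnn(46, "regression", c(128, 64, 32), seed = 5)
  expect_identical(n1$W, n2$W)
  expect_error(build_fcnn(46, "regression", c(10, 10)), "length 3")
})

test_that("fcnn input gradients match central finite differences", {
  m <- small_fcnn_regression()
  set.seed(21)
  for (r in 1:10) {
    x <- rnorm(46)
    g <- model_gradient(m, x)
    h <- 1e-4
    gn <- vapply(1:46, function(j) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      (predict(m, xp) - predict(m, xm)) / (2 * h)
    }, numeric(1))
    denom <- pmax(abs(gn), 1e-6)
    expect_lt(max(abs(g - gn) / denom), 1e-4)
  }
})

test_that("linear regression recovers a noiseless linear law exactly", {
  set.seed(8)
  X <- matrix(rnorm(120 * 46), 120, 46)
  w <- rnorm(46)
  y <- as.numeric(X %*% w) + 1.5
  m <- fit_model(model_spec("linear", "regression"), X, y)
  pred <- predict(m, X)
  expect_lt(max(abs(pred - y)), 1e-8)
  expect_lt(evaluate_regression(y, pred)$mae, 1e-6)
  expect_equal(evaluate_regression(y, pred)$r2, 1, tolerance = 1e-12)
  expect_error(fit_model(model_spec("linear", "classification")), "regression")
})

test_that("1-nearest-neighbour memorizes its training set", {
  set.seed(9)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- rnorm(60)
  m <- fit_model(model_spec("knn", "regression", list(k = 1L)), X, y)
  expect_equal(evaluate_regression(y, predict(m, X))$mae, 0,
               tolerance = 1e-12)
})

test_that("every family fits and predicts on both tasks", {
  set.seed(10)
  X <- matrix(rnorm(80 * 8), 80, 8)
  y <- as.numeric(X %*% rnorm(8))
  ycls <- ifelse(X[, 1] > 0, "pos", "neg")
  fams_reg <- c("linear", "svr_or_svm", "knn", "decision_tree",
                "random_forest", "gradient_boosting", "fcnn")
  for (fam in fams_reg) {
    hp <- if (fam == "fcnn") list(epochs = 10) else list()
    m <- fit_model(model_spec(fam, "regression", hp, seed = 2), X, y)
    p <- predict(m, X)
    expect_length(p, 80)
    expect_false(anyNA(p), info = fam)
  }
  for (fam in setdiff(fams_reg, "linear")) {
    hp <- if (fam == "fcnn") list(epochs = 10) else list()
    m <- fit_model(model_spec(fam, "classification", hp, seed = 2), X, ycls)
    p <- predict(m, X)
    expect_true(all(p %in% c("pos", "neg")), info = fam)
  }
})

test_that("predictions are deterministic after fitting", {
  set.seed(12)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- rnorm(50)
  m1 <- fit_model(model_spec("random_forest", "regression", seed = 4), X, y)
  m2 <- fit_model(model_spec("random_forest", "regression", seed = 4), X, y)
  expect_identical(predict(m1, X), predict(m2, X))
  mf1 <- fit_model(model_spec("fcnn", "regression", list(epochs = 15),
                              seed = 4), X, y)
  mf2 <- fit_model(model_spec("fcnn", "regression", list(epochs = 15),
                              seed = 4), X, y)
  expect_identical(predict(mf1, X), predict(mf2, X))
})

test_that("cross-validation folds are seeded, stratified and reproducible", {
  set.seed(13)
  X <- matrix(rnorm(100 * 5), 100, 5)
  ycls <- rep(c("a", "b"), each = 50)
  cv1 <- cross_validate(model_spec("decision_tree", "classification"),
                        X, ycls, folds = 5, seed = 77)
  cv2 <- cross_validate(model_spec("decision_tree", "classification"),
                        X, ycls, folds = 5, seed = 77)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$per_fold, cv2$per_fold)
  # stratification: every fold carries both classes in equal shares
  for (f in 1:5) {
    expect_equal(as.integer(table(ycls[cv1$folds == f])), c(10L, 10L))
  }
  # a class smaller than the fold count relaxes stratification with a warning
  ysmall <- c(rep("a", 97), rep("b", 3))
  expect_warning(cross_validate(model_spec("decision_tree", "classification"),
                                X, ysmall, folds = 5, seed = 1),
                 "stratification relaxed")
})

test_that("perfectly separable classes cross-validate to accuracy 1", {
  set.seed(14)
  X <- rbind(matrix(rnorm(40 * 4, mean = 5), 40, 4),
             matrix(rnorm(40 * 4, mean = -5), 40, 4))
  y <- rep(c("hi", "lo"), each = 40)
  cv <- cross_validate(model_spec("random_forest", "classification",
                                  list(ntree = 100), seed = 3),
                       X, y, folds = 5, seed = 3)
  expect_equal(cv$mean$accuracy, 1)
  expect_equal(cv$mean$weighted_f1, 1)
})

test_that("cross-validated MAE under Gaussian noise approaches sigma*sqrt(2/pi)", {
  set.seed(15)
  n <- 2000; sigma <- 0.1
  X <- matrix(rnorm(n * 10), n, 10)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(n, 0, sigma)
  cv <- cross_validate(model_spec("linear", "regression"), X, y,
                       folds = 5, seed = 5)
  expect_equal(cv$mean$mae, sigma * sqrt(2 / pi), tolerance = 0.15)
})

test_that("fcnn training loss decreases under the default schedule", {
  ds <- syn700()
  y <- wavelength_to_energy(ds$records$lambda_solid_nm)
  m <- fit_model(model_spec("fcnn", "regression", seed = 42),
                 ds$fingerprints, y)
  tr <- m$trace$train_loss
  expect_lt(tr[length(tr)], tr[1] / 10)
  # epoch-mean loss is non-increasing up to minibatch jitter: any upward
  # excursion from the running minimum stays small relative to the start
  expect_true(all(tr - cummin(tr) < 0.05 * tr[1]))
})
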