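# fine-discretization trapezoid oracle for the path integral, built directly
# on the gradient contract (independent of integrated_gradient's own loop)
ig_oracle <- function(model, x, baseline, n = 10000, target = NULL) {
  alpha <- seq(0, 1, length.out = n)
  pts <- outer(alpha, x - baseline) +
    matrix(baseline, n, length(x), byrow = TRUE)
  g <- model_gradient(model, pts, target = target)
  w <- rep(1, n); w[c(1, n)] <- 0.5; w <- w / (n - 1)
  (x - baseline) * colSums(g * w)
}

test_that("path points sample the straight line inclusively", {
  x <- c(1, 2, 3); b <- c(0, 0, 1)
  p2 <- path_points(x, b, 2)
  expect_equal(p2[1, ], b)
  expect_equal(p2[2, ], x)
  p3 <- path_points(x, b, 3)
  expect_equal(p3[2, ], (x + b) / 2)
  same <- path_points(x, x, 5)
  expect_true(all(apply(same, 1, function(r) all(r == x))))
  expect_equal(nrow(path_points(x, b, 100)), 100)
})

test_that("linear models give exact closed-form attributions", {
  set.seed(31)
  X <- matrix(rnorm(100 * 46), 100, 46)
  w <- rnorm(46)
  y <- as.numeric(X %*% w) + 2
  m <- fit_model(model_spec("linear", "regression"), X, y)
  x <- rnorm(46); base <- rnorm(46)
  un <- integrated_gradient(m, x, ig_config(baseline = base,
                                            variant = "unnormalized_eq4"))
  expect_equal(unname(un$attributions), w, tolerance = 1e-7)
  no <- integrated_gradient(m, x, ig_config(baseline = base,
                                            variant = "normalized_eq3"))
  expect_equal(unname(no$attributions), w * (x - base), tolerance = 1e-7)
  # completeness is exact for a linear map
  expect_equal(sum(no$attributions),
               no$model_output_at_x - no$model_output_at_baseline,
               tolerance = 1e-6)
})

test_that("trained-network attributions converge to the path-integral oracle", {
  m <- small_fcnn_regression()
  set.seed(32)
  x <- rnorm(46); base <- rep(0, 46)
  ig <- integrated_gradient(m, x, ig_config(baseline = base, n_steps = 100))
  ora <- ig_oracle(m, x, base)
  # a ReLU network is piecewise linear, so the trapezoid error decays like
  # 1/n_steps at gradient kinks; absolute agreement is the honest contract
  expect_lt(max(abs(unname(ig$attributions) - ora)), 1e-2)
  # discretization refinement is Cauchy: successive differences shrink
  a100 <- unname(integrated_gradient(m, x, ig_config(baseline = base,
                                                     n_steps = 100))$attributions)
  a1k <- unname(integrated_gradient(m, x, ig_config(baseline = base,
                                                    n_steps = 1000))$attributions)
  a10k <- unname(integrated_gradient(m, x, ig_config(baseline = base,
                                                     n_steps = 10000))$attributions)
  expect_lt(max(abs(a1k - ora)), 1e-3)
  expect_lt(max(abs(a10k - a1k)), max(abs(a1k - a100)) + 1e-12)
})

test_that("normalized attributions satisfy completeness on trained networks", {
  m <- syn700_reg_model()
  fp <- syn700()$fingerprints
  base <- rep(0, 46)
  for (i in 1:5) {
    x <- as.numeric(fp[i, ])
    ig <- integrated_gradient(m, x, ig_config(baseline = base))
    expect_lt(abs(sum(ig$attributions) -
                    (ig$model_output_at_x - ig$model_output_at_baseline)),
              1e-2)
  }
})

test_that("fraction-of-total attributions sum to one or refuse", {
  m <- small_fcnn_regression()
  set.seed(34)
  x <- rnorm(46)
  fr <- integrated_gradient(m, x, ig_config(variant = "fraction_of_total"))
  expect_equal(sum(fr$attributions), 1, tolerance = 1e-12)
  # x == baseline: attributions are all zero, so the fraction is undefined
  expect_error(integrated_gradient(m, rep(0, 46),
                                   ig_config(variant = "fraction_of_total")),
               "sum to 0")
})

test_that("zero path degenerates to zero attributions and equal outputs", {
  m <- small_fcnn_regression()
  x <- rep(1.3, 46)
  ig <- integrated_gradient(m, x, ig_config(baseline = x))
  expect_equal(unname(ig$attributions), rep(0, 46))
  expect_equal(ig$model_output_at_x, ig$model_output_at_baseline)
  # features sitting at the baseline value always get zero attribution
  x2 <- rep(0, 46); x2[c(3, 46)] <- c(1, 12)
  ig2 <- integrated_gradient(m, x2, ig_config(baseline = rep(0, 46)))
  expect_true(all(ig2$attributions[-c(3, 46)] == 0))
})

test_that("sweeps tabulate attributions along a feature grid", {
  m <- small_fcnn_regression()
  tmpl <- rep(0, 46); tmpl[10] <- 1
  cfg <- ig_config(variant = "unnormalized_eq4")
  sw <- ig_sweep(m, tmpl, 46, c(6, 12, 18), cfg)
  expect_equal(nrow(sw), 3)
  expect_equal(sw$value, c(6, 12, 18))
  expect_true(all(c("s10", "s46") %in% names(sw)))
  # a single-value sweep equals one direct call
  one <- ig_sweep(m, tmpl, 46, 12, cfg)
  x <- tmpl; x[46] <- 12
  direct <- integrated_gradient(m, x, cfg)
  expect_equal(one$s46, unname(direct$attributions[46]))
})

test_that("classification attribution targets the predicted class", {
  mc <- syn700_class_model()
  res <- classify_and_attribute(mc, TPE_SMILES)
  expect_true(res$predicted_class %in%
                c("AIE", "ACQ", "TADF", "AIDF", "RTP"))
  expect_equal(res$ig$config$target, res$predicted_class)
  # with the all-zero baseline, only active digits can carry attribution
  act <- which(as.numeric(res$fingerprint) != 0)
  expect_true(all(res$ig$attributions[-act] == 0))
  f <- tempfile(fileext = ".csv")
  write_ig_csv(res$ig, f)
  expect_equal(nrow(read.csv(f)), 46)
  unlink(f)
})
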