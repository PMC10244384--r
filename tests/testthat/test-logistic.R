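fdef7 <- feature_definition(c("R", "N", "D", "G", "I", "L", "F"))

test_that("all-zero features give the class prevalence as fitted probability", {
  X <- matrix(0, 40, 3, dimnames = list(NULL, c("R", "N", "D")))
  y <- rep(c(1, 0), c(10, 30))
  fit <- fit_logistic(X, y)
  p <- predict_avidity(fit, X)$p
  expect_equal(p, rep(0.25, 40), tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("R", "N")))
  expect_error(fit_logistic(X, rep(1, 10)), "both")
  expect_error(fit_logistic(X[1:2, ], c(0, 1)), "fewer")
})

test_that("prediction follows the logistic link with a strict threshold", {
  m <- structure(list(b0 = 0, weights = c(R = 1, N = -1),
                      fdef = NULL, threshold = 0.5, separable = FALSE,
                      converged = TRUE, ridge = 0, n = 10),
                 class = "avidity_logistic")
  out <- predict_avidity(m, c(R = 0, N = 0))
  expect_equal(out$p, 0.5)
  expect_equal(out$label, 0L)  # p == threshold calls low
  # monotone in a positive-weight feature
  ps <- predict_avidity(m, cbind(R = seq(0, 5, 1), N = 0))$p
  expect_true(all(diff(ps) > 0))
  # saturation
  m$b0 <- 50
  expect_equal(predict_avidity(m, c(R = 0, N = 0))$p, 1, tolerance = 1e-10)
  expect_error(predict_avidity(m, c(A = 1)), "dimension")
})

test_that("log-odds equal the linear predictor", {
  set.seed(71)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    m <- structure(list(b0 = rnorm(1), weights = rnorm(k), fdef = NULL,
                        threshold = 0.5, separable = FALSE, converged = TRUE,
                        ridge = 0, n = 1),
                   class = "avidity_logistic")
    x <- rnorm(k)
    p <- predict_avidity(m, matrix(x, 1))$p
    expect_equal(log(p / (1 - p)), m$b0 + sum(m$weights * x),
                 tolerance = 1e-10)
  }
})

test_that("separated data get a finite tiny-ridge fit and a flag", {
  X <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 1,
              dimnames = list(NULL, "R"))
  y <- rep(c(1, 0), c(10, 10))
  fit <- fit_logistic(X, y)
  expect_true(fit$separable)
  expect_true(is.finite(fit$b0) && all(is.finite(fit$weights)))
  # still classifies perfectly
  expect_equal(predict_avidity(fit, X)$label, y)
})

test_that("planted logistic weights are recovered on a large coupled panel", {
  truth_b0 <- -1.5
  truth_w <- c(2, 1.5, -1, 1, 2, -1.5, 1)
  gp <- generate_logistic_panel(2000, fdef7, truth_b0, truth_w, seed = 72)
  fit <- fit_logistic(gp$features, gp$panel$label, fdef = fdef7)
  # compare against truth within 3 standard errors from the information matrix
  g <- glm(gp$panel$label ~ gp$features, family = binomial())
  se <- summary(g)$coefficients[, "Std. Error"]
  est <- c(fit$b0, fit$weights)
  expect_true(all(abs(est - c(truth_b0, truth_w)) <= 3 * se))
})
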