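test_that("noiseless linear tables are recovered exactly", {
  tab <- generate_contacts(contact_spec(10, k = -62.89, gamma = 2.647,
                                        delta = 8.747, noise_sd = 0, seed = 3))
  m <- fit_contact_model(tab)
  expect_equal(m$k, -62.89, tolerance = 1e-8)
  expect_equal(m$gamma, 2.647, tolerance = 1e-8)
  expect_equal(m$delta, 8.747, tolerance = 1e-8)
  expect_equal(m$diagnostics$r_squared, 1)
  expect_equal(m$diagnostics$n, 10)
})

test_that("OLS matches the closed-form normal-equations oracle", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    tab <- data.frame(complex_id = seq_len(n),
                      n_apolar = sample(10:50, n, replace = TRUE),
                      n_polar = sample(1:15, n, replace = TRUE))
    tab$halflife_s <- -40 + 2 * tab$n_apolar + 7 * tab$n_polar + rnorm(n, 0, 10)
    if (length(unique(tab$n_apolar)) < 2 || length(unique(tab$n_polar)) < 2) next
    m <- try(fit_contact_model(tab), silent = TRUE)
    if (inherits(m, "try-error")) next  # collinear draw
    beta <- oracle_ols(cbind(1, tab$n_apolar, tab$n_polar), tab$halflife_s)
    expect_equal(c(m$k, m$gamma, m$delta), unname(beta), tolerance = 1e-9)
    # residuals orthogonal to regressors
    resid <- tab$halflife_s - predict_halflife(m, tab$n_apolar, tab$n_polar)
    expect_lt(abs(sum(resid)), 1e-6 * n)
    expect_lt(abs(sum(resid * tab$n_apolar)), 1e-6 * sum(abs(tab$n_apolar)))
    expect_lt(abs(sum(resid * tab$n_polar)), 1e-6 * sum(abs(tab$n_polar)))
  }
})

test_that("noisy estimates are unbiased over replicates", {
  reps <- 500
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    tab <- generate_contacts(contact_spec(30, noise_sd = 5, seed = 6000 + r))
    m <- fit_contact_model(tab)
    est[r, ] <- c(m$k, m$gamma, m$delta)
  }
  truth <- c(-62.89, 2.647, 8.747)
  for (j in 1:3) {
    se <- stats::sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - truth[j]), 3 * se + 1e-12)
  }
})

test_that("rank-deficient designs fail with the offending column named", {
  tab <- data.frame(complex_id = 1:5, n_apolar = rep(20, 5),
                    n_polar = 1:5, halflife_s = rnorm(5))
  expect_error(fit_contact_model(tab), "n_apolar")
  tab2 <- data.frame(complex_id = 1:2, n_apolar = 1:2, n_polar = 2:1,
                     halflife_s = rnorm(2))
  expect_error(fit_contact_model(tab2), "at least 3")
})

test_that("prediction is the plain linear evaluation", {
  m <- contact_model(-62.89, 2.647, 8.747)
  expect_equal(as.numeric(predict_halflife(m, 30, 5)), 60.255)
  expect_equal(as.numeric(predict_halflife(m, 0, 0)), m$k)
  expect_true(attr(predict_halflife(m, 0, 0), "below_zero"))
  # additivity
  p1 <- as.numeric(predict_halflife(m, 12, 3))
  p2 <- as.numeric(predict_halflife(m, 17, 9))
  expect_equal(p2 - p1, m$gamma * 5 + m$delta * 6)
})
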