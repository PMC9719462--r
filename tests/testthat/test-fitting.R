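# Simulate a clustered three-level response from known logit coefficients.
sim_mnl_data <- function(n_pat, visits, beta2, beta3, seed) {
  set.seed(seed)
  n <- n_pat * visits
  df <- data.frame(patient_id = rep(seq_len(n_pat), each = visits),
                   x = rnorm(n), w = rnorm(n))
  eta2 <- beta2[1] + beta2[2] * df$x + beta2[3] * df$w
  eta3 <- beta3[1] + beta3[2] * df$x + beta3[3] * df$w
  den <- 1 + exp(eta2) + exp(eta3)
  u <- runif(n)
  df$mo <- ifelse(u < exp(eta2) / den, 2L,
                  ifelse(u < (exp(eta2) + exp(eta3)) / den, 3L, 1L))
  df
}

test_that("pooled estimates agree with an independent multinomial fitter", {
  skip_if_not_installed("nnet")
  df <- sim_mnl_data(600, 3, c(-1, 0.8, -0.5), c(-2, 1.5, 0.3), seed = 5)
  fit <- fit_mnl_independence(df, "mo", c("x", "w"))
  ref <- nnet::multinom(factor(mo) ~ x + w, df, trace = FALSE, reltol = 1e-12)
  expect_equal(unname(fit$model$beta2), unname(coef(ref)["2", ]),
               tolerance = 1e-5)
  expect_equal(unname(fit$model$beta3), unname(coef(ref)["3", ]),
               tolerance = 1e-5)
  expect_true(fit$converged)
  expect_true(all(eigen(fit$vcov_robust, only.values = TRUE)$values > -1e-12))
})

test_that("estimates recover the generating coefficients within 3 robust SE", {
  b2 <- c(-1, 0.8, -0.5); b3 <- c(-2, 1.5, 0.3)
  df <- sim_mnl_data(1500, 3, b2, b3, seed = 17)
  fit <- fit_mnl_independence(df, "mo", c("x", "w"))
  se <- sqrt(diag(fit$vcov_robust))
  expect_true(all(abs(fit$theta - c(b2, b3)) < 3 * se))
})

test_that("estimates are invariant to observation shuffling", {
  df <- sim_mnl_data(200, 3, c(-0.5, 0.6, 0), c(-1.5, 1, 0.5), seed = 8)
  fit <- fit_mnl_independence(df, "mo", c("x", "w"))
  set.seed(1)
  fit2 <- fit_mnl_independence(df[sample(nrow(df)), ], "mo", c("x", "w"))
  expect_equal(fit$theta, fit2$theta, tolerance = 1e-10)
  expect_equal(fit$vcov_robust, fit2$vcov_robust, tolerance = 1e-8)
})

test_that("duplicating every cluster halves the sandwich and doubles the information", {
  df <- sim_mnl_data(250, 3, c(-0.5, 0.6, 0), c(-1.5, 1, 0.5), seed = 9)
  df2 <- rbind(df, transform(df, patient_id = patient_id + 10000L))
  f1 <- fit_mnl_independence(df, "mo", c("x", "w"))
  f2 <- fit_mnl_independence(df2, "mo", c("x", "w"))
  expect_equal(f2$theta, f1$theta, tolerance = 1e-8)
  expect_equal(f2$vcov_robust, f1$vcov_robust / 2, tolerance = 1e-6)
  expect_equal(f2$information, f1$information * 2, tolerance = 1e-6)
})

test_that("with one observation per cluster the sandwich is the classic HC covariance", {
  df <- sim_mnl_data(400, 1, c(-0.5, 0.6, 0), c(-1.5, 1, 0.5), seed = 10)
  fit <- fit_mnl_independence(df, "mo", c("x", "w"))
  # rebuild the HC estimator from per-observation scores
  X <- cbind(1, df$x, df$w)
  p <- ncol(X)
  P <- vapply(2:3, function(k) {
    e2 <- exp(X %*% fit$theta[1:3]); e3 <- exp(X %*% fit$theta[4:6])
    drop(if (k == 2) e2 else e3) / drop(1 + e2 + e3)
  }, numeric(nrow(df)))
  S <- cbind(X * ((df$mo == 2) - P[, 1]), X * ((df$mo == 3) - P[, 2]))
  hc <- fit$vcov_model %*% crossprod(S) %*% fit$vcov_model
  expect_equal(unname(fit$vcov_robust), unname(hc), tolerance = 1e-8)
})

test_that("symmetric null data give near-zero slopes", {
  # balanced levels, covariate orthogonal to the outcome by construction
  df <- data.frame(patient_id = 1:300,
                   mo = rep(1:3, 100),
                   x = rep(c(-1, 1), 150))
  fit <- fit_mnl_independence(df, "mo", "x")
  expect_lt(abs(fit$theta[2]), 1e-6)
  expect_lt(abs(fit$theta[4]), 1e-6)
})

test_that("QIC approaches AIC on independent data and is finite", {
  df <- sim_mnl_data(1200, 1, c(-1, 0.8, 0), c(-2, 1.5, 0), seed = 11)
  fit <- fit_mnl_independence(df, "mo", c("x", "w"))
  aic <- -2 * fit$loglik + 2 * length(fit$theta)
  expect_lt(abs(qic(fit) - aic) / aic, 0.05)
  expect_true(is.finite(qic(fit)))
})

test_that("a pure-noise covariate usually increases QIC", {
  worse <- 0
  for (r in 1:20) {
    df <- sim_mnl_data(300, 2, c(-1, 0.8, 0), c(-2, 1.2, 0), seed = 100 + r)
    set.seed(500 + r)
    df$noise <- rnorm(nrow(df))
    f0 <- fit_mnl_independence(df, "mo", "x")
    f1 <- fit_mnl_independence(df, "mo", c("x", "noise"))
    worse <- worse + (qic(f1) > qic(f0))
  }
  expect_gt(worse, 10)
})

test_that("backward elimination keeps significant covariates and drops noise", {
  df <- sim_mnl_data(800, 3, c(-1, 0.9, 0), c(-2, 1.4, 0), seed = 13)
  set.seed(77)
  df$noise <- rnorm(nrow(df))
  fit <- backward_eliminate(df, "mo", c("x", "w", "noise"))
  expect_true("x" %in% fit$covariates)
  expect_true(all(fit$wald$p_value <= 0.05))
  # a fully significant model is returned unchanged
  fit2 <- backward_eliminate(df, "mo", "x")
  expect_length(fit2$eliminated, 0L)
})

test_that("quasi-separation is flagged, not fatal", {
  df <- data.frame(patient_id = 1:80,
                   x = rep(c(0, 1), each = 40),
                   mo = rep(c(1L, 2L), each = 40))
  df$mo[c(1, 41)] <- c(2L, 1L)  # near-perfect separation
  df$mo[1:4] <- 3L              # a few level-3s so both logits exist
  fit <- suppressWarnings(fit_mnl_independence(df, "mo", "x",
                                               coef_bound = 5))
  expect_type(fit$separation, "logical")
})

test_that("an absent level yields a pinned -Inf logit and zero probability", {
  df <- data.frame(patient_id = 1:200, x = rnorm(200),
                   mo = rep(1:2, 100))
  fit <- fit_mnl_independence(df, "mo", "x")
  expect_equal(fit$absent_level, 3L)
  expect_equal(unname(fit$model$beta3["(Intercept)"]), -Inf)
  p <- mnl_probabilities(fit$model, c(x = 0))
  expect_equal(unname(p[1, "p3"]), 0)
})

test_that("OLS refits recover generating equations", {
  set.seed(3)
  n <- 2000
  df <- data.frame(patient_id = 1:n, cat_total = sample(0:40, n, TRUE),
                   age = runif(n, 0, 90))
  # noiseless linear data: exact recovery
  df$utility <- 1.26848 - 0.02159 * df$cat_total - 0.00188 * df$age
  sp <- fit_ols(df, c("cat_total", "age"))
  expect_equal(sp$intercept, 1.26848, tolerance = 1e-10)
  expect_equal(unname(sp$slopes), c(-0.02159, -0.00188), tolerance = 1e-10)
  # with noise: intercept recovered within simulation tolerance
  df$utility <- df$utility + rnorm(n, 0, 0.1)
  sp2 <- fit_ols(df, c("cat_total", "age"))
  expect_lt(abs(sp2$intercept - 1.26848), 0.02)
  # intercept-only fit is the sample mean
  sp3 <- fit_ols(df, character(0))
  expect_equal(sp3$intercept, mean(df$utility))
  expect_error(fit_ols(transform(df, utility = NA), "age"), "utilities")
})
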