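test_that("multinomial probabilities match a naive direct-exponentiation oracle", {
  set.seed(1)
  for (i in 1:50) {
    cv <- c("a", "b")
    m <- mnl_dimension_model(cv, beta2 = rnorm(3), beta3 = rnorm(3))
    x <- c(a = rnorm(1), b = rnorm(1))
    e2 <- exp(sum(m$beta2 * c(1, x)))
    e3 <- exp(sum(m$beta3 * c(1, x)))
    naive <- c(1, e2, e3) / (1 + e2 + e3)
    expect_equal(unname(drop(mnl_probabilities(m, x))), naive,
                 tolerance = 1e-10)
  }
})

test_that("zero coefficients give uniform probabilities and rows sum to one", {
  m <- mnl_dimension_model("x", beta2 = c(0, 0), beta3 = c(0, 0))
  expect_equal(unname(drop(mnl_probabilities(m, c(x = 3)))), rep(1 / 3, 3))
  set.seed(2)
  rows <- make_cat_rows(500)
  spec <- builtin_model("taiwan_mlr_items")
  for (d in eq5d_dimensions()) {
    p <- mnl_probabilities(spec$dimensions[[d]], rows)
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("saturating logits evaluate overflow-free at the published magnitudes", {
  # pain/discomfort items model carries a 104.76 slope on breathlessness
  spec <- builtin_model("taiwan_mlr_items")
  x <- data.frame(q1 = 5, q3 = 0, q4 = 5, q6 = 5, q8 = 5, age = 40,
                  sex_code = 0)
  p <- mnl_probabilities(spec$dimensions$pd, x)
  expect_true(all(is.finite(p)))
  expect_equal(unname(p[1, "p3"]), 1)
})

test_that("state prediction is argmax with ties resolved to the lower level", {
  # equal eta2 = eta3 > 0 makes p2 = p3 > p1: level 2 must win
  m <- mnl_dimension_model("x", beta2 = c(1, 0), beta3 = c(1, 0))
  p <- drop(mnl_probabilities(m, c(x = 0)))
  expect_equal(p[["p2"]], p[["p3"]])
  dims <- stats::setNames(rep(list(m), 5), eq5d_dimensions())
  spec <- mlr_response_spec("tie", dims)
  expect_equal(unname(predict_state_mlr(spec, data.frame(x = 0))[1, ]),
               rep(2L, 5))
})

test_that("a zero CAT total maps to full health under the total-score model", {
  st <- predict_state_mlr("taiwan_mlr_total",
                          data.frame(cat_total = 0, age = 60, sex_code = 0))
  expect_equal(unname(st[1, ]), rep(1L, 5))
})

test_that("predicted levels are monotone in the CAT total sweep", {
  for (sex in 0:1) {
    st <- predict_state_mlr("taiwan_mlr_total",
                            data.frame(cat_total = 0:40, age = 70,
                                       sex_code = sex))
    for (d in eq5d_dimensions())
      expect_false(is.unsorted(st[, d]), info = paste(d, "sex", sex))
  }
})

test_that("response-mapped utilities live in the 243-value tariff set", {
  rows <- make_cat_rows(400, seed = 4)
  u <- predict_utility_mlr("taiwan_mlr_items", rows)
  tariff_values <- utility_from_state(all_eq5d_states())
  expect_true(all(u %in% tariff_values))
  expect_equal(utility_from_state(attr(u, "state")), as.numeric(u))
})

test_that("direct OLS equations reproduce hand-evaluated values", {
  z <- data.frame(q3 = 0, q5 = 0, q6 = 0, q8 = 0)
  f <- data.frame(q3 = 5, q5 = 5, q6 = 5, q8 = 5)
  expect_equal(predict_utility_ols("hoyle_m3", z), 0.9831816)
  expect_equal(predict_utility_ols("hoyle_m3", f), 0.3769831)
  expect_equal(predict_utility_ols("lim_total",
                                   data.frame(cat_total = 0, age = 0)),
               1.1376)
  expect_equal(predict_utility_ols("lim_total_mod",
                                   data.frame(cat_total = 0, age = 0)),
               1.26848)
  # no clamping: the re-estimated intercepts sit above 1
  expect_gt(predict_utility_ols("hoyle_m3_mod", z), 1)
  expect_error(predict_utility_ols("lim_total", z), "missing covariate")
})

test_that("two-part group selection follows the printed expressions", {
  z8 <- as.data.frame(as.list(stats::setNames(rep(0, 8), paste0("q", 1:8))))
  u <- predict_utility_two_part("hoyle_m6", z8)
  expect_equal(attr(u, "group"), "low")
  expect_equal(as.numeric(u), 0.3183917)
  expect_equal(predict_utility_two_part("hoyle_m6", z8, branch = "middle"),
               0.8150928)
  expect_equal(predict_utility_two_part("hoyle_m6", z8, branch = "top"), 1)
  # literal pathology: the middle expression always exceeds the top one
  # (same slopes, larger intercept), so the utility-1 group is unreachable
  # and predictions stay below 1 — mirroring the published maximum of 0.79
  f8 <- as.data.frame(as.list(stats::setNames(rep(5, 8), paste0("q", 1:8))))
  uf <- predict_utility_two_part("hoyle_m6", f8)
  expect_equal(attr(uf, "group"), "middle")
  sweep <- make_cat_rows(500, seed = 31)
  expect_false("top" %in%
                 attr(predict_utility_two_part("hoyle_m6", sweep), "group"))
})

test_that("all frozen comparator models stay finite over random responses", {
  rows <- make_cat_rows(1000, seed = 9)
  for (nm in c("hoyle_m3", "hoyle_m3_mod", "lim_total", "lim_items",
               "lim_total_mod", "lim_items_mod")) {
    u <- predict_utility_ols(nm, rows)
    expect_true(all(is.finite(u)), info = nm)
  }
  for (nm in c("hoyle_m6", "hoyle_m6_mod")) {
    u <- predict_utility_two_part(nm, rows)
    expect_true(all(is.finite(u)), info = nm)
    expect_true(all(u <= 1), info = nm)
  }
})

test_that("literal two-part classification collapses a near-healthy cohort downward", {
  obs <- simulate_cohort(seed = 8)
  healthy <- obs[obs$cat_total <= 10, ]
  m6 <- mean(predict_utility_two_part("hoyle_m6", healthy))
  mlr <- mean(predict_utility_mlr("taiwan_mlr_total", healthy))
  expect_lt(m6, mlr - 0.2)
})

test_that("canonical ordinal grouping restores coherent probabilities", {
  rows <- make_cat_rows(200, seed = 12)
  u_lit <- predict_utility_two_part("hoyle_m6_mod", rows)
  u_can <- predict_utility_two_part("hoyle_m6_mod", rows,
                                    canonical_ordinal = TRUE)
  expect_true(all(is.finite(u_can)))
  expect_true(all(u_can <= 1) && all(u_lit <= 1))
  # the coherent construction can reach the utility-1 group at the top of
  # the item range; the literal printed expressions cannot
  f8 <- as.data.frame(as.list(stats::setNames(rep(5, 8), paste0("q", 1:8))))
  expect_equal(as.numeric(predict_utility_two_part("hoyle_m6_mod", f8,
                                                   canonical_ordinal = TRUE)),
               1)
  expect_lt(as.numeric(predict_utility_two_part("hoyle_m6_mod", f8)), 1)
})

test_that("MRM table reproduces hand-ranked knots and interpolates linearly", {
  tab <- build_mrm_table(data.frame(cat_total = c(0, 10, 20),
                                    utility = c(1, 0.8, 0.5)))
  expect_equal(tab$knot_utilities, c(1, 0.8, 0.5))
  expect_equal(predict_utility_mrm(tab, c(0, 10, 20)), c(1, 0.8, 0.5))
  expect_equal(predict_utility_mrm(tab, 5), 0.9)
  expect_equal(predict_utility_mrm(tab, 40), 0.5)  # clamped beyond max knot
  expect_error(predict_utility_mrm(tab, 41), "within")
})

test_that("MRM predictions are non-increasing and drawn from the training sample", {
  obs <- simulate_cohort(sim_params(n_patients = 80), seed = 13)
  tab <- build_mrm_table(obs)
  u <- predict_utility_mrm(tab, 0:40)
  expect_false(is.unsorted(rev(u)))
  expect_true(all(tab$knot_utilities %in% obs$utility))
  # degenerate sample: constant utility predicts that constant
  tab1 <- build_mrm_table(data.frame(cat_total = c(3, 17, 30),
                                     utility = rep(0.6, 3)))
  expect_equal(predict_utility_mrm(tab1, c(0, 15, 40)), rep(0.6, 3))
})

test_that("predict_observations echoes inputs and appends prediction columns", {
  obs <- make_obs(10, seed = 21)
  out <- predict_observations("taiwan_mlr_total", obs)
  expect_equal(out[names(obs)], obs)
  expect_true(all(c("pred_utility", "model", "pred_mo", "pred_ad") %in%
                    names(out)))
  expect_equal(unique(out$model), "taiwan_mlr_total")
  out2 <- predict_observations("lim_items", obs)
  expect_false("pred_mo" %in% setdiff(names(out2), names(obs)))
})
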