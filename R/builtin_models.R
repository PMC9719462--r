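#' Names of the built-in mapping models
#'
#' The registry holds the published CAT-to-EQ-5D-3L mapping equations with
#' their coefficients frozen as printed:
#' \describe{
#'   \item{taiwan_mlr_total}{response mapping, five multinomial logits on
#'     the CAT total score, age and sex (Taiwanese COPD cohort).}
#'   \item{taiwan_mlr_items}{response mapping on backward-selected CAT
#'     items (selection differs per dimension), age and sex.}
#'   \item{hoyle_m3}{direct OLS on items Q3, Q5, Q6, Q8 (UK).}
#'   \item{hoyle_m6}{two-part model: ordinal classifier into utility
#'     groups (1 / middle / low), then per-group equations (UK).}
#'   \item{hoyle_m3_mod, hoyle_m6_mod}{the same model forms re-estimated
#'     on the Taiwanese training cohort.}
#'   \item{lim_total, lim_items}{direct OLS on the CAT total + age, or on
#'     items Q3--Q6 and Q8 (South Korea).}
#'   \item{lim_total_mod, lim_items_mod}{the Lim forms re-estimated on the
#'     Taiwanese training cohort.}
#' }
#' The Mean Rank Method has no frozen coefficients — it is built from a
#' training sample with \code{\link{build_mrm_table}}.
#'
#' @return Character vector of registry names.
#' @export
builtin_model_names <- function() names(builtin_registry)

#' Retrieve a built-in model spec by name
#'
#' @param name one of \code{\link{builtin_model_names}}.
#' @return A \code{model_spec}.
#' @examples
#' builtin_model("lim_total")$intercept # 1.1376
#' @export
builtin_model <- function(name) {
  f <- builtin_registry[[name]]
  if (is.null(f))
    stop("unknown built-in model '", name, "'; see builtin_model_names()")
  f()
}

# Coefficients below are transcribed from the published formula table.
# Covariate naming: cat_total, age, sex_code (male = 1), q1..q8.

spec_taiwan_mlr_total <- function() {
  cv <- c("cat_total", "age", "sex_code")
  mlr_response_spec(
    name = "taiwan_mlr_total",
    note = "Response mapping on CAT total score, age, sex (Taiwan).",
    dimensions = list(
      mo = mnl_dimension_model(cv, c(-13.79, 0.37, 0.10, 0.64),
                                   c(-43.98, 0.52, 0.27, 10.33)),
      sc = mnl_dimension_model(cv, c(-14.04, 0.40, 0.06, 3.11),
                                   c(-35.06, 0.59, 0.13, 13.91)),
      ua = mnl_dimension_model(cv, c(-15.37, 0.48, 0.09, 2.04),
                                   c(-37.84, 0.75, 0.14, 13.42)),
      pd = mnl_dimension_model(cv, c(-5.61, 0.30, 0.01, -0.84),
                                   c(-31.06, 0.79, 0.02, 8.77)),
      ad = mnl_dimension_model(cv, c(-4.07, 0.28, -0.02, -0.41),
                                   c(-25.77, 1.39, -0.22, 3.75))
    )
  )
}

spec_taiwan_mlr_items <- function() {
  mlr_response_spec(
    name = "taiwan_mlr_items",
    note = "Response mapping on backward-selected CAT items (Taiwan).",
    dimensions = list(
      mo = mnl_dimension_model(
        c("q2", "q3", "q4", "q5", "q6", "q8", "age"),
        c(-10.89, -0.46, -0.04, 0.60, 0.63, 1.19, 0.39, 0.07),
        c(-37.51, -0.92, 1.26, 0.74, 0.47, 1.74, 0.01, 0.31)),
      sc = mnl_dimension_model(
        c("q2", "q5", "q6", "q7", "age", "sex_code"),
        c(-9.21, -0.39, 1.30, 1.11, 0.35, 0.03, 1.98),
        c(-29.54, -0.53, 1.80, 1.47, 0.79, 0.09, 12.68)),
      ua = mnl_dimension_model(
        c("q3", "q4", "q5", "q6", "q7", "age", "sex_code"),
        c(-11.90, 0.28, 0.43, 1.08, 1.52, 0.25, 0.06, 0.98),
        c(-33.79, 0.53, 0.37, 2.37, 1.68, 0.57, 0.11, 11.41)),
      pd = mnl_dimension_model(
        c("q1", "q3", "q4", "q6", "q8", "age", "sex_code"),
        c(-3.29, 0.03, 0.39, -0.02, 0.96, 0.72, -0.01, -1.15),
        c(-512.27, 37.26, -6.14, 104.76, 12.01, 19.15, -2.05, -30.83)),
      ad = mnl_dimension_model(
        c("q2", "q3", "q5", "q6", "q7", "age"),
        c(-2.78, -0.34, 0.59, 0.31, 0.64, 0.59, -0.03),
        c(-216.48, -4.28, 17.46, 7.08, 27.76, 28.40, -0.86))
    )
  )
}

spec_hoyle_m3 <- function() direct_ols_spec(
  "hoyle_m3", 0.9831816,
  c(q8 = -0.0220703, q6 = -0.0418119, q5 = -0.0312604, q3 = -0.0260971),
  note = "Direct OLS on four CAT items (UK)."
)

spec_hoyle_m3_mod <- function() direct_ols_spec(
  "hoyle_m3_mod", 1.03670,
  c(q8 = -0.01273, q6 = -0.06367, q5 = -0.03794, q3 = -0.01211),
  note = "Hoyle M3 form re-estimated on the Taiwanese training cohort."
)

spec_lim_total <- function() direct_ols_spec(
  "lim_total", 1.1376, c(cat_total = -0.0103, age = -0.0020),
  note = "Direct OLS on CAT total and age (South Korea)."
)

spec_lim_items <- function() direct_ols_spec(
  "lim_items", 1.0661,
  c(q3 = -0.0103, q4 = -0.0120, q5 = -0.0168, q6 = -0.0255, q8 = -0.0125),
  note = "Direct OLS on five CAT items (South Korea)."
)

spec_lim_total_mod <- function() direct_ols_spec(
  "lim_total_mod", 1.26848, c(cat_total = -0.02159, age = -0.00188),
  note = "Lim total-score form re-estimated on the Taiwanese cohort."
)

spec_lim_items_mod <- function() direct_ols_spec(
  "lim_items_mod", 1.05245,
  c(q3 = -0.01137, q4 = -0.00810, q5 = -0.03702, q6 = -0.05993,
    q8 = -0.01286),
  note = "Lim items form re-estimated on the Taiwanese cohort."
)

spec_hoyle_m6 <- function() two_part_spec(
  name = "hoyle_m6",
  slopes = c(q3 = 0.2536439, q4 = 0.1635303, q5 = 0.4407377,
             q6 = 0.3709118, q7 = 0.088462, q8 = 0.186294),
  intercept_top = -7.1242, intercept_mid = -1.4836,
  mid_denom = "own",
  eq_mid = list(intercept = 0.8150928,
                slopes = c(q3 = -0.0114207, q5 = -0.0102185,
                           q6 = -0.0270919, q8 = -0.0053779)),
  eq_low = list(intercept = 0.3183917, slope_cat_total = -0.00752),
  note = "Two-part mapping (UK)."
)

spec_hoyle_m6_mod <- function() two_part_spec(
  name = "hoyle_m6_mod",
  slopes = c(q3 = 0.2622, q4 = 0.3884, q5 = 0.8401, q6 = 1.0693,
             q7 = 0.1832, q8 = 0.1565),
  intercept_top = -10.9642, intercept_mid = -4.6737,
  mid_denom = "top",
  eq_mid = list(intercept = 0.92209,
                slopes = c(q3 = -0.01266, q5 = -0.01911, q6 = -0.03696,
                           q8 = -0.02121)),
  eq_low = list(intercept = 0.53984, slope_cat_total = -0.01008),
  note = paste("Hoyle M6 form re-estimated on the Taiwanese cohort;",
               "middle-group denominator reuses the top intercept as",
               "printed.")
)

builtin_registry <- list(
  taiwan_mlr_total = spec_taiwan_mlr_total,
  taiwan_mlr_items = spec_taiwan_mlr_items,
  hoyle_m3 = spec_hoyle_m3,
  hoyle_m6 = spec_hoyle_m6,
  hoyle_m3_mod = spec_hoyle_m3_mod,
  hoyle_m6_mod = spec_hoyle_m6_mod,
  lim_total = spec_lim_total,
  lim_items = spec_lim_items,
  lim_total_mod = spec_lim_total_mod,
  lim_items_mod = spec_lim_items_mod
)
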