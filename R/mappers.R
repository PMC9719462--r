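#' Multinomial logit level probabilities for one EQ-5D dimension
#'
#' Evaluates the level-1/2/3 probabilities of a three-level multinomial
#' logit with level 1 as the baseline:
#' \deqn{p_2 = e^{\eta_2} / (1 + e^{\eta_2} + e^{\eta_3}), \quad
#'       p_3 = e^{\eta_3} / (1 + e^{\eta_2} + e^{\eta_3}), \quad
#'       p_1 = 1 - p_2 - p_3,}
#' computed overflow-safely (log-sum-exp), so published coefficients as
#' large as a few hundred evaluate to saturated probabilities rather than
#' \code{NaN}.
#'
#' @param model an \code{\link{mnl_dimension_model}}.
#' @param x named numeric vector of covariate values, or a data.frame /
#'   matrix with one row per evaluation point, holding every covariate the
#'   model names.
#' @return A numeric matrix with columns \code{p1, p2, p3}, one row per
#'   evaluation point; rows sum to 1.
#' @examples
#' m <- mnl_dimension_model("cat_total", beta2 = c(0, 0), beta3 = c(0, 0))
#' mnl_probabilities(m, c(cat_total = 5)) # 1/3 each
#' @export
mnl_probabilities <- function(model, x) {
  stopifnot(inherits(model, "mnl_dimension_model"))
  X <- covariate_matrix(x, model$covariates)
  eta2 <- drop(X %*% model$beta2)
  eta3 <- drop(X %*% model$beta3)
  m <- pmax(0, eta2, eta3)
  e1 <- exp(-m)
  e2 <- exp(eta2 - m)
  e3 <- exp(eta3 - m)
  den <- e1 + e2 + e3
  cbind(p1 = e1 / den, p2 = e2 / den, p3 = e3 / den)
}

# Build the design matrix (intercept first) for the named covariates.
covariate_matrix <- function(x, covariates) {
  if (is.numeric(x) && is.null(dim(x))) x <- as.data.frame(as.list(x))
  x <- as.data.frame(x)
  if ("cat_total" %in% covariates && !"cat_total" %in% names(x) &&
      all(cat_item_cols() %in% names(x)))
    x$cat_total <- rowSums(x[cat_item_cols()])
  miss <- setdiff(covariates, names(x))
  if (length(miss))
    stop("missing covariate value(s): ", paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(x[covariates]))
  colnames(X) <- c("(Intercept)", covariates)
  X
}

#' Predict EQ-5D-3L states by response mapping
#'
#' For each observation, evaluates the five per-dimension multinomial
#' logits and assigns each dimension the level with the highest predicted
#' probability; on an exact tie the lowest (healthiest) level wins.
#'
#' @param spec a \code{model_spec} of kind \code{mlr_response} (object or
#'   built-in name).
#' @param newdata data.frame with the covariate columns the spec names
#'   (e.g. \code{cat_total} or \code{q1..q8}, \code{age},
#'   \code{sex_code}).
#' @return An n-by-5 integer matrix of predicted levels, columns
#'   \code{mo, sc, ua, pd, ad}.
#' @export
predict_state_mlr <- function(spec, newdata) {
  spec <- load_model_spec(spec)
  if (spec$kind != "mlr_response")
    stop("predict_state_mlr needs a spec of kind 'mlr_response'")
  newdata <- as.data.frame(newdata)
  out <- matrix(NA_integer_, nrow(newdata), 5L,
                dimnames = list(NULL, eq5d_dimensions()))
  for (d in eq5d_dimensions()) {
    p <- mnl_probabilities(spec$dimensions[[d]], newdata)
    out[, d] <- max.col(p, ties.method = "first")
  }
  out
}

#' Predict utilities by response mapping
#'
#' Composes \code{\link{predict_state_mlr}} with
#' \code{\link{utility_from_state}}: the predicted state of each
#' observation is scored with the tariff, so every prediction is one of
#' the 243 tariff values.
#'
#' @inheritParams predict_state_mlr
#' @param tariff a \code{tariff_table}.
#' @return Numeric vector of predicted utilities, with the predicted
#'   state matrix attached as attribute \code{"state"}.
#' @examples
#' nd <- data.frame(cat_total = c(0, 25), age = 60, sex_code = 1)
#' predict_utility_mlr("taiwan_mlr_total", nd)
#' @export
predict_utility_mlr <- function(spec, newdata, tariff = taiwan_tariff()) {
  st <- predict_state_mlr(spec, newdata)
  u <- utility_from_state(st, tariff)
  attr(u, "state") <- st
  u
}

#' Predict utilities with a direct OLS mapping
#'
#' Evaluates the linear equation \code{intercept + sum(slope * covariate)}
#' row-wise. Predictions are deliberately not clamped to [0, 1]: the
#' published re-estimated equations produce maxima above 1 and the
#' original analyses report them unclamped.
#'
#' @param spec a \code{model_spec} of kind \code{direct_ols} (object or
#'   built-in name).
#' @param newdata data.frame with the covariate columns the spec names.
#' @return Numeric vector of predicted utilities.
#' @examples
#' predict_utility_ols("hoyle_m3",
#'                     data.frame(q3 = 0, q5 = 0, q6 = 0, q8 = 0))
#' @export
predict_utility_ols <- function(spec, newdata) {
  spec <- load_model_spec(spec)
  if (spec$kind != "direct_ols")
    stop("predict_utility_ols needs a spec of kind 'direct_ols'")
  X <- covariate_matrix(as.data.frame(newdata), names(spec$slopes))
  drop(X %*% c(spec$intercept, spec$slopes))
}

#' Predict utilities with a two-part (group-then-regress) mapping
#'
#' Evaluates the published group expressions for membership in the
#' utility = 1 ("top"), middle and low groups, picks the group with the
#' largest value (ties resolved top > middle > low), and returns that
#' group's outcome equation: exactly 1 for the top group, a linear items
#' equation for the middle group, a linear CAT-total equation for the low
#' group.
#'
#' By default the expressions are evaluated literally as printed — in the
#' re-estimated variant the middle expression's denominator reuses the top
#' intercept, so the three values need not sum to one. Setting
#' \code{canonical_ordinal = TRUE} replaces them with the coherent
#' cumulative-logit construction (\code{p_top = expit(eta_top)},
#' \code{p_top + p_mid = expit(eta_mid)}) for sensitivity analysis.
#'
#' @param spec a \code{model_spec} of kind \code{two_part} (object or
#'   built-in name).
#' @param newdata data.frame with the CAT item columns (and
#'   \code{cat_total}, computed from the items when absent).
#' @param branch \code{"auto"} (select by maximum) or one of
#'   \code{"top"}, \code{"middle"}, \code{"low"} to force a branch's
#'   outcome equation (useful for audit).
#' @param canonical_ordinal use the coherent cumulative-logit group
#'   probabilities instead of the literal printed expressions.
#' @return Numeric vector of predicted utilities, with the selected group
#'   attached as attribute \code{"group"} when \code{branch = "auto"}.
#' @export
predict_utility_two_part <- function(spec, newdata,
                                     branch = c("auto", "top", "middle", "low"),
                                     canonical_ordinal = FALSE) {
  spec <- load_model_spec(spec)
  if (spec$kind != "two_part")
    stop("predict_utility_two_part needs a spec of kind 'two_part'")
  branch <- match.arg(branch)
  newdata <- as.data.frame(newdata)
  X <- covariate_matrix(newdata, names(spec$slopes))
  lin <- drop(X[, -1L, drop = FALSE] %*% spec$slopes)
  eta_top <- spec$intercept_top + lin
  eta_mid <- spec$intercept_mid + lin
  expit <- function(e) 1 / (1 + exp(-e))
  if (canonical_ordinal) {
    p_top <- expit(eta_top)
    p_mid <- pmax(expit(eta_mid) - p_top, 0)
  } else {
    p_top <- expit(eta_top)
    p_mid <- if (spec$mid_denom == "top") exp(eta_mid) / (1 + exp(eta_top))
             else expit(eta_mid)
  }
  p_low <- 1 - p_top - p_mid
  grp <- switch(branch,
    auto = {
      # ties: top beats middle beats low
      g <- rep("low", length(p_top))
      g[p_mid >= p_low] <- "middle"
      g[p_top >= pmax(p_mid, p_low)] <- "top"
      g
    },
    top = rep("top", length(p_top)),
    middle = rep("middle", length(p_top)),
    low = rep("low", length(p_top))
  )
  cat_total <- covariate_matrix(newdata, "cat_total")[, "cat_total"]
  Xm <- covariate_matrix(newdata, names(spec$eq_mid$slopes))
  u_mid <- drop(Xm %*% c(spec$eq_mid$intercept, spec$eq_mid$slopes))
  u_low <- spec$eq_low$intercept + spec$eq_low$slope_cat_total * cat_total
  u <- ifelse(grp == "top", 1, ifelse(grp == "middle", u_mid, u_low))
  if (branch == "auto") attr(u, "group") <- grp
  u
}

#' Predict utilities for an observation table with any mapping model
#'
#' Dispatches on the spec's kind and returns the input table with the
#' prediction columns appended: \code{pred_utility}, \code{model}, and —
#' for response mapping — the predicted state columns
#' \code{pred_mo .. pred_ad}.
#'
#' @param spec a \code{model_spec} (object, built-in name, or path to a
#'   JSON spec, including a serialized Mean Rank Method table).
#' @param df an observation data.frame (see \link{observations}).
#' @param tariff tariff used by response mapping.
#' @return The augmented data.frame.
#' @export
predict_observations <- function(spec, df, tariff = taiwan_tariff()) {
  spec <- load_model_spec(spec)
  out <- df
  u <- switch(spec$kind,
    mlr_response = {
      uu <- predict_utility_mlr(spec, df, tariff)
      st <- attr(uu, "state")
      colnames(st) <- paste0("pred_", colnames(st))
      out <- cbind(out, st)
      uu
    },
    direct_ols = predict_utility_ols(spec, df),
    two_part = predict_utility_two_part(spec, df),
    mrm = predict_utility_mrm(spec, covariate_matrix(df, "cat_total")[, 2L]),
    stop("unknown model kind: ", spec$kind)
  )
  out$pred_utility <- as.numeric(u)
  out$model <- spec$name
  out
}
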