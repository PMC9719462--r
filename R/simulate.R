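#' Parameters of the synthetic repeated-measures cohort generator
#'
#' The generator emulates a Taiwanese COPD clinic cohort followed over
#' repeated visits: 323 patients contributing between 1 and 16 visits
#' (mean about 7.2, truncated negative-binomial), each patient carrying a
#' latent severity (normal random intercept) that all of their visits
#' share, plus visit-level noise. At each visit the eight CAT items are
#' generated by thresholding the latent severity (plus item-level noise)
#' against a common set of ordinal cut points, and the EQ-5D-3L state is
#' sampled from the built-in total-score response-mapping model at the
#' visit's CAT total, age and sex; the utility column is the tariff value
#' of the sampled state. Airflow-severity stage (1..3) is assigned per
#' patient from their latent severity.
#'
#' Defaults were calibrated once against the cohort's published marginal
#' statistics (mean utility 0.917, mean CAT total 9.88, utility-CAT
#' correlation -0.69, 69.79\% of observations at utility 1, about 2327
#' observations) and are frozen; they are not meant to be re-tuned per
#' analysis.
#'
#' @param n_patients number of patients.
#' @param visit_mu,visit_size mean and dispersion of the untruncated
#'   negative-binomial visit-count distribution (truncated to 1..16).
#' @param age_mean,age_sd,age_range age distribution (normal, truncated).
#' @param p_male probability of male sex (coded 1).
#' @param sev_sd patient-level latent severity standard deviation.
#' @param sev_shape gamma shape of the latent severity distribution
#'   (standardized to mean 0, sd \code{sev_sd}); smaller values give a
#'   more right-skewed cohort (many mild patients, a thin severe tail),
#'   \code{Inf} gives a normal severity.
#' @param sev_sampling \code{"quantile"} (default) enrols each replicate
#'   cohort at the severity distribution's quantile grid — a balanced
#'   severity mix, as under quota enrolment — randomly assigned to
#'   patients; \code{"random"} draws severities i.i.d.
#' @param visit_sd visit-level severity noise standard deviation.
#' @param item_sd item-level noise standard deviation.
#' @param thresholds increasing ordinal cut points (length 5) shared by
#'   the eight CAT items.
#' @param stage_breaks latent-severity cut points assigning stages 1..3.
#' @param spec response-mapping spec used as the EQ-5D generator.
#' @param tariff tariff used to score the sampled states.
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(n_patients = 323,
                       visit_mu = 7.52, visit_size = 6,
                       age_mean = 63.5, age_sd = 11.9,
                       age_range = c(40, 95),
                       p_male = 0.12,
                       sev_sd = 0.49, sev_shape = 0.8,
                       sev_sampling = c("quantile", "random"),
                       visit_sd = 0.37, item_sd = 0.9,
                       thresholds = c(-0.85, 0.51, 1.51, 2.58, 4.23),
                       stage_breaks = c(-0.341, 0.209),
                       spec = "taiwan_mlr_total",
                       tariff = taiwan_tariff()) {
  stopifnot(n_patients >= 1, length(thresholds) == 5L,
            !is.unsorted(thresholds), length(stage_breaks) == 2L,
            p_male >= 0, p_male <= 1, visit_mu > 0, visit_size > 0,
            sev_sd >= 0, visit_sd >= 0, item_sd >= 0)
  structure(
    list(n_patients = n_patients, visit_mu = visit_mu,
         visit_size = visit_size, age_mean = age_mean, age_sd = age_sd,
         age_range = age_range, p_male = p_male, sev_sd = sev_sd,
         sev_shape = sev_shape, sev_sampling = match.arg(sev_sampling),
         visit_sd = visit_sd, item_sd = item_sd, thresholds = thresholds,
         stage_breaks = stage_breaks, spec = load_model_spec(spec),
         tariff = tariff),
    class = "sim_params"
  )
}

#' Simulate a synthetic repeated-measures COPD cohort
#'
#' @param params a \code{\link{sim_params}} object.
#' @param seed integer seed; the same seed always reproduces the same
#'   cohort.
#' @return A validated observation data.frame (see \link{observations})
#'   with columns \code{patient_id, visit, age, sex_code, q1..q8,
#'   cat_total, mo, sc, ua, pd, ad, utility, stage}.
#' @examples
#' obs <- simulate_cohort(sim_params(n_patients = 30), seed = 7)
#' mean(obs$utility)
#' @export
simulate_cohort <- function(params = sim_params(), seed) {
  stopifnot(inherits(params, "sim_params"))
  restore <- local_rng(seed)
  on.exit(restore())
  np <- params$n_patients

  nv <- sample_visits(np, params$visit_mu, params$visit_size,
                      params$sev_sampling)
  sev <- sample_severity(np, params$sev_sd, params$sev_shape,
                         params$sev_sampling)
  if (params$sev_sampling == "quantile") {
    # balanced cohort composition: age on the quantile grid, sex at its
    # expected count; assignment to patients is randomized
    age <- stats::qnorm((seq_len(np) - 0.5) / np,
                        params$age_mean, params$age_sd)
    age <- sample(pmin(pmax(age, params$age_range[1L]),
                       params$age_range[2L]))
    sex <- sample(rep(c(1L, 0L),
                      c(round(np * params$p_male),
                        np - round(np * params$p_male))))
  } else {
    age <- pmin(pmax(stats::rnorm(np, params$age_mean, params$age_sd),
                     params$age_range[1L]), params$age_range[2L])
    sex <- stats::rbinom(np, 1L, params$p_male)
  }
  stage <- 1L + findInterval(sev, params$stage_breaks)

  idx <- rep(seq_len(np), nv)
  n <- length(idx)
  z <- sev[idx] + stats::rnorm(n, 0, params$visit_sd)
  items <- vapply(seq_len(8L), function(j)
    findInterval(z + stats::rnorm(n, 0, params$item_sd), params$thresholds),
    integer(n))
  colnames(items) <- cat_item_cols()

  df <- data.frame(
    patient_id = sprintf("P%05d", idx),
    visit = unlist(lapply(nv, seq_len)),
    age = round(age[idx], 1), sex_code = sex[idx]
  )
  df <- cbind(df, items)
  df$cat_total <- as.integer(rowSums(items))
  st <- sample_states(params$spec, df)
  df <- cbind(df, st)
  df$utility <- utility_from_state(st, params$tariff)
  df$stage <- stage[idx]
  as_observations(df, check_utility = identical(params$tariff, taiwan_tariff()))
}

# Latent severity: standardized gamma (right-skewed) or normal.
# "quantile" sampling places the cohort at the distribution's quantile
# grid (a balanced severity mix, as under quota enrolment by severity);
# "random" draws i.i.d.
sample_severity <- function(n, sd, shape, sampling = "quantile") {
  if (sampling == "quantile") {
    pr <- (seq_len(n) - 0.5) / n
    q <- if (is.infinite(shape)) stats::qnorm(pr, 0, sd)
         else sd * (stats::qgamma(pr, shape = shape, rate = 1) - shape) /
           sqrt(shape)
    return(sample(q))
  }
  if (is.infinite(shape)) return(stats::rnorm(n, 0, sd))
  sd * (stats::rgamma(n, shape = shape, rate = 1) - shape) / sqrt(shape)
}

# Visit counts: negative binomial truncated to 1..16. In balanced
# ("quantile") mode the counts follow the distribution's quantile grid,
# randomly assigned to patients.
sample_visits <- function(n, mu, size, sampling = "quantile") {
  k <- 1:16
  pr <- stats::dnbinom(k, size = size, mu = mu)
  pr <- pr / sum(pr)
  if (sampling == "quantile") {
    cdf <- cumsum(pr)
    grid <- k[findInterval((seq_len(n) - 0.5) / n, cdf) + 1L]
    return(sample(grid))
  }
  sample(k, n, replace = TRUE, prob = pr)
}

sample_states <- function(spec, covars) {
  st <- matrix(NA_integer_, nrow(covars), 5L,
               dimnames = list(NULL, eq5d_dimensions()))
  for (d in eq5d_dimensions()) {
    p <- mnl_probabilities(spec$dimensions[[d]], covars)
    u <- stats::runif(nrow(covars))
    st[, d] <- 1L + (u > p[, 1L]) + (u > p[, 1L] + p[, 2L])
  }
  st
}

#' Simulate EQ-5D-3L responses from a response-mapping spec
#'
#' Samples each dimension's level from the spec's multinomial
#' probabilities at the supplied covariate rows — the parameter-recovery
#' harness used to test the fitting machinery.
#'
#' @param spec a \code{model_spec} of kind \code{mlr_response} (object or
#'   built-in name).
#' @param covars data.frame of covariate rows (plus any id columns, which
#'   are carried through).
#' @param seed integer seed.
#' @param tariff tariff used for the \code{utility} column.
#' @return \code{covars} with sampled \code{mo..ad} and \code{utility}
#'   columns appended.
#' @export
simulate_from_spec <- function(spec, covars, seed, tariff = taiwan_tariff()) {
  spec <- load_model_spec(spec)
  if (spec$kind != "mlr_response")
    stop("simulate_from_spec needs a spec of kind 'mlr_response'")
  restore <- local_rng(seed)
  on.exit(restore())
  covars <- as.data.frame(covars)
  st <- sample_states(spec, covars)
  out <- cbind(covars, st)
  out$utility <- utility_from_state(st, tariff)
  out
}
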