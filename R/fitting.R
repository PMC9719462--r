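#' Fit a per-dimension multinomial logit to repeated-measures data
#'
#' Fits a three-level multinomial logistic regression (level 1 baseline)
#' for one EQ-5D dimension by pooled maximum likelihood, and pairs the
#' estimates with a cluster-robust (sandwich) covariance in which scores
#' are summed within patients. Under an independence working correlation
#' the estimating equations coincide with the pooled likelihood score, so
#' this reproduces GEE point estimates for clustered visits while the
#' sandwich covariance absorbs the within-patient dependence.
#'
#' Estimation is Newton–Raphson with step halving, run to a gradient
#' max-norm below \code{tol} (default 1e-8) or \code{max_iter} iterations.
#' Quasi-separation is flagged (not fatal) when any coefficient magnitude
#' exceeds \code{coef_bound}. If one of levels 2/3 never occurs, the fit
#' reduces to a binary logit for the observed level and the absent level's
#' logit is pinned at \code{-Inf} (probability zero), with a flag.
#'
#' @param data observation data.frame; must contain the \code{dimension}
#'   column (levels 1..3), the covariate columns, and \code{patient_id}.
#' @param dimension one of \code{mo, sc, ua, pd, ad} (or any column of
#'   1..3 levels).
#' @param covariates character vector of covariate column names
#'   (\code{cat_total} is derived from the items when absent).
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @param coef_bound threshold for the quasi-separation flag.
#' @return An object of class \code{mnl_fit}: the fitted
#'   \code{\link{mnl_dimension_model}}, robust and model-based
#'   covariances, per-covariate joint Wald tests, log (quasi-)likelihood,
#'   QIC and a convergence report.
#' @seealso \code{\link{backward_eliminate}}, \code{\link{qic}}
#' @export
fit_mnl_independence <- function(data, dimension, covariates,
                                 tol = 1e-8, max_iter = 100L,
                                 coef_bound = 50) {
  data <- as.data.frame(data)
  if (!dimension %in% names(data))
    stop("dimension column '", dimension, "' not found")
  y <- as.integer(data[[dimension]])
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  if (!all(y %in% 1:3)) stop("dimension levels must be 1, 2 or 3")
  X <- covariate_matrix(data, covariates)
  cl <- as.character(data$patient_id)
  n <- length(y); p <- ncol(X)
  lev_obs <- sort(unique(y))
  if (length(lev_obs) < 2L)
    stop("need at least two observed levels of '", dimension, "'")
  if (!1L %in% lev_obs)
    stop("baseline level 1 of '", dimension, "' never observed")
  klev <- intersect(2:3, lev_obs)      # fitted non-baseline levels
  K <- length(klev)

  theta <- rep(0, K * p)
  Y <- vapply(klev, function(k) as.numeric(y == k), numeric(n))
  rowmax0 <- function(eta) {
    m <- eta[, 1L]
    if (ncol(eta) > 1L) for (j in 2L:ncol(eta)) m <- pmax(m, eta[, j])
    pmax(0, m)
  }
  probs <- function(th) {
    eta <- X %*% matrix(th, p, K)
    m <- rowmax0(eta)
    E <- exp(eta - m)
    den <- exp(-m) + rowSums(E)
    E / den                                   # n x K matrix of p_k
  }
  loglik_at <- function(th) {
    eta <- X %*% matrix(th, p, K)
    m <- rowmax0(eta)
    lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum(rowSums(Y * eta) - lse)
  }

  ll <- loglik_at(theta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    P <- probs(theta)
    R <- Y - P                                # n x K residuals
    grad <- as.vector(crossprod(X, R))        # stacked by level
    A <- matrix(0, K * p, K * p)              # information (-Hessian)
    for (a in seq_len(K)) for (b in seq_len(K)) {
      w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
      A[((a - 1) * p + 1):(a * p), ((b - 1) * p + 1):(b * p)] <-
        crossprod(X, X * w)
    }
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    step <- tryCatch(solve(A, grad), error = function(e) NULL)
    if (is.null(step)) {
      # quasi-separated regions flatten the information; a small ridge
      # keeps the ascent direction defined (reported covariances are
      # still computed from the unridged information)
      ridge <- 1e-8 * (1 + mean(diag(A)))
      step <- tryCatch(solve(A + diag(ridge, nrow(A)), grad),
                       error = function(e) NULL)
      if (is.null(step)) stop("singular information matrix")
    }
    lam <- 1
    repeat {
      th_new <- theta + lam * step
      ll_new <- loglik_at(th_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    theta <- theta + lam * step
    ll <- loglik_at(theta)
  }
  if (!converged && max(abs(grad)) > 1e-4)
    warning("fit_mnl_independence: no convergence in ", max_iter,
            " iterations (gradient max ", format(max(abs(grad))), ")")

  P <- probs(theta)
  S <- matrix(0, n, K * p)                    # per-observation scores
  for (a in seq_len(K))
    S[, ((a - 1) * p + 1):(a * p)] <- X * (Y[, a] - P[, a])
  G <- rowsum(S, cl)                          # cluster score sums
  Ainv <- tryCatch(solve(A), error = function(e)
    solve(A + diag(1e-8 * (1 + mean(diag(A))), nrow(A))))
  B <- crossprod(G)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  par_names <- as.vector(outer(colnames(X), paste0("lv", klev),
                               function(a, b) paste(b, a, sep = ":")))
  dimnames(V) <- dimnames(Ainv) <- list(par_names, par_names)

  # assemble the full 2-logit coefficient set (absent level pinned out)
  beta_of <- function(k) {
    if (k %in% klev) theta[((match(k, klev) - 1) * p + 1):(match(k, klev) * p)]
    else c(-Inf, rep(0, p - 1L))
  }
  model <- mnl_dimension_model(covariates, beta_of(2L), beta_of(3L))

  wald <- covariate_wald(theta, V, covariates, p, K)
  separated <- any(abs(theta) > coef_bound)
  fit <- structure(
    list(model = model, dimension = dimension, covariates = covariates,
         klev = klev, theta = theta, par_names = par_names,
         vcov_robust = V, vcov_model = Ainv, information = A,
         wald = wald, loglik = ll,
         n_obs = n, n_clusters = nrow(G),
         converged = converged, iterations = iter,
         separation = separated,
         absent_level = setdiff(2:3, klev)),
    class = "mnl_fit"
  )
  fit$qic <- qic(fit)
  fit
}

# Joint (K-df) robust Wald test per covariate across the fitted logits.
covariate_wald <- function(theta, V, covariates, p, K) {
  if (length(covariates) == 0L)
    return(data.frame(covariate = character(0), chisq = numeric(0),
                      df = integer(0), p_value = numeric(0)))
  rows <- lapply(seq_along(covariates), function(j) {
    idx <- (seq_len(K) - 1L) * p + j + 1L     # position of covariate j
    b <- theta[idx]
    Vj <- V[idx, idx, drop = FALSE]
    w <- tryCatch(drop(t(b) %*% solve(Vj, b)), error = function(e) NA_real_)
    data.frame(covariate = covariates[j], chisq = w, df = K,
               p_value = stats::pchisq(w, df = K, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat("Multinomial logit (independence working model), dimension '",
      x$dimension, "'\n", sep = "")
  cat("  ", x$n_obs, " observations in ", x$n_clusters, " clusters; ",
      if (x$converged) "converged" else "NOT converged", " in ",
      x$iterations, " iterations\n", sep = "")
  cat("  logLik ", format(x$loglik), ",  QIC ", format(x$qic), "\n", sep = "")
  if (x$separation) cat("  note: possible quasi-separation\n")
  print(x$wald, row.names = FALSE)
  invisible(x)
}

#' Quasi-likelihood information criterion of a fitted multinomial logit
#'
#' \deqn{QIC = -2\,QL(\hat\mu; y) + 2\,\mathrm{trace}(\hat\Omega_I
#'   \hat V_R)} where \eqn{QL} is the multinomial log-likelihood under the
#' independence working model, \eqn{\hat\Omega_I} the model-based
#' information and \eqn{\hat V_R} the cluster-robust covariance. With
#' independent clusters the trace tends to the parameter count and QIC
#' approaches AIC.
#'
#' @param fit an \code{mnl_fit}.
#' @return The QIC value (scalar).
#' @export
qic <- function(fit) {
  stopifnot(inherits(fit, "mnl_fit"))
  -2 * fit$loglik + 2 * sum(diag(fit$information %*% fit$vcov_robust))
}

#' Backward elimination under cluster-robust Wald tests
#'
#' Starting from the full covariate set, repeatedly drops the covariate
#' with the largest joint Wald p-value (both logit coefficients tested
#' together, robust covariance) among those exceeding \code{alpha}, and
#' refits, until every remaining covariate is significant at \code{alpha}.
#' Intercepts are never dropped.
#'
#' @inheritParams fit_mnl_independence
#' @param alpha type I error rate for retention (default 0.05).
#' @return The final \code{mnl_fit}, with the drop sequence in
#'   \code{$eliminated} (character vector, first dropped first).
#' @export
backward_eliminate <- function(data, dimension, covariates, alpha = 0.05,
                               ...) {
  dropped <- character(0)
  fit <- fit_mnl_independence(data, dimension, covariates, ...)
  repeat {
    w <- fit$wald
    cand <- w[!is.na(w$p_value) & w$p_value > alpha, , drop = FALSE]
    if (nrow(cand) == 0L || length(fit$covariates) == 0L) break
    worst <- cand$covariate[which.max(cand$p_value)]
    covariates <- setdiff(fit$covariates, worst)
    dropped <- c(dropped, worst)
    fit <- fit_mnl_independence(data, dimension, covariates, ...)
  }
  fit$eliminated <- dropped
  fit
}

#' Ordinary least squares refit of a direct utility mapping
#'
#' Regenerates a "re-estimated" direct mapping by least squares: utility
#' on the stated covariate set. Returns a ready-to-use
#' \code{direct_ols} \code{model_spec} with the residual standard error
#' and R-squared attached as attributes.
#'
#' @param data observation data.frame with observed \code{utility}.
#' @param covariates character vector of covariate column names.
#' @param name name given to the resulting spec.
#' @return A \code{model_spec} of kind \code{direct_ols}.
#' @examples
#' obs <- simulate_cohort(sim_params(n_patients = 50), seed = 3)
#' fit_ols(obs, c("cat_total", "age"), name = "refit_total")
#' @export
fit_ols <- function(data, covariates, name = "ols_refit") {
  data <- as.data.frame(data)
  if (is.null(data$utility) || anyNA(data$utility))
    stop("all observations must carry observed utilities")
  X <- covariate_matrix(data, covariates)
  fit <- stats::lm.fit(X, data$utility)
  cf <- fit$coefficients
  if (anyNA(cf)) stop("rank-deficient design: ",
                      paste(names(cf)[is.na(cf)], collapse = ", "))
  spec <- if (length(covariates) == 0L) {
    # intercept-only refit (degenerate but well defined: the sample mean)
    structure(list(kind = "direct_ols", name = name,
                   note = "re-estimated by OLS",
                   intercept = unname(cf[1L]),
                   slopes = stats::setNames(numeric(0), character(0))),
              class = c("direct_ols_spec", "model_spec"))
  } else {
    direct_ols_spec(name, cf[1L], cf[-1L], note = "re-estimated by OLS")
  }
  rss <- sum(fit$residuals^2)
  tss <- sum((data$utility - mean(data$utility))^2)
  attr(spec, "sigma") <- sqrt(rss / max(1, nrow(X) - length(cf)))
  attr(spec, "r_squared") <- if (tss > 0) 1 - rss / tss else NA_real_
  spec
}
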