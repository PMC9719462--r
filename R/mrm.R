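#' Build a Mean Rank Method mapping table
#'
#' The Mean Rank Method matches the source and target instruments
#' nonparametrically: a CAT total and an EQ-5D utility are equated when
#' they hold the same mean rank in their respective training samples. For
#' each distinct CAT total the mean rank (ties sharing the mean of their
#' rank positions, ascending in CAT) is converted to the percentile
#' \eqn{p = 1 - (\bar r - 0.5)/n} — the complement because higher CAT
#' means worse health — and the mapped utility is the lower-step empirical
#' quantile of the training utility sample at \eqn{p}. The resulting knot
#' table is non-increasing in the CAT total by construction.
#'
#' @param train observation data.frame carrying observed \code{utility}
#'   values (and CAT items or \code{cat_total}).
#' @return A \code{model_spec} of kind \code{mrm} (class
#'   \code{mrm_table}): distinct CAT totals with their mean ranks and knot
#'   utilities, plus the sorted utility sample. Serializable with
#'   \code{\link{write_model_spec}}.
#' @examples
#' tr <- data.frame(cat_total = c(0, 10, 20), utility = c(1, 0.8, 0.5))
#' tab <- build_mrm_table(tr)
#' predict_utility_mrm(tab, c(0, 5, 10)) # 1.0 0.9 0.8
#' @export
build_mrm_table <- function(train) {
  train <- as.data.frame(train)
  ct <- if ("cat_total" %in% names(train)) train$cat_total
        else covariate_matrix(train, "cat_total")[, 2L]
  u <- train$utility
  if (is.null(u)) stop("training observations must carry observed utilities")
  keep <- !is.na(ct) & !is.na(u)
  ct <- ct[keep]; u <- u[keep]
  n <- length(u)
  if (n == 0L) stop("empty training set")
  r <- rank(ct, ties.method = "average")
  mean_ranks <- tapply(r, ct, mean)
  cat_totals <- as.numeric(names(mean_ranks))
  us <- sort(u)
  p <- 1 - (as.numeric(mean_ranks) - 0.5) / n
  idx <- pmin(pmax(ceiling(p * n), 1L), n)  # lower-step empirical quantile
  new_mrm_table(cat_totals = cat_totals,
                mean_ranks = as.numeric(mean_ranks),
                knot_utilities = us[idx],
                utilities = us, n = n)
}

#' Construct a Mean Rank Method table from its components
#'
#' Mostly internal — used when deserializing a stored table; prefer
#' \code{\link{build_mrm_table}}.
#'
#' @param cat_totals sorted distinct CAT totals (knots).
#' @param mean_ranks their training mean ranks.
#' @param knot_utilities mapped utility at each knot.
#' @param utilities sorted training utility sample.
#' @param n training sample size.
#' @param name,note metadata.
#' @return A \code{model_spec} of kind \code{mrm}.
#' @export
new_mrm_table <- function(cat_totals, mean_ranks, knot_utilities, utilities,
                          n, name = "mrm", note = "") {
  o <- order(cat_totals)
  cat_totals <- cat_totals[o]
  mean_ranks <- mean_ranks[o]
  knot_utilities <- knot_utilities[o]
  if (is.unsorted(rev(knot_utilities)))
    stop("knot utilities must be non-increasing in the CAT total")
  structure(
    list(kind = "mrm", name = name, note = note,
         cat_totals = as.numeric(cat_totals),
         mean_ranks = as.numeric(mean_ranks),
         knot_utilities = as.numeric(knot_utilities),
         utilities = as.numeric(utilities), n = as.integer(n)),
    class = c("mrm_table", "model_spec")
  )
}

#' Predict utilities with a Mean Rank Method table
#'
#' Knot CAT totals return their mapped utility exactly; CAT totals between
#' knots are linearly interpolated; values beyond the extreme knots are
#' clamped to the nearest knot's utility. Predictions are monotone
#' non-increasing in the CAT total.
#'
#' @param table an \code{mrm_table} from \code{\link{build_mrm_table}}.
#' @param cat_total numeric vector of CAT totals in [0, 40].
#' @return Numeric vector of predicted utilities.
#' @export
predict_utility_mrm <- function(table, cat_total) {
  stopifnot(inherits(table, "mrm_table"))
  if (any(is.na(cat_total) | cat_total < 0 | cat_total > 40))
    stop("cat_total must be within [0, 40]")
  if (length(table$cat_totals) == 1L)
    return(rep(table$knot_utilities, length(cat_total)))
  stats::approx(table$cat_totals, table$knot_utilities, xout = cat_total,
                method = "linear", rule = 2)$y
}

#' @export
print.mrm_table <- function(x, ...) {
  cat("<mrm_table: ", length(x$cat_totals), " knots from ", x$n,
      " training observations>\n", sep = "")
  invisible(x)
}
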