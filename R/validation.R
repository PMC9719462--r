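#' Mean absolute error and root mean squared error
#'
#' Observation-level error summaries between predicted and observed
#' utilities: every visit is weighted equally.
#'
#' @param pred,actual numeric vectors of equal, nonzero length.
#' @return A scalar.
#' @examples
#' mae(c(0, 0.2), c(0, 0))  # 0.1
#' rmse(c(0, 0.2), c(0, 0)) # 0.1414...
#' @export
mae <- function(pred, actual) {
  check_paired(pred, actual)
  mean(abs(pred - actual))
}

#' @rdname mae
#' @export
rmse <- function(pred, actual) {
  check_paired(pred, actual)
  sqrt(mean((pred - actual)^2))
}

check_paired <- function(pred, actual) {
  if (length(pred) != length(actual))
    stop("pred and actual must have equal length")
  if (length(pred) == 0L) stop("empty input")
  invisible(NULL)
}

#' Pearson correlation
#'
#' Product-moment correlation between two paired numeric vectors, with
#' explicit degenerate-input errors.
#'
#' @param x,y numeric vectors of equal length (at least 2 pairs).
#' @return The correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  stats::cor(x, y, method = "pearson")
}

#' Subgroup validation report
#'
#' Summarizes prediction accuracy the way mapping studies tabulate it:
#' the full validation set, then three partitions into subgroups —
#' airflow-severity stage (1/2/3), observed-utility bands ([0, 0.25),
#' [0.25, 0.5), [0.5, 0.75), [0.75, Inf); lower-inclusive, top band
#' closed) and CAT-total bands (0–10, 11–20, 21–30, 31–40, inclusive
#' integer ranges). Each row reports the observation count, mean /
#' min / max predicted utility, MAE and RMSE.
#'
#' @param df data.frame with columns \code{pred_utility} and
#'   \code{utility} (observed); \code{cat_total} and \code{stage} are used
#'   when present.
#' @return A data.frame of class \code{validation_report} with columns
#'   \code{partition, subgroup, n, mean, min, max, mae, rmse}. Empty
#'   subgroups keep \code{n = 0} with \code{NA} summaries.
#' @export
subgroup_report <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$pred_utility)) stop("column 'pred_utility' is required")
  if (is.null(df$utility) || anyNA(df$utility))
    stop("observed 'utility' is required for every observation")
  row_of <- function(partition, subgroup, idx) {
    if (length(idx) == 0L)
      return(data.frame(partition = partition, subgroup = subgroup, n = 0L,
                        mean = NA_real_, min = NA_real_, max = NA_real_,
                        mae = NA_real_, rmse = NA_real_))
    p <- df$pred_utility[idx]; a <- df$utility[idx]
    data.frame(partition = partition, subgroup = subgroup, n = length(idx),
               mean = mean(p), min = min(p), max = max(p),
               mae = mae(p, a), rmse = rmse(p, a))
  }
  rows <- list(row_of("full", "full", seq_len(nrow(df))))
  if (!is.null(df$stage)) {
    for (s in 1:3)
      rows <- c(rows, list(row_of("stage", paste0("stage ", s),
                                  which(df$stage == s))))
  }
  ub <- utility_bands()
  for (i in seq_len(nrow(ub))) {
    idx <- if (is.finite(ub$hi[i]))
      which(df$utility >= ub$lo[i] & df$utility < ub$hi[i])
    else which(df$utility >= ub$lo[i])
    rows <- c(rows, list(row_of("utility", ub$label[i], idx)))
  }
  if (!is.null(df$cat_total)) {
    cb <- cat_bands()
    for (i in seq_len(nrow(cb)))
      rows <- c(rows, list(row_of("cat", cb$label[i],
                                  which(df$cat_total >= cb$lo[i] &
                                        df$cat_total <= cb$hi[i]))))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", "data.frame")
  out
}

# Band edges as tabulated in mapping studies; the bottom band is open
# below so states valued worse than dead still fall in a band.
utility_bands <- function() data.frame(
  lo = c(-Inf, 0.25, 0.5, 0.75), hi = c(0.25, 0.5, 0.75, Inf),
  label = c("utility: <0.25", "utility: 0.25 - <0.5",
            "utility: 0.5 - <0.75", "utility: >=0.75")
)

cat_bands <- function() data.frame(
  lo = c(0, 11, 21, 31), hi = c(10, 20, 30, 40),
  label = c("0 <= CAT <= 10", "11 <= CAT <= 20",
            "21 <= CAT <= 30", "31 <= CAT <= 40")
)

#' Bubble-chart grid of predicted versus observed utilities
#'
#' Bins paired predicted and observed utilities on a common grid over
#' [-0.7, 1] (half-open bins, final bin closed above) and counts pairs in
#' each cell — the data behind a calibration bubble chart, where bubble
#' size encodes the cell count and a well-calibrated model concentrates
#' mass on the diagonal.
#'
#' @param pred,actual numeric vectors of equal length; all finite.
#' @param bin_width bin width (default 0.05).
#' @return An object of class \code{bubble_grid}: a data.frame of
#'   occupied cells (\code{pred_bin}, \code{actual_bin} — bin lower
#'   edges — and \code{n}), with the bin edges and total count as
#'   attributes.
#' @export
bubble_grid <- function(pred, actual, bin_width = 0.05) {
  check_paired(pred, actual)
  if (!all(is.finite(pred)) || !all(is.finite(actual)))
    stop("pred and actual must be finite")
  edges <- round(seq(-0.7, 1, by = bin_width), 10)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin_of <- function(v) {
    if (any(v < edges[1L] | v > 1))
      stop("values outside the [-0.7, 1] utility range")
    i <- findInterval(v, edges, rightmost.closed = TRUE)
    edges[i]
  }
  cells <- stats::aggregate(
    list(n = rep(1L, length(pred))),
    by = list(pred_bin = bin_of(pred), actual_bin = bin_of(actual)),
    FUN = sum
  )
  cells <- cells[order(cells$pred_bin, cells$actual_bin), , drop = FALSE]
  rownames(cells) <- NULL
  structure(cells, class = c("bubble_grid", "data.frame"),
            bin_width = bin_width, edges = edges, total = length(pred))
}

#' Plot a bubble grid
#'
#' Base-graphics rendering of a \code{\link{bubble_grid}}: bubble area
#' proportional to the cell count, with the identity line.
#'
#' @param x a \code{bubble_grid}.
#' @param ... further arguments passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.bubble_grid <- function(x, ...) {
  w <- attr(x, "bin_width")
  cx <- 0.3 + 2.7 * sqrt(x$n / max(x$n))
  plot(x$pred_bin + w / 2, x$actual_bin + w / 2, cex = cx,
       xlim = c(-0.7, 1), ylim = c(-0.7, 1),
       xlab = "Predicted utility", ylab = "Observed utility", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Validate a mapping model on an observation table
#'
#' Convenience wrapper: predicts with \code{\link{predict_observations}},
#' then produces the subgroup report and bubble grid against the observed
#' utilities.
#'
#' @param spec a \code{model_spec} or built-in name.
#' @param df observation data.frame with observed \code{utility}.
#' @param tariff tariff for response mapping.
#' @param bin_width bubble-grid bin width.
#' @return List with \code{predictions}, \code{report} and \code{bubbles}.
#' @export
validate_model <- function(spec, df, tariff = taiwan_tariff(),
                           bin_width = 0.05) {
  pr <- predict_observations(spec, df, tariff)
  list(predictions = pr,
       report = subgroup_report(pr),
       bubbles = bubble_grid(pmin(pmax(pr$pred_utility, -0.7), 1),
                             pr$utility, bin_width))
}
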