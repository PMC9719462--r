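#' @title Long-format observation tables
#' @description
#' Observations are stored as a plain \code{data.frame}, one row per clinic
#' visit, with columns:
#' \itemize{
#'   \item \code{patient_id} — opaque patient identifier;
#'   \item \code{visit} — positive visit index;
#'   \item \code{age} — age in years at the visit;
#'   \item \code{sex_code} — 0/1 sex code (default coding: male = 1,
#'     female = 0; see \code{sex_coding});
#'   \item \code{q1}..\code{q8} — CAT item scores, each 0..5 (cough,
#'     phlegm, chest tightness, breathlessness, activities, confidence,
#'     sleep, energy);
#'   \item \code{cat_total} — row sum of the eight items (recomputed on
#'     read);
#'   \item optional \code{mo}, \code{sc}, \code{ua}, \code{pd}, \code{ad}
#'     — observed EQ-5D-3L levels (1..3);
#'   \item optional \code{utility} — observed utility;
#'   \item optional \code{stage} — airflow-limitation severity 1..3
#'     (stage 3 = FEV1 below 50\% predicted, the merged severe group).
#' }
#' @name observations
NULL

cat_item_cols <- function() paste0("q", 1:8)

required_obs_cols <- function()
  c("patient_id", "visit", "age", "sex_code", cat_item_cols())

#' Read a long-format observation table from CSV
#'
#' Reads comma-separated UTF-8 text with a header row, validates every row
#' and computes the CAT total. Rows with a missing or out-of-range CAT item
#' are rejected: the mapping models have no imputation rule, so predictions
#' require complete item responses.
#'
#' @param file path to a CSV file, or a connection.
#' @return A validated observation \code{data.frame} (see
#'   \link{observations}).
#' @seealso \code{\link{write_observations}}, \code{\link{as_observations}}
#' @export
read_observations <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  as_observations(df)
}

#' Validate a data frame of observations
#'
#' Checks column presence, CAT item ranges, EQ-5D levels and visit indices;
#' computes \code{cat_total}; and, where both an EQ-5D state and a utility
#' are present, checks that the utility equals the Taiwanese tariff value
#' of the state (within 1e-9).
#'
#' @param df a data.frame with the columns described in
#'   \link{observations}.
#' @param check_utility if \code{TRUE} (default), enforce the
#'   utility/tariff consistency check on rows carrying both.
#' @return The validated data.frame with \code{cat_total} (re)computed.
#' @export
as_observations <- function(df, check_utility = TRUE) {
  missing_cols <- setdiff(required_obs_cols(), names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  items <- cat_item_cols()
  for (cn in items) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      df[[cn]] <- v
    }
    bad <- which(is.na(v) | v < 0 | v > 5 | v != round(v))
    if (length(bad))
      stop(sprintf("CAT item '%s' out of range 0..5 (or missing) at row %d",
                   cn, bad[1L]))
  }
  if (any(is.na(df$visit) | df$visit < 1))
    stop("visit must be a positive integer")
  if (any(is.na(df$age) | df$age < 0))
    stop("age must be >= 0")
  if (!all(df$sex_code %in% c(0, 1)))
    stop("sex_code must be 0 or 1")
  df$cat_total <- as.integer(rowSums(df[items]))
  dims <- eq5d_dimensions()
  has_state_cols <- all(dims %in% names(df))
  if (has_state_cols) {
    present <- stats::complete.cases(df[dims])
    lv <- as.matrix(df[present, dims, drop = FALSE])
    if (length(lv) && !all(lv %in% 1:3))
      stop("EQ-5D levels must be 1, 2 or 3")
    if (check_utility && "utility" %in% names(df)) {
      both <- present & !is.na(df$utility)
      if (any(both)) {
        u <- utility_from_state(df[both, dims, drop = FALSE])
        off <- which(abs(u - df$utility[both]) > 1e-9)
        if (length(off))
          stop("utility inconsistent with tariff of the recorded EQ-5D ",
               "state at row ", which(both)[off[1L]])
      }
    }
  }
  if ("stage" %in% names(df)) {
    st <- df$stage[!is.na(df$stage)]
    if (length(st) && !all(st %in% 1:3))
      stop("stage must be 1, 2 or 3")
  }
  df
}

#' Write an observation table to CSV
#'
#' Inverse of \code{\link{read_observations}}: a round trip through
#' \code{write_observations} then \code{read_observations} reproduces the
#' table field for field.
#'
#' @param df a validated observation data.frame.
#' @param file output path or connection.
#' @export
write_observations <- function(df, file) {
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Split observations into training and validation sets by patient
#'
#' Partitions the distinct patients (never individual visits) at random so
#' that every observation of a patient falls on exactly one side, matching
#' the development protocol of holding out whole patients from a
#' repeated-measures cohort.
#'
#' @param df an observation data.frame.
#' @param n_train number of patients assigned to the training side.
#' @param seed integer seed; the same seed always yields the same
#'   partition.
#' @return A list with components \code{train} and \code{validation},
#'   each an observation data.frame.
#' @examples
#' obs <- simulate_cohort(sim_params(n_patients = 20), seed = 1)
#' sp <- split_by_patient(obs, n_train = 10, seed = 42)
#' length(unique(sp$train$patient_id)) # 10
#' @export
split_by_patient <- function(df, n_train, seed) {
  ids <- unique(df$patient_id)
  if (n_train > length(ids))
    stop(sprintf("n_train (%d) exceeds the number of distinct patients (%d)",
                 n_train, length(ids)))
  rng <- local_rng(seed)
  train_ids <- sample(ids, n_train)
  rng()
  in_train <- df$patient_id %in% train_ids
  list(
    train = df[in_train, , drop = FALSE],
    validation = df[!in_train, , drop = FALSE]
  )
}

# Set the RNG to a reproducible state and return a restorer callback.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Default sex coding used by the mapping models
#'
#' The mapping equations include a 0/1 sex covariate. The coding is not
#' universal across instruments, so it is explicit here: by default male
#' is coded 1 and female 0. Predictions that use sex are sensitive to this
#' coding; data prepared under the opposite convention must be recoded
#' before prediction.
#'
#' @return Named integer vector \code{c(male = 1, female = 0)}.
#' @export
sex_coding <- function() c(male = 1L, female = 0L)
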