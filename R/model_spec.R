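#' @title Mapping model specifications
#' @description
#' A \code{model_spec} is a tagged description of one mapping algorithm:
#' \itemize{
#'   \item \code{mlr_response} — five per-dimension multinomial logistic
#'     models; the predicted EQ-5D-3L state is scored with a tariff;
#'   \item \code{direct_ols} — a single linear equation for the utility;
#'   \item \code{two_part} — a classifier into utility groups (1, middle,
#'     low) plus per-group outcome equations;
#'   \item \code{mrm} — a Mean Rank Method lookup table.
#' }
#' Specs serialize to a versioned JSON document so fitted models can be
#' stored and exchanged; \code{load_model_spec} also resolves the names of
#' the built-in published models (see \code{\link{builtin_model_names}}).
#' @name model_spec
NULL

SPEC_SCHEMA_VERSION <- 1L

#' Per-dimension multinomial logit component
#'
#' Holds the level-2 and level-3 logit coefficient vectors of one EQ-5D
#' dimension, relative to level 1. Coefficient vectors are named, with
#' \code{"(Intercept)"} first followed by the covariates.
#'
#' @param covariates character vector of covariate (column) names.
#' @param beta2,beta3 numeric vectors of length \code{length(covariates)+1}
#'   (intercept first) for the level-2 and level-3 logits.
#' @return An object of class \code{mnl_dimension_model}.
#' @export
mnl_dimension_model <- function(covariates, beta2, beta3) {
  p <- length(covariates) + 1L
  if (length(beta2) != p || length(beta3) != p)
    stop("beta2 and beta3 must each have one coefficient per covariate ",
         "plus an intercept")
  nm <- c("(Intercept)", covariates)
  structure(
    list(covariates = covariates,
         beta2 = stats::setNames(as.numeric(beta2), nm),
         beta3 = stats::setNames(as.numeric(beta3), nm)),
    class = "mnl_dimension_model"
  )
}

#' Construct a response-mapping (MLR) model spec
#'
#' @param name model name.
#' @param dimensions named list of five \code{\link{mnl_dimension_model}}
#'   objects, names \code{mo, sc, ua, pd, ad}.
#' @param note free-text provenance note.
#' @return A \code{model_spec} of kind \code{mlr_response}.
#' @export
mlr_response_spec <- function(name, dimensions, note = "") {
  dims <- eq5d_dimensions()
  if (!setequal(names(dimensions), dims))
    stop("dimensions must be a named list over: ", paste(dims, collapse = ", "))
  if (!all(vapply(dimensions, inherits, TRUE, "mnl_dimension_model")))
    stop("each dimension entry must be an mnl_dimension_model")
  structure(
    list(kind = "mlr_response", name = name, note = note,
         dimensions = dimensions[dims]),
    class = c("mlr_response_spec", "model_spec")
  )
}

#' Construct a direct OLS model spec
#'
#' @param name model name.
#' @param intercept numeric intercept.
#' @param slopes named numeric vector of slope coefficients over CAT item
#'   columns (\code{q1}..\code{q8}), \code{cat_total} and/or \code{age}.
#' @param note free-text provenance note.
#' @return A \code{model_spec} of kind \code{direct_ols}.
#' @export
direct_ols_spec <- function(name, intercept, slopes, note = "") {
  if (length(slopes) < 1L || is.null(names(slopes)) || any(names(slopes) == ""))
    stop("slopes must be a non-empty named numeric vector")
  structure(
    list(kind = "direct_ols", name = name, note = note,
         intercept = as.numeric(intercept),
         slopes = vapply(slopes, as.numeric, 0)),
    class = c("direct_ols_spec", "model_spec")
  )
}

#' Construct a two-part model spec
#'
#' The classifier part consists of two logistic-style group expressions
#' sharing one set of item slopes with distinct intercepts: one for the
#' utility = 1 group and one for the middle (0.5 < utility < 1) group; the
#' low group's value is one minus the other two. The expressions are
#' evaluated exactly as published — in the re-estimated variant the middle
#' expression's denominator reuses the top intercept
#' (\code{mid_denom = "top"}) — so they need not form a coherent
#' probability triple; group selection by maximum remains well defined.
#'
#' @param name model name.
#' @param slopes named numeric vector of shared classifier slopes over CAT
#'   items.
#' @param intercept_top,intercept_mid classifier intercepts for the
#'   utility = 1 and middle groups.
#' @param mid_denom \code{"own"} (middle expression uses its own intercept
#'   in its denominator) or \code{"top"} (reuses the top intercept, as
#'   printed for the re-estimated variant).
#' @param eq_mid list with \code{intercept} and named \code{slopes}: the
#'   middle group's outcome equation.
#' @param eq_low list with \code{intercept} and \code{slope_cat_total}:
#'   the low group's outcome equation over the CAT total.
#' @param note free-text provenance note.
#' @return A \code{model_spec} of kind \code{two_part}.
#' @export
two_part_spec <- function(name, slopes, intercept_top, intercept_mid,
                          mid_denom = c("own", "top"), eq_mid, eq_low,
                          note = "") {
  mid_denom <- match.arg(mid_denom)
  stopifnot(is.numeric(slopes), !is.null(names(slopes)),
            is.list(eq_mid), is.list(eq_low))
  structure(
    list(kind = "two_part", name = name, note = note,
         slopes = slopes,
         intercept_top = as.numeric(intercept_top),
         intercept_mid = as.numeric(intercept_mid),
         mid_denom = mid_denom,
         eq_mid = list(intercept = as.numeric(eq_mid$intercept),
                       slopes = eq_mid$slopes),
         eq_low = list(intercept = as.numeric(eq_low$intercept),
                       slope_cat_total = as.numeric(eq_low$slope_cat_total))),
    class = c("two_part_spec", "model_spec")
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec kind=", x$kind, " name=", x$name, ">\n", sep = "")
  invisible(x)
}

#' Serialize a model spec to JSON
#'
#' @param spec a \code{model_spec}.
#' @param file optional path; when omitted the JSON text is returned.
#' @return The JSON text (invisibly when written to \code{file}).
#' @seealso \code{\link{load_model_spec}}
#' @export
write_model_spec <- function(spec, file = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  doc <- spec_to_list(spec)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

spec_to_list <- function(spec) {
  base <- list(schema_version = SPEC_SCHEMA_VERSION, kind = spec$kind,
               name = spec$name, note = spec$note)
  body <- switch(spec$kind,
    mlr_response = list(
      dimensions = lapply(spec$dimensions, function(d)
        list(covariates = as.list(d$covariates),
             beta2 = num_to_json(d$beta2),
             beta3 = num_to_json(d$beta3)))
    ),
    direct_ols = list(intercept = spec$intercept,
                      slopes = as.list(spec$slopes)),
    two_part = list(slopes = as.list(spec$slopes),
                    intercept_top = spec$intercept_top,
                    intercept_mid = spec$intercept_mid,
                    mid_denom = spec$mid_denom,
                    eq_mid = list(intercept = spec$eq_mid$intercept,
                                  slopes = as.list(spec$eq_mid$slopes)),
                    eq_low = list(intercept = spec$eq_low$intercept,
                                  slope_cat_total = spec$eq_low$slope_cat_total)),
    mrm = list(cat_totals = spec$cat_totals,
               mean_ranks = spec$mean_ranks,
               knot_utilities = spec$knot_utilities,
               utilities = spec$utilities,
               n = spec$n),
    stop("unknown model kind: ", spec$kind)
  )
  c(base, body)
}

#' Load a model spec from JSON or by built-in name
#'
#' @param x a built-in model name (see \code{\link{builtin_model_names}}),
#'   a path to a JSON spec file, or a JSON string.
#' @return A validated \code{model_spec}.
#' @examples
#' spec <- load_model_spec("hoyle_m3")
#' spec$intercept # 0.9831816
#' @export
load_model_spec <- function(x) {
  if (inherits(x, "model_spec")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (x %in% builtin_model_names()) return(builtin_model(x))
  if (!grepl("^\\s*\\{", x) && !file.exists(x))
    stop("'", x, "' is neither a built-in model name, an existing file, ",
         "nor JSON text")
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  spec_from_list(doc)
}

spec_from_list <- function(doc) {
  if (is.null(doc$kind)) stop("model spec document lacks a 'kind' tag")
  nm <- if (is.null(doc$name)) "unnamed" else doc$name
  note <- if (is.null(doc$note)) "" else doc$note
  switch(doc$kind,
    mlr_response = {
      dims <- lapply(doc$dimensions, function(d) {
        if (is.null(d$beta3))
          stop("mlr_response dimension lacks the level-3 coefficient block")
        mnl_dimension_model(unlist(d$covariates),
                            json_num(d$beta2), json_num(d$beta3))
      })
      mlr_response_spec(nm, dims, note)
    },
    direct_ols = direct_ols_spec(nm, doc$intercept, unlist(doc$slopes), note),
    two_part = two_part_spec(nm, unlist(doc$slopes), doc$intercept_top,
                             doc$intercept_mid, doc$mid_denom,
                             eq_mid = list(intercept = doc$eq_mid$intercept,
                                           slopes = unlist(doc$eq_mid$slopes)),
                             eq_low = doc$eq_low, note = note),
    mrm = new_mrm_table(cat_totals = json_num(doc$cat_totals),
                        mean_ranks = json_num(doc$mean_ranks),
                        knot_utilities = json_num(doc$knot_utilities),
                        utilities = json_num(doc$utilities),
                        n = doc$n, name = nm, note = note),
    stop("unknown model kind: ", doc$kind)
  )
}

# -Inf -> JSON null (a logit of a level unobserved at fit time).
num_to_json <- function(v)
  lapply(unname(v), function(x) if (is.finite(x)) x else NULL)

# JSON null -> -Inf (used for a logit of an unobserved level).
json_num <- function(x) {
  if (is.list(x)) vapply(x, function(v) if (is.null(v)) -Inf else as.numeric(v), 0)
  else as.numeric(x)
}
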