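#' Taiwanese EQ-5D-3L time-trade-off value set
#'
#' Returns the Taiwanese time-trade-off (TTO) tariff for the EQ-5D-3L: a
#' constant decrement applied to any state other than full health, a
#' decrement per dimension at level 2 or level 3, and an extra "N3"
#' decrement applied once if any dimension is at level 3.
#'
#' @return An object of class \code{tariff_table} with components
#'   \code{constant} (scalar), \code{dec2} and \code{dec3} (named numeric
#'   vectors over the five dimensions \code{mo}, \code{sc}, \code{ua},
#'   \code{pd}, \code{ad}) and \code{n3} (scalar).
#' @examples
#' tt <- taiwan_tariff()
#' utility_from_state(c(1, 1, 1, 1, 1), tt) # 1
#' utility_from_state(c(2, 1, 1, 1, 1), tt) # 0.692
#' @export
taiwan_tariff <- function() {
  new_tariff_table(
    constant = 0.185,
    dec2 = c(mo = 0.123, sc = 0.167, ua = 0.085, pd = 0.121, ad = 0.154),
    dec3 = c(mo = 0.272, sc = 0.276, ua = 0.208, pd = 0.261, ad = 0.282),
    n3 = 0.190,
    name = "taiwan_tto"
  )
}

#' Construct a tariff table
#'
#' Build a custom EQ-5D-3L value set with the same structure as
#' \code{\link{taiwan_tariff}} so alternative national tariffs can be
#' plugged into every mapping function.
#'
#' @param constant decrement applied to any non-full-health state.
#' @param dec2,dec3 named numeric vectors of per-dimension decrements for
#'   levels 2 and 3; names must be \code{mo, sc, ua, pd, ad}.
#' @param n3 decrement applied once if any dimension is at level 3.
#' @param name optional label.
#' @return A \code{tariff_table}.
#' @export
new_tariff_table <- function(constant, dec2, dec3, n3, name = "custom") {
  dims <- eq5d_dimensions()
  stopifnot(
    is.numeric(constant), length(constant) == 1L,
    is.numeric(n3), length(n3) == 1L
  )
  dec2 <- dec2[dims]
  dec3 <- dec3[dims]
  if (anyNA(dec2) || anyNA(dec3))
    stop("dec2 and dec3 must be named over dimensions: ",
         paste(dims, collapse = ", "))
  if (constant < 0 || n3 < 0 || any(dec2 < 0) || any(dec3 < 0))
    stop("all tariff decrements must be >= 0")
  if (any(dec3 < dec2))
    stop("level-3 decrements must be >= level-2 decrements in every dimension")
  structure(
    list(constant = constant, dec2 = dec2, dec3 = dec3, n3 = n3, name = name),
    class = "tariff_table"
  )
}

#' EQ-5D-3L dimension codes
#'
#' @return Character vector \code{c("mo","sc","ua","pd","ad")}: mobility,
#'   self-care, usual activities, pain/discomfort, anxiety/depression.
#' @export
eq5d_dimensions <- function() c("mo", "sc", "ua", "pd", "ad")

#' @export
print.tariff_table <- function(x, ...) {
  cat("EQ-5D-3L tariff table (", x$name, ")\n", sep = "")
  cat("  constant:", format(x$constant), "  N3:", format(x$n3), "\n")
  tab <- rbind(`level 2` = x$dec2, `level 3` = x$dec3)
  print(tab)
  invisible(x)
}

#' Convert EQ-5D-3L states to utilities
#'
#' Applies a tariff to one or more EQ-5D-3L states. The full-health state
#' (1,1,1,1,1) maps to utility 1; any other state is scored as
#' 1 minus the constant, minus the per-dimension level decrements, minus
#' the N3 decrement if any dimension is at level 3 (applied at most once).
#'
#' @param state an integer vector of length 5 (levels of mobility,
#'   self-care, usual activities, pain/discomfort, anxiety/depression, each
#'   in 1..3), or an n-by-5 matrix / data.frame of such states.
#' @param tariff a \code{tariff_table}; defaults to \code{taiwan_tariff()}.
#' @param literal if \code{TRUE}, evaluate the scoring formula verbatim so
#'   the constant is subtracted even from (1,1,1,1,1). Intended for audit
#'   only; the default treats full health as the anchor at 1.
#' @return Numeric vector of utilities, one per state.
#' @examples
#' utility_from_state(c(3, 3, 3, 3, 3)) # -0.674, the worst state
#' @export
utility_from_state <- function(state, tariff = taiwan_tariff(),
                               literal = FALSE) {
  m <- as_state_matrix(state)
  if (anyNA(m) || !all(m %in% c(1L, 2L, 3L)))
    stop("EQ-5D-3L levels must all be 1, 2 or 3")
  dec <- rep(0, nrow(m))
  for (j in seq_len(5L)) {
    lv <- m[, j]
    dec <- dec + ifelse(lv == 2L, tariff$dec2[[j]],
                        ifelse(lv == 3L, tariff$dec3[[j]], 0))
  }
  any3 <- rowSums(m == 3L) > 0L
  u <- 1 - tariff$constant - dec - tariff$n3 * any3
  if (!literal) {
    full <- rowSums(m == 1L) == 5L
    u[full] <- 1
  }
  unname(u)
}

#' All 243 EQ-5D-3L states
#'
#' @return A 243-by-5 integer matrix of every level combination, columns
#'   named by dimension.
#' @export
all_eq5d_states <- function() {
  g <- expand.grid(ad = 1:3, pd = 1:3, ua = 1:3, sc = 1:3, mo = 1:3)
  m <- as.matrix(g[, eq5d_dimensions()])
  storage.mode(m) <- "integer"
  m
}

# Coerce a state vector / matrix / data.frame to an n-by-5 integer matrix.
as_state_matrix <- function(state) {
  if (is.data.frame(state)) state <- as.matrix(state)
  if (is.matrix(state)) {
    if (ncol(state) != 5L) stop("state matrix must have 5 columns")
    m <- state
  } else {
    if (length(state) != 5L) stop("a state must have 5 levels")
    m <- matrix(state, nrow = 1L)
  }
  storage.mode(m) <- "integer"
  colnames(m) <- eq5d_dimensions()
  m
}
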