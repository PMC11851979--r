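#' Design factors of the simulation study
#'
#' The condition grid crosses five factors:
#' complexity of the nonlinear relationship (simple / medium / high),
#' number of Likert independent variables (3 / 5 / 10),
#' linear coefficient level (small: U\[0.1, 0.3\]; large: U\[0.5, 1\]),
#' nonlinear coefficient level (same two levels), and
#' error multiplier coferr (1 / 4 / 10) scaling the additive N(0,1) noise.
#' The full cartesian grid has 3 x 2 x 2 x 3 x 3 = 108 cells.
#'
#' @name design-factors
#' @keywords internal
NULL

.complexity_levels <- c("simple", "medium", "high")
.coef_levels <- c("small", "large")
.n_iv_levels <- c(3L, 5L, 10L)
.error_levels <- c(1, 4, 10)

#' Construct a condition specification
#'
#' One cell of the 108-condition design. Factors may be given either as
#' labels (`"simple"`, `"small"`, ...) or as the integer codes used in the
#' wide results table (complexity 1/2/3, coefficient levels 1/2).
#'
#' @param complexity `"simple"`, `"medium"` or `"high"` (or codes 1:3).
#' @param n_iv number of Likert independent variables: 3, 5 or 10.
#' @param linear_level `"small"` or `"large"` (or codes 1:2) — range of the
#'   linear coefficients.
#' @param nonlinear_level `"small"` or `"large"` (or codes 1:2) — range of
#'   the nonlinear coefficients.
#' @param error_coef error multiplier: 1, 4 or 10.
#' @return an object of class `condition_spec`.
#' @export
#' @examples
#' condition_spec("medium", 3, "small", "large", 1)
#' condition_spec(2, 3, 1, 2, 1) # same cell, integer coding
condition_spec <- function(complexity, n_iv, linear_level, nonlinear_level,
                           error_coef) {
  decode <- function(x, levels, what) {
    if (is.numeric(x)) {
      if (!x %in% seq_along(levels))
        stop(sprintf("invalid %s code: %s", what, x), call. = FALSE)
      levels[[x]]
    } else {
      x <- match.arg(x, levels)
      x
    }
  }
  complexity <- decode(complexity, .complexity_levels, "complexity")
  linear_level <- decode(linear_level, .coef_levels, "linear_level")
  nonlinear_level <- decode(nonlinear_level, .coef_levels, "nonlinear_level")
  if (!n_iv %in% .n_iv_levels)
    stop("n_iv must be one of 3, 5, 10", call. = FALSE)
  if (!error_coef %in% .error_levels)
    stop("error_coef must be one of 1, 4, 10", call. = FALSE)
  structure(
    list(complexity = complexity, n_iv = as.integer(n_iv),
         linear_level = linear_level, nonlinear_level = nonlinear_level,
         error_coef = as.numeric(error_coef)),
    class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf(
    "<condition %d> complexity=%s, n_iv=%d, linear=%s, nonlinear=%s, coferr=%g\n",
    condition_id(x), x$complexity, x$n_iv, x$linear_level,
    x$nonlinear_level, x$error_coef))
  invisible(x)
}

#' The full 108-cell condition grid
#'
#' Returns the design grid in its canonical order: complexity varies
#' fastest, then the nonlinear coefficient level, then the linear level,
#' then the error multiplier, and the number of IVs varies slowest. Row `i`
#' is condition `i`; this ordering is the one used in the wide results
#' table, so condition ids are comparable across functions.
#'
#' @return a data.frame with 108 rows and columns `condition_id`,
#'   `complexity`, `linear_level`, `nonlinear_level`, `error_coef`, `n_iv`
#'   (integer codes for the first three factor columns as in the results
#'   table, natural values for `error_coef` and `n_iv`).
#' @export
#' @examples
#' g <- condition_grid()
#' nrow(g) # 108
#' g[5, ]  # medium complexity, small linear, large nonlinear, coferr 1, 3 IVs
condition_grid <- function() {
  g <- expand.grid(
    complexity = 1:3,
    nonlinear_level = 1:2,
    linear_level = 1:2,
    error_coef = .error_levels,
    n_iv = .n_iv_levels,
    KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("complexity", "linear_level", "nonlinear_level",
             "error_coef", "n_iv")]
  data.frame(condition_id = seq_len(nrow(g)), g)
}

#' Map a condition id to its specification
#'
#' @param id integer in 1..108.
#' @return a `condition_spec`.
#' @export
#' @examples
#' condition_from_id(5)
condition_from_id <- function(id) {
  stopifnot(length(id) == 1, id %in% 1:108)
  g <- condition_grid()[id, ]
  condition_spec(g$complexity, g$n_iv, g$linear_level, g$nonlinear_level,
                 g$error_coef)
}

#' Map a condition specification to its id
#'
#' Inverse of [condition_from_id()]; the two form a bijection between
#' 1..108 and the grid cells.
#'
#' @param condition a `condition_spec`.
#' @return integer condition id.
#' @export
condition_id <- function(condition) {
  stopifnot(inherits(condition, "condition_spec"))
  ic <- match(condition$complexity, .complexity_levels)
  inl <- match(condition$nonlinear_level, .coef_levels)
  il <- match(condition$linear_level, .coef_levels)
  ie <- match(condition$error_coef, .error_levels)
  iv <- match(condition$n_iv, .n_iv_levels)
  as.integer(ic + 3 * (inl - 1) + 6 * (il - 1) + 12 * (ie - 1) + 36 * (iv - 1))
}
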