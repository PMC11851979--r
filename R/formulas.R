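#' @title Registry of the nine data-generating formulas
#' @description
#' Each (complexity, n_iv) cell selects one generating formula for the
#' outcome Y. Every formula is a sum of terms, each term a coefficient times
#' a product of univariate functions of the latent predictors, plus a
#' coferr-scaled standard-normal noise term:
#'
#' * simple complexity: main effects plus two-way interactions;
#' * medium complexity: main effects, two-way interactions and quadratics;
#' * high complexity: the medium terms plus one extra term — an exponential
#'   `exp(x)` for 3 and 5 IVs, and a bare linear term carrying a nonlinear
#'   coefficient for 10 IVs (the formulas are implemented exactly as
#'   published, including the 5-IV high-complexity formula reusing its
#'   first nonlinear coefficient on two interaction terms).
#'
#' A term is represented as `list(role, idx, vars, p, t)`: the coefficient
#' is `cof[idx]` or `conf[idx]` according to `role`, and the term value is
#' `prod_j vars[j]^p[j] * exp(t[j] * vars[j])` evaluated on the latent (or,
#' for the regression design, Likertized) columns.
#' @name formula-registry
#' @keywords internal
NULL

.term <- function(role, idx, vars, p, t = rep(0, length(vars))) {
  list(role = role, idx = as.integer(idx), vars = as.integer(vars),
       p = as.numeric(p), t = as.numeric(t))
}
.main <- function(role, idx, j) .term(role, idx, j, 1)
.inter <- function(idx, j, k) .term("conf", idx, c(j, k), c(1, 1))
.square <- function(idx, j) .term("conf", idx, j, 2)
.expterm <- function(idx, j) .term("conf", idx, j, 0, 1)

#' Generating terms for a condition
#'
#' Returns the ordered term list of the data-generating formula selected by
#' the condition's (complexity, n_iv) cell, excluding the noise term.
#'
#' @param condition a [condition_spec()].
#' @return a list of class `generating_design`: elements `terms` (list of
#'   term descriptors), `n_cof`, `n_conf` (required coefficient-vector
#'   lengths; note a coefficient may appear in more than one term).
#' @export
#' @examples
#' d <- generating_terms(condition_spec("medium", 3, "small", "large", 1))
#' length(d$terms) # 7: three mains, two interactions, two quadratics
generating_terms <- function(condition) {
  stopifnot(inherits(condition, "condition_spec"))
  cx <- condition$complexity
  k <- condition$n_iv
  mains <- function(n) lapply(seq_len(n), function(j) .main("cof", j, j))
  terms <- if (k == 3) {
    base <- c(mains(3), list(.inter(1, 1, 2), .inter(2, 2, 3)))
    switch(cx,
      simple = base,
      medium = c(base, list(.square(3, 1), .square(4, 2))),
      high = c(base, list(.square(3, 1), .square(4, 2), .expterm(5, 1))))
  } else if (k == 5) {
    if (cx == "high") {
      # published high-complexity 5-IV formula: conf1 multiplies both
      # interactions, the remaining nonlinear coefficients shift down
      c(mains(3), list(.inter(1, 1, 2), .inter(1, 4, 5),
                       .square(2, 1), .square(3, 5), .expterm(4, 4)))
    } else {
      base <- c(mains(3), list(.inter(1, 1, 2), .inter(2, 4, 5)))
      switch(cx,
        simple = base,
        medium = c(base, list(.square(3, 1), .square(4, 5))))
    }
  } else { # 10 IVs
    base <- c(mains(6), list(.inter(1, 7, 8), .inter(2, 9, 10)))
    switch(cx,
      simple = base,
      medium = c(base, list(.square(3, 5), .square(4, 10))),
      # the extra high-complexity term is the literal conf5 * x9
      high = c(base, list(.square(3, 5), .square(4, 10),
                          .term("conf", 5, 9, 1))))
  }
  roles <- vapply(terms, `[[`, "", "role")
  idx <- vapply(terms, `[[`, 1L, "idx")
  structure(
    list(terms = terms,
         n_cof = max(idx[roles == "cof"]),
         n_conf = max(idx[roles == "conf"])),
    class = "generating_design")
}

#' Regression design terms for the theoretical-maximum benchmark
#'
#' The theoretical maximum explainable variance Rt2 is the R-squared of an
#' ordinary least squares fit of Y on every generating term evaluated on
#' the *Likertized* predictors. This helper returns that term list: the
#' generating terms with duplicates (terms sharing one structure) collapsed.
#'
#' @param condition a [condition_spec()].
#' @return list of term descriptors (role/idx dropped; structure only).
#' @export
regression_terms <- function(condition) {
  d <- generating_terms(condition)
  keys <- vapply(d$terms, function(tm)
    paste(tm$vars, tm$p, tm$t, sep = "_", collapse = "|"), "")
  d$terms[!duplicated(keys)]
}

# Evaluate one term column on a numeric matrix (latent or Likert).
term_column <- function(tm, M) {
  out <- rep(1, nrow(M))
  for (j in seq_along(tm$vars)) {
    v <- M[, tm$vars[j]]
    if (tm$p[j] != 0) out <- out * v^tm$p[j]
    if (tm$t[j] != 0) out <- out * exp(tm$t[j] * v)
  }
  out
}

# Model matrix (without intercept) of a term list on M.
design_matrix <- function(terms, M) {
  cols <- vapply(terms, term_column, numeric(nrow(M)), M = M)
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = nrow(M))
  cols
}
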