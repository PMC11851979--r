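#' @title Reference performance oracles
#' @description
#' Two benchmark quantities anchor every MSSR decision:
#'
#' * **Rt2**, the theoretical maximum explainable variance: in-sample
#'   R-squared of an ordinary least squares fit of Y on *all* generating
#'   terms evaluated on the Likertized predictors. Because the regression
#'   contains every systematic term (up to Likertization), no predictor of
#'   the observed items can do better; the gap to 1 is the coferr noise
#'   plus the attenuation caused by discretization.
#' * **Rl2**, the linear benchmark: in-sample R-squared of a regression of
#'   Y on the Likert items entered linearly — the model a neural network
#'   must beat for its extra complexity to be worthwhile.
#'
#' The functions here estimate both once per condition on a dedicated
#' large sample (default n = 100,000), where in-sample optimism is
#' negligible; these condition-level values are what the wide decision
#' table reports. Inside the replication loop the same two benchmarks
#' are, by default, additionally re-fit per replication on the
#' replication's own partitions (see [run_replications()]).
#' @name oracles
#' @keywords internal
NULL

ols_r2 <- function(Z, y) {
  fit <- stats::lm.fit(cbind(1, Z), y)
  if (any(is.na(fit$coefficients))) {
    warning("singular design in oracle regression; dropped aliased columns")
  }
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("outcome has zero variance", call. = FALSE)
  1 - sum(fit$residuals^2) / sst
}

#' Estimate the theoretical maximum explainable variance Rt2
#'
#' @param condition a [condition_spec()].
#' @param coefs a [coefficient_set()].
#' @param n estimation sample size (default 100,000; at least 1000).
#' @param seed integer seed.
#' @param likert_method rounding convention passed to [likertize()].
#' @return in-sample R-squared of Y on the Likertized generating terms.
#' @export
#' @examples
#' \donttest{
#' estimate_rt2(condition_from_id(5), example_coefficients(1), seed = 1)
#' }
estimate_rt2 <- function(condition, coefs, n = 100000, seed,
                         likert_method = c("round", "ceiling")) {
  stopifnot(n >= 1000)
  ds <- generate_dataset(condition, n, coefs, seed, likert_method)
  Z <- design_matrix(regression_terms(condition), ds$X)
  ols_r2(Z, ds$Y)
}

#' Estimate the linear-benchmark performance Rl2
#'
#' R-squared of Y regressed on all Likert items entered linearly (main
#' effects only), on a large estimation sample.
#'
#' @inheritParams estimate_rt2
#' @return in-sample R-squared of the linear main-effects model.
#' @export
estimate_rl2 <- function(condition, coefs, n = 100000, seed,
                         likert_method = c("round", "ceiling")) {
  stopifnot(n >= 1000)
  ds <- generate_dataset(condition, n, coefs, seed, likert_method)
  ols_r2(ds$X, ds$Y)
}

#' Reference performance for a condition
#'
#' Computes Rt2 and Rl2 on a shared estimation sample size with
#' seed-isolated draws, for use as the fixed reference in the replication
#' loop.
#'
#' @inheritParams estimate_rt2
#' @return list of class `reference_performance`: `rt2`, `rl2`,
#'   `estimation_n`, `seed`.
#' @export
reference_performance <- function(condition, coefs, n = 100000, seed,
                                  likert_method = c("round", "ceiling")) {
  likert_method <- match.arg(likert_method)
  structure(
    list(rt2 = estimate_rt2(condition, coefs, n, derive_seed(seed, "rt2"),
                            likert_method),
         rl2 = estimate_rl2(condition, coefs, n, derive_seed(seed, "rl2"),
                            likert_method),
         estimation_n = as.integer(n), seed = as.integer(seed),
         likert_method = likert_method),
    class = "reference_performance")
}

# ---- semi-analytic population oracle ---------------------------------------

# Every univariate factor appearing in a term is x^p * exp(t*x); products
# and cross-moments therefore stay in the same family, and all required
# expectations under x ~ N(3, 1) have closed forms via the exponentially
# tilted measure: E[x^p e^{tx}] = e^{3t + t^2/2} E[(z + 3 + t)^p], z ~ N(0,1).

.z_central <- c(0, 1, 0, 3, 0, 15, 0, 105) # E[z^k], k = 1..8

# E[(mu + z)^p], z ~ N(0,1), integer p >= 0
.poly_moment <- function(mu, p) {
  if (p == 0) return(1)
  ks <- 0:p
  sum(choose(p, ks) * mu^(p - ks) *
        c(1, .z_central)[ks + 1])
}

# E[x^p e^{tx}] for x ~ N(3,1)
.norm_pt_moment <- function(p, t) {
  exp(3 * t + t^2 / 2) * .poly_moment(3 + t, p)
}

# E[(mu + z)^p 1{a < mu + z <= b}], z ~ N(0,1), p in 0..2
.trunc_raw <- function(mu, a, b, p) {
  al <- a - mu; be <- b - mu
  P <- stats::pnorm(be) - stats::pnorm(al)
  da <- ifelse(is.finite(al), stats::dnorm(al), 0)
  db <- ifelse(is.finite(be), stats::dnorm(be), 0)
  Ez1 <- da - db
  if (p == 0) return(P)
  if (p == 1) return(mu * P + Ez1)
  ada <- ifelse(is.finite(al), al * da, 0)
  bdb <- ifelse(is.finite(be), be * db, 0)
  Ez2 <- P + ada - bdb
  mu^2 * P + 2 * mu * Ez1 + Ez2
}

# E[x^p e^{tx} 1{X = v}] for x ~ N(3,1) and X the clipped Likert cell of x;
# cell boundaries depend on the rounding convention
.cell_pt_moment <- function(v, p, t, method = "round") {
  if (method == "round") {
    lo <- c(-Inf, 1.5, 2.5, 3.5, 4.5)[v]
    hi <- c(1.5, 2.5, 3.5, 4.5, Inf)[v]
  } else {
    lo <- c(-Inf, 1, 2, 3, 4)[v]
    hi <- c(1, 2, 3, 4, Inf)[v]
  }
  exp(3 * t + t^2 / 2) * .trunc_raw(3 + t, lo, hi, p)
}

#' Exact population R-squared of the Likert-term regression
#'
#' Semi-analytic oracle for the population analogue of [estimate_rt2()]:
#' the R-squared of the best linear predictor of Y from the generating
#' terms evaluated on the Likertized predictors, computed without Monte
#' Carlo. Because the predictors are independent and every term is a
#' product of univariate factors of the form `x^p exp(tx)`, all entries of
#' Var(Z), Cov(Z, Y) and Var(Y) factorize into univariate expectations:
#' closed-form N(3,1) polynomial/exponential moments for the latent side,
#' and per-Likert-cell truncated-normal moments (first, second and
#' exponential) for the observed side.
#'
#' @param condition a [condition_spec()].
#' @param coefs a [coefficient_set()].
#' @param likert_method rounding convention (see [likertize()]).
#' @return population R-squared in \[0, 1\].
#' @export
#' @examples
#' cond <- condition_from_id(5)
#' population_r2_quadrature(cond, example_coefficients(1)) # 0.90067
population_r2_quadrature <- function(condition, coefs,
                                     likert_method = c("round", "ceiling")) {
  likert_method <- match.arg(likert_method)
  d <- generating_terms(condition)
  yterms <- d$terms
  cvals <- vapply(yterms, function(tm)
    if (tm$role == "cof") coefs$cof[tm$idx] else coefs$conf[tm$idx], 0)
  zterms <- regression_terms(condition)
  vs <- 1:5
  pcell <- vapply(vs, .cell_pt_moment, 0, p = 0, t = 0,
                  method = likert_method)

  # per-variable (p, t) lookup for a term; vars absent from a term act as
  # the constant function (p = 0, t = 0)
  fun_of <- function(tm, j) {
    k <- match(j, tm$vars)
    if (is.na(k)) c(0, 0) else c(tm$p[k], tm$t[k])
  }
  vars_used <- sort(unique(unlist(c(
    lapply(yterms, `[[`, "vars"), lapply(zterms, `[[`, "vars")))))

  # E[prod_j f1_j(x_j) f2_j(x_j)] with both factors latent
  e_latent2 <- function(t1, t2) {
    out <- 1
    for (j in vars_used) {
      f1 <- fun_of(t1, j); f2 <- fun_of(t2, j)
      out <- out * .norm_pt_moment(f1[1] + f2[1], f1[2] + f2[2])
    }
    out
  }
  # E[prod_j g_j(X_j) f_j(x_j)]: g on the Likert cell, f latent within cell
  e_mixed <- function(ztm, ytm) {
    out <- 1
    for (j in vars_used) {
      g <- fun_of(ztm, j); f <- fun_of(ytm, j)
      gv <- vs^g[1] * exp(g[2] * vs)
      if (g[1] == 0 && g[2] == 0) gv <- rep(1, 5)
      cm <- vapply(vs, .cell_pt_moment, 0, p = f[1], t = f[2],
                   method = likert_method)
      out <- out * sum(gv * cm)
    }
    out
  }
  # E[prod_j g1_j(X_j) g2_j(X_j)]: both factors discrete
  e_likert2 <- function(z1, z2) {
    out <- 1
    for (j in vars_used) {
      g1 <- fun_of(z1, j); g2 <- fun_of(z2, j)
      gv <- vs^(g1[1] + g2[1]) * exp((g1[2] + g2[2]) * vs)
      out <- out * sum(gv * pcell)
    }
    out
  }

  const_term <- .term("cof", 1L, integer(0), numeric(0))
  ey <- sum(cvals * vapply(yterms, e_latent2, 0, t2 = const_term))
  ez <- vapply(zterms, e_likert2, 0, z2 = const_term)

  m <- length(zterms)
  Szz <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    v <- e_likert2(zterms[[i]], zterms[[j]]) - ez[i] * ez[j]
    Szz[i, j] <- v; Szz[j, i] <- v
  }
  czy <- vapply(seq_len(m), function(i) {
    sum(cvals * vapply(yterms, function(yt)
      e_mixed(zterms[[i]], yt), 0)) -
      ez[i] * ey
  }, 0)
  ey2 <- 0
  for (k in seq_along(yterms)) for (l in seq_along(yterms)) {
    ey2 <- ey2 + cvals[k] * cvals[l] * e_latent2(yterms[[k]], yterms[[l]])
  }
  vary <- ey2 - ey^2 + coefs$coferr^2

  beta <- solve(Szz, czy)
  as.numeric(crossprod(czy, beta) / vary)
}
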