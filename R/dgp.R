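#' Construct a coefficient set
#'
#' Bundles the drawn linear coefficients (`cof`), nonlinear coefficients
#' (`conf`) and the error multiplier (`coferr`) for one condition.
#' Lengths are validated against the formula selected by the condition.
#'
#' @param cof numeric vector of linear coefficients.
#' @param conf numeric vector of nonlinear coefficients.
#' @param coferr error multiplier (non-negative).
#' @param condition optional [condition_spec()]; when given, the vector
#'   lengths are checked against the formula's term counts.
#' @return object of class `coefficient_set`.
#' @export
coefficient_set <- function(cof, conf, coferr, condition = NULL) {
  stopifnot(is.numeric(cof), is.numeric(conf),
            is.numeric(coferr), length(coferr) == 1, coferr >= 0)
  if (!is.null(condition)) {
    d <- generating_terms(condition)
    if (length(cof) != d$n_cof || length(conf) != d$n_conf)
      stop(sprintf(
        "coefficient lengths (%d linear, %d nonlinear) do not match the %s/%d-IV formula (%d, %d)",
        length(cof), length(conf), condition$complexity, condition$n_iv,
        d$n_cof, d$n_conf), call. = FALSE)
  }
  structure(list(cof = as.numeric(cof), conf = as.numeric(conf),
                 coferr = as.numeric(coferr)),
            class = "coefficient_set")
}

#' Draw condition coefficients
#'
#' Draws each coefficient independently from the uniform range implied by
#' the condition's coefficient levels: small coefficients from U\[0.1, 0.3\],
#' large coefficients from U\[0.5, 1\]. The error multiplier is the
#' condition's `error_coef`. Deterministic given `seed`.
#'
#' @param condition a [condition_spec()].
#' @param seed integer seed.
#' @return a `coefficient_set`.
#' @export
#' @examples
#' cs <- draw_coefficients(condition_from_id(1), seed = 42)
#' all(cs$cof >= 0.1 & cs$cof <= 0.3)
draw_coefficients <- function(condition, seed) {
  stopifnot(inherits(condition, "condition_spec"))
  d <- generating_terms(condition)
  rng <- function(level) if (level == "small") c(0.1, 0.3) else c(0.5, 1)
  lin <- rng(condition$linear_level)
  non <- rng(condition$nonlinear_level)
  with_seed(derive_seed(seed, "coefficients"), {
    cof <- stats::runif(d$n_cof, lin[1], lin[2])
    conf <- stats::runif(d$n_conf, non[1], non[2])
    coefficient_set(cof, conf, condition$error_coef, condition)
  })
}

#' The published example coefficient set
#'
#' The saved coefficient draw printed for the medium-complexity, 3-IV cell
#' with small linear and large nonlinear coefficients:
#' Y = 0.29 x1 + 0.28 x2 + 0.13 x3 + 0.61 x1 x2 + 0.7 x2 x3
#'     + 0.81 x1^2 + 0.752 x2^2 + coferr N(0,1).
#'
#' @param coferr error multiplier (default 1, the condition-5 error level).
#' @return a `coefficient_set`.
#' @export
example_coefficients <- function(coferr = 1) {
  coefficient_set(c(0.29, 0.28, 0.13), c(0.61, 0.7, 0.81, 0.752), coferr,
                  condition_spec("medium", 3, "small", "large", 1))
}

#' Simulate latent continuous predictors
#'
#' Independent draws from N(3, 1) for each of `n_iv` columns: the "true"
#' continuous scores underlying the observed Likert items.
#'
#' @param n number of rows (respondents), `n >= 1`.
#' @param n_iv number of predictors: 3, 5 or 10.
#' @param seed integer seed.
#' @return an `n x n_iv` numeric matrix.
#' @export
simulate_latent <- function(n, n_iv, seed) {
  stopifnot(n >= 1)
  if (!n_iv %in% .n_iv_levels)
    stop("n_iv must be one of 3, 5, 10", call. = FALSE)
  with_seed(seed, matrix(stats::rnorm(n * n_iv, mean = 3, sd = 1),
                         nrow = n, ncol = n_iv))
}

#' Likertize latent scores
#'
#' Discretizes continuous scores to the observed 5-point scale: round to
#' an integer, then clip to the scale ends, so every value lands in
#' \{1, 2, 3, 4, 5\}. This rounding is the only measurement error carried
#' by the predictors.
#'
#' Two rounding conventions are supported. `"round"` (the default) maps to
#' the *nearest* integer; it is the convention that reproduces the
#' published reference results — the semi-analytic oracle shows the
#' published theoretical maximum for the example coefficient set (0.9009)
#' arises from nearest-integer cells (exact value 0.90067), not from
#' ceiling cells (exact value 0.8759). `"ceiling"` rounds up, the literal
#' reading of "rounding up"; it attenuates slightly more because the cell
#' boundaries are off-centre. Both are monotone and idempotent on 1..5.
#'
#' @param latent numeric vector or matrix.
#' @param method `"round"` (nearest integer, default) or `"ceiling"`.
#' @return integer vector/matrix of the same shape with values in 1..5.
#' @export
#' @examples
#' likertize(c(3.2, -0.7, 6.3, 3.0)) # 3 1 5 3
#' likertize(c(3.2, -0.7, 6.3, 3.0), method = "ceiling") # 4 1 5 3
likertize <- function(latent, method = c("round", "ceiling")) {
  method <- match.arg(method)
  out <- switch(method,
                round = round(latent),
                ceiling = ceiling(latent))
  out <- pmin(pmax(out, 1), 5)
  storage.mode(out) <- "integer"
  out
}

#' Evaluate the generating formula
#'
#' Computes the outcome Y on the *latent* (continuous) predictors — the
#' Likertized values are never used to generate Y — and adds
#' coferr-scaled standard-normal noise.
#'
#' @param latent latent matrix from [simulate_latent()].
#' @param condition a [condition_spec()] selecting the formula.
#' @param coefs a [coefficient_set()] (lengths must match the formula).
#' @param noise_seed integer seed for the noise draws, or `NULL` to omit
#'   noise (useful for oracle checks).
#' @return numeric outcome vector of length `nrow(latent)`.
#' @export
#' @examples
#' lat <- matrix(1, 1, 3)
#' evaluate_outcome(lat, condition_spec("medium", 3, "small", "large", 1),
#'                  example_coefficients(), noise_seed = NULL) # 3.572
evaluate_outcome <- function(latent, condition, coefs, noise_seed) {
  stopifnot(inherits(coefs, "coefficient_set"))
  d <- generating_terms(condition)
  if (length(coefs$cof) != d$n_cof || length(coefs$conf) != d$n_conf)
    stop("coefficient lengths do not match the formula term counts",
         call. = FALSE)
  if (ncol(latent) != condition$n_iv)
    stop("latent column count does not match condition n_iv", call. = FALSE)
  y <- numeric(nrow(latent))
  for (tm in d$terms) {
    cf <- if (tm$role == "cof") coefs$cof[tm$idx] else coefs$conf[tm$idx]
    y <- y + cf * term_column(tm, latent)
  }
  if (!is.null(noise_seed)) {
    y <- y + coefs$coferr *
      with_seed(noise_seed, stats::rnorm(nrow(latent)))
  }
  y
}

#' Generate one simulated dataset
#'
#' Full data-generating pipeline for one condition: latent predictors,
#' Likertization, outcome from the latent values plus noise. Sub-seeds for
#' the latent draws and the noise are derived deterministically from
#' `seed`, so the whole dataset is reproducible from
#' `(condition, n, coefs, seed)`.
#'
#' @param condition a [condition_spec()].
#' @param n sample size.
#' @param coefs a [coefficient_set()].
#' @param seed integer seed.
#' @param likert_method rounding convention passed to [likertize()].
#' @return object of class `simulated_dataset`: `X` (integer Likert matrix,
#'   columns `X1..Xk`), `Y` (numeric outcome), `latent` (continuous
#'   predictors, retained for oracle use), `condition`, `coefficients`,
#'   `seed`.
#' @export
generate_dataset <- function(condition, n, coefs, seed,
                             likert_method = c("round", "ceiling")) {
  likert_method <- match.arg(likert_method)
  latent <- simulate_latent(n, condition$n_iv, derive_seed(seed, "latent"))
  X <- likertize(latent, likert_method)
  colnames(X) <- paste0("X", seq_len(ncol(X)))
  Y <- evaluate_outcome(latent, condition, coefs, derive_seed(seed, "noise"))
  structure(list(X = X, Y = Y, latent = latent, condition = condition,
                 coefficients = coefs, seed = as.integer(seed),
                 likert_method = likert_method),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> n=%d, n_iv=%d, condition %d, seed %d\n",
              nrow(x$X), ncol(x$X), condition_id(x$condition), x$seed))
  invisible(x)
}

#' Export / import a simulated dataset as CSV
#'
#' Writes the observed data only (Likert columns `X1..Xk` and `Y`); the
#' latent scores are simulation-internal and are not exported.
#'
#' @param dataset a `simulated_dataset`.
#' @param path file path.
#' @return `write_dataset_csv` returns `path` invisibly;
#'   `read_dataset_csv` returns a data.frame.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(dataset$X, Y = dataset$Y)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  utils::read.csv(path)
}

#' Read a coefficient fixture file
#'
#' Ingests saved coefficient draws in long CSV form with columns
#' `condition_id`, `role` (`cof`, `conf` or `coferr`), `index`, `value`,
#' e.g. a deposited coefficient file accompanying the full-scale study.
#'
#' @param path CSV file path.
#' @param condition_id which condition's rows to extract.
#' @param condition optional [condition_spec()] for length validation.
#' @return a `coefficient_set`.
#' @export
read_coefficient_fixture <- function(path, condition_id, condition = NULL) {
  df <- utils::read.csv(path)
  need <- c("condition_id", "role", "index", "value")
  if (!all(need %in% names(df)))
    stop("fixture must have columns condition_id, role, index, value",
         call. = FALSE)
  df <- df[df$condition_id == condition_id, ]
  if (nrow(df) == 0)
    stop(sprintf("no rows for condition %s in %s", condition_id, path),
         call. = FALSE)
  pick <- function(role) {
    rows <- df[df$role == role, ]
    rows$value[order(rows$index)]
  }
  coferr <- pick("coferr")
  coefficient_set(pick("cof"), pick("conf"),
                  if (length(coferr)) coferr[1] else 1, condition)
}
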