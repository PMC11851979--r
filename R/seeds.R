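#' Derive a reproducible child seed
#'
#' Deterministically derives a child seed from a master seed and an arbitrary
#' set of keys (strings or integers). Every stochastic routine in the package
#' draws its randomness from a seed produced this way, so a whole simulation
#' — coefficients, latent draws, noise, splits, network initialisation — is
#' reproducible from one master seed, and conditions/replications are
#' seed-isolated: re-ordering their execution cannot change results.
#'
#' The scheme is a polynomial hash over the key components, folded into the
#' master seed modulo the Mersenne prime 2^31 - 1, so child seeds always fit
#' in a 32-bit signed integer.
#'
#' @param seed master seed, a non-negative integer.
#' @param ... keys identifying the consumer (character or numeric scalars),
#'   e.g. `derive_seed(1, "rep", 17)`.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "latent")
#' derive_seed(1, "rep", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  p <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% p
  for (key in list(...)) {
    codes <- if (is.character(key)) {
      utf8ToInt(paste(key, collapse = "\r"))
    } else {
      # integers are hashed through their decimal digits for portability
      utf8ToInt(paste(format(key, scientific = FALSE, trim = TRUE),
                      collapse = "\r"))
    }
    for (cc in codes) {
      h <- (h * 131 + cc + 7919) %% p
    }
    h <- (h * 31 + 17) %% p
  }
  as.integer(h %% (p - 2) + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}
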