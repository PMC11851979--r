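#' Construct a hyperparameter combination
#'
#' @param shape integer vector of hidden-layer widths, e.g. `c(10, 10)`.
#' @param learning_rate Adam step size.
#' @param patience epochs without validation improvement tolerated before
#'   training halts.
#' @param batch_size mini-batch size.
#' @return object of class `hyperparameters`.
#' @export
hyperparameters <- function(shape, learning_rate, patience, batch_size) {
  stopifnot(all(shape >= 1), learning_rate > 0, patience >= 1,
            batch_size >= 1)
  structure(list(shape = as.integer(shape),
                 learning_rate = as.numeric(learning_rate),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size)),
            class = "hyperparameters")
}

#' @export
print.hyperparameters <- function(x, ...) {
  cat(sprintf("<hp> shape=(%s), lr=%g, patience=%d, batch=%d\n",
              paste(x$shape, collapse = ","), x$learning_rate,
              x$patience, x$batch_size))
  invisible(x)
}

#' Hyperparameter search grids
#'
#' `hp_grid()` builds the full cartesian grid in canonical order (shape
#' slowest, then learning rate, then patience, then batch size fastest);
#' the default levels give the canonical 3 x 3 x 3 x 3 = 81 combinations:
#' shapes (10), (10, 10), (10, 10, 10); learning rates 1e-4, 1e-3, 1e-2;
#' patience 5, 10, 15; batch sizes 32, 64, 128. `hp_grid_fast()` is the
#' reduced 8-combination grid used for scaled-down runs: shapes (10) and
#' (10, 10), learning rates 1e-3 and 1e-2, patience 5, batch sizes 32
#' and 64.
#'
#' @param shapes list of hidden-layer width vectors.
#' @param learning_rates numeric vector.
#' @param patience integer vector.
#' @param batch_sizes integer vector.
#' @return list of [hyperparameters()] objects in canonical order.
#' @export
#' @examples
#' length(hp_grid()) # 81
#' length(hp_grid_fast()) # 8
hp_grid <- function(shapes = list(10L, c(10L, 10L), c(10L, 10L, 10L)),
                    learning_rates = c(0.0001, 0.001, 0.01),
                    patience = c(5L, 10L, 15L),
                    batch_sizes = c(32L, 64L, 128L)) {
  grid <- list()
  for (sh in shapes)
    for (lr in learning_rates)
      for (pa in patience)
        for (bs in batch_sizes)
          grid[[length(grid) + 1L]] <- hyperparameters(sh, lr, pa, bs)
  grid
}

#' @rdname hp_grid
#' @export
hp_grid_fast <- function() {
  hp_grid(shapes = list(10L, c(10L, 10L)),
          learning_rates = c(0.001, 0.01),
          patience = 5L,
          batch_sizes = c(32L, 64L))
}

#' Split a dataset into train / validation / test partitions
#'
#' Random, seed-deterministic split: 20% of all rows to the test set, then
#' 20% of the remaining training rows to the validation set (i.e. 64% /
#' 16% / 20% of the total).
#'
#' @param dataset a [generate_dataset()] result, or any list with matrix
#'   `X` and vector `Y`.
#' @param seed integer seed.
#' @return list with elements `train`, `validation`, `test`, each a list
#'   `X` (numeric matrix) / `y` (numeric vector), plus the row `indices`.
#' @export
#' @examples
#' ds <- generate_dataset(condition_from_id(1),
#'                        n = 1000, draw_coefficients(condition_from_id(1), 1),
#'                        seed = 1)
#' sp <- split_dataset(ds, seed = 2)
#' vapply(sp[c("train", "validation", "test")],
#'        function(p) nrow(p$X), 0L) # 640 160 200
split_dataset <- function(dataset, seed) {
  n <- nrow(dataset$X)
  if (n < 10) stop("dataset too small to split (need >= 10 rows)",
                   call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(n)
    n_test <- floor(0.2 * n)
    test_idx <- idx[seq_len(n_test)]
    rest <- idx[-seq_len(n_test)]
    n_val <- floor(0.2 * length(rest))
    val_idx <- rest[seq_len(n_val)]
    train_idx <- rest[-seq_len(n_val)]
    part <- function(ix) list(
      X = matrix(as.numeric(dataset$X[ix, , drop = FALSE]),
                 nrow = length(ix), dimnames = dimnames(dataset$X[ix, , drop = FALSE])),
      y = as.numeric(dataset$Y[ix]), indices = ix)
    list(train = part(train_idx), validation = part(val_idx),
         test = part(test_idx))
  })
}

#' Fit a feed-forward regression network
#'
#' Fully connected network with ReLU hidden layers and a single linear
#' output, trained by mini-batch Adam on mean-squared error. Training
#' stops early when the validation MSE has not improved for
#' `hp$patience` consecutive epochs, and the weights from the best
#' validation epoch are restored. Likert inputs are fed as their raw 1-5
#' codes by default.
#'
#' @param train,validation partitions from [split_dataset()] (lists with
#'   `X` and `y`).
#' @param hp a [hyperparameters()] object.
#' @param seed integer seed for weight initialisation and batch shuffling.
#' @param max_epochs epoch cap (default 200; early stopping governs in
#'   practice).
#' @param standardize if `TRUE`, centre/scale inputs by training-set mean
#'   and standard deviation before fitting (default `FALSE`).
#' @return object of class `nn_fit`: the fitted weights, `val_loss`
#'   (restored-best validation MSE), `epochs_run`, `best_epoch`, `hp`,
#'   `failed` flag, and `seed`.
#' @export
fit_nn <- function(train, validation, hp, seed, max_epochs = 200,
                   standardize = FALSE) {
  stopifnot(inherits(hp, "hyperparameters"))
  ctr <- NULL
  Xtr <- train$X
  Xval <- validation$X
  if (standardize) {
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    ctr <- list(mean = mu, sd = sdv)
    Xtr <- scale(Xtr, mu, sdv)
    Xval <- scale(Xval, mu, sdv)
  }
  res <- mlp_train_cpp(Xtr, train$y, Xval, validation$y,
                       hidden = hp$shape, lr = hp$learning_rate,
                       patience = hp$patience, batch_size = hp$batch_size,
                       max_epochs = as.integer(max_epochs),
                       seed = as.integer(seed))
  structure(list(weights = res$weights, biases = res$biases,
                 val_loss = res$val_loss, epochs_run = res$epochs_run,
                 best_epoch = res$best_epoch, failed = res$failed,
                 hp = hp, scaling = ctr, seed = as.integer(seed)),
            class = "nn_fit")
}

#' @export
print.nn_fit <- function(x, ...) {
  cat(sprintf("<nn_fit> shape=(%s), val MSE=%.5g, epochs=%d (best %d)%s\n",
              paste(x$hp$shape, collapse = ","), x$val_loss, x$epochs_run,
              x$best_epoch, if (isTRUE(x$failed)) " [FAILED]" else ""))
  invisible(x)
}

#' @param object an `nn_fit`.
#' @param newdata numeric matrix (or partition list with `X`).
#' @param ... unused.
#' @rdname fit_nn
#' @export
predict.nn_fit <- function(object, newdata, ...) {
  X <- if (is.list(newdata) && !is.null(newdata$X)) newdata$X else newdata
  X <- matrix(as.numeric(X), nrow = nrow(X))
  if (!is.null(object$scaling))
    X <- scale(X, object$scaling$mean, object$scaling$sd)
  as.numeric(mlp_predict_cpp(object$weights, object$biases, X))
}

#' Grid search over hyperparameter combinations
#'
#' Fits `repeats` networks per combination (each with a seed derived from
#' `seed`, the grid position and the repeat index), scores each
#' combination by its best restored validation MSE, and selects the
#' combination with the lowest score. Ties keep the earlier combination
#' in canonical grid order. Fitting several networks per combination and
#' keeping the best is the full-scale study protocol (`repeats = 10`);
#' the default is a single fit per combination. Combinations whose fits
#' all diverge are skipped; if every fit fails the search errors.
#'
#' @param train,validation partitions from [split_dataset()].
#' @param grid list of [hyperparameters()] (default [hp_grid()]).
#' @param seed integer seed.
#' @param max_epochs,standardize passed to [fit_nn()].
#' @param repeats networks fitted per combination (default 1).
#' @return object of class `grid_search_result`: `best_hp`, `best_fit`,
#'   and a `results` data.frame (one row per combination with its
#'   validation loss and epochs run).
#' @export
grid_search <- function(train, validation, grid = hp_grid(), seed,
                        max_epochs = 200, standardize = FALSE,
                        repeats = 1) {
  stopifnot(length(grid) >= 1, repeats >= 1)
  best <- NULL
  best_i <- NA_integer_
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    fit <- NULL
    for (k in seq_len(repeats)) {
      f <- fit_nn(train, validation, grid[[i]],
                  seed = derive_seed(seed, "hp", i, k),
                  max_epochs = max_epochs, standardize = standardize)
      if (isTRUE(f$failed)) next
      if (is.null(fit) || f$val_loss < fit$val_loss) fit <- f
    }
    rows[[i]] <- data.frame(
      combo = i,
      shape = paste(grid[[i]]$shape, collapse = "x"),
      learning_rate = grid[[i]]$learning_rate,
      patience = grid[[i]]$patience,
      batch_size = grid[[i]]$batch_size,
      val_loss = if (is.null(fit)) NA_real_ else fit$val_loss,
      epochs_run = if (is.null(fit)) NA_integer_ else fit$epochs_run,
      failed = is.null(fit))
    if (is.null(fit)) next
    if (is.null(best) || fit$val_loss < best$val_loss) {
      best <- fit
      best_i <- i
    }
  }
  if (is.null(best))
    stop("all grid-search fits failed (non-finite loss)", call. = FALSE)
  structure(list(best_hp = grid[[best_i]], best_fit = best,
                 best_index = best_i, results = do.call(rbind, rows)),
            class = "grid_search_result")
}

#' Test-set R-squared of a fitted model
#'
#' `R^2 = 1 - SSE / SST` on the held-out test partition, with SST taken
#' about the test-set mean. Can be negative when the model predicts worse
#' than the test mean. A zero-variance test outcome makes the quantity
#' undefined and returns `NA` with a warning.
#'
#' @param model an `nn_fit` (or anything with a `predict` method returning
#'   numeric predictions for `test$X`).
#' @param test test partition (list with `X` and `y`).
#' @return numeric scalar (possibly negative), or `NA` on failure.
#' @export
evaluate_r2 <- function(model, test) {
  stopifnot(length(test$y) >= 1)
  sst <- sum((test$y - mean(test$y))^2)
  if (sst <= 0) {
    warning("zero test-set variance; R-squared undefined")
    return(NA_real_)
  }
  pred <- stats::predict(model, test)
  sse <- sum((test$y - pred)^2)
  1 - sse / sst
}
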