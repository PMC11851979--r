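test_that("the canonical grid enumerates 81 combinations in order", {
  grid <- hp_grid()
  expect_length(grid, 81)
  # batch size varies fastest, shape slowest
  expect_equal(grid[[1]]$shape, 10L)
  expect_equal(grid[[1]]$learning_rate, 1e-4)
  expect_equal(grid[[1]]$patience, 5L)
  expect_equal(grid[[1]]$batch_size, 32L)
  expect_equal(grid[[2]]$batch_size, 64L)
  expect_equal(grid[[4]]$patience, 10L)
  expect_equal(grid[[10]]$learning_rate, 1e-3)
  expect_equal(grid[[28]]$shape, c(10L, 10L))
  expect_equal(grid[[81]]$shape, c(10L, 10L, 10L))
  expect_equal(grid[[81]]$batch_size, 128L)
  expect_length(hp_grid_fast(), 8)
})

test_that("splits have the 64/16/20 sizes and partition the rows", {
  ds <- generate_dataset(condition_from_id(1), 1000, cond1_midpoint(),
                         seed = 1)
  sp <- split_dataset(ds, seed = 2)
  expect_equal(nrow(sp$train$X), 640)
  expect_equal(nrow(sp$validation$X), 160)
  expect_equal(nrow(sp$test$X), 200)
  idx <- c(sp$train$indices, sp$validation$indices, sp$test$indices)
  expect_setequal(idx, 1:1000)
  expect_equal(length(idx), 1000)
  expect_identical(split_dataset(ds, 2)$train$indices, sp$train$indices)
  expect_false(identical(split_dataset(ds, 3)$train$indices,
                         sp$train$indices))

  # ragged n: sizes still within one row of the stated fractions
  ds2 <- generate_dataset(condition_from_id(1), 1037, cond1_midpoint(),
                          seed = 1)
  sp2 <- split_dataset(ds2, seed = 2)
  ns <- vapply(sp2, function(p) nrow(p$X), 0L)
  expect_equal(sum(ns), 1037)
  expect_lte(abs(ns[["test"]] - 0.2 * 1037), 1)
  expect_lte(abs(ns[["validation"]] - 0.16 * 1037), 1)

  tiny <- list(X = matrix(1:9, 9, 1), Y = 1:9)
  expect_error(split_dataset(tiny, 1), "small")
})

test_that("the network reaches the attenuation ceiling on linear data", {
  cond <- condition_spec("simple", 3, "large", "small", 1)
  cs <- coefficient_set(c(0.8, 0.7, 0.9), c(0, 0), 0, cond)
  ds <- generate_dataset(cond, 2000, cs, seed = 11)
  sp <- split_dataset(ds, seed = 12)
  fit <- fit_nn(sp$train, sp$validation, hyperparameters(10, 0.01, 10, 32),
                seed = 13)
  ceiling_exact <- population_r2_quadrature(cond, cs)
  expect_gt(evaluate_r2(fit, sp$test), 0.95 * ceiling_exact)
})

test_that("fits are deterministic in the seed and single-output", {
  ds <- generate_dataset(condition_from_id(1), 600, cond1_midpoint(),
                         seed = 21)
  sp <- split_dataset(ds, seed = 22)
  hp <- hyperparameters(c(10, 10), 0.01, 5, 32)
  f1 <- fit_nn(sp$train, sp$validation, hp, seed = 23)
  f2 <- fit_nn(sp$train, sp$validation, hp, seed = 23)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$val_loss, f2$val_loss)
  f3 <- fit_nn(sp$train, sp$validation, hp, seed = 24)
  expect_false(identical(f1$val_loss, f3$val_loss))
  pred <- predict(f1, sp$test)
  expect_length(pred, 120)
  expect_true(all(is.finite(pred)))
})

test_that("early stopping halts patience epochs after the best epoch", {
  ds <- generate_dataset(condition_from_id(1), 600, cond1_midpoint(),
                         seed = 31)
  sp <- split_dataset(ds, seed = 32)
  for (pat in c(5L, 10L)) {
    fit <- fit_nn(sp$train, sp$validation,
                  hyperparameters(10, 0.01, pat, 32), seed = 33)
    if (fit$epochs_run < 200) {
      expect_equal(fit$epochs_run - fit$best_epoch, pat)
    }
  }
})

test_that("raising the epoch cap never worsens the restored-best score", {
  ds <- generate_dataset(condition_from_id(1), 600, cond1_midpoint(),
                         seed = 41)
  sp <- split_dataset(ds, seed = 42)
  hp <- hyperparameters(10, 0.001, 200, 32) # patience > cap: no early stop
  short <- fit_nn(sp$train, sp$validation, hp, seed = 43, max_epochs = 30)
  long <- fit_nn(sp$train, sp$validation, hp, seed = 43, max_epochs = 100)
  expect_lte(long$val_loss, short$val_loss)
})

test_that("grid search picks the lowest validation loss in canonical order", {
  ds <- generate_dataset(condition_from_id(1), 600, cond1_midpoint(),
                         seed = 51)
  sp <- split_dataset(ds, seed = 52)
  grid <- hp_grid_fast()
  gs <- grid_search(sp$train, sp$validation, grid, seed = 53)
  expect_s3_class(gs, "grid_search_result")
  expect_equal(nrow(gs$results), 8)
  # chosen member is in the searched grid and is the first minimum
  expect_identical(gs$best_hp, grid[[gs$best_index]])
  expect_equal(gs$best_index, which(
    gs$results$val_loss == min(gs$results$val_loss))[1])
  expect_equal(gs$best_fit$val_loss, min(gs$results$val_loss))

  single <- grid_search(sp$train, sp$validation, list(grid[[3]]), seed = 53)
  expect_identical(single$best_hp, grid[[3]])
  expect_identical(grid_search(sp$train, sp$validation, grid, seed = 53)$
                     results$val_loss, gs$results$val_loss)
})

test_that("test-set R-squared follows its definition", {
  assign("predict.mssrnn_stub",
         function(object, newdata, ...) object$pred, envir = globalenv())
  withr::defer(rm("predict.mssrnn_stub", envir = globalenv()))
  stub <- function(pred) structure(list(pred = pred),
                                   class = "mssrnn_stub")
  test <- list(X = matrix(0, 5, 1), y = c(1, 2, 3, 4, 5))
  expect_equal(evaluate_r2(stub(c(1, 2, 3, 4, 5)), test), 1)
  expect_equal(evaluate_r2(stub(rep(3, 5)), test), 0)
  expect_lt(evaluate_r2(stub(c(5, 4, 3, 2, 1)), test), 0)
  degenerate <- list(X = matrix(0, 3, 1), y = rep(2, 3))
  expect_warning(out <- evaluate_r2(stub(rep(2, 3)), degenerate),
                 "variance")
  expect_true(is.na(out))
})
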