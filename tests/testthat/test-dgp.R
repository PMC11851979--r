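test_that("coefficient draws respect their level ranges and the gap", {
  for (id in c(1, 5, 8, 62, 108)) {
    cond <- condition_from_id(id)
    cs <- draw_coefficients(cond, seed = 7)
    lin <- if (cond$linear_level == "small") c(0.1, 0.3) else c(0.5, 1)
    non <- if (cond$nonlinear_level == "small") c(0.1, 0.3) else c(0.5, 1)
    expect_true(all(cs$cof >= lin[1] & cs$cof <= lin[2]))
    expect_true(all(cs$conf >= non[1] & cs$conf <= non[2]))
    # no draw falls in the designed gap between the two levels
    expect_false(any(cs$cof > 0.3 & cs$cof < 0.5))
    expect_false(any(cs$conf > 0.3 & cs$conf < 0.5))
    expect_true(cs$coferr %in% c(1, 4, 10))
    d <- generating_terms(cond)
    expect_length(cs$cof, d$n_cof)
    expect_length(cs$conf, d$n_conf)
  }
})

test_that("coefficient draws are deterministic in the seed", {
  cond <- condition_from_id(19)
  expect_identical(draw_coefficients(cond, 42), draw_coefficients(cond, 42))
  expect_false(identical(draw_coefficients(cond, 42),
                         draw_coefficients(cond, 43)))
})

test_that("latent predictors are N(3,1) draws of the requested shape", {
  lat <- simulate_latent(5, 3, seed = 1)
  expect_equal(dim(lat), c(5, 3))
  expect_false(identical(simulate_latent(5, 3, 1), simulate_latent(5, 3, 2)))
  expect_identical(simulate_latent(5, 3, 1), simulate_latent(5, 3, 1))
  expect_error(simulate_latent(10, 4, 1), "n_iv")

  big <- simulate_latent(100000, 3, seed = 99)
  expect_true(all(abs(colMeans(big) - 3) < 0.02))
  expect_true(all(abs(apply(big, 2, sd) - 1) < 0.02))
})

test_that("likertize maps all reals into 1..5 under both conventions", {
  x <- c(-10, -0.7, 0.2, 1, 1.2, 2.5, 3, 3.2, 4.9, 5, 6.3, 100)
  for (m in c("round", "ceiling")) {
    lx <- likertize(x, m)
    expect_true(all(lx %in% 1:5))
    expect_type(lx, "integer")
    # idempotent on the scale values
    expect_identical(likertize(1:5, m), 1:5)
    # monotone non-decreasing map
    expect_true(all(diff(likertize(sort(rnorm(500, 3, 2)), m)) >= 0))
  }
  expect_identical(likertize(c(3.2, -0.7, 6.3, 3.0)), c(3L, 1L, 5L, 3L))
  expect_identical(likertize(c(3.2, -0.7, 6.3, 3.0), "ceiling"),
                   c(4L, 1L, 5L, 3L))
})

test_that("empirical Likert cell frequencies match the normal-cell mass", {
  lat <- simulate_latent(100000, 3, seed = 5)
  for (m in c("round", "ceiling")) {
    lx <- likertize(lat, m)
    emp <- tabulate(lx, 5) / length(lx)
    expect_true(all(abs(emp - cell_probs(m)) < 0.01))
  }
})

test_that("the example coefficients evaluate the printed formula exactly", {
  cond5 <- condition_from_id(5)
  cs <- example_coefficients(1)
  y1 <- evaluate_outcome(matrix(1, 1, 3), cond5, cs, noise_seed = NULL)
  expect_equal(y1, 0.29 + 0.28 + 0.13 + 0.61 + 0.7 + 0.81 + 0.752)
  y3 <- evaluate_outcome(matrix(3, 1, 3), cond5, cs, noise_seed = NULL)
  expect_equal(y3, 27.948)
})

test_that("outcomes degenerate to scaled noise when all coefficients vanish", {
  cond <- condition_spec("simple", 3, 1, 1, 4)
  cs <- coefficient_set(rep(0, 3), rep(0, 2), 4, cond)
  lat <- simulate_latent(20000, 3, seed = 3)
  y <- evaluate_outcome(lat, cond, cs, noise_seed = 8)
  expect_lt(abs(var(y) - 16), 1)
  expect_lt(abs(mean(y)), 0.1)
})

test_that("the outcome is linear in each coefficient", {
  cond5 <- condition_from_id(5)
  lat <- simulate_latent(50, 3, seed = 10)
  base <- example_coefficients(1)
  y0 <- evaluate_outcome(lat, cond5, base, noise_seed = NULL)
  for (i in seq_along(base$conf)) {
    up <- base
    up$conf[i] <- up$conf[i] + 1
    y1 <- evaluate_outcome(lat, cond5, up, noise_seed = NULL)
    dn <- base
    dn$conf[i] <- dn$conf[i] - 1
    y2 <- evaluate_outcome(lat, cond5, dn, noise_seed = NULL)
    # finite difference is the term column itself, and symmetric
    expect_equal(y1 - y0, y0 - y2)
  }
})

test_that("coefficient length mismatches are rejected", {
  cond5 <- condition_from_id(5)
  bad <- coefficient_set(c(0.2, 0.2), c(0.2, 0.2), 1)
  expect_error(evaluate_outcome(matrix(1, 1, 3), cond5, bad, NULL),
               "lengths")
  expect_error(coefficient_set(c(0.2, 0.2), c(0.2, 0.2), 1, cond5),
               "match")
})

test_that("dataset generation composes the pieces reproducibly", {
  cond <- condition_from_id(1)
  cs <- cond1_midpoint()
  ds <- generate_dataset(cond, 1000, cs, seed = 77)
  expect_equal(dim(ds$X), c(1000, 3))
  expect_true(all(ds$X %in% 1:5))
  expect_length(ds$Y, 1000)
  expect_identical(ds, generate_dataset(cond, 1000, cs, seed = 77))
  # Y is computed from the latent values, not the Likert codes
  expect_equal(ds$Y,
               evaluate_outcome(ds$latent, cond, cs,
                                derive_seed(77, "noise")))
})

test_that("with no nonlinear signal and tiny noise Y is the linear score", {
  cond <- condition_spec("simple", 3, "small", "small", 1)
  cs <- coefficient_set(c(0.2, 0.25, 0.15), c(0, 0), 0.001, cond)
  ds <- generate_dataset(cond, 10000, cs, seed = 4)
  lin <- ds$latent %*% cs$cof
  expect_gt(cor(ds$Y, lin), 0.9999)
})

test_that("datasets and coefficient fixtures round-trip through CSV", {
  ds <- generate_dataset(condition_from_id(1), 50, cond1_midpoint(),
                         seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  expect_equal(as.matrix(back[, 1:3]), ds$X, ignore_attr = TRUE)
  expect_equal(back$Y, ds$Y)

  fixture <- system.file("extdata", "coefficients_reference.csv",
                         package = "mssrnn")
  cs <- read_coefficient_fixture(fixture, 5, condition_from_id(5))
  expect_equal(cs$cof, c(0.29, 0.28, 0.13))
  expect_equal(cs$conf, c(0.61, 0.7, 0.81, 0.752))
  expect_equal(cs$coferr, 1)
  expect_error(read_coefficient_fixture(fixture, 99), "no rows")
})
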