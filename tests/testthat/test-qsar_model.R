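# Network construction, metrics, splitting, training mechanics and
# model persistence.

small_config <- function(units = c(8L, 4L), epochs = 5L, seed = 1L,
                         lr = 0.01, dropout = 0) {
  qsar_config(layers = lapply(units, function(u)
    layer_spec(u, "relu", "he_normal", dropout)),
    l1 = 0, l2 = 0, learning_rate = lr, max_epochs = epochs,
    batch_size = 16L, seed = seed)
}

test_that("the default configuration is the tuned five-layer stack", {
  cfg <- qsar_config()
  expect_length(cfg$layers, 5L)
  expect_equal(unclass(cfg$layers[[1]]),
               list(units = 600L, activation = "tanh",
                    initializer = "he_normal", dropout = 0.1))
  expect_equal(unclass(cfg$layers[[5]]),
               list(units = 700L, activation = "tanh",
                    initializer = "uniform", dropout = 0.4))
  expect_equal(vapply(cfg$layers, `[[`, 0L, "units"),
               c(600L, 560L, 300L, 420L, 700L))
  expect_equal(cfg$l1, 0.00113)
  expect_equal(cfg$l2, 0.00015)
  expect_equal(cfg$learning_rate, 0.0001)
  expect_equal(cfg$max_epochs, 120L)
  expect_equal(cfg$split_fraction, 0.8)
  expect_error(qsar_config(layers = list()), "hidden layer")
})

test_that("parameter counts: closed form, hand case and enumeration", {
  expect_equal(count_parameters(qsar_config(), 342L), 1132481L)
  expect_equal(count_parameters(small_config(1L), 1L), 4L)

  set.seed(9)
  for (rep in 1:20) {
    units <- sample(1:40, sample(1:4, 1))
    cfg <- small_config(units, epochs = 0L)
    input_dim <- sample(1:30, 1)
    x <- matrix(rnorm(5 * input_dim), 5, input_dim)
    m <- qsar_net(x, rnorm(5), cfg)
    enumerated <- sum(lengths(m$params$W)) + sum(lengths(m$params$b))
    expect_equal(count_parameters(cfg, input_dim), enumerated)
  }
})

test_that("initialisation and training are seed-deterministic", {
  x <- matrix(rbinom(200, 1, 0.3), 20, 10)
  y <- rnorm(20)
  cfg <- small_config(epochs = 0L, seed = 7L)
  m1 <- qsar_net(x, y, cfg)
  m2 <- qsar_net(x, y, cfg)
  expect_identical(m1$params, m2$params)   # identical initial weights

  cfg5 <- small_config(epochs = 5L, seed = 7L, dropout = 0.2)
  f1 <- qsar_net(x, y, cfg5)
  f2 <- qsar_net(x, y, cfg5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})

test_that("train/test splits are disjoint, exhaustive and reproducible", {
  sp <- split_train_test(10L, 0.8, seed = 1L)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_identical(sp, split_train_test(10L, 0.8, seed = 1L))
  expect_false(identical(sp, split_train_test(10L, 0.8, seed = 2L)))
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_error(split_train_test(10L, 1.2), "fraction")
  expect_error(split_train_test(10L, 0), "fraction")
})

test_that("regression metrics match hand arithmetic and the loop oracle", {
  m <- regression_metrics(c(2, 4), c(1, 5))
  expect_equal(m$mse, 1)
  expect_equal(m$mae, 1)
  expect_equal(m$mape, 37.5)

  m1 <- regression_metrics(10, 9)
  expect_equal(m1$mse, 1)
  expect_equal(m1$mae, 1)
  expect_equal(m1$mape, 10)

  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mape, 0)

  set.seed(21)
  for (rep in 1:100) {
    k <- sample(1:30, 1)
    y <- rnorm(k, 5, 2); y[y == 0] <- 1
    yhat <- y + rnorm(k)
    got <- regression_metrics(y, yhat)
    want <- loop_metrics(y, yhat)
    expect_equal(got$mse, want$mse, tolerance = 1e-12)
    expect_equal(got$mae, want$mae, tolerance = 1e-12)
    expect_equal(got$mape, want$mape, tolerance = 1e-12)
    expect_lte(got$mae, sqrt(got$mse) + 1e-12)   # Jensen
  }

  mz <- regression_metrics(c(0, 1), c(1, 1))
  expect_false(mz$mape_defined)
  expect_true(is.na(mz$mape))
})

test_that("a constant target is fit to machine-level MSE", {
  set.seed(2)
  x <- matrix(rbinom(50 * 5, 1, 0.5), 50, 5)
  y <- rep(5.5, 50)
  cfg <- small_config(c(8L), epochs = 200L, lr = 0.02)
  m <- qsar_net(x, y, cfg)
  expect_lt(mean((m$fitted_values - 5.5)^2), 1e-3)
})

test_that("prediction is deterministic, order-invariant and schema-checked", {
  set.seed(3)
  x <- matrix(rbinom(30 * 6, 1, 0.4), 30, 6,
              dimnames = list(NULL, paste0("F", 1:6)))
  y <- rnorm(30)
  m <- qsar_net(x, y, small_config(epochs = 10L))

  newx <- x[c(1, 1, 5), ]
  p <- predict(m, newx)
  expect_equal(p[1], p[2])
  perm <- c(3, 1, 2)
  expect_equal(unname(predict(m, newx[perm, ])), unname(p[perm]))

  zero <- matrix(0L, 1, 6, dimnames = list("z", paste0("F", 1:6)))
  expect_true(is.finite(predict(m, zero)))

  wrong <- x[, 1:5]
  expect_error(predict(m, wrong), "columns")
  relabeled <- x
  colnames(relabeled) <- paste0("G", 1:6)
  expect_error(predict(m, relabeled), "schema")
})

test_that("saved models reload with bit-identical predictions", {
  set.seed(4)
  x <- matrix(rbinom(25 * 4, 1, 0.4), 25, 4,
              dimnames = list(NULL, paste0("F", 1:4)))
  m <- qsar_net(x, rnorm(25), small_config(epochs = 8L))
  dir <- withr::local_tempdir()
  save_qsar_net(m, file.path(dir, "model"))
  m2 <- load_qsar_net(file.path(dir, "model"))
  expect_identical(predict(m, x), predict(m2, x))
  expect_equal(m2$n_parameters, m$n_parameters)

  # version tag mismatch is an explicit error
  cfg_path <- file.path(dir, "model", "config.json")
  cfg <- jsonlite::read_json(cfg_path)
  cfg$version <- "999"
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, null = "null")
  expect_error(load_qsar_net(file.path(dir, "model")), "version")

  expect_error(load_qsar_net(file.path(dir, "nowhere")), "no model")
})

test_that("early stopping halts before the epoch cap", {
  set.seed(6)
  x <- matrix(rbinom(80 * 5, 1, 0.5), 80, 5)
  y <- rnorm(80)   # pure noise: validation loss stops improving quickly
  cfg <- small_config(c(8L), epochs = 100L, lr = 0.02)
  cfg$early_stop_patience <- 5L
  m <- qsar_net(x, y, cfg)
  expect_lt(nrow(m$history), 100L)
})

test_that("random search is seeded and ranked by validation MSE", {
  set.seed(8)
  x <- matrix(rbinom(60 * 5, 1, 0.5), 60, 5)
  y <- rnorm(60) + x[, 1]
  space <- list(learning_rate = c(0.001, 0.01, 0.05),
                l2 = c(0, 1e-4, 1e-3))
  base <- small_config(c(8L), epochs = 5L)
  r1 <- random_search(x, y, space, n_candidates = 4L, seed = 5L,
                      base_config = base)
  r2 <- random_search(x, y, space, n_candidates = 4L, seed = 5L,
                      base_config = base)
  expect_identical(attr(r1, "configs"), attr(r2, "configs"))
  expect_identical(r1$val_mse, sort(r1$val_mse))  # ranked ascending

  rs <- random_search(x, y, space, n_candidates = 1L, seed = 2L,
                      base_config = base)
  expect_equal(nrow(rs), 1L)
  expect_error(random_search(x, y, list(), 2L), "empty")
})
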