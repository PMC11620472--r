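# Deep feed-forward pIC50 regressor.
#
# A fully-connected network trained with Adam on mean-squared-error loss
# plus L1/L2 kernel penalties, with per-layer dropout. The default
# architecture is the tuned five-hidden-layer stack
# (600 tanh / 560 relu / 300 relu / 420 elu / 700 tanh, dropout
# 0.1/0.1/0.3/0.2/0.4) with a single linear output unit. Implemented
# directly on BLAS matrix operations: every forward/backward pass is a
# handful of dense GEMMs, which is fast enough for fingerprint-sized
# inputs on one CPU.

ACTIVATIONS <- c("tanh", "relu", "elu")
INITIALIZERS <- c("he_normal", "glorot_uniform", "glorot_normal", "uniform")

#' Hidden-layer specification
#'
#' @param units number of units (positive integer).
#' @param activation \code{"tanh"}, \code{"relu"} or \code{"elu"}.
#' @param initializer \code{"he_normal"}, \code{"glorot_uniform"},
#'   \code{"glorot_normal"} or \code{"uniform"} (scaled uniform on
#'   \eqn{[-0.05, 0.05]}).
#' @param dropout dropout rate in \eqn{[0, 1)}.
#' @return object of class \code{layer_spec}.
#' @export
layer_spec <- function(units, activation = "relu",
                       initializer = "glorot_uniform", dropout = 0) {
  activation <- match.arg(activation, ACTIVATIONS)
  initializer <- match.arg(initializer, INITIALIZERS)
  stopifnot(units >= 1, dropout >= 0, dropout < 1)
  structure(list(units = as.integer(units), activation = activation,
                 initializer = initializer, dropout = dropout),
            class = "layer_spec")
}

#' Model configuration for the pIC50 regressor
#'
#' Called with no arguments this returns the tuned default: five hidden
#' layers (600 tanh he_normal 0.1; 560 relu glorot_uniform 0.1; 300 relu
#' glorot_normal 0.3; 420 elu he_normal 0.2; 700 tanh uniform 0.4),
#' L1 = 0.00113 and L2 = 0.00015 kernel penalties, Adam at learning rate
#' 0.0001, up to 120 epochs, batch size 32 and an 80:20 train/test
#' split.
#'
#' @param layers list of \code{\link{layer_spec}} objects.
#' @param l1,l2 kernel penalty coefficients (hidden layers only).
#' @param learning_rate Adam step size.
#' @param optimizer only \code{"adam"} is supported.
#' @param max_epochs training epoch cap.
#' @param early_stop_patience epochs without validation improvement
#'   before stopping (\code{NULL} disables early stopping).
#' @param batch_size minibatch size.
#' @param split_fraction train fraction of the train/test split.
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return object of class \code{qsar_config}.
#' @export
qsar_config <- function(layers = list(
                          layer_spec(600, "tanh", "he_normal", 0.1),
                          layer_spec(560, "relu", "glorot_uniform", 0.1),
                          layer_spec(300, "relu", "glorot_normal", 0.3),
                          layer_spec(420, "elu", "he_normal", 0.2),
                          layer_spec(700, "tanh", "uniform", 0.4)),
                        l1 = 0.00113, l2 = 0.00015,
                        learning_rate = 0.0001, optimizer = "adam",
                        max_epochs = 120L, early_stop_patience = NULL,
                        batch_size = 32L, split_fraction = 0.8,
                        seed = 1L) {
  optimizer <- match.arg(optimizer, "adam")
  if (length(layers) == 0L) stop("at least one hidden layer is required")
  stopifnot(l1 >= 0, l2 >= 0, learning_rate >= 0,
            split_fraction > 0, split_fraction < 1, batch_size >= 1)
  layers <- lapply(layers, function(l) {
    if (inherits(l, "layer_spec")) l else do.call(layer_spec, l)
  })
  structure(list(layers = layers, l1 = l1, l2 = l2,
                 learning_rate = learning_rate, optimizer = optimizer,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 batch_size = as.integer(batch_size),
                 split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "qsar_config")
}

#' @export
print.qsar_config <- function(x, ...) {
  cat("pIC50 regressor configuration\n")
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  hidden %d: %4d units, %-4s, %-14s dropout %.2f\n",
                i - 1L, l$units, l$activation, l$initializer, l$dropout))
  }
  cat(sprintf("  l1 %g, l2 %g, adam lr %g, epochs <= %d, batch %d\n",
              x$l1, x$l2, x$learning_rate, x$max_epochs, x$batch_size))
  invisible(x)
}

#' Trainable parameter count of a network
#'
#' Closed-form count: for hidden layers of widths \eqn{d_1 \ldots d_L}
#' on \eqn{d_0} inputs, \eqn{\sum_i (d_{i-1} d_i + d_i)} plus the linear
#' output's \eqn{d_L + 1}.
#'
#' @param config a \code{\link{qsar_config}}.
#' @param input_dim number of input descriptors.
#' @return integer parameter count.
#' @export
count_parameters <- function(config, input_dim) {
  dims <- c(input_dim, vapply(config$layers, `[[`, 0L, "units"), 1L)
  as.integer(sum(as.numeric(dims[-length(dims)]) * dims[-1L] + dims[-1L]))
}

init_layer_weights <- function(fan_in, fan_out, initializer) {
  switch(initializer,
    he_normal = matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)),
                       fan_in, fan_out),
    glorot_normal = matrix(stats::rnorm(fan_in * fan_out, 0,
                                        sqrt(2 / (fan_in + fan_out))),
                           fan_in, fan_out),
    glorot_uniform = {
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    },
    uniform = matrix(stats::runif(fan_in * fan_out, -0.05, 0.05),
                     fan_in, fan_out))
}

init_network <- function(config, input_dim) {
  dims <- c(input_dim, vapply(config$layers, `[[`, 0L, "units"), 1L)
  inits <- c(vapply(config$layers, `[[`, "", "initializer"),
             "glorot_uniform")
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (i in seq_along(W)) {
    W[[i]] <- init_layer_weights(dims[i], dims[i + 1L], inits[i])
    b[[i]] <- numeric(dims[i + 1L])
  }
  list(W = W, b = b, dims = dims)
}

act_fun <- function(x, kind) {
  switch(kind, tanh = tanh(x), relu = pmax(x, 0),
         elu = ifelse(x > 0, x, expm1(x)))
}

act_grad <- function(a, z, kind) {
  switch(kind, tanh = 1 - a^2, relu = (z > 0) * 1,
         elu = ifelse(z > 0, 1, a + 1))
}

forward_pass <- function(params, X, acts, dropout = NULL) {
  L <- length(params$W)
  A <- X
  cache <- vector("list", L)
  for (i in seq_len(L - 1L)) {
    Z <- sweep(A %*% params$W[[i]], 2L, params$b[[i]], "+")
    H <- act_fun(Z, acts[i])
    mask <- NULL
    if (!is.null(dropout) && dropout[i] > 0) {
      mask <- matrix(stats::rbinom(length(H), 1L, 1 - dropout[i]),
                     nrow(H), ncol(H)) / (1 - dropout[i])
      H <- H * mask
    }
    cache[[i]] <- list(A_in = A, Z = Z, H = H, mask = mask)
    A <- H
  }
  out <- drop(sweep(A %*% params$W[[L]], 2L, params$b[[L]], "+"))
  list(yhat = out, cache = cache, A_last = A)
}

backward_pass <- function(params, fw, y, acts, l1, l2) {
  L <- length(params$W)
  n <- length(y)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- matrix(2 * (fw$yhat - y) / n, ncol = 1L)    # d(MSE)/d(out)
  gW[[L]] <- crossprod(fw$A_last, delta)
  gb[[L]] <- colSums(delta)
  upstream <- delta %*% t(params$W[[L]])
  for (i in rev(seq_len(L - 1L))) {
    cc <- fw$cache[[i]]
    if (!is.null(cc$mask)) upstream <- upstream * cc$mask
    dZ <- upstream * act_grad(act_fun(cc$Z, acts[i]), cc$Z, acts[i])
    gW[[i]] <- crossprod(cc$A_in, dZ) + l1 * sign(params$W[[i]]) +
      2 * l2 * params$W[[i]]
    gb[[i]] <- colSums(dZ)
    if (i > 1L) upstream <- dZ %*% t(params$W[[i]])
  }
  list(gW = gW, gb = gb)
}

penalty_value <- function(params, l1, l2) {
  L <- length(params$W)
  tot <- 0
  for (i in seq_len(L - 1L))     # hidden kernels only, not biases/output
    tot <- tot + l1 * sum(abs(params$W[[i]])) + l2 * sum(params$W[[i]]^2)
  tot
}

#' Seed-reproducible train/test split
#'
#' Partitions indices \code{1..n} into disjoint, exhaustive train and
#' test sets of sizes \code{round(fraction * n)} and the remainder.
#'
#' @param n number of observations (>= 2).
#' @param fraction train fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with integer vectors \code{train} and \code{test}.
#' @export
split_train_test <- function(n, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  stopifnot(n >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n)
  k <- round(fraction * n)
  list(train = sort(idx[seq_len(k)]), test = sort(idx[-seq_len(k)]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit the deep pIC50 regressor
#'
#' Trains a feed-forward network on a binary descriptor matrix with Adam
#' on mean-squared-error loss plus the configured L1/L2 kernel penalties
#' and per-layer dropout. Training history (per-epoch train and
#' validation MSE) is recorded; optional early stopping monitors the
#' validation loss. All randomness is governed by \code{config$seed}, so
#' a repeated call reproduces the model exactly.
#'
#' @param x numeric matrix of descriptors (rows = compounds); column
#'   names become the model's input schema.
#' @param y numeric response (pIC50), one value per row of \code{x}.
#' @param config a \code{\link{qsar_config}}.
#' @param validation optional list \code{(x, y)} used for the validation
#'   series and early stopping; when absent and early stopping is
#'   requested, a 10\% tail of the shuffled training data is held out.
#' @param verbose print a line every 10 epochs.
#' @return object of class \code{qsar_net} with elements \code{params},
#'   \code{config}, \code{schema}, \code{history}, \code{fitted_values},
#'   \code{y}.
#' @export
qsar_net <- function(x, y, config = qsar_config(), validation = NULL,
                     verbose = FALSE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= 1)
  acts <- vapply(config$layers, `[[`, "", "activation")
  drops <- vapply(config$layers, `[[`, 0, "dropout")
  schema <- colnames(x) %||% paste0("X", seq_len(ncol(x)))
  colnames(x) <- schema

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- init_network(config, ncol(x))

  if (is.null(validation) && !is.null(config$early_stop_patience)) {
    idx <- sample.int(nrow(x))
    n_val <- max(1L, round(0.1 * nrow(x)))
    vi <- idx[seq_len(n_val)]
    ti <- idx[-seq_len(n_val)]
    validation <- list(x = x[vi, , drop = FALSE], y = y[vi])
    x <- x[ti, , drop = FALSE]; y <- y[ti]
  }

  L <- length(params$W)
  m_W <- lapply(params$W, function(w) w * 0)
  v_W <- lapply(params$W, function(w) w * 0)
  m_b <- lapply(params$b, function(b) b * 0)
  v_b <- lapply(params$b, function(b) b * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  lr <- config$learning_rate

  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0))
  best_val <- Inf; wait <- 0L
  n <- nrow(x)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      bi <- ord[s:min(s + config$batch_size - 1L, n)]
      fw <- forward_pass(params, x[bi, , drop = FALSE], acts, drops)
      if (!all(is.finite(fw$yhat)))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      bw <- backward_pass(params, fw, y[bi], acts, config$l1, config$l2)
      t_step <- t_step + 1L
      corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
      for (i in seq_len(L)) {
        m_W[[i]] <- beta1 * m_W[[i]] + (1 - beta1) * bw$gW[[i]]
        v_W[[i]] <- beta2 * v_W[[i]] + (1 - beta2) * bw$gW[[i]]^2
        params$W[[i]] <- params$W[[i]] -
          lr * (m_W[[i]] / corr1) / (sqrt(v_W[[i]] / corr2) + eps)
        m_b[[i]] <- beta1 * m_b[[i]] + (1 - beta1) * bw$gb[[i]]
        v_b[[i]] <- beta2 * v_b[[i]] + (1 - beta2) * bw$gb[[i]]^2
        params$b[[i]] <- params$b[[i]] -
          lr * (m_b[[i]] / corr1) / (sqrt(v_b[[i]] / corr2) + eps)
      }
    }
    train_pred <- forward_pass(params, x, acts)$yhat
    train_mse <- mean((train_pred - y)^2)
    val_mse <- NA_real_
    if (!is.null(validation)) {
      val_pred <- forward_pass(params, validation$x, acts)$yhat
      val_mse <- mean((val_pred - validation$y)^2)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_mse = train_mse,
                                         val_mse = val_mse))
    if (verbose && epoch %% 10L == 0L)
      message(sprintf("epoch %3d  train MSE %.4f  val MSE %s", epoch,
                      train_mse,
                      ifelse(is.na(val_mse), "-", sprintf("%.4f", val_mse))))
    if (!is.null(config$early_stop_patience) && !is.na(val_mse)) {
      if (val_mse < best_val - 1e-9) { best_val <- val_mse; wait <- 0L }
      else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
      }
    }
  }

  fitted <- forward_pass(params, x, acts)$yhat
  structure(list(params = params, config = config, schema = schema,
                 history = history, fitted_values = fitted, y = y,
                 n_parameters = count_parameters(config, ncol(x))),
            class = "qsar_net")
}

#' Predict pIC50 for new compounds
#'
#' @param object a fitted \code{\link{qsar_net}}.
#' @param newdata descriptor matrix; its columns must match the model's
#'   input schema (use \code{\link{project_descriptors}} first if they
#'   do not).
#' @param ... unused.
#' @return numeric vector of predicted pIC50, named by rownames.
#' @export
predict.qsar_net <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$schema))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$schema))
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$schema))
    stop("newdata columns do not match the model's input schema; ",
         "apply project_descriptors() first")
  acts <- vapply(object$config$layers, `[[`, "", "activation")
  out <- forward_pass(object$params, newdata, acts)$yhat
  names(out) <- rownames(newdata)
  out
}

#' @export
print.qsar_net <- function(x, ...) {
  cat("Deep pIC50 regressor (", length(x$schema), " descriptors -> ",
      paste(vapply(x$config$layers, `[[`, 0L, "units"), collapse = "-"),
      " -> 1)\n", sep = "")
  cat("  ", x$n_parameters, " trainable parameters, ",
      nrow(x$history), " epochs trained\n", sep = "")
  if (nrow(x$history) > 0L)
    cat(sprintf("  final train MSE %.4f\n",
                x$history$train_mse[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.qsar_net <- function(object, ...) {
  m <- regression_metrics(object$y, object$fitted_values)
  out <- list(model = object, train_metrics = m)
  class(out) <- "summary.qsar_net"
  out
}

#' @export
print.summary.qsar_net <- function(x, ...) {
  print(x$model)
  cat("Training-set metrics:\n")
  print(x$train_metrics)
  invisible(x)
}

#' @export
residuals.qsar_net <- function(object, ...) object$y - object$fitted_values

#' Plot training history
#'
#' Train (and validation, when recorded) mean-squared error per epoch.
#'
#' @param x a \code{\link{qsar_net}}.
#' @param ... passed to \code{matplot}.
#' @export
plot.qsar_net <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) stop("model has no training history")
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "MSE", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Regression error metrics
#'
#' Mean squared error, mean absolute error and mean absolute percentage
#' error over \eqn{k} observations:
#' \deqn{MSE = \frac1k \sum (y_i - \hat y_i)^2, \quad
#'       MAE = \frac1k \sum |y_i - \hat y_i|, \quad
#'       MAPE = \frac{100}k \sum |(y_i - \hat y_i)/y_i|.}
#' MAPE is undefined when any \eqn{y_i = 0}; it is then reported as
#' \code{NA} with a flag.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return object of class \code{regression_metrics}: list with
#'   \code{mse}, \code{mae}, \code{mape} (percent), \code{n},
#'   \code{mape_defined}.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  err <- y - yhat
  mape_defined <- all(y != 0)
  structure(list(mse = mean(err^2), mae = mean(abs(err)),
                 mape = if (mape_defined) 100 * mean(abs(err / y)) else
                   NA_real_,
                 n = length(y), mape_defined = mape_defined),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("  MSE %.4f  MAE %.4f  MAPE %s  (n = %d)\n", x$mse, x$mae,
              if (x$mape_defined) sprintf("%.2f%%", x$mape) else
                "undefined (zero target)", x$n))
  invisible(x)
}

#' Randomised hyperparameter search
#'
#' Samples \code{n_candidates} configurations from a search space,
#' trains each on a fixed split and ranks them by validation MSE.
#'
#' @param x,y training data.
#' @param space named list of samplers; each element is either a vector
#'   to sample from or a function \code{function(k)} returning \code{k}
#'   draws. Recognised names: \code{learning_rate}, \code{l1}, \code{l2},
#'   \code{batch_size}, \code{layers} (list of layer lists to choose
#'   among).
#' @param n_candidates number of sampled configurations.
#' @param seed integer seed (sampling and training).
#' @param base_config template configuration.
#' @return data.frame ranked by ascending validation MSE, with a
#'   \code{configs} attribute holding the sampled \code{qsar_config}s in
#'   ranked order.
#' @export
random_search <- function(x, y, space, n_candidates = 10L, seed = 1L,
                          base_config = qsar_config()) {
  stopifnot(n_candidates >= 1)
  if (length(space) == 0L) stop("empty search space")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- function(s) if (is.function(s)) s(1L) else
    s[[sample.int(length(s), 1L)]]
  configs <- vector("list", n_candidates)
  for (k in seq_len(n_candidates)) {
    cfg <- base_config
    for (nm in names(space)) {
      val <- draw(space[[nm]])
      if (nm == "layers") cfg$layers <- lapply(val, function(l)
        if (inherits(l, "layer_spec")) l else do.call(layer_spec, l))
      else cfg[[nm]] <- val
    }
    cfg$seed <- base_config$seed
    configs[[k]] <- do.call(qsar_config, cfg[setdiff(names(cfg), NULL)])
  }
  sp <- split_train_test(nrow(x), base_config$split_fraction,
                         base_config$seed)
  res <- data.frame(candidate = seq_len(n_candidates),
                    val_mse = NA_real_, val_mae = NA_real_)
  for (k in seq_len(n_candidates)) {
    fit <- qsar_net(x[sp$train, , drop = FALSE], y[sp$train],
                    configs[[k]])
    m <- regression_metrics(y[sp$test],
                            predict(fit, x[sp$test, , drop = FALSE]))
    res$val_mse[k] <- m$mse
    res$val_mae[k] <- m$mae
  }
  ord <- order(res$val_mse)
  out <- res[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "configs") <- configs[ord]
  out
}

MODEL_FORMAT_VERSION <- "1"

#' Save / load a fitted regressor
#'
#' The model is written as a directory of portable text artifacts:
#' \code{config.json}, \code{schema.txt}, \code{weights.csv} (flattened,
#' column-major, tagged by layer) and \code{history.csv}. A reloaded
#' model reproduces predictions bit-for-bit.
#'
#' @param object a \code{\link{qsar_net}}.
#' @param path directory to create.
#' @export
save_qsar_net <- function(object, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- object$config
  cfg_list <- list(version = MODEL_FORMAT_VERSION,
                   layers = lapply(cfg$layers, unclass),
                   l1 = cfg$l1, l2 = cfg$l2,
                   learning_rate = cfg$learning_rate,
                   optimizer = cfg$optimizer, max_epochs = cfg$max_epochs,
                   early_stop_patience = cfg$early_stop_patience,
                   batch_size = cfg$batch_size,
                   split_fraction = cfg$split_fraction, seed = cfg$seed)
  jsonlite::write_json(cfg_list, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(object$schema, file.path(path, "schema.txt"))
  rows <- list()
  for (i in seq_along(object$params$W)) {
    rows[[2L * i - 1L]] <- data.frame(layer = i, kind = "W",
                                      value = as.numeric(object$params$W[[i]]))
    rows[[2L * i]] <- data.frame(layer = i, kind = "b",
                                 value = as.numeric(object$params$b[[i]]))
  }
  wdf <- do.call(rbind, rows)
  wdf$value <- sprintf("%.17g", wdf$value)  # exact double round-trip
  utils::write.csv(wdf, file.path(path, "weights.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(object$history, file.path(path, "history.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname save_qsar_net
#' @return \code{load_qsar_net} returns the restored \code{qsar_net}.
#' @export
load_qsar_net <- function(path) {
  cfg_file <- file.path(path, "config.json")
  if (!file.exists(cfg_file)) stop("no model found at ", path)
  cfg_list <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
  if (!identical(as.character(cfg_list$version), MODEL_FORMAT_VERSION))
    stop("model format version '", cfg_list$version,
         "' does not match supported version '", MODEL_FORMAT_VERSION, "'")
  layers <- lapply(seq_len(nrow(cfg_list$layers)), function(i)
    layer_spec(cfg_list$layers$units[i], cfg_list$layers$activation[i],
               cfg_list$layers$initializer[i], cfg_list$layers$dropout[i]))
  cfg <- qsar_config(layers = layers, l1 = cfg_list$l1, l2 = cfg_list$l2,
                     learning_rate = cfg_list$learning_rate,
                     max_epochs = cfg_list$max_epochs,
                     early_stop_patience = cfg_list$early_stop_patience,
                     batch_size = cfg_list$batch_size,
                     split_fraction = cfg_list$split_fraction,
                     seed = cfg_list$seed)
  schema <- readLines(file.path(path, "schema.txt"))
  wdf <- utils::read.csv(file.path(path, "weights.csv"))
  dims <- c(length(schema), vapply(cfg$layers, `[[`, 0L, "units"), 1L)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (i in seq_along(W)) {
    wv <- wdf$value[wdf$layer == i & wdf$kind == "W"]
    bv <- wdf$value[wdf$layer == i & wdf$kind == "b"]
    if (length(wv) != dims[i] * dims[i + 1L] || length(bv) != dims[i + 1L])
      stop("weight store is corrupt: layer ", i, " has wrong size")
    W[[i]] <- matrix(wv, dims[i], dims[i + 1L])
    b[[i]] <- bv
  }
  history <- utils::read.csv(file.path(path, "history.csv"))
  structure(list(params = list(W = W, b = b, dims = dims), config = cfg,
                 schema = schema, history = history,
                 fitted_values = NULL, y = NULL,
                 n_parameters = count_parameters(cfg, length(schema))),
            class = "qsar_net")
}
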