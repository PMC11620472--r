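# Independent oracles and small fixture builders shared across tests.

# Explicit-loop regression metrics (independent of regression_metrics).
loop_metrics <- function(y, yhat) {
  k <- length(y)
  mse <- 0; mae <- 0; mape <- 0
  for (i in seq_len(k)) {
    e <- y[i] - yhat[i]
    mse <- mse + e^2
    mae <- mae + abs(e)
    mape <- mape + abs(e / y[i])
  }
  list(mse = mse / k, mae = mae / k, mape = 100 * mape / k)
}

# Pairwise-concordance AUC (independent of the threshold-sweep curve).
concordance_auc <- function(scores, labels) {
  a <- scores[labels == "active"]
  d <- scores[labels == "decoy"]
  tot <- 0
  for (x in a) for (y in d)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(d))
}

# Random 0/1 fingerprint matrix.
random_fps <- function(n, nbits, density = 0.2, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * nbits, 1L, density), n, nbits,
         dimnames = list(sprintf("M%03d", seq_len(n)), NULL))
}

# Labeled score set with a given number of actives in the top slice:
# N total, A actives, the top n_top scores are assigned to actives/decoys
# so that exactly x of them are active.
ef_fixture <- function(N, A, n_top, x) {
  labels <- rep("decoy", N)
  top_active <- seq_len(x)
  labels[seq_len(n_top)][seq_len(x)] <- "active"
  remaining_active <- A - x
  labels[(n_top + 1):(n_top + remaining_active)] <- "active"
  scores <- seq(N, 1) / N  # strictly decreasing, no ties
  list(scores = scores, labels = labels)
}

# A small random trajectory (no planted structure).
random_traj <- function(n_frames = 10, n_atoms = 8, sd = 0.1, seed = 1) {
  set.seed(seed)
  base <- matrix(runif(n_atoms * 3), n_atoms, 3)
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames))
    coords[f, , ] <- base + matrix(rnorm(n_atoms * 3, 0, sd), n_atoms, 3)
  trajectory(coords)
}

# Apply one global rigid transform (same for every frame).
transform_traj <- function(traj, R, t_vec) {
  d <- dim(traj$coords)
  out <- traj$coords
  for (f in seq_len(d[1]))
    out[f, , ] <- sweep(matrix(traj$coords[f, , ], ncol = 3) %*% R,
                        2, t_vec, "+")
  trajectory(out, traj$atoms, traj$times)
}

# A unit 3N mode with the rigid-body subspace (3 translations, 3
# rotations about the centre of mass) projected out, so superposition
# cannot absorb any of the planted motion.
rigid_free_mode <- function(base, raw) {
  n <- nrow(base)
  rel <- sweep(base, 2, colMeans(base))
  basis <- matrix(0, n * 3, 6)
  for (k in 1:3) {
    m <- matrix(0, n, 3); m[, k] <- 1
    basis[, k] <- as.numeric(m)
  }
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  ax <- diag(3)
  for (k in 1:3)
    basis[, 3 + k] <- as.numeric(t(apply(rel, 1, function(r)
      cross3(ax[k, ], r))))
  q <- qr.Q(qr(basis))
  v <- as.numeric(raw)
  v <- v - q %*% crossprod(q, v)
  out <- matrix(v, n, 3)
  out / sqrt(sum(out^2))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}
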