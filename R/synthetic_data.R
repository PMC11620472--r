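# Synthetic-data generators with planted structure.
#
# Every stage of the screening pipeline can be exercised without
# external downloads: fingerprint/activity training sets with a planted
# linear structure-activity signal, active/decoy/control libraries with
# controlled Tanimoto separation, a hand-verified molecule panel for the
# rule filters, and C-alpha trajectories with planted collective modes.
# All generators are seed-deterministic; default scales mirror the
# study conditions (about 950 training compounds x 881 bits, a
# 2563-compound screening library, and a 20-active / 500-decoy /
# 1-control validation set).

#' Synthetic fingerprint/activity training set
#'
#' Bits are i.i.d. Bernoulli(\code{bit_density}); the response is
#' \code{pic50 = intercept + sum_k w_k bit_k + eps} with
#' \code{eps ~ N(0, noise_sd^2)} and \code{k_informative} nonzero
#' weights drawn uniformly from \code{[-weight_scale, weight_scale]}.
#' Ground truth is returned for parameter-recovery checks.
#'
#' @param n compounds (default 953, the training-set scale emulated).
#' @param d descriptor width (default 881).
#' @param bit_density Bernoulli rate of set bits (default 0.2).
#' @param k_informative number of bits carrying signal (default 20).
#' @param weight_scale half-width of the weight distribution (default 1).
#' @param noise_sd residual standard deviation in pIC50 units
#'   (default 0.3).
#' @param intercept baseline pIC50 (default 6).
#' @param seed integer seed.
#' @return list with \code{x} (0/1 matrix with ids/bit names), \code{y}
#'   (pIC50), \code{weights} (length-d true weights), \code{intercept},
#'   \code{noise_sd}, \code{seed}.
#' @export
sim_fingerprint_activity <- function(n = 953L, d = 881L,
                                     bit_density = 0.2,
                                     k_informative = 20L,
                                     weight_scale = 1, noise_sd = 0.3,
                                     intercept = 6, seed = 1L) {
  stopifnot(k_informative <= d, bit_density > 0, bit_density < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- matrix(stats::rbinom(n * d, 1L, bit_density), n, d,
              dimnames = list(sprintf("CPD%04d", seq_len(n)),
                              sprintf("FP%d", seq_len(d))))
  w <- numeric(d)
  idx <- sample.int(d, k_informative)
  w[idx] <- stats::runif(k_informative, -weight_scale, weight_scale)
  eps <- stats::rnorm(n, 0, noise_sd)
  y <- intercept + drop(x %*% w) + eps
  list(x = x, y = y, weights = w, intercept = intercept,
       noise_sd = noise_sd, seed = seed)
}

#' Synthetic active/decoy/control fingerprint library
#'
#' The control fingerprint has i.i.d. Bernoulli(\code{control_density})
#' bits. Each active is the control with every bit flipped independently
#' with probability \code{flip_rate}; decoys are fresh independent
#' Bernoulli(\code{control_density}) draws. Actives are therefore
#' similar to the control in expectation while decoys are not, giving a
#' controlled Tanimoto separation.
#'
#' @param control_density density of set bits (default 0.1).
#' @param n_active number of actives (default 20).
#' @param n_decoy number of decoys (default 500).
#' @param flip_rate per-bit flip probability for actives, in (0, 0.5)
#'   (default 0.05).
#' @param nbits fingerprint width (default 2048).
#' @param seed integer seed.
#' @return list with \code{control} (0/1 vector), \code{fps} (0/1
#'   matrix: actives then decoys), \code{labels}
#'   (\code{"active"}/\code{"decoy"} per row), \code{ids}.
#' @export
sim_active_decoy_library <- function(control_density = 0.1,
                                     n_active = 20L, n_decoy = 500L,
                                     flip_rate = 0.05, nbits = 2048L,
                                     seed = 1L) {
  stopifnot(flip_rate > 0, flip_rate < 0.5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  control <- stats::rbinom(nbits, 1L, control_density)
  act <- t(vapply(seq_len(n_active), function(i) {
    flip <- stats::rbinom(nbits, 1L, flip_rate)
    as.integer(xor(control, flip))
  }, integer(nbits)))
  dec <- matrix(stats::rbinom(n_decoy * nbits, 1L, control_density),
                n_decoy, nbits)
  fps <- rbind(act, dec)
  ids <- c(sprintf("ACT%03d", seq_len(n_active)),
           sprintf("DEC%03d", seq_len(n_decoy)))
  rownames(fps) <- ids
  list(control = control, fps = fps,
       labels = rep(c("active", "decoy"), c(n_active, n_decoy)),
       ids = ids, seed = seed)
}

#' Hand-verified molecule panel for the rule filters
#'
#' A fixed panel of small molecules spanning pass/fail cases of each
#' drug-likeness filter, with the expected Yes/No outcomes derived by
#' evaluating the rule bounds on the computed property values by hand:
#' small molecules fail Ghose/Muegge on mass, a steroidal-alkaloid-like
#' polycyclic fails Ghose on its atom count alone (74 > 70) while
#' passing every other filter, a long alkane breaks the lipophilicity
#' and rotatable-bond limits, a sugar drives TPSA over the Veber/Egan
#' limits, and a macrolide-like structure breaks the Lipinski bounds.
#'
#' @return data.frame with \code{id}, \code{smiles} and expected
#'   \code{Lipinski}, \code{Ghose}, \code{Veber}, \code{Egan},
#'   \code{Muegge} columns (\code{"Yes"}/\code{"No"}).
#' @export
molecule_panel <- function() {
  panel <- list(
    # id, smiles, lipinski, ghose, veber, egan, muegge
    list("ethanol", "CCO", "Yes", "No", "Yes", "Yes", "No"),
    list("benzene", "c1ccccc1", "Yes", "No", "Yes", "Yes", "No"),
    list("aspirin", "CC(=O)Oc1ccccc1C(=O)O", "Yes", "Yes", "Yes", "Yes",
         "No"),
    list("caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "Yes", "No", "Yes",
         "Yes", "No"),  # Ghose fails: WLOGP -1.03 < -0.4
    # steroidal-alkaloid-like: 74 atoms, fails Ghose on atom count alone
    list("steroid_alkaloid",
         "CC1CCC2C(C1)CCC3C2CC(O)C4C3CC(O)C4C(C)C5CCC(CN5C)",
         "Yes", "No", "Yes", "Yes", "Yes"),
    list("ibuprofen", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "Yes", "Yes", "Yes",
         "Yes", "Yes"),
    list("naproxen", "COc1ccc2cc(ccc2c1)C(C)C(=O)O", "Yes", "Yes", "Yes",
         "Yes", "Yes"),
    list("triacontane", paste0("C", paste(rep("C", 29), collapse = "")),
         "Yes", "No", "No", "No", "No"),
    list("sucrose", "OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O",
         "No", "No", "No", "No", "No"),
    list("glycerol", "OCC(O)CO", "Yes", "No", "Yes", "Yes", "No"),
    list("diphenhydramine", "CN(C)CCOC(c1ccccc1)c2ccccc2", "Yes", "Yes",
         "Yes", "Yes", "Yes"),
    list("octanoic_acid", "CCCCCCCC(=O)O", "Yes", "No", "Yes", "Yes",
         "No"),
    list("erythromycin_like",
         paste0("CCC1OC(=O)C(C)C(OC2CC(C)(OC)C(O)C(C)O2)C(C)C(",
                "OC3OC(C)CC(N(C)C)C3O)C(C)(O)CC(C)C(=O)C(C)C(O)C1(C)O"),
         "No", "No", "No", "No", "No"))
  out <- data.frame(
    id = vapply(panel, `[[`, "", 1L),
    smiles = vapply(panel, `[[`, "", 2L),
    Lipinski = vapply(panel, `[[`, "", 3L),
    Ghose = vapply(panel, `[[`, "", 4L),
    Veber = vapply(panel, `[[`, "", 5L),
    Egan = vapply(panel, `[[`, "", 6L),
    Muegge = vapply(panel, `[[`, "", 7L),
    stringsAsFactors = FALSE)
  out
}

#' Synthetic trajectory with planted collective modes
#'
#' Frame \eqn{t} is \code{base + sum_k c_k(t) v_k + noise}, where each
#' mode \eqn{v_k} is a unit 3N-vector, the coefficients are
#' deterministic sinusoids \eqn{c_k(t) = a_k \sqrt2 \sin(2\pi f_k t/T +
#' \phi_k)} with unit-variance time average (so the planted covariance
#' is \eqn{\sum_k a_k^2 v_k v_k^T + \sigma^2 I}), and the noise is
#' isotropic Gaussian with standard deviation \code{noise_sd} per
#' coordinate.
#'
#' @param n_frames number of frames.
#' @param n_atoms number of atoms.
#' @param modes list of modes, each a list with \code{direction}
#'   (atoms x 3 matrix, normalised to unit total length) and
#'   \code{amplitude} (nm). \code{NULL} plants no mode.
#' @param noise_sd isotropic noise sd per coordinate (nm).
#' @param base atoms x 3 base structure; default a coarse helix with
#'   0.38 nm spacing (C-alpha-like geometry).
#' @param seed integer seed (noise and phases).
#' @return a \code{\link{trajectory}}; planted quantities are attached
#'   as attribute \code{"planted"}.
#' @export
sim_trajectory <- function(n_frames = 500L, n_atoms = 50L, modes = NULL,
                           noise_sd = 0.05, base = NULL, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(base)) base <- helix_backbone(n_atoms)
  stopifnot(nrow(base) == n_atoms)
  coords <- array(NA_real_, c(n_frames, n_atoms, 3L))
  t_frac <- seq_len(n_frames) / n_frames
  mode_list <- list()
  if (!is.null(modes)) {
    for (k in seq_along(modes)) {
      v <- as.matrix(modes[[k]]$direction)
      v <- v / sqrt(sum(v^2))
      a <- modes[[k]]$amplitude
      phase <- stats::runif(1, 0, 2 * pi)
      coef <- a * sqrt(2) * sin(2 * pi * k * t_frac + phase)
      mode_list[[k]] <- list(direction = v, amplitude = a, coef = coef)
    }
  }
  for (f in seq_len(n_frames)) {
    fr <- base
    for (k in seq_along(mode_list))
      fr <- fr + mode_list[[k]]$coef[f] * mode_list[[k]]$direction
    fr <- fr + matrix(stats::rnorm(n_atoms * 3L, 0, noise_sd), n_atoms, 3L)
    coords[f, , ] <- fr
  }
  traj <- trajectory(coords)
  attr(traj, "planted") <- list(base = base, modes = mode_list,
                                noise_sd = noise_sd, seed = seed)
  traj
}

helix_backbone <- function(n_atoms, rise = 0.15, radius = 0.23,
                           turn = 100 * pi / 180) {
  i <- seq_len(n_atoms)
  cbind(radius * cos(turn * i), radius * sin(turn * i), rise * i)
}

#' Rigid-motion trajectory
#'
#' Every frame is a random proper rotation plus translation of the base
#' frame; internal geometry is exactly preserved, so RMSD after fitting,
#' and fluctuation measures, are identically zero up to round-off.
#'
#' @param base atoms x 3 base structure (>= 3 atoms); default a coarse
#'   helix of 20 atoms.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return a \code{\link{trajectory}}.
#' @export
sim_rigid_trajectory <- function(base = NULL, n_frames = 20L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(base)) base <- helix_backbone(20L)
  base <- as.matrix(base)
  stopifnot(nrow(base) >= 3L)
  coords <- array(NA_real_, c(n_frames, nrow(base), 3L))
  for (f in seq_len(n_frames)) {
    R <- random_rotation()
    t_vec <- stats::runif(3L, -1, 1)
    coords[f, , ] <- sweep(base %*% R, 2L, t_vec, "+")
  }
  trajectory(coords)
}

# Uniform random proper rotation (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  M <- matrix(stats::rnorm(9L), 3L, 3L)
  qr_dec <- qr(M)
  Q <- qr.Q(qr_dec)
  d <- diag(sign(diag(qr.R(qr_dec))))
  Q <- Q %*% d
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}
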