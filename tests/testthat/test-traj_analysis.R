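# Superposition, trajectory statistics, essential dynamics and MM/GBSA
# bookkeeping.

test_that("Kabsch superposition recovers rigid transforms", {
  set.seed(41)
  ref <- matrix(runif(30), 10, 3)
  fit0 <- kabsch_fit(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)

  mob <- sweep(ref %*% rotation_z(90), 2, c(1, -2, 0.5), "+")
  fit <- kabsch_fit(mob, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  R <- fit$rotation
  expect_equal(crossprod(R), diag(3), tolerance = 1e-8)
  expect_equal(det(R), 1, tolerance = 1e-8)
})

test_that("Kabsch never increases the deviation and rejects degeneracy", {
  set.seed(43)
  for (rep in 1:15) {
    a <- matrix(rnorm(24), 8, 3)
    b <- matrix(rnorm(24), 8, 3)
    raw <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(kabsch_fit(a, b)$rmsd, raw + 1e-12)
    R <- kabsch_fit(a, b)$rotation
    expect_equal(crossprod(R), diag(3), tolerance = 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
  }
  expect_error(kabsch_fit(matrix(rnorm(6), 2, 3),
                          matrix(rnorm(6), 2, 3)), "3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line + 0.1), "collinear|degenerate")
})

test_that("a mirror image cannot be superposed by a proper rotation", {
  set.seed(47)
  pts <- matrix(rnorm(12), 4, 3)
  mirror <- pts %*% diag(c(-1, 1, 1))
  fit <- kabsch_fit(mirror, pts)
  expect_gt(fit$rmsd, 0.05)

  # independent oracle: numeric optimisation over Euler angles
  euler_rmsd <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    R <- Rz %*% Ry %*% Rx
    A <- sweep(mirror, 2, colMeans(mirror))
    B <- sweep(pts, 2, colMeans(pts))
    sqrt(mean(rowSums((A %*% R - B)^2)))
  }
  grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, by = pi / 6),
                                b = seq(0, pi, by = pi / 6),
                                c = seq(0, 2 * pi, by = pi / 6)))
  vals <- apply(grid, 1, euler_rmsd)
  best <- stats::optim(grid[which.min(vals), ], euler_rmsd,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 2000))
  expect_equal(fit$rmsd, best$value, tolerance = 1e-3)
})

test_that("RMSD series vanish for static and rigid-motion trajectories", {
  base <- matrix(runif(36), 12, 3)
  static <- trajectory(array(rep(base, each = 5), c(5, 12, 3)))
  expect_equal(rmsd_series(static), rep(0, 5), tolerance = 1e-10)

  rigid <- sim_rigid_trajectory(base, n_frames = 8, seed = 3)
  expect_equal(rmsd_series(rigid), rep(0, 8), tolerance = 1e-8)
})

test_that("a uniform displacement is pure translation: zero after fitting", {
  base <- matrix(runif(30), 10, 3)
  coords <- array(rep(base, each = 2), c(2, 10, 3))
  coords[2, , 1] <- coords[2, , 1] + 0.1
  traj <- trajectory(coords)
  before <- sqrt(mean(rowSums((coords[2, , ] - base)^2)))
  expect_equal(before, 0.1, tolerance = 1e-12)
  expect_equal(rmsd_series(traj)[2], 0, tolerance = 1e-10)
})

test_that("RMSF recovers isotropic jitter and planted mobility", {
  sigma <- 0.05
  jit <- sim_trajectory(n_frames = 2000, n_atoms = 30, modes = NULL,
                        noise_sd = sigma, seed = 5)
  f <- rmsf(jit)
  expect_equal(mean(f), sigma * sqrt(3), tolerance = 0.1)

  static <- trajectory(array(rep(matrix(runif(30), 10, 3), each = 4),
                             c(4, 10, 3)))
  expect_equal(rmsf(static), rep(0, 10), tolerance = 1e-10)

  # planted high-mobility atom
  set.seed(6)
  base <- matrix(runif(60), 20, 3)
  coords <- array(rep(base, each = 400), c(400, 20, 3))
  coords <- coords + array(rnorm(length(coords), 0, 0.01),
                           dim(coords))
  coords[, 7, 1] <- coords[, 7, 1] + rnorm(400, 0, 0.2)
  expect_equal(which.max(rmsf(trajectory(coords))), 7L)
})

test_that("radius of gyration matches closed-form geometry", {
  expect_equal(radius_of_gyration(matrix(c(3, 1, 2), 1, 3)), 0)
  two <- rbind(c(-1, 0, 0), c(1, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radius_of_gyration(square), sqrt(0.5))

  # mass weighting vs explicit loop
  set.seed(51)
  fr <- matrix(rnorm(15), 5, 3)
  m <- runif(5, 1, 20)
  com <- colSums(fr * m) / sum(m)
  acc <- 0
  for (i in 1:5) acc <- acc + m[i] * sum((fr[i, ] - com)^2)
  expect_equal(radius_of_gyration(fr, m), sqrt(acc / sum(m)),
               tolerance = 1e-12)

  rigid <- sim_rigid_trajectory(n_frames = 6, seed = 9)
  expect_equal(diff(range(rg_series(rigid))), 0, tolerance = 1e-10)
})

test_that("SASA matches sphere geometry and additivity", {
  iso <- sasa(matrix(0, 1, 3), radii = 0.2)
  expect_equal(iso$total, 4 * pi * 0.34^2, tolerance = 2 / 960)

  two_far <- sasa(rbind(c(0, 0, 0), c(5, 0, 0)), radii = c(0.2, 0.15))
  expect_equal(two_far$total, 4 * pi * (0.34^2 + 0.29^2),
               tolerance = 2 / 960)

  # a tiny atom fully inside a much larger sphere is buried
  inside <- sasa(rbind(c(0, 0, 0), c(0.05, 0, 0)),
                 radii = c(0.5, 0.01))
  expect_equal(inside$per_atom[2], 0)
})

test_that("hydrogen bonds follow the geometric criterion", {
  # linear D-H...A at 0.29 nm
  fr <- rbind(D = c(0, 0, 0), H = c(0.1, 0, 0), A = c(0.29, 0, 0))
  expect_equal(count_hbonds(fr, donors = 1, hydrogens = 2,
                            acceptors = 3), 1L)
  # beyond the distance cutoff
  fr2 <- fr; fr2[3, 1] <- 0.40
  expect_equal(count_hbonds(fr2, 1, 2, 3), 0L)
  # H-D-A angle 45 degrees at 0.30 nm
  fr3 <- rbind(D = c(0, 0, 0),
               H = c(0.1 * cos(pi / 4), 0.1 * sin(pi / 4), 0),
               A = c(0.30, 0, 0))
  expect_equal(count_hbonds(fr3, 1, 2, 3), 0L)
})

test_that("PCA satisfies its spectral invariants", {
  tr <- sim_trajectory(n_frames = 100, n_atoms = 10, noise_sd = 0.03,
                       seed = 13)
  pc <- traj_pca(tr)
  expect_equal(sum(pc$fractions), 1, tolerance = 1e-9)
  expect_equal(sum(pc$eigenvalues), pc$trace, tolerance = 1e-9)
  expect_equal(crossprod(pc$eigenvectors), diag(30), tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_true(all(pc$eigenvalues >= -1e-10))

  static <- trajectory(array(rep(matrix(runif(30), 10, 3), each = 4),
                             c(4, 10, 3)))
  expect_equal(traj_pca(static)$eigenvalues, rep(0, 30),
               tolerance = 1e-12)

  expect_error(traj_pca(tr, window = 500), "window")
})

test_that("a planted mode dominates PCA with the expected fraction", {
  n_atoms <- 50
  set.seed(15)
  dir_mat <- matrix(rnorm(n_atoms * 3), n_atoms, 3)
  dir_mat <- dir_mat / sqrt(sum(dir_mat^2))
  a <- 0.5; sigma <- 0.05
  tr <- sim_trajectory(n_frames = 2000, n_atoms = n_atoms,
                       modes = list(list(direction = dir_mat,
                                         amplitude = a)),
                       noise_sd = sigma, seed = 15)
  pc <- traj_pca(tr)
  expected <- (a^2 + sigma^2) / (a^2 + 3 * n_atoms * sigma^2)
  expect_lt(abs(pc$fractions[1] - expected), 0.05)

  v <- as.numeric(t(dir_mat))  # x1 y1 z1 ... ordering of traj_pca
  cosine <- abs(sum(v * pc$eigenvectors[, 1]))
  expect_gt(cosine, 0.95)
})

test_that("DCCM flags zero-fluctuation atoms and recovers planted blocks", {
  static <- trajectory(array(rep(matrix(runif(30), 10, 3), each = 4),
                             c(4, 10, 3)))
  C0 <- dccm(static)
  expect_equal(unname(C0), matrix(0, 10, 10), ignore_attr = TRUE)
  expect_length(attr(C0, "undefined"), 10L)

  # two anti-correlated blocks along x, spatially interleaved so the
  # planted motion is not mistakable for a rigid-body rotation
  set.seed(99)
  n_atoms <- 20
  base <- matrix(runif(n_atoms * 3, 0, 2), n_atoms, 3)
  blockA <- seq(1, 20, by = 2); blockB <- seq(2, 20, by = 2)
  dir_mat <- matrix(0, n_atoms, 3)
  dir_mat[blockA, 1] <- 1
  dir_mat[blockB, 1] <- -1
  dir_mat <- dir_mat / sqrt(sum(dir_mat^2))
  tr <- sim_trajectory(n_frames = 5000, n_atoms = n_atoms, base = base,
                       modes = list(list(direction = dir_mat,
                                         amplitude = 0.4)),
                       noise_sd = 0.02, seed = 17)
  C <- dccm(tr)
  expect_equal(C, t(C), tolerance = 1e-12)
  expect_true(all(diag(C) == 1))
  expect_true(all(abs(C) <= 1 + 1e-12))
  intra <- C[blockA, blockA][upper.tri(matrix(0, 10, 10))]
  inter <- C[blockA, blockB]
  expect_gt(mean(intra), 0.8)
  expect_lt(mean(inter), -0.8)
})

test_that("independent atoms decorrelate with enough frames", {
  tr <- sim_trajectory(n_frames = 5000, n_atoms = 30, modes = NULL,
                       noise_sd = 0.05, seed = 19)
  C <- dccm(tr)
  off <- C[upper.tri(C)]
  expect_lt(mean(abs(off)), 0.1)
})

test_that("trajectory statistics agree with bio3d on a common fixture", {
  tr <- random_traj(n_frames = 12, n_atoms = 10, sd = 0.08, seed = 21)
  xyz <- t(vapply(1:12, function(f)
    as.numeric(t(matrix(tr$coords[f, , ], ncol = 3))), numeric(30)))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz[1, ],
                                            mobile = xyz))
  ref_rmsd <- bio3d::rmsd(xyz[1, ], fitted)   # bio3d rounds to 3 digits
  expect_lt(max(abs(rmsd_series(tr) - as.numeric(ref_rmsd))), 6e-4)
})

test_that("statistics are invariant under a global rigid transform", {
  tr <- random_traj(n_frames = 8, n_atoms = 12, sd = 0.05, seed = 23)
  moved <- transform_traj(tr, rotation_z(67), c(2, -1, 3))
  expect_equal(rmsd_series(moved), rmsd_series(tr), tolerance = 1e-8)
  expect_equal(rg_series(moved), rg_series(tr), tolerance = 1e-10)
  expect_equal(rmsf(moved), rmsf(tr), tolerance = 1e-8)
  expect_equal(traj_pca(moved)$eigenvalues, traj_pca(tr)$eigenvalues,
               tolerance = 1e-8)
  expect_equal(dccm(moved), dccm(tr), tolerance = 1e-6)
})

test_that("multi-model PDB files round-trip through nm with checks", {
  tr <- random_traj(n_frames = 3, n_atoms = 5, sd = 0.05, seed = 25)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, f)
  back <- read_multimodel_pdb(f)
  expect_equal(dim(back$coords), c(3L, 5L, 3L))
  expect_lt(max(abs(back$coords - tr$coords)), 2e-4)

  # explicit unit rule: 10 A in the file is 1 nm in memory
  single <- trajectory(array(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(1, 3, 3)))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(single, f2)
  expect_true(any(grepl("10.000", readLines(f2))))

  # inconsistent atom counts name the offending model
  lines <- readLines(f)
  atom_idx <- which(startsWith(lines, "ATOM"))
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-atom_idx[8]], f3)   # drop one atom from model 2
  expect_error(read_multimodel_pdb(f3), "model 2")

  f4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[!startsWith(lines, "ENDMDL")], f4)
  expect_error(read_multimodel_pdb(f4), "ENDMDL")
})

test_that("MM/GBSA bookkeeping completes the component table", {
  comp <- data.frame(
    id = c("Imperialine", "Veratramine", "Jervine", "Gelsemine"),
    dE_vdw = c(-22.13, -50.32, -7.74, -30.03),
    dE_elec = c(-0.16, -16.50, -0.52, -7.94),
    dG_GB = c(1.11, 18.39, 0.96, 9.13),
    dG_SA = c(-3.05, -6.49, -1.06, -3.73))
  out <- combine_mmgbsa(comp)
  expect_equal(out$dG_gas, c(-22.29, -66.82, -8.26, -37.97),
               tolerance = 0.021)
  expect_equal(out$dG_sol, c(-1.94, 11.90, -0.10, 5.40),
               tolerance = 0.021)
  expect_equal(out$dG_bind, c(-24.23, -54.92, -8.36, -32.57),
               tolerance = 0.021)

  zero <- combine_mmgbsa(data.frame(dE_vdw = 0, dE_elec = 0, dG_GB = 0,
                                    dG_SA = 0))
  expect_equal(unlist(zero[c("dG_gas", "dG_sol", "dG_bind")]),
               c(dG_gas = 0, dG_sol = 0, dG_bind = 0))

  expect_error(combine_mmgbsa(data.frame(dE_vdw = 1)), "missing")
  expect_error(combine_mmgbsa(data.frame(dE_vdw = NA, dE_elec = 0,
                                         dG_GB = 0, dG_SA = 0)),
               "finite")
})
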