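# Trajectory statistics and essential dynamics.
#
# Internal units follow the GROMACS convention: coordinates in nm,
# times in ps, masses in amu. PDB Angstroms are converted at ingest.

VDW_RADII_NM <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                  P = 0.180, F = 0.147, Cl = 0.175, Br = 0.185, I = 0.198)
DEFAULT_VDW_NM <- 0.170

#' Construct a trajectory object
#'
#' @param coords numeric array frames x atoms x 3 (nm).
#' @param atoms optional data.frame of per-atom metadata (\code{name},
#'   \code{elem}, \code{resid}, \code{chain}, \code{mass},
#'   \code{radius}).
#' @param times frame times (ps).
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(coords, atoms = NULL, times = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L,
            all(is.finite(coords)))
  n_atoms <- dim(coords)[2L]
  if (is.null(atoms))
    atoms <- data.frame(name = paste0("CA", seq_len(n_atoms)),
                        elem = "C", resid = seq_len(n_atoms), chain = "A",
                        mass = ATOMIC_MASS[["C"]],
                        radius = VDW_RADII_NM[["C"]])
  stopifnot(nrow(atoms) == n_atoms, all(atoms$mass > 0))
  if (is.null(times)) times <- seq_len(dim(coords)[1L]) - 1
  structure(list(coords = coords, atoms = atoms, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("Trajectory:", d[1L], "frames x", d[2L], "atoms (nm)\n")
  invisible(x)
}

#' @export
dim.trajectory <- function(x) dim(x$coords)

frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3L)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses MODEL/ENDMDL-delimited coordinate sets (via bio3d), converts
#' Angstroms to nm and assigns masses and van der Waals radii from
#' element tables. Atom counts must be identical across models.
#'
#' @param file path to a PDB file.
#' @param dt frame spacing in ps (frame times are \code{0, dt, 2dt, ...}).
#' @return a \code{\link{trajectory}}.
#' @export
read_multimodel_pdb <- function(file, dt = 1) {
  lines <- readLines(file, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 0L && !any(rec == "ENDMDL"))
    stop("multi-model PDB has MODEL records but no ENDMDL")
  if (length(model_starts) > 1L) {
    ends <- which(rec == "ENDMDL")
    counts <- vapply(seq_along(model_starts), function(k) {
      span <- rec[model_starts[k]:ends[k]]
      sum(span %in% c("ATOM  ", "HETATM"))
    }, 0L)
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop("model ", bad, " has ", counts[bad],
           " atoms; model 1 has ", counts[1L])
    }
  }
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(n_frames, n_atoms, 3L))
  for (f in seq_len(n_frames))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  elem <- pdb$atom$elesy
  elem[is.na(elem) | elem == ""] <- substr(trimws(pdb$atom$elety[
    is.na(elem) | elem == ""]), 1L, 1L)
  mass <- unname(ATOMIC_MASS[elem])
  mass[is.na(mass)] <- ATOMIC_MASS[["C"]]
  radius <- unname(VDW_RADII_NM[elem])
  radius[is.na(radius)] <- DEFAULT_VDW_NM
  atoms <- data.frame(name = trimws(pdb$atom$elety), elem = elem,
                      resid = pdb$atom$resno, chain = pdb$atom$chain,
                      mass = mass, radius = radius,
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms, times = dt * (seq_len(n_frames) - 1))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are converted from nm to Angstroms. Useful for building
#' plain-text fixtures and for interoperability with standard viewers.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param file output path.
#' @export
write_multimodel_pdb <- function(traj, file) {
  d <- dim(traj$coords)
  con <- file(file, "w")
  on.exit(close(con))
  at <- traj$atoms
  for (f in seq_len(d[1L])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f) * 10
    lines <- sprintf(
      "ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(d[2L]),
      substr(at$name, 1L, 4L), "ALA",
      ifelse(is.na(at$chain), "A", at$chain), at$resid,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], at$elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Kabsch superposition
#'
#' Least-squares optimal proper rotation and translation of a mobile
#' frame onto a reference over a selection of atoms, by singular value
#' decomposition of the cross-covariance with determinant correction
#' (so reflections are never used).
#'
#' @param mobile,reference atoms x 3 coordinate matrices (nm).
#' @param selection atom indices used for the fit (default all).
#' @return list with \code{coords} (the whole mobile frame after
#'   fitting), \code{rmsd} (over the selection, nm), \code{rotation}
#'   (3 x 3), \code{translation}.
#' @export
kabsch_fit <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, all(dim(mobile) == dim(reference)))
  sel <- selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3L) stop("Kabsch fit needs at least 3 selected atoms")
  A <- mobile[sel, , drop = FALSE]
  B <- reference[sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-30))
    stop("degenerate (collinear) selection: rotation is not unique")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- sweep(sweep(mobile, 2L, ca) %*% R, 2L, cb, "+")
  rmsd <- sqrt(mean(rowSums((fitted[sel, , drop = FALSE] - B)^2)))
  list(coords = fitted, rmsd = rmsd, rotation = R,
       translation = cb - ca %*% R)
}

#' Per-frame RMSD series
#'
#' Each frame is superposed onto the reference (Kabsch, over the
#' selection) before the deviation is measured.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param reference frame index or atoms x 3 matrix (default frame 1).
#' @param selection atom indices (default all).
#' @return numeric vector of per-frame RMSD (nm).
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL) {
  ref <- if (is.matrix(reference)) reference else
    frame_coords(traj, reference)
  vapply(seq_len(dim(traj$coords)[1L]), function(f)
    kabsch_fit(frame_coords(traj, f), ref, selection)$rmsd, 0)
}

# Superpose all frames onto a reference; returns array of fitted frames.
fit_frames <- function(traj, reference, selection = NULL) {
  d <- dim(traj$coords)
  out <- array(NA_real_, d)
  for (f in seq_len(d[1L]))
    out[f, , ] <- kabsch_fit(frame_coords(traj, f), reference,
                             selection)$coords
  out
}

mean_structure <- function(coords_array) {
  apply(coords_array, c(2L, 3L), mean)
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed on the mean structure (computed after an
#' initial fit to frame 1, then refined once), and
#' \eqn{RMSF_i = \sqrt{\langle |r_i(t) - \langle r_i \rangle|^2 \rangle}}.
#'
#' @param traj a \code{\link{trajectory}} with >= 2 frames.
#' @param selection atom indices used for fitting and reporting
#'   (default all).
#' @return numeric vector of per-atom RMSF (nm) over the selection.
#' @export
rmsf <- function(traj, selection = NULL) {
  d <- dim(traj$coords)
  stopifnot(d[1L] >= 2L)
  sel <- selection %||% seq_len(d[2L])
  fitted <- fit_frames(traj, frame_coords(traj, 1L), sel)
  m <- mean_structure(fitted)
  fitted <- fit_frames(trajectory(fitted, traj$atoms, traj$times), m, sel)
  m <- mean_structure(fitted)
  dev2 <- vapply(seq_along(sel), function(k) {
    i <- sel[k]
    mean((fitted[, i, 1L] - m[i, 1L])^2 + (fitted[, i, 2L] - m[i, 2L])^2 +
           (fitted[, i, 3L] - m[i, 3L])^2)
  }, 0)
  sqrt(dev2)
}

#' Radius of gyration of a frame
#'
#' \eqn{R_g = \sqrt{\sum m_i |r_i - r_{com}|^2 / \sum m_i}}.
#'
#' @param frame atoms x 3 coordinate matrix (nm).
#' @param masses atomic masses (amu); default unit masses.
#' @return radius of gyration (nm).
#' @export
radius_of_gyration <- function(frame, masses = NULL) {
  frame <- as.matrix(frame)
  stopifnot(nrow(frame) >= 1L)
  m <- masses %||% rep(1, nrow(frame))
  com <- colSums(frame * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(frame, 2L, com)^2)) / sum(m))
}

#' Per-frame radius-of-gyration series
#' @param traj a \code{\link{trajectory}}.
#' @return numeric vector (nm) using the trajectory's atomic masses.
#' @export
rg_series <- function(traj) {
  vapply(seq_len(dim(traj$coords)[1L]), function(f)
    radius_of_gyration(frame_coords(traj, f), traj$atoms$mass), 0)
}

# Deterministic near-uniform points on the unit sphere (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples \code{n_points} quadrature points on each atom's solvent
#' sphere (van der Waals radius + probe) and removes points buried in
#' any neighbouring atom's solvent sphere; the accessible area is the
#' surviving fraction times the sphere area. Deterministic: the point
#' set is a Fibonacci spiral, not random.
#'
#' @param frame atoms x 3 coordinate matrix (nm).
#' @param radii per-atom van der Waals radii (nm).
#' @param probe probe radius (nm); default 0.14 (water).
#' @param n_points quadrature points per atom; default 960.
#' @return list with \code{per_atom} (nm^2) and \code{total} (nm^2).
#' @export
sasa <- function(frame, radii, probe = 0.14, n_points = 960L) {
  frame <- as.matrix(frame)
  n <- nrow(frame)
  stopifnot(length(radii) == n)
  sph <- fibonacci_sphere(n_points)
  rs <- radii + probe
  dmat <- as.matrix(stats::dist(frame))
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sph * rs[i], 2L, frame[i, ], "+")
    nbr <- which(dmat[i, ] < rs[i] + rs & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      d2 <- (pts[, 1L] - frame[j, 1L])^2 + (pts[, 2L] - frame[j, 2L])^2 +
        (pts[, 3L] - frame[j, 3L])^2
      acc <- acc & d2 > rs[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * rs[i]^2 * mean(acc)
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

#' Count hydrogen bonds in a frame (geometric criterion)
#'
#' A bond is counted for a donor-acceptor pair when the donor-acceptor
#' distance is at most \code{r_cut} and the hydrogen-donor-acceptor
#' angle is at most \code{angle_cut} (the GROMACS default geometry).
#'
#' @param frame atoms x 3 coordinate matrix (nm).
#' @param donors indices of donor heavy atoms D.
#' @param hydrogens indices of the hydrogen bound to each donor
#'   (parallel to \code{donors}).
#' @param acceptors indices of acceptor atoms A.
#' @param r_cut donor-acceptor distance cutoff (nm), default 0.35.
#' @param angle_cut H-D-A angle cutoff (degrees), default 30.
#' @return integer count of hydrogen bonds.
#' @export
count_hbonds <- function(frame, donors, hydrogens, acceptors,
                         r_cut = 0.35, angle_cut = 30) {
  frame <- as.matrix(frame)
  stopifnot(length(donors) == length(hydrogens))
  n_bonds <- 0L
  for (k in seq_along(donors)) {
    D <- frame[donors[k], ]; H <- frame[hydrogens[k], ]
    for (a in acceptors) {
      if (a == donors[k] || a == hydrogens[k]) next
      A <- frame[a, ]
      if (sqrt(sum((A - D)^2)) > r_cut) next
      v1 <- H - D; v2 <- A - D
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang <= angle_cut) n_bonds <- n_bonds + 1L
    }
  }
  n_bonds
}

window_frames <- function(traj, window) {
  n <- dim(traj$coords)[1L]
  if (is.null(window)) return(seq_len(n))
  if (window > n) stop("window of ", window, " frames exceeds trajectory ",
                       "length ", n)
  seq.int(n - window + 1L, n)
}

#' Essential dynamics (PCA of coordinate covariance)
#'
#' Superposes the window frames onto their mean structure (one
#' refinement pass), builds the 3s x 3s covariance matrix of the
#' selected coordinates and eigendecomposes it. Eigenvalue fractions
#' sum to one; projections of the frames on the leading components are
#' returned.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param selection atom indices (default all).
#' @param window number of trailing frames to analyse (default all).
#' @param n_proj number of components to project frames on (default 2).
#' @return object of class \code{traj_pca}: list with
#'   \code{eigenvalues} (descending, nm^2), \code{eigenvectors}
#'   (orthonormal columns), \code{fractions}, \code{projections}
#'   (frames x n_proj), \code{trace}.
#' @export
traj_pca <- function(traj, selection = NULL, window = NULL, n_proj = 2L) {
  sel <- selection %||% seq_len(dim(traj$coords)[2L])
  fr <- window_frames(traj, window)
  if (length(fr) < 2L) stop("PCA needs a window of at least 2 frames")
  sub <- trajectory(traj$coords[fr, , , drop = FALSE], traj$atoms)
  fitted <- fit_frames(sub, frame_coords(sub, 1L), sel)
  m <- mean_structure(fitted)
  fitted <- fit_frames(trajectory(fitted, traj$atoms), m, sel)
  m <- mean_structure(fitted)
  X <- t(vapply(seq_along(fr), function(f)
    as.numeric(t(matrix(fitted[f, sel, ], ncol = 3L))), # x1 y1 z1 x2 ...
    numeric(3L * length(sel))))
  Xc <- sweep(X, 2L, colMeans(X))
  C <- crossprod(Xc) / (nrow(X) - 1L)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  n_proj <- min(n_proj, ncol(eg$vectors))
  structure(list(eigenvalues = ev, eigenvectors = eg$vectors,
                 fractions = if (sum(ev) > 0) ev / sum(ev) else ev,
                 projections = Xc %*% eg$vectors[, seq_len(n_proj),
                                                 drop = FALSE],
                 trace = sum(diag(C))),
            class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  k <- min(5L, length(x$fractions))
  cat("Essential dynamics:", length(x$eigenvalues), "modes\n")
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", x$fractions[seq_len(k)]), collapse = " "), "\n")
  invisible(x)
}

#' Dynamic cross-correlation matrix
#'
#' After superposing the window frames on their mean structure,
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}}}
#' with displacements about the window mean. Entries for atoms with zero
#' fluctuation are set to 0 and flagged in the \code{"undefined"}
#' attribute.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param selection atom indices (default all).
#' @param window number of trailing frames (default all).
#' @return symmetric matrix in \eqn{[-1, 1]} with unit diagonal for
#'   fluctuating atoms.
#' @export
dccm <- function(traj, selection = NULL, window = NULL) {
  sel <- selection %||% seq_len(dim(traj$coords)[2L])
  fr <- window_frames(traj, window)
  if (length(fr) < 2L) stop("DCCM needs a window of at least 2 frames")
  sub <- trajectory(traj$coords[fr, , , drop = FALSE], traj$atoms)
  fitted <- fit_frames(sub, frame_coords(sub, 1L), sel)
  m <- mean_structure(fitted)
  fitted <- fit_frames(trajectory(fitted, traj$atoms), m, sel)
  m <- mean_structure(fitted)
  s <- length(sel)
  nf <- length(fr)
  dx <- fitted[, sel, 1L, drop = FALSE] - rep(m[sel, 1L], each = nf)
  dy <- fitted[, sel, 2L, drop = FALSE] - rep(m[sel, 2L], each = nf)
  dz <- fitted[, sel, 3L, drop = FALSE] - rep(m[sel, 3L], each = nf)
  dx <- matrix(dx, nf, s); dy <- matrix(dy, nf, s); dz <- matrix(dz, nf, s)
  cross <- (crossprod(dx) + crossprod(dy) + crossprod(dz)) / nf
  amp <- diag(cross)
  denom <- sqrt(outer(amp, amp))
  C <- ifelse(denom > 0, cross / denom, 0)
  dg <- diag(C); dg[amp > 0] <- 1; diag(C) <- dg
  undef <- which(amp == 0)
  attr(C, "undefined") <- undef
  C
}

#' Combine MM/GBSA energy components
#'
#' Completes the bookkeeping of an end-point binding free-energy
#' decomposition: \eqn{\Delta G_{gas} = \Delta E_{vdW} + \Delta E_{elec}}
#' (bonded terms vanish in single-trajectory analyses),
#' \eqn{\Delta G_{sol} = \Delta G_{GB} + \Delta G_{SA}}, and
#' \eqn{\Delta G_{bind} = \Delta G_{gas} + \Delta G_{sol} - (-T\Delta S)}
#' with the entropy term taken as zero by default (its effect is
#' negligible when comparing ligands against one receptor). Derived
#' values are reported to 2 decimals.
#'
#' @param components data.frame with columns \code{dE_vdw},
#'   \code{dE_elec}, \code{dG_GB}, \code{dG_SA} (kcal/mol), optionally
#'   \code{id} and \code{TdS}.
#' @return the input with derived columns \code{dG_gas}, \code{dG_sol},
#'   \code{dG_bind} appended.
#' @export
combine_mmgbsa <- function(components) {
  comp <- as.data.frame(components)
  need <- c("dE_vdw", "dE_elec", "dG_GB", "dG_SA")
  miss <- setdiff(need, names(comp))
  if (length(miss) > 0L)
    stop("missing component column(s): ", paste(miss, collapse = ", "))
  vals <- as.matrix(comp[, need])
  if (any(!is.finite(vals))) stop("energy components must be finite")
  tds <- if ("TdS" %in% names(comp)) comp$TdS else 0
  comp$dG_gas <- round(comp$dE_vdw + comp$dE_elec, 2L)
  comp$dG_sol <- round(comp$dG_GB + comp$dG_SA, 2L)
  comp$dG_bind <- round(comp$dE_vdw + comp$dE_elec + comp$dG_GB +
                          comp$dG_SA - (-tds), 2L)
  comp
}
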