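#' @importFrom stats approx rnorm runif sd var setNames quantile
#' @importFrom utils combn head tail
NULL

# ---- containers -----------------------------------------------------------

#' Create a structure object
#'
#' A `cv_structure` holds one conformation: atom names, residue ids and an
#' n x 3 coordinate matrix in nanometres.
#'
#' @param atom_names character vector of atom names (e.g. `"CA"`).
#' @param residue_ids integer vector of residue ids, one per atom.
#' @param xyz numeric n x 3 matrix of coordinates in nm.
#' @return An object of class `cv_structure`.
#' @export
cv_structure <- function(atom_names, residue_ids, xyz) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L)
    stop("xyz must be a numeric n x 3 matrix")
  n <- nrow(xyz)
  if (length(atom_names) != n || length(residue_ids) != n)
    stop("atom_names, residue_ids and xyz must describe the same atom count")
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite")
  dimnames(xyz) <- NULL
  structure(list(atom_names = as.character(atom_names),
                 residue_ids = as.integer(residue_ids),
                 xyz = xyz),
            class = "cv_structure")
}

#' @export
print.cv_structure <- function(x, ...) {
  cat("<cv_structure> ", nrow(x$xyz), " atoms, ",
      length(unique(x$residue_ids)), " residues (coordinates in nm)\n", sep = "")
  invisible(x)
}

n_atoms <- function(s) nrow(s$xyz)

#' Create a trajectory object
#'
#' A `cv_trajectory` couples a topology (atom labels from a
#' [cv_structure()]) with an ordered set of coordinate frames.
#'
#' @param topology a `cv_structure` supplying atom names and residue ids.
#' @param frames list of n x 3 coordinate matrices (nm), or a 3-d array
#'   with dimensions frame x atom x 3.
#' @param times optional numeric vector of time stamps in ps, strictly
#'   increasing.
#' @return An object of class `cv_trajectory`.
#' @export
cv_trajectory <- function(topology, frames, times = NULL) {
  if (!inherits(topology, "cv_structure")) stop("topology must be a cv_structure")
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
  n <- n_atoms(topology)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n && ncol(f) == 3L,
               logical(1))
  if (!all(ok)) stop("every frame must be an n x 3 matrix matching the topology")
  if (!is.null(times)) {
    if (length(times) != length(frames)) stop("times length must equal frame count")
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames, times = times),
            class = "cv_trajectory")
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat("<cv_trajectory> ", length(x$frames), " frames x ",
      n_atoms(x$topology), " atoms\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

# ---- reading --------------------------------------------------------------

parse_error <- function(path, line, msg) {
  stop(sprintf("parse error in '%s' at line %d: %s", path, line, msg),
       call. = FALSE)
}

#' Read a structure from a PDB or GRO file
#'
#' Coordinates are converted to nm at the boundary (PDB files are in
#' Angstrom, GRO files already in nm).  For a multi-MODEL PDB the first
#' model is returned; use [read_trajectory()] for all models.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return A [cv_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (format == "gro") return(read_gro(path))
  if (file.size(path) == 0L) parse_error(path, 1L, "empty file")
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) parse_error(path, 1L, conditionMessage(e)))
  if (nrow(pdb$atom) == 0L) parse_error(path, 1L, "no ATOM/HETATM records")
  cv_structure(atom_names = pdb$atom$elety,
               residue_ids = pdb$atom$resno,
               xyz = cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z) / 10)
}

read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) parse_error(path, max(1L, length(lines)), "truncated GRO file")
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || n < 1L) parse_error(path, 2L, "invalid atom count")
  if (length(lines) < 2L + n) parse_error(path, length(lines), "fewer atom lines than declared")
  at <- lines[3:(2 + n)]
  resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
  aname <- trimws(substr(at, 11, 15))
  x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) parse_error(path, 2L + bad[1L], "malformed GRO atom record")
  cv_structure(aname, resid, cbind(x, y, z))
}

#' Read a multi-frame trajectory from a multi-MODEL PDB
#'
#' @param path file path to a PDB with one or more MODEL records.
#' @return A [cv_trajectory()]; frame count equals the MODEL count (one
#'   frame for a model-less PDB).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (file.size(path) == 0L) parse_error(path, 1L, "empty file")
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) parse_error(path, 1L, conditionMessage(e)))
  xyz <- pdb$xyz  # models x 3n, Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  topo <- cv_structure(pdb$atom$elety, pdb$atom$resno,
                       matrix(xyz[1L, ], ncol = 3L, byrow = TRUE) / 10)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE) / 10)
  cv_trajectory(topo, frames)
}

# ---- writing --------------------------------------------------------------

#' Write a structure or trajectory as a (multi-MODEL) PDB file
#'
#' Coordinates are written in Angstrom.
#'
#' @param x a [cv_structure()] or [cv_trajectory()].
#' @param path output file.
#' @param occupancy,bfactor optional per-atom columns (default 1 and 0).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, occupancy = NULL, bfactor = NULL) {
  if (inherits(x, "cv_structure")) {
    topo <- x
    xyz <- matrix(as.vector(t(x$xyz)) * 10, nrow = 1L)
  } else if (inherits(x, "cv_trajectory")) {
    topo <- x$topology
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f)) * 10))
  } else stop("x must be a cv_structure or cv_trajectory")
  n <- n_atoms(topo)
  if (is.null(occupancy)) occupancy <- rep(1, n)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  bio3d::write.pdb(file = path, xyz = xyz, resno = topo$residue_ids,
                   resid = rep("ALA", n), elety = topo$atom_names,
                   o = occupancy, b = bfactor)
  invisible(path)
}

# ---- selection ------------------------------------------------------------

#' Select C-alpha atoms
#'
#' Returns the (1-based) indices of CA atoms, optionally restricted to
#' inclusive residue-id intervals.  This is the generic alignment/measure
#' selection used for both path flavours; no secondary-structure detection
#' is attempted -- supply `residue_ranges` to restrict to structured
#' segments.
#'
#' @param structure a [cv_structure()].
#' @param residue_ranges optional list of length-2 vectors
#'   `c(first_resid, last_resid)` (inclusive).
#' @return Integer vector of atom indices, in file order.
#' @export
select_calpha <- function(structure, residue_ranges = NULL) {
  ca <- which(structure$atom_names == "CA")
  if (length(ca) == 0L) stop("selection is empty: structure has no CA atoms")
  if (!is.null(residue_ranges)) {
    rids <- range(structure$residue_ids)
    keep <- rep(FALSE, length(ca))
    for (rg in residue_ranges) {
      if (length(rg) != 2L || rg[1] > rg[2])
        stop("each residue range must be c(lo, hi) with lo <= hi")
      if (rg[1] > rids[2] || rg[2] < rids[1])
        stop(sprintf("residue range [%d, %d] lies outside residues [%d, %d]",
                     rg[1], rg[2], rids[1], rids[2]))
      keep <- keep | (structure$residue_ids[ca] >= rg[1] &
                      structure$residue_ids[ca] <= rg[2])
    }
    ca <- ca[keep]
    if (length(ca) == 0L) stop("selection is empty after residue restriction")
  }
  ca
}

# ---- superposition RMSD ---------------------------------------------------

coords_of <- function(x) {
  if (inherits(x, "cv_structure")) x$xyz
  else if (is.matrix(x) && ncol(x) == 3L) x
  else stop("expected a cv_structure or an n x 3 coordinate matrix")
}

check_selection <- function(sel, n, what = "selection") {
  sel <- as.integer(sel)
  if (length(sel) == 0L) stop(sprintf("%s must be non-empty", what))
  if (anyDuplicated(sel)) stop(sprintf("%s has duplicate indices", what))
  if (any(sel < 1L | sel > n))
    stop(sprintf("%s indices out of bounds (1..%d)", what, n))
  sel
}

#' Optimal-superposition RMSD
#'
#' Least-squares rigid-body superposition (rotation plus translation, no
#' reflection; Kabsch) of `mobile` onto `reference` fitted on the `align`
#' atoms, followed by the RMSD over the `measure` atoms.  The result is
#' invariant under rigid motions of either argument.
#'
#' @param mobile,reference [cv_structure()] objects or n x 3 coordinate
#'   matrices (nm).
#' @param align atom indices used for the fit (default: all atoms);
#'   at least 3 non-collinear atoms.
#' @param measure atom indices the RMSD is computed over (default:
#'   `align`).
#' @param fit if `FALSE`, skip the superposition and return the plain RMSD.
#' @return RMSD in nm.
#' @export
rmsd_superposed <- function(mobile, reference, align = NULL, measure = NULL,
                            fit = TRUE) {
  xm <- coords_of(mobile); xr <- coords_of(reference)
  n <- nrow(xm)
  if (nrow(xr) != n) stop("mobile and reference must have the same atom count")
  if (is.null(align)) align <- seq_len(n)
  align <- check_selection(align, n, "align")
  measure <- if (is.null(measure)) align else check_selection(measure, n, "measure")
  if (fit) {
    if (length(align) < 3L) stop("geometry error: need at least 3 align atoms")
    ca <- scale(xr[align, , drop = FALSE], scale = FALSE)
    sv <- svd(ca)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-300))
      stop("geometry error: align atoms are collinear")
    xm <- superpose_onto(xm, xr, align)
  }
  d <- xm[measure, , drop = FALSE] - xr[measure, , drop = FALSE]
  sqrt(sum(d * d) / length(measure))
}

# Fit `mobile` onto `reference` using the align atoms; returns all mobile
# coordinates transformed.  Proper rotation only (determinant correction).
superpose_onto <- function(mobile, reference, align) {
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(reference)),
                           mobile = matrix(as.vector(t(mobile)), nrow = 1L),
                           fixed.inds = bio3d::atom2xyz(align),
                           mobile.inds = bio3d::atom2xyz(align))
  matrix(fitted[1L, ], ncol = 3L, byrow = TRUE)
}

#' RMSD between the two end-state structures
#'
#' Convenience wrapper around [rmsd_superposed()] giving the end-to-end
#' distance `D` that anchors the terminal milestones of an arched path.
#'
#' @inheritParams rmsd_superposed
#' @param inactive,active the two end-state structures.
#' @return RMSD in nm.
#' @export
endpoint_distance <- function(inactive, active, align = NULL, measure = NULL) {
  rmsd_superposed(active, inactive, align = align, measure = measure)
}

# ---- milestone extraction -------------------------------------------------

#' Extract milestone frames at regular RMSD intervals
#'
#' Chooses `n` frames of a transition trajectory, keeping the first and
#' last frame fixed and picking interiors so that consecutive-milestone
#' RMSDs are as uniform as possible (the variance of consecutive RMSD
#' gaps is minimised over monotone frame subsequences).  Exhaustive
#' search is used for up to `exhaustive_max` frames; beyond that, frames
#' are picked at equal quantiles of the cumulative RMSD arc length.
#'
#' @param traj a [cv_trajectory()].
#' @param n number of milestones (>= 2).
#' @param align,measure atom selections passed to [rmsd_superposed()].
#' @param exhaustive_max largest frame count for exhaustive search.
#' @return List of [cv_structure()] milestones with attribute
#'   `"frame_indices"` (1-based).
#' @export
extract_milestones <- function(traj, n, align = NULL, measure = NULL,
                               exhaustive_max = 20L) {
  nf <- n_frames(traj)
  if (n < 2L) stop("n must be >= 2")
  if (n > nf) stop(sprintf("n (%d) exceeds frame count (%d)", n, nf))
  if (nf <= exhaustive_max) {
    rm_pair <- function(i, j) rmsd_superposed(traj$frames[[i]], traj$frames[[j]],
                                              align = align, measure = measure)
    D <- matrix(0, nf, nf)
    for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf)
      D[i, j] <- D[j, i] <- rm_pair(i, j)
    idx <- best_subsequence(D, nf, n)
  } else {
    steps <- vapply(seq_len(nf - 1L), function(i)
      rmsd_superposed(traj$frames[[i]], traj$frames[[i + 1L]],
                      align = align, measure = measure), numeric(1))
    arc <- c(0, cumsum(steps))
    targets <- seq(0, arc[nf], length.out = n)
    idx <- vapply(targets, function(t) which.min(abs(arc - t)), integer(1))
    idx <- unique(pmin(pmax(idx, 1L), nf))
    # guarantee n distinct monotone indices incl. end points
    while (length(idx) < n) {
      gaps <- which(diff(idx) > 1L)
      if (!length(gaps)) break
      g <- gaps[which.max(diff(idx)[gaps])]
      idx <- sort(c(idx, idx[g] + (idx[g + 1L] - idx[g]) %/% 2L))
    }
    idx[1L] <- 1L; idx[length(idx)] <- nf
  }
  out <- lapply(idx, function(i)
    cv_structure(traj$topology$atom_names, traj$topology$residue_ids,
                 traj$frames[[i]]))
  attr(out, "frame_indices") <- idx
  out
}

# exhaustive minimisation of var(consecutive RMSD gaps) over monotone
# subsequences with fixed end points
best_subsequence <- function(D, nf, n) {
  if (n == 2L) return(c(1L, nf))
  interiors <- combn(2:(nf - 1L), n - 2L)
  best <- NULL; best_v <- Inf
  for (k in seq_len(ncol(interiors))) {
    idx <- c(1L, interiors[, k], nf)
    gaps <- D[cbind(idx[-length(idx)], idx[-1L])]
    v <- var(gaps)
    if (v < best_v - 1e-15) { best_v <- v; best <- idx }
  }
  best
}
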