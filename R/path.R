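# Path collective variables: progress s and deviation z along a sequence
# of milestones, in the classic structure-based (RPATH) and Euclidean
# RMSD-plane (EPATH) formulations.

# ---- path definitions -----------------------------------------------------

#' Define a Euclidean (EPATH) path
#'
#' Milestones are points in the (RMSD_inactive, RMSD_active) plane; only
#' the two end milestones need to correspond to real structures.
#'
#' @param milestones numeric N x 2 matrix; column 1 is RMSD to the
#'   inactive reference, column 2 RMSD to the active reference (nm).
#' @param lambda smoothness parameter in nm^-2; if `NULL`, set by
#'   [suggest_lambda()].
#' @param align,measure optional atom selections recorded for projecting
#'   trajectories onto the path.
#' @return A `path_definition` with flavor `"EPATH"`.
#' @export
epath_definition <- function(milestones, lambda = NULL,
                             align = NULL, measure = NULL) {
  m <- as.matrix(milestones)
  if (ncol(m) != 2L) stop("milestones must be an N x 2 matrix")
  if (nrow(m) < 2L) stop("need at least 2 milestones")
  if (any(!is.finite(m)) || any(m < 0))
    stop("milestone RMSD components must be finite and >= 0")
  if (any(rowSums(abs(diff(m))) == 0))
    stop("consecutive milestones must be distinct")
  colnames(m) <- c("rmsd_inactive", "rmsd_active")
  p <- structure(list(flavor = "EPATH", milestones = m, lambda = NULL,
                      align = align, measure = measure),
                 class = "path_definition")
  p$lambda <- if (is.null(lambda)) suggest_lambda(p) else lambda
  if (p$lambda <= 0) stop("lambda must be > 0")
  p
}

#' Define a structure-based (RPATH) path
#'
#' @param structures list of [cv_structure()] milestones, ordered from
#'   the inactive to the active end state.
#' @param lambda smoothness parameter in nm^-1 (nm^-2 when
#'   `squared = TRUE`); if `NULL`, set by [suggest_lambda()].
#' @param align,measure atom selections used for every milestone RMSD.
#' @param squared if `TRUE` the exponent uses the squared RMSD
#'   (mean-square-deviation engine convention) rather than the linear
#'   RMSD of the classic definition.
#' @return A `path_definition` with flavor `"RPATH"`.
#' @export
rpath_definition <- function(structures, lambda = NULL,
                             align = NULL, measure = NULL, squared = FALSE) {
  if (length(structures) < 2L) stop("need at least 2 milestones")
  if (!all(vapply(structures, inherits, logical(1), "cv_structure")))
    stop("RPATH milestones must be cv_structure objects")
  na <- vapply(structures, n_atoms, integer(1))
  if (length(unique(na)) != 1L) stop("milestones must share one topology")
  p <- structure(list(flavor = "RPATH", milestones = structures,
                      lambda = NULL, align = align, measure = measure,
                      squared = isTRUE(squared)),
                 class = "path_definition")
  p$lambda <- if (is.null(lambda)) suggest_lambda(p) else lambda
  if (p$lambda <= 0) stop("lambda must be > 0")
  p
}

#' @export
print.path_definition <- function(x, ...) {
  n <- if (x$flavor == "EPATH") nrow(x$milestones) else length(x$milestones)
  unit <- if (x$flavor == "EPATH" || isTRUE(x$squared)) "nm^-2" else "nm^-1"
  cat(sprintf("<path_definition> %s, %d milestones, lambda = %.6g %s\n",
              x$flavor, n, x$lambda, unit))
  if (x$flavor == "EPATH") {
    m <- x$milestones
    cat(sprintf("  M1 = (%.4g, %.4g) ... M%d = (%.4g, %.4g) nm\n",
                m[1, 1], m[1, 2], n, m[n, 1], m[n, 2]))
  }
  invisible(x)
}

path_length <- function(path) {
  if (path$flavor == "EPATH") nrow(path$milestones) else length(path$milestones)
}

# ---- distances and s/z ----------------------------------------------------

#' Euclidean distance between milestones in the RMSD plane
#'
#' @param m,mi length-2 vectors `(rmsd_inactive, rmsd_active)` in nm.
#' @return Distance in nm.
#' @export
epath_distance <- function(m, mi) {
  m <- as.numeric(m); mi <- as.numeric(mi)
  if (length(m) != 2L || length(mi) != 2L)
    stop("points must have 2 components (rmsd_inactive, rmsd_active)")
  if (any(!is.finite(c(m, mi)))) stop("components must be finite")
  if (any(c(m, mi) < 0)) stop("RMSD components must be >= 0")
  sqrt(sum((m - mi)^2))
}

# softmax-style weighted index and deviation from exponent vector e = -lambda*d
# (max-shifted so large lambda cannot underflow all weights)
sz_from_exponents <- function(e, lambda) {
  idx <- seq_along(e)
  mx <- max(e)
  w <- exp(e - mx)
  sw <- sum(w)
  list(s = sum(idx * w) / sw, z = -(mx + log(sw)) / lambda)
}

#' EPATH progress and deviation for a point in the RMSD plane
#'
#' `s` is the exponentially weighted mean milestone index with weights
#' `exp(-lambda d^2)`; `z = -(1/lambda) log(sum exp(-lambda d^2))`.
#'
#' @param point length-2 vector or n x 2 matrix of
#'   `(rmsd_inactive, rmsd_active)` values in nm.
#' @param path an EPATH `path_definition`.
#' @return List with numeric `s` and `z` (vectors if `point` is a matrix).
#' @export
epath_sz <- function(point, path) {
  stopifnot(inherits(path, "path_definition"))
  if (path$flavor != "EPATH") stop("path flavor must be EPATH")
  pts <- if (is.matrix(point)) point else matrix(as.numeric(point), nrow = 1L)
  if (ncol(pts) != 2L) stop("point must have 2 components")
  if (any(!is.finite(pts))) stop("point components must be finite")
  m <- path$milestones
  s <- z <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    d2 <- (pts[k, 1] - m[, 1])^2 + (pts[k, 2] - m[, 2])^2
    r <- sz_from_exponents(-path$lambda * d2, path$lambda)
    s[k] <- r$s; z[k] <- r$z
  }
  list(s = s, z = z)
}

#' RPATH progress and deviation for a coordinate frame
#'
#' Computes the superposed RMSD `R[X - X_i]` to every structural
#' milestone and evaluates `s = sum(i exp(-lambda R_i)) / sum(exp(-lambda
#' R_i))`, `z = -(1/lambda) log(sum exp(-lambda R_i))` (exponent in
#' `R_i^2` when the path was built with `squared = TRUE`).
#'
#' @param frame a [cv_structure()] or n x 3 coordinate matrix.
#' @param path an RPATH `path_definition`.
#' @return List with scalars `s` and `z`, plus the milestone RMSD vector
#'   `rmsd`.
#' @export
rpath_sz <- function(frame, path) {
  stopifnot(inherits(path, "path_definition"))
  if (path$flavor != "RPATH") stop("path flavor must be RPATH")
  x <- coords_of(frame)
  if (nrow(x) != n_atoms(path$milestones[[1L]]))
    stop("frame atom count does not match path milestones")
  r <- vapply(path$milestones, function(ms)
    rmsd_superposed(x, ms, align = path$align, measure = path$measure),
    numeric(1))
  d <- if (isTRUE(path$squared)) r^2 else r
  out <- sz_from_exponents(-path$lambda * d, path$lambda)
  out$rmsd <- r
  out
}

# ---- arched path construction ---------------------------------------------

# quadratic Bezier with control point on the diagonal
bezier_point <- function(t, D, ctrl) {
  b <- cbind((1 - t)^2 * 0 + 2 * t * (1 - t) * ctrl + t^2 * D,
             (1 - t)^2 * D + 2 * t * (1 - t) * ctrl + t^2 * 0)
  colnames(b) <- c("rmsd_inactive", "rmsd_active")
  b
}

#' Build an arched EPATH in the RMSD plane
#'
#' Connects the end milestones `M1 = (0, D)` and `MN = (D, 0)` by a
#' quadratic Bezier bowing away from the origin, with milestones placed
#' at equal arc-length intervals.  `arch` is the fractional height of the
#' curve apex above the diagonal: the middle of the curve sits at
#' `((1+arch) D/2, (1+arch) D/2)`, so `arch = 0` degenerates to the
#' straight chord.
#'
#' @param end_distance the end-state RMSD `D` in nm (> 0), e.g. from
#'   [endpoint_distance()].
#' @param n_milestones number of milestones N (>= 2; default 8).
#' @param arch dimensionless arch height (>= 0; default 0.3).
#' @param lambda optional smoothness; default from [suggest_lambda()].
#' @param align,measure selections recorded for trajectory projection.
#' @param grid_points resolution of the numeric arc-length
#'   parameterization.
#' @return An EPATH `path_definition`.
#' @export
build_arched_path <- function(end_distance, n_milestones = 8L, arch = 0.3,
                              lambda = NULL, align = NULL, measure = NULL,
                              grid_points = 20001L) {
  if (end_distance <= 0) stop("end_distance must be > 0")
  if (n_milestones < 2L) stop("n_milestones must be >= 2")
  if (arch < 0) stop("arch must be >= 0")
  D <- end_distance
  ctrl <- (1 + 2 * arch) * D / 2  # apex of the curve lands at (1+arch)*D/2
  tt <- seq(0, 1, length.out = grid_points)
  pts <- bezier_point(tt, D, ctrl)
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  targets <- seq(0, arc[length(arc)], length.out = n_milestones)
  t_at <- approx(arc, tt, xout = targets, ties = "ordered")$y
  t_at[1L] <- 0; t_at[n_milestones] <- 1
  milestones <- bezier_point(t_at, D, ctrl)
  milestones[1L, ] <- c(0, D)
  milestones[n_milestones, ] <- c(D, 0)
  epath_definition(milestones, lambda = lambda, align = align,
                   measure = measure)
}

# ---- lambda ---------------------------------------------------------------

#' Suggest a smoothness parameter lambda
#'
#' Sets lambda so that the exponential weight of a neighbouring
#' milestone is about one half: `lambda = log(2) / mean(consecutive
#' RMSD)` for RPATH (squared RMSD when the path uses squared exponents)
#' and `lambda = log(2) / mean(consecutive d^2)` for EPATH.  This lands
#' between the rigid large-lambda regime (s snaps to one milestone) and
#' the washed-out small-lambda regime.
#'
#' @param path a `path_definition`.
#' @return lambda (nm^-2 for EPATH, nm^-1 for linear-exponent RPATH).
#' @export
suggest_lambda <- function(path) {
  stopifnot(inherits(path, "path_definition"))
  if (path$flavor == "EPATH") {
    m <- path$milestones
    gaps <- rowSums(diff(m)^2)
  } else {
    n <- length(path$milestones)
    gaps <- vapply(seq_len(n - 1L), function(i)
      rmsd_superposed(path$milestones[[i + 1L]], path$milestones[[i]],
                      align = path$align, measure = path$measure), numeric(1))
    if (isTRUE(path$squared)) gaps <- gaps^2
  }
  if (any(gaps <= 0)) stop("coincident consecutive milestones")
  log(2) / mean(gaps)
}

# ---- restraints -----------------------------------------------------------

#' Windowed harmonic restraint specification
#'
#' A parabolic restraint on an auxiliary CV (e.g. a microswitch
#' distance) that acts only while the path progress `s` is inside the
#' window `[s_lo, s_hi]` -- so end-point states are never restrained and
#' their relative stability is unaffected.  The window is entered and
#' left through a smooth half-cosine taper of width `taper`.
#'
#' @param cv name of the auxiliary CV column.
#' @param center target value `x0`.
#' @param kappa force constant (kJ/mol per CV-unit^2).
#' @param s_lo,s_hi progress window bounds, `1 <= s_lo < s_hi <= N`.
#' @param taper taper width in s units (clipped to half the window).
#' @return A restraint spec entry (list).
#' @export
restraint_harmonic <- function(cv, center, kappa, s_lo, s_hi, taper = 0.25) {
  if (s_lo >= s_hi) stop("need s_lo < s_hi")
  if (kappa < 0 || taper < 0) stop("kappa and taper must be >= 0")
  list(type = "harmonic", cv = cv, center = center, kappa = kappa,
       s_lo = s_lo, s_hi = s_hi, taper = taper)
}

#' One-sided wall on the path deviation z
#'
#' Loose upper wall `kappa * max(0, z - z_max)^2` keeping sampled
#' configurations near the path.
#'
#' @param z_max wall position.
#' @param kappa force constant (kJ/mol per z-unit^2).
#' @param cv restrained column name (default `"z"`).
#' @return A restraint spec entry (list).
#' @export
restraint_wall <- function(z_max, kappa, cv = "z") {
  if (kappa < 0) stop("kappa must be >= 0")
  list(type = "upper_wall", cv = cv, at = z_max, kappa = kappa)
}

# smooth bump: 0 outside [lo, hi], 1 on [lo+taper, hi-taper], cosine ramps
window_weight <- function(s, lo, hi, taper) {
  taper <- min(taper, (hi - lo) / 2)
  w <- numeric(length(s))
  inside <- s > lo & s < hi
  w[inside] <- 1
  if (taper > 0) {
    up <- inside & s < lo + taper
    w[up] <- 0.5 * (1 - cos(pi * (s[up] - lo) / taper))
    dn <- inside & s > hi - taper
    w[dn] <- 0.5 * (1 - cos(pi * (hi - s[dn]) / taper))
  }
  w
}

#' Evaluate the total restraint energy
#'
#' Sums windowed harmonic terms `w(s) kappa (x - x0)^2` and one-sided
#' deviation walls over a restraint specification list.  Exactly zero
#' when `s` lies outside every window (end-point states are free).
#'
#' @param s path progress value.
#' @param aux named list/vector of auxiliary CV values (must contain
#'   every restrained column, including `"z"` for walls).
#' @param spec list of entries from [restraint_harmonic()] /
#'   [restraint_wall()].
#' @return Energy in kJ/mol.
#' @export
restraint_energy <- function(s, aux, spec) {
  aux <- as.list(aux)
  e <- 0
  for (r in spec) {
    if (!r$cv %in% names(aux))
      stop(sprintf("unknown CV '%s' in restraint spec", r$cv))
    x <- as.numeric(aux[[r$cv]])
    if (r$type == "harmonic") {
      e <- e + window_weight(s, r$s_lo, r$s_hi, r$taper) *
        r$kappa * (x - r$center)^2
    } else if (r$type == "upper_wall") {
      e <- e + r$kappa * pmax(0, x - r$at)^2
    } else stop(sprintf("unknown restraint type '%s'", r$type))
  }
  e
}

# ---- trajectory projection ------------------------------------------------

#' Project a trajectory onto a path
#'
#' For an EPATH path the two reference structures are required: each
#' frame's RMSD to the inactive and active reference is computed with
#' the path's align/measure selections and fed to [epath_sz()].  For an
#' RPATH path each frame is scored with [rpath_sz()] and the RMSDs to
#' the first/last milestone are reported as `rmsd_inactive` /
#' `rmsd_active`.
#'
#' @param traj a [cv_trajectory()].
#' @param path a `path_definition`.
#' @param inactive,active reference [cv_structure()]s (EPATH only).
#' @return A `cv_series` data frame with columns `time`, `s`, `z`,
#'   `rmsd_inactive`, `rmsd_active`.
#' @export
project_trajectory <- function(traj, path, inactive = NULL, active = NULL) {
  stopifnot(inherits(traj, "cv_trajectory"), inherits(path, "path_definition"))
  nf <- n_frames(traj)
  times <- if (is.null(traj$times)) seq_len(nf) - 1 else traj$times
  if (path$flavor == "EPATH") {
    if (is.null(inactive) || is.null(active))
      stop("EPATH projection needs the inactive and active reference structures")
    ri <- vapply(traj$frames, function(f)
      rmsd_superposed(f, inactive, align = path$align, measure = path$measure),
      numeric(1))
    ra <- vapply(traj$frames, function(f)
      rmsd_superposed(f, active, align = path$align, measure = path$measure),
      numeric(1))
    sz <- epath_sz(cbind(ri, ra), path)
    out <- data.frame(time = times, s = sz$s, z = sz$z,
                      rmsd_inactive = ri, rmsd_active = ra)
  } else {
    rows <- lapply(traj$frames, rpath_sz, path = path)
    out <- data.frame(time = times,
                      s = vapply(rows, `[[`, numeric(1), "s"),
                      z = vapply(rows, `[[`, numeric(1), "z"),
                      rmsd_inactive = vapply(rows, function(r) r$rmsd[1L], numeric(1)),
                      rmsd_active = vapply(rows, function(r) tail(r$rmsd, 1L), numeric(1)))
  }
  class(out) <- c("cv_series", "data.frame")
  out
}

# ---- path (de)serialization -----------------------------------------------

#' Write a path definition to a plain-text config
#'
#' EPATH milestones are stored inline; RPATH structural milestones are
#' written to a companion multi-MODEL PDB referenced from the config.
#'
#' @param path a `path_definition`.
#' @param file output config file.
#' @return `file`, invisibly.
#' @export
write_path <- function(path, file) {
  lines <- c(sprintf("flavor %s", path$flavor),
             sprintf("lambda %.12g", path$lambda),
             sprintf("n_milestones %d", path_length(path)))
  if (path$flavor == "EPATH") {
    m <- path$milestones
    lines <- c(lines, sprintf("milestone %d %.12g %.12g",
                              seq_len(nrow(m)), m[, 1], m[, 2]))
  } else {
    pdbfile <- paste0(sub("\\.[^.]*$", "", file), "_milestones.pdb")
    topo <- path$milestones[[1L]]
    traj <- cv_trajectory(topo, lapply(path$milestones, `[[`, "xyz"))
    write_pdb(traj, pdbfile)
    lines <- c(lines, sprintf("milestones_pdb %s", basename(pdbfile)),
               sprintf("squared %s", if (isTRUE(path$squared)) "yes" else "no"))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a path definition written by [write_path()]
#'
#' @param file config file path.
#' @return A `path_definition`.
#' @export
read_path <- function(file) {
  lines <- readLines(file)
  toks <- strsplit(trimws(lines[nzchar(trimws(lines))]), "\\s+")
  kv <- setNames(lapply(toks, `[`, -1L), vapply(toks, `[`, character(1), 1L))
  flavor <- kv[["flavor"]][1L]
  lambda <- as.numeric(kv[["lambda"]][1L])
  if (flavor == "EPATH") {
    ms <- do.call(rbind, lapply(kv[names(kv) == "milestone"],
                                function(v) as.numeric(v[2:3])))
    epath_definition(ms, lambda = lambda)
  } else {
    pdb <- file.path(dirname(file), kv[["milestones_pdb"]][1L])
    traj <- read_trajectory(pdb)
    structs <- lapply(traj$frames, function(f)
      cv_structure(traj$topology$atom_names, traj$topology$residue_ids, f))
    rpath_definition(structs, lambda = lambda,
                     squared = identical(kv[["squared"]][1L], "yes"))
  }
}
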