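# Synthetic fixtures: toy two-state structures, noisy transition
# trajectories and biased Metropolis Monte-Carlo samples on analytic
# double-well potentials.  Every generator is deterministic per seed and
# records its parameters so any run can be reproduced.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

helix_trace <- function(n_atoms, radius = 0.23, rise = 0.15, turn = 100) {
  i <- seq_len(n_atoms) - 1L
  th <- i * turn * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * i)
}

rotate_about_y <- function(xyz, angle_deg, pivot) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
  sweep(sweep(xyz, 2, pivot) %*% R, 2, pivot, `+`)
}

#' Generate toy inactive/active end-state structures
#'
#' A helix-like C-alpha chain (the "inactive" state) and a copy whose
#' terminal segment is bent about a hinge (the "active" state) -- a
#' minimal stand-in for a receptor's two conformational end states.
#' Optional isotropic Gaussian noise perturbs both.
#'
#' @param n_atoms chain length (>= 4; default 20).
#' @param bend_angle hinge angle in degrees applied to the terminal half
#'   (default 60; 0 gives identical end states).
#' @param noise coordinate noise s.d. in nm (default 0).
#' @param seed RNG seed (default 1).
#' @return List with [cv_structure()] elements `inactive` and `active`
#'   and an attribute `"spec"` recording the parameters.
#' @export
make_toy_endstates <- function(n_atoms = 20L, bend_angle = 60, noise = 0,
                               seed = 1L) {
  if (n_atoms < 4L) stop("n_atoms must be >= 4")
  if (noise < 0) stop("noise must be >= 0")
  base <- helix_trace(n_atoms)
  hinge <- n_atoms %/% 2L
  bent <- base
  seg <- (hinge + 1L):n_atoms
  bent[seg, ] <- rotate_about_y(base[seg, , drop = FALSE], bend_angle,
                                base[hinge, ])
  with_seed(seed, {
    xa <- base + matrix(rnorm(3 * n_atoms, sd = noise), ncol = 3)
    xb <- bent + matrix(rnorm(3 * n_atoms, sd = noise), ncol = 3)
    nm <- rep("CA", n_atoms); rid <- seq_len(n_atoms)
    out <- list(inactive = cv_structure(nm, rid, xa),
                active = cv_structure(nm, rid, xb))
    attr(out, "spec") <- list(n_atoms = n_atoms, bend_angle = bend_angle,
                              noise = noise, seed = seed)
    out
  })
}

#' Generate a noisy interpolated transition trajectory
#'
#' Frames linearly interpolate the superposed end states; an optional
#' `detour` bulge displaces mid-path frames along a fixed random
#' direction field, mimicking the entropic basin of configurations far
#' from both references.  First and last frames are the exact end
#' states.
#'
#' @param inactive,active end-state [cv_structure()]s sharing one
#'   topology.
#' @param n_frames number of frames (>= 2; default 30).
#' @param noise per-frame Gaussian coordinate noise s.d. in nm
#'   (default 0.02; never applied to the end frames).
#' @param detour bulge magnitude in nm (RMS displacement at mid-path;
#'   default 0).
#' @param noise_scaling `"constant"` applies the same noise to every
#'   interior frame; `"midpath"` scales the noise s.d. with
#'   `sin(pi t)`, producing tight end basins and a diffuse mid-path
#'   ensemble like the entropic basin seen in activation transitions.
#' @param seed RNG seed (default 1).
#' @return A [cv_trajectory()] with times 0..(n_frames-1) ps.
#' @export
make_transition_trajectory <- function(inactive, active, n_frames = 30L,
                                       noise = 0.02, detour = 0,
                                       noise_scaling = c("constant", "midpath"),
                                       seed = 1L) {
  noise_scaling <- match.arg(noise_scaling)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (!identical(inactive$atom_names, active$atom_names) ||
      !identical(inactive$residue_ids, active$residue_ids))
    stop("end states must share one topology")
  n <- n_atoms(inactive)
  B <- superpose_onto(active$xyz, inactive$xyz, seq_len(n))
  with_seed(seed, {
    G <- matrix(rnorm(3 * n), ncol = 3)
    G <- G / sqrt(mean(rowSums(G^2)))  # unit RMS displacement field
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      t <- (k - 1) / (n_frames - 1)
      x <- (1 - t) * inactive$xyz + t * B + detour * sin(pi * t) * G
      sdk <- if (noise_scaling == "midpath") noise * sin(pi * t) else noise
      if (k > 1L && k < n_frames && sdk > 0)
        x <- x + matrix(rnorm(3 * n) * sdk, ncol = 3)
      frames[[k]] <- x
    }
    frames[[1L]] <- inactive$xyz
    frames[[n_frames]] <- B
    cv_trajectory(inactive, frames, times = seq_len(n_frames) - 1)
  })
}

# ---- model potentials -----------------------------------------------------

#' Analytic double-well potential
#'
#' `U(x) = barrier * ((x/x0)^2 - 1)^2` (kcal/mol): minima at +-x0, a
#' barrier of height `barrier` at x = 0.  The 2D variant adds a harmonic
#' transverse term `0.5 * k_y * y^2`.
#'
#' @param x,y coordinates.
#' @param barrier barrier height in kcal/mol (default 5).
#' @param x0 well position (default 1).
#' @param k_y transverse force constant (2D; default 2).
#' @return Potential energy in kcal/mol.
#' @export
double_well <- function(x, y = NULL, barrier = 5, x0 = 1, k_y = 2) {
  u <- barrier * ((x / x0)^2 - 1)^2
  if (!is.null(y)) u <- u + 0.5 * k_y * y^2
  u
}

#' Metropolis Monte-Carlo samples from a biased double well
#'
#' Samples `exp(-(U + V)/kT)` with the scaling bias `V = -bias_factor *
#' U`, recording the applied bias energy so that reweighting with
#' weights `exp(V/kT)` recovers the unbiased ensemble.  The stationary
#' law is exact (Metropolis), which makes these tables a clean fixture
#' for the reweighting estimators.
#'
#' @param form `"double_well_1d"` or `"double_well_2d"`.
#' @param n_samples number of recorded samples (default 2e5).
#' @param barrier,x0,k_y potential parameters (see [double_well()]).
#' @param bias_factor bias scale f in `V = -f U` (default 0.8).
#' @param kT thermal energy in kcal/mol (default [kT_kcal()] at 310 K).
#' @param step proposal s.d. (default 0.35).
#' @param burn_in discarded initial moves (default 1000).
#' @param seed RNG seed (default 1).
#' @param bias_column name for the bias column (default `"opes.bias"`).
#' @return A `colvar_table` with columns `time`, `x` (and `y` in 2D) and
#'   the bias column; attribute `"acceptance"` records the acceptance
#'   rate and `"spec"` all parameters.
#' @export
make_biased_samples <- function(form = c("double_well_1d", "double_well_2d"),
                                n_samples = 2e5, barrier = 5, x0 = 1, k_y = 2,
                                bias_factor = 0.8, kT = kT_kcal(), step = 0.35,
                                burn_in = 1000L, seed = 1L,
                                bias_column = "opes.bias") {
  form <- match.arg(form)
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (barrier <= 0) stop("barrier must be > 0")
  two_d <- form == "double_well_2d"
  utot <- function(p) {
    u <- double_well(p[1L], if (two_d) p[2L] else NULL, barrier, x0, k_y)
    u * (1 - bias_factor)  # U + V with V = -f U
  }
  d <- if (two_d) 2L else 1L
  with_seed(seed, {
    n_tot <- n_samples + burn_in
    prop <- matrix(rnorm(n_tot * d, sd = step), ncol = d)
    us <- runif(n_tot)
    cur <- rep(-x0, d) * c(1, rep(0, d - 1L))  # start in the left well
    e_cur <- utot(cur)
    acc <- 0L
    out <- matrix(0, n_samples, d)
    for (i in seq_len(n_tot)) {
      cand <- cur + prop[i, ]
      e_cand <- utot(cand)
      if (us[i] < exp(-(e_cand - e_cur) / kT)) {
        cur <- cand; e_cur <- e_cand; acc <- acc + 1L
      }
      if (i > burn_in) out[i - burn_in, ] <- cur
    }
    if (acc == 0L)
      stop("no moves accepted; reduce the proposal step size")
    u <- double_well(out[, 1L], if (two_d) out[, 2L] else NULL, barrier, x0, k_y)
    df <- data.frame(time = seq_len(n_samples) - 1)
    df$x <- out[, 1L]
    if (two_d) df$y <- out[, 2L]
    df[[bias_column]] <- -bias_factor * u
    class(df) <- c("colvar_table", "data.frame")
    attr(df, "acceptance") <- acc / n_tot
    attr(df, "spec") <- list(form = form, n_samples = n_samples,
                             barrier = barrier, x0 = x0, k_y = k_y,
                             bias_factor = bias_factor, kT = kT, step = step,
                             burn_in = burn_in, seed = seed)
    df
  })
}

#' Quadrature reference free-energy difference on a model potential
#'
#' Boltzmann integrals of `exp(-U/kT)` over two coordinate windows,
#' computed by adaptive quadrature: the exact counterpart of the
#' reweighted population ratio estimated from samples.
#'
#' @param window_a,window_b coordinate windows `c(lo, hi)`.
#' @param barrier,x0 potential parameters.
#' @param kT thermal energy (kcal/mol).
#' @return `deltaG = -kT log(P_b / P_a)` in kcal/mol.
#' @export
double_well_deltag_quadrature <- function(window_a, window_b, barrier = 5,
                                          x0 = 1, kT = kT_kcal()) {
  boltz <- function(x) exp(-double_well(x, barrier = barrier, x0 = x0) / kT)
  pa <- stats::integrate(boltz, window_a[1], window_a[2], rel.tol = 1e-10)$value
  pb <- stats::integrate(boltz, window_b[1], window_b[2], rel.tol = 1e-10)$value
  -kT * log(pb / pa)
}
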