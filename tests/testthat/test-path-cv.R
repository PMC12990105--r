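test_that("Euclidean milestone distance matches direct arithmetic", {
  expect_equal(epath_distance(c(0.3, 0.4), c(0.3, 0.4)), 0)
  expect_equal(epath_distance(c(0, 0), c(0.3, 0.4)), 0.5)
  set.seed(21)
  for (i in 1:20) {
    a <- runif(2); b <- runif(2)
    expect_equal(epath_distance(a, b), sqrt(sum((a - b)^2)))
  }
  expect_error(epath_distance(c(-0.1, 0), c(0, 0)), ">= 0")
})

test_that("EPATH s and z reproduce hand-evaluated values", {
  p <- epath_definition(rbind(c(0, 1), c(1, 0)), lambda = 1)
  r <- epath_sz(c(0.5, 0.5), p)
  expect_equal(r$s, 1.5)                     # symmetry forces the midpoint
  expect_equal(r$z, 0.5 - log(2))            # -ln(2 exp(-0.5))
  # at a milestone with huge lambda, s snaps to its index and z to 0
  p6 <- epath_definition(rbind(c(0, 1), c(0.5, 0.6), c(1, 0)), lambda = 1e6)
  r2 <- epath_sz(c(0.5, 0.6), p6)
  expect_equal(r2$s, 2, tolerance = 1e-6)
  expect_lt(abs(r2$z), 1e-6)
})

test_that("EPATH matches the naive direct-summation oracle", {
  set.seed(22)
  for (i in 1:200) {
    n <- sample(2:9, 1)
    m <- matrix(runif(2 * n, 0, 1.5), ncol = 2)
    p <- tryCatch(epath_definition(m, lambda = runif(1, 0.5, 60)),
                  error = function(e) NULL)
    if (is.null(p)) next
    pt <- runif(2, 0, 1.5)
    r <- epath_sz(pt, p)
    d <- sqrt((pt[1] - m[, 1])^2 + (pt[2] - m[, 2])^2)
    o <- oracle_sz(d, p$lambda, squared = TRUE)
    expect_equal(r$s, o$s, tolerance = 1e-10)
    expect_equal(r$z, o$z, tolerance = 1e-10)
  }
})

test_that("RPATH matches hand formulas and the direct-summation oracle", {
  set.seed(23)
  x1 <- random_structure(6)
  x2 <- cv_structure(x1$atom_names, x1$residue_ids,
                     x1$xyz + matrix(rnorm(18, sd = 0.2), ncol = 3))
  p <- rpath_definition(list(x1, x2), lambda = 3)
  # frame = rigid copy of X1: R1 = 0, s from the 2-milestone hand formula
  frame <- rigid_move(x1$xyz)
  r <- rpath_sz(frame, p)
  R2 <- rmsd_superposed(frame, x2)
  expect_equal(r$rmsd[1], 0, tolerance = 1e-9)
  expect_equal(r$s, (1 + 2 * exp(-3 * R2)) / (1 + exp(-3 * R2)), tolerance = 1e-9)
  # huge lambda snaps s to the matching milestone
  psharp <- rpath_definition(list(x1, x2), lambda = 1e6)
  expect_equal(rpath_sz(x2$xyz, psharp)$s, 2, tolerance = 1e-6)
  # random paths against the naive oracle
  for (i in 1:20) {
    n <- sample(2:4, 1)
    ms <- lapply(seq_len(n), function(k)
      cv_structure(x1$atom_names, x1$residue_ids,
                   x1$xyz + matrix(rnorm(18, sd = 0.2), ncol = 3)))
    pp <- rpath_definition(ms, lambda = runif(1, 0.5, 20))
    rr <- rpath_sz(frame, pp)
    o <- oracle_sz(rr$rmsd, pp$lambda)
    expect_equal(rr$s, o$s, tolerance = 1e-10)
    expect_equal(rr$z, o$z, tolerance = 1e-10)
  }
})

test_that("squared-exponent RPATH uses R^2 in the weights", {
  set.seed(24)
  x1 <- random_structure(5)
  x2 <- cv_structure(x1$atom_names, x1$residue_ids,
                     x1$xyz + matrix(rnorm(15, sd = 0.3), ncol = 3))
  p <- rpath_definition(list(x1, x2), lambda = 5, squared = TRUE)
  frame <- x1$xyz + matrix(rnorm(15, sd = 0.1), ncol = 3)
  r <- rpath_sz(frame, p)
  o <- oracle_sz(r$rmsd, 5, squared = TRUE)
  expect_equal(r$s, o$s, tolerance = 1e-10)
})

test_that("s stays inside (1, N) and z is non-positive on a milestone", {
  set.seed(25)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    m <- matrix(runif(2 * n, 0, 1.2), ncol = 2)
    p <- tryCatch(epath_definition(m, lambda = runif(1, 1, 100)),
                  error = function(e) NULL)
    if (is.null(p)) next
    r <- epath_sz(runif(2, 0, 1.2), p)
    expect_gte(r$s, 1); expect_lte(r$s, n)  # strict interior up to fp precision
    k <- sample(n, 1)
    expect_lte(epath_sz(m[k, ], p)$z, 0)  # zero-distance term makes sum >= 1
  }
})

test_that("milestone-walk trajectories give monotone rounded s", {
  p <- build_arched_path(1, 8, 0.3)
  sz <- epath_sz(p$milestones, p)
  expect_true(all(diff(round(sz$s)) >= 0))
  expect_equal(round(sz$s), 1:8, tolerance = 0)  # sharp-enough default lambda? no: rounded only
})

test_that("arched path hits the documented geometry", {
  # no interior points: exactly the two anchors
  p2 <- build_arched_path(1, 2, arch = 0.5)
  expect_equal(unname(p2$milestones), rbind(c(0, 1), c(1, 0)))
  # Bezier midpoint identity
  p3 <- build_arched_path(1, 3, arch = 0.3)
  expect_equal(unname(p3$milestones[2, ]), c(0.65, 0.65), tolerance = 1e-9)
  # equal arc-length spacing against dense integration
  p8 <- build_arched_path(1, 8, arch = 0.3)
  gaps <- oracle_arc_gaps(p8$milestones, 1, 0.3)
  expect_lt(max(gaps) - min(gaps), 1e-4)
  # curve bows away from the origin
  expect_true(all(rowSums(p8$milestones) >= 1 - 1e-12))
  # symmetric under axis swap + order reversal
  swapped <- p8$milestones[nrow(p8$milestones):1, c(2, 1)]
  expect_equal(unname(p8$milestones), unname(swapped), tolerance = 1e-9)
  # arch = 0 reduces to the straight chord
  p0 <- build_arched_path(1, 5, arch = 0)
  expect_equal(unname(p0$milestones[, 1]), seq(0, 1, length.out = 5), tolerance = 1e-6)
  expect_equal(rowSums(p0$milestones), rep(1, 5), tolerance = 1e-9)
  expect_error(build_arched_path(1, 5, arch = -0.1), "arch")
  expect_error(build_arched_path(1, 1), "n_milestones")
  expect_error(build_arched_path(0, 5), "end_distance")
})

test_that("suggest_lambda targets half-weight at the neighbouring milestone", {
  # equally spaced EPATH milestones with consecutive d^2 = 0.01 nm^2
  m <- cbind(seq(0, 0.4, by = 0.1), seq(0.4, 0, by = -0.1)) / sqrt(2)
  p <- epath_definition(m, lambda = 1)
  expect_equal(suggest_lambda(p), 100 * log(2), tolerance = 1e-9)
  # doubling all spacings quarters the EPATH lambda
  p2 <- epath_definition(2 * m, lambda = 1)
  expect_equal(suggest_lambda(p2), suggest_lambda(p) / 4, tolerance = 1e-9)
  # RPATH: linear in the mean consecutive RMSD
  set.seed(26)
  a <- random_structure(6)
  b <- cv_structure(a$atom_names, a$residue_ids,
                    a$xyz + matrix(rnorm(18, sd = 0.2), ncol = 3))
  pr <- rpath_definition(list(a, b), lambda = 1)
  gap <- rmsd_superposed(b, a)
  expect_equal(suggest_lambda(pr), log(2) / gap, tolerance = 1e-9)
})

test_that("restraint energy is windowed, smooth and zero at end points", {
  spec <- list(restraint_harmonic("pif", center = 0.5, kappa = 10,
                                  s_lo = 2, s_hi = 6))
  # end-point states are never restrained
  expect_equal(restraint_energy(1, list(pif = 2), spec), 0)
  expect_equal(restraint_energy(8, list(pif = 2), spec), 0)
  # harmonic minimum
  expect_equal(restraint_energy(4, list(pif = 0.5), spec), 0)
  # plateau arithmetic: kappa (dx)^2
  expect_equal(restraint_energy(4, list(pif = 0.7), spec), 10 * 0.2^2)
  # taper ramps from 0 to 1
  w_edge <- restraint_energy(2 + 1e-9, list(pif = 0.7), spec)
  expect_lt(w_edge, 1e-6)
  # z wall: one-sided
  wall <- list(restraint_wall(z_max = 0.1, kappa = 50))
  expect_equal(restraint_energy(4, list(z = 0.05), wall), 0)
  expect_equal(restraint_energy(4, list(z = 0.3), wall), 50 * 0.2^2)
  expect_error(restraint_energy(4, list(pif = 1), wall), "unknown CV")
})

test_that("path configs round-trip through the key-value format", {
  p <- build_arched_path(0.8, 6, 0.25)
  f <- tempfile(fileext = ".config")
  write_path(p, f)
  q <- read_path(f)
  expect_equal(q$flavor, "EPATH")
  expect_equal(unname(q$milestones), unname(p$milestones), tolerance = 1e-10)
  expect_equal(q$lambda, p$lambda, tolerance = 1e-10)
  # RPATH variant with companion multi-MODEL PDB
  set.seed(27)
  a <- random_structure(5)
  b <- cv_structure(a$atom_names, a$residue_ids,
                    a$xyz + matrix(rnorm(15, sd = 0.2), ncol = 3))
  pr <- rpath_definition(list(a, b), lambda = 4)
  fr <- tempfile(fileext = ".config")
  write_path(pr, fr)
  qr <- read_path(fr)
  expect_equal(qr$flavor, "RPATH")
  expect_equal(length(qr$milestones), 2L)
  expect_lt(rmsd_superposed(qr$milestones[[1]], a), 1e-3)  # PDB precision
})

test_that("trajectory projection reports s, z and both RMSDs per frame", {
  set.seed(28)
  es <- make_toy_endstates(seed = 5)
  traj <- make_transition_trajectory(es$inactive, es$active, n_frames = 12,
                                     noise = 0, seed = 5)
  D <- endpoint_distance(es$inactive, es$active)
  path <- build_arched_path(D, 8, 0.3)
  cs <- project_trajectory(traj, path, es$inactive, es$active)
  expect_s3_class(cs, "cv_series")
  expect_equal(nrow(cs), 12L)
  expect_equal(cs$rmsd_inactive[1], 0, tolerance = 1e-9)
  expect_equal(cs$rmsd_active[12], 0, tolerance = 1e-9)
  expect_true(all(diff(cs$rmsd_inactive) > -1e-9))  # monotone for clean interpolation
  expect_error(project_trajectory(traj, path), "reference structures")
})
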