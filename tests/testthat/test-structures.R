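test_that("PDB coordinates are converted from Angstrom to nm", {
  f <- write_tmp_lines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       2.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       3.000   2.000   3.000  1.00  0.00           C",
    "END"))
  s <- read_structure(f)
  expect_s3_class(s, "cv_structure")
  expect_equal(s$xyz[1, ], c(0.1, 0.2, 0.3))
  expect_equal(s$atom_names, rep("CA", 3))
})

test_that("degenerate files raise parse errors", {
  f <- tempfile(fileext = ".pdb"); file.create(f)
  expect_error(read_structure(f), "parse error")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "no such file")
  g <- write_tmp_lines(c("title", "nonsense"), ext = ".gro")
  expect_error(read_structure(g), "line 2")
})

test_that("GRO files are read in nm with fixed-width fields", {
  g <- write_tmp_lines(c(
    "toy", "    2",
    "    1ALA     CA    1   0.100   0.200   0.300",
    "    2ALA     CA    2   0.400   0.500   0.600",
    "   1.00000   1.00000   1.00000"), ext = ".gro")
  s <- read_structure(g)
  expect_equal(nrow(s$xyz), 2L)
  expect_equal(s$xyz[2, ], c(0.4, 0.5, 0.6))
  expect_equal(s$residue_ids, 1:2)
})

test_that("multi-model PDB trajectory has one frame per MODEL record", {
  for (k in c(1L, 4L, 7L)) {
    f <- write_tmp_lines(multimodel_pdb_lines(k))
    tr <- read_trajectory(f)
    expect_equal(length(tr$frames), k)
  }
  f <- write_tmp_lines(multimodel_pdb_lines(3L))
  tr <- read_trajectory(f)
  expect_equal(tr$frames[[2]][1, 1], 0.2)  # model 2 at x = 2 A
})

test_that("C-alpha selection honours residue ranges and validates them", {
  f <- write_tmp_lines(toy_chain_pdb_lines())
  s <- read_structure(f)
  expect_length(select_calpha(s), 5L)
  expect_equal(s$atom_names[select_calpha(s)], rep("CA", 5))
  expect_length(select_calpha(s, list(c(2, 4))), 3L)
  expect_length(select_calpha(s, list(c(1, 1), c(5, 5))), 2L)
  expect_error(select_calpha(s, list(c(99, 100))), "outside")
  no_ca <- cv_structure(c("N", "C"), c(1L, 1L), matrix(0, 2, 3))
  expect_error(select_calpha(no_ca), "no CA atoms")
})

test_that("superposed RMSD is zero for identical and rigidly moved copies", {
  set.seed(11)
  s <- random_structure(10)
  expect_equal(rmsd_superposed(s, s), 0)
  moved <- rigid_move(s$xyz, angle = c(pi / 2, 0, 0), shift = c(1, 1, 1))
  expect_lt(rmsd_superposed(moved, s$xyz), 1e-10)
})

test_that("superposed RMSD is symmetric and rigid-motion invariant", {
  set.seed(12)
  for (rep in 1:10) {
    a <- random_structure(8)$xyz
    b <- a + matrix(rnorm(24, sd = 0.05), ncol = 3)
    expect_equal(rmsd_superposed(a, b), rmsd_superposed(b, a), tolerance = 1e-9)
    expect_equal(rmsd_superposed(rigid_move(a), rigid_move(b)),
                 rmssd <- rmsd_superposed(a, b), tolerance = 1e-9)
    expect_lte(rmsd_superposed(a, b),
               rmsd_superposed(a, b, fit = FALSE) + 1e-12)
  }
})

test_that("superposition matches a dense rotation-search oracle", {
  set.seed(13)
  # 4-atom square with one displaced corner, plus random pairs
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0) * 0.5
  sq2 <- sq; sq2[3, ] <- sq2[3, ] + c(0.2, 0, 0) / sqrt(2)
  pairs <- list(list(a = sq, b = rigid_move(sq2)))
  for (k in 1:8) {
    n <- sample(5:20, 1)
    a <- random_structure(n)$xyz
    pairs[[k + 1]] <- list(a = a, b = rigid_move(a + matrix(rnorm(3 * n, sd = 0.08), ncol = 3)))
  }
  for (p in pairs) {
    impl <- rmsd_superposed(p$b, p$a)
    orac <- oracle_rmsd_search(p$b, p$a, n_coarse = 2e3, refine_rounds = 10L,
                               n_refine = 300L, n_keep = 15L)
    expect_lte(impl, min(orac$coarse_all) + 1e-9)
    expect_lt(abs(impl - orac$min), 1e-3)
  }
})

test_that("degenerate align sets are rejected", {
  line <- cbind(seq_len(5), 0, 0) * 0.1
  expect_error(rmsd_superposed(line, line + 0.1), "collinear")
  a <- random_structure(5)$xyz
  expect_error(rmsd_superposed(a, a, align = 1:2), "at least 3")
})

test_that("milestone extraction fixes end points and spaces RMSD evenly", {
  set.seed(14)
  a <- random_structure(6)$xyz
  b <- a + matrix(rnorm(18, sd = 0.3), ncol = 3)
  frames <- lapply(0:10 / 10, function(t) (1 - t) * a + t * b)
  traj <- traj_from_frames(frames)
  m2 <- extract_milestones(traj, 2)
  expect_equal(attr(m2, "frame_indices"), c(1L, 11L))
  m6 <- extract_milestones(traj, 6)
  expect_equal(attr(m6, "frame_indices"), c(1L, 3L, 5L, 7L, 9L, 11L))
  expect_error(extract_milestones(traj, 12), "exceeds")
})

test_that("chosen milestone subsequence is variance-optimal (exhaustive check)", {
  set.seed(15)
  a <- random_structure(6)$xyz
  b <- a + matrix(rnorm(18, sd = 0.3), ncol = 3)
  frames <- lapply(0:10 / 10, function(t)
    (1 - t) * a + t * b + matrix(rnorm(18, sd = 0.02), ncol = 3))
  traj <- traj_from_frames(frames)
  picked <- attr(extract_milestones(traj, 5), "frame_indices")
  D <- matrix(0, 11, 11)
  for (i in 1:10) for (j in (i + 1):11)
    D[i, j] <- D[j, i] <- rmsd_superposed(frames[[i]], frames[[j]])
  v_of <- function(idx) var(D[cbind(idx[-length(idx)], idx[-1])])
  v_best <- v_of(picked)
  combos <- combn(2:10, 3)
  for (k in seq_len(ncol(combos)))
    expect_lte(v_best, v_of(c(1, combos[, k], 11)) + 1e-12)
})

test_that("arc-length heuristic handles long trajectories", {
  set.seed(16)
  a <- random_structure(5)$xyz
  b <- a + matrix(rnorm(15, sd = 0.4), ncol = 3)
  frames <- lapply(seq(0, 1, length.out = 30), function(t) (1 - t) * a + t * b)
  ms <- extract_milestones(traj_from_frames(frames), 6)
  idx <- attr(ms, "frame_indices")
  expect_equal(idx[1], 1L)
  expect_equal(idx[6], 30L)
  expect_true(all(diff(idx) > 0))
})
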