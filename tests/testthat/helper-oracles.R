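# Independent oracles used across the suite.  Each recomputes the
# quantity under test from first principles, on a code path disjoint
# from the package implementation.

# naive direct-summation progress/deviation (no max-shift): the oracle
# for both path flavours, fed the per-milestone distances directly
oracle_sz <- function(d, lambda, squared = FALSE) {
  e <- if (squared) exp(-lambda * d^2) else exp(-lambda * d)
  list(s = sum(seq_along(d) * e) / sum(e),
       z = -log(sum(e)) / lambda)
}

# batch of uniform random rotation matrices via normalized quaternions;
# returns the n x 9 matrix of row-major rotation entries
random_rotation_entries <- function(n) {
  q <- matrix(rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

# perturb a unit quaternion by random rotations of angle <= ang
perturb_quaternion <- function(q0, n, ang) {
  ax <- matrix(rnorm(3 * n), ncol = 3)
  ax <- ax / sqrt(rowSums(ax^2))
  th <- runif(n, 0, ang)
  dq <- cbind(cos(th / 2), sin(th / 2) * ax)
  # Hamilton product q0 * dq
  w1 <- q0[1]; x1 <- q0[2]; y1 <- q0[3]; z1 <- q0[4]
  cbind(w1 * dq[, 1] - x1 * dq[, 2] - y1 * dq[, 3] - z1 * dq[, 4],
        w1 * dq[, 2] + x1 * dq[, 1] + y1 * dq[, 4] - z1 * dq[, 3],
        w1 * dq[, 3] - x1 * dq[, 4] + y1 * dq[, 1] + z1 * dq[, 2],
        w1 * dq[, 4] + x1 * dq[, 3] - y1 * dq[, 2] + z1 * dq[, 1])
}

quat_entries <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

# Dense random-rotation / translation search for the minimal RMSD of
# mobile onto reference (all atoms).  Optimal translation is the
# centroid match; RMSD^2(R) = (|A|^2 + |B|^2 - 2 tr(R M)) / n with
# M = t(B) %*% A on centred coordinates.  Optionally refines around the
# best rotation with shrinking-angle resampling.
oracle_rmsd_search <- function(mobile, reference, n_coarse = 1e5,
                               refine_rounds = 0L, n_refine = 2000L,
                               n_keep = 20L) {
  A <- scale(reference, scale = FALSE)
  B <- scale(mobile, scale = FALSE)
  n <- nrow(A)
  M <- t(B) %*% A
  const <- sum(A^2) + sum(B^2)
  mvec <- as.vector(t(M))  # row-major to match entry layout
  rmsd_of <- function(entries) {
    tr <- entries %*% mvec
    sqrt(pmax(const - 2 * tr, 0) / n)
  }
  q <- matrix(rnorm(4 * n_coarse), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  r <- rmsd_of(quat_entries(q))
  # descend from the n_keep best coarse rotations (the landscape over
  # SO(3) is multimodal), halving the perturbation angle each round
  starts <- order(r)[seq_len(min(n_keep, n_coarse))]
  best <- r[starts[1L]]; final_bq <- q[starts[1L], ]
  for (s0 in starts) {
    bq <- q[s0, ]; cur <- r[s0]; ang <- 0.4
    for (k in seq_len(refine_rounds)) {
      qq <- perturb_quaternion(bq, n_refine, ang)
      rr <- rmsd_of(quat_entries(qq))
      i <- which.min(rr)
      if (rr[i] < cur) { cur <- rr[i]; bq <- qq[i, ] }
      ang <- ang / 2
    }
    if (cur < best) { best <- cur; final_bq <- bq }
  }
  list(min = best, coarse_min = r[starts[1L]], coarse_all = r)
}

# independent greedy gromos reference: plain double-loop rewrite
oracle_gromos <- function(D, cutoff) {
  nf <- nrow(D)
  assigned <- rep(FALSE, nf)
  labels <- rep(NA_integer_, nf)
  clusters <- list()
  while (!all(assigned)) {
    best_i <- -1L; best_n <- -1L
    for (i in seq_len(nf)) {
      if (assigned[i]) next
      cnt <- 0L
      for (j in seq_len(nf))
        if (i != j && !assigned[j] && D[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best_n) { best_n <- cnt; best_i <- i }
    }
    mem <- best_i
    for (j in seq_len(nf))
      if (j != best_i && !assigned[j] && D[best_i, j] <= cutoff)
        mem <- c(mem, j)
    assigned[mem] <- TRUE
    clusters[[length(clusters) + 1L]] <- sort(mem)
  }
  ord <- order(-lengths(clusters))
  clusters <- clusters[ord]
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k - 1L
  list(labels = labels, sizes = lengths(clusters))
}

# dense numeric arc length of the arched Bezier between consecutive
# milestones, by resampling the curve on a fine grid
oracle_arc_gaps <- function(milestones, D, arch, n_grid = 2e5) {
  ctrl <- (1 + 2 * arch) * D / 2
  tt <- seq(0, 1, length.out = n_grid)
  bx <- 2 * tt * (1 - tt) * ctrl + tt^2 * D
  by <- (1 - tt)^2 * D + 2 * tt * (1 - tt) * ctrl
  arc <- c(0, cumsum(sqrt(diff(bx)^2 + diff(by)^2)))
  # arc position of each milestone = arc at nearest curve point
  pos <- vapply(seq_len(nrow(milestones)), function(i) {
    j <- which.min((bx - milestones[i, 1])^2 + (by - milestones[i, 2])^2)
    arc[j]
  }, numeric(1))
  diff(pos)
}
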