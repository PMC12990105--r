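# gromos conformational clustering and Shannon-entropy profiling of
# conformational heterogeneity along the path.

#' Pairwise superposed RMSD matrix of a trajectory
#'
#' @param traj a [cv_trajectory()].
#' @param selection atom indices used for both the fit and the measure
#'   (default: all atoms).
#' @return Symmetric n_frames x n_frames matrix of RMSDs (nm).
#' @export
rmsd_matrix <- function(traj, selection = NULL) {
  nf <- n_frames(traj)
  D <- matrix(0, nf, nf)
  if (nf > 1L)
    for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf)
      D[i, j] <- D[j, i] <- rmsd_superposed(traj$frames[[i]], traj$frames[[j]],
                                            align = selection)
  D
}

#' gromos conformational clustering
#'
#' Greedy RMSD-cutoff clustering: repeatedly take the unassigned frame
#' with the most unassigned neighbours within the cutoff (ties broken by
#' the lowest frame index); that frame and its unassigned neighbours
#' form the next cluster.  Clusters are reported by decreasing size with
#' 0-based ids.
#'
#' @param traj a [cv_trajectory()], or a precomputed RMSD matrix.
#' @param selection atom indices for the RMSD (default: all atoms).
#' @param cutoff neighbour cutoff in nm (default 0.14, i.e. 1.4 A on the
#'   secondary-structure C-alphas in the GPCR analyses).
#' @return A `cluster_assignment`: list with `labels` (per-frame 0-based
#'   cluster id), `centers` (representative frame index per cluster,
#'   1-based), `populations` (fractions summing to 1), `sizes` and
#'   `cutoff`.
#' @export
gromos_cluster <- function(traj, selection = NULL, cutoff = 0.14) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  D <- if (is.matrix(traj) && nrow(traj) == ncol(traj)) traj
       else rmsd_matrix(traj, selection)
  nf <- nrow(D)
  if (nf < 1L) stop("empty trajectory")
  neigh <- D <= cutoff
  diag(neigh) <- FALSE
  unassigned <- rep(TRUE, nf)
  labels <- integer(nf); centers <- integer(0)
  members_list <- list()
  while (any(unassigned)) {
    cand <- which(unassigned)
    counts <- vapply(cand, function(i) sum(neigh[i, ] & unassigned), integer(1))
    center <- cand[which.max(counts)]  # which.max takes the first = lowest index
    members <- c(center, which(neigh[center, ] & unassigned))
    members <- sort(unique(members))
    unassigned[members] <- FALSE
    centers <- c(centers, center)
    members_list[[length(members_list) + 1L]] <- members
  }
  sizes <- lengths(members_list)
  # decreasing size; equal sizes keep formation order (stable sort)
  ord <- order(-sizes)
  members_list <- members_list[ord]; centers <- centers[ord]; sizes <- sizes[ord]
  for (k in seq_along(members_list)) labels[members_list[[k]]] <- k - 1L
  structure(list(labels = labels, centers = centers,
                 populations = sizes / nf, sizes = sizes, cutoff = cutoff,
                 n_frames = nf),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d frames -> %d clusters (cutoff %.3g nm)\n",
              x$n_frames, length(x$sizes), x$cutoff))
  cat("  populations:", paste(sprintf("%.3g", head(x$populations, 8L)),
                              collapse = " "),
      if (length(x$sizes) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Write cluster assignments as two-column text
#'
#' @param assignment a `cluster_assignment`.
#' @param path output file (columns: frame index, cluster id).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(assignment, path) {
  writeLines(c("# frame cluster",
               sprintf("%d %d", seq_len(assignment$n_frames), assignment$labels)),
             path)
  invisible(path)
}

#' Shannon entropy of cluster populations
#'
#' `S/kB = -sum(p_i log p_i)` with `0 log 0 := 0`; populations are
#' renormalized (with a warning if they miss 1 by more than 1e-9).
#'
#' @param populations vector of fractional populations (or a
#'   `cluster_assignment`).
#' @return Dimensionless entropy in units of kB.
#' @export
shannon_entropy <- function(populations) {
  if (inherits(populations, "cluster_assignment"))
    populations <- populations$populations
  p <- as.numeric(populations)
  if (any(p < 0)) stop("populations must be >= 0")
  s <- sum(p)
  if (s <= 0) stop("populations sum to zero")
  if (abs(s - 1) > 1e-9)
    warning(sprintf("populations sum to %.6g; renormalizing", s))
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p)) + 0  # + 0 collapses IEEE negative zero
}

#' Shannon-entropy profile along path intervals
#'
#' Frames are grouped by their progress value `s` into the intervals
#' defined by `interval_edges` (milestone-to-milestone bins); gromos
#' clustering is run independently inside each interval and the Shannon
#' entropy of the resulting cluster populations reported, giving a
#' local measure of conformational heterogeneity along the transition.
#'
#' @param traj a [cv_trajectory()].
#' @param s_values per-frame progress values (same length as the
#'   trajectory).
#' @param interval_edges strictly increasing interval edges in s.
#' @param selection atom indices for the clustering RMSD.
#' @param cutoff gromos cutoff in nm (default 0.14).
#' @return An `entropy_profile` data frame with columns `s_lo`, `s_hi`,
#'   `n_frames`, `n_clusters`, `entropy` (NA for empty intervals).
#' @export
entropy_profile <- function(traj, s_values, interval_edges, selection = NULL,
                            cutoff = 0.14) {
  if (length(s_values) != n_frames(traj))
    stop("s_values length must equal the frame count")
  if (any(diff(interval_edges) <= 0))
    stop("interval_edges must be strictly increasing")
  bin <- findInterval(s_values, interval_edges, rightmost.closed = TRUE)
  bin[bin < 1L | bin > length(interval_edges) - 1L] <- NA_integer_
  if (all(is.na(bin))) stop("all frames fall outside the intervals")
  k <- length(interval_edges) - 1L
  out <- data.frame(s_lo = head(interval_edges, -1L),
                    s_hi = tail(interval_edges, -1L),
                    n_frames = 0L, n_clusters = 0L, entropy = NA_real_)
  for (b in seq_len(k)) {
    idx <- which(!is.na(bin) & bin == b)
    out$n_frames[b] <- length(idx)
    if (length(idx) == 0L) next
    sub <- cv_trajectory(traj$topology, traj$frames[idx])
    cl <- gromos_cluster(sub, selection = selection, cutoff = cutoff)
    out$n_clusters[b] <- length(cl$sizes)
    out$entropy[b] <- shannon_entropy(cl$populations)
  }
  attr(out, "cutoff") <- cutoff
  class(out) <- c("entropy_profile", "data.frame")
  out
}

#' Write an entropy profile as plain text
#'
#' @param profile an `entropy_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_entropy_profile <- function(profile, path) {
  writeLines(c(sprintf("# gromos cutoff %.6g nm; entropy in kB units",
                       attr(profile, "cutoff")),
               "# s_lo s_hi n_frames n_clusters entropy",
               sprintf("%.6g %.6g %d %d %.8g", profile$s_lo, profile$s_hi,
                       profile$n_frames, profile$n_clusters, profile$entropy)),
             path)
  invisible(path)
}
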