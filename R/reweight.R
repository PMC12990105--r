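# Reweighting biased CV time series to free-energy surfaces and
# free-energy-difference convergence traces.  Weights are the standard
# static reweighting factors w = exp(V_bias / kT) for samples drawn
# under the bias potential(s) V_bias.

KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/mol/K

#' Thermal energy kT in kcal/mol
#'
#' @param temperature in K (default 310, physiological).
#' @return kT in kcal/mol.
#' @export
kT_kcal <- function(temperature = 310) KB_KCAL * temperature

reweight_weights <- function(table, bias_columns, kT) {
  missing <- setdiff(bias_columns, colnames(table))
  if (length(missing))
    stop(sprintf("bias column(s) not in table: %s", paste(missing, collapse = ", ")))
  if (length(bias_columns) == 0L) return(rep(1, nrow(table)))
  v <- rowSums(as.matrix(table[, bias_columns, drop = FALSE]))
  # shift before exponentiating; the constant cancels in every estimate
  exp((v - max(v[is.finite(v)])) / kT)
}

#' Reweight biased samples to a 1D or 2D free-energy surface
#'
#' Per-frame weights `exp(sum(V_bias)/kT)` are histogrammed over the
#' grid and converted to `F = -kT log H`, min-shifted so the lowest
#' observed bin is zero.  Bins with no samples are flagged unobserved
#' (`NA` free energy), never reported as zero.
#'
#' @param table a `colvar_table` or data frame.
#' @param cv_columns one (FES1D) or two (FES2D) CV column names.
#' @param bias_columns names of the bias-energy columns entering the
#'   weights (may be empty for unbiased data).
#' @param kT thermal energy in the bias-column units
#'   (default [kT_kcal()] at 310 K).
#' @param breaks bin edges: a numeric vector (1D), a list of two vectors
#'   (2D), or a bin count from which edges span the data range.
#' @return An object of class `fes` (`fes1d` or `fes2d`) with elements
#'   `edges`, `mids`, `free_energy`, `counts`, `observed`, `kT`.
#' @export
reweight_fes <- function(table, cv_columns, bias_columns = character(),
                         kT = kT_kcal(), breaks = 50L) {
  if (kT <= 0) stop("kT must be > 0")
  missing <- setdiff(cv_columns, colnames(table))
  if (length(missing))
    stop(sprintf("CV column(s) not in table: %s", paste(missing, collapse = ", ")))
  ndim <- length(cv_columns)
  if (!ndim %in% 1:2) stop("cv_columns must name 1 or 2 columns")
  vals <- as.matrix(table[, cv_columns, drop = FALSE])
  w <- reweight_weights(table, bias_columns, kT)
  ok <- is.finite(w) & apply(is.finite(vals), 1L, all)
  n_rejected <- sum(!ok)
  if (n_rejected > 0)
    message(sprintf("reweight_fes: rejected %d row(s) with non-finite values", n_rejected))
  vals <- vals[ok, , drop = FALSE]; w <- w[ok]
  edges <- lapply(seq_len(ndim), function(k) {
    b <- if (is.list(breaks)) breaks[[k]] else breaks
    if (length(b) == 1L) seq(min(vals[, k]), max(vals[, k]), length.out = b + 1L)
    else as.numeric(b)
  })
  bin_of <- function(x, e) {
    i <- findInterval(x, e, rightmost.closed = TRUE)
    i[i < 1L | i > length(e) - 1L] <- NA_integer_
    i
  }
  ib <- lapply(seq_len(ndim), function(k) bin_of(vals[, k], edges[[k]]))
  inb <- !Reduce(`|`, lapply(ib, is.na))
  if (!any(inb)) stop("no samples fall inside the grid")
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  H <- array(0, dim = dims); cnt <- array(0L, dim = dims)
  flat <- ib[[1L]][inb]
  if (ndim == 2L) flat <- flat + (ib[[2L]][inb] - 1L) * dims[1L]
  tw <- rowsum(w[inb], flat)
  tc <- rowsum(rep(1L, sum(inb)), flat)
  H[as.integer(rownames(tw))] <- tw[, 1L]
  cnt[as.integer(rownames(tc))] <- tc[, 1L]
  observed <- cnt > 0L
  F <- array(NA_real_, dim = dims)
  F[observed] <- -kT * log(H[observed] / sum(H))
  F <- F - min(F[observed])
  mids <- lapply(edges, function(e) (head(e, -1L) + tail(e, -1L)) / 2)
  structure(list(cv = cv_columns, edges = edges, mids = mids,
                 free_energy = if (ndim == 1L) as.numeric(F) else F,
                 weights = if (ndim == 1L) as.numeric(H) else H,
                 counts = if (ndim == 1L) as.integer(cnt) else cnt,
                 observed = if (ndim == 1L) as.logical(observed) else observed,
                 kT = kT, n_samples = sum(inb), n_rejected = n_rejected),
            class = c(if (ndim == 1L) "fes1d" else "fes2d", "fes"))
}

#' @export
print.fes <- function(x, ...) {
  cat(sprintf("<%s> over %s; %d samples, kT = %.4g kcal/mol\n",
              class(x)[1L], paste(x$cv, collapse = " x "), x$n_samples, x$kT))
  rng <- range(x$free_energy, na.rm = TRUE)
  cat(sprintf("  free energy range [%.4g, %.4g] kcal/mol; %d/%d bins observed\n",
              rng[1], rng[2], sum(x$observed), length(x$observed)))
  invisible(x)
}

#' @export
plot.fes1d <- function(x, ...) {
  plot(x$mids[[1L]], x$free_energy, type = "l",
       xlab = x$cv[1L], ylab = "free energy (kcal/mol)", ...)
  invisible(x)
}

#' @export
plot.fes2d <- function(x, ...) {
  graphics::image(x$mids[[1L]], x$mids[[2L]], x$free_energy,
                  xlab = x$cv[1L], ylab = x$cv[2L], ...)
  graphics::contour(x$mids[[1L]], x$mids[[2L]], x$free_energy, add = TRUE)
  invisible(x)
}

#' Marginalize a 2D free-energy surface onto one CV
#'
#' Sums the reweighted probability over the other dimension and returns
#' `-kT log` of the marginal, min-shifted -- identical to reweighting
#' directly onto the retained CV with the same grid.
#'
#' @param fes a `fes2d` object.
#' @param margin dimension to keep (1 or 2).
#' @return A `fes1d` object.
#' @export
marginalize_fes <- function(fes, margin = 1L) {
  stopifnot(inherits(fes, "fes2d"), margin %in% 1:2)
  H <- if (margin == 1L) rowSums(fes$weights) else colSums(fes$weights)
  cnt <- if (margin == 1L) rowSums(fes$counts) else colSums(fes$counts)
  observed <- cnt > 0L
  F <- rep(NA_real_, length(H))
  F[observed] <- -fes$kT * log(H[observed] / sum(H))
  F <- F - min(F[observed])
  structure(list(cv = fes$cv[margin], edges = fes$edges[margin],
                 mids = fes$mids[margin], free_energy = F, weights = H,
                 counts = as.integer(cnt), observed = observed, kT = fes$kT,
                 n_samples = fes$n_samples, n_rejected = fes$n_rejected),
            class = c("fes1d", "fes"))
}

#' Write a FES as a plain-text table
#'
#' @param fes a `fes1d` or `fes2d` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# free energy (kcal/mol), kT = %.6g; CVs: %s",
                     fes$kT, paste(fes$cv, collapse = " ")), con)
  if (inherits(fes, "fes1d")) {
    writeLines(sprintf("# columns: %s free_energy count", fes$cv[1L]), con)
    writeLines(sprintf("%.8g %.8g %d", fes$mids[[1L]], fes$free_energy,
                       fes$counts), con)
  } else {
    writeLines(sprintf("# columns: %s %s free_energy count", fes$cv[1L],
                       fes$cv[2L]), con)
    g <- expand.grid(i = seq_along(fes$mids[[1L]]), j = seq_along(fes$mids[[2L]]))
    writeLines(sprintf("%.8g %.8g %.8g %d", fes$mids[[1L]][g$i],
                       fes$mids[[2L]][g$j], fes$free_energy[cbind(g$i, g$j)],
                       fes$counts[cbind(g$i, g$j)]), con)
  }
  invisible(path)
}

# ---- free-energy-difference traces ----------------------------------------

window_weight_sum <- function(x, w, window) sum(w[x >= window[1] & x <= window[2]])

#' Free-energy difference between two basins over simulation time
#'
#' At each stride time `t`, `deltaG(t) = -kT log(W_active(<=t) /
#' W_inactive(<=t))` over cumulative reweighted populations, so the
#' trace shows convergence of the activation free energy
#' (active minus inactive).  The trace starts at the first time both
#' basins hold at least one sample.
#'
#' @param table a `colvar_table` or data frame.
#' @param s_column progress-CV column name (default `"s"`).
#' @param bias_columns bias-energy column names.
#' @param kT thermal energy (same units as the bias columns).
#' @param inactive_window,active_window disjoint `c(lo, hi)` intervals of
#'   the progress CV defining the two basins.
#' @param stride report every `stride`-th row (default: 100 points).
#' @param time_column time column name.
#' @return A `deltag_trace` data frame with columns `time`, `delta_g`.
#' @export
deltag_trace <- function(table, s_column = "s", bias_columns = character(),
                         kT = kT_kcal(), inactive_window, active_window,
                         stride = NULL, time_column = "time") {
  if (max(inactive_window) > min(active_window) &&
      max(active_window) > min(inactive_window))
    stop("basin windows must be disjoint")
  s <- table[[s_column]]
  if (is.null(s)) stop(sprintf("no column '%s' in table", s_column))
  tm <- if (time_column %in% colnames(table)) table[[time_column]]
        else seq_len(nrow(table))
  o <- order(tm); s <- s[o]; tm <- tm[o]
  w <- reweight_weights(table, bias_columns, kT)[o]
  in_i <- s >= inactive_window[1] & s <= inactive_window[2]
  in_a <- s >= active_window[1] & s <= active_window[2]
  if (!any(in_i) || !any(in_a)) {
    empty <- c("inactive", "active")[c(!any(in_i), !any(in_a))]
    stop(sprintf("basin(s) with no samples: %s", paste(empty, collapse = ", ")))
  }
  Wi <- cumsum(w * in_i); Wa <- cumsum(w * in_a)
  if (is.null(stride)) stride <- max(1L, nrow(table) %/% 100L)
  at <- unique(c(seq(stride, length(s), by = stride), length(s)))
  at <- at[Wi[at] > 0 & Wa[at] > 0]
  out <- data.frame(time = tm[at], delta_g = -kT * log(Wa[at] / Wi[at]))
  attr(out, "kT") <- kT
  attr(out, "windows") <- list(inactive = inactive_window, active = active_window)
  class(out) <- c("deltag_trace", "data.frame")
  out
}

#' Final basin free-energy difference with a block-bootstrap error
#'
#' Splits the time series into `n_blocks` contiguous blocks and
#' resamples blocks with replacement to estimate the standard error of
#' the reweighted `deltaG = -kT log(W_active / W_inactive)`.
#'
#' @inheritParams deltag_trace
#' @param n_blocks number of contiguous blocks (default 20).
#' @param n_boot bootstrap replicates (default 200).
#' @param seed optional RNG seed for reproducible resampling.
#' @return List with `delta_g`, `se` and the bootstrap replicate vector
#'   `boot`.
#' @export
deltag_bootstrap <- function(table, s_column = "s", bias_columns = character(),
                             kT = kT_kcal(), inactive_window, active_window,
                             n_blocks = 20L, n_boot = 200L, seed = NULL) {
  s <- table[[s_column]]
  w <- reweight_weights(table, bias_columns, kT)
  in_i <- s >= inactive_window[1] & s <= inactive_window[2]
  in_a <- s >= active_window[1] & s <= active_window[2]
  if (sum(in_i) == 0 || sum(in_a) == 0) stop("a basin window holds no samples")
  dg_hat <- -kT * log(sum(w[in_a]) / sum(w[in_i]))
  blk <- as.integer(cut(seq_along(s), n_blocks, labels = FALSE))
  wi_b <- rowsum(w * in_i, blk)[, 1L]
  wa_b <- rowsum(w * in_a, blk)[, 1L]
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  boot <- vapply(seq_len(n_boot), function(b) {
    pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
    wa <- sum(wa_b[pick]); wi <- sum(wi_b[pick])
    if (wa <= 0 || wi <= 0) return(NA_real_)
    -kT * log(wa / wi)
  }, numeric(1))
  list(delta_g = dg_hat, se = sd(boot, na.rm = TRUE), boot = boot)
}

#' Average replicate deltaG traces
#'
#' Pointwise mean and sample standard deviation (n-1 denominator) over
#' replicas sharing a common time grid; use [resample_trace()] first if
#' the grids differ.
#'
#' @param traces list of >= 2 `deltag_trace` objects on identical time
#'   grids.
#' @return Data frame with columns `time`, `mean`, `sd` and class
#'   `deltag_ensemble`.
#' @export
replica_average <- function(traces) {
  if (length(traces) < 2L) stop("need at least 2 replica traces")
  t0 <- traces[[1L]]$time
  same <- vapply(traces, function(tr)
    length(tr$time) == length(t0) && all(abs(tr$time - t0) < 1e-9), logical(1))
  if (!all(same)) stop("replica traces must share one time grid (see resample_trace)")
  g <- vapply(traces, `[[`, numeric(length(t0)), "delta_g")
  out <- data.frame(time = t0,
                    mean = rowMeans(g),
                    sd = apply(g, 1L, sd))
  class(out) <- c("deltag_ensemble", "data.frame")
  out
}

#' Resample a deltaG trace onto a common time grid
#'
#' Linear interpolation within the trace's time span.
#'
#' @param trace a `deltag_trace`.
#' @param times target time grid.
#' @return A `deltag_trace` on the new grid.
#' @export
resample_trace <- function(trace, times) {
  g <- approx(trace$time, trace$delta_g, xout = times, rule = 2)$y
  out <- data.frame(time = times, delta_g = g)
  class(out) <- c("deltag_trace", "data.frame")
  out
}

#' @export
plot.deltag_trace <- function(x, ...) {
  plot(x$time, x$delta_g, type = "l", xlab = "time (ps)",
       ylab = expression(Delta * G ~ "(kcal/mol)"), ...)
  invisible(x)
}

#' @export
plot.deltag_ensemble <- function(x, ...) {
  ylim <- range(x$mean - x$sd, x$mean + x$sd)
  plot(x$time, x$mean, type = "n", ylim = ylim, xlab = "time (ps)",
       ylab = expression(Delta * G ~ "(kcal/mol)"), ...)
  graphics::polygon(c(x$time, rev(x$time)), c(x$mean + x$sd, rev(x$mean - x$sd)),
                    border = NA, col = grDevices::adjustcolor("orange", 0.3))
  graphics::lines(x$time, x$mean, col = "darkorange", lwd = 2)
  invisible(x)
}
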