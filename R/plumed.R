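# Bridge to the enhanced-sampling engine: COLVAR tables, PLUMED input
# blocks implementing the EPATH CV, and reference PDBs carrying
# alignment/measure weights in the occupancy/beta columns.

# ---- COLVAR ---------------------------------------------------------------

#' Read a PLUMED COLVAR file
#'
#' Parses the whitespace table behind a `#! FIELDS ...` header.  `#! SET`
#' and comment lines are skipped; an interior `#! FIELDS` line (restart)
#' must repeat the original header and its rows are concatenated.
#' Duplicate time stamps from restart overlaps are resolved by keeping
#' the last occurrence.
#'
#' @param path COLVAR file.
#' @param time_column name of the time column used for de-duplication
#'   (default `"time"`; skipped if absent).
#' @return A `colvar_table` (data frame of numeric columns).
#' @export
read_colvar <- function(path, time_column = "time") {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#! FIELDS"))
    parse_error(path, 1L, "missing '#! FIELDS' header")
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[1L])), "\\s+")[[1L]]
  nc <- length(fields)
  rows <- vector("list", length(lines)); nr <- 0L
  for (i in seq_along(lines)[-1L]) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#! FIELDS")) {
      f2 <- strsplit(trimws(sub("^#! FIELDS", "", ln)), "\\s+")[[1L]]
      if (!identical(f2, fields))
        parse_error(path, i, "restart FIELDS header differs from the first header")
      next
    }
    if (startsWith(ln, "#")) next
    vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
    if (length(vals) != nc || anyNA(vals))
      parse_error(path, i, sprintf("expected %d numeric values", nc))
    nr <- nr + 1L
    rows[[nr]] <- vals
  }
  if (nr == 0L) parse_error(path, length(lines), "no data rows")
  m <- do.call(rbind, rows[seq_len(nr)])
  colnames(m) <- fields
  df <- as.data.frame(m)
  if (time_column %in% fields) {
    keep <- !duplicated(df[[time_column]], fromLast = TRUE)
    df <- df[keep, , drop = FALSE]
    df <- df[order(df[[time_column]]), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("colvar_table", "data.frame")
  df
}

#' Write a COLVAR table
#'
#' Values are written with 12 significant digits, so a
#' read/write round trip is lossless at that precision.
#'
#' @param table data frame of numeric columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(table, path) {
  header <- paste("#! FIELDS", paste(colnames(table), collapse = " "))
  body <- do.call(paste, lapply(table, function(col) sprintf("%.12g", col)))
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- reference PDB with weights -------------------------------------------

#' Write a PLUMED-style reference PDB with alignment/measure weights
#'
#' Fixed-width PDB (Angstrom) where the occupancy column is 1 for atoms
#' in the `align` selection (0 otherwise) and the temperature-factor
#' column is 1 for atoms in the `measure` selection -- the weight dialect
#' engines use to separate the superposition fit from the displacement
#' measure.
#'
#' @param structure a [cv_structure()].
#' @param align,measure atom index selections (default: all atoms).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_pdb <- function(structure, align = NULL, measure = NULL, path) {
  n <- n_atoms(structure)
  align <- if (is.null(align)) seq_len(n) else check_selection(align, n, "align")
  measure <- if (is.null(measure)) align else check_selection(measure, n, "measure")
  occ <- as.numeric(seq_len(n) %in% align)
  b <- as.numeric(seq_len(n) %in% measure)
  write_pdb(structure, path, occupancy = occ, bfactor = b)
}

#' Read back a weighted reference PDB
#'
#' @param path file written by [write_reference_pdb()].
#' @return List with `structure`, `align` and `measure` selections.
#' @export
read_reference_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  s <- cv_structure(pdb$atom$elety, pdb$atom$resno,
                    cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z) / 10)
  list(structure = s,
       align = which(pdb$atom$o > 0.5),
       measure = which(pdb$atom$b > 0.5))
}

# ---- engine input emission ------------------------------------------------

fmt6 <- function(x) sprintf("%.6g", x)

# per-milestone squared-distance expression in variables x, y
epath_d2_terms <- function(milestones) {
  sprintf("((x-%s)^2+(y-%s)^2)", fmt6(milestones[, 1]), fmt6(milestones[, 2]))
}

#' Emit PLUMED input implementing an EPATH CV
#'
#' Generates deterministic engine input text: two superposition-RMSD
#' variables against written reference PDBs, explicit arithmetic
#' expressions for the progress `s` and deviation `z` over the milestone
#' tuples (constants embedded with 6 significant digits), and restraint
#' blocks mirroring [restraint_energy()].  Output is byte-identical for
#' identical inputs.
#'
#' @param path an EPATH `path_definition`.
#' @param inactive,active the end-state reference [cv_structure()]s.
#' @param dir if non-`NULL`, directory where `plumed.dat`,
#'   `ref_inactive.pdb` and `ref_active.pdb` are written.
#' @param restraints optional restraint spec list
#'   ([restraint_harmonic()] / [restraint_wall()]).
#' @param colvar_stride stride (steps) for the PRINT action.
#' @return The input text as a character vector of lines (invisibly when
#'   `dir` is given).
#' @export
write_epath_plumed <- function(path, inactive, active, dir = NULL,
                               restraints = NULL, colvar_stride = 500L) {
  stopifnot(inherits(path, "path_definition"))
  if (path$flavor != "EPATH") stop("path flavor must be EPATH")
  m <- path$milestones
  n <- nrow(m)
  lam <- fmt6(path$lambda)
  d2 <- epath_d2_terms(m)
  wsum <- paste(sprintf("exp(-%s*%s)", lam, d2), collapse = "+")
  num <- paste(sprintf("%d*exp(-%s*%s)", seq_len(n), lam, d2), collapse = "+")
  lines <- c(
    "# PLUMED input generated by epathcv (dialect: PLUMED 2.9)",
    sprintf("# EPATH: %d milestones, lambda = %s nm^-2", n, lam),
    "UNITS LENGTH=nm",
    "rmsd_inactive: RMSD REFERENCE=ref_inactive.pdb TYPE=OPTIMAL",
    "rmsd_active: RMSD REFERENCE=ref_active.pdb TYPE=OPTIMAL",
    paste0("s: CUSTOM ARG=rmsd_inactive,rmsd_active VAR=x,y PERIODIC=NO FUNC=(",
           num, ")/(", wsum, ")"),
    paste0("z: CUSTOM ARG=rmsd_inactive,rmsd_active VAR=x,y PERIODIC=NO FUNC=-(1/",
           lam, ")*log(", wsum, ")"))
  k <- 0L
  for (r in restraints %||% list()) {
    k <- k + 1L
    if (r$type == "harmonic") {
      # cosine taper written with portable step()/cos() only
      tp <- fmt6(min(r$taper, (r$s_hi - r$s_lo) / 2))
      w <- sprintf(paste0("step(s-%s)*step(%s-s)*(step(s-%s)*step(%s-s)",
                          "+step(%s-s)*0.5*(1-cos(pi*(s-%s)/%s))",
                          "+step(s-%s)*0.5*(1-cos(pi*(%s-s)/%s)))"),
                   fmt6(r$s_lo), fmt6(r$s_hi),
                   fmt6(r$s_lo + as.numeric(tp)), fmt6(r$s_hi - as.numeric(tp)),
                   fmt6(r$s_lo + as.numeric(tp)), fmt6(r$s_lo), tp,
                   fmt6(r$s_hi - as.numeric(tp)), fmt6(r$s_hi), tp)
      lines <- c(lines,
                 sprintf("rest%d: CUSTOM ARG=s,%s VAR=s,x PERIODIC=NO FUNC=%s*%s*(x-%s)^2",
                         k, r$cv, w, fmt6(r$kappa), fmt6(r$center)),
                 sprintf("BIASVALUE ARG=rest%d LABEL=restbias%d", k, k))
    } else if (r$type == "upper_wall") {
      lines <- c(lines,
                 sprintf("UPPER_WALLS ARG=%s AT=%s KAPPA=%s LABEL=wall%d",
                         r$cv, fmt6(r$at), fmt6(r$kappa), k))
    }
  }
  lines <- c(lines,
             sprintf("PRINT ARG=* STRIDE=%d FILE=COLVAR", as.integer(colvar_stride)))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_reference_pdb(inactive, path$align, path$measure,
                        file.path(dir, "ref_inactive.pdb"))
    write_reference_pdb(active, path$align, path$measure,
                        file.path(dir, "ref_active.pdb"))
    writeLines(lines, file.path(dir, "plumed.dat"))
    return(invisible(lines))
  }
  lines
}

#' Extract and evaluate a FUNC expression from emitted engine input
#'
#' Pulls the `FUNC=` arithmetic of a labelled CUSTOM action out of
#' [write_epath_plumed()] output and evaluates it at the given
#' `(rmsd_inactive, rmsd_active)` point using R's own expression parser
#' -- an interpreter independent of [epath_sz()], used for round-trip
#' checks.
#'
#' @param lines character vector of emitted input lines.
#' @param label action label (`"s"` or `"z"`).
#' @param x,y the two RMSD values in nm.
#' @return Numeric value of the expression.
#' @export
eval_plumed_func <- function(lines, label, x, y) {
  ln <- grep(sprintf("^%s: CUSTOM ", label), lines, value = TRUE)
  if (length(ln) != 1L) stop(sprintf("no unique CUSTOM action labelled '%s'", label))
  func <- sub(".*FUNC=", "", ln)
  eval(parse(text = func), list(x = x, y = y, pi = pi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
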