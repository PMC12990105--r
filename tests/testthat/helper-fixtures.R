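# Programmatic fixtures shared across test files.

# random compact structure with n atoms (coordinates ~ 0.3 nm scale)
random_structure <- function(n, sd = 0.3) {
  cv_structure(rep("CA", n), seq_len(n), matrix(rnorm(3 * n, sd = sd), ncol = 3))
}

# apply a random proper rotation + translation to a coordinate matrix
rigid_move <- function(xyz, angle = NULL, shift = NULL) {
  if (is.null(angle)) angle <- runif(3, -pi, pi)
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
  R <- Rz(angle[1]) %*% Ry(angle[2]) %*% Rz(angle[3])
  if (is.null(shift)) shift <- rnorm(3)
  sweep(xyz %*% R, 2, shift, `+`)
}

# five-residue toy chain with N/CA/C atoms per residue
toy_chain_pdb_lines <- function() {
  lines <- c()
  serial <- 0L
  for (r in 1:5) {
    for (at in c("N", "CA", "C")) {
      serial <- serial + 1L
      x <- r * 3.8 + ifelse(at == "N", -0.5, ifelse(at == "C", 0.5, 0))
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, at, r, x, 2.0, 3.0, substr(at, 1, 1)))
    }
  }
  c(lines, "END")
}

write_tmp_lines <- function(lines, ext = ".pdb") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# multi-model PDB text with k single-atom models
multimodel_pdb_lines <- function(k) {
  out <- c()
  for (m in seq_len(k)) {
    out <- c(out, sprintf("MODEL     %4d", m),
             sprintf("ATOM      1  CA  ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
                     m * 1.0, 0, 0),
             "ENDMDL")
  }
  c(out, "END")
}

# trajectory whose frames are supplied coordinate matrices
traj_from_frames <- function(frames) {
  n <- nrow(frames[[1]])
  cv_trajectory(cv_structure(rep("CA", n), seq_len(n), frames[[1]]), frames)
}

# trajectory of frames scattered around a set of well-separated
# conformer templates; `which` gives the template id per frame
conformer_trajectory <- function(templates, which, jitter = 0.005) {
  frames <- lapply(which, function(k)
    templates[[k]] + matrix(rnorm(length(templates[[k]]), sd = jitter),
                            ncol = 3))
  traj_from_frames(frames)
}
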