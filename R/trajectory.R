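#' Coarse-grained trajectory container
#'
#' Ordered coordinate frames for a fixed set of labeled particles. Used for
#' one-bead-per-residue ensembles from the simulator and for backbone atoms
#' read from multi-model PDB files.
#'
#' @param frames Numeric array `[n_frames, n_atoms, 3]` (Angstrom), or a
#'   single `n_atoms x 3` matrix for a one-frame trajectory.
#' @param resid Integer residue ids (1-based numbering), one per atom.
#' @param resname,atom,element Optional per-atom labels (recycled).
#' @param stride Frame stride metadata (simulation steps between frames).
#' @return Object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(frames, resid, resname = "GLY", atom = "CA",
                          element = "C", stride = 1L) {
  if (is.matrix(frames)) frames <- array(frames, c(1, dim(frames)))
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3)
  n_atoms <- dim(frames)[2]
  stopifnot(length(resid) == n_atoms)
  structure(
    list(frames = frames, resid = as.integer(resid),
         resname = rep_len(resname, n_atoms), atom = rep_len(atom, n_atoms),
         element = rep_len(element, n_atoms), stride = as.integer(stride)),
    class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory>", n_frames(x), "frames x", length(x$resid),
      "atoms (stride", x$stride, ")\n")
  invisible(x)
}

#' @rdname cg_trajectory
#' @param traj A `cg_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' @rdname cg_trajectory
#' @param f Frame index.
#' @return `traj_frame()`: an `n_atoms x 3` coordinate matrix.
#' @export
traj_frame <- function(traj, f) {
  m <- traj$frames[f, , , drop = FALSE]
  dim(m) <- dim(traj$frames)[2:3]
  m
}

# frames restricted to a set of frame indices
traj_subset <- function(traj, frames_idx) {
  out <- traj
  out$frames <- traj$frames[frames_idx, , , drop = FALSE]
  out
}

#' @rdname cg_trajectory
#' @param x A `cg_trajectory`.
#' @param ... Unused.
#' @method as_tibble cg_trajectory
#' @export
as_tibble.cg_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  na <- length(x$resid)
  xs <- as.numeric(t(x$frames[, , 1]))
  ys <- as.numeric(t(x$frames[, , 2]))
  zs <- as.numeric(t(x$frames[, , 3]))
  tibble(frame = rep(seq_len(nf), each = na),
         resid = rep(x$resid, nf),
         x = xs, y = ys, z = zs)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, one ATOM record per bead, residue ids
#' preserved. (Written directly because bio3d's writer emits single-model
#' files only; the output is readable by `bio3d::read.pdb(multi = TRUE)`.)
#'
#' @param traj A [cg_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  na <- length(traj$resid)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- traj_frame(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s%-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(na), substr(traj$atom, 1, 4), substr(traj$resname, 1, 4),
      traj$resid, m[, 1], m[, 2], m[, 3], traj$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a trajectory
#'
#' Uses `bio3d::read.pdb(multi = TRUE)` when bio3d is installed, otherwise a
#' minimal fixed-column ATOM/MODEL reader with identical output.
#'
#' @param path PDB file path.
#' @return A [cg_trajectory()].
#' @export
read_trajectory_pdb <- function(path) {
  if (requireNamespace("bio3d", quietly = TRUE)) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
    na <- ncol(xyz) / 3
    frames <- array(NA_real_, c(nrow(xyz), na, 3))
    for (d in 1:3) frames[, , d] <- xyz[, seq(d, ncol(xyz), by = 3)]
    return(cg_trajectory(frames, resid = pdb$atom$resno,
                         resname = pdb$atom$resid, atom = pdb$atom$elety,
                         element = ifelse(is.na(pdb$atom$elesy) |
                                            pdb$atom$elesy == "",
                                          substr(pdb$atom$elety, 1, 1),
                                          pdb$atom$elesy)))
  }
  lines <- readLines(path)
  atom <- grepl("^ATOM  ", lines)
  model_starts <- which(grepl("^MODEL", lines))
  if (length(model_starts) == 0) model_starts <- 1
  first_block <- lines[atom & seq_along(lines) <
                         c(model_starts, length(lines) + 1)[2]]
  rec <- lines[atom]
  n_per <- length(first_block)
  nf <- length(rec) / n_per
  xyz <- cbind(as.numeric(substr(rec, 31, 38)),
               as.numeric(substr(rec, 39, 46)),
               as.numeric(substr(rec, 47, 54)))
  frames <- array(NA_real_, c(nf, n_per, 3))
  for (d in 1:3) frames[, , d] <- matrix(xyz[, d], nrow = nf, byrow = TRUE)
  cg_trajectory(frames,
                resid = as.integer(substr(first_block, 23, 26)),
                resname = trimws(substr(first_block, 18, 21)),
                atom = trimws(substr(first_block, 13, 16)),
                element = trimws(substr(first_block, 77, 78)))
}

#' Plain XYZ trajectory I/O
#'
#' Simple multi-frame XYZ: per frame an atom count line, a comment line, and
#' `element x y z` rows. Residue ids are carried in the comment line so the
#' round trip is lossless for bead models.
#'
#' @param traj A [cg_trajectory()].
#' @param path File path.
#' @return `write_trajectory_xyz()`: `path` invisibly;
#'   `read_trajectory_xyz()`: a [cg_trajectory()].
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- length(traj$resid)
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(na), con)
    writeLines(paste("frame", f, "resid",
                     paste(traj$resid, collapse = ",")), con)
    m <- traj_frame(traj, f)
    writeLines(sprintf("%-2s %17.9f %17.9f %17.9f",
                       traj$element, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  na <- as.integer(lines[1])
  block <- na + 2L
  nf <- length(lines) %/% block
  resid <- as.integer(strsplit(sub(".*resid ", "", lines[2]), ",")[[1]])
  frames <- array(NA_real_, c(nf, na, 3))
  elem <- character(na)
  for (f in seq_len(nf)) {
    rows <- lines[((f - 1) * block + 3):((f - 1) * block + 2 + na)]
    parts <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
    if (f == 1) elem <- parts[, 1]
    frames[f, , ] <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
  }
  cg_trajectory(frames, resid = resid, element = elem)
}
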