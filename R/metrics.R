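#' Kabsch least-squares rigid superposition
#'
#' Optimal proper rotation and translation minimizing the RMSD between two
#' coordinate sets (SVD with determinant correction, so reflections are
#' excluded).
#'
#' @param mobile,reference `n x 3` coordinate matrices.
#' @param fit_idx Optional row indices used for the fit (the returned
#'   transform still applies to all rows); default: all.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `sweep(mobile %*% rotation, 2, -translation)`), and
#'   `rmsd` over the fitted points after superposition.
#' @export
kabsch_superpose <- function(mobile, reference, fit_idx = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3)
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(mobile))
  if (length(fit_idx) < 3) abort("need at least 3 fitted points")
  a <- mobile[fit_idx, , drop = FALSE]
  b <- reference[fit_idx, , drop = FALSE]
  if (nrow(a) != nrow(b)) abort("fitted point counts differ")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  sv <- svd(crossprod(a0, b0))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)) {
    abort("degenerate (collinear) fit selection")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  translation <- cb - as.numeric(ca %*% rot)
  fitted <- sweep(a0 %*% rot, 2, cb, "+")
  list(rotation = rot, translation = translation,
       rmsd = sqrt(mean(rowSums((fitted - b)^2))))
}

# apply a kabsch result to full coordinates
apply_superposition <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, fit$translation, "+")
}

resolve_selection <- function(traj, selection, what = "selection") {
  if (is.null(selection)) return(seq_along(traj$resid))
  idx <- which(traj$resid %in% selection)
  if (length(idx) == 0) {
    abort(sprintf("%s resolves to no atoms (missing ids: %s)", what,
                  paste(setdiff(selection, traj$resid), collapse = ", ")))
  }
  missing <- setdiff(selection, traj$resid)
  if (length(missing) > 0) {
    abort(sprintf("%s ids missing from trajectory: %s", what,
                  paste(missing, collapse = ", ")))
  }
  idx
}

#' Per-frame RMSD of a residue subset after superposition on a reference
#'
#' Each frame is rigidly superposed on the reference over `fit_selection`
#' (by default the whole chain) and the RMSD is then measured over
#' `measure_selection` — e.g. fit on the full domain, measure over the
#' 11-residue hydrophobic core.
#'
#' @param traj A [cg_trajectory()].
#' @param reference `n x 3` matrix or a one-frame [cg_trajectory()]
#'   (default: the first frame of `traj`).
#' @param fit_selection,measure_selection Residue-id vectors (`NULL` = all).
#' @return Tibble with columns `frame`, `rmsd` (Angstrom).
#' @export
subset_rmsd <- function(traj, reference = NULL, fit_selection = NULL,
                        measure_selection = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  ref <- reference_coords(traj, reference)
  fit_idx <- resolve_selection(traj, fit_selection, "fit_selection")
  ms_idx <- resolve_selection(traj, measure_selection, "measure_selection")
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- traj_frame(traj, f)
    sup <- kabsch_superpose(m, ref, fit_idx)
    mm <- apply_superposition(m, sup)
    sqrt(mean(rowSums((mm[ms_idx, , drop = FALSE] -
                         ref[ms_idx, , drop = FALSE])^2)))
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)), rmsd = out)
}

reference_coords <- function(traj, reference) {
  if (is.null(reference)) return(traj_frame(traj, 1))
  if (inherits(reference, "cg_trajectory")) return(traj_frame(reference, 1))
  if (is.list(reference) && !is.null(reference$coords)) {
    return(reference$coords)
  }
  stopifnot(is.matrix(reference), ncol(reference) == 3)
  reference
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are first superposed on the initial frame over `fit_selection`,
#' the mean structure is computed, every frame is re-superposed on that mean
#' (one iteration), and
#' \deqn{RMSF_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}}
#' is reported for the residues in `selection`.
#'
#' @inheritParams subset_rmsd
#' @param selection Residue ids to report (`NULL` = all).
#' @return Tibble with columns `resid`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = NULL, fit_selection = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2) abort("RMSF needs at least 2 frames")
  fit_idx <- resolve_selection(traj, fit_selection, "fit_selection")
  sel_idx <- resolve_selection(traj, selection, "selection")
  ref <- traj_frame(traj, 1)
  aligned <- lapply(seq_len(nf), function(f) {
    m <- traj_frame(traj, f)
    apply_superposition(m, kabsch_superpose(m, ref, fit_idx))
  })
  mean_struct <- Reduce(`+`, aligned) / nf
  aligned <- lapply(aligned, function(m) {
    apply_superposition(m, kabsch_superpose(m, mean_struct, fit_idx))
  })
  mean_struct <- Reduce(`+`, aligned) / nf
  msd <- Reduce(`+`, lapply(aligned, function(m) {
    rowSums((m - mean_struct)^2)
  })) / nf
  tibble(resid = traj$resid[sel_idx], rmsf = sqrt(msd[sel_idx]))
}

#' Hydrogen-bond acceptance criterion
#'
#' Geometric hydrogen-bond test: presence in a frame requires
#' donor-hydrogen-to-acceptor distance at or below `max_distance` and
#' donor-H-acceptor angle at or above `min_angle`. `distance_mode =
#' "heavy"` measures the (more conventional) donor-heavy-atom-to-acceptor
#' distance instead. For one-bead-per-residue trajectories a distance-only
#' surrogate on the residue pair is used with `surrogate_cutoff`.
#'
#' @param max_distance Angstrom (default 3.6).
#' @param min_angle Degrees at the hydrogen (default 135).
#' @param acceptor_elements Allowed acceptor elements.
#' @param distance_mode `"hydrogen"` (default, literal H-to-acceptor) or
#'   `"heavy"`.
#' @param surrogate_cutoff Bead-pair distance cutoff (Angstrom) in
#'   coarse-grained mode.
#' @return Object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_distance = 3.6, min_angle = 135,
                            acceptor_elements = c("C", "O", "N", "F", "S"),
                            distance_mode = c("hydrogen", "heavy"),
                            surrogate_cutoff = 7) {
  stopifnot(max_distance > 0, min_angle > 0, min_angle <= 180,
            surrogate_cutoff > 0)
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 acceptor_elements = acceptor_elements,
                 distance_mode = match.arg(distance_mode),
                 surrogate_cutoff = surrogate_cutoff),
            class = "hbond_criterion")
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For all-atom input, `donor` names the donor heavy atom and its hydrogen
#' and `acceptor` the acceptor atom; presence per frame requires both the
#' distance and the angle cutoff of the [hbond_criterion()]. For
#' one-bead-per-residue input (single atom per residue), `donor` and
#' `acceptor` are residue ids and a distance-only surrogate criterion on
#' the bead pair applies. Occupancy is `100 * present / total` percent.
#'
#' @param traj A [cg_trajectory()].
#' @param donor For atomistic input `list(resid =, heavy =, hydrogen =)`;
#'   for bead input a residue id.
#' @param acceptor For atomistic input `list(resid =, atom =)`; for bead
#'   input a residue id.
#' @param criterion A [hbond_criterion()].
#' @return List with `occupancy` (percent) and `presence`
#'   (tibble `frame`, `present`).
#' @export
hbond_occupancy <- function(traj, donor, acceptor,
                            criterion = hbond_criterion()) {
  stopifnot(inherits(traj, "cg_trajectory"),
            inherits(criterion, "hbond_criterion"))
  bead_mode <- !anyDuplicated(traj$resid)
  nf <- n_frames(traj)
  if (bead_mode && !is.list(donor)) {
    di <- resolve_selection(traj, donor, "donor")
    ai <- resolve_selection(traj, acceptor, "acceptor")
    present <- vapply(seq_len(nf), function(f) {
      m <- traj_frame(traj, f)
      sqrt(sum((m[di, ] - m[ai, ])^2)) <= criterion$surrogate_cutoff
    }, logical(1))
  } else {
    find_atom <- function(resid, name) {
      idx <- which(traj$resid == resid & traj$atom == name)
      if (length(idx) != 1) {
        abort(sprintf("atom %s of residue %d not found uniquely", name, resid))
      }
      idx
    }
    hi <- find_atom(donor$resid, donor$hydrogen)
    dyi <- find_atom(donor$resid, donor$heavy)
    ai <- find_atom(acceptor$resid, acceptor$atom)
    if (!traj$element[ai] %in% criterion$acceptor_elements) {
      abort(sprintf("acceptor element '%s' not in allowed set (%s)",
                    traj$element[ai],
                    paste(criterion$acceptor_elements, collapse = ", ")))
    }
    present <- vapply(seq_len(nf), function(f) {
      m <- traj_frame(traj, f)
      v_hd <- m[dyi, ] - m[hi, ]   # H -> donor heavy
      v_ha <- m[ai, ] - m[hi, ]    # H -> acceptor
      dist <- if (criterion$distance_mode == "hydrogen") {
        sqrt(sum(v_ha^2))
      } else {
        sqrt(sum((m[ai, ] - m[dyi, ])^2))
      }
      ang <- acos(pmin(pmax(sum(v_hd * v_ha) /
                              (sqrt(sum(v_hd^2)) * sqrt(sum(v_ha^2))),
                            -1), 1)) * 180 / pi
      dist <= criterion$max_distance && ang >= criterion$min_angle
    }, logical(1))
  }
  list(occupancy = 100 * mean(present),
       presence = tibble(frame = seq_len(nf), present = present))
}

#' Per-residue secondary-structure fractions from virtual C-alpha geometry
#'
#' Classifies each residue per frame by its virtual bond angle
#' `theta(i) = angle(r[i-1], r[i], r[i+1])` and virtual dihedral
#' `alpha(i) = dihedral(r[i-1], r[i], r[i+1], r[i+2])`:
#' helix for `theta` in [75, 115] degrees and `alpha` in [25, 100] (the
#' right-handed helical region, ideal values about 91 and 50), sheet for
#' `theta` in [100, 155] and `|alpha|` in [120, 180] (extended), coil
#' otherwise. Chain-terminal residues (incomplete window) and residues
#' adjacent to a chain break (consecutive-bead distance above
#' `break_distance`) are coil, the latter with a warning. Fractions over
#' frames sum to one per residue.
#'
#' @param traj A [cg_trajectory()] with one bead per residue.
#' @param selection Residue ids to report (`NULL` = all).
#' @param break_distance Chain-break threshold, Angstrom.
#' @return Tibble with columns `resid`, `helix`, `sheet`, `coil`.
#' @export
secondary_structure_fraction <- function(traj, selection = NULL,
                                         break_distance = 4.5) {
  stopifnot(inherits(traj, "cg_trajectory"))
  n <- length(traj$resid)
  if (n < 4) abort("need at least 4 consecutive residues")
  nf <- n_frames(traj)
  counts <- matrix(0L, n, 3, dimnames = list(NULL, c("helix", "sheet", "coil")))
  warned_break <- FALSE
  for (f in seq_len(nf)) {
    m <- traj_frame(traj, f)
    b <- m[-1, , drop = FALSE] - m[-n, , drop = FALSE]   # bond vectors
    blen <- sqrt(rowSums(b^2))
    broken <- blen > break_distance
    # theta at residues 2..n-1
    u1 <- -b[seq_len(n - 2), , drop = FALSE]
    u2 <- b[2:(n - 1), , drop = FALSE]
    cth <- rowSums(u1 * u2) / (sqrt(rowSums(u1^2)) * sqrt(rowSums(u2^2)))
    theta <- acos(pmin(pmax(cth, -1), 1)) * 180 / pi
    # dihedral at residues 2..n-2 (window i-1..i+2)
    b1 <- b[seq_len(n - 3), , drop = FALSE]
    b2 <- b[2:(n - 2), , drop = FALSE]
    b3 <- b[3:(n - 1), , drop = FALSE]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    b2h <- b2 / sqrt(rowSums(b2^2))
    alpha <- atan2(rowSums(cross3(n1, n2) * b2h),
                   rowSums(n1 * n2)) * 180 / pi
    cls <- rep(3L, n)  # coil
    for (i in 2:(n - 2)) {
      if (any(broken[max(1, i - 1):min(n - 1, i + 1)])) {
        warned_break <- TRUE
        next
      }
      th <- theta[i - 1]; al <- alpha[i - 1]
      if (th >= 75 && th <= 115 && al >= 25 && al <= 100) {
        cls[i] <- 1L
      } else if (th >= 100 && th <= 155 && abs(al) >= 120) {
        cls[i] <- 2L
      }
    }
    counts[cbind(seq_len(n), cls)] <- counts[cbind(seq_len(n), cls)] + 1L
  }
  if (warned_break) warn("chain break(s) detected; adjacent residues set to coil")
  sel_idx <- resolve_selection(traj, selection, "selection")
  tibble(resid = traj$resid[sel_idx],
         helix = counts[sel_idx, "helix"] / nf,
         sheet = counts[sel_idx, "sheet"] / nf,
         coil = counts[sel_idx, "coil"] / nf)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-frame distance between two selection centroids
#'
#' Euclidean distance between the unweighted centres of geometry of two
#' residue selections, e.g. the beta segments 198-200 and 206-208.
#'
#' @param traj A [cg_trajectory()].
#' @param selection_a,selection_b Residue-id vectors.
#' @return Tibble with columns `frame`, `distance` (Angstrom).
#' @export
segment_distance <- function(traj, selection_a, selection_b) {
  stopifnot(inherits(traj, "cg_trajectory"))
  ia <- resolve_selection(traj, selection_a, "selection_a")
  ib <- resolve_selection(traj, selection_b, "selection_b")
  d <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- traj_frame(traj, f)
    sqrt(sum((colMeans(m[ia, , drop = FALSE]) -
                colMeans(m[ib, , drop = FALSE]))^2))
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)), distance = d)
}

#' Per-frame radius of gyration of a selection
#'
#' Used as the operational readout for "loop widening": the unweighted
#' radius of gyration of the loop's beads.
#'
#' @param traj A [cg_trajectory()].
#' @param selection Residue ids.
#' @return Tibble with columns `frame`, `rg` (Angstrom).
#' @export
selection_gyration <- function(traj, selection) {
  stopifnot(inherits(traj, "cg_trajectory"))
  idx <- resolve_selection(traj, selection, "selection")
  rg <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- traj_frame(traj, f)[idx, , drop = FALSE]
    sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)), rg = rg)
}
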