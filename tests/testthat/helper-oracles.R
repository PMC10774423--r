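# Independent oracles used across the suite. Each deliberately uses a
# different algorithm than the package implementation it checks.

# Eq.-style fluctuation correlation by an explicit double loop
brute_force_correlation <- function(x, y, dt, lag) {
  n <- length(x)
  k <- as.integer(round(lag / dt))
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  acc <- 0
  for (t in seq_len(n - k)) acc <- acc + dx[t] * dy[t + k]
  1 + (acc / (n - k)) / (mx * my)
}

# rotation about z by theta degrees
rot_z <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# brute-force 1-degree grid search over z-rotations (for planar toys whose
# optimal superposition is a rotation about z)
grid_min_rmsd_z <- function(mobile, reference) {
  best <- Inf
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a0 <- sweep(mobile, 2, cm); b0 <- sweep(reference, 2, cr)
  for (deg in 0:359) {
    r <- a0 %*% rot_z(deg)
    best <- min(best, sqrt(mean(rowSums((r - b0)^2))))
  }
  best
}

# Horn's closed-form quaternion absolute orientation (independent of the
# SVD-based Kabsch path); returns RMSD after optimal superposition
horn_rmsd <- function(mobile, reference) {
  a0 <- sweep(mobile, 2, colMeans(mobile))
  b0 <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(a0, b0)
  sxx <- M[1, 1]; sxy <- M[1, 2]; sxz <- M[1, 3]
  syx <- M[2, 1]; syy <- M[2, 2]; syz <- M[2, 3]
  szx <- M[3, 1]; szy <- M[3, 2]; szz <- M[3, 3]
  N <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  sqrt(mean(rowSums((a0 %*% t(R) - b0)^2)))
}

# small helical / extended ideal C-alpha geometries
ideal_helix_coords <- function(n, rise = 1.5, radius = 2.3,
                               twist_deg = 100) {
  th <- (seq_len(n) - 1) * twist_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
}

ideal_extended_coords <- function(n, step = 3.5, wobble = 0.9) {
  cbind((seq_len(n) - 1) * step,
        wobble * rep_len(c(0, 1), n),
        rep(0, n))
}

# random rigid transform applied to every frame of a trajectory
random_rigid_transform <- function(traj, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3)
  R <- Rx %*% Ry %*% Rz
  tr <- runif(3, -20, 20)
  out <- traj
  for (f in seq_len(n_frames(traj))) {
    out$frames[f, , ] <- sweep(traj_frame(traj, f) %*% R, 2, tr, "+")
  }
  out
}

# tiny chain model for dynamics/REMD toys (hand-built cg_model)
toy_chain_model <- function(n = 5, spacing = 3.8, eps = 0.7) {
  coords <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  # slight zig-zag so contacts exist
  coords[, 2] <- rep_len(c(0, 1.8), n)
  rownames(coords) <- seq_len(n)
  build_cg_model(list(resid = seq_len(n), coords = coords),
                 contact_cutoff = 2.1 * spacing, eps = eps)
}
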