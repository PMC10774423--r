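square4 <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))

test_that("superposition of identical and rigidly moved sets is exact", {
  fit <- kabsch_superpose(square4, square4)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  moved <- sweep(square4 %*% rot_z(90), 2, c(5, -3, 2), "+")
  fit2 <- kabsch_superpose(moved, square4)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
})

test_that("Kabsch matches the 1-degree brute-force rotation grid", {
  set.seed(31)
  noisy <- square4 %*% rot_z(37)
  noisy[, 1:2] <- noisy[, 1:2] + matrix(rnorm(8, sd = 0.15), 4, 2)
  k <- kabsch_superpose(noisy, square4)
  g <- grid_min_rmsd_z(noisy, square4)
  expect_lte(k$rmsd, g + 1e-12)
  expect_lt(abs(k$rmsd - g), 1e-3)
})

test_that("degenerate (collinear) fit selections error", {
  line <- cbind(0:3, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(square4[1:2, ], square4[1:2, ]),
               "at least 3")
})

test_that("subset RMSD is zero on reference copies and matches closed form", {
  ref <- bir2_reference()
  frames <- array(rep(ref$coords, each = 5), c(5, nrow(ref$coords), 3))
  traj <- cg_trajectory(frames, ref$resid)
  expect_equal(subset_rmsd(traj, ref$coords)$rmsd, rep(0, 5),
               tolerance = 1e-10)
  # displace one of k measured beads by 1 A; fit on a disjoint rigid set
  fit_ids <- 163:200
  measure_ids <- 205:214          # k = 10
  f2 <- ref$coords
  f2[match(210, ref$resid), 1] <- f2[match(210, ref$resid), 1] + 1
  traj2 <- cg_trajectory(f2, ref$resid)
  out <- subset_rmsd(traj2, ref$coords, fit_selection = fit_ids,
                     measure_selection = measure_ids)
  expect_equal(out$rmsd, 1 / sqrt(10), tolerance = 1e-10)
})

test_that("planted deformations match an independent quaternion oracle", {
  ref <- bir2_reference()
  n <- nrow(ref$coords)
  set.seed(55)
  frames <- array(NA_real_, c(8, n, 3))
  for (f in 1:8) {
    deform <- ref$coords + matrix(rnorm(n * 3, sd = 0.4), n, 3)
    frames[f, , ] <- sweep(deform %*% rot_z(runif(1, 0, 360)), 2,
                           runif(3, -9, 9), "+")
  }
  traj <- cg_trajectory(frames, ref$resid)
  got <- subset_rmsd(traj, ref$coords)$rmsd
  oracle <- vapply(1:8, function(f) horn_rmsd(frames[f, , ], ref$coords),
                   numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("subset_rmsd with measure = fit equals the Kabsch fit RMSD", {
  ref <- bir2_reference()
  set.seed(66)
  frames <- array(rep(ref$coords, each = 3), c(3, nrow(ref$coords), 3)) +
    array(rnorm(3 * nrow(ref$coords) * 3, sd = 0.5),
          c(3, nrow(ref$coords), 3))
  traj <- cg_trajectory(frames, ref$resid)
  ids <- load_selections(name = "hydrophobic_core")
  via_subset <- subset_rmsd(traj, ref$coords, fit_selection = ids,
                            measure_selection = ids)$rmsd
  direct <- vapply(1:3, function(f) {
    kabsch_superpose(traj_frame(traj, f), ref$coords,
                     which(ref$resid %in% ids))$rmsd
  }, numeric(1))
  expect_equal(via_subset, direct, tolerance = 1e-12)
})

test_that("RMSF is zero for a static trajectory and errors on one frame", {
  ref <- bir2_reference()
  frames <- array(rep(ref$coords, each = 4), c(4, nrow(ref$coords), 3))
  traj <- cg_trajectory(frames, ref$resid)
  expect_equal(rmsf(traj)$rmsf, rep(0, nrow(ref$coords)), tolerance = 1e-12)
  expect_error(rmsf(cg_trajectory(ref$coords, ref$resid)), "2 frames")
})

test_that("isotropic jitter yields RMSF = sigma * sqrt(3)", {
  # static anchor beads carry the superposition; jittered beads are measured
  anchor <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10),
                  c(10, 10, 0))
  nf <- 20000
  sigma <- 0.2
  set.seed(77)
  frames <- array(0, c(nf, 7, 3))
  for (f in seq_len(nf)) {
    frames[f, 1:5, ] <- anchor
    frames[f, 6, ] <- c(5, 5, 5) + rnorm(3, sd = sigma)
    frames[f, 7, ] <- c(2, 6, 3) + rnorm(3, sd = sigma)
  }
  traj <- cg_trajectory(frames, resid = 1:7)
  out <- rmsf(traj, selection = 6:7, fit_selection = 1:5)
  expect_equal(out$rmsf, rep(sigma * sqrt(3), 2), tolerance = 0.03)
})

test_that("metrics are invariant under a global rigid transform", {
  ref <- bir2_reference()
  set.seed(88)
  n <- nrow(ref$coords)
  frames <- array(rep(ref$coords, each = 6), c(6, n, 3)) +
    array(rnorm(6 * n * 3, sd = 0.3), c(6, n, 3))
  traj <- cg_trajectory(frames, ref$resid)
  moved <- random_rigid_transform(traj, seed = 4)
  sel <- load_selections()
  expect_equal(subset_rmsd(moved, ref$coords)$rmsd,
               subset_rmsd(traj, ref$coords)$rmsd, tolerance = 1e-9)
  expect_equal(rmsf(moved)$rmsf, rmsf(traj)$rmsf, tolerance = 1e-9)
  expect_equal(segment_distance(moved, sel$beta1, sel$beta2)$distance,
               segment_distance(traj, sel$beta1, sel$beta2)$distance,
               tolerance = 1e-9)
})

test_that("surrogate hydrogen-bond occupancy counts planted frames exactly", {
  # two beads, planted present in 250 of 1000 frames
  nf <- 1000
  frames <- array(0, c(nf, 4, 3))
  present <- seq_len(nf) <= 250
  for (f in seq_len(nf)) {
    frames[f, 2, ] <- c(3.8, 0, 0)
    frames[f, 3, ] <- c(7.6, 0, 0)
    frames[f, 4, ] <- if (present[f]) c(3.8, 5, 0) else c(3.8, 12, 0)
  }
  traj <- cg_trajectory(frames, resid = 166:169)
  res <- hbond_occupancy(traj, 166, 169)
  expect_equal(res$occupancy, 25)
  expect_identical(res$presence$present, present)
})

test_that("geometric criterion applies both distance and angle cutoffs", {
  # atomistic toy: donor N, its H, acceptor O, all in one line then bent
  mk <- function(o_pos) {
    frames <- array(0, c(1, 3, 3))
    frames[1, 2, ] <- c(1, 0, 0)        # H
    frames[1, 3, ] <- o_pos             # O
    cg_trajectory(frames, resid = c(166, 166, 185),
                  atom = c("N", "H", "O"), element = c("N", "H", "O"))
  }
  donor <- list(resid = 166, heavy = "N", hydrogen = "H")
  acceptor <- list(resid = 185, atom = "O")
  # linear geometry, H...O = 2.0 A -> present
  expect_equal(hbond_occupancy(mk(c(3, 0, 0)), donor, acceptor)$occupancy,
               100)
  # distance boundary: 3.7 A every frame -> 0 percent
  expect_equal(hbond_occupancy(mk(c(4.7, 0, 0)), donor, acceptor)$occupancy,
               0)
  # right-angle geometry fails the 135-degree angle cutoff
  expect_equal(hbond_occupancy(mk(c(1, 2, 0)), donor, acceptor)$occupancy,
               0)
  # heavy-atom distance convention measures N...O instead
  crit_heavy <- hbond_criterion(distance_mode = "heavy")
  expect_equal(hbond_occupancy(mk(c(3.5, 0, 0)), donor, acceptor,
                               crit_heavy)$occupancy, 100)
  expect_equal(hbond_occupancy(mk(c(3.7, 0, 0)), donor, acceptor,
                               crit_heavy)$occupancy, 0)
  # disallowed acceptor element
  bad <- mk(c(3, 0, 0)); bad$element[3] <- "P"
  expect_error(hbond_occupancy(bad, donor, acceptor), "acceptor element")
})

test_that("ideal helix and strand geometries classify as planted", {
  nf <- 4
  hel <- ideal_helix_coords(12)
  traj_h <- cg_trajectory(array(rep(hel, each = nf), c(nf, 12, 3)), 1:12)
  ss_h <- secondary_structure_fraction(traj_h)
  interior <- 3:9
  expect_equal(ss_h$helix[interior], rep(1, length(interior)))
  ext <- ideal_extended_coords(12)
  traj_e <- cg_trajectory(array(rep(ext, each = nf), c(nf, 12, 3)), 1:12)
  ss_e <- secondary_structure_fraction(traj_e)
  expect_equal(ss_e$sheet[interior], rep(1, length(interior)))
  # 50/50 planted mixture
  mix <- array(NA_real_, c(2, 12, 3))
  mix[1, , ] <- hel
  mix[2, , ] <- ext
  ss_m <- secondary_structure_fraction(cg_trajectory(mix, 1:12))
  expect_equal(ss_m$helix[interior], rep(0.5, length(interior)))
  expect_equal(ss_m$sheet[interior], rep(0.5, length(interior)))
  # fractions always sum to one
  expect_equal(ss_m$helix + ss_m$sheet + ss_m$coil, rep(1, 12))
})

test_that("chain breaks coerce adjacent residues to coil with a warning", {
  hel <- ideal_helix_coords(12)
  hel[8:12, 3] <- hel[8:12, 3] + 30
  traj <- cg_trajectory(hel, 1:12)
  expect_warning(ss <- secondary_structure_fraction(traj), "break")
  expect_equal(ss$coil[7:8], c(1, 1))
})

test_that("segment distances follow the centroid geometry", {
  frames <- array(0, c(1, 4, 3))
  frames[1, 2, ] <- c(3, 4, 0)
  frames[1, 3, ] <- c(50, 0, 0)
  frames[1, 4, ] <- c(50, 5, 0)
  traj <- cg_trajectory(frames, resid = 1:4)
  expect_equal(segment_distance(traj, 1, 1)$distance, 0)
  expect_equal(segment_distance(traj, 1, 2)$distance, 5)
  expect_error(segment_distance(traj, 1, 99), "selection_b")
  # radius of gyration of a 3-4-5 pair is half the separation
  expect_equal(selection_gyration(traj, 1:2)$rg, 2.5)
})
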