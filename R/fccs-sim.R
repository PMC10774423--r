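#' Confocal detection volume
#'
#' 3D Gaussian detection profile with lateral 1/e^2 radius `w0` and axial
#' half-length `z0 = s * w0`; per-channel center offsets allow imperfect
#' co-registration of the green and red volumes (default: perfectly
#' co-registered).
#'
#' @param w0 Lateral 1/e^2 radius in micrometres.
#' @param s Structural parameter z0/w0 (>= 1).
#' @param offset_green,offset_red Numeric length-3 centre offsets (um).
#' @return Object of class `detection_volume`.
#' @export
detection_volume <- function(w0 = 0.25, s = 5,
                             offset_green = c(0, 0, 0),
                             offset_red = c(0, 0, 0)) {
  stopifnot(w0 > 0, s >= 1, length(offset_green) == 3, length(offset_red) == 3)
  structure(list(w0 = w0, s = s, z0 = s * w0,
                 offset = list(green = offset_green, red = offset_red)),
            class = "detection_volume")
}

# effective confocal volume, um^3 (pi^(3/2) w0^2 z0)
effective_volume <- function(volume) {
  pi^1.5 * volume$w0^2 * volume$z0
}

#' Emitter species for the FCCS simulator
#'
#' @param label One of `"green_only"`, `"red_only"`, `"dual"`.
#' @param count Number of particles (>= 0).
#' @param diffusion Diffusion coefficient, um^2/s.
#' @param brightness Peak emission rate at the volume centre, photons/s per
#'   particle (applied in both channels for `"dual"` species).
#' @return One-row tibble; rows can be stacked with [dplyr::bind_rows()].
#' @export
fccs_species <- function(label = c("green_only", "red_only", "dual"),
                         count, diffusion, brightness = 100) {
  label <- match.arg(label)
  stopifnot(count >= 0, count == round(count), diffusion >= 0, brightness > 0)
  tibble(label = label, count = as.integer(count),
         diffusion = diffusion, brightness = brightness)
}

#' Expected diffusion time through the detection volume
#'
#' Standard FCS relation `tau_D = w0^2 / (4 D)`, used to validate fitted
#' diffusion times against the simulator's ground truth.
#'
#' @param volume A [detection_volume()].
#' @param D Diffusion coefficient, um^2/s.
#' @return Diffusion time in seconds.
#' @examples
#' expected_tau_d(detection_volume(w0 = 0.25), D = 25)  # 6.25e-4 s
#' @export
expected_tau_d <- function(volume, D) {
  stopifnot(inherits(volume, "detection_volume"), D > 0)
  volume$w0^2 / (4 * D)
}

#' Simulate two-channel FCCS intensity traces with known ground truth
#'
#' Brownian emitters (green-only, red-only and dual-labeled) diffuse through
#' a periodic cubic box; each channel's intensity is the sum of per-particle
#' 3D Gaussian detection weights
#' \eqn{B \exp(-2 r_{xy}^2 / w_0^2 - 2 z^2 / z_0^2)}.
#' Positions evolve by independent per-axis Gaussian steps of standard
#' deviation \eqn{\sqrt{2 D\, dt}} with periodic wrapping, preserving constant
#' concentration. Optional Poisson shot noise; off by default so estimator
#' checks are deterministic given the particle paths.
#'
#' @param species Tibble of [fccs_species()] rows.
#' @param volume A [detection_volume()].
#' @param box_size Cubic box edge, um; must be at least `10 * w0`.
#' @param duration Trace duration, seconds.
#' @param dt Sampling interval, seconds; the RMS per-axis step
#'   `sqrt(2 D dt)` must stay below `w0/5` for every species.
#' @param seed Integer RNG seed; recorded in the ground-truth metadata.
#' @param shot_noise If `TRUE`, per-bin intensities are replaced by
#'   `rpois(I * dt) / dt`.
#' @param start_at_center If `TRUE`, all particles start at the box origin
#'   (the volume centre) instead of uniformly at random; mainly for static
#'   (`diffusion = 0`) emitter checks.
#' @return List with `traces` (tibble `time`, `green`, `red`),
#'   `ground_truth` (tibble with expected in-volume particle numbers `n_g`,
#'   `n_r`, `n_c`, per-species diffusion time, and the seed), and `seed`.
#' @export
simulate_fccs_traces <- function(species, volume = detection_volume(),
                                 box_size, duration, dt, seed,
                                 shot_noise = FALSE, start_at_center = FALSE) {
  stopifnot(inherits(volume, "detection_volume"), is.data.frame(species))
  if (box_size < 10 * volume$w0) {
    abort("box_size must be at least 10 * w0 so the box dwarfs the volume")
  }
  bad <- sqrt(2 * species$diffusion * dt) >= volume$w0 / 5
  if (any(bad)) {
    abort(paste0("RMS step exceeds w0/5 for species: ",
                 paste(species$label[bad], collapse = ", "),
                 "; reduce dt"))
  }
  n_steps <- floor(duration / dt)
  stopifnot(n_steps >= 2)
  set.seed(seed)

  green <- numeric(n_steps)
  red <- numeric(n_steps)
  half <- box_size / 2

  for (r in seq_len(nrow(species))) {
    sp <- species[r, ]
    if (sp$count == 0) next
    sigma <- sqrt(2 * sp$diffusion * dt)
    # one matrix (n_steps x count) per axis: uniform start + Brownian cumsum
    pos <- lapply(1:3, function(ax) {
      start <- if (start_at_center) rep(0, sp$count) else
        runif(sp$count, -half, half)
      steps <- matrix(rnorm(n_steps * sp$count, sd = sigma),
                      nrow = n_steps, ncol = sp$count)
      steps[1, ] <- start
      p <- apply(steps, 2, cumsum)
      # periodic wrap into [-half, half)
      p - box_size * floor((p + half) / box_size)
    })
    for (ch in c("green", "red")) {
      emits <- (ch == "green" && sp$label %in% c("green_only", "dual")) ||
        (ch == "red" && sp$label %in% c("red_only", "dual"))
      if (!emits) next
      off <- volume$offset[[ch]]
      w <- exp(-2 * ((pos[[1]] - off[1])^2 + (pos[[2]] - off[2])^2) /
                 volume$w0^2 -
                 2 * (pos[[3]] - off[3])^2 / volume$z0^2)
      contrib <- sp$brightness * rowSums(w)
      if (ch == "green") green <- green + contrib else red <- red + contrib
    }
  }

  if (shot_noise) {
    green <- stats::rpois(n_steps, green * dt) / dt
    red <- stats::rpois(n_steps, red * dt) / dt
  }

  veff <- effective_volume(volume)
  conc_factor <- veff / box_size^3
  gt <- dplyr::mutate(
    as_tibble(species),
    expected_n = .data$count * conc_factor,
    tau_d = ifelse(.data$diffusion > 0,
                   volume$w0^2 / (4 * .data$diffusion), Inf))
  n_of <- function(labels) sum(gt$expected_n[gt$label %in% labels])
  ground_truth <- tibble(
    n_g = n_of(c("green_only", "dual")),
    n_r = n_of(c("red_only", "dual")),
    n_c = n_of("dual"),
    seed = seed)
  ground_truth <- dplyr::bind_cols(ground_truth,
                                   tidyr::nest(gt, species = dplyr::everything()))

  list(traces = tibble(time = (seq_len(n_steps) - 1) * dt,
                       green = green, red = red),
       ground_truth = ground_truth,
       seed = seed)
}
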