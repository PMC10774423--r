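#' Langevin dynamics parameters
#'
#' BAOAB Langevin integration settings for the coarse-grained model. The
#' defaults keep the nominal simulation constants: collision frequency
#' `gamma = 2.0` ps^-1 and a 0.002 ps (2 fs) time step.
#'
#' @param step Time step, ps.
#' @param gamma Friction (collision frequency), ps^-1.
#' @param mass Bead mass, amu (default 110, an average residue).
#' @return Object of class `langevin_params`.
#' @export
langevin_params <- function(step = 0.002, gamma = 2.0, mass = 110) {
  stopifnot(step > 0, gamma > 0, mass > 0)
  structure(list(step = step, gamma = gamma, mass = mass),
            class = "langevin_params")
}

#' Temperature replica ladder
#'
#' Ordered replica temperatures with exchange bookkeeping. The default is
#' the eight-rung ladder 300.00, 303.72, 307.48, 311.26, 315.08, 318.93,
#' 322.82, 325.00 K (about 3.7 K spacing) with exchanges attempted every
#' 5000 steps (10 ps at the 2 fs step).
#'
#' @param temperatures Strictly increasing temperatures, K.
#' @param exchange_interval Steps between exchange attempts.
#' @return Object of class `replica_ladder`.
#' @export
replica_ladder <- function(temperatures = c(300.00, 303.72, 307.48, 311.26,
                                            315.08, 318.93, 322.82, 325.00),
                           exchange_interval = 5000) {
  if (any(diff(temperatures) < 0)) {
    abort("ladder temperatures must be non-decreasing")
  }
  stopifnot(exchange_interval >= 1)
  structure(list(temperatures = temperatures,
                 exchange_interval = as.integer(exchange_interval)),
            class = "replica_ladder")
}

#' Potential energy of a configuration under the Go model
#'
#' @param coords `n x 3` coordinate matrix (or `NULL` for the model's
#'   reference coordinates).
#' @param model A [build_cg_model()] object.
#' @return List with `energy` (kcal/mol) and per-term breakdown `terms`.
#' @export
cg_energy <- function(coords = NULL, model) {
  if (is.null(coords)) coords <- model$coords
  cg_energy_cpp(coords, cg_pack(model))
}

# Maxwell-Boltzmann velocities, A/ps
sample_velocities <- function(n, temperature, mass) {
  matrix(rnorm(n * 3, sd = sqrt(kB_KCAL * temperature * 418.4 / mass)),
         ncol = 3)
}

#' Advance a state by Langevin dynamics
#'
#' `langevin_step()` performs a single BAOAB update; `run_langevin()` runs
#' many steps and records frames every `stride` steps. Both consume the R
#' random number stream, so results are bit-reproducible after `set.seed()`.
#'
#' @param state List with `coords` and `vel` (`n x 3` matrices); `vel` may be
#'   omitted, in which case Maxwell-Boltzmann velocities at `temperature`
#'   are drawn.
#' @param model A [build_cg_model()] object.
#' @param temperature Kelvin.
#' @param params A [langevin_params()] object.
#' @return `langevin_step()`: the updated state (with `potential`);
#'   `run_langevin()`: list with `trajectory` ([cg_trajectory()]),
#'   `energies` (tibble `frame`, `potential`), and the final `state`.
#' @export
langevin_step <- function(state, model, temperature, params = langevin_params()) {
  if (any(!is.finite(state$coords))) abort("non-finite coordinates")
  if (is.null(state$vel)) {
    state$vel <- sample_velocities(nrow(state$coords), temperature,
                                   params$mass)
  }
  out <- cg_langevin_cpp(state$coords, state$vel, cg_pack(model),
                         params$mass, params$step, params$gamma, temperature,
                         n_steps = 1L, stride = 0L)
  list(coords = out$coords, vel = out$vel, potential = out$potential)
}

#' @rdname langevin_step
#' @param n_steps Number of integration steps.
#' @param stride Record a frame every `stride` steps (0 records nothing).
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @export
run_langevin <- function(model, temperature, params = langevin_params(),
                         n_steps = 10000, stride = 100, seed = NULL,
                         state = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- list(coords = model$coords, vel = NULL)
  if (is.null(state$vel)) {
    state$vel <- sample_velocities(nrow(state$coords), temperature,
                                   params$mass)
  }
  out <- cg_langevin_cpp(state$coords, state$vel, cg_pack(model),
                         params$mass, params$step, params$gamma, temperature,
                         n_steps = as.integer(n_steps),
                         stride = as.integer(stride))
  traj <- if (!is.null(out$frames)) {
    cg_trajectory(out$frames, resid = model$resid, stride = stride)
  } else NULL
  list(trajectory = traj,
       energies = tibble(frame = seq_along(out$energies),
                         potential = as.numeric(out$energies)),
       state = list(coords = out$coords, vel = out$vel,
                    potential = out$potential))
}

#' Metropolis acceptance probability for a temperature exchange
#'
#' \deqn{p = \min(1, \exp[(\beta_m - \beta_n)(E_m - E_n)])}
#'
#' @param beta_m,beta_n Inverse temperatures, 1/(kB T), mol/kcal.
#' @param e_m,e_n Potential energies, kcal/mol.
#' @return Acceptance probability in [0, 1].
#' @export
exchange_acceptance_prob <- function(beta_m, beta_n, e_m, e_n) {
  min(1, exp((beta_m - beta_n) * (e_m - e_n)))
}

#' Attempt a replica exchange between two rungs
#'
#' Draws a uniform variate against the Metropolis probability of
#' [exchange_acceptance_prob()]; on acceptance the two replicas swap
#' temperatures (velocities are rescaled by callers as needed).
#'
#' @param replica_m,replica_n Lists with `temperature` (K) and `energy`
#'   (kcal/mol).
#' @return List with `accepted` (logical) and `prob`.
#' @export
attempt_exchange <- function(replica_m, replica_n) {
  bm <- 1 / (kB_KCAL * replica_m$temperature)
  bn <- 1 / (kB_KCAL * replica_n$temperature)
  p <- exchange_acceptance_prob(bm, bn, replica_m$energy, replica_n$energy)
  list(accepted = runif(1) < p, prob = p)
}

#' Exchange probability from attempt bookkeeping
#'
#' @param attempts,acceptances Counts of attempted and successful exchanges.
#' @return Acceptance percentage (acceptances / attempts * 100).
#' @examples
#' exchange_probability(200000, 18000)  # 9
#' @export
exchange_probability <- function(attempts, acceptances) {
  stopifnot(all(acceptances <= attempts), all(attempts > 0))
  100 * acceptances / attempts
}

#' Cumulative simulation-time bookkeeping
#'
#' Total sampled time across a replica-exchange campaign:
#' per-replica duration x replicas x systems.
#'
#' @param per_replica_us Per-replica production length, microseconds.
#' @param n_replicas Replicas per system.
#' @param n_systems Number of protein systems.
#' @return Total time in microseconds.
#' @examples
#' cumulative_simulation_time(2, 8, 9)  # 144
#' @export
cumulative_simulation_time <- function(per_replica_us = 2, n_replicas = 8,
                                       n_systems = 9) {
  per_replica_us * n_replicas * n_systems
}

#' Temperature replica-exchange Langevin dynamics
#'
#' Runs one replica per ladder rung under the Go potential, attempting
#' neighbour exchanges every `ladder$exchange_interval` steps with
#' alternating even/odd pair sweeps. Replicas swap temperatures on
#' acceptance (velocities rescaled by `sqrt(T_new/T_old)`); frames are
#' binned by the temperature a replica currently holds, yielding
#' continuous-temperature ensembles per rung. A single-rung ladder degrades
#' to plain Langevin dynamics (documented behaviour, not an error). The
#' analysis ensemble is the lowest rung with the first half discarded
#' (see [analysis_ensemble()]).
#'
#' @param model A [build_cg_model()] object.
#' @param ladder A [replica_ladder()].
#' @param params A [langevin_params()].
#' @param n_steps Total steps per replica.
#' @param stride Steps between recorded frames.
#' @param seed Integer seed; controls the full run.
#' @return Object of class `remd_run`: `rung_trajectories` (list of
#'   [cg_trajectory()] per rung), `trajectory` (lowest rung),
#'   `ladder_stats` (tibble `pair`, `attempts`, `acceptances`, `rate_pct`),
#'   `energies` (tibble `cycle`, `rung`, `replica`, `energy`),
#'   `rung_history` (tibble `cycle`, `replica`, `rung`), `seed`.
#' @export
run_remd <- function(model, ladder = replica_ladder(),
                     params = langevin_params(), n_steps = 50000,
                     stride = 100, seed = 1) {
  stopifnot(inherits(model, "cg_model"), inherits(ladder, "replica_ladder"))
  set.seed(seed)
  temps <- ladder$temperatures
  R <- length(temps)
  interval <- min(ladder$exchange_interval, n_steps)
  n_cycles <- max(1L, n_steps %/% interval)
  packed <- cg_pack(model)
  n <- length(model$resid)

  rung_of_replica <- seq_len(R)
  states <- lapply(seq_len(R), function(r) {
    list(coords = model$coords,
         vel = sample_velocities(n, temps[r], params$mass))
  })
  rung_frames <- vector("list", R)
  stats_att <- stats_acc <- integer(max(R - 1, 1))
  energies <- vector("list", n_cycles)
  history <- vector("list", n_cycles)

  for (cycle in seq_len(n_cycles)) {
    pe <- numeric(R)
    for (r in seq_len(R)) {
      rung <- rung_of_replica[r]
      out <- cg_langevin_cpp(states[[r]]$coords, states[[r]]$vel, packed,
                             params$mass, params$step, params$gamma,
                             temps[rung], n_steps = interval,
                             stride = as.integer(stride))
      states[[r]] <- list(coords = out$coords, vel = out$vel)
      pe[r] <- out$potential
      if (!is.null(out$frames)) {
        rung_frames[[rung]] <- c(rung_frames[[rung]], list(out$frames))
      }
    }
    energies[[cycle]] <- tibble(cycle = cycle, rung = rung_of_replica,
                                replica = seq_len(R), energy = pe)
    history[[cycle]] <- tibble(cycle = cycle, replica = seq_len(R),
                               rung = rung_of_replica)
    if (R > 1) {
      start <- if (cycle %% 2 == 1) 1L else 2L
      replica_at <- match(seq_len(R), rung_of_replica)
      for (k in if (start > R - 1) integer() else seq(start, R - 1, by = 2)) {
        rm_ <- replica_at[k]; rn_ <- replica_at[k + 1]
        res <- attempt_exchange(
          list(temperature = temps[k], energy = pe[rm_]),
          list(temperature = temps[k + 1], energy = pe[rn_]))
        stats_att[k] <- stats_att[k] + 1L
        if (res$accepted) {
          stats_acc[k] <- stats_acc[k] + 1L
          rung_of_replica[rm_] <- k + 1L
          rung_of_replica[rn_] <- k
          states[[rm_]]$vel <- states[[rm_]]$vel * sqrt(temps[k + 1] / temps[k])
          states[[rn_]]$vel <- states[[rn_]]$vel * sqrt(temps[k] / temps[k + 1])
        }
      }
    }
  }

  rung_trajectories <- lapply(seq_len(R), function(rung) {
    fr <- rung_frames[[rung]]
    if (length(fr) == 0) return(NULL)
    all <- do.call(abind3, fr)
    cg_trajectory(all, resid = model$resid, stride = stride)
  })
  ladder_stats <- if (R > 1) {
    tibble(pair = paste0(seq_len(R - 1), "-", 2:R),
           attempts = stats_att, acceptances = stats_acc,
           rate_pct = ifelse(stats_att > 0,
                             exchange_probability(pmax(stats_att, 1),
                                                  stats_acc), NA_real_))
  } else {
    tibble(pair = character(), attempts = integer(), acceptances = integer(),
           rate_pct = numeric())
  }
  structure(
    list(rung_trajectories = rung_trajectories,
         trajectory = rung_trajectories[[1]],
         ladder_stats = ladder_stats,
         energies = dplyr::bind_rows(energies),
         rung_history = dplyr::bind_rows(history),
         ladder = ladder, seed = seed),
    class = "remd_run")
}

#' @export
print.remd_run <- function(x, ...) {
  cat("<remd_run>", length(x$rung_trajectories), "rungs, lowest-rung frames:",
      if (is.null(x$trajectory)) 0 else n_frames(x$trajectory), "\n")
  if (nrow(x$ladder_stats) > 0) {
    cat("  overall exchange rate:",
        round(exchange_probability(sum(x$ladder_stats$attempts),
                                   sum(x$ladder_stats$acceptances)), 1),
        "%\n")
  }
  invisible(x)
}

#' Analysis ensemble of a replica-exchange run
#'
#' The lowest-temperature rung with the first `discard_fraction` of frames
#' dropped as equilibration, mirroring the convention of analysing only the
#' final half of each replica's production run.
#'
#' @param remd An [run_remd()] result.
#' @param discard_fraction Leading fraction of frames to discard.
#' @return A [cg_trajectory()].
#' @export
analysis_ensemble <- function(remd, discard_fraction = 0.5) {
  stopifnot(inherits(remd, "remd_run"))
  traj <- remd$trajectory
  if (is.null(traj)) abort("run recorded no frames on the lowest rung")
  nf <- n_frames(traj)
  keep <- seq.int(floor(nf * discard_fraction) + 1L, nf)
  traj_subset(traj, keep)
}

# bind [n_i, n, 3] arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  nf <- vapply(parts, function(p) dim(p)[1], integer(1))
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(nf), d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
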