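test_that("zero-temperature dynamics quench toward the reference", {
  m <- toy_chain_model()
  set.seed(3)
  start <- list(coords = m$coords + matrix(rnorm(length(m$coords), sd = 0.8),
                                           ncol = 3),
                vel = matrix(0, nrow(m$coords), 3))
  run <- run_langevin(m, temperature = 0, n_steps = 8000, stride = 50,
                      state = start)
  pe <- run$energies$potential
  # the system relaxes toward the reference minimum: monotone once the
  # underdamped ringing has decayed, and the minimum energy is reached
  late <- pe[120:length(pe)]
  expect_true(all(diff(late) <= 1e-4))
  expect_lt(tail(pe, 1), head(pe, 1))
  e_min <- cg_energy(m$coords, m)$energy
  expect_equal(tail(pe, 1), e_min, tolerance = 0.01)
})

test_that("a tethered bead equilibrates to (3/2) kT potential energy", {
  kB <- 0.0019872
  model <- structure(
    list(resid = 1L, coords = matrix(0, 1, 3),
         bonds = tibble::tibble(i = integer(), j = integer(),
                                r0 = numeric(), k = numeric()),
         contacts = tibble::tibble(i = integer(), j = integer(),
                                   r0 = numeric(), eps = numeric()),
         restraints = tibble::tibble(i = integer(), j = integer(),
                                     r0 = numeric(), k = numeric(),
                                     label = character()),
         tethers = tibble::tibble(i = 1L, x = 0, y = 0, z = 0, k = 5),
         rep_sigma = 4, rep_eps = 1),
    class = "cg_model")
  run <- run_langevin(model, temperature = 300,
                      params = langevin_params(step = 0.01),
                      n_steps = 400000, stride = 20, seed = 8)
  mean_pe <- mean(run$energies$potential[1000:length(run$energies$potential)])
  expect_equal(mean_pe, 1.5 * kB * 300, tolerance = 0.03)
})

test_that("identical seeds give bit-identical trajectories", {
  m <- toy_chain_model()
  a <- run_langevin(m, 300, n_steps = 500, stride = 10, seed = 42)
  b <- run_langevin(m, 300, n_steps = 500, stride = 10, seed = 42)
  expect_identical(a$trajectory$frames, b$trajectory$frames)
  expect_identical(a$state, b$state)
})

test_that("langevin_step matches the first stride of a run and rejects bad input", {
  m <- toy_chain_model()
  set.seed(1)
  st0 <- list(coords = m$coords,
              vel = matrix(rnorm(15, sd = 2), 5, 3))
  set.seed(77)
  one <- langevin_step(st0, m, 300)
  set.seed(77)
  ref <- bir2dyn:::cg_langevin_cpp(st0$coords, st0$vel, bir2dyn:::cg_pack(m),
                                   110, 0.002, 2, 300, 1L, 0L)
  expect_identical(one$coords, ref$coords)
  st_bad <- st0
  st_bad$coords[1, 1] <- NaN
  expect_error(langevin_step(st_bad, m, 300), "non-finite")
})

test_that("exchange acceptance follows the Metropolis rule exactly", {
  # equal energies and equal temperatures always accept
  expect_equal(exchange_acceptance_prob(1.2, 1.5, 10, 10), 1)
  expect_equal(exchange_acceptance_prob(1.2, 1.2, -5, 30), 1)
  set.seed(4)
  r <- attempt_exchange(list(temperature = 300, energy = 12),
                        list(temperature = 305, energy = 12))
  expect_true(r$accepted)
  expect_equal(r$prob, 1)
})

test_that("acceptance at exponent -ln 2 is one half (10^5 trials)", {
  kB <- 0.0019872
  t_m <- 300; t_n <- 310
  b_m <- 1 / (kB * t_m); b_n <- 1 / (kB * t_n)
  de <- -log(2) / (b_m - b_n)     # (b_m - b_n)(E_m - E_n) = -ln 2
  expect_equal(exchange_acceptance_prob(b_m, b_n, de, 0), 0.5,
               tolerance = 1e-12)
  set.seed(12)
  acc <- vapply(1:100000, function(i) {
    attempt_exchange(list(temperature = t_m, energy = de),
                     list(temperature = t_n, energy = 0))$accepted
  }, logical(1))
  expect_equal(mean(acc), 0.5, tolerance = 0.01 / 0.5)
})

test_that("exchange and cumulative-time bookkeeping are exact", {
  expect_equal(exchange_probability(200000, 18000), 9)
  expect_equal(cumulative_simulation_time(2, 8, 9), 144)
  expect_error(exchange_probability(100, 200), "acceptances")
})

test_that("the default ladder carries the eight printed rungs", {
  lad <- replica_ladder()
  expect_length(lad$temperatures, 8)
  expect_equal(lad$temperatures[1], 300)
  expect_equal(lad$temperatures[8], 325)
  expect_true(all(diff(lad$temperatures) > 0))
  expect_equal(lad$exchange_interval, 5000L)
  expect_error(replica_ladder(c(310, 300)), "non-decreasing")
})
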