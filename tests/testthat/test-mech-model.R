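# Agent-based organoid shell model: forces, lumen bookkeeping, division,
# integration.

octa_state <- function(R = 10, n_substance = 0, params) {
  pos <- R * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  st <- initialize_sphere(6, R, params, jitter = 0)
  st$pos <- pos
  st$edges <- shell_adjacency(pos)
  st$n <- n_substance
  st$centre <- colMeans(pos)
  st$R_fit <- R
  st$V_lumen <- 4 / 3 * pi * R^3
  st
}

test_that("parameter validation enforces the documented invariants", {
  expect_error(simulation_params(ell_seal = 25, ell_rupt = 22), "ell_seal")
  expect_error(simulation_params(dt = 1), "stability")
  expect_error(simulation_params(k_spring = -1), "positive")
  expect_error(initialize_sphere(3, 10, simulation_params()), "at least 4")
})

test_that("two cells at rest length with zero pressure feel zero force", {
  p <- simulation_params()
  st <- initialize_sphere(4, 10, p, jitter = 0)
  st$pos <- rbind(c(0, 0, 0), c(p$ell0, 0, 0))
  st$edges <- matrix(c(1L, 2L), 1L)
  st$n <- 0
  f <- compute_forces(st, p)
  expect_equal(f$total, matrix(0, 2L, 3L))
})

test_that("octahedron at spring rest feels a purely radial force P * a_i", {
  R <- 10
  p <- simulation_params(ell0 = sqrt(2) * R, ell_rupt = sqrt(2) * R * 1.2,
                         ell_seal = sqrt(2) * R * 1.1)
  st <- octa_state(R, n_substance = 500, params = p)
  f <- compute_forces(st, p)
  expect_equal(max(abs(f$spring)), 0)
  P <- p$kappa * 500 / st$V_lumen
  a_i <- 4 * pi * R^2 / 6
  rhat <- st$pos / R
  expect_equal(f$total, rhat * P * a_i, tolerance = 1e-12)
  ## ideal-gas linearity: doubling n doubles the pressure term exactly
  st2 <- st; st2$n <- 1000
  f2 <- compute_forces(st2, p)
  expect_equal(f2$pressure, 2 * f$pressure)
})

test_that("spring forces sum to zero on arbitrary states (Newton's third law)", {
  p <- simulation_params()
  for (seed in 1:5) {
    set.seed(seed)
    st <- initialize_sphere(50, NULL, p, jitter = 2)
    st$pos <- st$pos + matrix(rnorm(150, sd = 1), 50L)
    f <- compute_forces(st, p)
    expect_lt(sqrt(sum(colSums(f$spring)^2)), 1e-8 * p$k_spring * p$ell0)
  }
})

test_that("lumen bookkeeping: influx is exact, outflux floors at zero", {
  p <- simulation_params(j_in = 1, j_out = 10)
  st <- initialize_sphere(10, NULL, p, jitter = 0)  # rest-packing radius
  n0 <- st$n
  st2 <- update_lumen(st, p, dt = 0.5)
  expect_equal(st2$n - n0, 5)        # J_in * N * dt = 1 * 10 * 0.5
  expect_true(st2$sealed)
  st$sealed <- FALSE
  st$n <- 1
  st3 <- update_lumen(st, p, dt = 0.5)
  expect_equal(st3$n, max(0, 1 + 1 * 10 * 0.5 - 10 * 0.5))
  st$n <- 0.1
  p2 <- simulation_params(j_in = 1e-12, j_out = 1e6)
  st4 <- update_lumen(st, p2, dt = 0.5)
  expect_equal(st4$n, 0)             # floored, never negative
})

test_that("a stretched lattice unseals in one call; a relaxed one reseals", {
  p <- simulation_params()
  st <- initialize_sphere(64, NULL, p, jitter = 0)
  stretch <- 1.01 * p$ell_rupt / lumenosc:::mean_edge_length(st$pos, st$edges)
  st$pos <- st$pos * stretch
  st2 <- update_lumen(st, p, dt = p$dt)
  expect_false(st2$sealed)
  expect_true(st2$rupture_event)
  st2$pos <- st2$pos / stretch * 0.99
  st3 <- update_lumen(st2, p, dt = p$dt)
  expect_true(st3$sealed)
})

test_that("pressure follows the van 't Hoff law at every recorded step", {
  p <- simulation_params(seed = 3)
  traj <- simulate_organoid(p, division_schedule("linear", m = 1),
                            t_end = 3, N0 = 32)
  expect_identical(traj$P, p$kappa * traj$n / traj$V_lumen)
})

test_that("sealed-phase substance bookkeeping is closed-form exact", {
  p <- simulation_params(seed = 4, j_in = 2)
  traj <- simulate_organoid(p, NULL, t_end = 2, N0 = 32)
  expect_true(all(traj$sealed == 1))
  incr <- diff(traj$n)
  expect_equal(incr, rep(p$j_in * 32 * p$dt, length(incr)), tolerance = 1e-12)
})

test_that("table-mode division reproduces the observed growth record exactly", {
  p <- simulation_params(seed = 5, dt = 0.02)
  sched <- division_schedule("table",
                             table = data.frame(t = c(0, 144),
                                                count = c(8, 107)))
  traj <- simulate_organoid(p, sched, t_end = 144, N0 = 8, record_every = 50)
  expect_equal(traj$N[nrow(traj)], 107)
  expect_true(all(diff(traj$N) >= 0))
})

test_that("zero division rate leaves the census unchanged", {
  p <- simulation_params(seed = 6)
  st <- initialize_sphere(20, NULL, p)
  st$time <- 1
  st2 <- divide_cells(st, division_schedule("linear", m = 0), p, dt = 0.01)
  expect_identical(st2$pos, st$pos)
  expect_identical(st2$ids, st$ids)
})

test_that("deterministic exponential division tracks N0 * exp(r t)", {
  p <- simulation_params(seed = 7, sigma = 0)
  sched <- division_schedule("exponential", r = 0.05, stochastic = FALSE)
  traj <- simulate_organoid(p, sched, t_end = 20, N0 = 16, jitter = 0,
                            record_every = 100)
  expect_equal(traj$N[nrow(traj)], round(16 * exp(0.05 * 20)), tolerance = 0.51)
})

test_that("the octahedron at full rest is a fixed point of the step map", {
  R <- 10
  p <- simulation_params(ell0 = sqrt(2) * R, ell_rupt = sqrt(2) * R * 1.2,
                         ell_seal = sqrt(2) * R * 1.1, sigma = 0, j_in = 1e-300,
                         rebuild_every = 1000L)
  st <- octa_state(R, n_substance = 0, params = p)
  st2 <- step_organoid(st, p)
  expect_lt(max(abs(st2$pos - st$pos)), 1e-9)
})

test_that("trajectories with the same seed are bit-identical", {
  p <- simulation_params(seed = 11)
  sched <- division_schedule("linear", m = 2)
  t1 <- simulate_organoid(p, sched, t_end = 2, N0 = 24)
  t2 <- simulate_organoid(p, sched, t_end = 2, N0 = 24)
  expect_identical(t1, t2)
  p0 <- simulation_params(seed = 11, sigma = 0)
  d1 <- simulate_organoid(p0, sched, t_end = 2, N0 = 24)
  d2 <- simulate_organoid(p0, sched, t_end = 2, N0 = 24)
  expect_identical(d1, d2)
})

test_that("the positional increment decomposes into drift plus recorded noise", {
  p <- simulation_params(seed = 12, sigma = 0.5)
  set.seed(1)
  st <- initialize_sphere(32, NULL, p, jitter = 0.5)
  f <- compute_forces(st, p)
  st2 <- step_organoid(st, p, record_noise = TRUE)
  xi <- attr(st2, "xi")
  drift <- f$total / p$gamma * p$dt
  expect_equal(st2$pos, st$pos + drift + p$sigma * sqrt(p$dt) * xi,
               tolerance = 1e-12)
})

test_that("the deterministic map converges at first order in dt", {
  run <- function(dt) {
    p <- simulation_params(seed = 1, sigma = 0, dt = dt,
                           rebuild_every = 10000L)
    st <- initialize_sphere(32, NULL, p, jitter = 0)
    st$pos <- st$pos * 1.02  # slightly inflated: non-trivial dynamics
    st$edges <- shell_adjacency(st$pos)
    for (i in seq_len(round(1 / dt))) st <- step_organoid(st, p)
    st$pos
  }
  x1 <- run(0.02); x2 <- run(0.01); x3 <- run(0.005)
  e1 <- max(abs(x1 - x2)); e2 <- max(abs(x2 - x3))
  order_est <- log2(e1 / e2)
  expect_gt(order_est, 0.9)
})

test_that("without influx the volume stays constant and nothing ruptures", {
  p <- simulation_params(seed = 13, j_in = 1e-300, sigma = 0, p0 = 1e-10)
  traj <- simulate_organoid(p, NULL, t_end = 5, N0 = 48, jitter = 0)
  expect_equal(sum(traj$rupture_event), 0)
  expect_lt(max(abs(traj$V_lumen / traj$V_lumen[1L] - 1)), 0.02)
})

test_that("a small organoid under linear division shows at least one full cycle", {
  p <- simulation_params(seed = 14)
  traj <- simulate_organoid(p, division_schedule("linear", m = 0.5),
                            t_end = 60, N0 = 9, record_every = 10)
  expect_gte(sum(traj$rupture_event), 1)
  ## deflation actually happened: the volume dropped after some rupture
  r_idx <- which(traj$rupture_event > 0)[1L]
  after <- traj$V_lumen[r_idx:min(nrow(traj), r_idx + 200L)]
  expect_lt(min(after) / traj$V_lumen[r_idx], 0.97)
})
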