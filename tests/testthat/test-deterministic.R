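test_that("with all rates zero the trajectory is constant", {
  tr <- simulate_deterministic(
    only_rates(), cell_state(M = 10.5, N = 3.25),
    myc_schedule("on", 5), 10
  )
  expect_true(all(tr$M == 10.5 & tr$N == 3.25))
  expect_true(all(tr$bli_signal == 13.75))
})

test_that("pure growth follows the scheme-exact discrete exponential", {
  p <- only_rates(k_M_prolif = 0.5, k_M_apop = 0.05)
  tr <- simulate_deterministic(p, cell_state(M = 1e6), myc_schedule("on"), 10)
  m10 <- tr$M[tr$time == 10]
  # the Euler map is exactly M0 * (1 + r dt)^n
  expect_equal(m10, 1e6 * (1 + 0.45 * 0.02)^500, tolerance = 1e-12)
  # over short horizons the discrete map matches the continuous exponential
  # inside the first-order error budget; the bias grows like t * r^2 * dt / 2
  m2 <- tr$M[tr$time == 2]
  expect_lt(abs(m2 - 1e6 * exp(0.9)) / (1e6 * exp(0.9)), 0.005)
  expect_lt(abs(m10 - 1e6 * exp(4.5)) / (1e6 * exp(4.5)), 0.025)
})

test_that("the mean-field system is linear in the initial counts", {
  p <- onco_params("lymphoma", "deficient")
  sched <- myc_schedule("on", 5)
  x0 <- cell_state(M = 1e5, N = 1e4, D = 500, E = 2)
  base <- simulate_deterministic(p, x0, sched, 20)
  scaled <- simulate_deterministic(p, 3.7 * x0, sched, 20)
  for (st in c("M", "N", "A", "D", "S", "E")) {
    expect_equal(scaled[[st]], 3.7 * base[[st]], tolerance = 1e-10)
  }
})

test_that("delay ablation moves the start of cell death to the switch", {
  x0 <- cell_state(N = 1e6)
  off <- myc_schedule("off")
  lagged <- simulate_deterministic(only_rates(k_N_apop = 2, tau_apop = 4.5), x0, off, 8)
  instant <- simulate_deterministic(only_rates(k_N_apop = 2, tau_apop = 0), x0, off, 8)
  live_lag <- lagged$N + lagged$A
  live_inst <- instant$N + instant$A
  expect_lt(live_inst[2], 1e6) # death begins within the first step
  expect_equal(live_lag[lagged$time < 4.5], rep(1e6, sum(lagged$time < 4.5)))
  expect_lt(live_lag[lagged$time == 4.5], 1e6)
})

test_that("zero-delay constant-program dynamics match the matrix exponential", {
  p <- onco_params("lymphoma", "deficient", tau_apop = 0)
  x0 <- cell_state(M = 1e6, N = 5e5, D = 2e5, E = 100)
  labs <- c("M", "N", "D", "S", "E")
  for (prog in c("on", "off")) {
    Q <- generator_matrix(p, prog)
    ref <- as.numeric(Matrix::expm(Q * 10) %*% x0[labs])
    fine <- oracle_fine_grid(p, x0, myc_schedule(prog), 10, refinement = 100)
    eng <- as.numeric(unlist(fine[fine$time == 10, labs]))
    expect_lt(max(abs(eng - ref)) / max(ref), 1e-3)
    expect_lt(abs(sum(eng) - sum(ref)) / sum(ref), 1e-3)
  }
})

test_that("refinement = 1 reproduces the production grid exactly", {
  p <- onco_params()
  x0 <- cell_state(M = 1e5)
  sched <- myc_schedule("on", 3)
  a <- simulate_deterministic(p, x0, sched, 10)
  b <- oracle_fine_grid(p, x0, sched, 10, refinement = 1)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_error(oracle_fine_grid(p, x0, sched, 10, refinement = 2.5), "integer")
})

test_that("refining the grid monotonically shrinks the discretization gap", {
  p <- onco_params("lymphoma", "competent")
  x0 <- cell_state(M = 1e6)
  sched <- myc_schedule("on", 5)
  ref <- oracle_fine_grid(p, x0, sched, 15, refinement = 64)
  gap <- vapply(c(1, 2, 4, 8), function(r) {
    tr <- oracle_fine_grid(p, x0, sched, 15, refinement = r)
    common <- tr$time %in% ref$time
    max(abs(tr$bli_signal[common] - ref$bli_signal[ref$time %in% tr$time])) /
      max(ref$bli_signal)
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
})

test_that("table-value rates never drive expected counts negative", {
  sc <- scenario_preset("fig5")
  expect_no_warning(
    simulate_deterministic(sc$params, sc$initial, sc$schedule, 40)
  )
})

test_that("t_end off the grid is rounded up with a warning", {
  p <- onco_params()
  expect_warning(
    tr <- simulate_deterministic(p, cell_state(M = 10), myc_schedule("on"), 0.05),
    "rounding up"
  )
  expect_equal(max(tr$time), 0.06)
})
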