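test_that("degenerate inputs pass through unchanged", {
  p <- onco_params()
  sched <- myc_schedule("on", 5)
  # empty tumor stays empty
  tr <- simulate_stochastic(p, cell_state(), sched, 10, seed = 1)
  expect_true(all(tr[, c("M", "N", "A", "D", "S", "E")] == 0))
  # all rates zero: nothing moves
  tr0 <- simulate_stochastic(only_rates(), cell_state(M = 10, N = 7, D = 3),
    sched, 5,
    seed = 2
  )
  expect_true(all(tr0$M == 10 & tr0$N == 7 & tr0$D == 3))
})

test_that("identical seeds reproduce trajectories bit-exactly", {
  p <- onco_params("lymphoma", "deficient")
  sched <- myc_schedule("on", 5)
  a <- simulate_stochastic(p, cell_state(M = 1e5), sched, 20, seed = 99)
  b <- simulate_stochastic(p, cell_state(M = 1e5), sched, 20, seed = 99)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- simulate_stochastic(p, cell_state(M = 1e5), sched, 20, seed = 100)
  expect_false(identical(a$bli_signal, c$bli_signal))
})

test_that("counts stay non-negative integers and senescence is absorbing", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      p <- random_params()
      tr <- simulate_stochastic(
        p, cell_state(M = 1e4, N = 1e3, D = 100, E = 10),
        myc_schedule("on", 2), 8,
        seed = sample.int(1e6, 1)
      )
      counts <- as.matrix(tr[, c("M", "N", "A", "D", "S", "E")])
      expect_true(all(counts >= 0))
      expect_true(all(counts == round(counts)))
      expect_true(all(diff(tr$S) >= 0))
    }
  })
})

test_that("without escape mutations the escaped state is exactly empty", {
  p <- onco_params("lymphoma", "competent") # k_relapse = 0
  tr <- simulate_stochastic(p, cell_state(M = 1e6), myc_schedule("on", 10),
    30,
    seed = 5
  )
  expect_identical(unique(tr$E), 0)
})

test_that("live signal is conserved until the commitment-to-death delay elapses", {
  # apoptosis commitment only: cells move N -> A from the very first step,
  # but no cell dies before tau_apop, so N + A is exactly conserved
  p <- only_rates(k_N_apop = 2, tau_apop = 4.5)
  tr <- simulate_stochastic(p, cell_state(N = 1e6), myc_schedule("off"), 8, seed = 3)
  expect_gt(tr$A[2], 0)
  live <- tr$N + tr$A
  expect_true(all(live[tr$time < 4.5] == 1e6))
  expect_lt(live[tr$time == 4.5], 1e6)
  # and the same bookkeeping holds in expectation
  dd <- simulate_deterministic(p, cell_state(N = 1e6), myc_schedule("off"), 8)
  expect_equal((dd$N + dd$A)[dd$time < 4.5], rep(1e6, sum(dd$time < 4.5)))
  expect_lt((dd$N + dd$A)[dd$time == 4.5], 1e6)
})

test_that("zero delay removes committed cells within the step", {
  p <- only_rates(k_N_apop = 2, tau_apop = 0)
  tr <- simulate_stochastic(p, cell_state(N = 1e5), myc_schedule("off"), 2, seed = 8)
  expect_identical(unique(tr$A), 0)
  expect_true(all(diff(tr$N) <= 0))
})

test_that("ensemble means track the mean-field engine (pure growth)", {
  # the deterministic engine is the exact expectation of the stochastic one,
  # so a 200-run mean of the growth factor must sit within Monte-Carlo error
  p <- only_rates(k_M_prolif = 0.5, k_M_apop = 0.05)
  sched <- myc_schedule("on")
  ens <- run_ensemble(p, cell_state(M = 1e4), sched, 10,
    n_runs = 200, base_seed = 21
  )
  finals <- ens$trajectories$M[ens$trajectories$time == 10] / 1e4
  det <- simulate_deterministic(p, cell_state(M = 1e4), sched, 10)
  expected <- det$M[det$time == 10] / 1e4
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
  # growth factor is near (not equal to) the continuous e^{0.45 * 10}
  expect_equal(expected, (1 + 0.45 * 0.02)^500, tolerance = 1e-12)
})

test_that("ensemble means track the mean-field engine (full scenario)", {
  sc <- scenario_preset("fig5")
  ens <- run_ensemble(sc$params, sc$initial, sc$schedule, 20,
    n_runs = 50, base_seed = 13
  )
  det <- simulate_deterministic(sc$params, sc$initial, sc$schedule, 20)
  mean_bli <- tapply(ens$trajectories$bli_signal, ens$trajectories$time, mean)
  rel <- abs(as.numeric(mean_bli) - det$bli_signal) / det$bli_signal
  expect_lt(max(rel), 0.05)
})

test_that("ensembles are reproducible and independent of replicate order", {
  p <- onco_params("lymphoma", "deficient")
  sched <- myc_schedule("on", 5)
  a <- run_ensemble(p, cell_state(M = 1e4), sched, 10, n_runs = 4, base_seed = 31)
  b <- run_ensemble(p, cell_state(M = 1e4), sched, 10, n_runs = 4, base_seed = 31)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$seeds, b$seeds)
  # run k is simulate() with the k-th spawned seed, regardless of the others
  solo <- simulate_stochastic(p, cell_state(M = 1e4), sched, 10,
    seed = a$seeds[3], run_id = "run_03"
  )
  sub <- a$trajectories[a$trajectories$run_id == "run_03", ]
  for (col in names(solo)) {
    expect_identical(solo[[col]], sub[[col]])
  }
})

test_that("replicate relapse times differ across an immunodeficient ensemble", {
  ens <- run_scenario("fig7", seed = 11)
  rt <- ens$summaries$relapse_time
  expect_gte(sum(is.finite(rt)), 2)
  expect_gt(length(unique(rt[is.finite(rt)])), 1)
})

test_that("single stochastic steps keep the delay queue in sync with A", {
  p <- onco_params(tau_apop = 0.1) # 5-step delay
  state <- cell_state(M = 5e4, N = 1e4)
  q <- delay_queue()
  t <- 0
  withr::with_seed(17, {
    for (i in 1:60) {
      st <- step_stochastic(state, t, q, p, "off")
      state <- st$state
      q <- st$queue
      t <- st$t
      expect_identical(sum(q$cells), state[["A"]])
      expect_true(all(state >= 0) && all(state == round(state)))
      expect_true(!is.unsorted(q$death_time)) # FIFO order preserved
    }
  })
  expect_gt(t, 1) # delay elapsed: deaths must have occurred
  expect_gt(sum(state), 0)
})

test_that("stochastic steps validate their inputs", {
  p <- onco_params()
  expect_error(
    step_stochastic(cell_state(M = 1.5), 0, delay_queue(), p, "on"),
    "integer"
  )
  expect_error(
    step_stochastic(cell_state(A = 5), 0, delay_queue(), p, "on"),
    "queue"
  )
  expect_error(
    simulate_stochastic(p, cell_state(M = 0.5), myc_schedule("on"), 1, seed = 1),
    "integer"
  )
})
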