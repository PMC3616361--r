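test_that("presets resolve to the four canonical run configurations", {
  f4 <- scenario_preset("fig4")
  f5 <- scenario_preset("fig5")
  f6 <- scenario_preset("fig6")
  f7 <- scenario_preset("fig7")
  expect_equal(f4$params$tau_apop, 0)
  expect_equal(f5$params$tau_apop, 4.5)
  expect_equal(f5$params$k_relapse, 0)
  expect_equal(f6$params$k_relapse, 3e-8)
  expect_equal(f7$n_replicates, 20L)
  expect_identical(scenario_preset("no_delay")$name, "fig4")
  expect_identical(scenario_preset("relapse_ensemble")$name, "fig7")
  expect_error(scenario_preset("fig99"), "Unknown preset")
  # all four share the growth-then-inactivation schedule
  for (sc in list(f4, f5, f6, f7)) {
    expect_equal(sc$schedule$switch_times, 10)
    expect_equal(unname(sc$initial["M"]), 1e6)
  }
})

test_that("the commitment-to-death delay sets the observed decline lag", {
  # with the delay, tumor shrinkage lags inactivation by 4-5 days even
  # though proliferative arrest is quasi-immediate
  with_delay <- run_scenario("fig5", deterministic = TRUE)
  lag <- onset_of_decline(with_delay)
  expect_gte(lag, 4)
  expect_lte(lag, 5 + 1e-9)
  # ablating the delay makes the decline start essentially at the switch
  no_delay <- run_scenario("fig4", deterministic = TRUE)
  expect_lt(onset_of_decline(no_delay), 0.5)
})

test_that("sustained regression without escape in the immunocompetent scenario", {
  ens <- run_scenario("fig5", seed = 19, n_runs = 5)
  trs <- ens$trajectories
  expect_identical(unique(trs$E), 0)
  # once the regression wave has passed, no proliferating states remain and
  # the live signal is monotonically non-increasing in every run
  for (id in unique(trs$run_id)) {
    late <- trs[trs$run_id == id & trs$time > 30, ]
    expect_true(all(diff(late$bli_signal) <= 0))
  }
})

test_that("escaped clones grow at about k_E_prolif - k_E_apop per day", {
  det <- run_scenario("fig6", deterministic = TRUE)
  win <- det$time >= 30 & det$time <= 45 # N long gone: pure escaped growth
  fit <- lm(log(E) ~ time, data = det[win, ])
  # the discrete scheme realizes log(1 + 0.49 dt)/dt, slightly below 0.49
  expect_equal(unname(coef(fit)[2]), 0.49, tolerance = 0.02)
})

test_that("raising the escape rate shortens time to first escape", {
  sc <- scenario_preset("fig6")
  first_escape <- function(kr, seeds) {
    p <- validate_onco_params(modifyList(sc$params, list(k_relapse = kr)))
    vapply(seeds, function(s) {
      tr <- simulate_stochastic(p, sc$initial, sc$schedule, 25, seed = s)
      esc <- which(tr$E > 0)
      if (length(esc)) tr$time[esc[1]] else Inf # censored: no escape yet
    }, numeric(1))
  }
  seeds <- 300 + 1:25
  lo <- first_escape(3e-8, seeds)
  hi <- first_escape(3e-7, seeds)
  w <- suppressWarnings(stats::wilcox.test(hi, lo, alternative = "less"))
  expect_lt(w$p.value, 0.01)
})

test_that("relapse-rate sensitivity tables cover the requested grid", {
  tab1 <- relapse_rate_sensitivity("fig6",
    k_relapse_grid = 3e-7, k_E_prolif_grid = 0.5,
    n_runs = 5, base_seed = 2, t_end = 60
  )
  expect_equal(nrow(tab1), 1)
  expect_true(is.finite(tab1$median_relapse_time))
  # no escape mutations, no relapse: the k_relapse = 0 row is all-absent
  tab0 <- relapse_rate_sensitivity("fig6",
    k_relapse_grid = 0, k_E_prolif_grid = c(0.5, 1),
    n_runs = 3, base_seed = 2, t_end = 30
  )
  expect_true(all(is.na(tab0$median_relapse_time)))
  expect_true(all(tab0$n_relapsed == 0))
  expect_error(relapse_rate_sensitivity("fig6",
    k_relapse_grid = numeric(), k_E_prolif_grid = 1
  ), "non-empty")
})
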