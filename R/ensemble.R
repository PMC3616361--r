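#' Run an ensemble of replicate stochastic simulations
#'
#' Repeats [simulate_stochastic()] `n_runs` times with per-run seeds spawned
#' deterministically from `base_seed` (a seeded `sample.int()` over the
#' 31-bit integer range), so the whole ensemble is reproducible and each
#' run's result is independent of replicate order.  Per-run regression and
#' relapse summaries are computed with [run_summary()] relative to the
#' schedule's first MYC-off switch.
#'
#' @inheritParams simulate_stochastic
#' @param n_runs Number of replicate runs (>= 1).
#' @param base_seed Integer seed from which per-run seeds are spawned.
#' @return An object of class `onco_ensemble`: a list with
#'   * `trajectories` — one long tibble of all runs (column `run_id`),
#'   * `summaries` — one row per run from [run_summary()],
#'   * `seeds` — the per-run seeds,
#'   and the shared `params`, `schedule`, `t_end`, `t_switch`, `base_seed`.
#' @examples
#' ens <- run_ensemble(
#'   onco_params(), cell_state(M = 1e4),
#'   myc_schedule("on", 5), t_end = 15, n_runs = 3, base_seed = 42
#' )
#' ens$summaries
#' @export
run_ensemble <- function(params, initial, schedule, t_end, n_runs = 20,
                         base_seed = 1L, bli_states = STATES) {
  if (n_runs < 1 || n_runs != round(n_runs)) {
    abort("n_runs must be a positive integer.")
  }
  seeds <- spawn_seeds(base_seed, n_runs)
  ids <- sprintf("run_%02d", seq_len(n_runs))

  trajs <- purrr::map2(seeds, ids, function(s, id) {
    simulate_stochastic(params, initial, schedule, t_end,
      seed = s, bli_states = bli_states, run_id = id
    )
  })
  summaries <- purrr::map2(trajs, seeds, function(tr, s) {
    dplyr::bind_cols(
      tibble::tibble(run_id = tr$run_id[1], seed = s),
      run_summary(tr)
    )
  })

  structure(
    list(
      trajectories = dplyr::bind_rows(trajs),
      summaries = dplyr::bind_rows(summaries),
      seeds = seeds,
      params = params,
      schedule = schedule,
      t_end = t_end,
      t_switch = first_off_time(schedule),
      base_seed = as.integer(base_seed),
      bli_states = bli_states
    ),
    class = "onco_ensemble"
  )
}

# deterministic per-run seed spawn: one seeded draw without replacement
# from the 31-bit range, so run k's seed depends only on base_seed and k
spawn_seeds <- function(base_seed, n_runs) {
  withr::with_seed(
    as.integer(base_seed),
    sample.int(.Machine$integer.max, n_runs)
  )
}

#' @export
print.onco_ensemble <- function(x, ...) {
  cat("<onco_ensemble> ", length(x$seeds), " stochastic runs, t_end = ",
    x$t_end, " d, base_seed = ", x$base_seed, "\n",
    sep = ""
  )
  print(x$summaries, ...)
  invisible(x)
}
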