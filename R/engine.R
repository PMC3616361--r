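# Exact multinomial draw of the cells leaving a state along each exit.
# rmultinom() only accepts 32-bit sizes; above that the draw is factored
# into the exact chain of conditional binomials (rbinom handles arbitrary
# sizes and returns doubles).
draw_moves <- function(n, probs) {
  if (n < 2147483647) {
    mv <- rmultinom(1L, n, c(probs, 1 - sum(probs)))
    return(mv[seq_along(probs)])
  }
  out <- numeric(length(probs))
  rem <- n
  prem <- 1
  for (j in seq_along(probs)) {
    x <- rbinom(1L, rem, min(probs[j] / prem, 1))
    out[j] <- x
    rem <- rem - x
    prem <- prem - probs[j]
    if (rem <= 0 || prem <= 0) break
  }
  out
}

# rbinom at any size (returns double above the integer range)
draw_births <- function(n, p) rbinom(1L, n, p)

# One Euler step of the six-state model, shared by both engines.
#
# counts: unnamed numeric length 6 (M, N, A, D, S, E); on: logical MYC
# program; pp: step_probs(); stochastic: multinomial/binomial draws vs
# expectations.  Returns length 7: updated counts (with this step's
# apoptosis commitments already added to A, deaths NOT yet applied) and the
# number of new commitments.  Transitions are drawn from start-of-step
# counts; births are added afterwards and only become eligible to move at
# the next step.
advance_state <- function(counts, on, pp, stochastic) {
  M <- counts[1L]; N <- counts[2L]; A <- counts[3L]
  D <- counts[4L]; S <- counts[5L]; E <- counts[6L]

  m_to_n <- m_to_a <- m_b <- 0
  if (M > 0) {
    pn <- if (on) 0 else pp$m_to_n
    if (stochastic) {
      mv <- draw_moves(M, c(pn, pp$m_to_a))
      m_to_n <- mv[1L]; m_to_a <- mv[2L]
      m_b <- draw_births(M, pp$m_birth)
    } else {
      m_to_n <- M * pn; m_to_a <- M * pp$m_to_a; m_b <- M * pp$m_birth
    }
  }

  n_to_m <- n_to_a <- n_to_d <- n_to_s <- n_to_e <- n_b <- 0
  if (N > 0) {
    pm <- if (on) pp$n_to_m else 0
    if (stochastic) {
      nv <- draw_moves(N, c(pm, pp$n_to_a, pp$n_to_d, pp$n_to_s, pp$n_to_e))
      n_to_m <- nv[1L]; n_to_a <- nv[2L]; n_to_d <- nv[3L]
      n_to_s <- nv[4L]; n_to_e <- nv[5L]
      n_b <- draw_births(N, pp$n_birth)
    } else {
      n_to_m <- N * pm; n_to_a <- N * pp$n_to_a; n_to_d <- N * pp$n_to_d
      n_to_s <- N * pp$n_to_s; n_to_e <- N * pp$n_to_e; n_b <- N * pp$n_birth
    }
  }

  d_to_a <- d_to_m <- 0
  if (D > 0) {
    pw <- if (on) pp$d_to_m else 0
    if (stochastic) {
      dv <- draw_moves(D, c(pp$d_to_a, pw))
      d_to_a <- dv[1L]; d_to_m <- dv[2L]
    } else {
      d_to_a <- D * pp$d_to_a; d_to_m <- D * pw
    }
  }

  e_to_a <- e_b <- 0
  if (E > 0) {
    if (stochastic) {
      e_to_a <- draw_births(E, pp$e_to_a)
      e_b <- draw_births(E, pp$e_birth)
    } else {
      e_to_a <- E * pp$e_to_a; e_b <- E * pp$e_birth
    }
  }

  commits <- m_to_a + n_to_a + d_to_a + e_to_a
  c(
    M - m_to_n - m_to_a + m_b + n_to_m + d_to_m,
    N - n_to_m - n_to_a - n_to_d - n_to_s - n_to_e + n_b + m_to_n,
    A + commits,
    D - d_to_a - d_to_m + n_to_d,
    S + n_to_s,
    E - e_to_a + e_b + n_to_e,
    commits
  )
}

# Fixed-step engine shared by simulate_stochastic()/simulate_deterministic().
# The apoptosis delay queue is an integer-indexed vector of scheduled death
# counts: commitments made during the step starting at t carry death time
# t + tau_apop and are removed during the step whose end time first reaches
# that death time.
run_engine <- function(params, initial, schedule, t_end,
                       stochastic = TRUE, dt = params$dt,
                       bli_states = STATES, run_id = NULL, seed = NA) {
  stopifnot(inherits(params, "onco_params"), inherits(schedule, "myc_schedule"))
  initial <- as_cell_state(initial)
  if (stochastic && any(initial != round(initial))) {
    abort("Stochastic engine requires non-negative integer initial counts.")
  }
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    abort("t_end must be a single positive duration (days).")
  }

  n_steps <- t_end / dt
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    warn(paste0("t_end (", t_end, ") is not a multiple of dt (", dt, "); rounding up."))
    n_steps <- as.integer(ceiling(n_steps - 1e-8))
  } else {
    n_steps <- as.integer(round(n_steps))
  }
  tau_steps <- as.integer(round(params$tau_apop / dt))

  # re-check the probability bound in case dt was overridden per run
  worst <- max(
    params$k_M_apop + params$k_inactivation,
    params$k_N_apop + params$k_diff + params$k_senesc +
      params$k_relapse + params$k_activation,
    params$k_D_apop + params$k_wake,
    params$k_E_apop,
    params$k_M_prolif, params$k_N_prolif, params$k_E_prolif
  ) * dt
  if (worst > 1) {
    abort(paste0(
      "Per-step probability ", signif(worst, 4), " exceeds 1 at dt = ", dt,
      "; use a smaller dt."
    ))
  }

  pp <- step_probs(params, dt)
  times <- round(dt * (0:n_steps), 9) # clean grid times (dt has few decimals)
  on_vec <- myc_program_at(schedule, times[seq_len(n_steps)]) == "on"

  out <- matrix(0, n_steps + 1L, 6L)
  counts <- unname(initial)
  out[1L, ] <- counts
  deaths <- numeric(n_steps + tau_steps + 2L)
  clamp_warn <- FALSE

  for (i in seq_len(n_steps)) {
    res <- advance_state(counts, on_vec[i], pp, stochastic)
    j <- if (tau_steps > 0L) i + tau_steps - 1L else i
    deaths[j] <- deaths[j] + res[7L]
    counts <- res[1:6]
    counts[3L] <- counts[3L] - deaths[i]
    if (!stochastic && any(counts < 0)) {
      if (any(counts < -1e-6 * max(1, sum(abs(counts))))) clamp_warn <- TRUE
      counts[counts < 0] <- 0
    }
    out[i + 1L, ] <- counts
  }
  if (clamp_warn) {
    warn("Euler undershoot produced negative expected counts; clamped to 0.")
  }

  new_trajectory(times, out, params, schedule,
    dt = dt, bli_states = bli_states,
    run_id = run_id %||% if (stochastic) "run_1" else "deterministic",
    seed = seed, stochastic = stochastic
  )
}

new_trajectory <- function(times, out, params, schedule, dt, bli_states,
                           run_id, seed, stochastic) {
  bli_states <- match.arg(bli_states, STATES, several.ok = TRUE)
  colnames(out) <- STATES
  traj <- tibble::as_tibble(as.data.frame(out))
  traj <- tibble::add_column(traj, time = times, .before = 1L)
  traj$bli_signal <- rowSums(out[, bli_states, drop = FALSE])
  traj$run_id <- run_id
  structure(traj,
    class = c("onco_trajectory", class(traj)),
    params = params, schedule = schedule, dt = dt,
    bli_states = bli_states, seed = seed, stochastic = stochastic,
    t_switch = first_off_time(schedule)
  )
}

#' @export
print.onco_trajectory <- function(x, ...) {
  cat(
    "<onco_trajectory> ", if (isTRUE(attr(x, "stochastic"))) "stochastic" else "deterministic",
    ", ", nrow(x) - 1L, " steps of dt = ", attr(x, "dt"), " d",
    if (!is.na(attr(x, "seed"))) paste0(", seed = ", attr(x, "seed")), "\n",
    sep = ""
  )
  NextMethod()
}

#' Simulate one stochastic trajectory
#'
#' Advances integer cell counts through the six-state model by fixed Euler
#' steps of `params$dt` days.  At each step the cells leaving each source
#' state are one multinomial draw over that state's open exits (so exits
#' are mutually exclusive and can never oversubscribe the state count),
#' births are binomial draws added to the mother state, and newly
#' apoptosis-committed cells join a FIFO delay queue from which they are
#' removed (`A` decreases) once `tau_apop` days have elapsed.  The
#' bioluminescence proxy `bli_signal` is the sum of the configured
#' signal-producing states; apoptosis-committed cells still produce signal
#' until actual death.
#'
#' The trajectory is a deterministic function of the inputs and `seed`:
#' the same seed reproduces it bit-exactly.
#'
#' @param params An [onco_params()] object.
#' @param initial Initial counts, from [cell_state()] (non-negative
#'   integers).
#' @param schedule A [myc_schedule()].
#' @param t_end Duration (days); rounded up to the grid with a warning if
#'   not a multiple of `dt`.
#' @param seed Integer RNG seed for this run.
#' @param bli_states States included in `bli_signal` (default: all six —
#'   every live cell produces signal).
#' @param run_id Label stored in the `run_id` column.
#' @return A tibble of class `onco_trajectory` with columns `time`, `M`,
#'   `N`, `A`, `D`, `S`, `E`, `bli_signal`, `run_id`.
#' @examples
#' traj <- simulate_stochastic(
#'   onco_params(), cell_state(M = 1e5),
#'   myc_schedule("on", 10), t_end = 20, seed = 1
#' )
#' tail(traj)
#' @export
#' @seealso [simulate_deterministic()], [run_ensemble()]
simulate_stochastic <- function(params, initial, schedule, t_end, seed = 1L,
                                bli_states = STATES, run_id = "run_1") {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("seed must be a single integer.")
  }
  withr::with_seed(
    as.integer(seed),
    run_engine(params, initial, schedule, t_end,
      stochastic = TRUE,
      bli_states = bli_states, run_id = run_id, seed = as.integer(seed)
    )
  )
}

#' Simulate the mean-field (deterministic) trajectory
#'
#' Integrates the expectation form of the same model: every multinomial or
#' binomial draw of the stochastic engine is replaced by its mean `n * p`,
#' making counts non-negative reals.  The apoptosis state follows the delay
#' form dA/dt = (commitment influx at t) - (commitment influx at t -
#' tau_apop), with zero commitment pre-history before t = 0, so apoptotic
#' removal only starts `tau_apop` days after the first commitments.  This
#' engine is the exact expectation of the stochastic one on the same grid
#' and serves as its variance-free reference.
#'
#' @inheritParams simulate_stochastic
#' @param dt Integration step (days); defaults to `params$dt`.
#' @return A tibble of class `onco_trajectory` (`run_id = "deterministic"`).
#' @examples
#' simulate_deterministic(
#'   onco_params(), cell_state(M = 1e6),
#'   myc_schedule("on", 10), t_end = 30
#' )
#' @export
simulate_deterministic <- function(params, initial, schedule, t_end,
                                   bli_states = STATES, dt = params$dt) {
  run_engine(params, initial, schedule, t_end,
    stochastic = FALSE, dt = dt,
    bli_states = bli_states, run_id = "deterministic"
  )
}

#' Fine-grid reference integration
#'
#' Integrates the deterministic model at `dt / refinement` by the method of
#' steps.  Used as a discretization-error oracle in verification: as the
#' grid is refined the Euler solution converges to the continuous-time
#' delay system, so a large-refinement run is a near-exact reference
#' trajectory.
#'
#' @inheritParams simulate_deterministic
#' @param refinement Integer grid-refinement factor (>= 1).
#' @return An `onco_trajectory` on the fine grid (spacing `dt/refinement`).
#' @export
oracle_fine_grid <- function(params, initial, schedule, t_end, refinement = 100,
                             bli_states = STATES) {
  if (refinement < 1 || refinement != round(refinement)) {
    abort("refinement must be a positive integer.")
  }
  simulate_deterministic(params, initial, schedule, t_end,
    bli_states = bli_states, dt = params$dt / refinement
  )
}
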