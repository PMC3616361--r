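#' Apoptosis commitment-to-death delay queue
#'
#' FIFO queue of cohorts of apoptosis-committed cells awaiting actual
#' death.  Each cohort records its scheduled death time; the total queued
#' count always equals the current `A` state of the accompanying cell-state
#' vector.
#'
#' @param death_time Non-decreasing death times (days).
#' @param cells Non-negative integer cohort sizes.
#' @return A tibble of class `onco_delay_queue` with columns `death_time`
#'   and `cells`.
#' @export
delay_queue <- function(death_time = numeric(), cells = numeric()) {
  if (length(death_time) != length(cells)) {
    abort("death_time and cells must have equal length.")
  }
  if (length(death_time) && is.unsorted(death_time)) {
    abort("Queue death times must be non-decreasing (FIFO).")
  }
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Queue cohort sizes must be non-negative integers.")
  }
  q <- tibble::tibble(death_time = as.numeric(death_time), cells = as.numeric(cells))
  class(q) <- c("onco_delay_queue", class(q))
  q
}

#' Advance the stochastic model by one Euler step
#'
#' Single-step form of [simulate_stochastic()], exposing the delay queue.
#' From start-of-step counts, the cells leaving each state are one
#' multinomial draw over that state's open exits under the current MYC
#' `program`; binomial births are added to the mother state; cells newly
#' committed to apoptosis are enqueued with death time `t + tau_apop`; and
#' every cohort whose death time falls within the step (`<= t + dt`) is
#' dequeued and removed from `A`.  Draws use R's global RNG stream
#' (`set.seed()` for reproducibility).
#'
#' @param state Named non-negative integer counts (see [cell_state()]).
#' @param t Time at the start of the step (days).
#' @param queue A [delay_queue()]; its total must equal `state["A"]`.
#' @param params An [onco_params()] object.
#' @param program MYC program in force during the step, `"on"` or `"off"`.
#' @return A list with elements `state` (counts at `t + dt`), `queue`
#'   (updated queue), `t` (`t + dt`), and `deaths` (cells removed this
#'   step).
#' @examples
#' set.seed(1)
#' st <- step_stochastic(
#'   cell_state(N = 1000), 0, delay_queue(),
#'   onco_params(), "off"
#' )
#' st$state
#' @export
step_stochastic <- function(state, t, queue, params, program = c("on", "off")) {
  stopifnot(inherits(params, "onco_params"))
  program <- match.arg(normalize_program(program), c("on", "off"))
  state <- as_cell_state(state)
  if (any(state != round(state))) {
    abort("Stochastic step requires integer counts.")
  }
  if (!inherits(queue, "onco_delay_queue")) {
    abort("queue must be a delay_queue().")
  }
  if (abs(sum(queue$cells) - state[["A"]]) > 1e-9) {
    abort("Delay-queue total must equal the A count.")
  }

  dt <- params$dt
  res <- advance_state(unname(state), program == "on", step_probs(params), TRUE)
  commits <- res[7L]
  if (commits > 0) {
    queue <- delay_queue(
      c(queue$death_time, t + max(params$tau_apop, 0)),
      c(queue$cells, commits)
    )
  }
  due <- queue$death_time <= t + dt + 1e-9
  deaths <- sum(queue$cells[due])
  counts <- res[1:6]
  counts[3L] <- counts[3L] - deaths
  queue <- queue[!due, , drop = FALSE]
  class(queue) <- c("onco_delay_queue", setdiff(class(queue), "onco_delay_queue"))

  list(
    state = setNames(counts, STATES),
    queue = queue,
    t = t + dt,
    deaths = deaths
  )
}
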