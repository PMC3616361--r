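#' Per-step exit probabilities of one cellular state
#'
#' The transition kernel shared by the stochastic and deterministic engines.
#' For a source state and a MYC program it returns the probability, over one
#' Euler step of length `dt`, of moving along each outgoing edge of the
#' state-transition graph, using the first-order rule `p = K * dt`.  Edge
#' gating follows the biology of the conditional system:
#'
#' * `M -> N` (rate `k_inactivation`) is open only while the program is
#'   off, and `N -> M` (rate `k_activation`) only while it is on — the
#'   tetracycline-controlled path is open in one direction at a time.
#' * `D -> M` (rate `k_wake`, dormant differentiated cells regaining the
#'   neoplastic state) is open only while the program is on.
#' * `S` is absorbing (senescence is irreversible cell-cycle arrest): the
#'   exit map is empty.
#' * `A` has no kernel exits: removal of apoptosis-committed cells is the
#'   engines' delayed-death bookkeeping, not a per-step probability.
#'
#' Proliferation is a birth event (the mother stays in state, one daughter
#' is added to the same state), not an exit; see [birth_probability()].
#'
#' @param params An [onco_params()] object.
#' @param state One of `"M"`, `"N"`, `"A"`, `"D"`, `"S"`, `"E"`.
#' @param program MYC program, `"on"` or `"off"`.
#' @return Named numeric vector of destination probabilities (possibly
#'   empty); the names are destination states.  Probabilities sum to at
#'   most 1.
#' @examples
#' p <- onco_params()
#' exit_probabilities(p, "N", "off") # apoptosis dominates MYC-off exits
#' exit_probabilities(p, "S", "off") # senescence is absorbing
#' @export
exit_probabilities <- function(params, state, program = c("on", "off")) {
  stopifnot(inherits(params, "onco_params"))
  state <- match.arg(state, STATES)
  program <- match.arg(normalize_program(program), c("on", "off"))
  on <- program == "on"
  dt <- params$dt

  # edges closed by program gating are omitted entirely; edges whose rate
  # constant happens to be zero (e.g. k_relapse in competent hosts) are kept
  # at probability 0 so callers can see the full open topology
  probs <- switch(state,
    M = {
      out <- c(A = params$k_M_apop * dt)
      if (!on) out <- c(N = params$k_inactivation * dt, out)
      out
    },
    N = {
      out <- c(
        A = params$k_N_apop * dt,
        D = params$k_diff * dt,
        S = params$k_senesc * dt,
        E = params$k_relapse * dt
      )
      if (on) out <- c(M = params$k_activation * dt, out)
      out
    },
    A = setNames(numeric(0), character(0)),
    D = {
      out <- c(A = params$k_D_apop * dt)
      if (on) out <- c(out, M = params$k_wake * dt)
      out
    },
    S = setNames(numeric(0), character(0)),
    E = c(A = params$k_E_apop * dt)
  )
  if (sum(probs) > 1) {
    abort(paste0(
      "Exit probabilities of state ", state, " sum to ",
      signif(sum(probs), 4), " > 1; use a smaller dt."
    ))
  }
  probs
}

#' Per-step birth probability of one cellular state
#'
#' Probability that a cell of the given state produces one daughter (added
#' to the same state) during one Euler step: `k_prolif * dt` for the
#' proliferating states `M`, `N` and `E`, zero for `A`, `D` and `S`.
#' Daughters born in a step only become eligible for transitions at the
#' next step.
#'
#' @inheritParams exit_probabilities
#' @return A single probability.
#' @export
birth_probability <- function(params, state) {
  stopifnot(inherits(params, "onco_params"))
  state <- match.arg(state, STATES)
  dt <- params$dt
  switch(state,
    M = params$k_M_prolif * dt,
    N = params$k_N_prolif * dt,
    E = params$k_E_prolif * dt,
    0
  )
}

# Precompute all per-step probabilities once per simulation.  Scalars, not
# named vectors: the inner loop runs tens of thousands of times.
step_probs <- function(params, dt = params$dt) {
  list(
    m_to_n = params$k_inactivation * dt, # off only
    m_to_a = params$k_M_apop * dt,
    m_birth = params$k_M_prolif * dt,
    n_to_m = params$k_activation * dt, # on only
    n_to_a = params$k_N_apop * dt,
    n_to_d = params$k_diff * dt,
    n_to_s = params$k_senesc * dt,
    n_to_e = params$k_relapse * dt,
    n_birth = params$k_N_prolif * dt,
    d_to_a = params$k_D_apop * dt,
    d_to_m = params$k_wake * dt, # on only
    e_to_a = params$k_E_apop * dt,
    e_birth = params$k_E_prolif * dt
  )
}
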