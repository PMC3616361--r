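#' Rate parameters for the six-state oncogene-addiction model
#'
#' Builds the full set of first-order rate constants governing transitions
#' between the six tumor-cell states (`M` MYC-on, `N` MYC-off, `A`
#' apoptosis-committed, `D` differentiated, `S` senescent, `E` escaped),
#' together with the apoptosis commitment-to-death delay `tau_apop` and the
#' Euler time step `dt`.  Defaults are the calibrated per-day values for
#' conditional MYC mouse models; two of them depend on context:
#'
#' * `k_D_apop` is tumor-type dependent: 0.05 (lymphoma), 0.002
#'   (osteosarcoma), 0.01 (hepatocellular carcinoma).
#' * `k_relapse` (MYC-off to escaped) is immune dependent: 0 in
#'   immunocompetent hosts, 3e-8 in immunodeficient hosts.
#' * `k_senesc` (MYC-off to senescent) is set to 0 in immunodeficient hosts,
#'   because oncogene inactivation-induced senescence requires intact host
#'   immunity (CD4+ T cells).  This gating is an interpretive modeling
#'   choice and can be overridden.
#'
#' Any rate can be overridden by name through `...`.  Per-step transition
#' probabilities are first order, `p = K * dt`, so the constructor checks
#' that for every state the worst-case total exit probability (over both MYC
#' programs) does not exceed 1; `tau_apop` must sit on the integration grid
#' and is rounded to the nearest multiple of `dt` with a warning otherwise.
#'
#' @param tumor_type One of `"lymphoma"`, `"osteosarcoma"`,
#'   `"hepatocellular"`.
#' @param immune_status One of `"competent"`, `"deficient"`.
#' @param ... Named overrides for individual fields (any `k_*` rate,
#'   `tau_apop`, `dt`).
#'
#' @return An object of class `onco_params`: a named list with the thirteen
#'   rate constants (day^-1), `tau_apop` (days) and `dt` (days), carrying
#'   `tumor_type` and `immune_status` as attributes.
#'
#' @examples
#' onco_params()                              # lymphoma, immunocompetent
#' onco_params("osteosarcoma", "deficient")
#' onco_params(k_N_apop = 1, dt = 0.05)       # overrides
#' @export
onco_params <- function(tumor_type = c("lymphoma", "osteosarcoma", "hepatocellular"),
                        immune_status = c("competent", "deficient"),
                        ...) {
  tumor_type <- match.arg(tumor_type)
  immune_status <- match.arg(immune_status)

  p <- list(
    k_M_prolif = 0.5,
    k_M_apop = 0.05,
    k_N_prolif = 0.1,
    k_N_apop = 2,
    k_diff = 0.02,
    k_senesc = if (immune_status == "competent") 0.001 else 0,
    k_relapse = if (immune_status == "competent") 0 else 3e-8,
    k_wake = 0.1,
    k_E_prolif = 0.5,
    k_E_apop = 0.01,
    k_D_apop = switch(tumor_type,
      lymphoma = 0.05,
      osteosarcoma = 0.002,
      hepatocellular = 0.01
    ),
    k_inactivation = 2,
    k_activation = 2,
    tau_apop = 4.5,
    dt = 0.02
  )

  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      abort(paste0(
        "Unknown parameter field(s): ",
        paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")
      ))
    }
    p[names(overrides)] <- overrides
  }

  p <- lapply(p, as.numeric)
  attr(p, "tumor_type") <- tumor_type
  attr(p, "immune_status") <- immune_status
  class(p) <- "onco_params"
  validate_onco_params(p)
}

#' Validate a set of model rate parameters
#'
#' Checks non-negativity of all rates, positivity of `dt`, that per-step
#' exit probabilities `K * dt` form a valid probability vector for every
#' state under either MYC program, and that `tau_apop` is an integer
#' multiple of `dt` (rounding it, with a warning, if not).
#'
#' @param p An `onco_params` object (or a named list with the same fields).
#' @return The validated (possibly tau-rounded) `onco_params` object,
#'   invisibly usable in pipes.
#' @export
validate_onco_params <- function(p) {
  rates <- setdiff(names(p), c("tau_apop", "dt"))
  for (f in c(rates, "tau_apop", "dt")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      abort(paste0("Field '", f, "' must be a single finite number."))
    }
    if (v < 0) abort(paste0("Field '", f, "' must be non-negative (got ", v, ")."))
  }
  if (p$dt <= 0) abort("Field 'dt' must be strictly positive.")

  # worst-case total exit probability per state across MYC programs
  exit_sums <- c(
    M = p$k_M_apop + p$k_inactivation, # program off
    N = p$k_N_apop + p$k_diff + p$k_senesc + p$k_relapse + p$k_activation, # on
    D = p$k_D_apop + p$k_wake, # program on
    E = p$k_E_apop
  ) * p$dt
  if (any(exit_sums > 1)) {
    bad <- names(exit_sums)[which.max(exit_sums)]
    abort(paste0(
      "Per-step exit probability for state ", bad, " is ",
      signif(max(exit_sums), 4), " > 1; use a smaller dt."
    ))
  }
  births <- c(p$k_M_prolif, p$k_N_prolif, p$k_E_prolif) * p$dt
  if (any(births > 1)) {
    abort("Per-step birth probability exceeds 1; use a smaller dt.")
  }

  tau_steps <- p$tau_apop / p$dt
  if (abs(tau_steps - round(tau_steps)) > 1e-8) {
    warn(paste0(
      "tau_apop (", p$tau_apop, ") is not a multiple of dt (", p$dt,
      "); rounding to ", round(tau_steps) * p$dt, "."
    ))
    p$tau_apop <- round(tau_steps) * p$dt
  }
  p
}

#' @export
print.onco_params <- function(x, ...) {
  cat("<onco_params> ", attr(x, "tumor_type"), ", immune-",
    attr(x, "immune_status"), "\n",
    sep = ""
  )
  flds <- unlist(x)
  cat(paste0("  ", format(names(flds)), " ", format(flds, digits = 6)),
    sep = "\n"
  )
  invisible(x)
}

#' Initial cell-count vector
#'
#' Convenience constructor for a state-count vector over the six cellular
#' states, in canonical order `M, N, A, D, S, E`.  Unspecified states start
#' at zero.
#'
#' @param M,N,A,D,S,E Non-negative cell counts.
#' @return A named numeric vector of length six.
#' @examples
#' cell_state(M = 1e6)
#' @export
cell_state <- function(M = 0, N = 0, A = 0, D = 0, S = 0, E = 0) {
  v <- c(M = M, N = N, A = A, D = D, S = S, E = E)
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("Cell counts must be finite and non-negative.")
  }
  v
}

# coerce user-supplied initial state to canonical order, filling zeros
as_cell_state <- function(x) {
  if (is.null(names(x))) {
    if (length(x) != 6L) abort("Unnamed initial state must have length 6 (M,N,A,D,S,E).")
    names(x) <- STATES
  }
  bad <- setdiff(names(x), STATES)
  if (length(bad)) abort(paste0("Unknown state name(s): ", paste(bad, collapse = ", ")))
  v <- setNames(numeric(6), STATES)
  v[names(x)] <- as.numeric(x)
  if (any(!is.finite(v)) || any(v < 0)) abort("Cell counts must be finite and non-negative.")
  v
}
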