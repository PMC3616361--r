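# A parameter set with every rate zeroed except those supplied, for
# isolating single transitions in engine tests.
only_rates <- function(..., tau_apop = 0, dt = 0.02) {
  zeros <- list(
    k_M_prolif = 0, k_M_apop = 0, k_N_prolif = 0, k_N_apop = 0,
    k_diff = 0, k_senesc = 0, k_relapse = 0, k_wake = 0,
    k_E_prolif = 0, k_E_apop = 0, k_D_apop = 0,
    k_inactivation = 0, k_activation = 0
  )
  on <- list(...)
  zeros[names(on)] <- on
  do.call(onco_params, c(list("lymphoma", "competent"),
    zeros,
    tau_apop = tau_apop, dt = dt
  ))
}

# Randomized but always-valid parameter set for property-style tests
# (total per-step exit probabilities stay well below 1 at dt = 0.02).
random_params <- function() {
  onco_params(
    sample(c("lymphoma", "osteosarcoma", "hepatocellular"), 1),
    sample(c("competent", "deficient"), 1),
    k_M_prolif = runif(1, 0, 1), k_M_apop = runif(1, 0, 0.5),
    k_N_prolif = runif(1, 0, 0.5), k_N_apop = runif(1, 0, 3),
    k_diff = runif(1, 0, 0.5), k_senesc = runif(1, 0, 0.1),
    k_relapse = runif(1, 0, 1e-4), k_wake = runif(1, 0, 0.5),
    k_E_prolif = runif(1, 0, 1), k_E_apop = runif(1, 0, 0.5),
    k_D_apop = runif(1, 0, 0.5),
    k_inactivation = runif(1, 0, 3), k_activation = runif(1, 0, 3),
    tau_apop = sample(c(0, 0.1, 1, 4.5), 1)
  )
}

# Dense 5-state generator matrix (M, N, D, S, E) of the zero-delay model
# under a constant MYC program; with tau_apop = 0 apoptosis-committed cells
# leave the system within the step, so A decouples and the rest is linear.
generator_matrix <- function(p, program) {
  on <- program == "on"
  labs <- c("M", "N", "D", "S", "E")
  Q <- matrix(0, 5, 5, dimnames = list(labs, labs))
  Q["M", "M"] <- p$k_M_prolif - p$k_M_apop - (if (on) 0 else p$k_inactivation)
  Q["N", "M"] <- if (on) 0 else p$k_inactivation
  Q["M", "N"] <- if (on) p$k_activation else 0
  Q["N", "N"] <- p$k_N_prolif - p$k_N_apop - p$k_diff - p$k_senesc -
    p$k_relapse - (if (on) p$k_activation else 0)
  Q["M", "D"] <- if (on) p$k_wake else 0
  Q["D", "N"] <- p$k_diff
  Q["D", "D"] <- -p$k_D_apop - (if (on) p$k_wake else 0)
  Q["S", "N"] <- p$k_senesc
  Q["E", "N"] <- p$k_relapse
  Q["E", "E"] <- p$k_E_prolif - p$k_E_apop
  Q
}
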