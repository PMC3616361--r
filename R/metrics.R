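# t_switch resolution: explicit argument wins, else the trajectory's
# schedule metadata (lost if the tibble went through dplyr verbs)
resolve_t_switch <- function(traj, t_switch) {
  ts <- t_switch %||% attr(traj, "t_switch")
  if (is.null(ts)) {
    abort("t_switch not supplied and not recoverable from the trajectory.")
  }
  if (!is.na(ts) && (ts < min(traj$time) || ts > max(traj$time))) {
    abort("t_switch lies outside the trajectory grid.")
  }
  ts
}

bli_at <- function(traj, t) traj$bli_signal[which.min(abs(traj$time - t))]

#' Onset of tumor decline after oncogene inactivation
#'
#' Time elapsed between MYC inactivation and the start of the decline in
#' total signal: the first time after `t_switch` at which `bli_signal`
#' falls below `frac` of its value at `t_switch` and stays below for at
#' least `persist` days (a guard against transient stochastic dips).  With
#' the apoptosis commitment-to-death delay in place this onset trails the
#' inactivation by roughly `tau_apop` even though proliferative arrest is
#' nearly immediate, reproducing the observed 4-5 day lag before tumor
#' shrinkage; with `tau_apop = 0` the decline starts essentially at the
#' switch.
#'
#' @param traj An `onco_trajectory`.
#' @param t_switch Inactivation time (days); defaults to the trajectory's
#'   first MYC-off switch.
#' @param frac Decline threshold as a fraction of the signal at `t_switch`.
#' @param persist Persistence window (days) the signal must stay below the
#'   threshold.
#' @return Days from `t_switch` to onset, or `NA` if the signal never
#'   declines.
#' @export
onset_of_decline <- function(traj, t_switch = NULL, frac = 0.99, persist = 1) {
  ts <- resolve_t_switch(traj, t_switch)
  if (is.na(ts)) {
    return(NA_real_)
  }
  thr <- frac * bli_at(traj, ts)
  dt <- traj$time[2] - traj$time[1]
  after <- which(traj$time > ts)
  if (!length(after)) {
    return(NA_real_)
  }
  below <- traj$bli_signal[after] < thr
  if (!any(below)) {
    return(NA_real_)
  }
  need <- max(1L, as.integer(ceiling(persist / dt)))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # a run of "below" long enough, or one still in force when the grid ends
  ok <- which(r$values & (r$lengths >= need | ends == length(below)))
  if (!length(ok)) {
    return(NA_real_)
  }
  traj$time[after[starts[ok[1]]]] - ts
}

#' Regression half-time
#'
#' Days after MYC inactivation for the total signal to fall to half of its
#' value at the inactivation time.  This operational statistic summarizes
#' the regression kinetics of one run; across replicate runs it varies very
#' little because regression is driven by large cell numbers.
#'
#' @inheritParams onset_of_decline
#' @return Days from `t_switch` to the half-signal crossing, or `NA` if the
#'   signal never falls that far.
#' @export
regression_half_time <- function(traj, t_switch = NULL) {
  ts <- resolve_t_switch(traj, t_switch)
  if (is.na(ts)) {
    return(NA_real_)
  }
  thr <- 0.5 * bli_at(traj, ts)
  after <- which(traj$time > ts & traj$bli_signal <= thr)
  if (!length(after)) {
    return(NA_real_)
  }
  traj$time[after[1]] - ts
}

#' Relapse time
#'
#' First time after the post-inactivation nadir at which the total signal
#' re-crosses `threshold_fraction` of the pre-inactivation peak.  Relapse
#' requires the signal to have first regressed below the threshold; a
#' trajectory that never declines, or never regrows past the threshold,
#' has no relapse time.  In immunocompetent hosts (`k_relapse = 0`) relapse
#' is impossible; in immunodeficient hosts its timing varies from run to
#' run because it descends from rare single-cell escape events.
#'
#' @inheritParams onset_of_decline
#' @param threshold_fraction Relapse threshold as a fraction of the
#'   pre-inactivation peak signal (default 0.5).
#' @return Relapse time (absolute days), or `NA` if the tumor never
#'   relapses.
#' @export
relapse_time <- function(traj, threshold_fraction = 0.5, t_switch = NULL) {
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    abort("threshold_fraction must be in (0, 1].")
  }
  ts <- resolve_t_switch(traj, t_switch)
  if (is.na(ts)) {
    return(NA_real_)
  }
  peak <- max(traj$bli_signal[traj$time <= ts])
  thr <- threshold_fraction * peak
  after <- which(traj$time >= ts)
  sig <- traj$bli_signal[after]
  if (min(sig) >= thr) {
    return(NA_real_)
  } # never regressed below threshold
  nadir <- after[which.min(sig)]
  recross <- which(traj$time > traj$time[nadir] & traj$bli_signal >= thr)
  if (!length(recross)) {
    return(NA_real_)
  }
  traj$time[recross[1]]
}

#' Per-run summary of regression and relapse kinetics
#'
#' @inheritParams relapse_time
#' @param frac,persist Passed to [onset_of_decline()].
#' @return A one-row tibble with `onset_of_decline`, `nadir_signal`,
#'   `nadir_time`, `regression_half_time` and `relapse_time` (days; `NA`
#'   where undefined).
#' @export
run_summary <- function(traj, t_switch = NULL, threshold_fraction = 0.5,
                        frac = 0.99, persist = 1) {
  ts <- resolve_t_switch(traj, t_switch)
  if (is.na(ts)) {
    idx <- which.min(traj$bli_signal)
  } else {
    cand <- which(traj$time >= ts)
    idx <- cand[which.min(traj$bli_signal[cand])]
  }
  tibble::tibble(
    onset_of_decline = onset_of_decline(traj, ts, frac = frac, persist = persist),
    nadir_signal = traj$bli_signal[idx],
    nadir_time = traj$time[idx],
    regression_half_time = regression_half_time(traj, ts),
    relapse_time = relapse_time(traj, threshold_fraction, ts)
  )
}

#' Regression-versus-relapse variability of an ensemble
#'
#' Coefficients of variation (sd/mean) of the regression half-time and of
#' the relapse time across the runs of an ensemble, each computed over the
#' runs in which the quantity is defined.  Regression, carried by large
#' cell numbers, is nearly identical across runs; relapse timing, seeded by
#' rare escape events, spreads — so `cv_relapse > cv_regression` whenever
#' relapse occurs at all.
#'
#' @param ensemble An [run_ensemble()] result.
#' @return A one-row tibble: `cv_regression`, `cv_relapse` (each `NA` when
#'   defined in fewer than 2 runs), `n_regression`, `n_relapse` (counts of
#'   runs with the quantity defined) and `n_runs`.
#' @export
variability_report <- function(ensemble) {
  stopifnot(inherits(ensemble, "onco_ensemble"))
  s <- ensemble$summaries
  cv <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x) / mean(x)
  }
  tibble::tibble(
    cv_regression = cv(s$regression_half_time),
    cv_relapse = cv(s$relapse_time),
    n_regression = sum(is.finite(s$regression_half_time)),
    n_relapse = sum(is.finite(s$relapse_time)),
    n_runs = nrow(s)
  )
}
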