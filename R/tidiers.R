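#' Tidy a trajectory into long state/count form
#'
#' @param x An `onco_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `run_id`, `state` (factor in
#'   canonical order `M`,`N`,`A`,`D`,`S`,`E`) and `cells`.
#' @export
tidy.onco_trajectory <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("time", "run_id", dplyr::all_of(STATES)) |>
    tidyr::pivot_longer(dplyr::all_of(STATES),
      names_to = "state", values_to = "cells"
    ) |>
    dplyr::mutate(state = factor(.data$state, levels = STATES))
}

#' One-row overview of a trajectory
#'
#' @param x An `onco_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: engine, seed, grid (`dt`, `t_end`), peak and
#'   final total signal, and final escaped-cell count.
#' @export
glance.onco_trajectory <- function(x, ...) {
  tibble::tibble(
    engine = if (isTRUE(attr(x, "stochastic"))) "stochastic" else "deterministic",
    seed = attr(x, "seed"),
    dt = attr(x, "dt"),
    t_end = max(x$time),
    peak_signal = max(x$bli_signal),
    final_signal = x$bli_signal[nrow(x)],
    final_escaped = x$E[nrow(x)]
  )
}

#' Per-run summaries of an ensemble
#'
#' @param x An `onco_ensemble`.
#' @param ... Unused.
#' @return The ensemble's summary tibble: one row per run with seed,
#'   onset, nadir, regression half-time and relapse time.
#' @export
tidy.onco_ensemble <- function(x, ...) x$summaries

#' One-row overview of an ensemble
#'
#' @param x An `onco_ensemble`.
#' @param ... Unused.
#' @return [variability_report()] plus the base seed and duration.
#' @export
glance.onco_ensemble <- function(x, ...) {
  dplyr::bind_cols(
    variability_report(x),
    tibble::tibble(base_seed = x$base_seed, t_end = x$t_end)
  )
}

#' Plot a simulated trajectory
#'
#' Total signal (bioluminescence proxy) and, optionally, the six state
#' populations over time on a log scale; zero counts are dropped from the
#' log-scaled panel.
#'
#' @param object An `onco_trajectory`.
#' @param states Also draw the individual state populations.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.onco_trajectory <- function(object, states = TRUE, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(
      ggplot2::aes(y = ifelse(.data$bli_signal > 0, .data$bli_signal, NA)),
      linewidth = 0.9
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (days)", y = "cells (log scale)",
      title = "Tumor burden (total signal-producing cells)"
    )
  if (states) {
    long <- tidy.onco_trajectory(object) |> dplyr::filter(.data$cells > 0)
    p <- p + ggplot2::geom_line(
      data = long,
      ggplot2::aes(y = .data$cells, colour = .data$state),
      alpha = 0.7, linewidth = 0.4
    ) +
      ggplot2::labs(colour = "state")
  }
  ts <- attr(object, "t_switch")
  if (!is.null(ts) && !is.na(ts)) {
    p <- p + ggplot2::geom_vline(xintercept = ts, linetype = "dashed", alpha = 0.5)
  }
  p
}

#' Overlay plot of an ensemble of runs
#'
#' Total signal of every replicate run over time (log scale), the classic
#' view of regression/relapse variability: the regression limbs of all
#' runs coincide while relapse limbs fan out.
#'
#' @param object An `onco_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.onco_ensemble <- function(object, ...) {
  df <- object$trajectories |> dplyr::filter(.data$bli_signal > 0)
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$time, y = .data$bli_signal, group = .data$run_id)
  ) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (days)", y = "cells (log scale)",
      title = paste0(
        "Ensemble of ", length(object$seeds),
        " stochastic runs (base seed ", object$base_seed, ")"
      )
    )
  if (!is.na(object$t_switch)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$t_switch,
      linetype = "dashed", alpha = 0.5
    )
  }
  p
}

#' @export
plot.onco_trajectory <- function(x, ...) print(autoplot.onco_trajectory(x, ...))

#' @export
plot.onco_ensemble <- function(x, ...) print(autoplot.onco_ensemble(x, ...))
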