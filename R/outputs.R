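#' Write simulation outputs to a directory
#'
#' Serializes a result to tidy CSVs plus a JSON run record and a file
#' manifest.  Trajectory CSVs use the schema `t, M, N, A, D, S, E,
#' bli_signal, run_id`; floats are written at full (shortest
#' round-trippable) precision so re-running with the same seeds reproduces
#' the files byte-for-byte.  The run record captures the package version,
#' the full parameter/schedule configuration and every seed, which is
#' sufficient to regenerate the outputs exactly.  An overlay plot is also
#' written unless `plot = FALSE`.
#'
#' @param result An `onco_trajectory`, an `onco_ensemble`, or a plain
#'   data frame (e.g. a [relapse_rate_sensitivity()] table).
#' @param out_dir Output directory; created if missing.
#' @param plot Also write `plot.png`.
#' @return Invisibly, the manifest tibble (`file`, `md5`, `bytes`), which
#'   is also written as `manifest.csv`.
#' @export
write_outputs <- function(result, out_dir, plot = TRUE) {
  UseMethod("write_outputs")
}

traj_csv <- function(traj, path) {
  out <- tibble::as_tibble(traj)[, c("time", STATES, "bli_signal", "run_id")]
  names(out)[1] <- "t"
  readr::write_csv(out, path)
  path
}

finish_outputs <- function(out_dir, files, record) {
  rec_path <- file.path(out_dir, "run_record.json")
  jsonlite::write_json(record, rec_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, rec_path)
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files)
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

record_skeleton <- function(params, schedule, t_end, bli_states) {
  list(
    package = "oncoaddict",
    version = as.character(packageVersion("oncoaddict")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = c(
      list(
        tumor_type = attr(params, "tumor_type"),
        immune_status = attr(params, "immune_status")
      ),
      unclass(params),
      list(
        initial_program = schedule$initial_program,
        switch_times = schedule$switch_times,
        switch_programs = schedule$switch_programs,
        t_end = t_end,
        bli_states = bli_states
      )
    )
  )
}

#' @export
write_outputs.onco_trajectory <- function(result, out_dir, plot = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- traj_csv(result, file.path(
    out_dir,
    paste0("trajectory_", result$run_id[1], ".csv")
  ))
  if (plot) {
    p <- autoplot(result)
    ggplot2::ggsave(file.path(out_dir, "plot.png"), p,
      width = 7, height = 4.5, dpi = 150
    )
    files <- c(files, file.path(out_dir, "plot.png"))
  }
  record <- record_skeleton(
    attr(result, "params"), attr(result, "schedule"),
    max(result$time), attr(result, "bli_states")
  )
  record$seed <- attr(result, "seed")
  record$engine <- if (isTRUE(attr(result, "stochastic"))) "stochastic" else "deterministic"
  finish_outputs(out_dir, files, record)
}

#' @export
write_outputs.onco_ensemble <- function(result, out_dir, plot = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runs <- split(result$trajectories, result$trajectories$run_id)
  files <- purrr::imap_chr(runs, function(tr, id) {
    traj_csv(tr, file.path(out_dir, paste0("trajectory_", id, ".csv")))
  })
  sum_path <- file.path(out_dir, "summaries.csv")
  readr::write_csv(result$summaries, sum_path)
  files <- c(files, sum_path)
  if (plot) {
    p <- autoplot(result)
    ggplot2::ggsave(file.path(out_dir, "plot.png"), p,
      width = 7, height = 4.5, dpi = 150
    )
    files <- c(files, file.path(out_dir, "plot.png"))
  }
  record <- record_skeleton(
    result$params, result$schedule, result$t_end, result$bli_states
  )
  record$base_seed <- result$base_seed
  record$run_seeds <- result$seeds
  record$engine <- "stochastic"
  finish_outputs(out_dir, files, record)
}

#' @export
write_outputs.data.frame <- function(result, out_dir, plot = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "result.csv")
  readr::write_csv(tibble::as_tibble(result), path)
  record <- list(
    package = "oncoaddict",
    version = as.character(packageVersion("oncoaddict")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  finish_outputs(out_dir, path, record)
}
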