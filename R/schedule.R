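#' Piecewise-constant MYC on/off program
#'
#' The MYC transgene program is the experimentally controlled variable of
#' the tetracycline system (doxycycline added to or withdrawn from the
#' drinking water).  A schedule is an initial program plus an ordered list
#' of switch events; the program is piecewise constant and left-closed: a
#' switch takes effect at exactly its switch time.
#'
#' @param initial_program `"on"` or `"off"`; the program in force from t = 0.
#' @param switch_times Strictly increasing, non-negative switch times (days).
#' @param switch_programs Programs in force from each switch time onward.
#'   Defaults to alternating starting opposite to `initial_program`.
#' @return An object of class `myc_schedule`.
#' @examples
#' myc_schedule("on", switch_times = 10)        # MYC inactivated at day 10
#' myc_schedule("on")                           # never inactivated
#' @export
myc_schedule <- function(initial_program = c("on", "off"),
                         switch_times = numeric(),
                         switch_programs = NULL) {
  initial_program <- normalize_program(initial_program)
  if (identical(initial_program, c("on", "off"))) initial_program <- "on"
  if (length(initial_program) != 1L || !initial_program %in% c("on", "off")) {
    abort("initial_program must be 'on' or 'off'.")
  }
  switch_times <- as.numeric(switch_times)
  if (length(switch_times)) {
    if (any(!is.finite(switch_times)) || any(switch_times < 0)) {
      abort("Switch times must be finite and non-negative.")
    }
    if (is.unsorted(switch_times, strictly = TRUE)) {
      abort("Switch times must be strictly increasing.")
    }
  }
  if (is.null(switch_programs)) {
    two <- c("on", "off")
    start <- if (initial_program == "on") "off" else "on"
    switch_programs <- rep_len(c(start, setdiff(two, start)), length(switch_times))
  }
  switch_programs <- normalize_program(switch_programs)
  if (length(switch_programs) != length(switch_times)) {
    abort("switch_programs must have one entry per switch time.")
  }
  if (!all(switch_programs %in% c("on", "off"))) {
    abort("Programs must be 'on' or 'off'.")
  }
  structure(
    list(
      initial_program = initial_program,
      switch_times = switch_times,
      switch_programs = switch_programs
    ),
    class = "myc_schedule"
  )
}

# YAML 1.1 parses bare on/off as logicals; accept both spellings
normalize_program <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "on", "off")
  as.character(x)
}

#' Evaluate a MYC schedule
#'
#' Returns the program in force at each time `t`.  Intervals are
#' left-closed: at a switch time the new program already applies.
#'
#' @param schedule A [myc_schedule()].
#' @param t Vector of times (days), all non-negative.
#' @return Character vector of `"on"`/`"off"`, one per element of `t`.
#' @examples
#' sched <- myc_schedule("on", switch_times = 10)
#' myc_program_at(sched, c(5, 10, 20))
#' @export
myc_program_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "myc_schedule"))
  if (any(t < 0)) abort("Times must be non-negative.")
  progs <- c(schedule$initial_program, schedule$switch_programs)
  progs[findInterval(t, schedule$switch_times) + 1L]
}

#' @export
print.myc_schedule <- function(x, ...) {
  cat("<myc_schedule> initial:", x$initial_program, "\n")
  if (length(x$switch_times)) {
    cat(paste0(
      "  t = ", format(x$switch_times), " d -> ", x$switch_programs
    ), sep = "\n")
  } else {
    cat("  (no switches)\n")
  }
  invisible(x)
}

# first time at which the program becomes "off" (the inactivation time used
# by the regression/relapse metrics); NA if the program is never off
first_off_time <- function(schedule) {
  if (schedule$initial_program == "off") {
    return(0)
  }
  i <- which(schedule$switch_programs == "off")
  if (length(i)) schedule$switch_times[i[1]] else NA_real_
}
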