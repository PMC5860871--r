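#' Build the event schedule for one constant-TOA block
#'
#' A block presents `n_trials` trials at a fixed trial onset asynchrony
#' (TOA), the interval from one trial's onset to the next.  The schedule
#' records the onset times used both to simulate BOLD runs and to build
#' GLM predictors.
#'
#' @param toa_s Trial onset asynchrony in seconds (> 0).
#' @param n_trials Number of trials in the block (>= 1).
#' @param start_s Onset of the first trial, seconds from run start.
#' @param duration_s Modeled event duration in seconds; 0 (default)
#'   treats each trial as an impulse at its onset.
#' @return An object of class `event_schedule`: a list with `toa_s`,
#'   `onsets_s`, `duration_s`, `n_trials`.
#' @examples
#' sched <- make_event_schedule(toa_s = 3, n_trials = 16)
#' sched$onsets_s   # 0, 3, ..., 45
#' @export
make_event_schedule <- function(toa_s, n_trials, start_s = 0, duration_s = 0) {
  if (!is.numeric(toa_s) || length(toa_s) != 1L || !is.finite(toa_s) || toa_s <= 0)
    stop("'toa_s' must be a single positive number, got ", deparse(toa_s))
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1 ||
      n_trials != round(n_trials))
    stop("'n_trials' must be a positive integer, got ", deparse(n_trials))
  if (duration_s < 0) stop("'duration_s' must be >= 0")
  structure(
    list(
      toa_s = as.numeric(toa_s),
      onsets_s = start_s + (seq_len(n_trials) - 1) * toa_s,
      duration_s = as.numeric(duration_s),
      n_trials = as.integer(n_trials)
    ),
    class = "event_schedule"
  )
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf(
    "Event schedule: %d trials, TOA %g s, onsets %g..%g s (duration %g s)\n",
    x$n_trials, x$toa_s, x$onsets_s[1], x$onsets_s[x$n_trials], x$duration_s
  ))
  invisible(x)
}

# span of the block in seconds, from first onset to end of last event
schedule_end <- function(sched) {
  sched$onsets_s[sched$n_trials] + sched$duration_s
}

#' Lay out one run of constant-TOA blocks
#'
#' Places one block per TOA condition sequentially, separated by a rest
#' gap, and returns the schedules plus the run length in volumes.  The
#' gap prevents the hemodynamic response of one block from bleeding into
#' the next.
#'
#' @param toas_s TOA per block, seconds (one block per element, in
#'   presentation order).
#' @param n_trials Trials per block.
#' @param gap_s Rest interval between the last onset of a block and the
#'   first onset of the next, seconds.
#' @param tr_s Repetition time, seconds.
#' @param duration_s Event duration passed to [make_event_schedule()].
#' @param tail_s Rest after the final block before the run ends.
#' @return List with `schedules` (list of `event_schedule`) and `n_vols`.
#' @export
layout_run <- function(toas_s, n_trials = 16, gap_s = 20, tr_s = 1,
                       duration_s = 0, tail_s = gap_s) {
  if (gap_s <= 0) stop("'gap_s' must be positive")
  schedules <- vector("list", length(toas_s))
  start <- 0
  for (i in seq_along(toas_s)) {
    schedules[[i]] <- make_event_schedule(toas_s[i], n_trials,
                                          start_s = start,
                                          duration_s = duration_s)
    start <- schedule_end(schedules[[i]]) + gap_s
  }
  total_s <- schedule_end(schedules[[length(schedules)]]) + tail_s
  list(schedules = schedules, n_vols = as.integer(ceiling(total_s / tr_s)))
}

#' Write event schedules as a TSV event table
#'
#' One row per trial with columns `onset`, `duration`, `toa`, `block`,
#' `run`.
#'
#' @param schedules List of `event_schedule` (one run) or list of such
#'   lists (multiple runs).
#' @param path Output file path.
#' @export
write_event_tsv <- function(schedules, path) {
  if (inherits(schedules[[1]], "event_schedule")) schedules <- list(schedules)
  rows <- list()
  for (r in seq_along(schedules)) {
    for (b in seq_along(schedules[[r]])) {
      s <- schedules[[r]][[b]]
      rows[[length(rows) + 1L]] <- data.frame(
        onset = s$onsets_s, duration = s$duration_s,
        toa = s$toa_s, block = b, run = r
      )
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
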