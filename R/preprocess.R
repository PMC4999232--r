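# stimulus phase at time t, rounded so that presses landing exactly on an
# occlusion configuration do not wrap to 359.999... degrees
.stimulus_phase <- function(t, f) {
  round(360 * f * t, 6) %% 360
}

# Convert button-press event logs into trial series sampled at
# self-occlusion configurations, plus descriptive response statistics.
# A "trial" is the interval between two consecutive self-occluding
# configurations; responses are down-sampled onto that grid.

#' Convert a block's event log into a trial series
#'
#' A clear press is attributed to the latest occlusion onset at or before
#' the press (block onset counts as an onset for presses preceding the
#' first occlusion). The percept `theta` of each inter-occlusion interval
#' is the key state after attributing, last press wins within an interval;
#' intervals before the first clear press, and intervals governed by a
#' MIXED press until the next clear press, are missing.
#'
#' @param log A `response_log` data frame with columns `time_s`, `key` and
#'   `block` (an empty log yields an all-missing series).
#' @param schedule The block's [occlusion_event_times()] schedule.
#' @param block Which block of `log` to convert (default: the only one).
#' @param block_start_s Run time of block onset; subtracted from press
#'   times so they are measured from block onset.
#' @return An object of class `trial_series`: a list with `condition`,
#'   `occlusion_times_s`, `theta` (1 = CW, 0 = CCW, `NA` = missing; one
#'   entry per inter-occlusion interval), `press_times_s` and
#'   `press_phases_deg`.
#' @export
events_to_trials <- function(log, schedule, block = NULL, block_start_s = 0) {
  stopifnot(inherits(schedule, "occlusion_schedule"))
  if (!is.null(block)) log <- log[log$block == block, , drop = FALSE]
  ev <- schedule$event_times_s
  n <- length(ev)
  bounds <- c(0, ev)
  times <- log$time_s - block_start_s
  keys <- as.character(log$key)
  o <- order(times)
  times <- times[o]; keys <- keys[o]
  inside <- times >= 0 & times <= schedule$block_duration_s + 1e-9
  times <- times[inside]; keys <- keys[inside]
  # trial index of each press: k such that bounds[k] <= t < bounds[k+1]
  trial <- pmin(findInterval(times, bounds), n)
  val <- ifelse(keys == "CW", 1, ifelse(keys == "CCW", 0, NA_real_))
  last <- findInterval(seq_len(n), trial)  # last press at or before trial k
  theta <- ifelse(last == 0L, NA_real_, val[pmax(last, 1L)])
  f <- schedule$condition$shift_freq_rps
  structure(list(condition = schedule$condition,
                 occlusion_times_s = ev,
                 theta = as.numeric(theta),
                 press_times_s = times,
                 press_keys = keys,
                 press_phases_deg = .stimulus_phase(times, f)),
            class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf(
    "<trial series '%s': %d trials (%d missing), %d presses>\n",
    x$condition$label, length(x$theta), sum(is.na(x$theta)),
    length(x$press_times_s)))
  invisible(x)
}

#' Fraction of clear-percept responses
#'
#' Number of CW and CCW presses divided by the total number of presses,
#' mixed-percept presses included.
#'
#' @param log A `response_log` data frame (any number of blocks).
#' @return Proportion in `[0, 1]`.
#' @export
clear_fraction <- function(log) {
  if (nrow(log) == 0L)
    stop("undefined: the event log contains no presses", call. = FALSE)
  mean(log$key %in% c("CW", "CCW"))
}

#' Perceptual phase durations
#'
#' Durations between consecutive percept changes, in seconds. A change is
#' the boundary at which `theta` differs from the previous non-missing
#' trial; the final, incomplete phase is excluded, as is the opening phase
#' (it has no observed start).
#'
#' @param series A [events_to_trials()] result.
#' @return Numeric vector of durations (possibly empty).
#' @export
phase_durations <- function(series) {
  stopifnot(inherits(series, "trial_series"))
  theta <- series$theta
  obs <- which(!is.na(theta))
  if (length(obs) < 2L) return(numeric(0))
  chg <- obs[-1L][theta[obs[-1L]] != theta[obs[-length(obs)]]]
  if (length(chg) < 2L) return(numeric(0))
  # percept adopted during trial k took over at the occlusion opening it
  starts <- c(0, series$occlusion_times_s)[chg]
  diff(starts)
}

#' Histogram of transition presses over stimulus phase
#'
#' Transition presses are clear presses whose key differs from the
#' previous clear press within the block (the first clear press of a block
#' is an onset report, not a transition). Each is binned by the phase
#' shift of the stimulus at press time.
#'
#' @param log A `response_log` data frame.
#' @param schedule The block's [occlusion_event_times()] schedule (used for
#'   the phase of the rotation; presses are taken relative to block onset).
#' @param bin_deg Bin width in degrees; must divide 360.
#' @param block,block_start_s See [events_to_trials()].
#' @return Data frame with `phase_deg` (bin lower edge) and `count`;
#'   counts sum to the number of transition presses.
#' @export
press_phase_histogram <- function(log, schedule, bin_deg = 10,
                                  block = NULL, block_start_s = 0) {
  stopifnot(inherits(schedule, "occlusion_schedule"))
  if (360 %% bin_deg != 0)
    stop("'bin_deg' must divide 360", call. = FALSE)
  if (!is.null(block)) log <- log[log$block == block, , drop = FALSE]
  clear <- log[log$key %in% c("CW", "CCW"), , drop = FALSE]
  clear <- clear[order(clear$time_s), , drop = FALSE]
  times <- clear$time_s - block_start_s
  keys <- as.character(clear$key)
  edges <- seq(0, 360, by = bin_deg)
  counts <- integer(length(edges) - 1L)
  if (length(keys) > 1L) {
    trans <- which(keys[-1L] != keys[-length(keys)]) + 1L
    f <- schedule$condition$shift_freq_rps
    ph <- .stimulus_phase(times[trans], f)
    counts <- as.integer(table(cut(ph, edges, right = FALSE,
                                   include.lowest = TRUE)))
  }
  data.frame(phase_deg = edges[-length(edges)], count = counts)
}
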