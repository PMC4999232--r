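# Synthetic observers that emit button-press event logs with the response
# structure of bistable Lissajous viewing: an initial report shortly after
# block onset, presses clustering in a latency window after self-occlusion
# events, occasional mixed-percept presses followed by a corrective clear
# press, and unimodal long-tailed phase-duration distributions.

#' Observer configuration
#'
#' @param mode `"markov"` for a memoryless observer that flips its percept
#'   at each self-occlusion with a fixed probability, or `"bayes"` for an
#'   observer that forward-samples the generative stability-prior model
#'   (see [forward_filter()]).
#' @param switch_prob Per-occlusion flip probability (markov mode).
#' @param model_params A [model_params()] object (bayes mode).
#' @param rt_mean_s,rt_sd_s Mean and SD of the truncated-normal response
#'   latency after an occlusion event, in seconds.
#' @param mixed_rate Probability that a press is replaced by a
#'   mixed-percept press followed by a corrective clear press.
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return An object of class `observer_config`.
#' @export
observer_config <- function(mode = c("markov", "bayes"), switch_prob = NULL,
                            model_params = NULL, rt_mean_s = 0.55,
                            rt_sd_s = 0.15, mixed_rate = 0.04, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "markov") {
    if (is.null(switch_prob) || switch_prob < 0 || switch_prob > 1)
      stop("markov mode needs 'switch_prob' in [0, 1]", call. = FALSE)
  } else {
    if (is.null(model_params) || !inherits(model_params, "model_params"))
      stop("bayes mode needs 'model_params'", call. = FALSE)
  }
  if (rt_mean_s < 0 || rt_sd_s < 0)
    stop("latency parameters must be non-negative", call. = FALSE)
  if (mixed_rate < 0 || mixed_rate >= 1)
    stop("'mixed_rate' must be in [0, 1)", call. = FALSE)
  structure(list(mode = mode, switch_prob = switch_prob,
                 model_params = model_params, rt_mean_s = rt_mean_s,
                 rt_sd_s = rt_sd_s, mixed_rate = mixed_rate, seed = seed),
            class = "observer_config")
}

# truncated-normal sampler on [lower, upper), vectorized in upper
.rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0)
    return(pmin(pmax(rep(mean, n), lower), upper * (1 - 1e-9)))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
  pmin(pmax(x, lower), upper * (1 - 1e-9))
}

# Turn a per-trial percept sequence into a press log. theta[k] is the
# percept held during trial k = [bounds[k], bounds[k+1]); a press is
# emitted at the trial start plus a latency whenever the percept changes
# (and for the initial report at block onset).
.emit_presses <- function(theta, bounds, config) {
  n <- length(theta)
  gaps <- diff(bounds)
  press_trials <- c(1L, 1L + which(diff(theta) != 0))
  base <- bounds[press_trials]
  lat <- .rtrunc_norm(length(press_trials), config$rt_mean_s, config$rt_sd_s,
                      0, gaps[press_trials])
  times <- base + lat
  keys <- ifelse(theta[press_trials] == 1, "CW", "CCW")
  mixed <- stats::runif(length(times)) < config$mixed_rate
  if (any(mixed)) {
    idx <- which(mixed)
    room <- bounds[press_trials[idx] + 1L] - times[idx]
    corr_t <- times[idx] + stats::runif(length(idx), 0.2, 0.6) * room
    times <- c(times, corr_t)
    keys[idx] <- "MIXED"
    keys <- c(keys, ifelse(theta[press_trials[idx]] == 1, "CW", "CCW"))
  }
  o <- order(times)
  data.frame(time_s = times[o], key = keys[o], stringsAsFactors = FALSE)
}

.check_latency <- function(config, gaps) {
  if (config$rt_mean_s >= min(gaps))
    stop("latency distribution incompatible with the inter-occlusion ",
         "interval", call. = FALSE)
}

#' Simulate a memoryless (Markov) observer on one block
#'
#' The initial percept is uniform at block onset and reported after a
#' response latency; at each self-occlusion the percept flips with
#' probability `switch_prob`, and a press is emitted only when the percept
#' changes. With probability `mixed_rate` a press is replaced by a MIXED
#' press followed by a corrective clear press within the same
#' inter-occlusion interval. Phase durations are geometric in units of
#' inter-occlusion intervals, giving the sharp-rise/long-tail shape typical
#' of bistable perception.
#'
#' @param schedule An [occlusion_event_times()] schedule.
#' @param config An [observer_config()] with `mode = "markov"`.
#' @return A `response_log` data frame with columns `time_s`, `key`
#'   (`CW`/`CCW`/`MIXED`) and `block`; the simulated per-trial percept is
#'   attached as attribute `percept`.
#' @export
simulate_markov <- function(schedule, config) {
  stopifnot(inherits(schedule, "occlusion_schedule"),
            inherits(config, "observer_config"))
  if (config$mode != "markov") stop("config mode must be 'markov'",
                                    call. = FALSE)
  ev <- schedule$event_times_s
  n <- length(ev)
  bounds <- c(0, ev)
  .check_latency(config, diff(bounds))
  if (!is.null(config$seed)) set.seed(config$seed)
  init <- sample(0:1, 1L)
  flips <- stats::runif(n - 1L) < config$switch_prob
  theta <- (init + cumsum(c(0L, flips))) %% 2
  log <- .emit_presses(theta, bounds, config)
  log$block <- 1L
  structure(log, percept = theta, schedule = schedule,
            class = c("response_log", "data.frame"))
}

#' Simulate an observer that forward-samples the stability-prior model
#'
#' Trial by trial, the predicted probability of clockwise rotation is
#' computed from the stability prior (mean = previous percept, precision
#' reset to `pi_init` after each new perceptual decision, otherwise decayed
#' by the precision-weighted prediction error) and the percept is sampled
#' as a Bernoulli draw from the response-mapped probability. Presses are
#' emitted on percept changes exactly as in [simulate_markov()].
#'
#' @inheritParams simulate_markov
#' @param config An [observer_config()] with `mode = "bayes"`; its
#'   `model_params` supply `pi_init` (scalar or named by condition label),
#'   `pi_sensory` and `zeta`.
#' @return A `response_log` data frame; see [simulate_markov()].
#' @export
simulate_bayes <- function(schedule, config) {
  stopifnot(inherits(schedule, "occlusion_schedule"),
            inherits(config, "observer_config"))
  if (config$mode != "bayes") stop("config mode must be 'bayes'",
                                   call. = FALSE)
  ev <- schedule$event_times_s
  n <- length(ev)
  bounds <- c(0, ev)
  .check_latency(config, diff(bounds))
  if (!is.null(config$seed)) set.seed(config$seed)
  mp <- config$model_params
  pi_init <- .pi_init_for(mp, schedule$condition$label)
  theta <- integer(n)
  pe <- numeric(n)
  theta[1] <- stats::rbinom(1L, 1L, 0.5)  # initial percept, uniform
  pe[1] <- theta[1] - 0.5
  pi_cur <- pi_init
  if (n >= 2) for (k in 2:n) {
    new_decision <- (k == 2L) || (theta[k - 1L] != theta[k - 2L])
    pi_cur <- if (new_decision) pi_init
              else .decay_precision(pi_cur, mp$pi_sensory, pe[k - 1L])
    p_post <- posterior_prob_cw(theta[k - 1L], pi_cur)
    theta[k] <- stats::rbinom(1L, 1L, response_map(p_post, mp$zeta))
    pe[k] <- theta[k] - p_post
  }
  log <- .emit_presses(theta, bounds, config)
  log$block <- 1L
  structure(log, percept = theta, schedule = schedule,
            class = c("response_log", "data.frame"))
}

.simulate_block <- function(schedule, config) {
  switch(config$mode,
         markov = simulate_markov(schedule, config),
         bayes = simulate_bayes(schedule, config))
}

#' Simulate a cohort of observers over randomized runs
#'
#' Each subject completes `n_runs` runs; every run draws its own random
#' block order and per-block observer noise, with all seeds derived
#' deterministically from the master seed.
#'
#' @param n_subjects,n_runs Cohort dimensions.
#' @param configs A single [observer_config()] applied to every condition,
#'   or a list named by condition label.
#' @param seed Master integer seed.
#' @param design List of four conditions, as from [study_design()].
#' @param block_duration_s Block duration in seconds.
#' @return An object of class `lissa_cohort`: a list with `logs` (one
#'   `response_log` per subject x run, carrying `subject`, `run` and the
#'   run schedule as attributes), `design` and `seed`.
#' @export
simulate_cohort <- function(n_subjects, n_runs, configs, seed,
                            design = study_design(), block_duration_s = 80) {
  stopifnot(n_subjects >= 1, n_runs >= 1)
  if (inherits(configs, "observer_config"))
    configs <- stats::setNames(rep(list(configs), length(design)),
                               names(design))
  if (!all(names(design) %in% names(configs)))
    stop("'configs' must cover every condition label", call. = FALSE)
  set.seed(seed)
  n_cells <- n_subjects * n_runs
  order_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  block_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_cells * 4L),
                        nrow = n_cells)
  schedules <- lapply(design, occlusion_event_times,
                      block_duration_s = block_duration_s)
  logs <- vector("list", n_cells)
  cell <- 0L
  for (s in seq_len(n_subjects)) for (r in seq_len(n_runs)) {
    cell <- cell + 1L
    rs <- run_schedule(design, seed = order_seeds[cell],
                       block_duration_s = block_duration_s)
    parts <- lapply(seq_len(4L), function(b) {
      lab <- rs$blocks$label[b]
      cfg <- configs[[lab]]
      cfg$seed <- block_seeds[cell, b]
      blk <- .simulate_block(schedules[[lab]], cfg)
      data.frame(time_s = blk$time_s + rs$blocks$start_s[b], key = blk$key,
                 block = b, condition_label = lab, stringsAsFactors = FALSE)
    })
    log <- do.call(rbind, parts)
    logs[[cell]] <- structure(log, subject = s, run = r, schedule = rs,
                              class = c("response_log", "data.frame"))
  }
  structure(list(logs = logs, design = design, seed = seed,
                 n_subjects = n_subjects, n_runs = n_runs,
                 block_duration_s = block_duration_s),
            class = "lissa_cohort")
}

#' @export
print.lissa_cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d subjects x %d runs, %d event logs>\n",
              x$n_subjects, x$n_runs, length(x$logs)))
  invisible(x)
}

#' Bind a cohort's event logs into one data frame
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Data frame with columns `subject`, `run`, `block`,
#'   `condition_label`, `time_s`, `key`.
#' @export
cohort_events <- function(cohort) {
  stopifnot(inherits(cohort, "lissa_cohort"))
  do.call(rbind, lapply(cohort$logs, function(lg) {
    data.frame(subject = attr(lg, "subject"), run = attr(lg, "run"),
               block = lg$block, condition_label = lg$condition_label,
               time_s = lg$time_s, key = lg$key, stringsAsFactors = FALSE)
  }))
}
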