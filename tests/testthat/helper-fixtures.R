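# Shared fixtures: all built in code at test time.

slow_small <- condition_spec(0.15, 2.05)
fast_small <- condition_spec(0.30, 2.05)

# a block schedule with n occlusion events at shifting frequency f
schedule_n <- function(n, f = 0.30) {
  occlusion_event_times(condition_spec(f, 2.05), n / (2 * f))
}

# hand-built response log for one block
make_log <- function(time_s, key, block = 1L) {
  structure(data.frame(time_s = time_s, key = key,
                       block = rep(block, length(time_s)),
                       stringsAsFactors = FALSE),
            class = c("response_log", "data.frame"))
}

# percept sequence forward-sampled from the stability-prior model
simulate_percepts_for_test <- function(pi0, n, seed, f = 0.30) {
  sched <- schedule_n(n, f)
  log <- simulate_bayes(sched, observer_config(
    "bayes", model_params = model_params(pi_init = pi0),
    rt_mean_s = 0, rt_sd_s = 0, mixed_rate = 0, seed = seed))
  as.numeric(attr(log, "percept"))
}

# trial series with a prescribed theta sequence on a uniform schedule
make_series <- function(theta, f = 0.30) {
  sched <- schedule_n(length(theta), f)
  bounds <- c(0, sched$event_times_s)
  obs <- which(!is.na(theta))
  times <- bounds[obs] + 0.2
  keys <- ifelse(theta[obs] == 1, "CW", "CCW")
  # only emit presses at the start and at changes
  chg <- c(TRUE, diff(theta[obs]) != 0)
  events_to_trials(make_log(times[chg], keys[chg]), sched)
}
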