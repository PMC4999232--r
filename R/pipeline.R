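# End-to-end pipeline: simulate -> preprocess -> conventional stats ->
# model inversion -> random-effects BMS -> summary report, with plain CSV
# event/trial logs and JSON result records.

.SCHEMA_VERSION <- "1.0"

# small stable FNV-1a hash of a serialized configuration, for tagging
# output files; plumbing, not cryptography
.config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' @param n_subjects,n_runs Cohort dimensions.
#' @param observer_mode `"markov"` or `"bayes"`.
#' @param switch_prob Named per-condition flip probabilities (markov); the
#'   defaults are the condition-level transition rates the generator
#'   emulates (0.34 slow, 0.12 fast).
#' @param pi_init Named per-condition initial precisions (bayes); default
#'   2.0 slow, 3.0 fast.
#' @param pi_sensory,zeta Fixed model parameters for simulation and
#'   inversion.
#' @param rt_mean_s,rt_sd_s,mixed_rate Observer response parameters.
#' @param priors A [prior_spec()] for inversion.
#' @param seed Master seed.
#' @param n_mc Monte-Carlo draws for BMS exceedance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 18, n_runs = 8,
                            observer_mode = c("bayes", "markov"),
                            switch_prob = c(slow_small = 0.34,
                                            fast_small = 0.12,
                                            slow_big = 0.34,
                                            fast_big = 0.12),
                            pi_init = c(slow_small = 2.0, fast_small = 3.0,
                                        slow_big = 2.0, fast_big = 3.0),
                            pi_sensory = 1, zeta = 1,
                            rt_mean_s = 0.55, rt_sd_s = 0.15,
                            mixed_rate = 0.04,
                            priors = prior_spec(), seed = 1, n_mc = 1e5) {
  observer_mode <- match.arg(observer_mode)
  structure(list(n_subjects = n_subjects, n_runs = n_runs,
                 observer_mode = observer_mode, switch_prob = switch_prob,
                 pi_init = pi_init, pi_sensory = pi_sensory, zeta = zeta,
                 rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
                 mixed_rate = mixed_rate, priors = priors, seed = seed,
                 n_mc = n_mc),
            class = "pipeline_config")
}

.observer_configs <- function(config) {
  design <- study_design()
  lapply(stats::setNames(names(design), names(design)), function(lab) {
    if (config$observer_mode == "markov")
      observer_config("markov", switch_prob = config$switch_prob[[lab]],
                      rt_mean_s = config$rt_mean_s,
                      rt_sd_s = config$rt_sd_s,
                      mixed_rate = config$mixed_rate)
    else
      observer_config("bayes",
                      model_params = model_params(
                        pi_init = config$pi_init,
                        pi_sensory = config$pi_sensory,
                        zeta = config$zeta),
                      rt_mean_s = config$rt_mean_s,
                      rt_sd_s = config$rt_sd_s,
                      mixed_rate = config$mixed_rate)
  })
}

#' Preprocess every run of a cohort into trial series
#'
#' @param cohort A [simulate_cohort()] result.
#' @return List with `series` (per run: list of `trial_series` named by
#'   condition label, with `subject`/`run` attributes) and `table` (long
#'   data frame of all trials).
#' @export
cohort_trials <- function(cohort) {
  stopifnot(inherits(cohort, "lissa_cohort"))
  schedules <- lapply(cohort$design, occlusion_event_times,
                      block_duration_s = cohort$block_duration_s)
  series <- lapply(cohort$logs, function(lg) {
    rs <- attr(lg, "schedule")
    out <- lapply(seq_len(nrow(rs$blocks)), function(b) {
      lab <- rs$blocks$label[b]
      events_to_trials(lg, schedules[[lab]], block = b,
                       block_start_s = rs$blocks$start_s[b])
    })
    names(out) <- rs$blocks$label
    attr(out, "subject") <- attr(lg, "subject")
    attr(out, "run") <- attr(lg, "run")
    out
  })
  rows <- lapply(series, function(run) {
    do.call(rbind, lapply(names(run), function(lab) {
      s <- run[[lab]]
      data.frame(subject = attr(run, "subject"), run = attr(run, "run"),
                 condition_label = lab,
                 trial_index = seq_along(s$theta),
                 occlusion_time_s = s$occlusion_times_s,
                 theta = s$theta, stringsAsFactors = FALSE)
    }))
  })
  list(series = series, table = do.call(rbind, rows))
}

#' Conventional analysis of a cohort
#'
#' Computes the per-run transition probability for every condition,
#' averages across runs within subject, and submits the subject x 2 x 2
#' table to the repeated-measures ANOVA.
#'
#' @param trials A [cohort_trials()] result.
#' @return List with `per_run` (long data frame of transition
#'   probabilities), `per_subject` (run-averaged, see [aggregate_runs()]),
#'   `condition_means` and `anova`.
#' @export
conventional_analysis <- function(trials) {
  per_run <- do.call(rbind, lapply(trials$series, function(run) {
    data.frame(subject = attr(run, "subject"), run = attr(run, "run"),
               condition_label = names(run),
               value = vapply(run, transition_probability, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  per_subject <- aggregate_runs(per_run)
  list(per_run = per_run,
       per_subject = per_subject,
       condition_means = attr(per_subject, "condition_means"),
       anova = rm_anova_2x2(per_subject))
}

#' Fit both models to every run of a cohort
#'
#' Inverts the stability-prior model (model A) per run over its four
#' condition blocks jointly and scores the prior-free control (model B) on
#' the same trials; per-subject log evidences are the sums over runs
#' (independent sessions).
#'
#' @param trials A [cohort_trials()] result.
#' @param priors A [prior_spec()].
#' @param params A [model_params()] with the fixed `pi_sensory` and
#'   `zeta`.
#' @return List with `per_run` (data frame: subject, run, per-condition
#'   `pi_` estimates, `lme_a`, `lme_b`, `converged`), `pi_subject`
#'   (run-averaged per-condition posterior estimates per subject) and
#'   `lme` (subjects x 2 matrix for [rfx_bms()]).
#' @export
fit_cohort <- function(trials, priors = prior_spec(),
                       params = model_params()) {
  rows <- lapply(trials$series, function(run) {
    fit <- fit_stability_model(run, priors = priors, params = params)
    pis <- as.list(fit$pi_init_map)
    names(pis) <- paste0("pi_", names(pis))
    cbind(data.frame(subject = attr(run, "subject"), run = attr(run, "run")),
          as.data.frame(pis),
          data.frame(lme_a = fit$lme, lme_b = model_b_evidence(run),
                     converged = fit$converged))
  })
  per_run <- do.call(rbind, rows)
  pi_cols <- grep("^pi_", names(per_run), value = TRUE)
  pi_subject <- stats::aggregate(per_run[pi_cols],
                                 by = list(subject = per_run$subject), mean)
  lme_a <- tapply(per_run$lme_a, per_run$subject, sum)
  lme_b <- tapply(per_run$lme_b, per_run$subject, sum)
  lme <- cbind(stability_prior = as.numeric(lme_a),
               no_prior = as.numeric(lme_b))
  rownames(lme) <- names(lme_a)
  list(per_run = per_run, pi_subject = pi_subject, lme = lme)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, preprocesses it, runs the conventional analysis,
#' inverts both models, performs random-effects BMS, and (optionally)
#' writes event CSV, trials CSV and JSON result records to `out_dir`.
#' Fully reproducible from the configuration and its seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return List with `cohort`, `trials`, `conventional`, `fits`, `bms`
#'   and `summary` (per-condition transition probabilities and mean
#'   `pi_init`, the ANOVA table, exceedance probabilities, config hash and
#'   seed).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- .config_hash(unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("simulate",
                  simulate_cohort(config$n_subjects, config$n_runs,
                                  .observer_configs(config), config$seed))
  trials <- stage("preprocess", cohort_trials(cohort))
  conv <- stage("conventional", conventional_analysis(trials))
  mp <- model_params(pi_sensory = config$pi_sensory, zeta = config$zeta)
  fits <- stage("fit", fit_cohort(trials, priors = config$priors,
                                  params = mp))
  bms <- stage("bms", rfx_bms(fits$lme, n_mc = config$n_mc,
                              seed = config$seed + 1L))
  pi_means <- colMeans(fits$pi_subject[grep("^pi_",
                                            names(fits$pi_subject))])
  names(pi_means) <- sub("^pi_", "", names(pi_means))
  summary <- list(schema_version = .SCHEMA_VERSION,
                  config_hash = hash, seed = config$seed,
                  transition_probability = as.list(conv$condition_means),
                  anova = conv$anova,
                  pi_init_mean = as.list(pi_means),
                  exceedance_prob = as.list(bms$exceedance_prob))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(schema_version = .SCHEMA_VERSION, config_hash = hash,
                 seed = config$seed)
    wjson <- function(x, file)
      jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    utils::write.csv(format_times(cohort_events(cohort)),
                     file.path(out_dir, "events.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(format_times(trials$table),
                     file.path(out_dir, "trials.csv"), row.names = FALSE,
                     quote = FALSE)
    wjson(c(meta, list(condition_means = as.list(conv$condition_means),
                       anova = conv$anova)), "conv.json")
    wjson(c(meta, list(per_run = fits$per_run)), "fitsA.json")
    wjson(c(meta, list(lme = as.data.frame(fits$lme))), "fitsB.json")
    wjson(c(meta, list(alpha = as.list(bms$alpha),
                       expected_prob = as.list(bms$expected_prob),
                       exceedance_prob = as.list(bms$exceedance_prob))),
          "bms.json")
    wjson(summary, "summary.json")
  }
  list(cohort = cohort, trials = trials, conventional = conv, fits = fits,
       bms = bms, summary = summary)
}

# seconds with 6 decimals, '.' decimal separator
format_times <- function(df) {
  for (col in intersect(c("time_s", "occlusion_time_s"), names(df)))
    df[[col]] <- sprintf("%.6f", df[[col]])
  df
}
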