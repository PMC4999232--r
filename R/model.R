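# Generative Bayesian model of perceptual stability.
#
# The percept on trial t (theta = 1 clockwise, 0 counter-clockwise) is
# predicted from a 'perceptual stability' prior whose mean is the percept
# reported on the previous trial and whose precision pi_stability is reset
# to pi_init whenever a new perceptual decision was just made, and
# otherwise decays multiplicatively by a precision-weighted prediction
# error:
#   pi(t) = pi(t-1) * exp(-(pi_sensory / pi(t-1)) * |PE(t-1)|).
# Combining the stability prior with a symmetric bimodal likelihood over
# the two percepts gives posterior odds
#   r = exp(((theta0 - mu)^2 - (theta1 - mu)^2) * pi / (-2)),
# hence P(theta = 1) = 1 / (r + 1); a unit sigmoid with exponent zeta maps
# this to the response probability, and PE(t) = theta(t) - P(theta = 1)(t).
#
# Model inversion estimates xi = log(pi_init) per condition by MAP under a
# standard-normal prior on xi (log-normal on the precision), with a
# Laplace approximation to the log-model evidence. The prior-free control
# model fixes pi_init = pi_sensory = 0, so every trial is predicted at
# probability 1/2.

.PROB_FLOOR <- 1e-12
.PI_FLOOR <- 1e-12

#' Model parameters
#'
#' @param pi_init Initial precision of the stability prior; a scalar or a
#'   vector named by condition label.
#' @param pi_sensory Precision of the sensory representation (fixed at 1
#'   for inversion).
#' @param zeta Response-noise exponent of the unit sigmoid (fixed at 1 for
#'   inversion).
#' @return An object of class `model_params`.
#' @export
model_params <- function(pi_init = 1, pi_sensory = 1, zeta = 1) {
  if (any(pi_init < 0)) stop("'pi_init' must be >= 0", call. = FALSE)
  if (pi_sensory < 0) stop("'pi_sensory' must be >= 0", call. = FALSE)
  if (zeta <= 0) stop("'zeta' must be > 0", call. = FALSE)
  structure(list(pi_init = pi_init, pi_sensory = pi_sensory, zeta = zeta,
                 theta0 = 0, theta1 = 1),
            class = "model_params")
}

.pi_init_for <- function(params, label) {
  p <- params$pi_init
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  if (!label %in% names(p))
    stop("no 'pi_init' entry for condition '", label, "'", call. = FALSE)
  unname(p[[label]])
}

#' Log-normal prior on the initial precision
#'
#' @param mean_log,var_log Mean and variance of `log(pi_init)`; the
#'   defaults (`log(1)` and 1) centre the prior on a precision of 1.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mean_log = 0, var_log = 1) {
  if (var_log <= 0) stop("'var_log' must be > 0", call. = FALSE)
  structure(list(mean_log = mean_log, var_log = var_log),
            class = "prior_spec")
}

#' Posterior probability of clockwise rotation
#'
#' Combines the stability prior (mean `mu`, precision `pi`) with the
#' symmetric bimodal likelihood over the two percepts: the posterior odds
#' of counter-clockwise over clockwise are
#' `r = exp(((0 - mu)^2 - (1 - mu)^2) * pi / (-2))` and
#' `P(theta = 1) = 1 / (r + 1)`.
#'
#' @param mu Prior mean (the previously reported percept, 0 or 1).
#' @param pi Prior precision, `>= 0`.
#' @return Probability of the clockwise percept.
#' @examples
#' posterior_prob_cw(1, 2)  # 1 / (1 + exp(-1)) = 0.731
#' posterior_prob_cw(0, 2)  # the mirror case, 0.269
#' @export
posterior_prob_cw <- function(mu, pi) {
  if (any(pi < 0)) stop("'pi' must be >= 0", call. = FALSE)
  r <- exp(((0 - mu)^2 - (1 - mu)^2) * pi / (-2))
  1 / (r + 1)
}

#' Unit-sigmoid response mapping
#'
#' @param p Probability in `(0, 1)`.
#' @param zeta Exponent `> 0`; 1 is the identity.
#' @return `p^zeta / (p^zeta + (1 - p)^zeta)`.
#' @export
response_map <- function(p, zeta = 1) {
  if (zeta <= 0) stop("'zeta' must be > 0", call. = FALSE)
  p^zeta / (p^zeta + (1 - p)^zeta)
}

#' Precision decay by precision-weighted prediction error
#'
#' @param pi_prev Precision on the previous trial, `> 0`.
#' @param pi_sensory Sensory precision.
#' @param pe_prev Prediction error on the previous trial.
#' @return `pi_prev * exp(-(pi_sensory / pi_prev) * |pe_prev|)`, never
#'   exceeding `pi_prev`.
#' @examples
#' update_precision(2, 1, 0.5)  # 2 * exp(-0.25) = 1.558
#' @export
update_precision <- function(pi_prev, pi_sensory, pe_prev) {
  if (any(pi_prev <= 0)) stop("'pi_prev' must be > 0", call. = FALSE)
  pi_prev * exp(-(pi_sensory / pi_prev) * abs(pe_prev))
}

# decay tolerating the degenerate pi = 0 (prior-free) corner
.decay_precision <- function(pi_prev, pi_sensory, pe_prev) {
  if (pi_prev <= .PI_FLOOR) return(pi_prev)
  max(update_precision(pi_prev, pi_sensory, pe_prev), .PI_FLOOR)
}

#' Run the forward filter over a trial series
#'
#' Applies the stability-prior recursion to the reported percepts of one
#' condition: the prior mean is the previous reported percept, the
#' precision resets to `pi_init` on trials following a new perceptual
#' decision (including the trial after the first report) and otherwise
#' decays by the precision-weighted prediction error. The first
#' non-missing trial is the initial report: it is treated as a reset with
#' a flat prediction of 1/2. Missing (mixed-percept) trials carry the
#' state across without decay.
#'
#' @param series A [events_to_trials()] result with at least two
#'   non-missing trials.
#' @param params A [model_params()] object.
#' @return A `latent_trajectory` data frame with one row per trial:
#'   `theta`, `mu_stability`, `pi_stability`, `p_cw` (posterior
#'   probability of clockwise), `theta_hat` (response-mapped prediction),
#'   `pe` (prediction error) and `t0` (trial follows a new perceptual
#'   decision).
#' @export
forward_filter <- function(series, params) {
  stopifnot(inherits(series, "trial_series"),
            inherits(params, "model_params"))
  theta <- series$theta
  obs <- which(!is.na(theta))
  if (length(obs) < 2L)
    stop("the series needs at least 2 non-missing trials", call. = FALSE)
  pi_init <- .pi_init_for(params, series$condition$label)
  n <- length(theta)
  out <- data.frame(trial = seq_len(n), theta = theta,
                    mu_stability = NA_real_, pi_stability = NA_real_,
                    p_cw = NA_real_, theta_hat = NA_real_, pe = NA_real_,
                    t0 = FALSE)
  # initial report: flat prediction, reset
  f1 <- obs[1L]
  out$pi_stability[f1] <- pi_init
  out$p_cw[f1] <- 0.5
  out$theta_hat[f1] <- 0.5
  out$pe[f1] <- theta[f1] - 0.5
  out$t0[f1] <- TRUE
  pi_cur <- pi_init
  for (j in seq_along(obs)[-1L]) {
    k <- obs[j]
    prev <- obs[j - 1L]
    new_decision <- (j == 2L) ||
      (theta[prev] != theta[obs[j - 2L]])
    pi_cur <- if (new_decision) pi_init
              else .decay_precision(pi_cur, params$pi_sensory, out$pe[prev])
    mu <- theta[prev]
    p_post <- posterior_prob_cw(mu, pi_cur)
    out$mu_stability[k] <- mu
    out$pi_stability[k] <- pi_cur
    out$p_cw[k] <- p_post
    out$theta_hat[k] <- response_map(p_post, params$zeta)
    out$pe[k] <- theta[k] - p_post
    out$t0[k] <- new_decision
  }
  class(out) <- c("latent_trajectory", "data.frame")
  out
}

# Bernoulli log-likelihood of one condition's series under a given
# pi_init. The first non-missing trial (the initial report) enters at
# probability 1/2 so that both models score the same trial set; trials
# with a defined previous percept are scored at the response-mapped
# prediction. Returns the log-likelihood and the number of scored trials.
.series_loglik <- function(series, pi_init, pi_sensory, zeta) {
  theta <- series$theta
  obs <- which(!is.na(theta))
  if (length(obs) == 0L) return(list(ll = 0, n = 0L))
  ll <- log(0.5)  # initial report
  if (length(obs) >= 2L) {
    pi_cur <- pi_init
    pe_prev <- theta[obs[1L]] - 0.5
    for (j in seq_along(obs)[-1L]) {
      k <- obs[j]
      prev <- obs[j - 1L]
      new_decision <- (j == 2L) || (theta[prev] != theta[obs[j - 2L]])
      pi_cur <- if (new_decision) pi_init
                else .decay_precision(pi_cur, pi_sensory, pe_prev)
      p_post <- posterior_prob_cw(theta[prev], pi_cur)
      th <- response_map(p_post, zeta)
      th <- min(max(th, .PROB_FLOOR), 1 - .PROB_FLOOR)
      ll <- ll + theta[k] * log(th) + (1 - theta[k]) * log(1 - th)
      pe_prev <- theta[k] - p_post
    }
  }
  list(ll = ll, n = length(obs))
}

.as_series_list <- function(series) {
  if (inherits(series, "trial_series")) {
    series <- stats::setNames(list(series), series$condition$label)
  }
  if (is.null(names(series)))
    names(series) <- vapply(series, function(s) s$condition$label, "")
  series
}

#' Log-joint density of percept data and log-precisions
#'
#' Sum of the Bernoulli log-likelihood of the reported percepts under the
#' forward filter run with `pi_init = exp(xi)` per condition, plus the
#' Gaussian log-prior density of each `xi`.
#'
#' @param series A `trial_series` or a list of them named by condition
#'   label.
#' @param xi Numeric vector of log initial precisions, named by condition
#'   label (matching `series`).
#' @param priors A [prior_spec()] object.
#' @param params A [model_params()] object supplying the fixed
#'   `pi_sensory` and `zeta`.
#' @return Scalar log-joint density.
#' @export
log_joint <- function(series, xi, priors = prior_spec(),
                      params = model_params()) {
  series <- .as_series_list(series)
  if (!setequal(names(series), names(xi)))
    stop("condition sets of 'series' and 'xi' must match", call. = FALSE)
  ll <- sum(vapply(names(series), function(lab)
    .series_loglik(series[[lab]], exp(xi[[lab]]), params$pi_sensory,
                   params$zeta)$ll, numeric(1)))
  lp <- sum(stats::dnorm(unlist(xi), priors$mean_log, sqrt(priors$var_log),
                         log = TRUE))
  ll + lp
}

#' Invert the stability-prior model on one run
#'
#' Estimates `xi = log(pi_init)` for each condition by MAP using
#' quasi-Newton (BFGS) ascent on the log-joint with multiple axis-aligned
#' starts. The log-joint separates across conditions (each has its own
#' free parameter and its own data), so the optimisation is performed
#' condition-wise and the posterior covariance is diagonal: the inverse
#' negative Hessian at the MAP from central finite differences. The
#' approximate log-model evidence is the Laplace estimate
#' `log_joint(MAP) + (d/2) log(2 pi) + (1/2) log det(cov)`.
#'
#' @param series_by_condition List of `trial_series` named by condition
#'   label (conditions with fewer than two non-missing trials contribute
#'   their prior only).
#' @param priors A [prior_spec()].
#' @param params A [model_params()]; its `pi_init` entry is ignored.
#' @param starts Numeric vector of start values for each 1-D search.
#' @return An object of class `fit_result` with `xi_map`, `pi_init_map`,
#'   `posterior_cov`, `lme`, `n_trials` and `converged`.
#' @export
fit_stability_model <- function(series_by_condition, priors = prior_spec(),
                                params = model_params(),
                                starts = c(-1, 0, 1)) {
  series <- .as_series_list(series_by_condition)
  labs <- names(series)
  sd_prior <- sqrt(priors$var_log)
  xi <- stats::setNames(numeric(length(labs)), labs)
  vars <- stats::setNames(numeric(length(labs)), labs)
  total <- 0
  n_trials <- 0L
  converged <- TRUE
  h <- 1e-4
  for (lab in labs) {
    ser <- series[[lab]]
    f <- function(x)
      .series_loglik(ser, exp(x), params$pi_sensory, params$zeta)$ll +
      stats::dnorm(x, priors$mean_log, sd_prior, log = TRUE)
    best <- NULL
    for (x0 in starts) {
      opt <- stats::optim(x0, function(x) -f(x), method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-10))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (best$convergence != 0) converged <- FALSE
    xi[lab] <- best$par
    total <- total + (-best$value)
    n_trials <- n_trials +
      .series_loglik(ser, exp(best$par), params$pi_sensory, params$zeta)$n
    d2 <- (f(best$par + h) - 2 * (-best$value) + f(best$par - h)) / h^2
    if (!is.finite(d2) || d2 >= -1e-8) {
      converged <- FALSE
      d2 <- min(d2, 0, na.rm = TRUE) - 1 / priors$var_log  # diagonal loading
    }
    vars[lab] <- -1 / d2
  }
  d <- length(labs)
  lme <- total + (d / 2) * log(2 * pi) + 0.5 * sum(log(vars))
  structure(list(xi_map = xi, pi_init_map = exp(xi),
                 posterior_cov = diag(vars, nrow = d),
                 lme = lme, n_trials = n_trials, converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<stability-model fit>\n  pi_init MAP:",
      paste(sprintf("%s=%.3f", names(x$pi_init_map), x$pi_init_map),
            collapse = ", "),
      sprintf("\n  lme: %.2f nats over %d trials%s\n", x$lme, x$n_trials,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Log evidence of the prior-free control model
#'
#' With `pi_init` and `pi_sensory` fixed at zero the stability prior is
#' flat and every scored trial is predicted at probability 1/2; the model
#' has no free parameters, so the log evidence is exactly
#' `n * log(1/2)` for `n` non-missing trials.
#'
#' @param series_by_condition A `trial_series` or a list of them.
#' @return Scalar log-model evidence in nats.
#' @export
model_b_evidence <- function(series_by_condition) {
  series <- .as_series_list(series_by_condition)
  n <- sum(vapply(series, function(s) sum(!is.na(s$theta)), integer(1)))
  n * log(0.5)
}
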