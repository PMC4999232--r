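test_that("posterior, response map and precision decay match hand values", {
  expect_equal(posterior_prob_cw(1, 0), 0.5)
  expect_equal(posterior_prob_cw(1, 2), 1 / (1 + exp(-1)),
               tolerance = 1e-10)
  expect_equal(posterior_prob_cw(1, 2), 0.7311, tolerance = 1e-4)
  # the two modes are symmetric
  for (pi0 in c(0.3, 1, 4))
    expect_equal(posterior_prob_cw(0, pi0), 1 - posterior_prob_cw(1, pi0))
  expect_equal(response_map(0.3, 1), 0.3)
  expect_equal(response_map(0.5, 7), 0.5)
  expect_equal(response_map(0.7311, 2), 0.8808, tolerance = 1e-4)
  expect_equal(update_precision(2, 1, 0.5), 2 * exp(-0.25))
  expect_equal(update_precision(2, 1, 0.5), 1.5576, tolerance = 1e-4)
  expect_equal(update_precision(3, 1, 0), 3)
  expect_equal(update_precision(3, 0, 0.7), 3)
  expect_true(update_precision(2, 1, 0.4) <= 2)
  expect_error(update_precision(0, 1, 0.1), "pi_prev")
})

test_that("the forward filter resets, decays and drifts toward 1/2", {
  mp <- model_params(pi_init = 1, pi_sensory = 1)
  ts <- make_series(rep(1, 24))
  tr <- forward_filter(ts, mp)
  # trial after the reset: posterior at mu = 1, pi = 1 mapped by zeta = 1
  expect_equal(tr$p_cw[2], 1 / (1 + exp(-0.5)), tolerance = 1e-10)
  expect_equal(tr$p_cw[2], 0.6225, tolerance = 1e-4)
  # under a constant percept the precision decays and p_cw falls to 1/2
  # (strictly, until the precision reaches its numerical floor)
  expect_true(all(diff(tr$pi_stability[-1]) <= 0))
  expect_true(all(diff(tr$pi_stability[2:6]) < 0))
  expect_true(all(diff(tr$p_cw[-1]) <= 0))
  expect_lt(tr$p_cw[24], tr$p_cw[2])
  expect_true(all(tr$p_cw > 0.5 - 1e-12))
  # with pi_sensory = 0 the precision never decays between switches
  tr0 <- forward_filter(ts, model_params(pi_init = 2, pi_sensory = 0))
  expect_equal(tr0$pi_stability[-1], rep(2, 23))
  # reset correctness: pi equals pi_init on trials after a percept change
  theta <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 1, 1, 0)
  trs <- forward_filter(make_series(theta), model_params(pi_init = 3))
  after_change <- which(c(FALSE, diff(theta) != 0)) + 1L
  after_change <- after_change[after_change <= length(theta)]
  expect_equal(trs$pi_stability[after_change],
               rep(3, length(after_change)))
  expect_true(all(trs$t0[after_change]))
})

test_that("a stronger prior pulls predictions toward the previous percept", {
  theta <- c(1, 1, 0, 1, 1, 1, 0, 0, 1, 1, 1, 1, 0, 1, 0, 0)
  ts <- make_series(theta)
  lo <- forward_filter(ts, model_params(pi_init = 1))
  hi <- forward_filter(ts, model_params(pi_init = 3))
  idx <- which(!is.na(lo$mu_stability))
  up <- idx[lo$mu_stability[idx] == 1]
  dn <- idx[lo$mu_stability[idx] == 0]
  expect_true(all(hi$p_cw[up] > lo$p_cw[up]))
  expect_true(all(hi$p_cw[dn] < lo$p_cw[dn]))
})

test_that("the filter carries state across missing trials without decay", {
  sched <- occlusion_event_times(slow_small, 80)
  ev <- sched$event_times_s
  # MIXED at interval 6 masks trials 6-8 until the CW press at interval 9
  log <- make_log(c(0.5, ev[5] + 0.3, ev[8] + 0.4),
                  c("CW", "MIXED", "CW"))
  ts <- events_to_trials(log, sched)
  expect_true(all(is.na(ts$theta[6:8])))
  tr <- forward_filter(ts, model_params(pi_init = 2))
  expect_true(all(is.na(tr$p_cw[6:8])))
  # precision at trial 9 continues the decay chain from trial 5
  pe5 <- tr$pe[5]
  expect_equal(tr$pi_stability[9],
               update_precision(tr$pi_stability[5], 1, pe5))
})

test_that("log-joint has closed-form pieces and a unimodal profile", {
  ts <- make_series(rep(c(1, 0), 12))
  # with a flat prediction every trial the likelihood is n log(1/2)
  expect_equal(model_b_evidence(ts), 24 * log(0.5))
  expect_equal(model_b_evidence(make_series(rep(1, 96))), 96 * log(0.5))
  expect_equal(model_b_evidence(make_series(rep(1, 96))), -66.542,
               tolerance = 1e-3)
  # prior-only: an all-missing series leaves the standard-normal prior
  # density at its mean, log(1/sqrt(2 pi))
  sched <- occlusion_event_times(slow_small, 80)
  empty <- events_to_trials(make_log(numeric(0), character(0)), sched)
  expect_equal(log_joint(empty, stats::setNames(0, "slow_small")),
               -0.5 * log(2 * pi))
  # vanishing precision forces a flat prediction on every scored trial
  xi_flat <- stats::setNames(log(1e-12), ts$condition$label)
  expect_equal(log_joint(ts, xi_flat),
               24 * log(0.5) + stats::dnorm(log(1e-12), 0, 1, log = TRUE),
               tolerance = 1e-6)
  # unimodality over a 1-D grid
  theta <- simulate_percepts_for_test(pi0 = 2, n = 200, seed = 31)
  ts2 <- make_series(theta)
  grid <- seq(-3, 3, by = 0.05)
  prof <- vapply(grid, function(x)
    log_joint(ts2, stats::setNames(x, ts2$condition$label)), numeric(1))
  peak <- which.max(prof)
  expect_gt(peak, 1)
  expect_lt(peak, length(grid))
  expect_true(all(diff(prof[1:peak]) > 0))
  expect_true(all(diff(prof[peak:length(grid)]) < 0))
})

test_that("inversion recovers generating precisions and the prior limit", {
  # prior-only limit: an empty series gives MAP xi = 0 and lme = 0
  sched <- occlusion_event_times(slow_small, 80)
  empty <- events_to_trials(make_log(numeric(0), character(0)), sched)
  fit0 <- fit_stability_model(list(slow_small = empty))
  expect_equal(unname(fit0$xi_map), 0, tolerance = 1e-6)
  expect_equal(fit0$lme, 0, tolerance = 1e-6)
  # long-series recovery of pi_init = 2 within 20 percent
  theta <- simulate_percepts_for_test(pi0 = 2, n = 2000, seed = 41)
  fit <- fit_stability_model(list(slow_small = make_series(theta)))
  expect_lt(abs(fit$pi_init_map[[1]] - 2) / 2, 0.2)
  expect_true(fit$converged)
  expect_true(all(diag(fit$posterior_cov) > 0))
})

test_that("Laplace evidence agrees with 1-D quadrature", {
  theta <- simulate_percepts_for_test(pi0 = 2, n = 200, seed = 51)
  ts <- make_series(theta)
  fit <- fit_stability_model(list(ts))
  f <- function(x) vapply(x, function(xx)
    log_joint(ts, stats::setNames(xx, ts$condition$label)), numeric(1))
  fmax <- f(fit$xi_map[[1]])
  quad <- log(stats::integrate(function(x) exp(f(x) - fmax), -8, 8,
                               rel.tol = 1e-10)$value) + fmax
  expect_lt(abs(fit$lme - quad), 0.1)
})

test_that("the stability model outscores the prior-free control on its own data", {
  theta <- simulate_percepts_for_test(pi0 = 3, n = 1000, seed = 61)
  ts <- make_series(theta)
  fit <- fit_stability_model(list(x = ts))
  expect_gt(fit$lme, model_b_evidence(ts))
})
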