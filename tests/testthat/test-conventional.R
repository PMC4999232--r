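test_that("transition probability follows its definition", {
  theta <- rep(c(1, 0), each = 2, times = 6)[1:24]  # 11 changes
  ts <- make_series(theta)
  expect_equal(transition_probability(ts),
               sum(diff(theta) != 0) / 24)
  expect_equal(transition_probability(make_series(rep(1, 24))), 0)
  # 6 transitions over 24 occlusions
  th <- rep(c(1, 0), times = c(4, 4))
  th <- c(th, th, th)  # switches at 5, 9, 13, 17, 21 -> 5 changes
  expect_equal(transition_probability(make_series(th)), 5 / 24)
})

test_that("transition probability estimates the markov flip rate", {
  sched <- schedule_n(10000)
  log <- simulate_markov(sched,
                         observer_config("markov", switch_prob = 0.34,
                                         rt_mean_s = 0, rt_sd_s = 0,
                                         mixed_rate = 0, seed = 23))
  tp <- transition_probability(events_to_trials(log, sched))
  expect_lt(abs(tp - 0.34), 3 * sqrt(0.34 * 0.66 / 10000))
})

test_that("run aggregation averages runs before subjects", {
  labs <- names(study_design())
  d1 <- expand.grid(subject = 1:3, run = 1, condition_label = labs,
                    stringsAsFactors = FALSE)
  d1$value <- stats::runif(nrow(d1))
  agg1 <- aggregate_runs(d1)
  merged <- merge(agg1, d1, by = c("subject", "condition_label"))
  expect_equal(merged$value.x, merged$value.y)  # identity for single runs
  d2 <- data.frame(subject = 1, run = 1:2, condition_label = labs[1],
                   value = c(0.2, 0.4))
  d2 <- rbind(d2, data.frame(subject = 1, run = 1,
                             condition_label = labs[-1],
                             value = 0.5))
  agg2 <- aggregate_runs(d2)
  expect_equal(agg2$value[agg2$condition_label == labs[1]], 0.3)
  # two-stage averaging with unbalanced runs differs from the pooled mean
  d3 <- data.frame(subject = 1, run = 1:9,
                   condition_label = labs[1],
                   value = c(rep(0.1, 8), 0.9))
  d3b <- rbind(d3, data.frame(subject = 1, run = 1,
                              condition_label = labs[-1], value = 0.5))
  agg3 <- aggregate_runs(d3b)
  expect_equal(agg3$value[agg3$condition_label == labs[1]], mean(d3$value))
  d4 <- d1[d1$subject != 1 | d1$condition_label != labs[1], ]
  expect_error(aggregate_runs(d4), "every subject")
})

test_that("the 2x2 ANOVA matches aov and the paired-t equivalence", {
  labs <- names(study_design())
  for (s in 1:3) {
    set.seed(100 + s)
    d <- expand.grid(subject = factor(1:18), condition_label = labs,
                     stringsAsFactors = FALSE)
    d$value <- stats::rnorm(nrow(d), sd = 0.1) +
      0.2 * grepl("slow", d$condition_label)
    res <- rm_anova_2x2(d)
    # oracle 1: aov with a within-subject error stratum
    parts <- strsplit(d$condition_label, "_")
    d$freq <- factor(vapply(parts, `[[`, "", 1))
    d$size <- factor(vapply(parts, `[[`, "", 2))
    fit <- summary(stats::aov(value ~ freq * size +
                                Error(subject / (freq * size)), data = d))
    f_aov <- c(fit[["Error: subject:freq"]][[1]]["freq", "F value"],
               fit[["Error: subject:size"]][[1]]["size", "F value"],
               fit[["Error: subject:freq:size"]][[1]]["freq:size",
                                                      "F value"])
    expect_equal(res$F, unname(f_aov), tolerance = 1e-8)
    # oracle 2: each F is the squared paired t on the marginal contrast
    wide <- stats::reshape(d[c("subject", "condition_label", "value")],
                           idvar = "subject", timevar = "condition_label",
                           direction = "wide")
    v <- function(lab) wide[[paste0("value.", lab)]]
    contrasts <- list(
      (v("slow_small") + v("slow_big")) / 2 -
        (v("fast_small") + v("fast_big")) / 2,
      (v("slow_small") + v("fast_small")) / 2 -
        (v("slow_big") + v("fast_big")) / 2,
      (v("slow_small") - v("slow_big")) -
        (v("fast_small") - v("fast_big")))
    t2 <- vapply(contrasts, function(x)
      unname(stats::t.test(x)$statistic^2), numeric(1))
    expect_equal(res$F, t2, tolerance = 1e-8)
    expect_true(all(res$eta_p_sq >= 0 & res$eta_p_sq <= 1))
    expect_equal(res$eta_p_sq, res$F / (res$F + res$df2), tolerance = 1e-10)
  }
})

test_that("the ANOVA is invariant to relabeling and location shifts", {
  labs <- names(study_design())
  set.seed(42)
  d <- expand.grid(subject = 1:10, condition_label = labs,
                   stringsAsFactors = FALSE)
  d$value <- stats::runif(nrow(d))
  res <- rm_anova_2x2(d)
  perm <- d
  perm$subject <- c(7, 3, 9, 1, 5, 10, 2, 8, 4, 6)[perm$subject]
  expect_equal(rm_anova_2x2(perm)[c("F", "p", "eta_p_sq")],
               res[c("F", "p", "eta_p_sq")], tolerance = 1e-10)
  shift <- d
  shift$value <- shift$value + 5
  expect_equal(rm_anova_2x2(shift)[c("F", "p", "eta_p_sq")],
               res[c("F", "p", "eta_p_sq")], tolerance = 1e-8)
})

test_that("degenerate tables are handled explicitly", {
  labs <- names(study_design())
  d <- expand.grid(subject = 1:6, condition_label = labs,
                   stringsAsFactors = FALSE)
  d$value <- d$subject * 0.1  # identical across conditions
  res <- rm_anova_2x2(d)
  expect_equal(res$F, rep(0, 3))
  d2 <- d
  d2$value <- d2$value + 0.3 * grepl("slow", d2$condition_label)
  expect_error(rm_anova_2x2(d2), "degenerate")
})
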