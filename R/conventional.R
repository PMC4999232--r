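# Conventional analysis: transition probabilities, run-then-subject
# aggregation, and the 2x2 repeated-measures ANOVA with partial eta
# squared computed from the within-subject sums-of-squares decomposition.

#' Transition probability of a trial series
#'
#' Number of perceptual transitions (changes between consecutive
#' non-missing percepts) divided by the number of scheduled self-occlusion
#' events, i.e. the probability that a self-occlusion is accompanied by a
#' transition in perception.
#'
#' @param series A [events_to_trials()] result.
#' @return Proportion in `[0, 1]`.
#' @export
transition_probability <- function(series) {
  stopifnot(inherits(series, "trial_series"))
  n_events <- length(series$occlusion_times_s)
  if (n_events == 0L)
    stop("undefined: the schedule contains no occlusion events",
         call. = FALSE)
  theta <- series$theta[!is.na(series$theta)]
  if (length(theta) < 2L) return(0)
  sum(diff(theta) != 0) / n_events
}

#' Average cell values across runs within subject
#'
#' First averaging level of the two-stage summary (runs within subject,
#' then subjects). Input is one value per subject x run x condition.
#'
#' @param data Data frame with columns `subject`, `run`,
#'   `condition_label` and `value`.
#' @return Data frame with one row per subject x condition and the
#'   run-mean `value`; per-condition grand means (mean of subject means)
#'   are attached as attribute `condition_means`.
#' @export
aggregate_runs <- function(data) {
  need <- c("subject", "run", "condition_label", "value")
  if (!all(need %in% names(data)))
    stop("'data' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  counts <- table(data$subject, data$condition_label)
  if (any(counts == 0L))
    stop("every subject needs at least one run per condition",
         call. = FALSE)
  agg <- stats::aggregate(value ~ subject + condition_label, data = data,
                          FUN = mean)
  agg <- agg[order(agg$subject, agg$condition_label), , drop = FALSE]
  rownames(agg) <- NULL
  grand <- stats::aggregate(value ~ condition_label, data = agg, FUN = mean)
  structure(agg,
            condition_means = stats::setNames(grand$value,
                                              grand$condition_label))
}

#' Two-by-two repeated-measures ANOVA with partial eta squared
#'
#' Within-subject decomposition for a complete subject x (frequency x
#' size) table. Each effect is tested against its own subject-by-effect
#' interaction with 1 and n - 1 degrees of freedom; at a single numerator
#' degree of freedom no sphericity correction is needed. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Data frame with columns `subject`, `freq`, `size` (each a
#'   two-level factor or character) and `value`, one row per subject and
#'   cell. A `condition_label` column of the form `slow_small` may be
#'   supplied instead of `freq`/`size`.
#' @return Data frame with one row per effect (`freq`, `size`,
#'   `freq:size`) and columns `F`, `df1`, `df2`, `p`, `eta_p_sq`.
#' @export
rm_anova_2x2 <- function(data) {
  if (!("freq" %in% names(data)) && "condition_label" %in% names(data)) {
    parts <- strsplit(as.character(data$condition_label), "_", fixed = TRUE)
    data$freq <- vapply(parts, `[[`, "", 1L)
    data$size <- vapply(parts, `[[`, "", 2L)
  }
  need <- c("subject", "freq", "size", "value")
  if (!all(need %in% names(data)))
    stop("'data' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  subj <- factor(data$subject)
  A <- factor(data$freq)
  B <- factor(data$size)
  n <- nlevels(subj)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  if (nlevels(A) != 2L || nlevels(B) != 2L)
    stop("'freq' and 'size' must each have exactly 2 levels", call. = FALSE)
  if (nrow(data) != 4L * n || any(table(subj, A, B) != 1L))
    stop("a complete subject x 2 x 2 table is required", call. = FALSE)
  y <- data$value
  gm <- mean(y)
  m_s <- tapply(y, subj, mean)
  m_a <- tapply(y, A, mean)
  m_b <- tapply(y, B, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_as <- tapply(y, list(A, subj), mean)
  m_bs <- tapply(y, list(B, subj), mean)
  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, 2)) -
                      outer(rep(1, 2), m_b) + gm)^2)
  ss_as <- 2 * sum((m_as - outer(m_a, rep(1, n)) -
                      outer(rep(1, 2), m_s) + gm)^2)
  ss_bs <- 2 * sum((m_bs - outer(m_b, rep(1, n)) -
                      outer(rep(1, 2), m_s) + gm)^2)
  fit_abs <- m_ab[cbind(A, B)] + m_as[cbind(A, subj)] + m_bs[cbind(B, subj)] -
    m_a[A] - m_b[B] - m_s[subj] + gm
  ss_abs <- sum((y - fit_abs)^2)
  one <- function(effect, ss_eff, ss_err) {
    if (ss_err <= .Machine$double.eps * max(1, abs(ss_eff))) {
      if (ss_eff <= .Machine$double.eps)
        return(data.frame(effect = effect, F = 0, df1 = 1, df2 = n - 1L,
                          p = 1, eta_p_sq = 0))
      stop("degenerate ANOVA: zero error variance for effect '", effect,
           "'", call. = FALSE)
    }
    Fv <- (ss_eff / 1) / (ss_err / (n - 1L))
    data.frame(effect = effect, F = Fv, df1 = 1, df2 = n - 1L,
               p = stats::pf(Fv, 1, n - 1L, lower.tail = FALSE),
               eta_p_sq = ss_eff / (ss_eff + ss_err))
  }
  rbind(one("freq", ss_a, ss_as),
        one("size", ss_b, ss_bs),
        one("freq:size", ss_ab, ss_abs))
}
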