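# Random-effects Bayesian model selection over per-subject log-model
# evidences: variational estimation of the Dirichlet posterior over model
# frequencies, expected model probabilities and exceedance probabilities.

#' Random-effects Bayesian model selection
#'
#' Treats the model generating each subject's data as a random effect:
#' model frequencies in the population follow a Dirichlet distribution
#' whose posterior is estimated by variational iteration. Per-subject
#' responsibilities are proportional to
#' `exp(lme + digamma(alpha_k) - digamma(sum(alpha)))`, the Dirichlet
#' counts are the prior counts plus the responsibility column sums, and
#' the two alternate until the counts change by less than `1e-6`.
#' Exceedance probabilities (the probability that a model is the most
#' frequent one in the population) are computed by Monte-Carlo sampling of
#' frequency vectors from the Dirichlet posterior; with exactly two models
#' the closed-form Beta tail probability is also returned.
#'
#' @param lme Numeric matrix of log-model evidences, subjects x models
#'   (at least 2 columns), in nats.
#' @param alpha0 Dirichlet prior count per model (uniform prior).
#' @param n_mc Number of Monte-Carlo draws, at least 10000.
#' @param seed Integer seed for the draws; `NULL` continues the current
#'   RNG stream.
#' @return An object of class `bms_result` with `alpha`, `expected_prob`
#'   (`alpha / sum(alpha)`), `exceedance_prob` (Monte-Carlo),
#'   `exceedance_exact` (two models only, else `NULL`), `responsibilities`
#'   and `n_mc_samples`.
#' @examples
#' lme <- cbind(A = rep(10, 18), B = rep(0, 18))
#' rfx_bms(lme, n_mc = 1e4, seed = 1)  # exceedance of A: 1 - 0.5^19
#' @export
rfx_bms <- function(lme, alpha0 = 1, n_mc = 1e5, seed = NULL) {
  lme <- as.matrix(lme)
  if (ncol(lme) < 2L) stop("at least 2 models are required", call. = FALSE)
  if (!all(is.finite(lme)))
    stop("log-model evidences must be finite", call. = FALSE)
  if (n_mc < 1e4) stop("'n_mc' must be at least 10000", call. = FALSE)
  K <- ncol(lme)
  if (is.null(colnames(lme))) colnames(lme) <- paste0("model", seq_len(K))
  alpha <- rep(alpha0, K)
  for (it in seq_len(500L)) {
    u <- sweep(lme, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- exp(u - apply(u, 1L, max))
    g <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(g)
    done <- max(abs(alpha_new - alpha)) < 1e-6
    alpha <- alpha_new
    if (done) break
  }
  names(alpha) <- colnames(lme)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(stats::rgamma(n_mc * K, shape = rep(alpha, each = n_mc)),
                  nrow = n_mc)
  win <- max.col(draws, ties.method = "first")
  xp <- tabulate(win, nbins = K) / n_mc
  names(xp) <- colnames(lme)
  exact <- NULL
  if (K == 2L) {
    exact <- c(stats::pbeta(0.5, alpha[2L], alpha[1L]),
               stats::pbeta(0.5, alpha[1L], alpha[2L]))
    names(exact) <- colnames(lme)
  }
  structure(list(alpha = alpha,
                 expected_prob = alpha / sum(alpha),
                 exceedance_prob = xp,
                 exceedance_exact = exact,
                 responsibilities = g,
                 n_mc_samples = as.integer(n_mc)),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<random-effects BMS>\n")
  cat("  alpha:          ",
      paste(sprintf("%s=%.2f", names(x$alpha), x$alpha), collapse = ", "),
      "\n")
  cat("  expected prob:  ",
      paste(sprintf("%s=%.3f", names(x$expected_prob), x$expected_prob),
            collapse = ", "), "\n")
  cat("  exceedance prob:",
      paste(sprintf("%s=%.4f", names(x$exceedance_prob),
                    x$exceedance_prob), collapse = ", "), "\n")
  invisible(x)
}
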