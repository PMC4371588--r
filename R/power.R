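#' Monte Carlo power for the slope-variance likelihood-ratio tests
#'
#' Estimates the power of the specific (`"1df"`) or generalized (`"2df"`)
#' slope-variance test by simulation: in each replication a complete
#' dataset of `N` trajectories is drawn from the design's implied moments,
#' the full and restricted models are fitted by maximum likelihood, and
#' the test rejects when the -2 log-likelihood difference exceeds the
#' central chi-square `1 - alpha` quantile with the test's degrees of
#' freedom.
#'
#' The `"1df"` (specific) test compares \{`sigma2_S` free, `sigma_IS` = 0\}
#' against \{both 0\}; the `"2df"` (generalized) test compares \{both
#' free\} against \{both 0\}. Replications in which either fit fails to
#' converge are excluded from the tally (with a warning above 1%
#' exclusions, a hard failure above 50%).
#'
#' @param design an `lgcm_design`.
#' @param N sample size per replication; defaults to the design's planned
#'   `N`.
#' @param test `"1df"` or `"2df"`.
#' @param alpha significance level.
#' @param n_replications number of Monte Carlo replications.
#' @param seed integer seed; runs with the same seed are bit-reproducible.
#' @return an object of class `lgcm_power` with the estimated `power`, a
#'   Clopper-Pearson 95% binomial interval, and bookkeeping fields.
#' @export
monte_carlo_power <- function(design, N = design$N, test = c("1df", "2df"),
                              alpha = 0.05, n_replications = 1000,
                              seed = NULL) {
  test <- match.arg(test)
  if (is.null(N)) stop("supply a sample size N", call. = FALSE)
  if (n_replications < 1)
    stop("n_replications must be >= 1", call. = FALSE)
  mom <- implied_moments(design)   # validates
  tc <- test_constraints(test)
  crit <- qchisq(1 - alpha, df = tc$df)
  if (!is.null(seed)) set.seed(seed)
  rejections <- 0L
  excluded <- 0L
  for (rep in seq_len(n_replications)) {
    y <- MASS::mvrnorm(n = N, mu = mom$mu, Sigma = mom$Sigma)
    m <- sample_moments(y)
    full <- fit_lgcm(moments = m, occasions = design$occasions,
                     fix_slope_var_zero = tc$full$fix_slope_var_zero,
                     fix_cov_zero = tc$full$fix_cov_zero)
    restricted <- fit_lgcm(moments = m, occasions = design$occasions,
                           fix_slope_var_zero = TRUE, fix_cov_zero = TRUE)
    if (!full$converged || !restricted$converged) {
      excluded <- excluded + 1L
      next
    }
    lrt <- likelihood_ratio(full, restricted)
    if (lrt$statistic > crit) rejections <- rejections + 1L
  }
  if (excluded > 0.5 * n_replications)
    stop("more than 50% of Monte Carlo replications failed to converge; ",
         "the design or optimizer is pathological", call. = FALSE)
  if (excluded > 0.01 * n_replications)
    warning(sprintf("%d of %d replications excluded for non-convergence",
                    excluded, n_replications), call. = FALSE)
  used <- n_replications - excluded
  p <- rejections / used
  structure(
    list(power = p,
         method = "monte_carlo", test = test, alpha = alpha, N = N,
         n_replications = used,
         mc_interval = binom_interval(rejections, used),
         n_excluded = excluded,
         df = tc$df),
    class = "lgcm_power")
}

# Clopper-Pearson 95% interval for x successes out of n.
binom_interval <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

# Per-observation ML discrepancy gap between the test's restricted and
# full models, evaluated at the design's population moments. Multiplied by
# N this is the noncentrality parameter of the test.
discrepancy_gap <- function(design, test = c("1df", "2df")) {
  test <- match.arg(test)
  mom <- implied_moments(design)
  m <- list(mean = mom$mu, cov = mom$Sigma, n = 1L)
  tc <- test_constraints(test)
  full <- fit_lgcm(moments = m, occasions = design$occasions,
                   fix_slope_var_zero = tc$full$fix_slope_var_zero,
                   fix_cov_zero = tc$full$fix_cov_zero)
  restricted <- fit_lgcm(moments = m, occasions = design$occasions,
                         fix_slope_var_zero = TRUE, fix_cov_zero = TRUE)
  max(0, restricted$discrepancy - full$discrepancy)
}

#' Analytic power approximation for the slope-variance tests
#'
#' Uses the noncentral chi-square approximation: the restricted and full
#' models of the chosen test are fitted to the design's population moments
#' (not to data), the noncentrality parameter is
#' \eqn{ncp = N (F_{restricted} - F_{full})}, and power is the upper tail
#' probability of the noncentral chi-square beyond the central
#' `1 - alpha` quantile. When the intercept-slope covariance is nonzero
#' under the `"1df"` test both fitted models are misspecified; the same
#' recipe applies and reduces to the standard one when `sigma_IS = 0`.
#'
#' @inheritParams monte_carlo_power
#' @return an object of class `lgcm_power` with the analytic `power` and
#'   noncentrality parameter `ncp`.
#' @export
analytic_power <- function(design, N = design$N, test = c("1df", "2df"),
                           alpha = 0.05) {
  test <- match.arg(test)
  if (is.null(N)) stop("supply a sample size N", call. = FALSE)
  tc <- test_constraints(test)
  gap <- discrepancy_gap(design, test)
  ncp <- N * gap
  crit <- qchisq(1 - alpha, df = tc$df)
  structure(
    list(power = pchisq(crit, df = tc$df, ncp = ncp, lower.tail = FALSE),
         method = "analytic", test = test, alpha = alpha, N = N,
         ncp = ncp, df = tc$df),
    class = "lgcm_power")
}

#' Smallest sample size reaching a target power
#'
#' The noncentrality parameter grows linearly in `N`, so analytic power is
#' strictly increasing in `N` whenever the design carries a nonzero effect
#' for the chosen test; integer bisection then finds the smallest `N`
#' whose analytic power reaches the target.
#'
#' @inheritParams analytic_power
#' @param target_power desired power, with `alpha < target_power < 1`.
#' @param max_N search cap.
#' @return the smallest integer `N` with
#'   `analytic_power(design, N, ...) >= target_power`.
#' @export
sample_size_for_power <- function(design, target_power,
                                  test = c("1df", "2df"), alpha = 0.05,
                                  max_N = 1e7) {
  test <- match.arg(test)
  if (!(alpha < target_power && target_power < 1))
    stop("need alpha < target_power < 1", call. = FALSE)
  tc <- test_constraints(test)
  gap <- discrepancy_gap(design, test)
  if (gap <= 0)
    stop("design has no effect for this test (zero noncentrality); ",
         "the target power is unattainable", call. = FALSE)
  crit <- qchisq(1 - alpha, df = tc$df)
  pow <- function(n) pchisq(crit, df = tc$df, ncp = n * gap,
                            lower.tail = FALSE)
  if (pow(max_N) < target_power)
    stop("target power not reached below N = ", max_N, call. = FALSE)
  lo <- 1L; hi <- as.integer(max_N)
  while (lo < hi) {
    mid <- lo + (hi - lo) %/% 2L
    if (pow(mid) >= target_power) hi <- mid else lo <- mid + 1L
  }
  lo
}

#' @export
print.lgcm_power <- function(x, ...) {
  label <- if (x$test == "1df") "specific 1-df slope-variance test"
           else "generalized 2-df variance-covariance test"
  cat(sprintf("Power estimate (%s)\n", label))
  cat(sprintf("  method = %s, N = %d, alpha = %g\n", x$method, x$N, x$alpha))
  cat(sprintf("  power = %.4f\n", x$power))
  if (x$method == "monte_carlo") {
    cat(sprintf("  95%% CI [%.4f, %.4f] from %d replications (%d excluded)\n",
                x$mc_interval["lower"], x$mc_interval["upper"],
                x$n_replications, x$n_excluded))
  } else {
    cat(sprintf("  noncentrality = %.4f on %d df\n", x$ncp, x$df))
  }
  invisible(x)
}
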