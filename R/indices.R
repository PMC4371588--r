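#' Effective error of the slope-variance test
#'
#' The effective error \eqn{\sigma^2_{eff}} is the hypothetical measurement
#' error variance that would be incurred if the latent slope could be
#' measured directly; two designs with equal effective error have equal
#' power for the 1-df slope-variance likelihood-ratio test. For a linear
#' LGCM it has the closed form
#' \deqn{\sigma^2_{eff} = \frac{\sigma^2_\epsilon}{\sum_j t_j^2 -
#'   \left(\sum_j t_j\right)^2 / (M + \sigma^2_\epsilon / \sigma^2_I)}}
#' which coincides with the generalized-least-squares precision
#' \eqn{1 / (t' V^{-1} t)} where
#' \eqn{V = \sigma^2_I \mathbf{1}\mathbf{1}' + \sigma^2_\epsilon I}.
#'
#' When `sigma2_I = 0` the subtraction term vanishes
#' (\eqn{\sigma^2_\epsilon/\sigma^2_I \to \infty}) and the denominator is
#' \eqn{\sum_j t_j^2}. As `sigma2_I` grows large the denominator tends to
#' the occasion sum of squares about the mean (SST), giving the
#' growth-rate-reliability limit \eqn{\sigma^2_\epsilon / SST}.
#'
#' @param occasions numeric vector of measurement times.
#' @param sigma2_eps residual variance, > 0.
#' @param sigma2_I intercept variance, >= 0.
#' @return the scalar effective error variance.
#' @examples
#' effective_error_slope(c(0, 2, 4), 9.20, 39.63)
#' @export
effective_error_slope <- function(occasions, sigma2_eps, sigma2_I) {
  if (inherits(occasions, "lgcm_design")) occasions <- occasions$occasions
  if (!is.finite(sigma2_eps) || sigma2_eps <= 0)
    stop("sigma2_eps must be > 0", call. = FALSE)
  if (!is.finite(sigma2_I) || sigma2_I < 0)
    stop("sigma2_I must be >= 0", call. = FALSE)
  t <- as.numeric(occasions)
  M <- length(t)
  sum_t <- sum(t)
  sum_t2 <- sum(t^2)
  denom <- if (sigma2_I == 0) sum_t2 else
    sum_t2 - sum_t^2 / (M + sigma2_eps / sigma2_I)
  if (!is.finite(denom) || denom <= .Machine$double.eps * max(1, sum_t2))
    stop("degenerate design: effective-error denominator is not positive ",
         "(occasions carry no usable spread)", call. = FALSE)
  sigma2_eps / denom
}

# Effective error on a continuous relaxation of the equal-spacing sums, so
# that M can be treated as a real number by the equivalence solver.
# baseline_zero: sum t = MT/2,       sum t^2 = M(2M-1)T^2 / (6(M-1))
# no_baseline:   sum t = (M+1)T/2,   sum t^2 = (M+1)(2M+1)T^2 / (6M)
# Both reduce to the brute-force sums at integer M.
effective_error_relaxed <- function(M, T, sigma2_eps, sigma2_I,
                                    convention = "baseline_zero") {
  if (convention == "baseline_zero") {
    sum_t <- M * T / 2
    sum_t2 <- M * (2 * M - 1) * T^2 / (6 * (M - 1))
  } else {
    sum_t <- (M + 1) * T / 2
    sum_t2 <- (M + 1) * (2 * M + 1) * T^2 / (6 * M)
  }
  denom <- if (sigma2_I == 0) sum_t2 else
    sum_t2 - sum_t^2 / (M + sigma2_eps / sigma2_I)
  if (!is.finite(denom) || denom <= 0)
    stop("degenerate design: effective-error denominator is not positive",
         call. = FALSE)
  sigma2_eps / denom
}

#' Closed-form occasion sums for equally spaced grids
#'
#' For the equally spaced grid without a baseline occasion,
#' \eqn{t_j = j T / M}, the sums entering the effective error have closed
#' forms \eqn{\sum_j t_j = (M+1) T / 2} and
#' \eqn{\sum_j t_j^2 = (M+1)(2M+1) T^2 / (6M)}.
#'
#' @param M number of occasions, >= 1.
#' @param T total study time, > 0.
#' @return a list with components `sum_t` and `sum_t2`.
#' @export
substitution_sums <- function(M, T) {
  if (M < 1 || M != round(M)) stop("M must be an integer >= 1", call. = FALSE)
  if (T <= 0) stop("T must be > 0", call. = FALSE)
  list(sum_t = (M + 1) * T / 2,
       sum_t2 = (M + 1) * (2 * M + 1) * T^2 / (6 * M))
}

#' Effective curve reliability (ECR)
#'
#' \eqn{ECR = \sigma^2_S / (\sigma^2_S + \sigma^2_{eff})}: the slope
#' variance normalized by its effective error, interpretable as an effect
#' size for the slope-variance test.
#'
#' @param sigma2_S slope variance, >= 0.
#' @param sigma2_eff effective error variance, >= 0; not both zero.
#' @return reliability in \[0, 1\].
#' @export
ecr <- function(sigma2_S, sigma2_eff) {
  if (sigma2_S < 0 || sigma2_eff < 0)
    stop("variances must be >= 0", call. = FALSE)
  if (sigma2_S == 0 && sigma2_eff == 0)
    stop("ECR undefined when both sigma2_S and sigma2_eff are zero",
         call. = FALSE)
  sigma2_S / (sigma2_S + sigma2_eff)
}

#' Growth rate reliability (GRR)
#'
#' Willett's index \eqn{GRR = \sigma^2_S / (\sigma^2_S + \sigma^2_\epsilon
#' / SST)} with \eqn{SST = \sum_j (t_j - \bar t)^2}. GRR equals ECR in the
#' limit of asymptotically large intercept variance.
#'
#' @param sigma2_S slope variance, >= 0.
#' @param sigma2_eps residual variance, > 0.
#' @param occasions numeric vector of measurement times with positive SST.
#' @return reliability in \[0, 1\].
#' @export
grr <- function(sigma2_S, sigma2_eps, occasions) {
  if (inherits(occasions, "lgcm_design")) occasions <- occasions$occasions
  t <- as.numeric(occasions)
  sst <- sum((t - mean(t))^2)
  if (sst <= 0)
    stop("degenerate design: occasions have zero spread (SST = 0)",
         call. = FALSE)
  sigma2_S / (sigma2_S + sigma2_eps / sst)
}

#' Growth curve reliability at time zero (GCR)
#'
#' The proportion of observed-score variance due to true scores at the
#' occasion where the slope loading is zero:
#' \eqn{GCR_0 = \sigma^2_I / (\sigma^2_I + \sigma^2_\epsilon)}.
#'
#' @param sigma2_I intercept variance, >= 0.
#' @param sigma2_eps residual variance, > 0.
#' @return reliability in \[0, 1).
#' @export
gcr0 <- function(sigma2_I, sigma2_eps) {
  if (sigma2_I < 0) stop("sigma2_I must be >= 0", call. = FALSE)
  if (sigma2_eps <= 0) stop("sigma2_eps must be > 0", call. = FALSE)
  sigma2_I / (sigma2_I + sigma2_eps)
}

#' Design quality indices for an LGCM study design
#'
#' Computes the effective error together with the reliability and
#' effect-size indices ECR, GRR and GCR from a design's own parameters.
#' All values are kept in full precision; rounding to two decimals happens
#' only in the print method.
#'
#' @param design an `lgcm_design`.
#' @return an object of class `lgcm_indices`: a list with components
#'   `sigma2_eff`, `ecr`, `grr`, `gcr0`, and `cor_IS` (the implied
#'   intercept-slope correlation, `NA` when undefined).
#' @examples
#' octo <- lgcm_design(M = 3, T = 4, sigma2_eps = 9.20, sigma2_I = 39.63,
#'                     sigma2_S = 0.53, sigma_IS = -0.69)
#' design_indices(octo)
#' @export
design_indices <- function(design) {
  problems <- validate_design(design)
  if (length(problems))
    stop("invalid design:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  s2eff <- effective_error_slope(design$occasions, design$sigma2_eps,
                                 design$sigma2_I)
  out <- list(
    sigma2_eff = s2eff,
    ecr = ecr(design$sigma2_S, s2eff),
    grr = grr(design$sigma2_S, design$sigma2_eps, design$occasions),
    gcr0 = gcr0(design$sigma2_I, design$sigma2_eps),
    cor_IS = if (design$sigma2_I > 0 && design$sigma2_S > 0)
      design$sigma_IS / sqrt(design$sigma2_I * design$sigma2_S)
    else NA_real_)
  class(out) <- "lgcm_indices"
  out
}

#' @export
print.lgcm_indices <- function(x, ...) {
  cat("LGCM design indices\n")
  fmt <- "  %-28s %12.6f   (%.2f)\n"
  cat(sprintf(fmt, "Effective error sigma2_eff", x$sigma2_eff, x$sigma2_eff))
  cat(sprintf(fmt, "ECR (effective curve rel.)", x$ecr, x$ecr))
  cat(sprintf(fmt, "GRR (growth rate rel.)", x$grr, x$grr))
  cat(sprintf(fmt, "GCR (growth curve rel., t=0)", x$gcr0, x$gcr0))
  if (!is.na(x$cor_IS))
    cat(sprintf(fmt, "Intercept-slope correlation", x$cor_IS, x$cor_IS))
  invisible(x)
}

#' @export
as.data.frame.lgcm_indices <- function(x, ...) {
  data.frame(index = c("sigma2_eff", "ecr", "grr", "gcr0", "cor_IS"),
             value = c(x$sigma2_eff, x$ecr, x$grr, x$gcr0, x$cor_IS),
             rounded = round(c(x$sigma2_eff, x$ecr, x$grr, x$gcr0, x$cor_IS),
                             2))
}
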