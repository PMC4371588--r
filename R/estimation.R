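#' Simulate complete longitudinal data from a study design
#'
#' Draws `N` independent trajectories from the multivariate normal
#' distribution with the design's model-implied mean vector and covariance
#' matrix. The result is an `N x M` matrix; column `j` holds the scores at
#' occasion `t_j`.
#'
#' @param design an `lgcm_design`.
#' @param N sample size; at least `M + 2` so the sample covariance has
#'   enough degrees of freedom.
#' @param seed optional integer seed; when given, results are reproducible
#'   and the caller's RNG state is left untouched.
#' @return numeric matrix with `N` rows and `M` columns, with the occasion
#'   times attached as attribute `"occasions"` and as column names
#'   `y_<t>`.
#' @export
simulate_lgcm <- function(design, N, seed = NULL) {
  mom <- implied_moments(design)   # validates the design
  if (N < design$M + 2)
    stop("N must be at least M + 2 for covariance estimation", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  y <- MASS::mvrnorm(n = N, mu = mom$mu, Sigma = mom$Sigma)
  y <- matrix(y, nrow = N)
  colnames(y) <- paste0("y_", format(design$occasions, trim = TRUE))
  attr(y, "occasions") <- design$occasions
  y
}

#' @rdname simulate_lgcm
#' @param object an `lgcm_design` (for the [stats::simulate()] generic).
#' @param nsim number of datasets to draw.
#' @param ... ignored.
#' @return for `simulate.lgcm_design`, a list of `nsim` data matrices.
#' @export
simulate.lgcm_design <- function(object, nsim = 1, seed = NULL, ...,
                                 N = object$N) {
  if (is.null(N))
    stop("design has no planned sample size; supply `N`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simulate_lgcm(object, N), simplify = FALSE)
}

# ---- maximum likelihood fitting --------------------------------------------

# Sufficient statistics with the ML (divide-by-N) covariance convention.
sample_moments <- function(data) {
  y <- as.matrix(data)
  n <- nrow(y)
  xbar <- colMeans(y)
  centred <- sweep(y, 2, xbar)
  S <- crossprod(centred) / n
  list(mean = xbar, cov = S, n = n)
}

# ML discrepancy F(theta) = log|Sigma| + tr(S Sigma^-1) + d' Sigma^-1 d
#                           - log|S| - M,  d = xbar - Lambda nu.
# The latent means are profiled out by generalized least squares, which is
# exact because they are always unconstrained. Returns +Inf-like penalty on
# non-PD proposals so bound-constrained optimizers can roam freely.
lgcm_discrepancy <- function(psi, Lambda, S, xbar, logdetS) {
  M <- nrow(S)
  Sigma <- Lambda %*% psi$Psi %*% t(Lambda) + diag(psi$sigma2_eps, M)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(list(F = 1e10, nu = c(NA_real_, NA_real_)))
  logdet <- 2 * sum(log(diag(R)))
  Sinv <- chol2inv(R)
  A <- crossprod(Lambda, Sinv %*% Lambda)
  b <- crossprod(Lambda, Sinv %*% xbar)
  nu <- unname(drop(solve(A, b)))
  d <- xbar - drop(Lambda %*% nu)
  Fval <- logdet + sum(Sinv * S) + drop(crossprod(d, Sinv %*% d)) -
    logdetS - M
  list(F = Fval, nu = nu)
}

# Map a free-parameter vector to (Psi, sigma2_eps) under the constraints.
# Free vectors:
#   unconstrained:     (sigma2_I, sigma2_S, r, sigma2_eps), sigma_IS = r * sd
#   fix_cov_zero:      (sigma2_I, sigma2_S, sigma2_eps)
#   fix_slope_var_zero (implies cov zero): (sigma2_I, sigma2_eps)
param_map <- function(fix_slope_var_zero, fix_cov_zero) {
  if (fix_slope_var_zero) {
    list(names = c("sigma2_I", "sigma2_eps"),
         lower = c(0, 1e-10), upper = c(Inf, Inf),
         unpack = function(p) list(
           Psi = matrix(c(p[1], 0, 0, 0), 2, 2), sigma2_eps = p[2]),
         pack = function(s2I, s2S, r, s2e) c(s2I, s2e))
  } else if (fix_cov_zero) {
    list(names = c("sigma2_I", "sigma2_S", "sigma2_eps"),
         lower = c(0, 0, 1e-10), upper = c(Inf, Inf, Inf),
         unpack = function(p) list(
           Psi = matrix(c(p[1], 0, 0, p[2]), 2, 2), sigma2_eps = p[3]),
         pack = function(s2I, s2S, r, s2e) c(s2I, s2S, s2e))
  } else {
    list(names = c("sigma2_I", "sigma2_S", "r_IS", "sigma2_eps"),
         lower = c(0, 0, -0.9999, 1e-10), upper = c(Inf, Inf, 0.9999, Inf),
         unpack = function(p) {
           cov <- p[3] * sqrt(p[1] * p[2])
           list(Psi = matrix(c(p[1], cov, cov, p[2]), 2, 2),
                sigma2_eps = p[4])
         },
         pack = function(s2I, s2S, r, s2e) c(s2I, s2S, r, s2e))
  }
}

# Method-of-moments start values: project the sample covariance onto the
# (1, t) column space (equivalent to per-row OLS intercept/slope scores),
# subtract the OLS noise contribution, floor variances at small positives.
mom_start <- function(Lambda, S) {
  M <- nrow(S)
  G <- solve(crossprod(Lambda))        # (Lambda'Lambda)^-1
  B <- G %*% t(Lambda)                 # OLS score operator
  P <- Lambda %*% B
  s2e <- if (M > 2) sum(diag((diag(M) - P) %*% S)) / (M - 2) else
    0.5 * min(diag(S))
  s2e <- max(s2e, 1e-6 * mean(diag(S)), 1e-8)
  Psi0 <- B %*% S %*% t(B) - s2e * G
  floor_I <- max(1e-6 * S[1, 1], 1e-8)
  s2I <- max(Psi0[1, 1], floor_I)
  s2S <- max(Psi0[2, 2], floor_I)
  r0 <- Psi0[1, 2] / sqrt(s2I * s2S)
  r0 <- min(max(r0, -0.95), 0.95)
  list(sigma2_I = s2I, sigma2_S = s2S, r = r0, sigma2_eps = s2e)
}

#' Fit a linear latent growth curve model by maximum likelihood
#'
#' Minimizes the multivariate-normal ML discrepancy
#' \deqn{F(\theta) = \ln|\Sigma(\theta)| + tr(S \Sigma(\theta)^{-1}) +
#'   (\bar x - \mu(\theta))' \Sigma(\theta)^{-1} (\bar x - \mu(\theta)) -
#'   \ln|S| - M}
#' where `S` is the sample covariance with the ML (divide-by-N) convention.
#' The reported `minus2ll` is `N * F`, i.e. relative to the saturated
#' model; the convention is consistent across fits so differences between
#' nested fits are exact -2 log-likelihood-ratio statistics.
#'
#' Raw data and sufficient statistics are interchangeable by sufficiency:
#' raw data are reduced to `(mean, cov, n)` before fitting. Latent means
#' are profiled out analytically; the covariance parameters are optimized
#' under bound constraints (variances >= 0, intercept-slope correlation in
#' (-1, 1)) from method-of-moments starting values.
#'
#' @param data `N x M` matrix of complete trajectories (e.g. from
#'   [simulate_lgcm()]); alternatively `NULL` when `moments` is given.
#' @param occasions measurement times for the columns of `data`; taken
#'   from the data's `"occasions"` attribute when absent.
#' @param moments optional sufficient statistics: a list with components
#'   `mean`, `cov` (ML convention) and `n`.
#' @param fix_slope_var_zero fix the slope variance at 0 (implies
#'   `fix_cov_zero`; a zero-variance slope cannot covary).
#' @param fix_cov_zero fix the intercept-slope covariance at 0.
#' @param start optional named list of starting values
#'   (`sigma2_I`, `sigma2_S`, `r`, `sigma2_eps`).
#' @param control passed to [stats::nlminb()].
#' @return an object of class `lgcm_fit` with components `estimates`
#'   (named vector: `mu_I`, `mu_S`, `sigma2_I`, `sigma2_S`, `sigma_IS`,
#'   `sigma2_eps`), `discrepancy` (the minimized `F`), `minus2ll`,
#'   `converged`, `n_obs`, `n_free` and the constraint flags.
#' @export
fit_lgcm <- function(data = NULL, occasions = NULL, moments = NULL,
                     fix_slope_var_zero = FALSE,
                     fix_cov_zero = fix_slope_var_zero,
                     start = NULL, control = list()) {
  if (fix_slope_var_zero && !fix_cov_zero)
    stop("fix_slope_var_zero implies fix_cov_zero ",
         "(a zero-variance slope cannot covary)", call. = FALSE)
  if (is.null(moments)) {
    if (is.null(data)) stop("supply `data` or `moments`", call. = FALSE)
    if (is.null(occasions)) occasions <- attr(data, "occasions")
    if (is.null(occasions))
      stop("occasion times are required (argument or data attribute)",
           call. = FALSE)
    moments <- sample_moments(data)
  } else if (is.null(occasions)) {
    occasions <- attr(moments, "occasions")
    if (is.null(occasions))
      stop("occasion times are required alongside `moments`", call. = FALSE)
  }
  t <- as.numeric(occasions)
  M <- length(t)
  S <- as.matrix(moments$cov)
  xbar <- as.numeric(moments$mean)
  n <- moments$n
  if (nrow(S) != M || length(xbar) != M)
    stop("moments do not match the number of occasions", call. = FALSE)
  Rs <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(Rs))
    stop("sample covariance matrix is not positive definite", call. = FALSE)
  logdetS <- 2 * sum(log(diag(Rs)))
  Lambda <- cbind(1, t)

  map <- param_map(fix_slope_var_zero, fix_cov_zero)
  st <- mom_start(Lambda, S)
  if (!is.null(start)) st <- modifyList(st, start)
  p0 <- map$pack(st$sigma2_I, st$sigma2_S, st$r, st$sigma2_eps)
  p0 <- pmin(pmax(p0, map$lower), map$upper)

  objective <- function(p)
    lgcm_discrepancy(map$unpack(p), Lambda, S, xbar, logdetS)$F
  ctrl <- modifyList(list(eval.max = 2000, iter.max = 1000,
                          rel.tol = 1e-14, abs.tol = 1e-30), control)
  opt <- nlminb(p0, objective, lower = map$lower, upper = map$upper,
                control = ctrl)
  # second pass from the first optimum polishes boundary solutions
  opt2 <- nlminb(opt$par, objective, lower = map$lower, upper = map$upper,
                 control = ctrl)
  if (opt2$objective <= opt$objective) opt <- opt2

  F0 <- objective(p0)
  # Under tight tolerances nlminb labels boundary optima "singular
  # convergence" and noise-floor objectives "false convergence"; after the
  # polish pass these are genuine optima, so only hitting the
  # iteration/evaluation limits or a non-finite objective counts as failure.
  converged <- is.finite(opt$objective) && opt$objective < 1e9 &&
    (opt$convergence == 0 ||
       grepl("singular convergence|false convergence", opt$message))
  if (opt$objective > F0 + 1e-12) {       # monotone safeguard
    opt$par <- p0
    opt$objective <- F0
    converged <- FALSE
  }
  psi <- map$unpack(opt$par)
  final <- lgcm_discrepancy(psi, Lambda, S, xbar, logdetS)
  est <- c(mu_I = final$nu[1], mu_S = final$nu[2],
           sigma2_I = psi$Psi[1, 1], sigma2_S = psi$Psi[2, 2],
           sigma_IS = psi$Psi[1, 2], sigma2_eps = psi$sigma2_eps)
  structure(
    list(estimates = est,
         discrepancy = final$F,
         minus2ll = n * final$F,
         converged = converged,
         n_obs = n,
         n_free = length(map$lower) + 2L,
         fix_slope_var_zero = fix_slope_var_zero,
         fix_cov_zero = fix_cov_zero,
         occasions = t),
    class = "lgcm_fit")
}

#' @export
print.lgcm_fit <- function(x, digits = 5, ...) {
  cat("Linear LGCM maximum likelihood fit\n")
  constraints <- c(
    if (x$fix_slope_var_zero) "sigma2_S = 0",
    if (x$fix_cov_zero) "sigma_IS = 0")
  cat(sprintf("  Constraints: %s\n",
              if (length(constraints)) paste(constraints, collapse = ", ")
              else "none"))
  print(round(x$estimates, digits))
  cat(sprintf("  -2 log-likelihood (vs saturated): %.*f   [N = %d]\n",
              digits, x$minus2ll, x$n_obs))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.lgcm_fit <- function(object, ...) object$estimates

#' @export
logLik.lgcm_fit <- function(object, ...) {
  structure(-object$minus2ll / 2, df = object$n_free,
            nobs = object$n_obs, class = "logLik")
}

#' Likelihood-ratio statistic for nested LGCM fits
#'
#' Computes `restricted$minus2ll - full$minus2ll`, clipped below at zero
#' (boundary solutions can produce tiny negative differences), together
#' with the test's degrees of freedom: the number of additional covariance
#' constraints the restricted model imposes.
#'
#' @param full,restricted `lgcm_fit` objects on the same data with nested
#'   constraint sets (the restricted constraints must contain the full's).
#' @return list with components `statistic` and `df`.
#' @export
likelihood_ratio <- function(full, restricted) {
  count <- function(f) f$fix_slope_var_zero + f$fix_cov_zero
  nested <- restricted$fix_slope_var_zero >= full$fix_slope_var_zero &&
    restricted$fix_cov_zero >= full$fix_cov_zero &&
    count(restricted) > count(full)
  if (!nested)
    stop("restricted model must impose strictly more constraints than ",
         "the full model", call. = FALSE)
  if (full$n_obs != restricted$n_obs)
    stop("fits use different sample sizes", call. = FALSE)
  list(statistic = max(0, restricted$minus2ll - full$minus2ll),
       df = count(restricted) - count(full))
}

# Constraint sets for the two supported slope-variance tests.
#   "1df" (specific):    full  {sigma2_S free, sigma_IS = 0}
#                        restr {sigma2_S = 0,  sigma_IS = 0}
#   "2df" (generalized): full  {both free}
#                        restr {sigma2_S = 0,  sigma_IS = 0}
test_constraints <- function(test = c("1df", "2df")) {
  test <- match.arg(test)
  list(full = list(fix_slope_var_zero = FALSE,
                   fix_cov_zero = (test == "1df")),
       restricted = list(fix_slope_var_zero = TRUE, fix_cov_zero = TRUE),
       df = if (test == "1df") 1L else 2L)
}
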