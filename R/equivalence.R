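.adjustable <- c("sigma2_eps", "sigma2_I", "T", "M", "N")

.default_bounds <- list(sigma2_eps = c(1e-8, 1e6),
                        sigma2_I = c(0, 1e9),
                        T = c(1e-3, 1e3),
                        M = c(2, 1000),
                        N = c(2, 1e7))

# Effective error of `design` with `param` set to `value`. M is evaluated
# on the continuous relaxation of the equal-spacing sums (baseline at zero)
# because fractional occasion counts have no literal grid.
eff_at <- function(design, param, value) {
  if (param == "M") {
    effective_error_relaxed(value, design$T, design$sigma2_eps,
                            design$sigma2_I)
  } else {
    d <- design_with(design, param, value)
    effective_error_slope(d$occasions, d$sigma2_eps, d$sigma2_I)
  }
}

# Bracketed root of f on [lo, hi] (monotone f), refined until the achieved
# relative discrepancy against `target` is within tol.
solve_bracketed <- function(f, lo, hi, target, tol) {
  f_lo <- f(lo); f_hi <- f(hi)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0) {
    attain <- sort(c(f_lo, f_hi) + target)
    stop(sprintf(paste0("no solution in the given bounds: target ",
                        "sigma2_eff = %g is outside the attainable range ",
                        "[%g, %g]"), target, attain[1], attain[2]),
         call. = FALSE)
  }
  if (f_lo == 0) return(lo)
  if (f_hi == 0) return(hi)
  root <- uniroot(f, c(lo, hi), f.lower = f_lo, f.upper = f_hi,
                  tol = .Machine$double.eps^0.9, maxiter = 2000)$root
  if (abs(f(root)) / abs(target) > tol) {
    # fall back to plain bisection down to machine resolution
    a <- lo; b <- hi; fa <- f_lo
    for (i in 1:200) {
      m <- (a + b) / 2
      if (m == a || m == b) break
      fm <- f(m)
      if (fm == 0) { a <- m; break }
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
    }
    cand <- c(root, a, b)
    root <- cand[which.min(abs(vapply(cand, f, numeric(1))))]
  }
  root
}

#' Solve for a power-equivalent design by computer-adjusting one parameter
#'
#' Two designs are power-equivalent for the 1-df slope-variance test when
#' their effective errors agree. Given a reference design and a candidate
#' whose remaining parameters are fixed user choices, this solves for the
#' single *computer-adjusted* parameter (`sigma2_eps`, `sigma2_I`, `T` or
#' `M`) that makes the candidate's effective error match the reference's.
#' A bracketed root finder is used: the effective error is monotone in
#' each supported parameter on equally spaced grids, so a sign change over
#' the bounds guarantees convergence.
#'
#' `adjust = "M"` is solved on a continuous relaxation of the equal-spacing
#' sums; because fractional occasion counts are not realizable, the two
#' flanking integers and their achieved effective errors are reported
#' alongside the continuous root. `adjust = "N"` defines equivalence on
#' analytic power rather than effective error (the effective error does
#' not involve `N`): the returned value is the sample size at which the
#' candidate's noncentrality matches the reference's at its planned `N`.
#'
#' The effect parameters `sigma2_S`, `sigma_IS` and the latent means are
#' never adjustable: they parameterize the effect under test, not the
#' design's error.
#'
#' @param reference an `lgcm_design`; defines the target effective error
#'   (and, for `adjust = "N"`, the target power at `reference$N`).
#' @param candidate an `lgcm_design` holding the user-chosen values of all
#'   non-adjusted parameters; defaults to the reference itself.
#' @param adjust which parameter to computer-adjust: one of
#'   `"sigma2_eps"`, `"sigma2_I"`, `"T"`, `"M"`, `"N"`.
#' @param bounds length-2 numeric search interval; defaults per parameter
#'   to `sigma2_eps` (1e-8, 1e6), `sigma2_I` (0, 1e9), `T` (1e-3, 1e3),
#'   `M` (2, 1000), `N` (2, 1e7).
#' @param tol relative tolerance on the matched effective error (or
#'   noncentrality).
#' @param alpha significance level used when `adjust = "N"`.
#' @return an object of class `lgcm_equivalence`: a list with the solved
#'   `value`, the `target` and `achieved` effective error (or power), the
#'   completed candidate `design` (value rounded to an integer for `M` and
#'   `N`), and for integer parameters a data frame `integer_neighbors` of
#'   the two flanking integers with their achieved values.
#' @examples
#' octo <- lgcm_design(M = 3, T = 4, sigma2_eps = 9.20, sigma2_I = 39.63,
#'                     sigma2_S = 0.53, sigma_IS = -0.69, N = 250)
#' # five occasions over the same span tolerate a noisier instrument:
#' solve_equivalent_design(octo, design_with(octo, "M", 5),
#'                         adjust = "sigma2_eps")
#' @export
solve_equivalent_design <- function(reference, candidate = reference,
                                    adjust, bounds = NULL, tol = 1e-10,
                                    alpha = 0.05) {
  adjust <- match.arg(adjust, .adjustable)
  if (is.null(bounds)) bounds <- .default_bounds[[adjust]]
  if (length(bounds) != 2 || bounds[1] >= bounds[2])
    stop("bounds must be an increasing length-2 interval", call. = FALSE)

  if (adjust == "N") {
    if (is.null(reference$N))
      stop("adjusting N requires the reference design to carry a planned N",
           call. = FALSE)
    gap_ref <- discrepancy_gap(reference, "1df")
    gap_cand <- discrepancy_gap(candidate, "1df")
    if (gap_cand <= 0)
      stop("candidate design has no effect for the 1-df test; ",
           "no sample size can match the reference power", call. = FALSE)
    target <- analytic_power(reference, test = "1df", alpha = alpha)$power
    value <- reference$N * gap_ref / gap_cand
    if (value < bounds[1] || value > bounds[2])
      stop(sprintf("no solution in the given bounds: required N = %g",
                   value), call. = FALSE)
    neighbors <- unique(c(floor(value), ceiling(value)))
    achieved_nb <- vapply(neighbors, function(n)
      analytic_power(candidate, N = n, test = "1df", alpha = alpha)$power,
      numeric(1))
    design <- candidate
    design$N <- as.integer(round(value))
    out <- list(adjust = "N", value = value, target = target,
                achieved = analytic_power(candidate, N = value,
                                          test = "1df",
                                          alpha = alpha)$power,
                quantity = "analytic power",
                design = design,
                integer_neighbors = data.frame(value = neighbors,
                                               achieved = achieved_nb))
    class(out) <- "lgcm_equivalence"
    return(out)
  }

  target <- effective_error_slope(reference$occasions, reference$sigma2_eps,
                                  reference$sigma2_I)
  f <- function(v) eff_at(candidate, adjust, v) - target
  value <- solve_bracketed(f, bounds[1], bounds[2], target, tol)
  achieved <- eff_at(candidate, adjust, value)
  out <- list(adjust = adjust, value = value, target = target,
              achieved = achieved, quantity = "sigma2_eff")
  if (adjust == "M") {
    neighbors <- unique(c(floor(value), ceiling(value)))
    out$integer_neighbors <- data.frame(
      value = neighbors,
      achieved = vapply(neighbors, function(m) eff_at(candidate, "M", m),
                        numeric(1)))
    out$design <- design_with(candidate, "M", round(value))
  } else {
    out$design <- design_with(candidate, adjust, value)
  }
  class(out) <- "lgcm_equivalence"
  out
}

#' @export
print.lgcm_equivalence <- function(x, ...) {
  cat("Power-equivalent design solution\n")
  cat(sprintf("  computer-adjusted parameter: %s = %.6g\n", x$adjust,
              x$value))
  cat(sprintf("  target %s = %.8g, achieved = %.8g\n", x$quantity,
              x$target, x$achieved))
  if (!is.null(x$integer_neighbors)) {
    cat("  integer neighbors:\n")
    for (i in seq_len(nrow(x$integer_neighbors)))
      cat(sprintf("    %s = %d -> %s = %.8g\n", x$adjust,
                  as.integer(x$integer_neighbors$value[i]), x$quantity,
                  x$integer_neighbors$achieved[i]))
  }
  invisible(x)
}

#' Trace an iso-power curve over a pair of design parameters
#'
#' For each value of `x_param` in `x_grid`, fixes that value on a copy of
#' the reference design and computer-adjusts `y_param` so the resulting
#' design is power-equivalent to the reference (equal effective error).
#' Grid points where no solution exists within the bounds are flagged
#' infeasible rather than dropped, so curves keep their full x extent.
#'
#' `x_param` may additionally be `"sigma2_S"`: the slope variance does not
#' enter the effective error, so the curve instead holds the effective
#' curve reliability (ECR) constant by scaling the target effective error
#' proportionally to `sigma2_S`. `sigma2_S` is never a `y_param`.
#'
#' @param reference an `lgcm_design` defining the target.
#' @param x_param parameter swept along the x axis: one of `"sigma2_eps"`,
#'   `"sigma2_I"`, `"T"`, `"M"`, `"sigma2_S"`.
#' @param x_grid numeric vector of x values (integers for `"M"`).
#' @param y_param parameter solved at each x: one of `"sigma2_eps"`,
#'   `"sigma2_I"`, `"T"`, `"M"`.
#' @param bounds search interval for `y_param`; same defaults as
#'   [solve_equivalent_design()].
#' @param tol relative tolerance on the matched effective error.
#' @return an object of classes `iso_power_curve` and `data.frame` with
#'   columns `x`, `y`, `sigma2_eff` and `feasible`.
#' @export
iso_power_curve <- function(reference, x_param, x_grid, y_param,
                            bounds = NULL, tol = 1e-10) {
  x_ok <- c(setdiff(.adjustable, "N"), "sigma2_S")
  y_ok <- setdiff(.adjustable, "N")
  x_param <- match.arg(x_param, x_ok)
  y_param <- match.arg(y_param, y_ok)
  if (x_param == y_param)
    stop("x_param and y_param must differ", call. = FALSE)
  if (is.null(bounds)) bounds <- .default_bounds[[y_param]]
  ref_eff <- effective_error_slope(reference$occasions, reference$sigma2_eps,
                                   reference$sigma2_I)
  if (x_param == "sigma2_S" && reference$sigma2_S <= 0)
    stop("sweeping sigma2_S requires a reference with sigma2_S > 0",
         call. = FALSE)
  y <- eff <- rep(NA_real_, length(x_grid))
  feasible <- logical(length(x_grid))
  for (i in seq_along(x_grid)) {
    xv <- x_grid[i]
    if (x_param == "sigma2_S") {
      candidate <- reference
      candidate$sigma2_S <- xv
      target <- ref_eff * xv / reference$sigma2_S  # constant ECR
    } else {
      candidate <- design_with(reference, x_param, xv)
      target <- ref_eff
    }
    res <- tryCatch({
      f <- function(v) eff_at(candidate, y_param, v) - target
      root <- solve_bracketed(f, bounds[1], bounds[2], target, tol)
      list(y = root, eff = eff_at(candidate, y_param, root))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      y[i] <- res$y
      eff[i] <- res$eff
      feasible[i] <- TRUE
    }
  }
  out <- data.frame(x = x_grid, y = y, sigma2_eff = eff, feasible = feasible)
  attr(out, "x_param") <- x_param
  attr(out, "y_param") <- y_param
  attr(out, "target_sigma2_eff") <- ref_eff
  class(out) <- c("iso_power_curve", "data.frame")
  out
}

#' @export
plot.iso_power_curve <- function(x, ...) {
  ok <- x$feasible
  plot(x$x[ok], x$y[ok], type = "b", pch = 16,
       xlab = attr(x, "x_param"), ylab = attr(x, "y_param"),
       main = "Iso-power curve", ...)
  if (any(!ok))
    graphics::rug(x$x[!ok], col = "red")
  invisible(x)
}
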