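#' Equally spaced measurement occasions
#'
#' Build an occasion grid of `M` equally spaced measurement times over a
#' total study time of `T` years. Two conventions are supported:
#'
#' * `"baseline_zero"` (default): a baseline measurement at time 0, so
#'   \eqn{t_j = (j-1) T / (M-1)}. For `M = 3`, `T = 4` this gives
#'   \{0, 2, 4\}.
#' * `"no_baseline"`: the first measurement falls at `T/M`, so
#'   \eqn{t_j = j T / M}. This is the grid under which the closed-form
#'   substitution identities for \eqn{\sum t_j} and \eqn{\sum t_j^2} hold
#'   exactly (see [substitution_sums()]).
#'
#' @param M integer number of occasions, at least 2.
#' @param T total study time in years (time of the last occasion), positive.
#' @param convention `"baseline_zero"` or `"no_baseline"`.
#' @return numeric vector of `M` non-decreasing times with last element `T`.
#' @examples
#' equal_spaced_occasions(3, 4)                  # 0 2 4
#' equal_spaced_occasions(3, 4, "no_baseline")   # 4/3 8/3 4
#' @export
equal_spaced_occasions <- function(M, T,
                                   convention = c("baseline_zero",
                                                  "no_baseline")) {
  convention <- match.arg(convention)
  if (length(M) != 1L || !is.finite(M) || M < 2 || M != round(M))
    stop("invalid design: M must be an integer >= 2", call. = FALSE)
  if (length(T) != 1L || !is.finite(T) || T <= 0)
    stop("invalid design: T must be a positive study time", call. = FALSE)
  M <- as.integer(M)
  if (convention == "baseline_zero") {
    (seq_len(M) - 1) * T / (M - 1)
  } else {
    seq_len(M) * T / M
  }
}

#' Specify a linear latent growth curve study design
#'
#' A design bundles the occasion grid with the population parameters of a
#' linear LGCM: residual variance \eqn{\sigma^2_\epsilon}, latent intercept
#' and slope variances \eqn{\sigma^2_I}, \eqn{\sigma^2_S}, their covariance
#' \eqn{\sigma_{IS}}, the latent means \eqn{\mu_I}, \eqn{\mu_S}, and an
#' optional planned sample size `N`.
#'
#' Occasions may be given explicitly via `occasions` (overriding `M`/`T`),
#' or as an equally spaced grid built from `M` and `T` (see
#' [equal_spaced_occasions()]).
#'
#' @param M number of occasions (ignored when `occasions` is given).
#' @param T total study time in years (ignored when `occasions` is given).
#' @param occasions optional explicit vector of measurement times.
#' @param sigma2_eps residual (measurement error) variance, > 0.
#' @param sigma2_I latent intercept variance, >= 0.
#' @param sigma2_S latent slope variance (per year squared), >= 0.
#' @param sigma_IS latent intercept-slope covariance; must satisfy
#'   \eqn{\sigma_{IS}^2 \le \sigma^2_I \sigma^2_S}.
#' @param mu_I,mu_S latent intercept and slope means; default 0 (the mean
#'   structure does not affect covariance-structure power when correctly
#'   specified).
#' @param N optional planned sample size (positive integer).
#' @param convention grid convention for equally spaced occasions.
#' @return an object of class `lgcm_design`.
#' @examples
#' # Octogenarian-twin memory example: 3 occasions over 4 years
#' octo <- lgcm_design(M = 3, T = 4, sigma2_eps = 9.20, sigma2_I = 39.63,
#'                     sigma2_S = 0.53, sigma_IS = -0.69, N = 250)
#' octo
#' @export
lgcm_design <- function(M = NULL, T = NULL, occasions = NULL,
                        sigma2_eps, sigma2_I, sigma2_S,
                        sigma_IS = 0, mu_I = 0, mu_S = 0, N = NULL,
                        convention = c("baseline_zero", "no_baseline")) {
  convention <- match.arg(convention)
  if (is.null(occasions)) {
    if (is.null(M) || is.null(T))
      stop("supply either `occasions` or both `M` and `T`", call. = FALSE)
    occasions <- equal_spaced_occasions(M, T, convention)
  } else {
    occasions <- as.numeric(occasions)
  }
  design <- structure(
    list(occasions = occasions,
         M = length(occasions),
         T = if (length(occasions)) max(occasions) else NA_real_,
         sigma2_eps = as.numeric(sigma2_eps),
         sigma2_I = as.numeric(sigma2_I),
         sigma2_S = as.numeric(sigma2_S),
         sigma_IS = as.numeric(sigma_IS),
         mu_I = as.numeric(mu_I),
         mu_S = as.numeric(mu_S),
         N = if (is.null(N)) NULL else as.integer(N)),
    class = "lgcm_design")
  problems <- validate_design(design)
  if (length(problems))
    stop("invalid design:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  design
}

#' Validate a study design
#'
#' Checks every invariant of an `lgcm_design` and returns a character
#' vector describing each violation (empty when the design is valid).
#' Unlike the constructor this never throws, so it can be used
#' diagnostically.
#'
#' @param design an `lgcm_design` (or a bare list with the same fields).
#' @return character vector of violation descriptions; `character(0)` if
#'   the design is valid.
#' @export
validate_design <- function(design) {
  problems <- character(0)
  t <- design$occasions
  if (length(t) < 2)
    problems <- c(problems,
                  "occasions: at least 2 measurement occasions are required (slope unidentified otherwise)")
  if (length(t) >= 2) {
    if (is.unsorted(t))
      problems <- c(problems, "occasions: times must be non-decreasing")
    if (length(unique(t)) < 2)
      problems <- c(problems,
                    "occasions: at least two distinct times are required (slope unidentified otherwise)")
  }
  if (any(!is.finite(t)))
    problems <- c(problems, "occasions: times must be finite")
  if (!is.null(design$T) && length(t) && is.finite(design$T) &&
      abs(design$T - max(t)) > 1e-12 * max(1, abs(max(t))))
    problems <- c(problems, "T: total study time must equal the last occasion")
  if (!is.finite(design$sigma2_eps) || design$sigma2_eps <= 0)
    problems <- c(problems, "sigma2_eps: residual variance must be > 0")
  if (!is.finite(design$sigma2_I) || design$sigma2_I < 0)
    problems <- c(problems, "sigma2_I: intercept variance must be >= 0")
  if (!is.finite(design$sigma2_S) || design$sigma2_S < 0)
    problems <- c(problems, "sigma2_S: slope variance must be >= 0")
  if (is.finite(design$sigma_IS) && is.finite(design$sigma2_I) &&
      is.finite(design$sigma2_S) &&
      design$sigma_IS^2 > design$sigma2_I * design$sigma2_S * (1 + 1e-12))
    problems <- c(problems,
                  "sigma_IS: latent covariance matrix not positive semidefinite (sigma_IS^2 > sigma2_I * sigma2_S)")
  if (!is.null(design$N) && (!is.finite(design$N) || design$N < 1))
    problems <- c(problems, "N: sample size must be a positive integer")
  problems
}

#' Model-implied moments of the observed variables
#'
#' Assembles the loading matrix \eqn{\Lambda = [1 \; t]} and returns the
#' model-implied mean vector \eqn{\mu = \Lambda \nu} and covariance matrix
#' \eqn{\Sigma = \Lambda \Psi \Lambda' + \sigma^2_\epsilon I} of the `M`
#' observed variables. Elementwise,
#' \eqn{\Sigma_{ij} = \sigma^2_I + \sigma_{IS}(t_i + t_j) +
#' \sigma^2_S t_i t_j + \delta_{ij} \sigma^2_\epsilon}.
#'
#' @param design an `lgcm_design`.
#' @return a list with components `Sigma` (M x M symmetric matrix) and
#'   `mu` (length-M vector).
#' @export
implied_moments <- function(design) {
  problems <- validate_design(design)
  if (length(problems))
    stop("invalid design:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  t <- design$occasions
  Lambda <- cbind(1, t)
  Psi <- matrix(c(design$sigma2_I, design$sigma_IS,
                  design$sigma_IS, design$sigma2_S), 2, 2)
  Sigma <- Lambda %*% Psi %*% t(Lambda) + diag(design$sigma2_eps, length(t))
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- drop(Lambda %*% c(design$mu_I, design$mu_S))
  dimnames(Sigma) <- NULL
  list(Sigma = Sigma, mu = mu)
}

#' Replace one design parameter
#'
#' Returns a copy of the design with `param` set to `value`, regenerating
#' the occasion grid when the grid itself changes: times are rescaled
#' proportionally for `T` and rebuilt equally spaced with a baseline at
#' zero for `M`. Useful for building candidate designs for
#' [solve_equivalent_design()].
#'
#' @param design an `lgcm_design`.
#' @param param one of `"sigma2_eps"`, `"sigma2_I"`, `"sigma2_S"`, `"T"`,
#'   `"M"`, `"N"`.
#' @param value the new value (an integer for `M` and `N`).
#' @return the modified `lgcm_design`.
#' @export
design_with <- function(design, param, value) {
  switch(param,
    sigma2_eps = { design$sigma2_eps <- value },
    sigma2_I = { design$sigma2_I <- value },
    sigma2_S = { design$sigma2_S <- value },
    N = { design$N <- as.integer(round(value)) },
    T = {
      design$occasions <- design$occasions * (value / design$T)
      design$T <- value
    },
    M = {
      m <- as.integer(round(value))
      design$occasions <- equal_spaced_occasions(m, design$T)
      design$M <- m
    },
    stop("unknown design parameter: ", param, call. = FALSE))
  design
}

#' @export
print.lgcm_design <- function(x, digits = 4, ...) {
  cat("Linear latent growth curve study design\n")
  cat(sprintf("  Occasions (M = %d, T = %g years): %s\n", x$M, x$T,
              paste(format(x$occasions, digits = digits), collapse = ", ")))
  cat(sprintf("  Residual variance  sigma2_eps = %g\n", x$sigma2_eps))
  cat(sprintf("  Intercept variance sigma2_I   = %g\n", x$sigma2_I))
  cat(sprintf("  Slope variance     sigma2_S   = %g\n", x$sigma2_S))
  cat(sprintf("  Covariance         sigma_IS   = %g", x$sigma_IS))
  if (x$sigma2_I > 0 && x$sigma2_S > 0)
    cat(sprintf("  (correlation %.2f)",
                x$sigma_IS / sqrt(x$sigma2_I * x$sigma2_S)))
  cat("\n")
  cat(sprintf("  Latent means       (mu_I, mu_S) = (%g, %g)\n", x$mu_I, x$mu_S))
  if (!is.null(x$N)) cat(sprintf("  Planned sample size N = %d\n", x$N))
  invisible(x)
}

#' @export
summary.lgcm_design <- function(object, ...) {
  out <- list(design = object, indices = design_indices(object))
  class(out) <- "summary.lgcm_design"
  out
}

#' @export
print.summary.lgcm_design <- function(x, ...) {
  print(x$design)
  cat("\n")
  print(x$indices)
  invisible(x)
}

# ---- design configuration files -------------------------------------------

.design_keys <- c("M", "T", "occasions", "sigma2_eps", "sigma2_I",
                  "sigma2_S", "sigma_IS", "mu_I", "mu_S", "N")

#' Read a study design from a configuration file
#'
#' Designs are stored as flat YAML with keys `M`, `T`, `occasions`
#' (optional explicit list, overriding `M`/`T`), `sigma2_eps`, `sigma2_I`,
#' `sigma2_S`, `sigma_IS`, `mu_I`, `mu_S`, `N`. Unknown keys are rejected
#' so typos fail fast. A missing `sigma_IS` (or missing means) defaults to
#' 0 with a notice.
#'
#' @param path path to a YAML design file.
#' @return an `lgcm_design`.
#' @seealso [export_design()]
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 resolves a bare `N` key to boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "N"
  unknown <- setdiff(names(cfg), .design_keys)
  if (length(unknown))
    stop("unknown design configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(cfg$occasions) && (is.null(cfg$M) || is.null(cfg$T)))
    stop("design configuration needs `occasions` or both `M` and `T`",
         call. = FALSE)
  for (key in c("sigma_IS", "mu_I", "mu_S")) {
    if (is.null(cfg[[key]])) {
      message("design configuration: `", key, "` not given, defaulting to 0")
      cfg[[key]] <- 0
    }
  }
  lgcm_design(M = cfg$M, T = cfg$T, occasions = cfg$occasions,
              sigma2_eps = cfg$sigma2_eps, sigma2_I = cfg$sigma2_I,
              sigma2_S = cfg$sigma2_S, sigma_IS = cfg$sigma_IS,
              mu_I = cfg$mu_I, mu_S = cfg$mu_S, N = cfg$N)
}

#' Write a study design to a configuration file
#'
#' Serializes the design as flat YAML readable by [read_design()]. Numeric
#' fields are written with 17 significant digits so the round trip is
#' lossless (field-for-field equality).
#'
#' @param design an `lgcm_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_design <- function(design, path) {
  problems <- validate_design(design)
  if (length(problems))
    stop("invalid design:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    sprintf("occasions: [%s]", paste(num(design$occasions), collapse = ", ")),
    sprintf("sigma2_eps: %s", num(design$sigma2_eps)),
    sprintf("sigma2_I: %s", num(design$sigma2_I)),
    sprintf("sigma2_S: %s", num(design$sigma2_S)),
    sprintf("sigma_IS: %s", num(design$sigma_IS)),
    sprintf("mu_I: %s", num(design$mu_I)),
    sprintf("mu_S: %s", num(design$mu_S)))
  if (!is.null(design$N)) lines <- c(lines, sprintf("'N': %d", design$N))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
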