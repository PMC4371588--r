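# Shared fixtures and independent oracles, built in code.

# Octogenarian-twin memory worked example: three occasions over four years.
octo_design <- function(N = 250)
  lgcm_design(M = 3, T = 4, sigma2_eps = 9.20, sigma2_I = 39.63,
              sigma2_S = 0.53, sigma_IS = -0.69, N = N)

# A random valid design with an interior latent covariance matrix.
random_design <- function(M = sample(3:6, 1), equal_spaced = TRUE) {
  s2I <- runif(1, 1, 50)
  s2S <- runif(1, 0.1, 5)
  occ <- if (equal_spaced) NULL else sort(runif(M, 0, 10))
  lgcm_design(M = M, T = runif(1, 2, 10), occasions = occ,
              sigma2_eps = runif(1, 0.5, 20), sigma2_I = s2I,
              sigma2_S = s2S,
              sigma_IS = runif(1, -0.8, 0.8) * sqrt(s2I * s2S),
              mu_I = runif(1, -5, 5), mu_S = runif(1, -2, 2))
}

# Matrix oracle for the effective error: the generalized-least-squares
# precision of the slope given V = sigma2_I * 11' + sigma2_eps * I.
eff_oracle <- function(occasions, sigma2_eps, sigma2_I) {
  t <- as.numeric(occasions)
  M <- length(t)
  V <- sigma2_I * matrix(1, M, M) + sigma2_eps * diag(M)
  1 / drop(t %*% solve(V) %*% t)
}

# Brute-force implied moments, elementwise from the scalar formula.
moments_oracle <- function(design) {
  t <- design$occasions
  M <- length(t)
  Sigma <- matrix(NA_real_, M, M)
  for (i in seq_len(M)) for (j in seq_len(M))
    Sigma[i, j] <- design$sigma2_I + design$sigma_IS * (t[i] + t[j]) +
      design$sigma2_S * t[i] * t[j] + (i == j) * design$sigma2_eps
  list(Sigma = Sigma, mu = design$mu_I + t * design$mu_S)
}

# Plain bisection on a monotone function, independent of the package's
# solver; used as the oracle for equivalence roots.
bisect_oracle <- function(f, lo, hi, iters = 200) {
  flo <- f(lo)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# Candidate perturbations chosen so the equivalence root is always
# bracketed for the generator's parameter ranges: sigma2_eps and T sweep
# sigma2_eff over (0, inf); sigma2_I and M get only a mild
# residual-variance perturbation because their attainable sigma2_eff
# ranges are bounded.
perturbed_candidate <- function(ref, adjust) {
  switch(adjust,
         sigma2_eps = design_with(ref, "T", ref$T * 1.3),
         T = design_with(ref, "sigma2_eps", ref$sigma2_eps * 1.4),
         sigma2_I = design_with(ref, "sigma2_eps", ref$sigma2_eps * 1.05),
         M = design_with(ref, "sigma2_eps", ref$sigma2_eps * 1.1))
}

population_moments_list <- function(design, n = 1000L) {
  mom <- implied_moments(design)
  list(mean = mom$mu, cov = mom$Sigma, n = n)
}
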