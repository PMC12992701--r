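# shared fixtures and independent oracles

# numerical convolution of two Gaussian kernels against shared white noise:
# the normative definition of every covariance component
quad_kernel_cov <- function(va, Ba, vb, Bb, dt) {
  stats::integrate(function(u) va * exp(-Ba * (dt + u)^2 / 2) *
                     vb * exp(-Bb * u^2 / 2),
                   -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# independent MVN log-density (solve/determinant route, no Cholesky sharing
# with the package internals)
oracle_mvn_logpdf <- function(x, mean, S) {
  d <- length(x)
  as.numeric(-0.5 * d * log(2 * pi) -
               0.5 * determinant(S, logarithm = TRUE)$modulus -
               0.5 * drop(t(x - mean) %*% solve(S, x - mean)))
}

oracle_ig_logpdf <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

random_theta <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kernels <- lapply(seq_len(k), function(a) {
    factor_kernel(v0 = runif(1, 0.2, 2) * sample(c(-1, 1), 1),
                  v1 = runif(1, 0.2, 2),
                  B0 = runif(1, 0.1, 4), B1 = runif(1, 0.1, 4))
  })
  mogp_hyperparams(kernels, nugget = runif(1, 0, 0.5),
                   means = rnorm(k, 0, 0.5))
}

# small long-format panel data frame
toy_long <- function(n = 2, p = 2, times = list(c(0, 1, 2), c(0, 2)),
                     seed = 7) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n)) {
    ti <- times[[((i - 1) %% length(times)) + 1]]
    for (g in seq_len(p)) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = paste0("s", i), time = ti,
        biomarker = paste0("g", g), value = rnorm(length(ti)))
    }
  }
  do.call(rbind, rows)
}

# fully specified tiny state for deterministic model checks
tiny_state <- function(panel, k, seed = 1) {
  set.seed(seed)
  n <- panel$n; p <- panel$p; q <- panel$q
  dynfa:::new_state(
    A = matrix(rnorm(p * k), p, k),
    Z = matrix(rbinom(p * k, 1, 0.6), p, k),
    M = matrix(rnorm(n * p, 5, 1), n, p),
    Y = matrix(rnorm(n * k * q), n, k * q),
    pi = rep(0.3, k), rho2 = rep(1.5, k),
    sigma2 = runif(p, 0.5, 1.5), phi2 = runif(p, 0.2, 0.8))
}
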