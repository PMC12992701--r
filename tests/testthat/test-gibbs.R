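# Full-conditional correctness against independent conjugate/brute-force
# oracles, the two-stage factor block update, determinism, and predictive
# reconstruction.

make_tiny <- function(n = 2, p = 3, k = 1, seed = 5) {
  set.seed(seed)
  cfg <- sim_config(n = n, p = p, k = k, design = "regular", times = c(0, 1),
                    score_mode = "iid", corr = diag(1, k),
                    loading_mean = 2, loading_sd = 0.5, reg_prob = 0.6,
                    mu_range = c(4, 6), sigma_g = 0.5, phi_g = 0.5)
  simulate_panel(cfg, seed = seed)
}

test_that("subject-mean update matches the conjugate two-Gaussian product", {
  ds <- make_tiny()
  panel <- ds$panel
  pr <- dfa_priors(panel$p, mu_g = colMeans(panel$X))
  st <- tiny_state(panel, 1, seed = 2)
  # empirical moments of repeated draws with the rest of the state fixed
  set.seed(3)
  R <- 20000
  draws <- matrix(NA_real_, R, 2)  # mu_{11}, mu_{2,3}
  for (r in seq_len(R)) {
    up <- dynfa:::update_means_and_noise(st, panel, pr)
    draws[r, ] <- c(up$M[1, 1], up$M[2, 3])
  }
  # oracle: precision-weighted average of prior and residual mean
  L <- st$A * st$Z
  Yo <- dynfa:::observed_scores(st, panel, 1)
  r0 <- panel$X - Yo %*% t(L)
  for (ii in 1:2) {
    i <- c(1, 2)[ii]; g <- c(1, 3)[ii]
    rows <- which(panel$row_subject == i)
    prec <- 1 / st$sigma2[g] + length(rows) / st$phi2[g]
    mn <- (pr$mu_g[g] / st$sigma2[g] + sum(r0[rows, g]) / st$phi2[g]) / prec
    expect_lt(abs(mean(draws[, ii]) - mn), 4 * sqrt(1 / (prec * R)))
    expect_lt(abs(var(draws[, ii]) - 1 / prec),
              5 * (1 / prec) * sqrt(2 / R))
  }
})

test_that("subject means collapse to the grand mean as sigma_g^2 -> 0", {
  ds <- make_tiny()
  panel <- ds$panel
  pr <- dfa_priors(panel$p, mu_g = colMeans(panel$X))
  st <- tiny_state(panel, 1, seed = 2)
  st$sigma2 <- rep(1e-12, panel$p)
  set.seed(4)
  up <- dynfa:::update_means_and_noise(st, panel, pr)
  expect_equal(up$M[1, ], unname(pr$mu_g), tolerance = 1e-4)
})

test_that("collapsed loading update matches the brute-force two-point
           marginal at p = k = q_i = 1", {
  # single biomarker, single factor, single time, one subject
  long <- data.frame(subject = "s1", time = c(0, 1), biomarker = "g1",
                     value = c(1.8, 0.3))
  panel <- suppressWarnings(dfa_panel(long))
  pr <- dfa_priors(1, c0 = 1, d0 = 3, mu_g = 0)
  st <- dynfa:::new_state(A = matrix(0.5), Z = matrix(1L),
                          M = matrix(0, 1, 1), Y = matrix(c(1.2, -0.7), 1, 2),
                          pi = 0.25, rho2 = 2, sigma2 = 1, phi2 = 0.4)
  # brute force: P(Z=1 | rest) with A integrated out by quadrature
  y <- st$Y[1, ]; x <- panel$X[, 1]
  lik1 <- integrate(function(a) {
    sapply(a, function(ai) {
      prod(dnorm(x, ai * y, sqrt(st$phi2))) * dnorm(ai, 0, sqrt(st$rho2))
    })
  }, -Inf, Inf, rel.tol = 1e-12)$value
  lik0 <- prod(dnorm(x, 0, sqrt(st$phi2)))
  pz_true <- st$pi * lik1 / (st$pi * lik1 + (1 - st$pi) * lik0)
  set.seed(11)
  R <- 40000
  zdraw <- numeric(R)
  for (r in seq_len(R)) {
    up <- dynfa:::update_loadings(st, panel, pr)
    zdraw[r] <- up$Z[1, 1]
  }
  expect_equal(mean(zdraw), pz_true,
               tolerance = 4 * sqrt(pz_true * (1 - pz_true) / R))
})

test_that("no residual association and a tiny pi give near-zero inclusion", {
  ds <- make_tiny(n = 6, p = 2)
  panel <- ds$panel
  pr <- dfa_priors(2, mu_g = colMeans(panel$X))
  st <- tiny_state(panel, 1, seed = 13)
  # make the data exactly the subject means: residual = 0 everywhere
  st$M <- matrix(0, panel$n, panel$p)
  panel$X[] <- 0
  st$Y[] <- rnorm(length(st$Y))
  st$pi <- 1e-6
  set.seed(14)
  z <- replicate(300, dynfa:::update_loadings(st, panel, pr)$Z[1, 1])
  expect_lt(mean(z), 0.02)
})

test_that("pi update is Beta(c0 + #included, d0 + #excluded)", {
  # force inclusion via huge loadings and strong signal
  ds <- make_tiny(n = 10, p = 4, seed = 21)
  panel <- ds$panel
  pr <- dfa_priors(4, mu_g = colMeans(panel$X))
  st <- tiny_state(panel, 1, seed = 22)
  st$M <- matrix(0, panel$n, panel$p)
  st$Y[] <- rnorm(length(st$Y), 0, 1)
  Yo <- dynfa:::observed_scores(st, panel, 1)
  panel$X <- Yo %*% t(matrix(10, 4, 1))   # exact strong signal, all loaded
  st$phi2 <- rep(0.01, 4)
  set.seed(23)
  pis <- replicate(4000, dynfa:::update_loadings(st, panel, pr)$pi)
  expect_equal(mean(pis), (pr$c0 + 4) / (pr$c0 + 4 + pr$d0),
               tolerance = 0.02)
})

test_that("factor block update matches direct joint-Gaussian conditioning", {
  # k = 2, q_i = 2, p = 3: empirical mean/cov of the two-stage block draw
  # against conditioning in the joint Gaussian of (scores, observations)
  set.seed(31)
  k <- 2; p <- 3; q <- 2
  long <- expand.grid(subject = "s1", time = c(0, 1),
                      biomarker = paste0("g", 1:p))
  long$value <- rnorm(nrow(long), 5, 2)
  panel <- suppressWarnings(dfa_panel(long))
  th <- normalize_unit_variance(mogp_hyperparams(
    list(factor_kernel(0.9, 0.5, 0.8, 1.5), factor_kernel(0.7, 0.8, 1.2, 0.6)),
    nugget = 0.15, means = c(0.3, -0.2)))$theta
  pr <- dfa_priors(p, mu_g = colMeans(panel$X))
  st <- tiny_state(panel, k, seed = 32)
  st$Z[] <- 1L
  cache <- dynfa:::make_factor_cache(panel, th)
  R <- 20000
  draws <- matrix(NA_real_, R, k * q)
  set.seed(33)
  for (r in seq_len(R)) {
    up <- dynfa:::update_factors(st, panel, th, cache)
    draws[r, ] <- up$Y[1, ]
  }
  # oracle: joint Gaussian of (y, x); x = mu + (I_q (x) L) P y + e where P
  # reorders factor-major scores to time-major
  L <- st$A * st$Z
  S <- build_cov(th, panel$grid)
  perm <- as.vector(t(matrix(seq_len(k * q), q, k)))  # factor-major -> time-major
  Pm <- diag(k * q)[perm, , drop = FALSE]
  Lbig <- kronecker(diag(1, q), L) %*% Pm             # (p q) x (k q)
  noise <- diag(rep(st$phi2, times = q))
  mu_x <- rep(st$M[1, ], times = q)
  cm <- rep(th$means, each = q)
  Sxx <- Lbig %*% S %*% t(Lbig) + noise
  Sxy <- Lbig %*% S
  xv <- as.vector(t(panel$X))                          # time-major stack of x_j
  post_mean <- cm + drop(t(Sxy) %*% solve(Sxx, xv - mu_x - Lbig %*% cm))
  post_cov <- S - t(Sxy) %*% solve(Sxx, Sxy)
  se_mean <- sqrt(diag(post_cov) / R)
  expect_lt(max(abs(colMeans(draws) - post_mean) / se_mean), 4)
  emp_cov <- cov(draws)
  se_cov <- sqrt((outer(diag(post_cov), diag(post_cov)) + post_cov^2) / R)
  expect_lt(max(abs(emp_cov - post_cov) / se_cov), 5)
})

test_that("a subject with no observations is drawn from the MOGP prior", {
  # two subjects, one with visits only at times the other never has;
  # group structure still draws each correctly -- here test the prior-draw
  # branch via a pattern with zero observed times
  th <- normalize_unit_variance(random_theta(2, seed = 41))$theta
  long <- data.frame(subject = "s1", time = c(0, 1, 2), biomarker = "g1",
                     value = c(1, 2, 3))
  panel <- suppressWarnings(dfa_panel(long))
  # manufacture an extra subject with no visits
  panel$n <- 2L
  panel$subjects <- c("s1", "s2")
  panel$V <- rbind(panel$V, rep(FALSE, panel$q))
  panel$q_i <- c(panel$q_i, 0L)
  pr <- dfa_priors(1, mu_g = 2)
  st <- tiny_state(panel, 2, seed = 42)
  st <- dynfa:::new_state(A = st$A, Z = st$Z,
                          M = rbind(st$M, 0), Y = rbind(st$Y, 0),
                          pi = st$pi, rho2 = st$rho2,
                          sigma2 = st$sigma2, phi2 = st$phi2)
  cache <- dynfa:::make_factor_cache(panel, th)
  set.seed(43)
  R <- 20000
  draws <- matrix(NA_real_, R, 2 * panel$q)
  for (r in seq_len(R)) {
    draws[r, ] <- dynfa:::update_factors(st, panel, th, cache)$Y[2, ]
  }
  S <- build_cov(th, panel$grid)
  cm <- rep(th$means, each = panel$q)
  expect_lt(max(abs(colMeans(draws) - cm)) / sqrt(max(diag(S)) / R), 5)
  emp <- cov(draws)
  se <- sqrt((outer(diag(S), diag(S)) + S^2) / R)
  expect_lt(max(abs(emp - S) / se), 5)
})

test_that("chains are reproducible for a fixed seed and differ across seeds", {
  ds <- make_tiny(n = 4, p = 3, seed = 51)
  th <- normalize_unit_variance(random_theta(1, seed = 52))$theta
  cfg <- gibbs_config(n_iter = 60, thin = 2, seed = 9)
  s1 <- run_gibbs(ds$panel, th, cfg)
  s2 <- run_gibbs(ds$panel, th, cfg)
  expect_identical(s1$chains[[1]]$Y, s2$chains[[1]]$Y)
  expect_identical(s1$chains[[1]]$A, s2$chains[[1]]$A)
  s3 <- run_gibbs(ds$panel, th, gibbs_config(n_iter = 60, thin = 2, seed = 10))
  expect_false(identical(s1$chains[[1]]$Y, s3$chains[[1]]$Y))
})

test_that("scores concentrate on truth when loadings are fixed and noise is
           small", {
  set.seed(61)
  cfg <- sim_config(n = 3, p = 8, k = 1, design = "regular", times = 0:3,
                    corr = diag(1, 1), loading_mean = 3, loading_sd = 0.3,
                    reg_prob = 1, mu_range = c(0, 0.01), sigma_g = 0,
                    phi_g = 0.01)
  ds <- simulate_panel(cfg, seed = 62)
  panel <- ds$panel
  th <- normalize_unit_variance(mogp_hyperparams(
    list(factor_kernel(0.7, 0.7, 1, 1)), nugget = 0.1))$theta
  pr <- dfa_priors(8, mu_g = rep(0, 8))
  st <- tiny_state(panel, 1, seed = 63)
  st$A <- ds$truth$L; st$Z[] <- 1L
  st$M <- ds$truth$M
  st$phi2 <- rep(1e-4, 8)
  cache <- dynfa:::make_factor_cache(panel, th)
  set.seed(64)
  up <- dynfa:::update_factors(st, panel, th, cache)
  expect_equal(up$Y[1, ], as.vector(t(ds$truth$Y[1, , ])), tolerance = 0.05)
})

test_that("posterior predictive bands behave at degenerate settings", {
  ds <- make_tiny(n = 3, p = 2, seed = 71)
  th <- normalize_unit_variance(random_theta(1, seed = 72))$theta
  smp <- run_gibbs(ds$panel, th, gibbs_config(n_iter = 40, seed = 1))
  # single retained draw: zero-width band equal to that draw's curve
  one <- smp
  for (nm in c("A", "Z", "M", "Y")) {
    one$chains[[1]][[nm]] <- one$chains[[1]][[nm]][, , 32, drop = FALSE]
  }
  for (nm in c("pi", "rho2", "sigma2", "phi2")) {
    one$chains[[1]][[nm]] <- one$chains[[1]][[nm]][, 32, drop = FALSE]
  }
  pp <- posterior_predictive(one, "s001", "g001")
  expect_equal(pp$lower, pp$median)
  expect_equal(pp$upper, pp$median)
  # L = 0 draws: band centred on the subject-biomarker mean draws
  zero <- one
  zero$chains[[1]]$Z[] <- 0L
  pp0 <- posterior_predictive(zero, "s001", "g001")
  expect_equal(pp0$median, rep(zero$chains[[1]]$M[1, 1, 1], length(pp0$time)))
  expect_error(posterior_predictive(smp, "nope", "g001"), "unknown subject")
  expect_error(posterior_predictive(smp, "s001", "nope"), "unknown biomarker")
})

test_that("posterior predictive covers held-out noiseless curves", {
  # smooth factors, moderate noise; >= 90% of held-out true curve values
  # inside the 95% band
  th_gen <- normalize_unit_variance(mogp_hyperparams(
    list(factor_kernel(1, 0.5, 0.08, 0.08)), nugget = 0.02))$theta
  cfg <- sim_config(n = 10, p = 6, k = 1, design = "regular", times = 0:7,
                    score_mode = "mogp", theta = th_gen, loading_mean = 3,
                    reg_prob = 0.5, mu_range = c(4, 8), sigma_g = 0.5,
                    phi_g = 0.3)
  ds <- simulate_panel(cfg, seed = 81)
  smp <- run_gibbs(ds$panel, th_gen, gibbs_config(n_iter = 300, seed = 2))
  smp <- align_draws(smp)
  inside <- total <- 0
  for (i in c(1, 4, 7)) for (g in c(1, 3, 5)) {
    truth_curve <- ds$truth$M[i, g] +
      ds$truth$L[g, 1] * ds$truth$Y[i, 1, ]
    pp <- posterior_predictive(smp, i, g)
    inside <- inside + sum(pp$lower <= truth_curve & truth_curve <= pp$upper)
    total <- total + length(truth_curve)
  }
  expect_gte(inside / total, 0.9)
})
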