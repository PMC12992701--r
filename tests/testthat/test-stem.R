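# Penalized objective, M-step, trailing-average estimator and the StEM driver.

draw_scores <- function(theta, grid, n, seed) {
  set.seed(seed)
  S <- build_cov(theta, grid)
  ch <- chol(S)
  cm <- rep(theta$means, each = length(grid))
  t(cm + t(ch) %*% matrix(rnorm(nrow(S) * n), nrow(S), n))
}

test_that("penalized objective at lambda = 0 is the sum of MVN log-densities", {
  th <- normalize_unit_variance(random_theta(2, seed = 5))$theta
  grid <- c(0, 0.5, 1.3, 2)
  Y <- draw_scores(th, grid, 6, seed = 6)
  got <- penalized_score_loglik(Y, th, grid, lambda = 0)
  S <- build_cov(th, grid)
  cm <- rep(th$means, each = length(grid))
  want <- sum(vapply(1:6, function(i) oracle_mvn_logpdf(Y[i, ], cm, S),
                     numeric(1)))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("penalty enters linearly with slope minus the decay sum", {
  th <- normalize_unit_variance(random_theta(2, seed = 7))$theta
  grid <- 0:3
  Y <- draw_scores(th, grid, 4, seed = 8)
  b <- sum(vapply(th$kernels, function(kr) kr$B0 + kr$B1, numeric(1)))
  l0 <- penalized_score_loglik(Y, th, grid, 0)
  for (lam in c(0.5, 2, 10)) {
    expect_equal(penalized_score_loglik(Y, th, grid, lam), l0 - lam * b,
                 tolerance = 1e-10)
  }
})

test_that("duplicating the subject set doubles the likelihood part only", {
  th <- normalize_unit_variance(random_theta(2, seed = 9))$theta
  grid <- 0:3
  Y <- draw_scores(th, grid, 5, seed = 10)
  lam <- 1.7
  b <- sum(vapply(th$kernels, function(kr) kr$B0 + kr$B1, numeric(1)))
  single <- penalized_score_loglik(Y, th, grid, lam)
  doubled <- penalized_score_loglik(rbind(Y, Y), th, grid, lam)
  expect_equal(doubled, 2 * (single + lam * b) - lam * b, tolerance = 1e-8)
})

test_that("M-step recovers generating hyperparameters from dense scores", {
  th_gen <- normalize_unit_variance(mogp_hyperparams(
    list(factor_kernel(0.8, 0.45, 0.5, 1.2), factor_kernel(-0.7, 0.6, 0.9, 0.4)),
    nugget = 0.1, means = c(0.8, -0.5)))$theta
  grid <- seq(0, 6, by = 0.75)
  Y <- draw_scores(th_gen, grid, 400, seed = 11)
  ms <- m_step(Y, grid, lambda = 0, theta_init = dynfa:::init_theta(grid, 2))
  expect_equal(cross_correlation_matrix(ms$theta)[1, 2],
               cross_correlation_matrix(th_gen)[1, 2], tolerance = 0.08)
  expect_equal(ms$theta$means, th_gen$means, tolerance = 0.15)
  # unit variance by construction
  expect_equal(diag(build_cov(ms$theta, grid))[c(1, 10)], c(1, 1),
               tolerance = 1e-10)
})

test_that("M-step never degrades the objective and matches an independent
           optimizer at lambda = 0", {
  th_gen <- normalize_unit_variance(random_theta(2, seed = 13))$theta
  grid <- seq(0, 4, by = 0.5)
  Y <- draw_scores(th_gen, grid, 120, seed = 14)
  ms <- m_step(Y, grid, 0, theta_init = th_gen)
  # starting from the returned optimum does not move (ascent contract)
  ms2 <- m_step(Y, grid, 0, theta_init = ms$theta)
  expect_gte(ms2$objective, ms$objective - 1e-6)
  # independent route: Nelder-Mead from a perturbed start on the same
  # penalized likelihood
  objf <- dynfa:::make_mstep_objective(Y, grid, 0, 2)
  set.seed(15)
  # independent direct fit from a perturbed start: m_step must do at least
  # as well as the simplex route
  start <- dynfa:::theta_to_trans(th_gen) + rnorm(8, 0, 0.2)
  for (restart in 1:3) {
    nm <- optim(start, objf$neg_obj, method = "Nelder-Mead",
                control = list(maxit = 20000, reltol = 1e-14))
    start <- nm$par
  }
  expect_gte(ms$objective, -nm$value - 1e-4)
  # and an independent polish started at m_step's solution cannot improve it
  polish <- optim(dynfa:::theta_to_trans(ms$theta), objf$neg_obj,
                  method = "Nelder-Mead",
                  control = list(maxit = 20000, reltol = 1e-14))
  expect_lt(abs(ms$objective - (-polish$value)), 1e-4)
})

test_that("a large penalty drives the decay parameters down", {
  th_gen <- normalize_unit_variance(random_theta(2, seed = 17))$theta
  grid <- 0:7
  Y <- draw_scores(th_gen, grid, 40, seed = 18)
  b_of <- function(ms) sum(vapply(ms$theta$kernels,
                                  function(kr) kr$B0 + kr$B1, numeric(1)))
  ms0 <- m_step(Y, grid, 0, theta_init = dynfa:::init_theta(grid, 2))
  ms_big <- m_step(Y, grid, 200, theta_init = dynfa:::init_theta(grid, 2))
  expect_lt(b_of(ms_big), b_of(ms0))
})

test_that("trailing-average estimator handles degenerate traces", {
  th1 <- normalize_unit_variance(random_theta(2, seed = 19))$theta
  th2 <- normalize_unit_variance(random_theta(2, seed = 20))$theta
  p1 <- dynfa:::theta_to_trans(th1); c1 <- th1$means
  p2 <- dynfa:::theta_to_trans(th2); c2 <- th2$means
  # constant trace returns that constant
  tr <- list(par = rbind(p1, p1, p1), means = rbind(c1, c1, c1), k = 2)
  est <- estimate_from_trace(tr, 3)
  expect_equal(dynfa:::theta_to_trans(est), unname(p1), tolerance = 1e-10)
  # m = 1 returns the last iterate
  tr2 <- list(par = rbind(p1, p2), means = rbind(c1, c2), k = 2)
  expect_equal(dynfa:::theta_to_trans(estimate_from_trace(tr2, 1)),
               unname(p2), tolerance = 1e-10)
  # alternating trace with even m averages to the transformed-space midpoint
  tr3 <- list(par = rbind(p1, p2, p1, p2), means = rbind(c1, c2, c1, c2),
              k = 2)
  mid <- estimate_from_trace(tr3, 4)
  expect_equal(dynfa:::theta_to_trans(mid), unname((p1 + p2) / 2),
               tolerance = 1e-10)
  expect_equal(mid$means, (c1 + c2) / 2, tolerance = 1e-12)
  expect_error(estimate_from_trace(tr3, 9), "exceeds")
})

test_that("stem_fit is deterministic and honours n_iters = m = 1", {
  ds <- simulate_panel(regular_sim_config(8, p = 10, k = 2), seed = 23)
  cfg <- stem_config(n_iters = 3, m = 2, s_chain_len = 30)
  f1 <- stem_fit(ds$panel, 2, lambda = 0.5, config = cfg, seed = 77)
  f2 <- stem_fit(ds$panel, 2, lambda = 0.5, config = cfg, seed = 77)
  expect_identical(f1$trace$par, f2$trace$par)
  expect_identical(f1$corr, f2$corr)
  f3 <- stem_fit(ds$panel, 2, lambda = 0.5, config = cfg, seed = 78)
  expect_false(identical(f1$trace$par, f3$trace$par))
  # single iteration, m = 1: the estimate is that iteration's M-step output
  one <- stem_fit(ds$panel, 2, lambda = 0,
                  config = stem_config(n_iters = 1, m = 1, s_chain_len = 20),
                  seed = 5)
  expect_equal(dynfa:::theta_to_trans(one$theta), unname(one$trace$par[1, ]),
               tolerance = 1e-12)
})

test_that("StEM trace shows no systematic drift after warm-up", {
  ds <- simulate_panel(regular_sim_config(30, p = 20, k = 2), seed = 29)
  sf <- stem_fit(ds$panel, 2, lambda = 0,
                 config = stem_config(n_iters = 24, m = 8, s_chain_len = 80),
                 seed = 30)
  corrs <- vapply(9:24, function(l) {
    cross_correlation_matrix(
      dynfa:::trans_to_theta(sf$trace$par[l, ], 2))[1, 2]
  }, numeric(1))
  first <- mean(corrs[1:8]); second <- mean(corrs[9:16])
  expect_lt(abs(first - second), 0.25)
})
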