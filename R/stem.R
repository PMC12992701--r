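# Stochastic EM for the MOGP hyperparameters.
#
# The marginal likelihood of the observed panel integrates over all latent
# variables and is intractable, so hyperparameters (Theta, C) are estimated
# by stochastic EM: the S-step runs the Gibbs sampler at the current
# estimates and takes ONE random post-burn-in draw of the augmented factor
# scores; the M-step maximizes the roughness-penalized augmented-grid MVN
# log-likelihood of that draw by quasi-Newton (L-BFGS-B). The iterates form
# a homogeneous Markov chain whose trailing average is the estimator.
#
# M-step parameterization (unconstrained, per factor): beta0, beta1 in R and
# log B0, log B1, with stationary-variance shares
#   (w_xi, w_eta, w_nugget) = (beta0^2, beta1^2, 1) / (1 + beta0^2 + beta1^2),
# and amplitudes v0 = sign(beta0) sqrt(w_xi sqrt(B0/pi)),
# v1 = sqrt(w_eta sqrt(B1/pi)), nugget_a = w_nugget. Every factor's
# stationary variance is therefore exactly 1 by construction (the
# identifiability constraint), and sign(beta0) carries the sign of the
# shared-process amplitude so negative cross-correlations are reachable.
# Constant means c_a have a closed-form GLS profile solution and are profiled
# out inside the objective.

#' Stochastic EM configuration
#'
#' @param n_iters Number of StEM iterations (default 200).
#' @param m Trailing window: the final estimate averages the last \code{m}
#'   iterates in the transformed parameter space (default 50).
#' @param s_chain_len Gibbs iterations per S-step (default 500).
#' @param s_burn_frac S-step burn-in fraction (default 0.2); the single
#'   score draw is taken uniformly from the post-burn-in iterations.
#' @param optim_control Control list passed to \code{\link[stats]{optim}}
#'   (L-BFGS-B) in the M-step.
#' @return Object of class \code{"stem_config"}.
#' @export
stem_config <- function(n_iters = 200L, m = 50L, s_chain_len = 500L,
                        s_burn_frac = 0.2,
                        optim_control = list(maxit = 100L)) {
  stopifnot(n_iters >= 1, m >= 1, m <= n_iters, s_chain_len >= 1,
            s_burn_frac >= 0, s_burn_frac < 1)
  structure(list(n_iters = as.integer(n_iters), m = as.integer(m),
                 s_chain_len = as.integer(s_chain_len),
                 s_burn_frac = s_burn_frac, optim_control = optim_control),
            class = "stem_config")
}

# ---- transformed parameterization ------------------------------------------

# pack a unit-variance theta into the transformed kernel parameters
# (beta0, beta1, logB0, logB1) per factor, concatenated
theta_to_trans <- function(theta) {
  unlist(lapply(seq_len(theta$k), function(a) {
    kr <- theta$kernels[[a]]
    w0 <- kr$v0^2 * sqrt(pi / kr$B0)
    w1 <- kr$v1^2 * sqrt(pi / kr$B1)
    wn <- max(theta$nugget[a], 1e-10)
    tot <- w0 + w1 + wn
    c(sign(kr$v0 + (kr$v0 == 0)) * sqrt(w0 / wn),
      sqrt(w1 / wn), log(kr$B0), log(kr$B1))
  }))
}

# inverse: transformed kernel parameters (+ means) -> unit-variance theta
trans_to_theta <- function(par, k, means = rep(0, k)) {
  kernels <- vector("list", k)
  nug <- numeric(k)
  for (a in seq_len(k)) {
    b0 <- par[(a - 1L) * 4L + 1L]; b1 <- par[(a - 1L) * 4L + 2L]
    B0 <- exp(par[(a - 1L) * 4L + 3L]); B1 <- exp(par[(a - 1L) * 4L + 4L])
    denom <- 1 + b0^2 + b1^2
    w0 <- b0^2 / denom; w1 <- b1^2 / denom
    nug[a] <- 1 / denom
    kernels[[a]] <- factor_kernel(
      v0 = sign(b0 + (b0 == 0)) * sqrt(w0 * sqrt(B0 / pi)),
      v1 = sqrt(w1 * sqrt(B1 / pi)),
      B0 = B0, B1 = B1)
  }
  mogp_hyperparams(kernels, nugget = nug, means = means)
}

sum_decay <- function(theta) {
  sum(vapply(theta$kernels, function(kr) kr$B0 + kr$B1, numeric(1)))
}

# scale-aware neutral start: correlation halves at a quarter of the time span,
# equal variance shares, zero means
init_theta <- function(grid, k) {
  span <- max(diff(range(grid)), 1)
  B <- 4 * log(2) / (span / 4)^2
  trans_to_theta(rep(c(1, 1, log(B), log(B)), k), k)
}

# ---- penalized objective ----------------------------------------------------

#' Roughness-penalized augmented-grid score log-likelihood
#'
#' The M-step objective: the sum over subjects of the MVN log-density of the
#' augmented factor-score vector vec(Y_i_aug^T) on the common grid, with mean
#' c_a per factor and covariance built from \code{theta}, minus
#' \code{lambda} times the sum of all kernel decay parameters
#' (B_a0 + B_a1). The covariance is built and factorized once (common grid).
#'
#' @param y_aug n x (k q) matrix of factor-major stacked score draws, one row
#'   per subject.
#' @param theta A \code{\link{mogp_hyperparams}} (its \code{means} are the
#'   c_a).
#' @param grid Common time grid (length q).
#' @param lambda Roughness penalty, >= 0.
#' @return Scalar penalized log-likelihood.
#' @export
penalized_score_loglik <- function(y_aug, theta, grid, lambda = 0) {
  stopifnot(inherits(theta, "mogp_hyperparams"), lambda >= 0)
  q <- length(grid); k <- theta$k
  if (ncol(y_aug) != k * q) stop("y_aug has wrong width", call. = FALSE)
  S <- build_cov(theta, grid)
  ch <- chol_jitter(S, "M-step score covariance")
  cm <- rep(theta$means, each = q)
  ctr <- t(y_aug) - cm
  z <- backsolve(ch, ctr, transpose = TRUE)
  n <- nrow(y_aug)
  ll <- -0.5 * n * (k * q) * log(2 * pi) - n * sum(log(diag(ch))) -
    0.5 * sum(z^2)
  ll - lambda * sum_decay(theta)
}

# internal M-step objective with c profiled out; returns NEGATIVE penalized
# log-likelihood (for minimization). Precomputes the centered scatter once.
make_mstep_objective <- function(y_aug, grid, lambda, k) {
  q <- length(grid); n <- nrow(y_aug)
  wbar <- colMeans(y_aug)
  ctr <- t(y_aug) - wbar
  S0 <- tcrossprod(ctr)                     # sum_i (w_i - wbar)(w_i - wbar)'
  D <- kronecker(diag(1, k), rep(1, q))     # kq x k mean design
  const <- 0.5 * n * (k * q) * log(2 * pi)
  list(
    neg_obj = function(par) {
      val <- tryCatch({
        theta <- trans_to_theta(par, k)
        S <- build_cov(theta, grid)
        ch <- chol_jitter(S, "M-step score covariance")
        Sinv <- chol2inv(ch)
        chat <- solve(crossprod(D, Sinv %*% D), crossprod(D, Sinv %*% wbar))
        r <- wbar - drop(D %*% chat)
        quad <- sum(Sinv * S0) + n * drop(crossprod(r, Sinv %*% r))
        -( -const - n * sum(log(diag(ch))) - 0.5 * quad -
             lambda * sum_decay(theta) )
      }, error = function(e) NA_real_)
      if (!is.finite(val)) 1e10 else val
    },
    chat = function(par) {
      theta <- trans_to_theta(par, k)
      S <- build_cov(theta, grid)
      Sinv <- chol2inv(chol_jitter(S, "M-step score covariance"))
      drop(solve(crossprod(D, Sinv %*% D), crossprod(D, Sinv %*% wbar)))
    }
  )
}

#' M-step: maximize the penalized score log-likelihood
#'
#' Quasi-Newton (L-BFGS-B) maximization of
#' \code{\link{penalized_score_loglik}} in the transformed unit-variance
#' parameterization, with the constant means c_a profiled out in closed form
#' (GLS). Never returns a point worse than the initial one: if the optimizer
#' fails or degrades the objective, the initial parameters are returned with
#' \code{improved = FALSE}.
#'
#' @param y_aug n x (k q) matrix of augmented score draws.
#' @param grid Common time grid.
#' @param lambda Roughness penalty.
#' @param theta_init Starting \code{\link{mogp_hyperparams}} (normalized to
#'   unit variance internally).
#' @param control \code{\link[stats]{optim}} control list.
#' @return List: \code{theta} (unit-variance, with profiled means),
#'   \code{par} (transformed kernel parameters), \code{objective} (penalized
#'   log-likelihood at the returned point), \code{improved}.
#' @export
m_step <- function(y_aug, grid, lambda, theta_init,
                   control = list(maxit = 100L)) {
  k <- theta_init$k
  theta_init <- normalize_unit_variance(theta_init)$theta
  par0 <- theta_to_trans(theta_init)
  objf <- make_mstep_objective(y_aug, grid, lambda, k)
  lower <- rep(c(-Inf, -Inf, -6, -6), k)
  upper <- rep(c(Inf, Inf, 10, 10), k)
  par0 <- pmin(pmax(par0, lower), upper)
  f0 <- objf$neg_obj(par0)
  fit <- tryCatch(
    stats::optim(par0, objf$neg_obj, method = "L-BFGS-B",
                 lower = lower, upper = upper, control = control),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value > f0) {
    par <- par0; val <- f0; improved <- FALSE
    if (is.null(fit)) warning("M-step optimizer failed; keeping previous estimate",
                              call. = FALSE)
  } else {
    par <- fit$par; val <- fit$value; improved <- fit$value < f0
  }
  # canonical sign: the objective is invariant in the sign of the
  # factor-specific share parameter, so fix it positive (keeps trailing
  # averages of the trace meaningful)
  par[seq(2, by = 4, length.out = k)] <- abs(par[seq(2, by = 4, length.out = k)])
  chat <- objf$chat(par)
  list(theta = trans_to_theta(par, k, means = chat), par = par,
       objective = -val, improved = improved)
}

# ---- StEM driver ------------------------------------------------------------

#' Fit MOGP hyperparameters by stochastic EM
#'
#' Alternates the S-step (a Gibbs chain of \code{s_chain_len} iterations at
#' the current hyperparameter estimates, from which one post-burn-in draw of
#' the augmented factor scores is taken uniformly at random) with the M-step
#' (\code{\link{m_step}}). The Gibbs state is carried across iterations. The
#' final estimate is the component-wise average of the last \code{m} iterates
#' in the transformed parameter space.
#'
#' @param panel A \code{\link{dfa_panel}}.
#' @param k Number of latent factors.
#' @param lambda Roughness penalty, >= 0.
#' @param config A \code{\link{stem_config}}.
#' @param priors A \code{\link{dfa_priors}}.
#' @param seed Integer seed (fixed seed gives an identical trace).
#' @param theta_init Optional starting hyperparameters; default is a
#'   scale-aware neutral start (correlation halving at a quarter of the time
#'   span, equal variance shares, zero means).
#' @return Object of class \code{"stem_fit"}: final \code{theta}
#'   (unit-variance \code{\link{mogp_hyperparams}}), the estimated
#'   cross-correlation matrix \code{corr}, the per-iteration \code{trace}
#'   (transformed kernel parameters, means, penalized objective,
#'   M-step improvement flags), \code{lambda}, and the final Gibbs state.
#' @export
stem_fit <- function(panel, k, lambda = 0, config = stem_config(),
                     priors = default_priors(panel), seed = 1L,
                     theta_init = NULL) {
  stopifnot(inherits(panel, "dfa_panel"), k >= 1,
            inherits(config, "stem_config"))
  set.seed(as.integer(seed))
  if (is.null(theta_init)) {
    # neutral kernel start, then one M-step on the initial factor scores:
    # starting the score prior at the correlation/smoothness the initial
    # state itself implies avoids an early prior-state conflict that can
    # push the sampler into the dense-loadings representation
    theta <- init_theta(panel$grid, k)
    state <- init_state(panel, priors, k, theta)
    ms0 <- m_step(state$Y, panel$grid, lambda, theta,
                  control = config$optim_control)
    theta <- ms0$theta
  } else {
    theta <- normalize_unit_variance(theta_init)$theta
    state <- init_state(panel, priors, k, theta)
  }
  n_par <- 4L * k
  trace_par <- matrix(NA_real_, config$n_iters, n_par)
  trace_c <- matrix(NA_real_, config$n_iters, k)
  trace_obj <- numeric(config$n_iters)
  improved <- logical(config$n_iters)
  burn <- floor(config$s_chain_len * config$s_burn_frac)
  for (l in seq_len(config$n_iters)) {
    draw_at <- if (burn + 1L >= config$s_chain_len) config$s_chain_len else
      sample(seq.int(burn + 1L, config$s_chain_len), 1L)
    res <- gibbs_engine(panel, theta, priors, state, config$s_chain_len,
                        keep = draw_at, collect = "y")
    state <- res$state
    y_draw <- matrix(res$draws$Y[, , 1L], panel$n, k * panel$q)
    ms <- m_step(y_draw, panel$grid, lambda, theta,
                 control = config$optim_control)
    theta <- ms$theta
    trace_par[l, ] <- ms$par
    trace_c[l, ] <- theta$means
    trace_obj[l] <- ms$objective
    improved[l] <- ms$improved
  }
  est <- estimate_from_trace(list(par = trace_par, means = trace_c, k = k),
                             config$m)
  structure(list(theta = est, corr = cross_correlation_matrix(est),
                 trace = list(par = trace_par, means = trace_c,
                              objective = trace_obj, improved = improved,
                              k = k),
                 lambda = lambda, config = config, priors = priors,
                 final_state = state, seed = seed),
            class = "stem_fit")
}

#' Trailing-average estimate from a StEM trace
#'
#' Averages the last \code{m} iterates in the transformed parameter space
#' (share parameters and log decay rates for the kernels, raw values for the
#' constant means) and back-transforms to a unit-variance hyperparameter set.
#'
#' @param trace A trace as stored in a \code{\link{stem_fit}} object (list
#'   with matrices \code{par}, \code{means}, and \code{k}), or a
#'   \code{stem_fit} itself.
#' @param m Number of trailing iterations to average.
#' @return A \code{\link{mogp_hyperparams}}.
#' @export
estimate_from_trace <- function(trace, m) {
  if (inherits(trace, "stem_fit")) trace <- trace$trace
  n <- nrow(trace$par)
  if (m > n) stop("'m' exceeds the trace length", call. = FALSE)
  rows <- seq.int(n - m + 1L, n)
  par <- colMeans(trace$par[rows, , drop = FALSE])
  cs <- colMeans(trace$means[rows, , drop = FALSE])
  trans_to_theta(par, trace$k, means = cs)
}

#' @export
print.stem_fit <- function(x, ...) {
  cat("Stochastic EM fit:", x$trace$k, "factors, lambda =", x$lambda,
      ",", nrow(x$trace$par), "iterations\n")
  cat("estimated cross-correlations:\n")
  print(round(x$corr, 3))
  invisible(x)
}
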