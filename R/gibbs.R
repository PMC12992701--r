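# Block Gibbs sampler for all unknowns except the MOGP hyperparameters.
#
# One systematic scan updates, in fixed order:
#   1. subject-biomarker means M and the variances sigma_g^2, phi_g^2,
#   2. the loadings machinery (Z, A jointly per (g, a) with A marginalized
#      out of the inclusion draw; then pi_a and rho_a^2),
#   3. each subject's augmented factor scores in two stages: the scores at
#      the subject's observed times from their MVN full conditional, then the
#      scores at the remaining grid times from the MOGP conditional.
# All conditionals follow from conjugacy; they are locked to brute-force
# oracles (numerical integration / joint-Gaussian conditioning) in the tests.
# Subjects sharing a visit pattern share all pattern-level matrix factors, so
# updates vectorize across subjects.

#' Gibbs sampler run-length configuration
#'
#' @param n_iter Total iterations per chain.
#' @param burn_frac Fraction of iterations discarded as burn-in (default 0.2).
#' @param thin Keep every \code{thin}-th post-burn-in draw.
#' @param n_chains Number of independent chains.
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @return Object of class \code{"gibbs_config"}.
#' @export
gibbs_config <- function(n_iter = 2000L, burn_frac = 0.2, thin = 1L,
                         n_chains = 1L, seed = 1L) {
  stopifnot(n_iter >= 1, burn_frac >= 0, burn_frac < 1, thin >= 1, n_chains >= 1)
  if (n_iter * (1 - burn_frac) < 1) stop("no iterations after burn-in", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_frac = burn_frac,
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "gibbs_config")
}

rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# ---- conditional updates ----------------------------------------------------

# M, sigma^2, phi^2 full conditionals (conjugate Normal / Inverse-Gamma)
update_means_and_noise <- function(state, panel, priors) {
  n <- panel$n; p <- panel$p
  k <- ncol(state$A)
  L <- loadings_of(state)
  Yo <- observed_scores(state, panel, k)
  r0 <- panel$X - Yo %*% t(L)                       # x - L y, visit-major
  Sr <- rowsum(r0, panel$row_subject, reorder = TRUE)
  if (nrow(Sr) < n) {                                # subjects with no visits
    full <- matrix(0, n, p)
    full[as.integer(rownames(Sr)), ] <- Sr
    Sr <- full
  }
  prec <- outer(panel$q_i, 1 / state$phi2) +
    matrix(1 / state$sigma2, n, p, byrow = TRUE)
  pmean <- (matrix(priors$mu_g / state$sigma2, n, p, byrow = TRUE) +
              Sr %*% diag(1 / state$phi2, p)) / prec
  state$M <- pmean + matrix(stats::rnorm(n * p), n, p) / sqrt(prec)

  dev <- sweep(state$M, 2, priors$mu_g)
  state$sigma2 <- rinvgamma(p, priors$c2 + n / 2,
                            priors$d2 + 0.5 * colSums(dev^2))
  R <- r0 - state$M[panel$row_subject, , drop = FALSE]
  state$phi2 <- rinvgamma(p, priors$c3 + nrow(panel$X) / 2,
                          priors$d3 + 0.5 * colSums(R^2))
  state
}

# collapsed (Z, A) update per factor column, then pi and rho^2
update_loadings <- function(state, panel, priors) {
  p <- panel$p; k <- ncol(state$A)
  L <- loadings_of(state)
  Yo <- observed_scores(state, panel, k)
  R <- panel$X - state$M[panel$row_subject, , drop = FALSE] - Yo %*% t(L)
  for (a in seq_len(k)) {
    ya <- Yo[, a]
    Ea <- R + outer(ya, L[, a])                     # residual with factor a out
    syy <- sum(ya^2)
    sye <- drop(crossprod(Ea, ya))
    pvar <- 1 / (1 / state$rho2[a] + syy / state$phi2)
    pmn <- (sye / state$phi2) * pvar
    # Bayes factor for Z_ga = 1 with A_ga integrated out (log space)
    log_bf <- 0.5 * log(pvar / state$rho2[a]) + 0.5 * pmn^2 / pvar
    pz <- stats::plogis(log(state$pi[a]) - log1p(-state$pi[a]) + log_bf)
    z <- stats::rbinom(p, 1L, pz)
    anew <- stats::rnorm(p)
    state$A[, a] <- ifelse(z == 1L, pmn + anew * sqrt(pvar),
                           anew * sqrt(state$rho2[a]))
    state$Z[, a] <- z
    L[, a] <- state$A[, a] * z
    R <- Ea - outer(ya, L[, a])
  }
  nz <- colSums(state$Z)
  state$pi <- stats::rbeta(k, priors$c0 + nz, priors$d0 + p - nz)
  state$rho2 <- rinvgamma(k, priors$c1 + p / 2,
                          priors$d1 + 0.5 * colSums(state$A^2))
  state
}

# pattern-level factors shared by all subjects with the same visit set
make_factor_cache <- function(panel, theta) {
  q <- panel$q; k <- theta$k
  S <- build_cov(theta, panel$grid)
  cm <- rep(theta$means, each = q)
  pat_key <- apply(panel$V, 1, function(v) paste(which(v), collapse = ","))
  groups <- split(seq_len(panel$n), pat_key)
  cache <- lapply(groups, function(subj) {
    pos <- which(panel$V[subj[1], ])
    obs <- as.vector(outer(pos, (seq_len(k) - 1L) * q, "+"))
    add <- setdiff(seq_len(k * q), obs)
    rows <- unlist(lapply(subj, function(i) which(panel$row_subject == i)))
    out <- list(subjects = subj, pos = pos, obs = obs, add = add,
                rows = rows, cm_obs = cm[obs], cm_add = cm[add])
    if (length(obs)) {
      Soo <- S[obs, obs, drop = FALSE]
      out$chol_oo <- chol_jitter(Soo, "observed-time prior covariance")
      out$inv_oo <- chol2inv(out$chol_oo)
      if (length(add)) {
        K <- S[add, obs, drop = FALSE] %*% out$inv_oo
        Sc <- S[add, add, drop = FALSE] - K %*% t(S[add, obs, drop = FALSE])
        out$K <- K
        out$chol_cond <- chol_jitter((Sc + t(Sc)) / 2, "conditional score covariance")
      }
    } else {
      out$chol_full <- chol_jitter(S, "prior covariance")
    }
    out
  })
  list(S = S, chol_S = chol_jitter(S, "prior covariance"), cm = cm,
       groups = cache, k = k, q = q)
}

# two-stage block update of every subject's augmented scores
update_factors <- function(state, panel, theta, cache) {
  k <- cache$k; q <- cache$q
  L <- loadings_of(state)
  W <- L / state$phi2                              # p x k, columns l_.a / phi^2
  G <- crossprod(L, W)                             # k x k likelihood precision
  E <- (panel$X - state$M[panel$row_subject, , drop = FALSE]) %*% W  # m x k
  for (grp in cache$groups) {
    qo <- length(grp$pos); ns <- length(grp$subjects)
    if (qo == 0L) {                                # no data: prior draw
      z <- matrix(stats::rnorm(k * q * ns), k * q, ns)
      draws <- cache$cm + t(cache$chol_S) %*% z
      state$Y[grp$subjects, ] <- t(draws)
      next
    }
    d <- k * qo
    P <- grp$inv_oo + kronecker(G, diag(1, qo))
    cholP <- chol_jitter((P + t(P)) / 2, "score posterior precision")
    # likelihood linear term per subject: vec over (time, factor) of D_i W,
    # assembled for the whole group by an array reshape (rows are contiguous
    # and time-ordered per subject)
    B <- matrix(aperm(array(E[grp$rows, , drop = FALSE], c(qo, ns, k)),
                      c(1L, 3L, 2L)), d, ns)
    rhs <- B + drop(grp$inv_oo %*% grp$cm_obs)
    mean_obs <- backsolve(cholP, backsolve(cholP, rhs, transpose = TRUE))
    y_obs <- mean_obs + backsolve(cholP, matrix(stats::rnorm(d * ns), d, ns))
    Ynew <- matrix(0, k * q, ns)
    Ynew[grp$obs, ] <- y_obs
    if (length(grp$add)) {
      cmean <- grp$cm_add + grp$K %*% (y_obs - grp$cm_obs)
      y_add <- cmean + t(grp$chol_cond) %*%
        matrix(stats::rnorm(length(grp$add) * ns), length(grp$add), ns)
      Ynew[grp$add, ] <- y_add
    }
    state$Y[grp$subjects, ] <- t(Ynew)
  }
  state
}

# exact conditional of one subject's observed-time scores given the rest:
# returns mean vector and covariance (used by oracles and tests)
factor_block_conditional <- function(state, panel, theta, i, cache = NULL) {
  if (is.null(cache)) cache <- make_factor_cache(panel, theta)
  grp <- NULL
  for (g in cache$groups) if (i %in% g$subjects) { grp <- g; break }
  L <- loadings_of(state)
  W <- L / state$phi2
  G <- crossprod(L, W)
  qo <- length(grp$pos)
  if (qo == 0L) {
    return(list(mean = cache$cm, cov = cache$S))
  }
  P <- grp$inv_oo + kronecker(G, diag(1, qo))
  rows <- which(panel$row_subject == i)
  D <- panel$X[rows, , drop = FALSE] - matrix(state$M[i, ], qo, panel$p, byrow = TRUE)
  rhs <- as.vector(D %*% W) + drop(grp$inv_oo %*% grp$cm_obs)
  V <- chol2inv(chol_jitter((P + t(P)) / 2, "score posterior precision"))
  list(mean = drop(V %*% rhs), cov = V, obs_idx = grp$obs)
}

# ---- chain driver -----------------------------------------------------------

# one systematic scan
gibbs_scan <- function(state, panel, theta, priors, cache) {
  state <- update_means_and_noise(state, panel, priors)
  state <- update_loadings(state, panel, priors)
  update_factors(state, panel, theta, cache)
}

# run n_iter scans from `state`; retain draws at iterations in `keep`
gibbs_engine <- function(panel, theta, priors, state, n_iter, keep = integer(),
                         collect = c("all", "y"), cache = NULL) {
  collect <- match.arg(collect)
  if (is.null(cache)) cache <- make_factor_cache(panel, theta)
  nk <- length(keep)
  draws <- NULL
  if (nk) {
    k <- cache$k
    draws <- list(Y = array(NA_real_, c(panel$n, k * cache$q, nk)))
    if (collect == "all") {
      draws$A <- array(NA_real_, c(panel$p, k, nk))
      draws$Z <- array(NA_real_, c(panel$p, k, nk))
      draws$M <- array(NA_real_, c(panel$n, panel$p, nk))
      draws$pi <- matrix(NA_real_, k, nk)
      draws$rho2 <- matrix(NA_real_, k, nk)
      draws$sigma2 <- matrix(NA_real_, panel$p, nk)
      draws$phi2 <- matrix(NA_real_, panel$p, nk)
      draws$loglik <- numeric(nk)
    }
  }
  slot <- 1L
  for (it in seq_len(n_iter)) {
    state <- gibbs_scan(state, panel, theta, priors, cache)
    if (nk && slot <= nk && it == keep[slot]) {
      draws$Y[, , slot] <- state$Y
      if (collect == "all") {
        draws$A[, , slot] <- state$A
        draws$Z[, , slot] <- state$Z
        draws$M[, , slot] <- state$M
        draws$pi[, slot] <- state$pi
        draws$rho2[, slot] <- state$rho2
        draws$sigma2[, slot] <- state$sigma2
        draws$phi2[, slot] <- state$phi2
        draws$loglik[slot] <- complete_data_loglik(panel, state, theta, priors)
      }
      slot <- slot + 1L
    }
  }
  list(state = state, draws = draws, cache = cache)
}

#' Run the block Gibbs sampler
#'
#' Samples the latent state (means, noise variances, sparse loadings, factor
#' scores on the full time grid) conditional on fixed MOGP hyperparameters.
#' The hyperparameters are normalized to unit stationary factor variance on
#' entry (the model's identifiability constraint).
#'
#' @param panel A \code{\link{dfa_panel}}.
#' @param theta A \code{\link{mogp_hyperparams}}.
#' @param config A \code{\link{gibbs_config}}.
#' @param priors A \code{\link{dfa_priors}}; defaults to
#'   \code{\link{dfa_priors}(p)} with \code{mu_g} fixed to empirical
#'   biomarker means.
#' @return Object of class \code{"dfa_samples"}: per-chain retained draws of
#'   all latent quantities (burn-in removed, thinned), the complete-data log
#'   density of each retained draw, and metadata. Draws are unaligned; see
#'   \code{\link{align_draws}}.
#' @export
run_gibbs <- function(panel, theta, config = gibbs_config(),
                      priors = default_priors(panel)) {
  stopifnot(inherits(panel, "dfa_panel"), inherits(theta, "mogp_hyperparams"),
            inherits(config, "gibbs_config"))
  theta <- normalize_unit_variance(theta)$theta
  burn <- floor(config$n_iter * config$burn_frac)
  keep <- seq.int(burn + 1L, config$n_iter, by = config$thin)
  chains <- vector("list", config$n_chains)
  cache <- NULL
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    state <- init_state(panel, priors, theta$k, theta)
    res <- gibbs_engine(panel, theta, priors, state, config$n_iter,
                        keep = keep, collect = "all", cache = cache)
    cache <- res$cache
    chains[[ch]] <- res$draws
  }
  structure(list(chains = chains, theta = theta, priors = priors,
                 config = config, grid = panel$grid, n = panel$n,
                 p = panel$p, k = theta$k, kept = keep,
                 subjects = panel$subjects, biomarkers = panel$biomarkers,
                 alignment = NULL),
            class = "dfa_samples")
}

#' @export
print.dfa_samples <- function(x, ...) {
  cat("Posterior samples:", length(x$chains), "chain(s) x",
      dim(x$chains[[1]]$Y)[3], "retained draws;",
      x$k, "factors,", x$p, "biomarkers,", x$n, "subjects\n")
  if (!is.null(x$alignment)) cat("(signed-permutation aligned)\n")
  invisible(x)
}

# total retained draws across chains
n_draws <- function(samples) {
  sum(vapply(samples$chains, function(ch) dim(ch$Y)[3], integer(1)))
}

# flatten chain/draw indexing: returns list(chain, slot) for draw j
draw_index <- function(samples, j) {
  sizes <- vapply(samples$chains, function(ch) dim(ch$Y)[3], integer(1))
  ch <- findInterval(j - 1L, cumsum(c(0L, sizes)), rightmost.closed = TRUE)
  list(chain = ch, slot = j - c(0L, cumsum(sizes))[ch])
}

# ---- posterior predictive ---------------------------------------------------

#' Posterior predictive biomarker trajectory
#'
#' Reconstructs the trajectory of one biomarker for one subject over an
#' arbitrary time grid: for each retained draw, scores at grid times are read
#' from the draw directly (times on the fitted grid) or drawn from the MOGP
#' conditional given the draw's full-grid scores (novel times), and the curve
#' mu_ig + sum_a l_ga y_ia(t) is evaluated. Pointwise median and 2.5/97.5
#' percentiles are returned.
#'
#' @param samples A \code{\link{run_gibbs}} result (align first for
#'   multi-chain summaries).
#' @param subject Subject identifier (as in the fitted panel) or index.
#' @param biomarker Biomarker identifier or index.
#' @param times Numeric vector of prediction times (default: fitted grid).
#' @param include_noise Add observation noise phi_g^2 to each draw's curve.
#' @return Data frame with columns \code{time}, \code{median}, \code{lower},
#'   \code{upper}.
#' @export
posterior_predictive <- function(samples, subject, biomarker,
                                 times = samples$grid, include_noise = FALSE) {
  stopifnot(inherits(samples, "dfa_samples"))
  i <- if (is.numeric(subject)) as.integer(subject) else match(subject, samples$subjects)
  g <- if (is.numeric(biomarker)) as.integer(biomarker) else match(biomarker, samples$biomarkers)
  if (is.na(i) || i < 1 || i > samples$n) stop("unknown subject", call. = FALSE)
  if (is.na(g) || g < 1 || g > samples$p) stop("unknown biomarker", call. = FALSE)
  k <- samples$k; q <- length(samples$grid)
  on_grid <- match(times, samples$grid)
  novel <- which(is.na(on_grid))
  if (length(novel)) {
    # MOGP conditional of scores at novel times given full-grid scores
    S_full <- build_cov(samples$theta, samples$grid)
    tn <- times[novel]
    # cross-covariance between novel-time and grid scores (factor-major)
    cross <- matrix(0, k * length(novel), k * q)
    for (a in seq_len(k)) for (b in seq_len(k)) {
      lagm <- outer(tn, samples$grid, "-")
      blk <- if (a == b) {
        cp_auto_cov(samples$theta$kernels[[a]], 0, lagm)
      } else {
        cp_cross_cov(samples$theta$kernels[[a]], samples$theta$kernels[[b]], lagm)
      }
      cross[(a - 1L) * length(novel) + seq_along(novel),
            (b - 1L) * q + seq_len(q)] <- blk
    }
    Snn <- matrix(0, k * length(novel), k * length(novel))
    for (a in seq_len(k)) for (b in seq_len(k)) {
      lagm <- outer(tn, tn, "-")
      blk <- if (a == b) {
        cp_auto_cov(samples$theta$kernels[[a]], samples$theta$nugget[a], lagm)
      } else {
        cp_cross_cov(samples$theta$kernels[[a]], samples$theta$kernels[[b]], lagm)
      }
      Snn[(a - 1L) * length(novel) + seq_along(novel),
          (b - 1L) * length(novel) + seq_along(novel)] <- blk
    }
    ch_full <- chol_jitter(S_full, "prior covariance")
    inv_full <- chol2inv(ch_full)
    Kn <- cross %*% inv_full
    Sc <- Snn - Kn %*% t(cross)
    chol_c <- chol_jitter((Sc + t(Sc)) / 2, "predictive conditional covariance")
    cm_full <- rep(samples$theta$means, each = q)
    cm_nov <- rep(samples$theta$means, each = length(novel))
  }
  nd <- n_draws(samples)
  curves <- matrix(NA_real_, nd, length(times))
  j <- 0L
  for (ch in seq_along(samples$chains)) {
    dr <- samples$chains[[ch]]
    for (s in seq_len(dim(dr$Y)[3])) {
      j <- j + 1L
      Lrow <- dr$A[g, , s] * dr$Z[g, , s]
      yi <- dr$Y[i, , s]
      sc <- matrix(NA_real_, k, length(times))
      ok <- !is.na(on_grid)
      if (any(ok)) {
        sc[, ok] <- t(matrix(yi, q, k))[, on_grid[ok], drop = FALSE]
      }
      if (length(novel)) {
        cmean <- cm_nov + drop(Kn %*% (yi - cm_full))
        ydraw <- cmean + drop(t(chol_c) %*% stats::rnorm(length(cmean)))
        sc[, novel] <- t(matrix(ydraw, length(novel), k))
      }
      cv <- dr$M[i, g, s] + drop(Lrow %*% sc)
      if (include_noise) cv <- cv + stats::rnorm(length(cv), 0, sqrt(dr$phi2[g, s]))
      curves[j, ] <- cv
    }
  }
  data.frame(
    time = times,
    median = apply(curves, 2, stats::median),
    lower = apply(curves, 2, stats::quantile, probs = 0.025),
    upper = apply(curves, 2, stats::quantile, probs = 0.975)
  )
}

# simulate observations X given the current state (used by joint-distribution
# correctness checks): returns a visit-major matrix like panel$X
draw_observations_given_state <- function(panel, state) {
  k <- ncol(state$A)
  L <- loadings_of(state)
  Yo <- observed_scores(state, panel, k)
  mu <- state$M[panel$row_subject, , drop = FALSE] + Yo %*% t(L)
  mu + matrix(stats::rnorm(length(mu), 0,
                           rep(sqrt(state$phi2), each = nrow(mu))),
              nrow(mu), ncol(mu))
}
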