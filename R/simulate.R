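# Synthetic-data generation.
#
# Two study designs are shipped: a regular design (every subject observed at
# the same q = 8 equally spaced times; k = 4 factors regulating p = 100
# biomarkers, 10% sparsity, slab loadings ~ N(4, 1), sigma_g = phi_g = 0.5,
# grand means equally spaced in [4, 16]) and an irregular design emulating a
# sparse clinical study (n = 101 subjects, p = 35 biomarkers, 2-5 visits per
# subject on integer days 0..49, about half the subjects with only 2 visits).
# Factor scores can be drawn either iid over time from a k x k correlation
# matrix (matching the regular design's fixed-covariance description) or from
# a convolution-process MOGP for temporally smooth trajectories.

# default true cross-correlation matrix: preserves non-zero cross-correlations
# between all factor pairs while remaining positive definite
default_truth_corr <- function(k) {
  vals <- c(0.6, 0.3, 0.1, 0.3, 0.1, 0.1)
  R <- diag(1, k)
  if (k > 1) {
    ut <- which(upper.tri(R))
    R[ut] <- rep_len(vals, length(ut))
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
  }
  R
}

#' Simulation design configuration
#'
#' @param n Number of subjects.
#' @param p Number of biomarkers.
#' @param k Number of latent factors.
#' @param design \code{"regular"} (all subjects share \code{times}) or
#'   \code{"irregular"} (per-subject visit counts drawn from
#'   \code{visit_range} over integer days \code{0..(n_days-1)}).
#' @param times Common observation times for the regular design.
#' @param visit_range Inclusive range of per-subject visit counts
#'   (irregular design).
#' @param prop_two_visits Probability a subject gets the minimum visit count
#'   (irregular design); remaining counts uniform over the rest of the range.
#' @param n_days Number of unique integer days (irregular design).
#' @param score_mode \code{"iid"}: scores iid over time, MVN(0, \code{corr});
#'   \code{"mogp"}: scores drawn from the convolution-process prior
#'   \code{theta}.
#' @param corr True k x k factor cross-correlation matrix (unit diagonal,
#'   positive semi-definite) for \code{score_mode = "iid"}.
#' @param theta \code{\link{mogp_hyperparams}} for \code{score_mode = "mogp"}
#'   (normalized internally to unit stationary variance).
#' @param loading_mean,loading_sd Slab distribution of non-zero loadings.
#' @param reg_prob Expected proportion of biomarkers regulated per factor
#'   (Beta prior mean; c0 = reg_prob p, d0 = (1 - reg_prob) p).
#' @param mu_range Range of the equally spaced biomarker grand means.
#' @param sigma_g Subject-biomarker mean standard deviation.
#' @param phi_g Observation noise standard deviation.
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(n, p = 100, k = 4, design = c("regular", "irregular"),
                       times = 0:7, visit_range = c(2L, 5L),
                       prop_two_visits = 0.5, n_days = 50L,
                       score_mode = c("iid", "mogp"),
                       corr = default_truth_corr(k), theta = NULL,
                       loading_mean = 4, loading_sd = 1, reg_prob = 0.1,
                       mu_range = c(4, 16), sigma_g = 0.5, phi_g = 0.5) {
  design <- match.arg(design)
  score_mode <- match.arg(score_mode)
  stopifnot(n >= 1, p >= 1, k >= 1, sigma_g >= 0, phi_g >= 0,
            reg_prob >= 0, reg_prob <= 1, loading_sd >= 0)
  if (score_mode == "iid") {
    if (!isTRUE(all.equal(diag(corr), rep(1, k))) ||
        !isTRUE(all.equal(corr, t(corr)))) {
      stop("'corr' must be symmetric with unit diagonal", call. = FALSE)
    }
    if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      stop("'corr' must be positive semi-definite", call. = FALSE)
    }
  } else if (is.null(theta)) {
    stop("score_mode = 'mogp' requires 'theta'", call. = FALSE)
  }
  structure(list(n = n, p = p, k = k, design = design, times = times,
                 visit_range = as.integer(visit_range),
                 prop_two_visits = prop_two_visits, n_days = as.integer(n_days),
                 score_mode = score_mode, corr = corr, theta = theta,
                 loading_mean = loading_mean, loading_sd = loading_sd,
                 reg_prob = reg_prob, mu_range = mu_range,
                 sigma_g = sigma_g, phi_g = phi_g),
            class = "sim_config")
}

#' Regular-design benchmark configuration
#'
#' The regular simulation design: k = 4 factors, p = 100 biomarkers, q_i = 8
#' common time points, each factor expected to regulate 10\% of biomarkers,
#' non-zero loadings ~ N(4, 1), grand means equally spaced in [4, 16],
#' sigma_g = phi_g = 0.5, and factor scores iid over time with correlated
#' factors (zero factor means).
#'
#' @param n Number of subjects.
#' @param ... Overrides passed to \code{\link{sim_config}}.
#' @return A \code{\link{sim_config}}.
#' @export
regular_sim_config <- function(n, ...) {
  args <- list(n = n, p = 100, k = 4, design = "regular", times = 0:7,
               score_mode = "iid", loading_mean = 4, loading_sd = 1,
               reg_prob = 0.1, mu_range = c(4, 16), sigma_g = 0.5, phi_g = 0.5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

#' Irregular sparse-sampling configuration
#'
#' Emulates a sparse clinical design: n = 101 subjects, p = 35 biomarkers,
#' per-subject visit counts between 2 and 5 (about half the subjects with
#' only 2 visits) drawn without replacement from the 50 integer days 0..49.
#'
#' @param ... Overrides passed to \code{\link{sim_config}}.
#' @return A \code{\link{sim_config}}.
#' @export
irregular_sim_config <- function(...) {
  args <- list(n = 101, p = 35, k = 2, design = "irregular",
               visit_range = c(2L, 5L), prop_two_visits = 0.5, n_days = 50L,
               score_mode = "iid", mu_range = c(4, 16),
               sigma_g = 0.5, phi_g = 0.5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

#' Generate a synthetic panel with ground truth
#'
#' Draws inclusion probabilities pi_a ~ Beta(reg_prob p, (1 - reg_prob) p),
#' indicators Z_ga ~ Bern(pi_a), slab loadings from N(loading_mean,
#' loading_sd^2) where included, factor scores per the configured mode,
#' subject-biomarker means mu_ig ~ N(mu_g, sigma_g^2) and assembles
#' x_ijg = mu_ig + sum_a l_ga y_ija + N(0, phi_g^2).
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed; the dataset is bit-reproducible given
#'   (config, seed).
#' @return List of class \code{"sim_dataset"} with elements \code{panel}
#'   (a \code{\link{dfa_panel}}), and \code{truth}: loadings \code{L},
#'   indicators \code{Z}, inclusion probabilities \code{pi}, scores \code{Y}
#'   (n x k x q array on the full grid), cross-correlation matrix \code{corr},
#'   means \code{mu_g}, \code{M}, and the config.
#' @export
simulate_panel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  n <- config$n; p <- config$p; k <- config$k

  # sampling design
  if (config$design == "regular") {
    grid <- sort(config$times)
    visit_pos <- rep(list(seq_along(grid)), n)
  } else {
    days <- seq.int(0L, config$n_days - 1L)
    lo <- config$visit_range[1]; hi <- config$visit_range[2]
    counts <- ifelse(stats::runif(n) < config$prop_two_visits, lo,
                     if (hi > lo) sample(seq.int(lo + 1L, hi), n, replace = TRUE) else lo)
    vis <- lapply(counts, function(m) sort(sample(days, m)))
    grid <- sort(unique(unlist(vis)))
    visit_pos <- lapply(vis, function(v) match(v, grid))
  }
  q <- length(grid)

  # sparsity + loadings
  c0 <- config$reg_prob * p; d0 <- (1 - config$reg_prob) * p
  pi_a <- stats::rbeta(k, c0, d0)
  Z <- matrix(stats::rbinom(p * k, 1L, rep(pi_a, each = p)), p, k)
  A <- matrix(stats::rnorm(p * k, config$loading_mean, config$loading_sd), p, k)
  L <- A * Z

  # factor scores on the full grid, per subject (k x q), plus truth correlation
  if (config$score_mode == "iid") {
    corr <- config$corr
    cc <- chol(corr + diag(1e-12, k))
    Y <- array(0, dim = c(n, k, q))
    for (i in seq_len(n)) {
      Y[i, , ] <- t(cc) %*% matrix(stats::rnorm(k * q), k, q)
    }
  } else {
    nt <- normalize_unit_variance(config$theta)$theta
    corr <- cross_correlation_matrix(nt)
    S <- build_cov(nt, grid)
    ch <- chol_jitter(S, "simulation score covariance")
    cm <- rep(nt$means, each = q)
    Y <- array(0, dim = c(n, k, q))
    for (i in seq_len(n)) {
      w <- cm + drop(t(ch) %*% stats::rnorm(k * q))
      Y[i, , ] <- t(matrix(w, q, k))
    }
  }

  # means and observations
  mu_g <- if (p == 1) mean(config$mu_range) else
    seq(config$mu_range[1], config$mu_range[2], length.out = p)
  M <- matrix(stats::rnorm(n * p, rep(mu_g, each = n), config$sigma_g), n, p)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- visit_pos[[i]]
    Yi <- matrix(Y[i, , pos], k, length(pos))
    Xi <- matrix(M[i, ], length(pos), p, byrow = TRUE) + t(L %*% Yi) +
      matrix(stats::rnorm(length(pos) * p, 0, config$phi_g), length(pos), p)
    rows[[i]] <- data.frame(
      subject = sprintf("s%03d", i),
      time = rep(grid[pos], times = p),
      biomarker = rep(sprintf("g%03d", seq_len(p)), each = length(pos)),
      value = as.vector(Xi)
    )
  }
  long <- do.call(rbind, rows)
  panel <- suppressWarnings(dfa_panel(long))

  truth <- list(L = L, Z = Z, A = A, pi = pi_a, Y = Y, corr = corr,
                mu_g = mu_g, M = M, grid = grid, config = config, seed = seed)
  structure(list(panel = panel, truth = truth), class = "sim_dataset")
}
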