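# Model state, priors and deterministic model equations.
#
# Observation model (long form): x_ijg = mu_ig + sum_a l_ga y_ija + e_ijg,
# e_ijg ~ N(0, phi_g^2), with loadings l_ga = Z_ga * A_ga under a point-mass
# mixture (spike-and-slab) prior and factor scores y_ia(t) under the
# convolution-process MOGP prior of kernel.R.

#' Longitudinal biomarker panel
#'
#' Validates and indexes a long-format panel of biomarker measurements with
#' subject-specific, possibly irregular observation times. Internally the
#' panel is stored visit-major: one row per observed (subject, time) visit
#' holding all p biomarker values, which is the layout the Gibbs sampler
#' vectorizes over.
#'
#' @param data Data frame with columns \code{subject}, \code{time},
#'   \code{biomarker}, \code{value} (extra columns ignored).
#' @return An object of class \code{"dfa_panel"}: a list with the observation
#'   matrix \code{X} (rows = visits, columns = biomarkers), visit metadata
#'   (\code{row_subject}, \code{row_pos}), the common time grid \code{grid}
#'   (union of all visit times), subject/biomarker identifiers, the visit
#'   indicator matrix \code{V} (n x q) and per-subject visit counts \code{q_i}.
#' @details Every visit must record all p biomarkers; duplicated
#'   (subject, time, biomarker) triples are an error. Subjects with a single
#'   visit are allowed with a warning (they contribute little to smoothness
#'   estimation).
#' @export
dfa_panel <- function(data) {
  need <- c("subject", "time", "biomarker", "value")
  if (!all(need %in% names(data))) {
    stop("panel data must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[need]
  data$time <- as.numeric(data$time)
  data$value <- as.numeric(data$value)
  if (any(!is.finite(data$time))) stop("non-numeric or non-finite times", call. = FALSE)
  if (any(!is.finite(data$value))) stop("non-numeric or non-finite values", call. = FALSE)
  key <- paste(data$subject, data$time, data$biomarker, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicated (subject, time, biomarker) triple: ",
         gsub("\r", ", ", d), call. = FALSE)
  }
  subjects <- sort(unique(data$subject))
  biomarkers <- sort(unique(data$biomarker))
  grid <- sort(unique(data$time))
  n <- length(subjects); p <- length(biomarkers); q <- length(grid)

  si <- match(data$subject, subjects)
  gi <- match(data$biomarker, biomarkers)
  ti <- match(data$time, grid)

  vkey <- paste(si, ti, sep = "\r")
  visits <- unique(data.frame(si = si, ti = ti))
  visits <- visits[order(visits$si, visits$ti), , drop = FALSE]
  m <- nrow(visits)
  X <- matrix(NA_real_, m, p, dimnames = list(NULL, biomarkers))
  vrow <- match(vkey, paste(visits$si, visits$ti, sep = "\r"))
  X[cbind(vrow, gi)] <- data$value
  if (anyNA(X)) {
    miss <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("incomplete visit: subject ", subjects[visits$si[miss[1]]],
         " at time ", grid[visits$ti[miss[2]]],
         " lacks some biomarkers; every visit must record all ", p,
         " biomarkers", call. = FALSE)
  }
  V <- matrix(FALSE, n, q)
  V[cbind(visits$si, visits$ti)] <- TRUE
  q_i <- tabulate(visits$si, nbins = n)
  if (any(q_i < 2)) {
    warning(sum(q_i < 2), " subject(s) have fewer than 2 visits", call. = FALSE)
  }
  structure(list(X = X, row_subject = visits$si, row_pos = visits$ti,
                 grid = grid, subjects = subjects, biomarkers = biomarkers,
                 V = V, q_i = q_i, n = n, p = p, q = q),
            class = "dfa_panel")
}

#' @export
print.dfa_panel <- function(x, ...) {
  cat("Longitudinal biomarker panel:", x$n, "subjects,", x$p, "biomarkers,",
      x$q, "unique times\n")
  cat("visits per subject:\n")
  print(table(x$q_i))
  invisible(x)
}

#' Convert a panel back to long format
#'
#' @param panel A \code{\link{dfa_panel}}.
#' @return Data frame with columns subject, time, biomarker, value.
#' @export
panel_to_long <- function(panel) {
  stopifnot(inherits(panel, "dfa_panel"))
  m <- nrow(panel$X); p <- panel$p
  data.frame(
    subject = rep(panel$subjects[panel$row_subject], times = p),
    time = rep(panel$grid[panel$row_pos], times = p),
    biomarker = rep(panel$biomarkers, each = m),
    value = as.vector(panel$X)
  )
}

#' Prior hyperparameter configuration
#'
#' Hyperparameters of the conjugate priors: Beta(c0, d0) for the inclusion
#' probabilities pi_a, Inverse-Gamma(c1, d1) for the slab variances rho_a^2,
#' Inverse-Gamma(c2, d2) for the subject-mean variances sigma_g^2,
#' Inverse-Gamma(c3, d3) for the noise variances phi_g^2, and the fixed
#' biomarker grand means mu_g.
#'
#' @param p Number of biomarkers.
#' @param c0,d0 Beta hyperparameters for pi_a; defaults 0.1 p and 0.9 p so
#'   that E(pi_a) = 0.1 (each factor expected to regulate 10\% of biomarkers).
#' @param c1,d1,c2,d2,c3,d3 Inverse-Gamma hyperparameters (weakly informative
#'   defaults of 1).
#' @param mu_g Fixed grand mean per biomarker (length p); when fitting, this
#'   is set to the empirical mean of each biomarker over all subject-times.
#' @return Object of class \code{"dfa_priors"}.
#' @export
dfa_priors <- function(p, c0 = 0.1 * p, d0 = 0.9 * p,
                       c1 = 1, d1 = 1, c2 = 1, d2 = 1, c3 = 1, d3 = 1,
                       mu_g = rep(0, p)) {
  vals <- c(c0 = c0, d0 = d0, c1 = c1, d1 = d1, c2 = c2, d2 = d2, c3 = c3, d3 = d3)
  if (any(vals <= 0) || any(!is.finite(vals))) {
    stop("all prior hyperparameters must be positive and finite", call. = FALSE)
  }
  if (length(mu_g) != p) stop("'mu_g' must have length p", call. = FALSE)
  structure(c(as.list(vals), list(mu_g = mu_g, p = p)), class = "dfa_priors")
}

# priors with mu_g fixed to empirical biomarker means, the default when fitting
default_priors <- function(panel, ...) {
  dfa_priors(panel$p, mu_g = colMeans(panel$X), ...)
}

#' Prior mean of the inclusion probability
#'
#' Mean of the Beta(c0, d0) prior on pi_a, the expected proportion of
#' biomarkers regulated by a factor.
#'
#' @param priors A \code{\link{dfa_priors}} object.
#' @return c0 / (c0 + d0).
#' @export
prior_inclusion_mean <- function(priors) {
  stopifnot(inherits(priors, "dfa_priors"))
  priors$c0 / (priors$c0 + priors$d0)
}

# ---- latent state -----------------------------------------------------------

# Latent state holds everything the Gibbs sampler updates:
#   A (p x k slab coefficients), Z (p x k inclusion indicators),
#   M (n x p subject-biomarker means), Y (n x kq factor scores on the full
#   grid, factor-major: column (a-1) q + j is factor a at grid time j),
#   pi (k), rho2 (k), sigma2 (p), phi2 (p).
new_state <- function(A, Z, M, Y, pi, rho2, sigma2, phi2) {
  structure(list(A = A, Z = Z, M = M, Y = Y, pi = pi, rho2 = rho2,
                 sigma2 = sigma2, phi2 = phi2), class = "dfa_state")
}

loadings_of <- function(state) state$A * state$Z

# Data-informed starting state (uses the current RNG stream for jitter).
#
# Loadings and scores are initialized from a varimax-rotated truncated SVD of
# the within-subject-centered data. The rotation matters: the factor model
# with correlated scores and sparse loadings has a competing, nearly
# observationally equivalent representation with orthogonalized scores and
# dense loadings; a sampler started near the dense mode can stay there for
# many scans. Varimax starts the chain near the sparse mode, which the
# spike-and-slab prior then refines.
init_state <- function(panel, priors, k, theta = NULL, jitter_sd = 0.05) {
  n <- panel$n; p <- panel$p; q <- panel$q
  m <- nrow(panel$X)
  means <- if (is.null(theta)) rep(0, k) else theta$means
  v <- pmax(apply(panel$X, 2, stats::var), 1e-4)
  M <- matrix(priors$mu_g, n, p, byrow = TRUE)
  Y <- matrix(rep(rep(means, each = q), each = n), n, k * q)
  if (m > k && p > k) {
    sub_mean <- rowsum(panel$X, panel$row_subject)[panel$row_subject, ,
                                                   drop = FALSE] /
      panel$q_i[panel$row_subject]
    Xc <- panel$X - sub_mean
    sv <- svd(Xc, nu = k, nv = k)
    L0 <- sv$v %*% diag(sv$d[seq_len(k)] / sqrt(m), k)
    if (k > 1) {
      # oblique rotation: with cross-correlated factors the sparse loading
      # axes are an oblique (not orthogonal) rotation of the SVD basis
      rot <- tryCatch(stats::promax(L0)$rotmat,
                      error = function(e) stats::varimax(L0,
                                                         normalize = FALSE)$rotmat)
      L0 <- L0 %*% rot
    }
    # alternating least squares with per-column hard thresholding: pulls the
    # rotated SVD solution into the sparse-loadings representation (regression
    # scores on a sparsified loading matrix pick up the cross-correlation the
    # orthogonal SVD scores cannot express)
    Ls <- L0; Fs <- NULL
    for (it in 1:5) {
      thr <- 0.3 * apply(abs(Ls), 2, max)
      Zc <- abs(Ls) > matrix(thr, p, k, byrow = TRUE)
      Ls <- Ls * Zc
      Fs <- Xc %*% Ls %*% solve(crossprod(Ls) + diag(1e-8, k))
      if (it < 5) {
        Ls <- t(solve(crossprod(Fs) + diag(1e-8, k), crossprod(Fs, Xc)))
      }
    }
    # anchor factor signs so initial score cross-correlations are
    # non-negative against factor 1, matching the neutral positive-share
    # start of the hyperparameter estimate (a sign conflict between the
    # score prior and the initial state pushes the chain toward the dense
    # representation)
    if (k > 1) for (a in 2:k) {
      if (stats::cor(Fs[, 1], Fs[, a]) < 0) {
        Fs[, a] <- -Fs[, a]
        Ls[, a] <- -Ls[, a]
      }
    }
    A <- Ls + matrix(stats::rnorm(p * k, 0, jitter_sd), p, k)
    Z <- 1L * (Ls != 0)
    idx <- outer(panel$row_pos, (seq_len(k) - 1L) * q, "+")
    for (a in seq_len(k)) {
      Y[cbind(panel$row_subject, idx[, a])] <- Fs[, a]
    }
    Y <- Y + matrix(stats::rnorm(n * k * q, 0, jitter_sd), n, k * q)
    phi2 <- pmax(colMeans((Xc - Fs %*% t(Ls))^2), 1e-3)
  } else {
    pi0 <- prior_inclusion_mean(priors)
    Z <- matrix(stats::rbinom(p * k, 1L, pi0), p, k)
    A <- matrix(stats::rnorm(p * k, 0, 1), p, k)
    phi2 <- v / 2
  }
  pi_init <- pmin(pmax(colMeans(matrix(Z, p, k)), 0.05), 0.95)
  new_state(A = A, Z = Z, M = M, Y = Y, pi = pi_init,
            rho2 = pmax(colMeans(matrix(A^2, p, k)), 0.5),
            sigma2 = v / 2, phi2 = phi2)
}

# scores of subject i as a k x q matrix over the full grid
subject_scores <- function(state, i, k, q) {
  t(matrix(state$Y[i, ], q, k))
}

#' Model mean for one subject
#'
#' Predicted mean matrix M_i + L Y_i (p x q_i) at subject i's observed times,
#' where L = A * Z and Y_i restricts the augmented factor scores to the
#' subject's visit grid positions.
#'
#' @param state A latent-state object as produced by the sampler.
#' @param panel A \code{\link{dfa_panel}}.
#' @param i Subject index (1..n).
#' @return p x q_i matrix of model means.
#' @export
model_mean <- function(state, panel, i) {
  stopifnot(inherits(panel, "dfa_panel"))
  if (i < 1 || i > panel$n) stop("subject index out of range", call. = FALSE)
  k <- ncol(state$A); q <- panel$q
  if (ncol(state$Y) != k * q || nrow(state$A) != panel$p) {
    stop("state dimensions inconsistent with panel", call. = FALSE)
  }
  pos <- which(panel$V[i, ])
  L <- loadings_of(state)
  Yi <- subject_scores(state, i, k, q)[, pos, drop = FALSE]
  matrix(state$M[i, ], panel$p, length(pos)) + L %*% Yi
}

# ---- densities --------------------------------------------------------------

ig_logpdf <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

mvn_logpdf <- function(x, mean, chol_S) {
  z <- backsolve(chol_S, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(chol_S))) - 0.5 * sum(z^2)
}

#' Complete-data log joint density
#'
#' The log of f(X, state | theta, priors): Gaussian observation terms, the
#' MVN MOGP prior on each subject's augmented factor scores, and all prior
#' densities (means, variances, loadings, inclusion indicators, sparsity and
#' slab hyperparameters). This is the quantity whose latent variables the
#' stochastic EM integrates out by simulation, and the criterion used to pick
#' the reference draw for signed-permutation alignment.
#'
#' @param panel A \code{\link{dfa_panel}}.
#' @param state Latent state (augmented: scores on the full grid).
#' @param theta A \code{\link{mogp_hyperparams}}.
#' @param priors A \code{\link{dfa_priors}}.
#' @return Scalar log density.
#' @export
complete_data_loglik <- function(panel, state, theta, priors) {
  stopifnot(inherits(panel, "dfa_panel"), inherits(theta, "mogp_hyperparams"),
            inherits(priors, "dfa_priors"))
  n <- panel$n; p <- panel$p; q <- panel$q; k <- theta$k
  if (any(!is.finite(state$Y)) || any(!is.finite(state$A))) {
    stop("non-finite latent state", call. = FALSE)
  }
  L <- loadings_of(state)
  # observation terms, visit-major
  Yo <- observed_scores(state, panel, k)
  R <- panel$X - state$M[panel$row_subject, , drop = FALSE] - Yo %*% t(L)
  ll <- sum(stats::dnorm(R, 0, rep(sqrt(state$phi2), each = nrow(R)), log = TRUE))
  # subject-biomarker means
  ll <- ll + sum(stats::dnorm(state$M,
                              matrix(priors$mu_g, n, p, byrow = TRUE),
                              matrix(sqrt(state$sigma2), n, p, byrow = TRUE),
                              log = TRUE))
  # MOGP prior on augmented scores (common grid, shared Cholesky)
  S <- build_cov(theta, panel$grid)
  ch <- chol_jitter(S, "MOGP prior covariance")
  cm <- rep(theta$means, each = q)
  ll <- ll + sum(vapply(seq_len(n), function(i) {
    mvn_logpdf(state$Y[i, ], cm, ch)
  }, numeric(1)))
  # loadings machinery
  ll <- ll + sum(stats::dnorm(state$A, 0,
                              matrix(sqrt(state$rho2), p, k, byrow = TRUE),
                              log = TRUE))
  ll <- ll + sum(state$Z * log(matrix(state$pi, p, k, byrow = TRUE)) +
                   (1 - state$Z) * log(matrix(1 - state$pi, p, k, byrow = TRUE)))
  ll <- ll + sum(stats::dbeta(state$pi, priors$c0, priors$d0, log = TRUE))
  ll <- ll + sum(ig_logpdf(state$rho2, priors$c1, priors$d1))
  ll <- ll + sum(ig_logpdf(state$sigma2, priors$c2, priors$d2))
  ll <- ll + sum(ig_logpdf(state$phi2, priors$c3, priors$d3))
  ll
}

# scores at observed visit rows: m x k matrix aligned with panel$X rows
observed_scores <- function(state, panel, k) {
  q <- panel$q
  idx <- outer(panel$row_pos, (seq_len(k) - 1L) * q, "+")  # m x k column index
  m <- nrow(idx)
  out <- matrix(0, m, k)
  for (a in seq_len(k)) {
    out[, a] <- state$Y[cbind(panel$row_subject, idx[, a])]
  }
  out
}
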