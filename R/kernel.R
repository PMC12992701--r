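# Convolution-process MOGP kernel machinery.
#
# Each latent factor trajectory is y_a(t) = xi_a(t) + eta_a(t) + eps_a(t),
# where xi_a = h_a0 * tau_0 convolves a base white-noise process shared by all
# factors, eta_a = h_a1 * tau_a convolves a factor-specific one, and eps_a(t)
# is iid N(0, psi^2).  All smoothing kernels are Gaussian,
# h(t) = v * exp(-B t^2 / 2), B > 0.  Convolving two such kernels against a
# common white-noise process gives the closed-form covariance used throughout:
#
#   int h_a(dt + u) h_b(u) du
#     = v_a v_b sqrt(2*pi / (B_a + B_b)) * exp(-B_a B_b dt^2 / (2 (B_a + B_b)))
#
# so the auto-covariance of one component is v^2 sqrt(pi/B) exp(-B dt^2 / 4).

#' Per-factor convolution-kernel parameters
#'
#' Bundles the amplitude and decay parameters of the two Gaussian smoothing
#' kernels attached to one latent factor: \code{v0, B0} for the kernel applied
#' to the shared base process (which induces cross-correlation between
#' factors) and \code{v1, B1} for the kernel applied to the factor-specific
#' base process.
#'
#' @param v0,v1 Kernel amplitudes (finite reals; signs are meaningful for
#'   \code{v0}, whose products determine cross-correlation signs).
#' @param B0,B1 Kernel decay parameters (strictly positive). Larger values
#'   give rougher trajectories: the correlation between two time points decays
#'   as \code{exp(-B dt^2/4)}.
#' @return An object of class \code{"factor_kernel"}.
#' @export
factor_kernel <- function(v0, v1, B0, B1) {
  stopifnot(length(v0) == 1L, length(v1) == 1L, length(B0) == 1L, length(B1) == 1L)
  if (!is.finite(v0) || !is.finite(v1)) {
    stop("kernel amplitudes must be finite", call. = FALSE)
  }
  if (!is.finite(B0) || !is.finite(B1) || B0 <= 0 || B1 <= 0) {
    stop("kernel decay parameters B0, B1 must be finite and > 0", call. = FALSE)
  }
  structure(list(v0 = v0, v1 = v1, B0 = B0, B1 = B1), class = "factor_kernel")
}

#' Multi-output GP hyperparameter set
#'
#' Collects the per-factor convolution-kernel parameters, the white-noise
#' nugget variance and the constant factor means for a k-factor model.
#'
#' @param kernels List of \code{k} \code{\link{factor_kernel}} objects.
#' @param nugget Nugget variance psi^2 (non-negative). A scalar is shared by
#'   all factors; a length-k vector gives factor-specific nuggets (as arise
#'   after unit-variance normalization).
#' @param means Constant factor mean functions c_a, length k (default zeros).
#' @return An object of class \code{"mogp_hyperparams"}.
#' @export
mogp_hyperparams <- function(kernels, nugget = 0, means = NULL) {
  if (inherits(kernels, "factor_kernel")) kernels <- list(kernels)
  stopifnot(is.list(kernels), length(kernels) >= 1L)
  ok <- vapply(kernels, inherits, logical(1), "factor_kernel")
  if (!all(ok)) stop("'kernels' must be a list of factor_kernel objects", call. = FALSE)
  k <- length(kernels)
  if (length(nugget) == 1L) nugget <- rep(nugget, k)
  if (length(nugget) != k) stop("'nugget' must have length 1 or k", call. = FALSE)
  if (any(!is.finite(nugget)) || any(nugget < 0)) {
    stop("nugget variance must be finite and non-negative", call. = FALSE)
  }
  if (is.null(means)) means <- rep(0, k)
  if (length(means) != k || any(!is.finite(means))) {
    stop("'means' must be a finite vector of length k", call. = FALSE)
  }
  structure(list(kernels = kernels, nugget = nugget, means = means, k = k),
            class = "mogp_hyperparams")
}

#' @export
print.mogp_hyperparams <- function(x, ...) {
  cat("MOGP hyperparameters (", x$k, " factor", if (x$k > 1) "s", ")\n", sep = "")
  tab <- t(vapply(x$kernels, function(kr) c(kr$v0, kr$v1, kr$B0, kr$B1), numeric(4)))
  colnames(tab) <- c("v0", "v1", "B0", "B1")
  rownames(tab) <- paste0("factor", seq_len(x$k))
  print(cbind(tab, nugget = x$nugget, mean = x$means), ...)
  invisible(x)
}

# covariance contributed by convolving Gaussian kernels (va,Ba) and (vb,Bb)
# against one shared white-noise process, at time lag dt (vectorized over dt)
cp_kernel_cov <- function(va, Ba, vb, Bb, dt) {
  va * vb * sqrt(2 * pi / (Ba + Bb)) * exp(-Ba * Bb * dt^2 / (2 * (Ba + Bb)))
}

#' Auto-covariance of one factor trajectory
#'
#' Stationary auto-covariance C_aa(dt) of a single convolution-process factor:
#' the shared-kernel component plus the specific-kernel component plus the
#' nugget at zero lag,
#' \deqn{C_{aa}(dt) = v_0^2 \sqrt{\pi/B_0} e^{-B_0 dt^2/4} +
#'                    v_1^2 \sqrt{\pi/B_1} e^{-B_1 dt^2/4} + \delta(dt)\psi^2.}
#'
#' @param params A \code{\link{factor_kernel}}.
#' @param nugget Nugget variance psi^2 (non-negative scalar).
#' @param dt Time lag(s); any real, vectorized.
#' @return Covariance value(s), same length as \code{dt}.
#' @export
cp_auto_cov <- function(params, nugget = 0, dt = 0) {
  stopifnot(inherits(params, "factor_kernel"))
  if (length(nugget) != 1L || !is.finite(nugget) || nugget < 0) {
    stop("nugget must be a non-negative scalar", call. = FALSE)
  }
  cp_kernel_cov(params$v0, params$B0, params$v0, params$B0, dt) +
    cp_kernel_cov(params$v1, params$B1, params$v1, params$B1, dt) +
    (dt == 0) * nugget
}

#' Cross-covariance between two factor trajectories
#'
#' Covariance C_ab(dt) induced by the shared base process only:
#' \deqn{C_{ab}(dt) = v_{a0} v_{b0} \sqrt{2\pi/(B_{a0}+B_{b0})}
#'       \exp\{-B_{a0} B_{b0} dt^2 / (2 (B_{a0}+B_{b0}))\}.}
#' At dt = 0 this is \eqn{v_{a0} v_{b0} \sqrt{2\pi} / \sqrt{B_{a0}+B_{b0}}}.
#'
#' @param params_a,params_b \code{\link{factor_kernel}} objects for the two factors.
#' @param dt Time lag(s), vectorized.
#' @return Covariance value(s).
#' @export
cp_cross_cov <- function(params_a, params_b, dt = 0) {
  stopifnot(inherits(params_a, "factor_kernel"), inherits(params_b, "factor_kernel"))
  cp_kernel_cov(params_a$v0, params_a$B0, params_b$v0, params_b$B0, dt)
}

#' Joint covariance matrix of factor scores on a time grid
#'
#' Builds the kq x kq covariance matrix of the factor-major stacked score
#' vector vec(Y^T) = (y_1(t_1)..y_1(t_q), ..., y_k(t_1)..y_k(t_q)) under the
#' convolution-process MOGP prior. Diagonal blocks use
#' \code{\link{cp_auto_cov}} (nugget on their diagonals), off-diagonal blocks
#' use \code{\link{cp_cross_cov}}.
#'
#' @param theta A \code{\link{mogp_hyperparams}} object.
#' @param times Sorted (non-decreasing) numeric vector of observation times.
#' @return A symmetric positive semi-definite kq x kq matrix.
#' @export
build_cov <- function(theta, times) {
  stopifnot(inherits(theta, "mogp_hyperparams"))
  q <- length(times)
  if (q < 1L) stop("'times' must be non-empty", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be sorted ascending", call. = FALSE)
  k <- theta$k
  lag <- outer(times, times, "-")
  out <- matrix(0, k * q, k * q)
  for (a in seq_len(k)) {
    ia <- (a - 1L) * q + seq_len(q)
    out[ia, ia] <- cp_auto_cov(theta$kernels[[a]], theta$nugget[a], lag)
    if (a < k) for (b in seq((a + 1L), k)) {
      ib <- (b - 1L) * q + seq_len(q)
      blk <- cp_cross_cov(theta$kernels[[a]], theta$kernels[[b]], lag)
      out[ia, ib] <- blk
      out[ib, ia] <- t(blk)
    }
  }
  out
}

# stationary variance C_aaY(0) of each factor, nugget included
factor_variances <- function(theta) {
  vapply(seq_len(theta$k), function(a) {
    cp_auto_cov(theta$kernels[[a]], theta$nugget[a], 0)
  }, numeric(1))
}

#' Lag-zero cross-correlation between two factors
#'
#' The concurrent correlation rho_ab = C_ab(0) / sqrt(C_aa(0) C_bb(0)),
#' constant over time under the stationary convolution-process construction
#' (nugget included in the variances).
#'
#' @param theta A \code{\link{mogp_hyperparams}}.
#' @param a,b Distinct factor indices in 1..k.
#' @return Correlation in [-1, 1].
#' @seealso \code{\link{cross_correlation_matrix}}
#' @export
cross_correlation <- function(theta, a, b) {
  stopifnot(inherits(theta, "mogp_hyperparams"))
  k <- theta$k
  if (a == b) stop("'a' and 'b' must be distinct factor indices", call. = FALSE)
  if (a < 1 || a > k || b < 1 || b > k) stop("factor index out of range", call. = FALSE)
  va <- cp_auto_cov(theta$kernels[[a]], theta$nugget[a], 0)
  vb <- cp_auto_cov(theta$kernels[[b]], theta$nugget[b], 0)
  if (va <= 0 || vb <= 0) {
    stop("cross-correlation undefined: factor with zero stationary variance",
         call. = FALSE)
  }
  cp_cross_cov(theta$kernels[[a]], theta$kernels[[b]], 0) / sqrt(va * vb)
}

#' Cross-correlation matrix of all factors
#'
#' @param theta A \code{\link{mogp_hyperparams}}.
#' @return k x k correlation matrix with unit diagonal.
#' @export
cross_correlation_matrix <- function(theta) {
  k <- theta$k
  out <- diag(1, k)
  if (k > 1) for (a in 1:(k - 1)) for (b in (a + 1):k) {
    out[a, b] <- out[b, a] <- cross_correlation(theta, a, b)
  }
  out
}

#' Normalize hyperparameters to unit stationary factor variance
#'
#' Rescales each factor's kernel amplitudes and nugget share so that the
#' stationary variance C_aa(0) equals 1 for every factor; this is the
#' identifiability constraint fixing the scale ambiguity between loadings and
#' factor scores. The returned scale s_a = sqrt(C_aa(0)) can be absorbed into
#' loading column a (L[, a] * s_a leaves L Y unchanged). Constant means c_a
#' are divided by s_a for the same reason. Cross-correlations are invariant.
#'
#' @param theta A \code{\link{mogp_hyperparams}} with all C_aa(0) > 0.
#' @return List with elements \code{theta} (normalized) and \code{scales}
#'   (length-k vector of s_a).
#' @export
normalize_unit_variance <- function(theta) {
  stopifnot(inherits(theta, "mogp_hyperparams"))
  v <- factor_variances(theta)
  if (any(v <= 0)) stop("cannot normalize: factor with non-positive variance", call. = FALSE)
  s <- sqrt(v)
  kernels <- lapply(seq_len(theta$k), function(a) {
    kr <- theta$kernels[[a]]
    factor_kernel(kr$v0 / s[a], kr$v1 / s[a], kr$B0, kr$B1)
  })
  list(theta = mogp_hyperparams(kernels, nugget = theta$nugget / s^2,
                                means = theta$means / s),
       scales = s)
}

# Cholesky with one round of jitter (1e-8 * mean diag) if the first attempt
# fails; hard error on the second failure.
chol_jitter <- function(S, context = "covariance") {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-8 * mean(diag(S))
    ch <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (is.null(ch)) {
      stop("Cholesky factorization failed (after jitter) for ", context, call. = FALSE)
    }
  }
  ch
}
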