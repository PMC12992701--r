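# Top-level model-fitting interface.

#' Dynamic factor analysis for sparse irregular longitudinal biomarkers
#'
#' Fits the full model: a stochastic EM pass estimates the multi-output
#' Gaussian process hyperparameters (kernel amplitudes and decay rates,
#' nugget, constant factor means) under a roughness penalty; a block Gibbs
#' sampler then draws the sparse loadings, subject-biomarker means, noise
#' variances and factor trajectories conditional on those estimates; and
#' posterior draws are signed-permutation aligned before summarization.
#'
#' @param data A long-format data frame (columns subject, time, biomarker,
#'   value) or a \code{\link{dfa_panel}}.
#' @param k Number of latent factors (pre-specified; compare several in
#'   practice).
#' @param lambda Roughness penalty on the kernel decay parameters; select
#'   with \code{\link{cross_validate_lambda}}.
#' @param stem A \code{\link{stem_config}} for hyperparameter estimation.
#' @param gibbs A \code{\link{gibbs_config}} for posterior sampling (its
#'   seed is derived from \code{seed}).
#' @param priors A \code{\link{dfa_priors}}; by default \code{mu_g} is fixed
#'   to the empirical biomarker means and E(pi_a) = 0.1.
#' @param seed Integer seed controlling the whole fit.
#' @return Object of class \code{"dynfa"} with components \code{theta}
#'   (estimated hyperparameters), \code{corr} (factor cross-correlation
#'   matrix), \code{samples} (aligned posterior draws), \code{stem} (the
#'   \code{\link{stem_fit}}), \code{panel}, \code{priors} and \code{call}.
#' @seealso \code{\link{posterior_predictive}}, \code{\link{align_to_truth}},
#'   \code{\link{simulate_panel}}
#' @export
dynfa <- function(data, k, lambda = 0,
                  stem = stem_config(),
                  gibbs = gibbs_config(),
                  priors = NULL, seed = 1L) {
  cl <- match.call()
  panel <- if (inherits(data, "dfa_panel")) data else dfa_panel(data)
  if (is.null(priors)) priors <- default_priors(panel)
  sf <- stem_fit(panel, k, lambda, config = stem, priors = priors, seed = seed)
  gibbs$seed <- as.integer(seed) + 10000L
  samples <- run_gibbs(panel, sf$theta, gibbs, priors = priors)
  samples <- align_draws(samples)
  structure(list(theta = sf$theta, corr = sf$corr, samples = samples,
                 stem = sf, panel = panel, priors = priors, k = k,
                 lambda = lambda, seed = seed, call = cl),
            class = "dynfa")
}

# p x k x ndraw array of loading draws, chains concatenated
loading_draws <- function(samples) {
  arr <- lapply(samples$chains, function(dr) dr$A * dr$Z)
  out <- array(unlist(arr), dim = c(samples$p, samples$k, n_draws(samples)))
  dimnames(out) <- list(samples$biomarkers, paste0("factor", seq_len(samples$k)),
                        NULL)
  out
}

#' Posterior summary of factor loadings
#'
#' @param samples Aligned \code{\link{run_gibbs}} draws (or a \code{dynfa}
#'   fit).
#' @param prob Credible level for the interval (default 0.95).
#' @return Data frame: biomarker, factor, posterior median, interval bounds
#'   and posterior inclusion probability P(Z = 1 | data).
#' @export
loading_summary <- function(samples, prob = 0.95) {
  if (inherits(samples, "dynfa")) samples <- samples$samples
  stopifnot(inherits(samples, "dfa_samples"))
  ld <- loading_draws(samples)
  zd <- array(unlist(lapply(samples$chains, function(dr) dr$Z)),
              dim = dim(ld))
  al <- (1 - prob) / 2
  out <- expand.grid(biomarker = samples$biomarkers,
                     factor = seq_len(samples$k), stringsAsFactors = FALSE)
  out$median <- as.vector(apply(ld, c(1, 2), stats::median))
  out$lower <- as.vector(apply(ld, c(1, 2), stats::quantile, probs = al))
  out$upper <- as.vector(apply(ld, c(1, 2), stats::quantile, probs = 1 - al))
  out$incl_prob <- as.vector(apply(zd, c(1, 2), mean))
  out
}

#' @export
print.dynfa <- function(x, ...) {
  cat("Dynamic factor analysis fit\n")
  cat("  subjects:", x$panel$n, " biomarkers:", x$panel$p,
      " unique times:", x$panel$q, "\n")
  cat("  factors:", x$k, "  roughness penalty lambda:", x$lambda, "\n")
  cat("  factor cross-correlations:\n")
  print(round(x$corr, 3))
  invisible(x)
}

#' @export
summary.dynfa <- function(object, prob = 0.95, ...) {
  ls <- loading_summary(object$samples, prob)
  sel <- ls[ls$incl_prob > 0.5, , drop = FALSE]
  structure(list(fit = object, loadings = ls, selected = sel, prob = prob),
            class = "summary.dynfa")
}

#' @export
print.summary.dynfa <- function(x, ...) {
  print(x$fit)
  cat("\nBiomarkers with posterior inclusion probability > 0.5:\n")
  if (nrow(x$selected)) {
    df <- x$selected
    df[c("median", "lower", "upper", "incl_prob")] <-
      lapply(df[c("median", "lower", "upper", "incl_prob")], round, 3)
    print(df, row.names = FALSE)
  } else cat("  (none)\n")
  invisible(x)
}

#' Posterior median loading matrix
#'
#' @param object A \code{dynfa} fit.
#' @param ... Unused.
#' @return p x k matrix of posterior median loadings.
#' @export
coef.dynfa <- function(object, ...) {
  ld <- loading_draws(object$samples)
  apply(ld, c(1, 2), stats::median)
}

# posterior median fitted values at observed cells, visit-major
fitted_matrix <- function(object) {
  samples <- object$samples
  panel <- object$panel
  nd <- n_draws(samples)
  acc <- array(NA_real_, c(nrow(panel$X), panel$p, nd))
  j <- 0L
  k <- samples$k; q <- panel$q
  for (ch in seq_along(samples$chains)) {
    dr <- samples$chains[[ch]]
    for (s in seq_len(dim(dr$Y)[3])) {
      j <- j + 1L
      st <- new_state(A = matrix(dr$A[, , s], panel$p, k),
                      Z = matrix(dr$Z[, , s], panel$p, k),
                      M = matrix(dr$M[, , s], panel$n, panel$p),
                      Y = matrix(dr$Y[, , s], panel$n, k * q),
                      pi = dr$pi[, s], rho2 = dr$rho2[, s],
                      sigma2 = dr$sigma2[, s], phi2 = dr$phi2[, s])
      Yo <- observed_scores(st, panel, k)
      acc[, , j] <- st$M[panel$row_subject, , drop = FALSE] +
        Yo %*% t(loadings_of(st))
    }
  }
  apply(acc, c(1, 2), stats::median)
}

#' @export
fitted.dynfa <- function(object, ...) {
  fm <- fitted_matrix(object)
  long <- panel_to_long(object$panel)
  long$value <- as.vector(fm)
  names(long)[names(long) == "value"] <- "fitted"
  long
}

#' @export
residuals.dynfa <- function(object, ...) {
  fm <- fitted_matrix(object)
  long <- panel_to_long(object$panel)
  long$residual <- long$value - as.vector(fm)
  long
}

#' Predict biomarker trajectories
#'
#' Posterior predictive median and 95\% band for one subject and biomarker
#' over an arbitrary time grid (see \code{\link{posterior_predictive}}).
#'
#' @param object A \code{dynfa} fit.
#' @param subject Subject id or index.
#' @param biomarker Biomarker id or index.
#' @param times Prediction times (default: the fitted grid).
#' @param include_noise Add observation noise.
#' @param ... Unused.
#' @export
predict.dynfa <- function(object, subject, biomarker,
                          times = object$panel$grid, include_noise = FALSE,
                          ...) {
  posterior_predictive(object$samples, subject, biomarker, times,
                       include_noise)
}

#' Plot posterior median factor trajectories
#'
#' One panel per factor; each line is a subject's posterior median factor
#' score over the common time grid.
#'
#' @param x A \code{dynfa} fit.
#' @param ... Passed to \code{\link[graphics]{matplot}}.
#' @export
plot.dynfa <- function(x, ...) {
  samples <- x$samples
  k <- samples$k; q <- length(samples$grid); n <- samples$n
  yd <- lapply(samples$chains, function(dr) dr$Y)
  yall <- array(unlist(yd), dim = c(n, k * q, n_draws(samples)))
  med <- apply(yall, c(1, 2), stats::median)
  old <- graphics::par(mfrow = c(1, k))
  on.exit(graphics::par(old))
  for (a in seq_len(k)) {
    graphics::matplot(samples$grid, t(med[, (a - 1L) * q + seq_len(q)]),
                      type = "l", lty = 1,
                      xlab = "time", ylab = "factor score",
                      main = paste("factor", a), ...)
  }
  invisible(x)
}
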