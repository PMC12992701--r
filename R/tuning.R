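# Roughness-penalty selection by subject-level cross-validation.

#' Candidate grid for the roughness penalty
#'
#' Log-spaced grid lambda_j = exp(ln_min + j step), j = 0, 1, ...,
#' inclusive of both endpoints when \code{step} divides the range. The
#' default (-4, 4, 0.5) gives 17 candidates from 0.02 to 54.60.
#'
#' @param ln_min,ln_max Range of ln(lambda).
#' @param step Step length on the log scale (> 0).
#' @return Numeric vector of lambda values.
#' @export
lambda_grid <- function(ln_min = -4, ln_max = 4, step = 0.5) {
  if (!is.finite(ln_min) || !is.finite(ln_max) || ln_min > ln_max) {
    stop("invalid range: need ln_min <= ln_max", call. = FALSE)
  }
  if (!is.finite(step) || step <= 0) stop("'step' must be > 0", call. = FALSE)
  exp(seq(ln_min, ln_max, by = step))
}

# posterior-median predictions of all biomarkers for one subject at one time,
# from retained draws; time may be off the fitted grid (MOGP conditional)
predict_subject_time <- function(samples, i, tstar) {
  k <- samples$k; q <- length(samples$grid)
  pos <- match(tstar, samples$grid)
  if (is.na(pos)) {
    pp_rows <- vapply(seq_len(samples$p), function(g) {
      posterior_predictive(samples, i, g, times = tstar)$median
    }, numeric(1))
    return(pp_rows)
  }
  nd <- n_draws(samples)
  pred <- matrix(NA_real_, nd, samples$p)
  j <- 0L
  for (ch in seq_along(samples$chains)) {
    dr <- samples$chains[[ch]]
    for (s in seq_len(dim(dr$Y)[3])) {
      j <- j + 1L
      L <- matrix(dr$A[, , s] * dr$Z[, , s], samples$p, k)
      y <- dr$Y[i, (seq_len(k) - 1L) * q + pos, s]
      pred[j, ] <- dr$M[i, , s] + drop(L %*% y)
    }
  }
  apply(pred, 2, stats::median)
}

#' Select the roughness penalty by cross-validation
#'
#' Subjects are partitioned into \code{n_folds} approximately equal groups.
#' For each candidate lambda and each fold, hyperparameters are fitted by
#' \code{\link{stem_fit}} on the training subjects only; one randomly chosen
#' visit of each test subject is then held out, the Gibbs sampler is run on
#' the panel with those visits removed under the frozen hyperparameters, and
#' the held-out biomarker values are predicted by posterior medians. The fold
#' MAE is the mean absolute prediction error over test subjects and
#' biomarkers; lambda_opt minimizes the fold-averaged MAE.
#'
#' Test subjects with a single visit are skipped with a warning (nothing
#' would remain to condition on).
#'
#' @param panel A \code{\link{dfa_panel}}.
#' @param k Number of factors.
#' @param lambdas Candidate penalty values (see \code{\link{lambda_grid}}).
#' @param n_folds Number of folds (>= 2).
#' @param stem A \code{\link{stem_config}} for the per-fold fits (typically
#'   scaled down relative to the final fit).
#' @param gibbs A \code{\link{gibbs_config}} for the per-fold predictive runs.
#' @param priors A \code{\link{dfa_priors}}.
#' @param seed Integer seed; the whole procedure is deterministic given
#'   (seed, lambdas, configs).
#' @return Object of class \code{"cv_lambda"}: \code{lambda},
#'   \code{fold_mae} (lambda x fold), \code{mean_mae}, \code{lambda_opt},
#'   \code{folds} (subject assignment), \code{heldout}.
#' @export
cross_validate_lambda <- function(panel, k, lambdas = lambda_grid(),
                                  n_folds = 5L,
                                  stem = stem_config(n_iters = 20L, m = 5L,
                                                     s_chain_len = 100L),
                                  gibbs = gibbs_config(n_iter = 400L,
                                                       thin = 2L),
                                  priors = default_priors(panel),
                                  seed = 1L) {
  stopifnot(inherits(panel, "dfa_panel"), n_folds >= 2)
  if (panel$n < n_folds) stop("more folds than subjects", call. = FALSE)
  set.seed(as.integer(seed))
  fold_of <- sample(rep_len(seq_len(n_folds), panel$n))
  long <- panel_to_long(panel)
  # pre-choose one held-out visit per (eligible) subject
  heldout <- rep(NA_real_, panel$n)
  for (i in seq_len(panel$n)) {
    ti <- panel$grid[panel$V[i, ]]
    if (length(ti) < 2) next
    heldout[i] <- ti[sample.int(length(ti), 1L)]
  }
  skipped <- which(is.na(heldout))
  if (length(skipped)) {
    warning(length(skipped),
            " single-visit subject(s) skipped in CV prediction", call. = FALSE)
  }
  fold_mae <- matrix(NA_real_, length(lambdas), n_folds)
  for (jl in seq_along(lambdas)) {
    for (f in seq_len(n_folds)) {
      test_sub <- panel$subjects[fold_of == f]
      train_long <- long[!(long$subject %in% test_sub), , drop = FALSE]
      train_panel <- suppressWarnings(dfa_panel(train_long))
      fit <- stem_fit(train_panel, k, lambdas[jl], config = stem,
                      priors = dfa_priors(panel$p, mu_g = priors$mu_g),
                      seed = seed + 1009L * jl + f)
      # remove held-out visits of test subjects, keep everything else
      drop_key <- paste(panel$subjects[fold_of == f], heldout[fold_of == f])
      drop_key <- drop_key[!is.na(heldout[fold_of == f])]
      part <- long[!(paste(long$subject, long$time) %in% drop_key), , drop = FALSE]
      part_panel <- suppressWarnings(dfa_panel(part))
      gc_f <- gibbs_config(n_iter = gibbs$n_iter, burn_frac = gibbs$burn_frac,
                           thin = gibbs$thin, n_chains = 1L,
                           seed = seed + 2003L * jl + f)
      samples <- run_gibbs(part_panel, fit$theta, gc_f,
                           priors = dfa_priors(panel$p, mu_g = priors$mu_g))
      errs <- c()
      for (i in which(fold_of == f)) {
        if (is.na(heldout[i])) next
        ii <- match(panel$subjects[i], part_panel$subjects)
        pred <- predict_subject_time(samples, ii, heldout[i])
        pos <- match(heldout[i], panel$grid)
        row <- which(panel$row_subject == i & panel$row_pos == pos)
        errs <- c(errs, abs(pred - panel$X[row, ]))
      }
      fold_mae[jl, f] <- mean(errs)
    }
  }
  mean_mae <- rowMeans(fold_mae)
  structure(list(lambda = lambdas, fold_mae = fold_mae, mean_mae = mean_mae,
                 lambda_opt = lambdas[which.min(mean_mae)],
                 folds = fold_of, heldout = heldout),
            class = "cv_lambda")
}

#' @export
print.cv_lambda <- function(x, ...) {
  cat("Cross-validated roughness penalty selection\n")
  print(data.frame(lambda = round(x$lambda, 4), mean_mae = x$mean_mae))
  cat("lambda_opt =", x$lambda_opt, "\n")
  invisible(x)
}
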