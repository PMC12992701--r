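# Signed-permutation (label-switching + sign-flip) handling.
#
# Permuting factor labels and flipping factor signs jointly in (L columns,
# Y rows) leaves L %*% Y, and hence the observation likelihood, unchanged:
# there are 2^k k! such transformations. Posterior draws are aligned to a
# reference draw before summarization; simulation estimates are aligned to
# the generating truth before scoring.

#' Signed permutation of factor labels
#'
#' @param perm Integer permutation of 1..k.
#' @param signs Vector of +/-1 of length k.
#' @return Object of class \code{"signed_perm"}.
#' @details Convention: applying the transformation maps column a of the
#'   loading matrix to \code{signs[a] * L[, perm[a]]} (and row a of the score
#'   matrix to \code{signs[a] * Y[perm[a], ]}), so the product L Y is
#'   invariant.
#' @export
signed_perm <- function(perm, signs) {
  k <- length(perm)
  if (!setequal(perm, seq_len(k))) stop("'perm' must be a permutation of 1..k", call. = FALSE)
  if (length(signs) != k || !all(signs %in% c(-1, 1))) {
    stop("'signs' must be a +/-1 vector of length k", call. = FALSE)
  }
  structure(list(perm = as.integer(perm), signs = signs), class = "signed_perm")
}

#' Apply a signed permutation to loadings and scores
#'
#' @param sp A \code{\link{signed_perm}}.
#' @param L p x k loading matrix (or NULL).
#' @param Y k x q factor score matrix (or NULL).
#' @return List with transformed \code{L} and \code{Y}; \code{L \%*\% Y} is
#'   unchanged.
#' @export
sp_apply <- function(sp, L = NULL, Y = NULL) {
  stopifnot(inherits(sp, "signed_perm"))
  k <- length(sp$perm)
  out <- list(L = NULL, Y = NULL)
  if (!is.null(L)) {
    if (ncol(L) != k) stop("L has wrong number of columns", call. = FALSE)
    out$L <- sweep(L[, sp$perm, drop = FALSE], 2, sp$signs, "*")
  }
  if (!is.null(Y)) {
    if (nrow(Y) != k) stop("Y has wrong number of rows", call. = FALSE)
    out$Y <- sweep(Y[sp$perm, , drop = FALSE], 1, sp$signs, "*")
  }
  out
}

# composition: applying sp1 then sp2 equals applying sp_compose(sp2, sp1)
sp_compose <- function(sp2, sp1) {
  signed_perm(sp1$perm[sp2$perm], sp2$signs * sp1$signs[sp2$perm])
}

# transform a correlation matrix: rho'_{ab} = s_a s_b rho_{perm[a], perm[b]}
sp_apply_corr <- function(sp, corr) {
  out <- corr[sp$perm, sp$perm, drop = FALSE]
  out * tcrossprod(sp$signs)
}

#' Enumerate all signed permutations
#'
#' @param k Number of factors (guarded at k <= 8; 2^k k! candidates).
#' @return List of \code{\link{signed_perm}} objects, length 2^k k!.
#' @export
enumerate_signed_perms <- function(k) {
  if (k > 8) stop("k too large to enumerate signed permutations; use align_draws",
                  call. = FALSE)
  perms <- all_perms(k)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  out <- vector("list", nrow(signs) * length(perms))
  j <- 0L
  for (pm in perms) for (s in seq_len(nrow(signs))) {
    j <- j + 1L
    out[[j]] <- signed_perm(pm, unname(signs[s, ]))
  }
  out
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_perms(k - 1L)
  out <- list()
  for (s in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(s, k, after = pos - 1L)
  }
  out
}

# best signed permutation of `L` toward `ref` by mean absolute difference;
# exhaustive for k <= 6, greedy column matching above
best_sp_to_ref <- function(L, ref) {
  k <- ncol(L)
  if (k <= 6) {
    cands <- enumerate_signed_perms(k)
    costs <- vapply(cands, function(sp) {
      mean(abs(sp_apply(sp, L = L)$L - ref))
    }, numeric(1))
    return(cands[[which.min(costs)]])
  }
  # greedy: for each target column pick the best remaining source column/sign
  avail <- seq_len(k)
  perm <- integer(k); signs <- numeric(k)
  for (a in seq_len(k)) {
    costs <- vapply(avail, function(b) {
      min(mean(abs(L[, b] - ref[, a])), mean(abs(-L[, b] - ref[, a])))
    }, numeric(1))
    b <- avail[which.min(costs)]
    perm[a] <- b
    signs[a] <- if (mean(abs(L[, b] - ref[, a])) <=
                    mean(abs(-L[, b] - ref[, a]))) 1 else -1
    avail <- setdiff(avail, b)
  }
  signed_perm(perm, signs)
}

#' Align posterior draws by signed permutation
#'
#' Transforms every retained draw (within and across chains) by the signed
#' permutation minimizing the mean absolute difference between its loading
#' matrix and a reference loading matrix; the same transformation is applied
#' to the draw's factor scores, inclusion indicators, sparsity and slab
#' parameters. The reference defaults to the retained draw with the highest
#' complete-data log density.
#'
#' @param samples A \code{\link{run_gibbs}} result.
#' @param reference Optional p x k loading matrix to align to.
#' @return The samples object with aligned draws and the applied
#'   transformations stored in \code{$alignment}.
#' @export
align_draws <- function(samples, reference = NULL) {
  stopifnot(inherits(samples, "dfa_samples"))
  k <- samples$k; q <- length(samples$grid)
  if (is.null(reference)) {
    best <- c(-Inf, NA, NA)
    for (ch in seq_along(samples$chains)) {
      ll <- samples$chains[[ch]]$loglik
      s <- which.max(ll)
      if (ll[s] > best[1]) best <- c(ll[s], ch, s)
    }
    dr <- samples$chains[[best[2]]]
    reference <- dr$A[, , best[3]] * dr$Z[, , best[3]]
  }
  applied <- vector("list", length(samples$chains))
  for (ch in seq_along(samples$chains)) {
    dr <- samples$chains[[ch]]
    nk <- dim(dr$Y)[3]
    applied[[ch]] <- vector("list", nk)
    for (s in seq_len(nk)) {
      L <- matrix(dr$A[, , s] * dr$Z[, , s], samples$p, k)
      sp <- best_sp_to_ref(L, reference)
      applied[[ch]][[s]] <- sp
      dr$A[, , s] <- matrix(dr$A[, sp$perm, s], samples$p, k) *
        matrix(sp$signs, samples$p, k, byrow = TRUE)
      dr$Z[, , s] <- matrix(dr$Z[, sp$perm, s], samples$p, k)
      dr$pi[, s] <- dr$pi[sp$perm, s]
      dr$rho2[, s] <- dr$rho2[sp$perm, s]
      # scores: rows of each subject's k x q matrix, stored factor-major
      Ys <- dr$Y[, , s, drop = FALSE]
      dim(Ys) <- c(samples$n, q, k)
      Ys <- Ys[, , sp$perm, drop = FALSE]
      Ys <- sweep(Ys, 3, sp$signs, "*")
      dim(Ys) <- c(samples$n, q * k)
      dr$Y[, , s] <- Ys
    }
    samples$chains[[ch]] <- dr
  }
  samples$alignment <- applied
  samples
}

#' Align an estimated cross-correlation matrix to a known truth
#'
#' Exhaustively searches all 2^k k! signed permutations for the one
#' minimizing the mean absolute difference (MAD) between the transformed
#' estimated cross-correlations and the true ones (off-diagonal entries;
#' correlations transform by index permutation and sign products s_a s_b).
#' Used for scoring simulation recoveries, where the labelling of estimated
#' factors is arbitrary.
#'
#' @param rho_hat Estimated k x k cross-correlation matrix.
#' @param rho_true True k x k cross-correlation matrix.
#' @param L_hat,L_true Optional loading matrices used to break ties among
#'   equal-MAD candidates (smallest mean absolute loading difference wins).
#' @return List with the minimizing \code{sp} (\code{\link{signed_perm}}),
#'   the achieved \code{mad}, and the transformed matrix \code{rho_aligned}.
#' @export
align_to_truth <- function(rho_hat, rho_true, L_hat = NULL, L_true = NULL) {
  k <- nrow(rho_true)
  stopifnot(all(dim(rho_hat) == c(k, k)))
  if (k > 8) stop("k too large to enumerate; use align_draws", call. = FALSE)
  cands <- enumerate_signed_perms(k)
  off <- upper.tri(rho_true)
  mads <- vapply(cands, function(sp) {
    if (k == 1) return(0)
    mean(abs(sp_apply_corr(sp, rho_hat)[off] - rho_true[off]))
  }, numeric(1))
  best <- which(mads <= min(mads) + 1e-15)
  pick <- best[1]
  if (length(best) > 1 && !is.null(L_hat) && !is.null(L_true)) {
    lcost <- vapply(best, function(j) {
      mean(abs(sp_apply(cands[[j]], L = L_hat)$L - L_true))
    }, numeric(1))
    pick <- best[which.min(lcost)]
  }
  sp <- cands[[pick]]
  list(sp = sp, mad = mads[pick], rho_aligned = sp_apply_corr(sp, rho_hat))
}
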