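# Readers/writers and the two preprocessing steps used with sparse clinical
# panels: regressing out a per-subject covariate (age) biomarker-wise, and
# coarsening irregular observation times onto a reference grid.

#' Read a long-format biomarker panel from delimited text
#'
#' @param path File with columns \code{subject}, \code{time},
#'   \code{biomarker}, \code{value}.
#' @param sep Field separator (default comma).
#' @return A validated \code{\link{dfa_panel}}.
#' @export
read_panel <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  dfa_panel(df)
}

#' Write a panel as long-format delimited text
#'
#' @param panel A \code{\link{dfa_panel}}.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_panel <- function(panel, path, sep = ",") {
  utils::write.table(panel_to_long(panel), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Regress a subject-level covariate out of every biomarker
#'
#' Per biomarker g, fits the ordinary least squares regression of the raw
#' values on an intercept and the subject covariate (age), pooling all
#' observations of all subjects, and replaces each value by its residual.
#' The residuals of every biomarker have exactly zero sample correlation
#' with the covariate.
#'
#' @param panel A \code{\link{dfa_panel}}.
#' @param ages Either a named numeric vector (names = subject ids) or a data
#'   frame with columns \code{subject} and \code{age}; every subject must be
#'   covered.
#' @return A new \code{\link{dfa_panel}} of residuals, with the fitted
#'   coefficients in attribute \code{"coefficients"} (2 x p: intercept, slope).
#' @export
regress_out_age <- function(panel, ages) {
  stopifnot(inherits(panel, "dfa_panel"))
  if (is.data.frame(ages)) {
    a <- stats::setNames(ages$age, ages$subject)
  } else a <- ages
  if (!all(panel$subjects %in% names(a))) {
    stop("age missing for some subjects", call. = FALSE)
  }
  av <- as.numeric(a[as.character(panel$subjects[panel$row_subject])])
  if (stats::var(av) == 0) {
    stop("constant age vector: regression design is rank deficient", call. = FALSE)
  }
  D <- cbind(1, av)
  fit <- stats::lm.fit(D, panel$X)
  out <- panel
  out$X <- panel$X - D %*% fit$coefficients
  attr(out, "coefficients") <- fit$coefficients
  out
}

#' Coarsen observation times onto a reference grid
#'
#' Maps each observed time to the nearest reference time (ties broken toward
#' the earlier reference time). When two visits of the same subject map to
#' the same reference time, the earlier visit is kept and the later one
#' dropped (reported in the map). Shift diagnostics summarize how close the
#' mapping is to a constant per-subject time shift.
#'
#' @param panel A \code{\link{dfa_panel}}.
#' @param ref_times Sorted vector of unique reference times (e.g.
#'   \code{seq(0, 49, by = 7)}).
#' @return List with \code{panel} (coarsened \code{\link{dfa_panel}}),
#'   \code{map} (data frame: subject, time, ref_time, kept) and
#'   \code{diagnostics} (per-subject shift standard deviation and the
#'   maximum over subjects).
#' @export
map_to_reference_grid <- function(panel, ref_times) {
  stopifnot(inherits(panel, "dfa_panel"))
  ref_times <- as.numeric(ref_times)
  if (length(ref_times) < 1) stop("empty reference grid", call. = FALSE)
  if (is.unsorted(ref_times, strictly = TRUE)) {
    stop("'ref_times' must be sorted and unique", call. = FALSE)
  }
  # visit-level mapping
  vt <- panel$grid[panel$row_pos]
  nearest <- vapply(vt, function(t0) {
    d <- abs(ref_times - t0)
    ref_times[which.min(d)]       # which.min takes the earlier on ties
  }, numeric(1))
  vis <- data.frame(subject = panel$subjects[panel$row_subject],
                    time = vt, ref_time = nearest, kept = TRUE,
                    stringsAsFactors = FALSE)
  # collision policy: within subject keep the earlier original visit
  ord <- order(vis$subject, vis$time)
  dup <- duplicated(vis[ord, c("subject", "ref_time")])
  vis$kept[ord][dup] <- FALSE
  n_drop <- sum(!vis$kept)
  if (n_drop) message(n_drop, " visit(s) dropped by reference-grid collisions")
  keep_rows <- which(vis$kept)
  long <- data.frame(
    subject = rep(vis$subject[keep_rows], times = panel$p),
    time = rep(vis$ref_time[keep_rows], times = panel$p),
    biomarker = rep(panel$biomarkers, each = length(keep_rows)),
    value = as.vector(panel$X[keep_rows, , drop = FALSE])
  )
  shifts <- vis$time[keep_rows] - vis$ref_time[keep_rows]
  by_sub <- split(shifts, vis$subject[keep_rows])
  shift_sd <- vapply(by_sub, function(s) if (length(s) > 1) stats::sd(s) else 0,
                     numeric(1))
  list(panel = suppressWarnings(dfa_panel(long)),
       map = vis,
       diagnostics = list(shift_sd = shift_sd,
                          max_shift_sd = max(shift_sd)))
}
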