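#' One-sample t-test with explicit degenerate handling
#'
#' Tests whether the mean of `values` differs from `mu0` (two-sided).
#' Four-level qualitative predictions can be unanimous across subjects, so
#' the zero-variance case is handled explicitly rather than erroring:
#' `sd = 0` with `mean == mu0` gives `t = 0, p = 1`; `sd = 0` with
#' `mean != mu0` is flagged degenerate with `p = 0` and a warning (the
#' difference is unanimous, its scale unestimable).
#'
#' @param values numeric vector, `n >= 2`.
#' @param mu0 null mean.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
one_sample_t <- function(values, mu0) {
  n <- length(values)
  if (n < 2L) stop("one-sample t-test needs at least 2 values")
  s <- stats::sd(values)
  if (s == 0) {
    if (mean(values) == mu0) {
      return(list(t = 0, df = n - 1L, p = 1, degenerate = FALSE))
    }
    warning("zero variance with mean != mu0: unanimous difference, p set to 0")
    return(list(t = sign(mean(values) - mu0) * Inf, df = n - 1L, p = 0,
                degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up procedure controlling the false discovery rate at `q`:
#' with sorted p-values `p(1) <= ... <= p(m)`, reject the hypotheses of rank
#' `<= k* = max{k : p(k) <= (k/m) q}`. Adjusted p-values use the cumulative
#' minimum formula (as `p.adjust(method = "BH")`).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q target false discovery rate.
#' @return list with `adjusted` (same order as input) and `reject` (logical).
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  ord <- order(pvalues)
  thresh <- (seq_len(m) / m) * q
  below <- which(pvalues[ord] <= thresh)
  reject <- rep(FALSE, m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  list(adjusted = adjusted, reject = reject)
}

#' Differential-expression predictions for unobserved markers
#'
#' Compares the imputed level of every molecular marker across subjects to
#' the level imputed for the idealized control under the same fitted
#' program, with a one-sample t-test per marker and Benjamini-Hochberg
#' correction across all tested markers.
#'
#' @param imputed matrix of imputed full states (rows = subjects, columns
#'   named by node) — typically the per-subject modal imputed states of a
#'   [fit_program()] result — or a list of named state vectors.
#' @param control named full state imputed for the idealized control.
#' @param markers character vector of marker (molecular node) ids to test.
#' @param q target false discovery rate.
#' @return data.frame of class `diff_marker_table`: per marker the group
#'   `mean_level`, `control_level`, `t`, `df`, `p`, `p_adj`, `direction`
#'   (`"up"`, `"down"` or `"none"`), `significant`, `degenerate`.
#' @export
differential_markers <- function(imputed, control, markers, q = 0.05) {
  if (is.list(imputed) && !is.data.frame(imputed) && !is.matrix(imputed)) {
    imputed <- do.call(rbind, imputed)
  }
  imputed <- as.matrix(imputed)
  if (nrow(imputed) < 2L) stop("need at least 2 subjects")
  miss <- setdiff(markers, colnames(imputed))
  if (length(miss)) stop("imputed states are missing marker(s): ",
                         paste(miss, collapse = ", "))
  rows <- lapply(markers, function(mk) {
    vals <- imputed[, mk]
    mu0 <- as.numeric(control[[mk]])
    tt <- withCallingHandlers(
      one_sample_t(vals, mu0),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(marker = mk, mean_level = mean(vals), control_level = mu0,
               t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  bh <- bh_adjust(tab$p, q = q)
  tab$p_adj <- bh$adjusted
  tab$significant <- bh$reject
  tab$direction <- ifelse(!tab$significant, "none",
                          ifelse(tab$mean_level > tab$control_level, "up",
                                 "down"))
  if (any(tab$degenerate)) {
    warning("zero-variance unanimous difference for marker(s): ",
            paste(tab$marker[tab$degenerate], collapse = ", "))
  }
  class(tab) <- c("diff_marker_table", "data.frame")
  tab
}
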