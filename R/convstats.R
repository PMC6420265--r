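#' Estimate total egg chambers from a count of mounted ovaries
#'
#' Scoring repression per egg chamber requires the total number of egg
#' chambers examined; with three to four egg chambers per ovariole and 16 to
#' 18 ovarioles per ovary, an average of 60 egg chambers per mounted ovary
#' is used.
#'
#' @param n_ovaries Number of mounted ovaries (>= 0).
#' @param per_ovary Average egg chambers per ovary.
#' @return Integer estimate `n_ovaries * per_ovary`.
#' @export
estimate_total_egg_chambers <- function(n_ovaries, per_ovary = 60L) {
  if (any(n_ovaries < 0)) stop("n_ovaries must be >= 0")
  as.integer(round(n_ovaries * per_ovary))
}

#' Repression / conversion frequency with Wilson confidence interval
#'
#' Computes the percentage of repressed units (egg chambers or females)
#' among those scored, reported to one decimal place, with a Wilson 95%
#' score interval (boundary-safe for zero numerators; the interval is a
#' package addition, not part of the original scoring scheme).
#'
#' @param n_repressed,n_total Nonnegative integers with
#'   `n_repressed <= n_total`, `n_total > 0`.
#' @return Object of class `repression_frequency`: list with n_repressed,
#'   n_total, frequency (percent, 1 decimal), frequency_raw, ci_low, ci_high
#'   (percent).
#' @export
repression_frequency <- function(n_repressed, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_repressed < 0 || n_repressed > n_total) {
    stop("n_repressed must lie in [0, n_total]")
  }
  raw <- 100 * n_repressed / n_total
  ci <- suppressWarnings(
    prop.test(n_repressed, n_total, correct = FALSE)$conf.int
  )
  structure(list(
    n_repressed = n_repressed, n_total = n_total,
    frequency = round(raw, 1L), frequency_raw = raw,
    ci_low = 100 * ci[1], ci_high = 100 * ci[2]
  ), class = "repression_frequency")
}

#' @export
print.repression_frequency <- function(x, ...) {
  cat(sprintf("%s%% (%d/%d; Wilson 95%% CI %.1f-%.1f%%)\n",
              format(x$frequency, nsmall = 1), x$n_repressed, x$n_total,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Homogeneity chi-square test on an r x c contingency table
#'
#' Pearson chi-square test that the rows share one outcome distribution,
#' with optional Yates continuity correction on 2 x 2 tables. The test is
#' delegated to [stats::chisq.test()]; low expected counts are reported via
#' the `low_expected` flag instead of a warning so callers can decide.
#'
#' @param counts Integer matrix (>= 2 rows and columns, all counts >= 0).
#' @param correct Apply the Yates continuity correction (2 x 2 only).
#' @return List with statistic, df, p_value, correction, low_expected and
#'   the expected counts.
#' @export
homogeneity_chi2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("table must have at least 2 rows and 2 columns")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate margins: a row or column total is zero")
  }
  fit <- suppressWarnings(chisq.test(counts, correct = correct))
  list(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    correction = correct && all(dim(counts) == 2L),
    low_expected = any(fit$expected < 5),
    expected = fit$expected
  )
}
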