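# Accuracy statistics: RMSD, Bland-Altman limits of agreement, and the
# identity connecting them.
#
# For a series of signed differences d_1..d_n:
#   RMSD     = sqrt(mean(d^2))                       (1/n inside the root)
#   limits   = mean(d) +/- 1.96 * sd(d)              (sample SD, n-1)
#   limit CI = limit +/- t(0.975, df) * sqrt(3 sd^2 / n)
# and the exact identity  RMSD^2 = mean^2 + sd^2 (n-1)/n  lets an RMSD table
# be recovered from a limits table without the raw data.

#' Root mean square deviation of a difference series
#'
#' `sqrt(mean(values^2))` with the 1/n divisor — not the sample variance's
#' 1/(n-1) — so a constant nonzero offset is fully reflected, unlike the
#' mean difference in which signed errors cancel.
#'
#' @param values numeric vector of signed differences (mm or degrees), n >= 1.
#' @return Non-negative scalar in the units of `values`.
#' @examples
#' rmsd(c(3, 4))   # sqrt(12.5)
#' rmsd(c(-1, 1))  # 1, while mean(c(-1, 1)) is 0
#' @export
rmsd <- function(values) {
  if (length(values) < 1L) stop("rmsd needs at least one value")
  if (!all(is.finite(values))) stop("rmsd: values must all be finite")
  sqrt(mean(values^2))
}

#' Bland-Altman limits of agreement with confidence intervals
#'
#' Limits are `mean(d) +/- 1.96 sd(d)` with the sample SD (n-1 divisor);
#' the 1.96 multiplier is fixed, not t-based. Each limit gets a 95%
#' confidence interval of half-width `t(0.975, df) * sqrt(3 sd^2 / n)`,
#' where `sqrt(3 sd^2 / n)` is the standard error of a limit. The degrees
#' of freedom for t are `n - 1` by default (`df_mode = "n_minus_1"`, the
#' conventional choice); `df_mode = "n"` is available because published
#' tables are sometimes computed that way and the two differ by under 2%
#' at n = 10.
#'
#' @param values numeric vector of signed differences, n >= 3.
#' @param df_mode `"n_minus_1"` (default) or `"n"`.
#' @return Object of class `agreement_result`: `n`, `mean_diff`, `sd`,
#'   `lower_limit`, `upper_limit`, `ci_lower_limit`, `ci_upper_limit`
#'   (each a length-2 vector), `se_limit`, `t_crit`, `t_df`.
#' @examples
#' bland_altman(c(-1, 0, 1))  # limits -1.96, +1.96
#' @export
bland_altman <- function(values, df_mode = c("n_minus_1", "n")) {
  df_mode <- match.arg(df_mode)
  n <- length(values)
  if (n < 3L) stop("bland_altman needs n >= 3 (limit CIs are meaningless below)")
  if (!all(is.finite(values))) stop("bland_altman: values must all be finite")
  m <- mean(values)
  s <- stats::sd(values)
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  df <- if (df_mode == "n_minus_1") n - 1L else n
  tc <- stats::qt(0.975, df)
  se <- sqrt(3 * s^2 / n)
  hw <- tc * se
  structure(list(n = n, mean_diff = m, sd = s,
                 lower_limit = lo, upper_limit = hi,
                 ci_lower_limit = c(lo - hw, lo + hw),
                 ci_upper_limit = c(hi - hw, hi + hw),
                 se_limit = se, t_crit = tc, t_df = df),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n=%d mean=%.3f sd=%.3f\n", x$n,
              x$mean_diff, x$sd))
  cat(sprintf("  lower limit %.2f (%.2f to %.2f)\n", x$lower_limit,
              x$ci_lower_limit[1], x$ci_lower_limit[2]))
  cat(sprintf("  upper limit %.2f (%.2f to %.2f)\n", x$upper_limit,
              x$ci_upper_limit[1], x$ci_upper_limit[2]))
  invisible(x)
}

#' Recover mean, SD and implied RMSD from limits of agreement
#'
#' Inverts the limit construction: `mean = (upper + lower)/2`,
#' `sd = (upper - lower)/(2 * 1.96)`, and applies the exact identity
#' `rmsd = sqrt(mean^2 + sd^2 (n-1)/n)` linking the sample SD to the 1/n
#' RMSD. This lets an RMSD accuracy table be cross-checked against a
#' published limits-of-agreement table with no access to the raw series.
#'
#' @param lower,upper the limits of agreement (same units).
#' @param n number of specimens behind the limits, n >= 2.
#' @return List with `mean_diff`, `sd`, `implied_rmsd`.
#' @examples
#' stats_from_limits(-1.84, 4.77, 10)$implied_rmsd  # ~2.17
#' @export
stats_from_limits <- function(lower, upper, n) {
  if (!is.finite(lower) || !is.finite(upper)) stop("limits must be finite")
  if (upper < lower) stop("upper limit is below lower limit")
  if (n < 2L) stop("n must be >= 2")
  m <- (upper + lower) / 2
  s <- (upper - lower) / (2 * 1.96)
  list(mean_diff = m, sd = s,
       implied_rmsd = sqrt(m^2 + s^2 * (n - 1) / n))
}

#' Classify an RMSD value against the clinical accuracy cutoff
#'
#' The conventional cutoffs are 2 mm for translational and 4 degrees for
#' rotational differences; values at the cutoff count as within (the
#' criterion is inclusive).
#'
#' @param rmsd_value non-negative RMSD (mm or degrees).
#' @param kind `"translational"` or `"rotational"`.
#' @param cutoffs named numeric vector with elements `translational` (mm)
#'   and `rotational` (degrees).
#' @return Logical: is the value within the cutoff?
#' @export
classify_accuracy <- function(rmsd_value,
                              kind = c("translational", "rotational"),
                              cutoffs = c(translational = 2, rotational = 4)) {
  kind <- match.arg(kind)
  if (!is.finite(rmsd_value) || rmsd_value < 0)
    stop("rmsd_value must be a finite non-negative number")
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  rmsd_value <= cutoffs[[kind]]
}

#' Round half away from zero
#'
#' Report tables round to 2 decimals with halves away from zero (the usual
#' half-up convention of published tables), unlike base `round()`'s
#' round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
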