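# Proportion-of-significance per photo period and the two-proportion test
# between regimens.

#' Proportion of seconds with a significant directed difference
#'
#' Within the union of the named photo periods, counts the analyzed seconds
#' where the pair's Tukey-adjusted p-value falls below `alpha` AND the
#' difference has the requested direction. Seconds significant in the
#' opposite direction do not count: the direction is fixed a priori
#' ("`direction` moved more than the other level"). `n_seconds` counts
#' analyzed (post-stride) seconds, not wall-clock seconds.
#'
#' @param trajectory A `contrast_trajectory`.
#' @param regimen The `regimen` the trajectory was computed under.
#' @param period_labels Photo-period labels to pool (e.g.
#'   `c("dark3", "dark4", "dark5")`).
#' @param pair Two level names, `c(a, b)`; must match a pair present in the
#'   trajectory (in either order).
#' @param direction Level expected to move more (default `pair[1]`).
#' @param alpha Significance level; defaults to the trajectory's own alpha.
#' @return A `period_proportion`: pair, direction, periods, `n_seconds`,
#'   `n_significant`, `proportion` (also formatted as percent to 2 decimals).
#' @export
proportion_significant <- function(trajectory, regimen, period_labels, pair,
                                   direction = pair[1], alpha = NULL) {
  pg_assert(inherits(trajectory, "contrast_trajectory"),
            "trajectory must come from pairwise_trajectory()")
  pg_assert(length(pair) == 2, "pair must name two levels")
  pg_assert(direction %in% pair, "direction must be one of the pair's levels")
  alpha <- alpha %||% attr(trajectory, "alpha")
  secs <- period_seconds(regimen, period_labels)
  rows <- trajectory[(trajectory$level_a == pair[1] & trajectory$level_b == pair[2]) |
                       (trajectory$level_a == pair[2] & trajectory$level_b == pair[1]), ,
                     drop = FALSE]
  pg_assert(nrow(rows) > 0,
            sprintf("pair %s vs %s not present in the trajectory", pair[1], pair[2]))
  rows <- rows[rows$time_s %in% secs, , drop = FALSE]
  pg_assert(nrow(rows) > 0, "trajectory does not cover the requested periods")
  n_sig <- sum(rows$p_adj < alpha & !is.na(rows$direction) &
                 rows$direction == direction)
  structure(list(
    pair = pair, direction = direction, periods = period_labels,
    alpha = alpha, n_seconds = nrow(rows), n_significant = n_sig,
    proportion = n_sig / nrow(rows)
  ), class = "period_proportion")
}

#' @export
print.period_proportion <- function(x, ...) {
  cat(sprintf("%s > %s over %s: %d / %d analyzed seconds = %.2f%%\n",
              x$direction, setdiff(x$pair, x$direction),
              paste(x$periods, collapse = " u "),
              x$n_significant, x$n_seconds, 100 * x$proportion))
  invisible(x)
}

#' Compare two proportions of significance
#'
#' Two-proportion z test with Yates' continuity correction, computed as the
#' corrected chi-square of the equivalent 2x2 contingency table:
#' `chi2 = (|p1 - p2| - (1/n1 + 1/n2)/2)^2 / (phat (1 - phat) (1/n1 + 1/n2))`
#' with pooled `phat = (x1 + x2) / (n1 + n2)`, the correction clipped so it
#' never overshoots a zero difference, and p from chi-square with 1 df. A
#' degenerate pooled proportion (0 or 1) yields `chi2 = 0`, `p = 1` with a
#' warning.
#'
#' @param a,b `period_proportion` objects (or lists with `n_significant` and
#'   `n_seconds`).
#' @return A `prop_comparison`: both inputs, `chi_sq`, `df` (1), `p_value`.
#' @export
compare_proportions <- function(a, b) {
  x1 <- a$n_significant; n1 <- a$n_seconds
  x2 <- b$n_significant; n2 <- b$n_seconds
  pg_assert(n1 > 0 && n2 > 0, "n_seconds must be > 0 for both proportions")
  p1 <- x1 / n1; p2 <- x2 / n2
  phat <- (x1 + x2) / (n1 + n2)
  if (phat <= 0 || phat >= 1) {
    warning("pooled proportion is degenerate (0 or 1); chi-square set to 0",
            call. = FALSE)
    chi2 <- 0; pv <- 1
  } else {
    inv <- 1 / n1 + 1 / n2
    num <- max(abs(p1 - p2) - inv / 2, 0)
    chi2 <- num^2 / (phat * (1 - phat) * inv)
    pv <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(a = a, b = b, chi_sq = chi2, df = 1L, p_value = pv),
            class = "prop_comparison")
}

#' @export
print.prop_comparison <- function(x, ...) {
  cat(sprintf("two-proportion z test (Yates): %.2f%% (%d/%d) vs %.2f%% (%d/%d)\n",
              100 * x$a$proportion, x$a$n_significant, x$a$n_seconds,
              100 * x$b$proportion, x$b$n_significant, x$b$n_seconds))
  cat(sprintf("  chi-squared = %.4g, df = 1, p = %.4g\n", x$chi_sq, x$p_value))
  invisible(x)
}
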