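# Estimated marginal means and per-second Tukey-adjusted pairwise contrasts.

emm_rows <- function(fit, group_factor, times) {
  design <- fit$design
  pg_assert(group_factor %in% names(design$xlevels),
            sprintf("'%s' is not a parametric factor of the model", group_factor))
  levs <- design$xlevels[[group_factor]]
  others <- setdiff(names(design$xlevels), group_factor)
  other_grid <- if (length(others)) {
    expand.grid(design$xlevels[others], stringsAsFactors = FALSE)
  } else data.frame(row.names = 1)
  n_o <- nrow(other_grid)

  sm_vars <- unique(vapply(Filter(function(b) b$type == "smooth", design$blocks),
                           function(b) b$meta$var, ""))
  nd <- data.frame(
    t_ = rep(times, times = length(levs) * n_o),
    g_ = rep(rep(levs, each = length(times)), times = n_o),
    stringsAsFactors = FALSE
  )
  names(nd) <- c(if (length(sm_vars)) sm_vars[1] else "time_s", group_factor)
  for (v in sm_vars) nd[[v]] <- nd[[1]]
  for (f in others) nd[[f]] <- rep(other_grid[[f]], each = length(times) * length(levs))

  Xn <- design_rows(fit, nd, include_random = FALSE)
  # average over the equally weighted combinations of the other factors
  grp <- rep(seq_len(length(times) * length(levs)), times = n_o)
  L <- rowsum(Xn, grp) / n_o
  list(L = L, levels = levs, times = times)
}

#' Estimated marginal means at a time point
#'
#' Model-based group means at `Time = t_s`: predictions with random effects
#' zeroed and the other parametric factors averaged with equal weights over
#' their levels (the least-squares-means convention).
#'
#' @param fit A `pgam` fit.
#' @param group_factor Parametric factor whose levels are compared.
#' @param t_s Time point (seconds) within the fitted range.
#' @return Data frame: `level`, `emm`, `se`, `df`.
#' @export
emm_at <- function(fit, group_factor, t_s) {
  pg_assert(length(t_s) == 1, "t_s must be a single time point")
  er <- emm_rows(fit, group_factor, t_s)
  mu <- as.numeric(er$L %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((er$L %*% fit$Vb) * er$L), 0))
  data.frame(level = er$levels, emm = mu, se = se, df = fit$df_residual,
             stringsAsFactors = FALSE)
}

#' Per-second Tukey-adjusted pairwise contrast trajectory
#'
#' At every requested time point, all unordered pairs of `group_factor`
#' levels are compared on the EMM scale: `diff = EMM_a - EMM_b`,
#' `t = diff / SE`, and the adjusted p-value is
#' `P(Q[m, df] >= sqrt(2) * |t|)` from the studentized range distribution
#' with `m` group means and `df = n - total edf` (for `m = 2` this reduces
#' analytically to the two-sided t-test, which is used directly). Adjustment
#' is across the pairs at each second only, not across seconds — the
#' per-second workflow's time-wise multiplicity is deliberately left
#' uncorrected and documented.
#'
#' @param fit A `pgam` fit.
#' @param group_factor Parametric factor to compare.
#' @param times Time points (default: the distinct fitted covariate values).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A `contrast_trajectory` data frame: `time_s`, `level_a`,
#'   `level_b`, `pair`, `diff`, `se`, `t_ratio`, `df`, `p_adj`, `direction`,
#'   `significant`.
#' @export
pairwise_trajectory <- function(fit, group_factor, times = NULL, alpha = 0.05) {
  design <- fit$design
  pg_assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  if (is.null(times)) {
    sm <- Filter(function(b) b$type == "smooth", design$blocks)
    tvar <- if (length(sm)) sm[[1]]$meta$var else "time_s"
    times <- sort(unique(as.numeric(design$frame[[tvar]])))
  }
  er <- emm_rows(fit, group_factor, times)
  levs <- er$levels
  m <- length(levs)
  pg_assert(m >= 2, "need at least 2 levels to compare")
  nt <- length(times)
  df <- fit$df_residual

  pairs <- utils::combn(m, 2)
  out <- vector("list", ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    rows_i <- (i - 1L) * nt + seq_len(nt)
    rows_j <- (j - 1L) * nt + seq_len(nt)
    D <- er$L[rows_i, , drop = FALSE] - er$L[rows_j, , drop = FALSE]
    diff <- as.numeric(D %*% fit$coefficients)
    se <- sqrt(pmax(rowSums((D %*% fit$Vb) * D), 0))
    zero_se <- se <= 0
    if (any(zero_se & abs(diff) > 1e-10)) {
      pg_stop("degenerate contrast: zero standard error with a nonzero difference",
              "pg_error_validation")
    }
    tval <- ifelse(zero_se, 0, diff / se)
    p <- if (m == 2) 2 * pt(-abs(tval), df) else
      ptukey(sqrt(2) * abs(tval), nmeans = m, df = df, lower.tail = FALSE)
    p[zero_se] <- 1
    out[[q]] <- data.frame(
      time_s = times,
      level_a = levs[i], level_b = levs[j],
      pair = paste(levs[i], "-", levs[j]),
      diff = diff, se = se, t_ratio = tval, df = df, p_adj = p,
      direction = ifelse(diff > 0, levs[i], ifelse(diff < 0, levs[j], NA)),
      significant = p < alpha & diff != 0,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  attr(out, "alpha") <- alpha
  attr(out, "group_factor") <- group_factor
  attr(out, "n_means") <- m
  class(out) <- c("contrast_trajectory", "data.frame")
  out
}

#' Minimal tile plot of a contrast trajectory
#'
#' One horizontal band per pair; seconds where the pair differs significantly
#' are drawn as ticks colored by which level is larger.
#'
#' @param x A `contrast_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.contrast_trajectory <- function(x, ...) {
  pairs <- unique(x$pair)
  graphics::plot(range(x$time_s), c(0.5, length(pairs) + 0.5), type = "n",
                 xlab = "time (s)", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_along(pairs), labels = pairs, las = 1)
  for (i in seq_along(pairs)) {
    d <- x[x$pair == pairs[i] & x$significant, ]
    if (!nrow(d)) next
    up <- d$direction == d$level_a
    graphics::segments(d$time_s, i - 0.35, d$time_s, i + 0.35,
                       col = ifelse(up, "#1b7837", "#762a83"))
  }
  invisible(x)
}
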