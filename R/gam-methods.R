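# Term-wise inference, basis-dimension adequacy checks and AIC comparison.

pinv <- function(V, tol = 1e-10) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  keep <- e$values > max(abs(e$values)) * tol
  if (!any(keep)) return(matrix(0, nrow(V), ncol(V)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Wald tests for every model term
#'
#' Parametric coefficients get two-sided Wald t-tests on
#' `df = n - total edf` residual degrees of freedom. Each smooth (and
#' random-effect) term gets a Wald quadratic form of its coefficients against
#' the pseudo-inverse of its covariance block, referred to an F distribution
#' with numerator df equal to the rounded term edf (an approximation to the
#' full penalized-smooth test, documented as such).
#'
#' @param fit A `pgam` fit.
#' @return Data frame: `term`, `kind`, `statistic`, `df1`, `df2`, `edf`,
#'   `p_value`.
#' @export
term_tests <- function(fit) {
  pg_assert(inherits(fit, "pgam"), "fit must be a pgam")
  df2 <- fit$df_residual
  out <- list()
  for (b in fit$design$blocks) {
    if (b$type == "parametric") {
      keep <- b$cols[colnames(fit$Vb)[b$cols] != "(Intercept)"]
      for (j in keep) {
        se <- sqrt(fit$Vb[j, j])
        tval <- fit$coefficients[j] / se
        out[[length(out) + 1L]] <- data.frame(
          term = colnames(fit$Vb)[j], kind = "parametric",
          statistic = tval, df1 = 1, df2 = df2, edf = 1,
          p_value = 2 * pt(-abs(tval), df2)
        )
      }
    } else {
      bb <- fit$coefficients[b$cols]
      Vj <- fit$Vb[b$cols, b$cols, drop = FALSE]
      X2 <- as.numeric(bb %*% pinv(Vj) %*% bb)
      df1 <- max(1, round(fit$edf[b$label]))
      Fstat <- X2 / df1
      out[[length(out) + 1L]] <- data.frame(
        term = b$label, kind = if (b$type == "smooth") "smooth" else "random",
        statistic = Fstat, df1 = df1, df2 = df2, edf = fit$edf[b$label],
        p_value = pf(Fstat, df1, df2, lower.tail = FALSE)
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Basis-dimension adequacy check
#'
#' For every smooth: `k_prime` (available basis dimension after the centering
#' constraint), the term's edf, and a residual-roughness index
#' `k_index = mean((r[t+1] - r[t])^2) / (2 * mean(r^2))` over time-adjacent
#' residual pairs within each series. White-noise residuals give an index
#' near 1; unmodeled trend (k too small) leaves positive autocorrelation and
#' pushes the index below 1. A randomization p-value is obtained by permuting
#' the residuals (`n_shuffle` times); a smooth is flagged when its edf is
#' within 0.5 of `k_prime` (saturation) or the p-value falls below `alpha`.
#' When the residual variance is numerically negligible relative to the
#' response variance (a noiseless fit) the check has nothing to measure: the
#' p-value is `NA` and no flags are raised.
#'
#' @param fit A `pgam` fit.
#' @param n_shuffle Number of residual permutations (default 500).
#' @param alpha Flagging threshold for the randomization p-value.
#' @return Data frame: `term`, `k_prime`, `edf`, `k_index`, `p_value`,
#'   `flagged`.
#' @export
check_basis_dimension <- function(fit, n_shuffle = 500, alpha = 0.05) {
  pg_assert(inherits(fit, "pgam"), "fit must be a pgam")
  res <- fit$residuals
  frame <- fit$design$frame
  sm <- Filter(function(b) b$type == "smooth", fit$design$blocks)
  if (!length(sm)) return(data.frame())
  tvar <- sm[[1]]$meta$var
  series_cols <- setdiff(names(frame), tvar)
  series_cols <- series_cols[vapply(frame[series_cols], function(v)
    is.factor(v) || is.character(v), logical(1))]
  series <- if (length(series_cols)) {
    interaction(frame[series_cols], drop = TRUE)
  } else factor(rep(1, length(res)))
  ord <- order(series, frame[[tvar]])
  r <- res[ord]; s <- as.integer(series[ord])
  same <- s[-1] == s[-length(s)]

  msq <- mean(r^2)
  degenerate <- msq < 1e-10 * max(var(fit$y), .Machine$double.eps)
  k_index_of <- function(rr) mean((rr[-1] - rr[-length(rr)])[same]^2) / (2 * mean(rr^2))
  if (!degenerate) {
    obs <- k_index_of(r)
    perm <- vapply(seq_len(n_shuffle), function(i) k_index_of(sample(r)), 0)
    pval <- (1 + sum(perm <= obs)) / (n_shuffle + 1)
  } else {
    obs <- NA_real_; pval <- NA_real_
  }

  out <- do.call(rbind, lapply(sm, function(b) {
    data.frame(
      term = b$label, k_prime = length(b$cols), edf = fit$edf[b$label],
      k_index = obs, p_value = pval,
      # a numerically noiseless fit leaves nothing for the adequacy check to
      # measure: neither the roughness index nor edf saturation is evidence
      # of an undersized basis there
      flagged = !degenerate &&
        ((length(b$cols) - fit$edf[b$label] < 0.5) ||
           (!is.na(pval) && pval < alpha))
    )
  }))
  rownames(out) <- NULL
  out
}

#' Rank fitted models by AIC
#'
#' `AIC = -2 * Gaussian log-likelihood + 2 * (total edf + 1)`, the penalized
#' effective-parameter count (the +1 is the residual variance). Models must
#' have been fitted to identical response data.
#'
#' @param ... `pgam` fits.
#' @param labels Optional model names.
#' @return Data frame sorted by ascending AIC: `model`, `edf`, `aic`,
#'   `delta_aic`.
#' @export
compare_models_aic <- function(..., labels = NULL) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "pgam")) {
    fits <- fits[[1]]
  }
  pg_assert(length(fits) >= 1 && all(vapply(fits, inherits, TRUE, "pgam")),
            "supply pgam fits")
  y0 <- fits[[1]]$y
  for (f in fits[-1]) {
    pg_assert(isTRUE(all.equal(f$y, y0)),
              "models were not fitted to identical response data")
  }
  labels <- labels %||% paste0("model", seq_along(fits))
  out <- data.frame(
    model = labels,
    edf = vapply(fits, function(f) f$edf_total + 1, 0),
    aic = vapply(fits, `[[`, 0, "aic")
  )
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}
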