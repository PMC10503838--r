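# Penalized least-squares fitting with REML or GCV smoothness selection.
#
# At fixed smoothing parameters the estimate is the generalized ridge
# solution beta = (X'X + sum_j lambda_j S_j)^-1 X'y. Smoothing parameters are
# chosen by minimizing the (Gaussian, variance-profiled) restricted
# likelihood
#   2 * nll = (n - Mp) * (log(2 pi phi) + 1) + log|X'X + S_lambda|
#             - log|S_lambda|_+
# with phi = (RSS + beta' S_lambda beta) / (n - Mp) and Mp the total
# unpenalized dimension, or by minimizing GCV = n * RSS / (n - edf)^2.

embed_penalty <- function(S, cols, p) {
  ij <- which(S != 0, arr.ind = TRUE)
  Matrix::sparseMatrix(i = cols[ij[, 1]], j = cols[ij[, 2]], x = S[ij],
                       dims = c(p, p))
}

#' Fit an additive model
#'
#' @param design A `pg_design` from [build_design()].
#' @param selection `"REML"` (default, taken from the spec) or `"GCV"`;
#'   ignored when `lambda` is supplied.
#' @param lambda Optional vector of fixed smoothing parameters, one per
#'   penalized block in design order (smooths first, then random effects);
#'   when given, selection is bypassed and the generalized ridge solution at
#'   those values is returned.
#' @param control List: `maxit` (optimizer iterations, default 500),
#'   `tol` (relative convergence tolerance, default 1e-10).
#' @return A `pgam` fit: coefficients, their covariance `Vb` (scaled by
#'   `sigma2 = RSS / (n - edf)`), per-term effective degrees of freedom,
#'   smoothing parameters, fitted values, deviance explained, AIC and the
#'   design needed for prediction.
#' @export
fit_gam <- function(design, selection = NULL, lambda = NULL,
                    control = list()) {
  pg_assert(inherits(design, "pg_design"), "design must come from build_design()")
  ctrl <- modifyList(list(maxit = 500, tol = 1e-8), control)
  selection <- selection %||% design$spec$selection
  X <- design$X; y <- design$y; n <- design$n; p <- design$p
  blocks <- design$blocks
  pen <- which(vapply(blocks, function(b) !is.null(b$S), logical(1)))
  ranks <- vapply(blocks[pen], `[[`, 0, "rank")
  Mp <- p - sum(ranks)
  pg_assert(n > Mp, "more unpenalized coefficients than observations")

  XtX <- Matrix::forceSymmetric(Matrix::crossprod(X))
  Xty <- as.numeric(Matrix::crossprod(X, y))
  Sfull <- lapply(blocks[pen], function(b) embed_penalty(b$S, b$cols, p))
  tss <- sum((y - mean(y))^2)

  solve_at <- function(lam) {
    A <- XtX
    for (j in seq_along(lam)) A <- A + lam[j] * Sfull[[j]]
    A <- Matrix::forceSymmetric(A)
    ch <- tryCatch(Matrix::Cholesky(A, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- as.numeric(Matrix::solve(ch, Xty))
    fitted <- as.numeric(X %*% beta)
    rss <- sum((y - fitted)^2)
    penv <- 0
    for (j in seq_along(lam)) {
      b <- blocks[[pen[j]]]
      bb <- beta[b$cols]
      penv <- penv + lam[j] * sum(bb * (b$S %*% bb))
    }
    list(A = A, ch = ch, beta = beta, fitted = fitted, rss = rss, penv = penv)
  }

  # log-lambda is clamped to a wide box: beyond it the criterion is flat to
  # machine precision, and the plateau lets the simplex search terminate on
  # otherwise unbounded ridges (e.g. a smooth of a constant signal).
  rho_clamp <- function(rho) pmin(pmax(rho, -25), 25)

  reml_score <- function(rho) {
    rho <- rho_clamp(rho)
    sol <- solve_at(exp(rho))
    if (is.null(sol)) return(1e35)
    phi <- (sol$rss + sol$penv) / (n - Mp)
    if (!is.finite(phi) || phi <= 0) phi <- .Machine$double.xmin
    ldA <- 2 * as.numeric(Matrix::determinant(sol$ch, sqrt = TRUE)$modulus)
    ldS <- sum(ranks * rho) +
      sum(vapply(blocks[pen], `[[`, 0, "logdet_plus"))
    0.5 * ((n - Mp) * (log(2 * pi * phi) + 1) + ldA - ldS)
  }

  edf_trace <- function(sol) {
    M <- Matrix::solve(sol$ch, XtX)
    as.numeric(Matrix::diag(M))
  }

  gcv_score <- function(rho) {
    rho <- rho_clamp(rho)
    sol <- solve_at(exp(rho))
    if (is.null(sol)) return(1e35)
    edf <- sum(edf_trace(sol))
    n * sol$rss / (n - edf)^2
  }

  trace_env <- new.env()
  trace_env$evals <- 0L
  if (is.null(lambda) && length(pen)) {
    score <- if (selection == "REML") reml_score else gcv_score
    score_traced <- function(rho) { trace_env$evals <- trace_env$evals + 1L; score(rho) }
    rho0 <- vapply(seq_along(pen), function(j) {
      b <- blocks[[pen[j]]]
      d <- as.numeric(Matrix::diag(XtX))[b$cols]
      log(max(sum(d), 1e-8) / max(sum(diag(b$S)), 1e-8))
    }, 0)
    if (length(pen) == 1L) {
      opt <- optimize(score_traced, interval = rho0 + c(-18, 18), tol = 1e-7)
      rho_hat <- opt$minimum
      score_val <- opt$objective
    } else {
      opt <- optim(rho0, score_traced, method = "Nelder-Mead",
                   control = list(maxit = ctrl$maxit, reltol = ctrl$tol))
      restarts <- 0L
      while (opt$convergence != 0 && restarts < 3L) {
        # restart the simplex from the incumbent; a restart that no longer
        # improves the criterion counts as converged (plateau optimum)
        opt2 <- optim(opt$par, score_traced, method = "Nelder-Mead",
                      control = list(maxit = ctrl$maxit, reltol = ctrl$tol))
        improved <- opt$value - opt2$value
        if (opt2$value <= opt$value) opt <- opt2
        if (improved < 1e-6 * (abs(opt$value) + 1)) opt$convergence <- 0L
        restarts <- restarts + 1L
      }
      if (opt$convergence != 0) {
        pg_stop(sprintf(
          "smoothing-parameter search did not converge (%d evaluations, last criterion %.6g)",
          trace_env$evals, opt$value), "pg_error_convergence")
      }
      rho_hat <- rho_clamp(opt$par)
      score_val <- opt$value
    }
    lambda <- exp(rho_hat)
  } else if (is.null(lambda)) {
    lambda <- numeric(0)
    score_val <- NA_real_
  } else {
    pg_assert(length(lambda) == length(pen) && all(lambda >= 0),
              sprintf("lambda must supply %d non-negative value(s)", length(pen)))
    score_val <- NA_real_
  }

  sol <- solve_at(lambda)
  if (is.null(sol)) {
    pg_stop("penalized normal equations are rank deficient at the final smoothing parameters",
            "pg_error_convergence")
  }
  diagF <- edf_trace(sol)
  edf_total <- sum(diagF)
  edf <- vapply(blocks, function(b) sum(diagF[b$cols]), 0)
  names(edf) <- vapply(blocks, `[[`, "", "label")
  sigma2 <- sol$rss / (n - edf_total)
  Ainv <- as.matrix(Matrix::solve(sol$ch, Matrix::Diagonal(p)))
  Ainv <- (Ainv + t(Ainv)) / 2
  Vb <- sigma2 * Ainv
  cn <- colnames(X)
  dimnames(Vb) <- list(cn, cn)
  ll <- -n / 2 * (log(2 * pi * sol$rss / n) + 1)

  structure(list(
    coefficients = setNames(sol$beta, cn),
    Vb = Vb,
    lambda = setNames(lambda, vapply(blocks[pen], `[[`, "", "label")),
    edf = edf, edf_total = edf_total,
    sigma2 = sigma2, df_residual = n - edf_total,
    fitted.values = sol$fitted, residuals = y - sol$fitted,
    y = y, rss = sol$rss, tss = tss,
    dev_expl = if (tss > 0) 1 - sol$rss / tss else 0,
    n = n, logLik = ll, aic = -2 * ll + 2 * (edf_total + 1),
    selection = if (length(pen)) selection else NA_character_,
    criterion = score_val,
    design = design
  ), class = "pgam")
}

#' @export
print.pgam <- function(x, ...) {
  cat(sprintf("<pgam> n = %d, total edf = %.2f, deviance explained = %.1f%%\n",
              x$n, x$edf_total, 100 * x$dev_expl))
  cat("terms:\n")
  for (nm in names(x$edf)) cat(sprintf("  %-28s edf %8.3f\n", nm, x$edf[nm]))
  if (length(x$lambda)) {
    cat("lambda:", paste(sprintf("%s = %.4g", names(x$lambda), x$lambda),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

# Rebuild model-matrix rows for new data, in the fitted coefficient order.
design_rows <- function(fit, newdata, include_random = FALSE,
                        allow_extrapolation = FALSE) {
  design <- fit$design
  n_new <- nrow(newdata)
  Xn <- matrix(0, n_new, design$p)
  for (b in design$blocks) {
    if (b$type == "parametric") {
      if (is.null(design$par_terms)) {
        Xn[, b$cols] <- 1
      } else {
        nd <- newdata
        for (f in names(design$xlevels)) {
          pg_assert(f %in% names(nd),
                    sprintf("newdata lacks factor '%s'", f))
          v <- factor(as.character(nd[[f]]), levels = design$xlevels[[f]])
          if (anyNA(v) && !anyNA(nd[[f]])) {
            pg_stop(sprintf("unknown level in factor '%s'", f), "pg_error_lookup")
          }
          nd[[f]] <- v
        }
        tt <- delete.response(design$par_terms)
        mf <- model.frame(tt, nd, xlev = design$xlevels)
        Xn[, b$cols] <- model.matrix(tt, mf)
      }
    } else if (b$type == "smooth") {
      m <- b$meta
      pg_assert(m$var %in% names(newdata),
                sprintf("newdata lacks covariate '%s'", m$var))
      x <- as.numeric(newdata[[m$var]])
      outside <- x < m$xr[1] | x > m$xr[2]
      if (any(outside) && !allow_extrapolation) {
        pg_stop(sprintf("'%s' outside the fitted range [%g, %g]; set allow_extrapolation = TRUE to override",
                        m$var, m$xr[1], m$xr[2]), "pg_error_validation")
      }
      rows <- if (is.na(m$level)) seq_len(n_new) else
        which(as.character(newdata[[m$by]]) == m$level)
      if (length(rows)) {
        B <- pspline_eval(x[rows], m$knots, outer_ok = TRUE)
        Xn[rows, b$cols] <- B %*% m$Z
      }
    } else if (b$type == "random" && include_random) {
      m <- b$meta
      if (m$factor %in% names(newdata)) {
        j <- match(as.character(newdata[[m$factor]]), m$levels)
        ok <- which(!is.na(j))
        Xn[cbind(ok, b$cols[j[ok]])] <- 1
      }
    }
  }
  Xn
}

#' Predict from a fitted additive model
#'
#' @param object A `pgam` fit.
#' @param newdata Data frame with the covariate and factor columns of the
#'   model. When omitted, fitted values are returned.
#' @param include_random Include the random-intercept contribution (matched by
#'   level)? Default `FALSE`: predictions are population-level, with random
#'   effects zeroed.
#' @param se.fit Also return standard errors (`sqrt(x0' Vb x0)`)?
#' @param allow_extrapolation Permit covariate values outside the fitted
#'   range (basis evaluates to its boundary extension)? Default `FALSE`.
#' @param ... Unused.
#' @return A list with `fit` (and `se.fit` plus 95% limits `lwr`/`upr` when
#'   `se.fit = TRUE`), or the `fit` vector alone when `se.fit = FALSE`.
#' @export
predict.pgam <- function(object, newdata = NULL, include_random = FALSE,
                         se.fit = TRUE, allow_extrapolation = FALSE, ...) {
  if (is.null(newdata)) {
    Xn <- as.matrix(object$design$X)
  } else {
    Xn <- design_rows(object, newdata, include_random, allow_extrapolation)
  }
  mu <- as.numeric(Xn %*% object$coefficients)
  if (!se.fit) return(mu)
  se <- sqrt(pmax(rowSums((Xn %*% object$Vb) * Xn), 0))
  list(fit = mu, se.fit = se, lwr = mu - 1.96 * se, upr = mu + 1.96 * se)
}
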