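# Design and penalty construction for the additive model engine.
#
# The linear predictor is: treatment-coded parametric factors (+ intercept),
# one sum-to-zero-constrained cubic B-spline block with a second-order
# difference penalty (P-spline) per smooth (per by-level for factor-by
# smooths), and one ridge-penalized indicator block per random-effect factor
# (a Gaussian random intercept per assay).

#' Declare a smooth term
#'
#' @param var Continuous covariate name (default `"time_s"`).
#' @param k Basis dimension: the number of B-spline basis functions before the
#'   centering constraint, hence the upper limit (`k - 1`) on the smooth's
#'   effective degrees of freedom. Must be >= 3.
#' @param by Optional factor name; a separate smooth of `var` is then
#'   estimated for every level of `by`.
#' @return A `pg_smooth` term descriptor.
#' @export
smooth_term <- function(var = "time_s", k = 130, by = NULL) {
  pg_assert(is.numeric(k) && length(k) == 1 && k >= 3,
            "basis dimension k must be >= 3")
  structure(list(var = var, k = as.integer(k), by = by), class = "pg_smooth")
}

#' Specify an additive model
#'
#' Identity-link Gaussian additive model: parametric factor main effects plus
#' penalized smooths of a continuous covariate (optionally one smooth per
#' factor level) plus random-intercept terms.
#'
#' @param response Response column name (default `"rsums"`).
#' @param parametric Character vector of parametric factor names.
#' @param smooths List of [smooth_term()] descriptors.
#' @param random Character vector of random-intercept factor names (e.g. the
#'   assay identifier).
#' @param selection Smoothing-parameter selection criterion, `"REML"`
#'   (default) or `"GCV"`.
#' @return A `pg_spec` object.
#' @export
model_spec <- function(response = "rsums", parametric = character(),
                       smooths = list(), random = character(),
                       selection = c("REML", "GCV")) {
  selection <- match.arg(selection)
  pg_assert(length(response) == 1, "exactly one response")
  for (sm in smooths) {
    pg_assert(inherits(sm, "pg_smooth"), "smooths must be smooth_term() objects")
    if (!is.null(sm$by)) {
      pg_assert(sm$by %in% parametric,
                sprintf("by-factor '%s' must also appear as a parametric factor",
                        sm$by))
    }
  }
  structure(list(response = response, parametric = parametric,
                 smooths = smooths, random = random, selection = selection),
            class = "pg_spec")
}

# Cubic B-spline basis on equally spaced knots spanning xr; k basis columns.
pspline_knots <- function(k, xr) {
  h <- diff(xr) / (k - 3)
  xr[1] + h * (-3:k)
}

pspline_eval <- function(x, knots, outer_ok = FALSE) {
  splines::splineDesign(knots, x, ord = 4, outer.ok = outer_ok)
}

# Null-space transform of a single linear constraint c'beta = 0.
constraint_null <- function(cons) {
  qr.Q(qr(matrix(cons, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
}

#' Build the design and penalty blocks of a model
#'
#' Each smooth is centered (sum-to-zero over the observed rows of its level)
#' so that parametric main effects stay estimable; its quadratic penalty is
#' the second-order difference penalty transformed into the constrained
#' basis. Random-effect factors contribute an indicator block with an
#' identity (ridge) penalty.
#'
#' @param spec A `pg_spec`.
#' @param data A data frame (typically a `group_series`) containing the
#'   response, the smooth covariates and all declared factors.
#' @return A `pg_design`: response vector `y`, sparse model matrix `X`, and a
#'   list of `blocks` carrying column indices, penalties, ranks and the
#'   metadata needed to rebuild basis rows at prediction time.
#' @export
build_design <- function(spec, data) {
  pg_assert(inherits(spec, "pg_spec"), "spec must come from model_spec()")
  pg_assert(spec$response %in% names(data),
            sprintf("response '%s' not found in data", spec$response))
  y <- as.numeric(data[[spec$response]])
  pg_assert(all(is.finite(y)), "response contains non-finite values")
  n <- length(y)

  for (f in c(spec$parametric, spec$random)) {
    pg_assert(f %in% names(data), sprintf("factor '%s' not found in data", f))
    if (!is.factor(data[[f]])) {
      data[[f]] <- factor(data[[f]], levels = canonical_levels(data[[f]]))
    }
    data[[f]] <- droplevels(data[[f]])
  }

  blocks <- list()
  Xparts <- list()
  col0 <- 0L

  # parametric part (always includes the intercept)
  if (length(spec$parametric)) {
    par_terms <- terms(reformulate(spec$parametric))
    mf <- model.frame(par_terms, data)
    Xp <- model.matrix(par_terms, mf)
    xlevels <- lapply(setNames(spec$parametric, spec$parametric),
                      function(f) levels(data[[f]]))
  } else {
    par_terms <- NULL
    Xp <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    xlevels <- list()
  }
  blocks[[length(blocks) + 1L]] <- list(
    label = "parametric", type = "parametric",
    cols = col0 + seq_len(ncol(Xp)), S = NULL, rank = 0L, logdet_plus = 0,
    meta = list(coef_names = colnames(Xp))
  )
  Xparts[[length(Xparts) + 1L]] <- Matrix::Matrix(Xp, sparse = TRUE)
  col0 <- col0 + ncol(Xp)

  # smooth blocks
  for (sm in spec$smooths) {
    pg_assert(sm$var %in% names(data),
              sprintf("smooth covariate '%s' not found in data", sm$var))
    x_all <- as.numeric(data[[sm$var]])
    xr <- range(x_all)
    if (length(unique(x_all)) < 2 * sm$k) {
      pg_stop(sprintf(
        "smooth of '%s' with k = %d needs at least %d distinct covariate values (%d found)",
        sm$var, sm$k, 2 * sm$k, length(unique(x_all))), "pg_error_basis")
    }
    knots <- pspline_knots(sm$k, xr)
    D <- diff(diag(sm$k), differences = 2)
    lev_set <- if (is.null(sm$by)) NA_character_ else levels(data[[sm$by]])
    for (lev in lev_set) {
      rows <- if (is.na(lev)) seq_len(n) else which(data[[sm$by]] == lev)
      if (!length(rows)) {
        pg_stop(sprintf("no data for by-level '%s' of smooth on '%s'",
                        lev, sm$var), "pg_error_basis")
      }
      B <- pspline_eval(x_all[rows], knots)
      Z <- constraint_null(colSums(B))
      Bc <- B %*% Z
      S <- crossprod(D %*% Z)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      rk <- sum(ev > max(ev) * 1e-9)
      label <- if (is.na(lev)) sprintf("s(%s)", sm$var) else
        sprintf("s(%s):%s%s", sm$var, sm$by, lev)
      Xs <- Matrix::sparseMatrix(
        i = rep(rows, ncol(Bc)),
        j = rep(seq_len(ncol(Bc)), each = length(rows)),
        x = as.vector(Bc), dims = c(n, ncol(Bc)),
        dimnames = list(NULL, paste0(label, ".", seq_len(ncol(Bc))))
      )
      blocks[[length(blocks) + 1L]] <- list(
        label = label, type = "smooth",
        cols = col0 + seq_len(ncol(Bc)), S = S, rank = rk,
        logdet_plus = sum(log(ev[ev > max(ev) * 1e-9])),
        meta = list(var = sm$var, k = sm$k, by = sm$by, level = lev,
                    knots = knots, Z = Z, xr = xr)
      )
      Xparts[[length(Xparts) + 1L]] <- Xs
      col0 <- col0 + ncol(Bc)
    }
  }

  # random-intercept blocks (ridge-penalized indicators)
  for (rf in spec$random) {
    f <- data[[rf]]
    nl <- nlevels(f)
    Xr <- Matrix::sparseMatrix(
      i = seq_len(n), j = as.integer(f), x = 1, dims = c(n, nl),
      dimnames = list(NULL, paste0(rf, levels(f)))
    )
    blocks[[length(blocks) + 1L]] <- list(
      label = paste0("s(", rf, ")"), type = "random",
      cols = col0 + seq_len(nl), S = diag(nl), rank = nl, logdet_plus = 0,
      meta = list(factor = rf, levels = levels(f))
    )
    Xparts[[length(Xparts) + 1L]] <- Xr
    col0 <- col0 + nl
  }

  X <- do.call(cbind, Xparts)
  frame <- data[, setdiff(names(data), spec$response), drop = FALSE]
  structure(
    list(y = y, X = X, blocks = blocks, spec = spec, n = n, p = ncol(X),
         par_terms = par_terms, xlevels = xlevels, frame = frame),
    class = "pg_design"
  )
}

#' @export
print.pg_design <- function(x, ...) {
  cat(sprintf("<pg_design> n = %d, p = %d; blocks: %s\n", x$n, x$p,
              paste(vapply(x$blocks, `[[`, "", "label"), collapse = ", ")))
  invisible(x)
}
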