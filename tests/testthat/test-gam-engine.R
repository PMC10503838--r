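make_series <- function(n = 300, n_lev = 3, seed = 1, noise = 0.3,
                        effect = c(0, 0, 0)) {
  set.seed(seed)
  levs <- c("WT", "HT", "HM")[seq_len(n_lev)]
  df <- expand.grid(time_s = seq(0, 99, length.out = n / n_lev / 2),
                    assay_id = c("a1", "a2"), geno = levs,
                    stringsAsFactors = FALSE)
  df$geno <- factor(df$geno, levels = levs)
  df$rsums <- 10 + sin(df$time_s / 12) + effect[as.integer(df$geno)] +
    rnorm(nrow(df), 0, noise)
  df
}

test_that("design dimensions follow the constrained basis bookkeeping", {
  df <- make_series(n = 360)
  spec <- model_spec("rsums", "geno",
                     list(smooth_term("time_s", 10, by = "geno")), "assay_id")
  d <- build_design(spec, df)
  sm <- Filter(function(b) b$type == "smooth", d$blocks)
  expect_length(sm, 3)
  for (b in sm) expect_length(b$cols, 9) # k - 1 after centering
  re <- Filter(function(b) b$type == "random", d$blocks)[[1]]
  expect_length(re$cols, 2)
  expect_equal(re$S, diag(2))
  expect_equal(d$p, 1 + 2 + 3 * 9 + 2)

  expect_error(smooth_term("time_s", 2), class = "pg_error_validation")
  # too few distinct covariate values for the requested k
  small <- df[df$time_s %in% unique(df$time_s)[1:8], ]
  expect_error(build_design(model_spec("rsums", "geno",
                                       list(smooth_term("time_s", 10, by = "geno"))),
                            small),
               class = "pg_error_basis")
})

test_that("fitting at frozen lambda reproduces the dense ridge solution", {
  rd <- random_small_design(101)
  fit <- fit_gam(rd$design, lambda = rd$lambda)
  oracle <- dense_ridge_solve(rd$design, rd$lambda)
  expect_lt(max(abs(fit$coefficients - oracle)) / max(abs(oracle)), 1e-8)
})

test_that("a constant response yields a null fit", {
  df <- make_series(n = 300, noise = 0)
  df$rsums <- 7.5
  spec <- model_spec("rsums", smooths = list(smooth_term("time_s", 10)))
  fit <- fit_gam(build_design(spec, df))
  # the penalty drives the smooth to its unpenalized null space: for a
  # second-difference penalty that is the (centered) linear trend, one
  # effective degree of freedom, whose coefficient is 0 for constant data
  expect_lte(fit$edf["s(time_s)"], 1.01)
  expect_lt(fit$dev_expl, 1e-6)
  expect_equal(unname(fit$fitted.values), rep(7.5, nrow(df)))
})

test_that("a curve inside the basis span is recovered noiselessly", {
  set.seed(2)
  x <- seq(0, 100, length.out = 400)
  spec <- model_spec("rsums", smooths = list(smooth_term("time_s", 12)))
  d0 <- build_design(spec, data.frame(time_s = x, rsums = 0))
  beta <- c(5, rnorm(11, 0, 2))
  y <- as.numeric(d0$X %*% beta)
  fit <- fit_gam(build_design(spec, data.frame(time_s = x, rsums = y)))
  expect_gte(fit$dev_expl, 0.999)
  chk <- check_basis_dimension(fit, n_shuffle = 99)
  expect_false(any(chk$flagged))
})

test_that("edf accounting is additive and monotone in lambda", {
  rd <- random_small_design(77)
  fit <- fit_gam(rd$design, lambda = rd$lambda)
  # independent dense trace of the influence matrix
  X <- as.matrix(rd$design$X)
  P <- matrix(0, ncol(X), ncol(X))
  pen <- Filter(function(b) !is.null(b$S), rd$design$blocks)
  for (j in seq_along(pen)) {
    P[pen[[j]]$cols, pen[[j]]$cols] <- rd$lambda[j] * pen[[j]]$S
  }
  Fmat <- solve(crossprod(X) + P, crossprod(X))
  expect_lt(abs(fit$edf_total - sum(diag(Fmat))), 1e-6)
  expect_equal(sum(fit$edf), fit$edf_total, tolerance = 1e-9)

  df <- make_series(n = 200, n_lev = 1)
  spec <- model_spec("rsums", smooths = list(smooth_term("time_s", 12)))
  d <- build_design(spec, df)
  edfs <- vapply(10^seq(-4, 4, by = 1),
                 function(l) fit_gam(d, lambda = l)$edf["s(time_s)"], 0)
  expect_true(all(diff(edfs) < 1e-8))
})

test_that("REML fits agree with an independent penalized-spline implementation", {
  set.seed(7)
  n <- 400
  x <- sort(runif(n, 0, 10))
  y <- 3 + sin(x) + 0.5 * cos(2.3 * x) + rnorm(n, 0, 0.3)
  df <- data.frame(time_s = x, rsums = y)
  spec <- model_spec("rsums", smooths = list(smooth_term("time_s", 15)))
  fit <- fit_gam(build_design(spec, df))
  g <- mgcv::gam(rsums ~ s(time_s, bs = "ps", k = 15, m = c(2, 2)),
                 data = df, method = "REML")
  expect_lt(max(abs(fit$fitted.values - fitted(g))), 0.01 * sd(y))
  expect_lt(abs(fit$edf_total - sum(g$edf)), 0.5)
  expect_lt(abs(fit$sigma2 - g$sig2) / g$sig2, 0.02)
  nd <- data.frame(time_s = c(1.5, 5, 8.7))
  pm <- predict(fit, nd)
  pg <- mgcv::predict.gam(g, nd, se.fit = TRUE)
  expect_lt(max(abs(pm$fit - as.numeric(pg$fit))), 0.01 * sd(y))
  expect_lt(max(abs(pm$se.fit - as.numeric(pg$se.fit)) / as.numeric(pg$se.fit)), 0.05)
})

test_that("parametric Wald p-values are roughly uniform under the null", {
  ps <- vapply(1:60, function(s) {
    df <- make_series(n = 240, seed = s, noise = 0.5)
    spec <- model_spec("rsums", "geno",
                       list(smooth_term("time_s", 8)), character())
    tt <- term_tests(fit_gam(build_design(spec, df)))
    tt$p_value[tt$term == "genoHM"]
  }, 0)
  expect_gte(mean(ps < 0.05), 0)      # sanity
  expect_lte(mean(ps < 0.05), 0.15)   # no gross anti-conservatism
  expect_gt(mean(ps > 0.5), 0.25)     # p-values spread over (0, 1)
})

test_that("smooth term tests separate flat from structured by-levels", {
  set.seed(9)
  df <- make_series(n = 360, noise = 0.3)
  # remove the time structure from HM only
  df$rsums[df$geno == "HM"] <- 10 + rnorm(sum(df$geno == "HM"), 0, 0.3)
  spec <- model_spec("rsums", "geno",
                     list(smooth_term("time_s", 10, by = "geno")))
  tt <- term_tests(fit_gam(build_design(spec, df)))
  p_wt <- tt$p_value[tt$term == "s(time_s):genoWT"]
  p_hm <- tt$p_value[tt$term == "s(time_s):genoHM"]
  expect_lt(p_wt, 1e-6)
  expect_gt(p_hm, 0.05)
})

test_that("basis check flags deliberate underfitting but not white residuals", {
  set.seed(12)
  x <- seq(0, 100, length.out = 500)
  y_fast <- sin(x) + rnorm(500, 0, 0.2) # wiggles far beyond a k=4 basis
  fit_small <- fit_gam(build_design(
    model_spec("rsums", smooths = list(smooth_term("time_s", 4))),
    data.frame(time_s = x, rsums = y_fast)))
  chk <- check_basis_dimension(fit_small, n_shuffle = 199)
  expect_lt(chk$k_index, 0.8)
  expect_true(chk$flagged)

  y_ok <- sin(x / 20) + rnorm(500, 0, 0.3)
  fit_ok <- fit_gam(build_design(
    model_spec("rsums", smooths = list(smooth_term("time_s", 12))),
    data.frame(time_s = x, rsums = y_ok)))
  chk2 <- check_basis_dimension(fit_ok, n_shuffle = 199)
  expect_gt(chk2$k_index, 0.8)
  expect_gt(chk2$p_value, 0.01)

  # saturated smooth (lambda forced to ~0) trips the edf-saturation rule
  fit_sat <- fit_gam(build_design(
    model_spec("rsums", smooths = list(smooth_term("time_s", 6))),
    data.frame(time_s = x, rsums = y_ok)), lambda = 1e-10)
  chk3 <- check_basis_dimension(fit_sat, n_shuffle = 99)
  expect_true(chk3$flagged)
})

test_that("AIC ranking prefers the structured model and is reproducible", {
  df <- make_series(n = 300, noise = 0.3, effect = c(0, 1, -2))
  spec_full <- model_spec("rsums", "geno", list(smooth_term("time_s", 10)))
  spec_null <- model_spec("rsums")
  d_full <- build_design(spec_full, df)
  f1 <- fit_gam(d_full)
  f1b <- fit_gam(d_full)
  f0 <- fit_gam(build_design(spec_null, df))
  expect_identical(f1$aic, f1b$aic)
  cmp <- compare_models_aic(f1, f0, labels = c("full", "intercept"))
  expect_equal(cmp$model[1], "full")
  expect_gt(cmp$delta_aic[2], 2)

  df2 <- make_series(n = 300, seed = 99)
  f2 <- fit_gam(build_design(spec_null, df2))
  expect_error(compare_models_aic(f1, f2), class = "pg_error_validation")
})

test_that("prediction is consistent with the fit and guards its range", {
  df <- make_series(n = 240)
  spec <- model_spec("rsums", "geno",
                     list(smooth_term("time_s", 8, by = "geno")), "assay_id")
  fit <- fit_gam(build_design(spec, df))
  pr <- predict(fit, df[17, ], include_random = TRUE)
  expect_equal(pr$fit, fit$fitted.values[17], tolerance = 1e-10)

  # intercept-only closed form
  f0 <- fit_gam(build_design(model_spec("rsums"), df))
  p0 <- predict(f0, df[1, , drop = FALSE])
  expect_equal(p0$fit, mean(df$rsums))
  expect_equal(p0$se.fit, sqrt(f0$sigma2 / nrow(df)), tolerance = 1e-10)

  expect_error(predict(fit, data.frame(time_s = 1e5, geno = "WT", assay_id = "a1")),
               class = "pg_error_validation")
  out <- predict(fit, data.frame(time_s = 1e5, geno = "WT", assay_id = "a1"),
                 allow_extrapolation = TRUE)
  expect_true(is.finite(out$fit))
})
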