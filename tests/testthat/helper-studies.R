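# Shared study constructors for unit and acceptance tests. All fixtures are
# generated in code; nothing is read from disk.

# Genotype set with no effect anywhere (type-I calibration studies).
null_genotypes <- function() {
  g <- list(dark_mult = 1, light_mult = 1, rebound_halfsat_min = 1)
  list(WT = g, HT = g, HM = g)
}

# One replicate of the type-I calibration study: constant-dark 600-s baseline
# protocol (2-min acclimation + 8-min analysis), 6 assays x 3 genotypes x 16
# fish, aggregated at a 60-s stride so rolling windows do not overlap.
# Returns the HM main-effect p-value and the per-second WT-greater-than-HM
# proportion of significance over the analysis window.
run_null_study <- function(seed) {
  reg <- build_baseline_regimen(8 / 60, "IR_only", acclim_min = 2)
  cfg <- sim_config(regimen = reg, n_assays = 6, n_fish_per_group = 16,
                    groups = null_genotypes(), seed = seed)
  st <- simulate_study(cfg)
  gs <- aggregate_group_mean(st$traces, stride_s = 60, start_s = 120)
  spec <- model_spec("rsums", "geno",
                     list(smooth_term("time_s", 4, by = "geno")), "assay_id")
  fit <- fit_gam(build_design(spec, gs))
  tt <- term_tests(fit)
  traj <- pairwise_trajectory(fit, "geno", times = seq(120, max(gs$time_s)))
  pp <- proportion_significant(traj, reg, "baseline", c("WT", "HM"), "WT")
  list(p_hm = tt$p_value[tt$term == "genoHM"], prop = pp$proportion)
}

# One arm of the rebound-recovery study: reduced dark-light repeat protocol
# (10-min acclimation + 2 x [7.5-min dark + light_min light] + 5-min final
# dark), WT vs HM at the default mechanism, 6 assays x 12 fish, per-second
# analysis; the smooth basis is kept coarser than the 60-s rolling window
# (k = 20) so period plateaus and the rebound are tracked but the window's
# boundary ramp is not chased.
run_recovery_arm <- function(seed, light_min) {
  reg <- build_repeat_regimen(10, 2, 7.5, light_min, 5)
  cfg <- sim_config(regimen = reg, n_assays = 6, n_fish_per_group = 12,
                    groups = default_genotypes()[c("WT", "HM")], seed = seed)
  st <- simulate_study(cfg)
  gs <- aggregate_group_mean(st$traces, stride_s = 1, start_s = 600)
  spec <- model_spec("rsums", "geno",
                     list(smooth_term("time_s", 20, by = "geno")), "assay_id")
  fit <- fit_gam(build_design(spec, gs))
  tt <- term_tests(fit)
  darks <- c("dark2", "dark3")
  traj <- pairwise_trajectory(fit, "geno",
                              times = unlist(lapply(darks, period_seconds,
                                                    regimen = reg)))
  pp <- proportion_significant(traj, reg, darks, c("WT", "HM"), "WT")
  list(p_hm = tt$p_value[tt$term == "genoHM"], prop = pp$proportion)
}

# A random small penalized design plus random fixed smoothing parameters,
# for fitter-vs-dense-oracle equivalence checks.
random_small_design <- function(seed) {
  set.seed(seed)
  n <- sample(80:400, 1)
  k <- sample(5:15, 1)
  n_lev <- sample(1:3, 1)
  use_re <- runif(1) < 0.5
  df <- data.frame(
    time_s = sort(runif(n, 0, 100)),
    geno = factor(sample(paste0("g", seq_len(n_lev)), n, replace = TRUE)),
    assay_id = sample(sprintf("a%d", 1:4), n, replace = TRUE)
  )
  df$rsums <- rnorm(n, 10, 3) + as.numeric(df$geno) + sin(df$time_s / 7)
  spec <- model_spec(
    "rsums",
    parametric = if (n_lev > 1) "geno" else character(),
    smooths = list(smooth_term("time_s", k,
                               by = if (n_lev > 1) "geno" else NULL)),
    random = if (use_re) "assay_id" else character()
  )
  design <- build_design(spec, df)
  n_pen <- sum(vapply(design$blocks, function(b) !is.null(b$S), logical(1)))
  list(design = design, lambda = exp(runif(n_pen, -3, 3)))
}

# Dense-matrix generalized ridge solve, the independent oracle for fit_gam
# at frozen smoothing parameters.
dense_ridge_solve <- function(design, lambda) {
  X <- as.matrix(design$X)
  P <- matrix(0, ncol(X), ncol(X))
  pen <- Filter(function(b) !is.null(b$S), design$blocks)
  for (j in seq_along(pen)) {
    P[pen[[j]]$cols, pen[[j]]$cols] <- lambda[j] * pen[[j]]$S
  }
  solve(crossprod(X) + P, crossprod(X, design$y))
}

# Brute-force O(n * w) trailing window sum.
brute_rolling_sum <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in w:n) {
    s <- 0
    for (i in (t - w + 1):t) s <- s + x[i]
    out[t] <- s
  }
  out
}

# Tiny in-memory well_traces builder for aggregation tests.
make_traces <- function(mat, assay, geno, well = sprintf("w%02d", seq_len(ncol(mat)))) {
  wells <- data.frame(assay_id = assay, well_id = well,
                      geno = factor(geno, levels = photogam:::canonical_levels(geno)),
                      stringsAsFactors = FALSE)
  photogam:::new_well_traces(mat, wells, "geno")
}
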