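test_that("degenerate zero-inflation produces an all-zero trace", {
  cfg <- sim_config(regimen = build_repeat_regimen(2, 1, 2, 2, 2),
                    zero_inflation_dark = 1, zero_inflation_light = 1, seed = 1)
  expect_true(all(simulate_well(cfg, 0, "WT", seed = 9) == 0))
})

test_that("stationary traces match the zero-inflated Gamma moments", {
  reg <- build_baseline_regimen(10000 / 3600, "IR_only")
  cfg <- sim_config(regimen = reg, onset_spike_amp = 0, rebound_amp = 0,
                    zero_inflation_dark = 0.6, zero_inflation_light = 0.6,
                    base_rate_dark = 0.5, base_rate_light = 0.5,
                    burst_shape = 0.7, burst_scale = 2.0, seed = 1)
  x <- simulate_well(cfg, 0, "WT", seed = 42)
  mu <- (1 - 0.6) * 0.7 * 2.0 * 0.5
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(length(x)))
})

test_that("saturating rebound fraction follows the Michaelis form", {
  expect_equal(rebound_fraction(2, 1), 2 / 3)
  expect_equal(rebound_fraction(2, 6), 1 / 4)
  expect_equal(rebound_fraction(1, 1), 1 / 2) # half the ceiling at halfsat
  expect_equal(rebound_fraction(0, 3), 0)
})

test_that("dark rebound in the rate profile is duration- and genotype-graded", {
  for (L in c(2, 7.5)) {
    reg <- build_repeat_regimen(2, 1, 2, L, 5)
    cfg <- sim_config(regimen = reg, onset_spike_amp = 0)
    dark2 <- reg$periods[reg$periods$label == "dark2", ]
    for (g in c("WT", "HM")) {
      rp <- photogam:::rate_profile(cfg, g)
      base_dark <- cfg$base_rate_dark * cfg$groups[[g]]$dark_mult
      # first second of the post-light dark carries the full saturating factor
      frac <- rebound_fraction(L, cfg$groups[[g]]$rebound_halfsat_min)
      expect_equal(rp$rate[dark2$start_s + 1] / base_dark,
                   1 + cfg$rebound_amp * frac, tolerance = 1e-10)
    }
  }
  # non-decreasing in light duration, non-increasing in half-saturation
  d <- c(0.5, 1, 2, 4, 6, 7.5)
  expect_true(all(diff(rebound_fraction(d, 1)) >= 0))
  hs <- c(0.5, 1, 2, 6, 10)
  expect_true(all(diff(rebound_fraction(2, hs)) <= 0))
})

test_that("expected trajectories place light above dark baseline", {
  reg <- build_repeat_regimen(2, 1, 3, 3, 3)
  cfg <- sim_config(regimen = reg)
  ex <- photogam:::expected_movement(cfg, "WT")
  light1 <- period_seconds(reg, "light1") + 1L
  dark1 <- period_seconds(reg, "dark1") + 1L
  expect_gt(mean(ex[light1]), mean(ex[dark1]))
})

test_that("empirical zero fraction converges to the configured probability", {
  reg <- build_baseline_regimen(1e5 / 3600, "IR_only")
  cfg <- sim_config(regimen = reg, zero_inflation_dark = 0.65, seed = 1)
  x <- simulate_well(cfg, 0, "WT", seed = 77)
  n <- length(x)
  p_hat <- mean(x == 0)
  ci <- 0.65 + c(-1, 1) * qnorm(0.999) * sqrt(0.65 * 0.35 / n)
  expect_gt(p_hat, ci[1]); expect_lt(p_hat, ci[2])
})

test_that("positive movement distances are right-skewed", {
  cfg <- sim_config(regimen = build_repeat_regimen(2, 2, 3, 3, 3), seed = 4)
  x <- simulate_well(cfg, 0, "WT", seed = 5)
  pos <- x[x > 0]
  skew <- mean((pos - mean(pos))^3) / sd(pos)^3
  expect_gt(skew, 0)
})

test_that("study simulation is deterministic and byte-identical on disk", {
  cfg <- sim_config(regimen = build_repeat_regimen(1, 1, 1, 1, 1),
                    n_assays = 2, n_fish_per_group = 3, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_study(cfg, d1)
  s2 <- simulate_study(cfg, d2)
  expect_identical(s1$traces$distance, s2$traces$distance)
  for (f in c("traces.csv", "metadata.csv", "regimen.json", "sim_truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # per-well substreams: a well can be regenerated in isolation (layout is
  # assay-major with 3 fish per genotype, so assay 2's first HT fish is
  # within-assay well 4, column 9 + 4)
  w <- simulate_well(cfg, s1$truth$assay_effects$assay02, "HT",
                     seed = photogam:::well_seed(7, 2, 4))
  expect_identical(s1$traces$distance[, 13], w)
})

test_that("zero assay variability yields exactly zero assay effects", {
  cfg <- sim_config(regimen = build_repeat_regimen(1, 1, 1, 1, 1),
                    n_assays = 4, n_fish_per_group = 2, assay_sd = 0, seed = 3)
  st <- simulate_study(cfg)
  expect_true(all(unlist(st$truth$assay_effects) == 0))
})

test_that("simulator truth matches the analytical expected rolling sums", {
  reg <- build_repeat_regimen(2, 1, 2, 2, 2)
  cfg <- sim_config(regimen = reg, n_assays = 40, n_fish_per_group = 12,
                    groups = default_genotypes()["WT"], assay_sd = 0, seed = 8)
  st <- simulate_study(cfg)
  gs <- aggregate_group_mean(st$traces, stride_s = 1, start_s = 59)
  emp <- tapply(gs$rsums, gs$time_s, mean)
  truth <- st$truth$expected_rsums$WT[-(1:59)]
  # grand-mean trajectory over 480 fish tracks the analytical expectation
  expect_lt(mean(abs(emp - truth)) / mean(truth), 0.05)
})
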