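test_that("rolling sum obeys its closed-form cases", {
  r <- rolling_sum(rep(1, 120))
  expect_true(all(is.na(r[1:59])))
  expect_true(all(r[60:120] == 60))

  expect_true(all(rolling_sum(rep(0, 200))[60:200] == 0))

  # 5-mm impulse at 0-based second 100 covers defined seconds 100..159
  x <- rep(0, 300); x[101] <- 5
  r <- rolling_sum(x)
  t0 <- seq_along(x) - 1L
  expect_true(all(r[!is.na(r) & t0 >= 100 & t0 <= 159] == 5))
  expect_true(all(r[!is.na(r) & (t0 < 100 | t0 > 159)] == 0))

  expect_error(rolling_sum(rep(1, 10), 60), class = "pg_error_validation")
  expect_error(rolling_sum(rep(1, 10), 0), class = "pg_error_validation")
})

test_that("rolling sum matches the brute-force double loop", {
  set.seed(11)
  for (i in 1:5) {
    w <- sample(c(5, 17, 60), 1)
    x <- round(rgamma(400, 0.5, 1), 3)
    expect_equal(rolling_sum(x, w), brute_rolling_sum(x, w), tolerance = 1e-12)
  }
  xi <- sample(0:20, 500, replace = TRUE)
  expect_identical(rolling_sum(xi, 60), brute_rolling_sum(xi, 60))
})

test_that("window telescoping conserves total distance", {
  set.seed(3)
  x <- rgamma(600, 0.6, 1)
  r <- rolling_sum(x, 60)
  # non-overlapping windows ending at 0-based seconds 59, 119, ... tile [0, 600)
  ends <- seq(60, 600, by = 60)
  expect_equal(sum(r[ends]), sum(x), tolerance = 1e-10)
})

test_that("trace CSV round-trip preserves wells and rejects malformed input", {
  m <- matrix(round(rgamma(120 * 4, 0.5, 1), 3), 120, 4)
  tr <- make_traces(m, assay = rep(c("a1", "a2"), each = 2),
                    geno = rep(c("WT", "HM"), 2))
  dir <- withr::local_tempdir()
  tp <- file.path(dir, "traces.csv"); mp <- file.path(dir, "meta.csv")
  write_well_traces(tr, tp, mp)
  rd <- read_well_traces(tp, mp)
  expect_equal(rd$n_seconds, 120)
  expect_equal(unname(rd$distance), unname(tr$distance))
  expect_equal(as.character(rd$wells$geno), as.character(tr$wells$geno))
  expect_equal(levels(rd$wells$geno), c("WT", "HM")) # canonical ordering

  # a skipped second is a gap error naming the well
  long <- read.csv(tp)
  long2 <- long[!(long$well_id == "w02" & long$time_s == 50), ]
  tp2 <- file.path(dir, "gap.csv")
  write.csv(long2, tp2, row.names = FALSE)
  expect_error(read_well_traces(tp2, mp), "w02")

  # negative distances rejected
  long3 <- long; long3$distance_mm[5] <- -1
  tp3 <- file.path(dir, "neg.csv")
  write.csv(long3, tp3, row.names = FALSE)
  expect_error(read_well_traces(tp3, mp), class = "pg_error_validation")

  # factor level outside a declared domain rejected
  expect_error(
    read_well_traces(tp, mp, factor_domains = list(geno = c("WT", "HT"))),
    class = "pg_error_validation"
  )
})

test_that("group aggregation averages fish within assay cells", {
  x <- rgamma(200, 0.6, 1)
  m <- cbind(x, x)
  tr <- make_traces(m, assay = c("a1", "a1"), geno = c("WT", "WT"))
  gs <- aggregate_group_mean(tr, stride_s = 1)
  expect_equal(gs$rsums, rolling_sum(x)[-(1:59)])

  a <- rgamma(200, 0.6, 1); b <- rgamma(200, 0.6, 1)
  tr2 <- make_traces(cbind(a, b), assay = c("a1", "a1"), geno = c("WT", "WT"))
  gs2 <- aggregate_group_mean(tr2, stride_s = 1)
  expect_equal(gs2$rsums, ((rolling_sum(a) + rolling_sum(b)) / 2)[-(1:59)])
})

test_that("aggregation is invariant to trace order and counts cells correctly", {
  set.seed(21)
  m <- matrix(rgamma(150 * 6, 0.5, 1), 150, 6)
  geno <- rep(c("WT", "HM"), each = 3)
  tr <- make_traces(m, assay = rep("a1", 6), geno = geno)
  perm <- c(4, 1, 6, 2, 5, 3)
  tr_p <- make_traces(m[, perm], assay = rep("a1", 6), geno = geno[perm],
                      well = sprintf("w%02d", perm))
  g1 <- aggregate_group_mean(tr)
  g2 <- aggregate_group_mean(tr_p)
  expect_equal(g1$rsums, g2$rsums)
  # one series per (assay x genotype) cell
  expect_equal(nrow(unique(g1[c("assay_id", "geno")])), 2)
})

test_that("empty assay-by-group cells are dropped with a warning", {
  m <- matrix(rgamma(120 * 3, 0.5, 1), 120, 3)
  tr <- make_traces(m, assay = c("a1", "a1", "a2"), geno = c("WT", "HM", "WT"))
  expect_warning(gs <- aggregate_group_mean(tr), "empty")
  expect_equal(nrow(unique(gs[c("assay_id", "geno")])), 3)
})

test_that("simulated study counts and shapes match the layout", {
  cfg <- sim_config(regimen = build_repeat_regimen(2, 1, 2, 2, 2),
                    n_assays = 6, n_fish_per_group = 16, seed = 2)
  st <- simulate_study(cfg)
  expect_equal(ncol(st$traces$distance), 6 * 3 * 16)
  expect_equal(nrow(st$traces$distance), regimen_duration(cfg$regimen))
  gs <- aggregate_group_mean(st$traces, stride_s = 1, start_s = 120)
  expect_equal(nrow(unique(gs[c("assay_id", "geno")])), 18)
})
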