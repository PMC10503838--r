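# Zero-inflated Gamma trace simulator. Each second a fish either stays still
# (probability depends on the light state) or moves a Gamma-distributed
# distance scaled by a deterministic rate profile that carries the
# photoperiod-locked dynamics: light > dark baseline, a brief transient after
# every illumination switch, and a post-illumination dark rebound whose
# amplitude saturates (Michaelis-type) in the duration of the preceding light
# period with a per-group half-saturation.

#' Default genotype parameter set
#'
#' Wild types rebound after ~1 min of light; homozygous mutants need ~6 min
#' and carry a basal deficit in darkness; heterozygotes sit in between.
#'
#' @return Named list of per-group parameters (`dark_mult`, `light_mult`,
#'   `rebound_halfsat_min`).
#' @export
default_genotypes <- function() {
  list(
    WT = list(dark_mult = 1.00, light_mult = 1, rebound_halfsat_min = 1),
    HT = list(dark_mult = 0.95, light_mult = 1, rebound_halfsat_min = 2),
    HM = list(dark_mult = 0.70, light_mult = 1, rebound_halfsat_min = 6)
  )
}

#' Simulation configuration
#'
#' Bundles the regimen, study layout and mechanism parameters of a synthetic
#' study. Defaults emulate the statistical structure the analysis assumes:
#' severely right-skewed, zero-inflated per-second movement; higher activity
#' in light than dark; an onset transient at every illumination switch; a
#' duration-dependent dark rebound; and a log-normal assay-level multiplier.
#'
#' @param regimen A `regimen` (default: the 4-cycle 7.5+7.5 repeat protocol).
#' @param n_assays Number of assays (plates) (default 6).
#' @param n_fish_per_group Fish per group within each assay (default 16).
#' @param groups Named list of per-group parameters; see [default_genotypes()].
#' @param group_factor Name of the group factor column (default `"geno"`).
#' @param zero_inflation_dark,zero_inflation_light Probability that a fish
#'   does not move at all in a given second, per light state.
#' @param burst_shape,burst_scale Gamma parameters of the positive movement
#'   distance (mm per active second).
#' @param base_rate_dark,base_rate_light Baseline activity multipliers per
#'   light state (dimensionless; light > dark).
#' @param onset_spike_amp,onset_spike_decay_s Relative amplitude and decay
#'   constant (s) of the transient following any illumination switch.
#' @param rebound_amp Ceiling of the dark-rebound multiplier (dimensionless;
#'   the rate is multiplied by up to `1 + rebound_amp`).
#' @param rebound_decay_s Relaxation constant (s) of the rebound within a dark
#'   period.
#' @param assay_sd SD of the assay-level random log-multiplier.
#' @param seed Integer master seed; per-well substreams are derived from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(regimen = build_repeat_regimen(),
                       n_assays = 6, n_fish_per_group = 16,
                       groups = default_genotypes(), group_factor = "geno",
                       zero_inflation_dark = 0.65, zero_inflation_light = 0.40,
                       burst_shape = 0.7, burst_scale = 2.0,
                       base_rate_dark = 0.35, base_rate_light = 1.0,
                       onset_spike_amp = 1.0, onset_spike_decay_s = 15,
                       rebound_amp = 2.5, rebound_decay_s = 600,
                       assay_sd = 0.12, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  pg_assert(inherits(regimen, "regimen"), "regimen must be a regimen object")
  probs <- c(zero_inflation_dark, zero_inflation_light)
  pg_assert(all(probs >= 0 & probs <= 1), "zero-inflation probabilities must be in [0, 1]")
  pg_assert(all(c(burst_shape, burst_scale, base_rate_dark, base_rate_light,
                  onset_spike_decay_s, rebound_decay_s) > 0),
            "all scale/rate parameters must be > 0")
  pg_assert(onset_spike_amp >= 0 && rebound_amp >= 0 && assay_sd >= 0,
            "amplitudes and assay_sd must be >= 0")
  pg_assert(n_assays >= 1 && n_fish_per_group >= 1,
            "n_assays and n_fish_per_group must be >= 1")
  pg_assert(length(groups) >= 1 && !is.null(names(groups)),
            "groups must be a named list")
  for (g in groups) {
    pg_assert(all(c("rebound_halfsat_min") %in% names(g)) &&
                g$rebound_halfsat_min > 0,
              "each group needs rebound_halfsat_min > 0")
  }
  cfg
}

#' Saturating rebound fraction
#'
#' Fraction of the rebound ceiling mounted after `d_min` minutes of preceding
#' illumination: `s / (s + 1)` with `s = d_min / halfsat_min` (Michaelis
#' form; half the ceiling at `d_min = halfsat_min`).
#'
#' @param d_min Preceding light duration, minutes (>= 0).
#' @param halfsat_min Half-saturation light duration, minutes (> 0).
#' @return Numeric in `[0, 1)`.
#' @export
rebound_fraction <- function(d_min, halfsat_min) {
  s <- d_min / halfsat_min
  s / (s + 1)
}

# Deterministic per-second rate multiplier for one group under a regimen,
# before zero-inflation, burst draw and assay effect.
rate_profile <- function(config, group) {
  reg <- config$regimen
  p <- reg$periods
  gp <- config$groups[[group]]
  pg_assert(!is.null(gp), sprintf("unknown group '%s'", group))
  n <- regimen_duration(reg)
  t <- seq_len(n) - 1L
  state <- p$light_state[findInterval(t, p$start_s)]
  base <- ifelse(state == "white",
                 config$base_rate_light * (gp$light_mult %||% 1),
                 config$base_rate_dark * (gp$dark_mult %||% 1))
  rate <- base

  # transient after every illumination switch
  switches <- p$start_s[-1][p$light_state[-1] != p$light_state[-nrow(p)]]
  if (config$onset_spike_amp > 0 && length(switches)) {
    last_sw <- findInterval(t, switches)
    dt <- t - c(-Inf, switches)[last_sw + 1L]
    rate <- rate * (1 + config$onset_spike_amp *
                      ifelse(is.finite(dt), exp(-dt / config$onset_spike_decay_s), 0))
  }

  # dark rebound after each light -> dark switch, saturating in the duration
  # of the preceding light period
  if (config$rebound_amp > 0 && nrow(p) > 1) {
    for (i in seq.int(2L, nrow(p))) {
      if (p$light_state[i] == "IR_only" && p$light_state[i - 1L] == "white") {
        d_min <- (p$end_s[i - 1L] - p$start_s[i - 1L]) / 60
        frac <- rebound_fraction(d_min, gp$rebound_halfsat_min)
        rows <- t >= p$start_s[i] & t < p$end_s[i]
        rate[rows] <- rate[rows] *
          (1 + config$rebound_amp * frac *
             exp(-(t[rows] - p$start_s[i]) / config$rebound_decay_s))
      }
    }
  }
  list(rate = rate, state = state,
       pzero = ifelse(state == "white", config$zero_inflation_light,
                      config$zero_inflation_dark))
}

# Expected per-second movement (mm) for one group at assay effect 0.
expected_movement <- function(config, group) {
  rp <- rate_profile(config, group)
  (1 - rp$pzero) * config$burst_shape * config$burst_scale * rp$rate
}

# Deterministic substream seed for (master seed, assay index, well index);
# kept below 2^31 and computed in exact double arithmetic.
well_seed <- function(seed, assay_i, well_i) {
  as.integer((abs(as.numeric(seed)) %% 1e6 * 1009 +
                assay_i * 7919 + well_i * 104729 + 1) %% 2147483647)
}

#' Simulate a single fish's trace
#'
#' One second at a time, movement is
#' `Bernoulli(1 - pi_state) * Gamma(burst_shape, burst_scale) * rate(t)`
#' where the deterministic `rate(t)` carries the baseline light/dark levels,
#' the onset transient, the saturating dark rebound, and the assay's
#' log-multiplier.
#'
#' @param config A `sim_config`.
#' @param assay_effect Assay-level log-multiplier applied as `exp(assay_effect)`.
#' @param group Name of a group declared in `config$groups`.
#' @param seed Optional integer seed for this well's substream; when `NULL`
#'   the current RNG state is used.
#' @return Numeric vector of per-second distances (mm), one per regimen second.
#' @export
simulate_well <- function(config, assay_effect = 0, group = "WT", seed = NULL) {
  rp <- rate_profile(config, group)
  n <- length(rp$rate)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  active <- rbinom(n, 1L, 1 - rp$pzero)
  burst <- rgamma(n, shape = config$burst_shape, scale = config$burst_scale)
  active * burst * rp$rate * exp(assay_effect)
}

#' Simulate a complete study
#'
#' Generates `n_assays x groups x n_fish_per_group` complete well traces plus
#' the ground truth that produced them. With a directory the dataset also
#' lands on disk in the documented formats (`traces.csv`, `metadata.csv`,
#' `regimen.json`, `sim_truth.json`); an identical seed yields byte-identical
#' files regardless of generation order because every well draws from its own
#' `(seed, assay, well)` substream.
#'
#' @param config A `sim_config`.
#' @param dir Optional output directory (created if needed).
#' @return Invisibly, a list: `traces` (a `well_traces`), `truth` (assay
#'   effects, per-group expected rolling-sum trajectories, parameters),
#'   `regimen`, `config`.
#' @export
simulate_study <- function(config, dir = NULL) {
  groups <- names(config$groups)
  n_s <- regimen_duration(config$regimen)
  n_wells <- config$n_assays * length(groups) * config$n_fish_per_group

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(well_seed(config$seed, 0L, 0L))
  assay_effects <- if (config$assay_sd > 0) {
    rnorm(config$n_assays, 0, config$assay_sd)
  } else rep(0, config$n_assays)
  assay_ids <- sprintf("assay%02d", seq_len(config$n_assays))
  names(assay_effects) <- assay_ids

  wells <- data.frame(
    assay_id = rep(assay_ids, each = length(groups) * config$n_fish_per_group),
    grp = rep(rep(groups, each = config$n_fish_per_group), config$n_assays),
    stringsAsFactors = FALSE
  )
  wells$well_id <- sprintf("w%03d",
                           rep(seq_len(length(groups) * config$n_fish_per_group),
                               config$n_assays))
  names(wells)[names(wells) == "grp"] <- config$group_factor

  dist <- matrix(0, n_s, n_wells)
  for (j in seq_len(n_wells)) {
    a_i <- match(wells$assay_id[j], assay_ids)
    w_i <- (j - 1L) %% (length(groups) * config$n_fish_per_group) + 1L
    dist[, j] <- simulate_well(config, assay_effects[a_i],
                               wells[[config$group_factor]][j],
                               seed = well_seed(config$seed, a_i, w_i))
  }
  wells[[config$group_factor]] <- factor(wells[[config$group_factor]],
                                         levels = canonical_levels(groups))
  traces <- new_well_traces(dist, wells, config$group_factor)

  truth <- list(
    assay_effects = as.list(assay_effects),
    expected_rsums = lapply(setNames(groups, groups), function(g) {
      unname(rolling_sum(expected_movement(config, g)))
    }),
    group_params = config$groups,
    seed = config$seed
  )

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) pg_stop(sprintf("cannot create '%s'", dir), "pg_error_io")
    write_well_traces(traces, file.path(dir, "traces.csv"),
                      file.path(dir, "metadata.csv"))
    write_regimen(config$regimen, file.path(dir, "regimen.json"))
    jsonlite::write_json(truth, file.path(dir, "sim_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(traces = traces, truth = truth, regimen = config$regimen,
                 config = config))
}
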