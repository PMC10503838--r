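# End-to-end orchestration: simulate (or read) -> aggregate -> fit ->
# contrasts -> proportions -> cross-regimen comparison, with artifacts on
# disk between stages so partial reruns and external audit are possible.

#' Regimen presets by name
#'
#' `"repeat-<dark>+<light>"` (high-intensity white), `"dim-<dark>+<light>"`
#' (low-intensity white), `"baseline-light"`, `"baseline-dark"`.
#'
#' @param name Preset name, e.g. `"repeat-7.5+2"`.
#' @return A `regimen`.
#' @export
regimen_preset <- function(name) {
  m <- regmatches(name, regexec("^(repeat|dim)-([0-9.]+)\\+([0-9.]+)$", name))[[1]]
  if (length(m)) {
    return(build_repeat_regimen(
      dark_min = as.numeric(m[3]), light_min = as.numeric(m[4]),
      intensity = if (m[2] == "dim") "low" else "high"
    ))
  }
  if (name == "baseline-light") return(build_baseline_regimen(12, "white"))
  if (name == "baseline-dark") return(build_baseline_regimen(12, "IR_only"))
  pg_stop(sprintf("unknown regimen preset '%s'", name), "pg_error_lookup")
}

# Tiny FNV-1a hash over a string, for config provenance.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Assemble a pipeline run configuration
#'
#' @param arms Named list of arms; each arm is a list with either `sim`
#'   (a [sim_config()]) or `traces`/`metadata`/`regimen` file paths.
#' @param model A [model_spec()]; applied to every arm.
#' @param contrast List: `factor` (the compared factor), `pair` (two levels),
#'   `direction` (level expected larger; default `pair[1]`), `periods`
#'   (photo-period labels pooled for the proportion; default
#'   `c("dark3","dark4","dark5")`).
#' @param comparisons List of length-2 character vectors naming arm pairs
#'   whose proportions are tested against each other.
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed; arm `i` simulates with `seed + i - 1`.
#' @param write_traces Persist the full per-well trace CSVs (large)?
#' @param check_shuffles Residual permutations for the basis check.
#' @return A `run_config`.
#' @export
run_config <- function(arms, model, contrast, comparisons = list(),
                       alpha = 0.05, seed = 1L, write_traces = FALSE,
                       check_shuffles = 200L) {
  pg_assert(is.list(arms) && length(arms) >= 1 && !is.null(names(arms)),
            "arms must be a named list")
  pg_assert(inherits(model, "pg_spec"), "model must come from model_spec()")
  pg_assert(all(c("factor", "pair") %in% names(contrast)),
            "contrast needs at least 'factor' and 'pair'")
  pg_assert(contrast$factor %in% model$parametric,
            "contrast factor must be a parametric factor of the model")
  contrast$direction <- contrast$direction %||% contrast$pair[1]
  contrast$periods <- contrast$periods %||% c("dark3", "dark4", "dark5")
  for (cmp in comparisons) {
    pg_assert(length(cmp) == 2 && all(cmp %in% names(arms)),
              "each comparison must name two declared arms")
  }
  structure(list(arms = arms, model = model, contrast = contrast,
                 comparisons = comparisons, alpha = alpha,
                 seed = as.integer(seed), write_traces = isTRUE(write_traces),
                 check_shuffles = as.integer(check_shuffles)),
            class = "run_config")
}

stage_log <- function(report, stage, t0, detail) {
  dt <- as.numeric(proc.time()[3] - t0)
  message(sprintf("[photogam] %-22s %7.2fs  %s", stage, dt, detail))
  report
}

#' Run the full analysis pipeline
#'
#' Executes, per arm: (1) trace simulation or ingestion, (2) rolling-sum
#' aggregation to assay-level group means, (3) additive-model fit with
#' adequacy diagnostics, (4) the per-second Tukey-adjusted contrast
#' trajectory, (5) the proportion of significance over the configured photo
#' periods; then compares the configured arm pairs with the two-proportion
#' test. All intermediates are persisted under `out_dir`; an identical
#' config and seed reproduces identical artifact payloads.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the run report (also written as `report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  pg_assert(inherits(config, "run_config"), "config must come from run_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warns <- character(0)
  report <- list(
    provenance = list(
      package = "photogam",
      version = as.character(packageVersion("photogam")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config_hash = fnv1a(paste(deparse(config), collapse = ""))
    ),
    arms = list(), proportions = list(), comparisons = list()
  )
  props <- list()

  withCallingHandlers({
    for (ai in seq_along(config$arms)) {
      arm_name <- names(config$arms)[ai]
      arm <- config$arms[[ai]]
      arm_dir <- file.path(out_dir, arm_name)
      dir.create(arm_dir, recursive = TRUE, showWarnings = FALSE)

      t0 <- proc.time()[3]
      if (!is.null(arm$sim)) {
        sim <- arm$sim
        sim$seed <- config$seed + ai - 1L
        study <- simulate_study(sim, dir = if (config$write_traces)
          file.path(arm_dir, "data") else NULL)
        traces <- study$traces
        regimen <- study$regimen
      } else {
        pg_assert(all(c("traces", "metadata", "regimen") %in% names(arm)),
                  sprintf("arm '%s' needs sim or traces/metadata/regimen paths",
                          arm_name))
        traces <- read_well_traces(arm$traces, arm$metadata)
        regimen <- read_regimen(arm$regimen)
      }
      write_regimen(regimen, file.path(arm_dir, "regimen.json"))
      stage_log(report, paste0(arm_name, ": data"), t0,
                sprintf("%d wells x %d s", ncol(traces$distance),
                        traces$n_seconds))

      t0 <- proc.time()[3]
      series <- aggregate_group_mean(
        traces, stride_s = regimen$sampling_stride_s,
        start_s = max(regimen$analysis_start_s, 59L)
      )
      write_group_series(series, file.path(arm_dir, "group_series.csv"))
      stage_log(report, paste0(arm_name, ": aggregate"), t0,
                sprintf("%d rows", nrow(series)))

      t0 <- proc.time()[3]
      design <- build_design(config$model, series)
      fit <- fit_gam(design)
      tt <- term_tests(fit)
      kchk <- check_basis_dimension(fit, n_shuffle = config$check_shuffles)
      fit_summary <- list(
        n = fit$n, edf_total = fit$edf_total, edf = as.list(fit$edf),
        lambda = as.list(fit$lambda), sigma2 = fit$sigma2,
        deviance_explained = fit$dev_expl, aic = fit$aic,
        selection = fit$selection, term_tests = tt
      )
      jsonlite::write_json(fit_summary, file.path(arm_dir, "fit_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      jsonlite::write_json(kchk, file.path(arm_dir, "diagnostics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      stage_log(report, paste0(arm_name, ": fit"), t0,
                sprintf("edf %.1f, dev.expl %.1f%%", fit$edf_total,
                        100 * fit$dev_expl))

      t0 <- proc.time()[3]
      traj <- pairwise_trajectory(fit, config$contrast$factor,
                                  alpha = config$alpha)
      write.csv(as.data.frame(traj), file.path(arm_dir, "contrasts.csv"),
                row.names = FALSE, quote = FALSE)
      stage_log(report, paste0(arm_name, ": contrasts"), t0,
                sprintf("%d rows", nrow(traj)))

      t0 <- proc.time()[3]
      periods <- intersect(config$contrast$periods, regimen$periods$label)
      pg_assert(length(periods) > 0,
                sprintf("arm '%s': none of the configured periods exist", arm_name))
      pp <- proportion_significant(traj, regimen, periods,
                                   pair = config$contrast$pair,
                                   direction = config$contrast$direction,
                                   alpha = config$alpha)
      props[[arm_name]] <- pp
      report$proportions[[arm_name]] <- list(
        pair = pp$pair, direction = pp$direction, periods = pp$periods,
        n = pp$n_seconds, x = pp$n_significant,
        proportion_pct = round(100 * pp$proportion, 2)
      )
      stage_log(report, paste0(arm_name, ": proportions"), t0,
                sprintf("%.2f%%", 100 * pp$proportion))

      report$arms[[arm_name]] <- list(
        n_wells = ncol(traces$distance), n_seconds = traces$n_seconds,
        fit = fit_summary[c("n", "edf_total", "deviance_explained", "aic",
                            "sigma2")],
        flagged_smooths = kchk$term[kchk$flagged]
      )
    }

    for (cmp in config$comparisons) {
      pc <- compare_proportions(props[[cmp[1]]], props[[cmp[2]]])
      report$comparisons[[paste(cmp, collapse = " vs ")]] <- list(
        arms = cmp, chi_sq = pc$chi_sq, df = pc$df, p_value = pc$p_value
      )
    }
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  report$warnings <- warns
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}

#' Read a pipeline configuration from YAML
#'
#' Mirrors [run_config()]: arms with embedded `sim` blocks (regimen given as
#' a preset name or `build_repeat_regimen` arguments), a `model` block with
#' `smooths: [{var, k, by}]`, `contrast`, `comparisons`, `alpha`, `seed`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  build_reg <- function(r) {
    if (is.character(r)) regimen_preset(r) else do.call(build_repeat_regimen, r)
  }
  arms <- lapply(x$arms, function(a) {
    if (!is.null(a$sim)) {
      s <- a$sim
      s$regimen <- build_reg(s$regimen %||% "repeat-7.5+7.5")
      if (!is.null(s$groups)) s$groups <- lapply(s$groups, as.list)
      list(sim = do.call(sim_config, s))
    } else a
  })
  smooths <- lapply(x$model$smooths, function(s) {
    smooth_term(var = s$var %||% "time_s", k = s$k, by = s$by)
  })
  model <- model_spec(
    response = x$model$response %||% "rsums",
    parametric = unlist(x$model$parametric),
    smooths = smooths,
    random = unlist(x$model$random) %||% character(),
    selection = x$model$selection %||% "REML"
  )
  run_config(
    arms = arms, model = model, contrast = x$contrast,
    comparisons = lapply(x$comparisons, unlist),
    alpha = x$alpha %||% 0.05, seed = x$seed %||% 1L,
    write_traces = isTRUE(x$write_traces),
    check_shuffles = x$check_shuffles %||% 200L
  )
}
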