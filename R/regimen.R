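# Photoperiod schedules: ordered, contiguous, half-open [start_s, end_s)
# intervals of constant illumination, 0-based seconds from recording start.

#' Illumination presets
#'
#' Irradiance / illuminance pairs for the light-box settings used throughout:
#' infrared only (invisible to the larvae, 0 lx) and three white intensities.
#'
#' @format A data frame with columns `name`, `light_state`,
#'   `irradiance_uW_cm2`, `illuminance_lx`.
#' @export
light_presets <- data.frame(
  name              = c("IR", "low", "med", "high"),
  light_state       = c("IR_only", "white", "white", "white"),
  irradiance_uW_cm2 = c(116.0, 20.5, 240.0, 469.4),
  illuminance_lx    = c(0, 300, 4000, 8000),
  stringsAsFactors  = FALSE
)

preset_row <- function(name) {
  i <- match(name, light_presets$name)
  pg_assert(!is.na(i), sprintf("unknown light preset '%s'", name))
  light_presets[i, ]
}

new_regimen <- function(periods, analysis_start_s, sampling_stride_s) {
  validate_regimen(structure(
    list(
      periods = periods,
      analysis_start_s = as.integer(analysis_start_s),
      sampling_stride_s = as.integer(sampling_stride_s)
    ),
    class = "regimen"
  ))
}

validate_regimen <- function(x) {
  p <- x$periods
  need <- c("label", "start_s", "end_s", "light_state",
            "irradiance_uW_cm2", "illuminance_lx")
  pg_assert(is.data.frame(p) && all(need %in% names(p)),
            "regimen periods must contain label/start_s/end_s/light_state/irradiance_uW_cm2/illuminance_lx")
  pg_assert(nrow(p) >= 1, "regimen must contain at least one period")
  pg_assert(all(p$start_s < p$end_s), "each period must satisfy start_s < end_s")
  pg_assert(p$start_s[1] == 0, "first period must start at second 0")
  if (nrow(p) > 1) {
    pg_assert(all(p$start_s[-1] == p$end_s[-nrow(p)]),
              "periods must be contiguous and non-overlapping")
  }
  pg_assert(!anyDuplicated(p$label), "period labels must be unique")
  pg_assert(all(p$light_state %in% c("IR_only", "white")),
            "light_state must be 'IR_only' or 'white'")
  pg_assert(all(p$irradiance_uW_cm2 >= 0), "irradiance must be >= 0")
  pg_assert(all(p$illuminance_lx[p$light_state == "IR_only"] == 0),
            "IR_only periods must have illuminance 0 lx")
  pg_assert(x$analysis_start_s >= 0 && x$analysis_start_s < max(p$end_s),
            "analysis_start_s must fall inside the regimen")
  pg_assert(x$sampling_stride_s >= 1, "sampling_stride_s must be >= 1")
  x
}

#' Total regimen duration in seconds
#' @param regimen A `regimen` object.
#' @return Integer number of seconds.
#' @export
regimen_duration <- function(regimen) max(regimen$periods$end_s)

#' Build a dark-light repeat regimen
#'
#' Schedule of a dark acclimation, `n_cycles` alternating dark/light cycles,
#' and (optionally) a terminal dark period. Dark periods run under infrared
#' illumination; light periods use the chosen white intensity. Post-acclimation
#' dark periods are numbered `dark1 .. dark{n_cycles+1}` with the terminal
#' dark carrying the last number, so the default 4-cycle protocol ends in
#' `dark5`. The analysis window starts at the end of acclimation and repeat
#' assays are analyzed at a 1-s stride.
#'
#' @param acclim_min Dark acclimation duration, minutes (default 30).
#' @param n_cycles Number of dark+light cycles (default 4).
#' @param dark_min,light_min Cycle component durations, minutes (defaults 7.5).
#' @param final_dark_min Terminal dark duration, minutes (default 25).
#' @param intensity White-light intensity preset, `"low"` (20.5 uW/cm2, ~300 lx)
#'   or `"high"` (469.4 uW/cm2, ~8000 lx); `"med"` is also accepted.
#' @param include_final_dark Include the terminal dark period? Some early
#'   assays were run without it.
#' @return A `regimen` object with `2 + 2 * n_cycles` periods (one fewer when
#'   `include_final_dark = FALSE`).
#' @examples
#' r <- build_repeat_regimen()
#' regimen_duration(r) # 6900 s
#' @export
build_repeat_regimen <- function(acclim_min = 30, n_cycles = 4,
                                 dark_min = 7.5, light_min = 7.5,
                                 final_dark_min = 25,
                                 intensity = c("high", "low", "med"),
                                 include_final_dark = TRUE) {
  intensity <- match.arg(intensity)
  durs <- c(acclim_min, dark_min, light_min,
            if (include_final_dark) final_dark_min)
  pg_assert(all(durs > 0), "all period durations must be positive")
  pg_assert(n_cycles >= 1, "n_cycles must be >= 1")
  ir <- preset_row("IR"); wh <- preset_row(intensity)

  lab <- "acclimation"; st <- "IR_only"
  for (i in seq_len(n_cycles)) {
    lab <- c(lab, paste0("dark", i), paste0("light", i))
    st <- c(st, "IR_only", "white")
  }
  dur <- c(acclim_min, rep(c(dark_min, light_min), n_cycles))
  if (include_final_dark) {
    lab <- c(lab, paste0("dark", n_cycles + 1))
    st <- c(st, "IR_only")
    dur <- c(dur, final_dark_min)
  }
  ends <- cumsum(round(dur * 60))
  periods <- data.frame(
    label = lab,
    start_s = c(0L, ends[-length(ends)]),
    end_s = ends,
    light_state = st,
    irradiance_uW_cm2 = ifelse(st == "IR_only",
                               ir$irradiance_uW_cm2, wh$irradiance_uW_cm2),
    illuminance_lx = ifelse(st == "IR_only",
                            ir$illuminance_lx, wh$illuminance_lx),
    stringsAsFactors = FALSE
  )
  new_regimen(periods, analysis_start_s = round(acclim_min * 60),
              sampling_stride_s = 1L)
}

#' Build a constant-illumination baseline regimen
#'
#' A single analysis period of unchanging illumination (the long-recording
#' baseline protocol), analyzed at one data point per 30 seconds. An optional
#' acclimation period of the same illumination can be prepended.
#'
#' @param duration_h Analysis duration in hours (> 0).
#' @param light_state `"white"` or `"IR_only"`.
#' @param intensity White intensity preset when `light_state = "white"`.
#' @param acclim_min Acclimation minutes before the analysis period (default 0).
#' @return A `regimen` with sampling stride 30 s.
#' @examples
#' build_baseline_regimen(12, "white")   # one 43200-s period
#' build_baseline_regimen(12, "IR_only") # 0 lx throughout
#' @export
build_baseline_regimen <- function(duration_h,
                                   light_state = c("white", "IR_only"),
                                   intensity = "high", acclim_min = 0) {
  light_state <- match.arg(light_state)
  pg_assert(is.numeric(duration_h) && length(duration_h) == 1 && duration_h > 0,
            "duration_h must be a positive number")
  pg_assert(acclim_min >= 0, "acclim_min must be >= 0")
  pr <- if (light_state == "white") preset_row(intensity) else preset_row("IR")
  acc_s <- round(acclim_min * 60)
  tot_s <- acc_s + round(duration_h * 3600)
  lab <- "baseline"; starts <- acc_s
  if (acc_s > 0) { lab <- c("acclimation", lab); starts <- c(0L, acc_s) }
  periods <- data.frame(
    label = lab,
    start_s = starts,
    end_s = c(starts[-1], tot_s),
    light_state = pr$light_state,
    irradiance_uW_cm2 = pr$irradiance_uW_cm2,
    illuminance_lx = pr$illuminance_lx,
    stringsAsFactors = FALSE
  )
  new_regimen(periods, analysis_start_s = acc_s, sampling_stride_s = 30L)
}

#' Map time points to photo-period labels
#'
#' Periods are half-open `[start_s, end_s)`, so each second inside the
#' analysis window maps to exactly one period and the regimen end itself is
#' out of range.
#'
#' @param regimen A `regimen`.
#' @param t_s Integer second(s), `analysis_start_s <= t_s < regimen end`
#'   (acclimation seconds are allowed when `within_analysis = FALSE`).
#' @param within_analysis Require `t_s >= analysis_start_s`? Default `TRUE`.
#' @return Character vector of period labels.
#' @export
period_of <- function(regimen, t_s, within_analysis = TRUE) {
  lo <- if (within_analysis) regimen$analysis_start_s else 0L
  bad <- t_s < lo | t_s >= regimen_duration(regimen)
  if (any(bad)) {
    pg_stop(sprintf("time point(s) out of range [%d, %d): %s", lo,
                    regimen_duration(regimen),
                    paste(head(t_s[bad], 5), collapse = ", ")),
            "pg_error_lookup")
  }
  idx <- findInterval(t_s, regimen$periods$start_s)
  regimen$periods$label[idx]
}

#' Seconds belonging to a set of photo periods
#'
#' @param regimen A `regimen`.
#' @param labels Period labels; unknown labels raise a lookup error.
#' @return Sorted integer vector of seconds in the union of the periods.
#' @export
period_seconds <- function(regimen, labels) {
  p <- regimen$periods
  unknown <- setdiff(labels, p$label)
  if (length(unknown)) {
    pg_stop(sprintf("unknown period label(s): %s",
                    paste(unknown, collapse = ", ")), "pg_error_lookup")
  }
  rows <- p[p$label %in% labels, , drop = FALSE]
  sort(unlist(Map(function(a, b) seq.int(a, b - 1L), rows$start_s, rows$end_s),
              use.names = FALSE))
}

#' Write / read a regimen as JSON
#'
#' The serialized form holds the period table plus `analysis_start_s` and
#' `sampling_stride_s`; reading it back reproduces the regimen exactly.
#'
#' @param regimen A `regimen`.
#' @param path File path.
#' @return `read_regimen` returns a `regimen`; `write_regimen` its path,
#'   invisibly.
#' @export
write_regimen <- function(regimen, path) {
  jsonlite::write_json(
    list(periods = regimen$periods,
         analysis_start_s = regimen$analysis_start_s,
         sampling_stride_s = regimen$sampling_stride_s),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_regimen
#' @export
read_regimen <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as.data.frame(x$periods, stringsAsFactors = FALSE)
  p$start_s <- as.integer(p$start_s); p$end_s <- as.integer(p$end_s)
  new_regimen(p, x$analysis_start_s, x$sampling_stride_s)
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %d periods, %d s total, analysis from %d s, stride %d s\n",
              nrow(x$periods), regimen_duration(x), x$analysis_start_s,
              x$sampling_stride_s))
  print(x$periods, row.names = FALSE)
  invisible(x)
}
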