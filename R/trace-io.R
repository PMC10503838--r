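# Per-fish locomotor traces, the rolling-sum response, and aggregation to
# assay-level group means (the model's analysis unit).

# Canonical factor-level orderings so that model reference levels are the
# conventional ones (WT, dark, youngest stage) wherever those labels occur.
canonical_levels <- function(values) {
  u <- unique(as.character(values))
  for (ord in list(c("WT", "HT", "HM"), c("dark", "light"))) {
    if (all(u %in% ord)) return(ord[ord %in% u])
  }
  if (!anyNA(suppressWarnings(as.numeric(u)))) return(u[order(as.numeric(u))])
  sort(u)
}

new_well_traces <- function(distance, wells, factors) {
  pg_assert(is.matrix(distance) && ncol(distance) == nrow(wells),
            "distance matrix columns must match well metadata rows")
  structure(
    list(distance = distance, wells = wells, factors = factors,
         n_seconds = nrow(distance)),
    class = "well_traces"
  )
}

#' @export
print.well_traces <- function(x, ...) {
  cat(sprintf("<well_traces> %d wells x %d s; factors: %s\n",
              ncol(x$distance), x$n_seconds,
              paste(x$factors, collapse = ", ")))
  invisible(x)
}

#' Read per-well locomotor traces
#'
#' Reads a long-format trace table (`assay_id, well_id, time_s, distance_mm`;
#' one row per fish per second, `time_s` 0-based) together with plate
#' metadata keyed by `(assay_id, well_id)` whose remaining columns are group
#' factors (e.g. `geno`, `illu`, `dev`). Every well must provide a complete
#' gap-free series of the same length; distances must be non-negative.
#'
#' @param path Trace CSV path.
#' @param metadata_path Metadata CSV path.
#' @param factor_domains Optional named list of allowed levels per factor
#'   column; metadata values outside a declared domain raise an error.
#' @return A `well_traces` object: a seconds-by-wells distance matrix plus the
#'   per-well metadata.
#' @export
read_well_traces <- function(path, metadata_path, factor_domains = NULL) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  md <- read.csv(metadata_path, stringsAsFactors = FALSE)
  pg_assert(all(c("assay_id", "well_id", "time_s", "distance_mm") %in% names(tr)),
            "trace CSV must have columns assay_id, well_id, time_s, distance_mm")
  pg_assert(all(c("assay_id", "well_id") %in% names(md)),
            "metadata CSV must have columns assay_id, well_id")
  factors <- setdiff(names(md), c("assay_id", "well_id"))
  pg_assert(length(factors) >= 1, "metadata must declare at least one group factor")
  for (f in names(factor_domains %||% list())) {
    bad <- setdiff(unique(md[[f]]), factor_domains[[f]])
    if (length(bad)) {
      pg_stop(sprintf("factor '%s' has level(s) outside its domain: %s", f,
                      paste(bad, collapse = ", ")))
    }
  }
  pg_assert(all(is.finite(tr$distance_mm)) && all(tr$distance_mm >= 0),
            "distances must be finite and >= 0")

  key <- paste(tr$assay_id, tr$well_id, sep = "\r")
  mkey <- paste(md$assay_id, md$well_id, sep = "\r")
  pg_assert(!anyDuplicated(mkey), "duplicated (assay_id, well_id) in metadata")
  missing_md <- setdiff(unique(key), mkey)
  if (length(missing_md)) {
    pg_stop(sprintf("%d well(s) lack metadata rows", length(missing_md)))
  }

  n_s <- max(tr$time_s) + 1L
  wells <- md[mkey %in% key, , drop = FALSE]
  mkey <- paste(wells$assay_id, wells$well_id, sep = "\r")
  dist <- matrix(NA_real_, n_s, nrow(wells))
  col <- match(key, mkey)
  pg_assert(all(tr$time_s >= 0), "time_s must be >= 0")
  idx <- tr$time_s + 1L + (col - 1L) * n_s
  pg_assert(!anyDuplicated(idx), "duplicated (well, second) rows in trace CSV")
  dist[idx] <- tr$distance_mm
  gaps <- colSums(is.na(dist)) > 0
  if (any(gaps)) {
    w <- which(gaps)[1]
    pg_stop(sprintf("trace for well %s/%s has missing second(s), e.g. t = %d",
                    wells$assay_id[w], wells$well_id[w],
                    which(is.na(dist[, w]))[1] - 1L))
  }
  for (f in factors) {
    wells[[f]] <- factor(wells[[f]], levels = factor_domains[[f]] %||%
                           canonical_levels(wells[[f]]))
  }
  new_well_traces(dist, wells, factors)
}

#' Write well traces and metadata to the long CSV dialect
#'
#' Inverse of [read_well_traces()]; used by the simulator so synthetic studies
#' land in the same on-disk format as recorded ones.
#'
#' @param traces A `well_traces` object.
#' @param path Trace CSV path.
#' @param metadata_path Metadata CSV path.
#' @return The trace path, invisibly.
#' @export
write_well_traces <- function(traces, path, metadata_path) {
  w <- traces$wells
  n_s <- traces$n_seconds
  long <- data.frame(
    assay_id = rep(w$assay_id, each = n_s),
    well_id = rep(w$well_id, each = n_s),
    time_s = rep.int(seq_len(n_s) - 1L, nrow(w)),
    distance_mm = as.vector(traces$distance)
  )
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  md <- w
  for (f in traces$factors) md[[f]] <- as.character(md[[f]])
  write.csv(md, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trailing rolling sum of a per-second distance series
#'
#' `r[t] = sum(d[(t - window_s + 1):t])` for 0-based seconds
#' `t >= window_s - 1`; earlier seconds are undefined (`NA`). With the default
#' 60-s window the result is total distance moved per minute, at every second.
#' The window is causal (trailing), so no second's response uses future
#' movement.
#'
#' @param distance_per_s Numeric vector of non-negative per-second distances.
#' @param window_s Window length in seconds (>= 1; default 60).
#' @return Numeric vector of the same length; first `window_s - 1` entries `NA`.
#' @examples
#' rolling_sum(rep(1, 120))[60:64] # 60 mm/min once the window fills
#' @export
rolling_sum <- function(distance_per_s, window_s = 60L) {
  pg_assert(window_s >= 1, "window_s must be >= 1")
  n <- length(distance_per_s)
  if (n < window_s) pg_stop("series shorter than the rolling window")
  cs <- cumsum(distance_per_s)
  out <- c(rep(NA_real_, window_s - 1L),
           cs[window_s:n] - c(0, cs)[seq_len(n - window_s + 1L)])
  out
}

rolling_sum_matrix <- function(m, window_s = 60L) {
  n <- nrow(m)
  pg_assert(n >= window_s, "series shorter than the rolling window")
  cs <- apply(m, 2, cumsum)
  out <- matrix(NA_real_, n, ncol(m))
  out[window_s:n, ] <- cs[window_s:n, , drop = FALSE] -
    rbind(0, cs[seq_len(n - window_s), , drop = FALSE])
  out
}

#' Aggregate traces to assay-level group-mean rolling sums
#'
#' Computes each well's rolling sum and averages across the fish of every
#' `(assay, group)` cell at each second, producing the assay-level group mean
#' trajectories that are the model's analysis unit. Cells of the full
#' `assay x group` crossing with no wells are dropped with a warning.
#'
#' @param traces A `well_traces` object.
#' @param factors Factor columns defining the groups (default: all declared).
#' @param stride_s Keep one analyzed second every `stride_s` (1 for repeat
#'   assays, 30 for baseline assays).
#' @param window_s Rolling window (default 60 s).
#' @param start_s First analyzed second (default: first second with a defined
#'   rolling sum, `window_s - 1`; pipelines pass the regimen's
#'   `analysis_start_s`).
#' @return A data frame (`group_series`) with columns `assay_id`, the group
#'   factors, `time_s`, `rsums`.
#' @export
aggregate_group_mean <- function(traces, factors = traces$factors,
                                 stride_s = 1L, window_s = 60L,
                                 start_s = NULL) {
  pg_assert(inherits(traces, "well_traces"), "traces must be a well_traces object")
  pg_assert(all(factors %in% names(traces$wells)),
            "unknown factor column(s) requested")
  pg_assert(stride_s >= 1, "stride_s must be >= 1")
  start_s <- as.integer(start_s %||% (window_s - 1L))
  pg_assert(start_s >= window_s - 1L,
            "start_s precedes the first defined rolling-sum second")

  R <- rolling_sum_matrix(traces$distance, window_s)
  keep <- seq.int(start_s + 1L, traces$n_seconds, by = stride_s) # 1-based rows
  R <- R[keep, , drop = FALSE]
  times <- keep - 1L

  w <- traces$wells
  cell <- interaction(c(list(w$assay_id), lapply(factors, function(f) w[[f]])),
                      drop = TRUE, lex.order = TRUE, sep = "\r")
  full <- interaction(c(list(w$assay_id), lapply(factors, function(f) w[[f]])),
                      drop = FALSE, lex.order = TRUE, sep = "\r")
  empty <- setdiff(levels(full), levels(cell))
  if (length(empty)) {
    warning(sprintf("dropping %d empty assay x group cell(s): %s",
                    length(empty),
                    paste(gsub("\r", "/", empty), collapse = ", ")),
            call. = FALSE)
  }

  # mean across the wells of each cell at every kept second
  G <- t(rowsum(t(R), cell) / as.vector(table(cell)))
  cells <- do.call(rbind, strsplit(colnames(G), "\r", fixed = TRUE))
  out <- data.frame(
    assay_id = rep(cells[, 1], each = length(times)),
    stringsAsFactors = FALSE
  )
  for (j in seq_along(factors)) {
    out[[factors[j]]] <- factor(rep(cells[, j + 1], each = length(times)),
                                levels = levels(w[[factors[j]]]))
  }
  out$time_s <- rep.int(times, ncol(G))
  out$rsums <- as.vector(G)
  attr(out, "window_s") <- window_s
  attr(out, "stride_s") <- as.integer(stride_s)
  class(out) <- c("group_series", "data.frame")
  out
}

#' Write / read group-mean series
#' @param series A `group_series` data frame.
#' @param path CSV path.
#' @return `read_group_series` returns the data frame; the writer its path.
#' @export
write_group_series <- function(series, path) {
  df <- as.data.frame(series)
  fac <- vapply(df, is.factor, logical(1))
  df[fac] <- lapply(df[fac], as.character)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_group_series
#' @param factors Columns to re-read as group factors (default: everything
#'   except `assay_id`, `time_s`, `rsums`).
#' @export
read_group_series <- function(path, factors = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  factors <- factors %||% setdiff(names(df), c("assay_id", "time_s", "rsums"))
  for (f in factors) df[[f]] <- factor(df[[f]], levels = canonical_levels(df[[f]]))
  class(df) <- c("group_series", "data.frame")
  df
}
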