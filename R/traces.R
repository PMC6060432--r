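#' Baseline window helper
#'
#' The control baseline is the 10 minutes preceding the first condition
#' change; R0 (the reference ratio) is the mean ratio over this window.
#'
#' @param protocol A [protocol()] object.
#' @param length_min Baseline length in minutes (default 10).
#' @return Numeric `c(start, end)` in minutes.
#' @export
baseline_window <- function(protocol, length_min = 10) {
  ev <- protocol_event_time(protocol)
  c(max(0, ev - length_min), ev)
}

check_trace <- function(trace, value_col) {
  trace <- as_tibble(trace)
  need <- c("cell_id", "time_min", value_col)
  miss <- setdiff(need, names(trace))
  if (length(miss) > 0) {
    abort(paste0("trace lacks column(s): ", paste(miss, collapse = ", ")))
  }
  trace
}

per_cell <- function(trace, fn) {
  trace %>%
    group_by(.data$cell_id) %>%
    dplyr::group_modify(~ fn(.x)) %>%
    ungroup()
}

#' Correct baseline drift by linear fit
#'
#' Long recordings show a slow linear drift of the ratio baseline
#' (photobleaching acting unequally on the two channels). A least-squares
#' line is fitted to the baseline-window samples only -- fitting through
#' stimulus periods would absorb real signal -- extrapolated over the whole
#' trace, and subtracted; the baseline mean is added back so the baseline
#' level is preserved while its slope is removed. Any post-event step riding
#' on the drift is preserved exactly.
#'
#' @param trace Ratio-trace tibble (`cell_id`, `time_min`, `R`); missing
#'   samples (`NA`) are excluded from the fit, never interpolated.
#' @param baseline Numeric `c(start, end)` in minutes; needs at least 5
#'   non-missing samples inside and must lie within the trace support.
#' @return A tibble of the same shape with the drift removed from `R`.
#' @export
correct_drift <- function(trace, baseline) {
  trace <- check_trace(trace, "R")
  if (length(baseline) != 2 || baseline[2] <= baseline[1]) {
    abort("`baseline` must be c(start, end) with end > start")
  }
  per_cell(trace, function(tr) {
    if (baseline[1] < min(tr$time_min) - 1e-9 ||
      baseline[2] > max(tr$time_min) + 1e-9) {
      abort("baseline window lies outside the trace support")
    }
    in_bl <- tr$time_min >= baseline[1] & tr$time_min <= baseline[2] & !is.na(tr$R)
    if (sum(in_bl) < 5) abort("need at least 5 baseline samples to fit drift")
    fit <- lm(R ~ time_min, data = tr[in_bl, ])
    line <- coef(fit)[1] + coef(fit)[2] * tr$time_min
    tibble(
      time_min = tr$time_min,
      R = tr$R - line + mean(tr$R[in_bl])
    )
  })[, c("cell_id", "time_min", "R")]
}

#' Baseline-relative ratio trace
#'
#' Expresses a ratio trace as the percent change relative to its baseline
#' mean: `100 * (R - R0) / R0`, with `R0` the mean ratio over the baseline
#' window. The baseline mean of the output is 0 by construction.
#'
#' @inheritParams correct_drift
#' @return A relative-trace tibble (`cell_id`, `time_min`, `value`), `value`
#'   in percent.
#' @export
relative_ratio <- function(trace, baseline) {
  trace <- check_trace(trace, "R")
  if (length(baseline) != 2 || baseline[2] <= baseline[1]) {
    abort("`baseline` must be c(start, end) with end > start")
  }
  per_cell(trace, function(tr) {
    in_bl <- tr$time_min >= baseline[1] & tr$time_min <= baseline[2] & !is.na(tr$R)
    if (!any(in_bl)) abort("no baseline samples in window")
    r0 <- mean(tr$R[in_bl])
    if (!is.finite(r0) || r0 <= 0) abort("baseline mean R0 must be > 0")
    tibble(time_min = tr$time_min, value = 100 * (tr$R - r0) / r0)
  })[, c("cell_id", "time_min", "value")]
}

running_median5 <- function(x) {
  n <- length(x)
  out <- x
  if (n < 3) {
    return(out)
  }
  for (i in seq_len(n)) {
    half <- min(2, i - 1, n - i) # shrink symmetrically at the edges
    if (half == 0) next # endpoints pass through
    win <- x[(i - half):(i + half)]
    out[i] <- if (is.na(x[i])) NA_real_ else median(win, na.rm = TRUE)
  }
  out
}

#' Sliding five-point median filter
#'
#' Smooths a relative trace with a centered five-point running median to
#' eliminate sharp single-frame artifacts from transient loss of focus. At
#' the edges the window shrinks symmetrically (three points at the second and
#' second-to-last samples; endpoints pass through). Missing samples stay
#' missing and are ignored within windows.
#'
#' @param trace Relative-trace tibble (`cell_id`, `time_min`, `value`).
#' @return A tibble of the same shape.
#' @export
median_filter5 <- function(trace) {
  trace <- check_trace(trace, "value")
  per_cell(trace, function(tr) {
    tibble(time_min = tr$time_min, value = running_median5(tr$value))
  })[, c("cell_id", "time_min", "value")]
}

#' Relative-ratio value at a time after the event
#'
#' Reads the trace at the sample nearest to `event_time + t_after`; when the
#' target falls exactly between two samples, the earlier sample wins.
#'
#' @param trace Relative-trace tibble (typically median-filtered).
#' @param t_after Minutes after the event.
#' @param event_time Event time in minutes (e.g.
#'   [protocol_event_time()]).
#' @return A tibble `cell_id`, `time_min` (the sample used), `value`.
#' @export
timepoint_value <- function(trace, t_after, event_time) {
  trace <- check_trace(trace, "value")
  target <- event_time + t_after
  per_cell(trace, function(tr) {
    if (target > max(tr$time_min) + 1e-9 || target < min(tr$time_min) - 1e-9) {
      abort("requested timepoint lies outside the trace support")
    }
    d <- abs(tr$time_min - target)
    # earlier sample wins ties
    i <- which(d <= min(d) + 1e-12)[1]
    tibble(time_min = tr$time_min[i], value = tr$value[i])
  })[, c("cell_id", "time_min", "value")]
}

#' Slope of the relative ratio over a post-event window
#'
#' Ordinary least-squares slope of the (drift-corrected, unfiltered) relative
#' trace over `[event_time + window[1], event_time + window[2]]`, in percent
#' per minute. Missing samples are excluded; at least 3 samples are required.
#'
#' @param trace Relative-trace tibble.
#' @param window Numeric `c(start, end)` in minutes after the event; the
#'   canonical elimination-rate window is `c(2, 7)`.
#' @param event_time Event time in minutes.
#' @return A tibble `cell_id`, `slope` (percent/min), `window_start`,
#'   `window_end`, `n_points`, `rse` (residual standard error).
#' @export
estimate_slope <- function(trace, window = c(2, 7), event_time = 10) {
  trace <- check_trace(trace, "value")
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("`window` must be c(start, end) with end > start")
  }
  lo <- event_time + window[1]
  hi <- event_time + window[2]
  per_cell(trace, function(tr) {
    sel <- tr$time_min >= lo - 1e-9 & tr$time_min <= hi + 1e-9 & !is.na(tr$value)
    if (sum(sel) < 3) abort("need at least 3 samples in the slope window")
    fit <- lm(value ~ time_min, data = tr[sel, ])
    df_resid <- sum(sel) - 2
    rse <- if (df_resid > 0) sqrt(sum(fit$residuals^2) / df_resid) else NA_real_
    tibble(
      slope = unname(coef(fit)[2]),
      window_start = window[1], window_end = window[2],
      n_points = sum(sel),
      rse = rse
    )
  })[, c("cell_id", "slope", "window_start", "window_end", "n_points", "rse")]
}

#' Group mean and SEM over cells
#'
#' Per-timepoint mean and standard error of the mean over the cells with a
#' defined value. All traces must share a common time grid.
#'
#' @param traces Relative-trace tibble holding at least 2 cells.
#' @return An object of class `group_trace_summary`: a tibble `time_min`,
#'   `mean`, `sem`, `n`.
#' @export
group_summary <- function(traces) {
  traces <- check_trace(traces, "value")
  ids <- unique(traces$cell_id)
  if (length(ids) < 2) abort("group summary needs at least 2 traces")
  grids <- traces %>%
    group_by(.data$cell_id) %>%
    summarise(grid = list(sort(.data$time_min)), .groups = "drop")
  ref <- grids$grid[[1]]
  same <- vapply(
    grids$grid,
    function(g) length(g) == length(ref) && all(abs(g - ref) < 1e-9),
    logical(1)
  )
  if (!all(same)) abort("all traces must share a common time grid")
  out <- traces %>%
    group_by(.data$time_min) %>%
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) %>%
    arrange(.data$time_min)
  out$mean[out$n == 0] <- NA_real_
  class(out) <- c("group_trace_summary", class(out))
  out
}
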