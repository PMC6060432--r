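#' Superfusion protocol
#'
#' A protocol describes the timed extracellular conditions of a recording:
#' extracellular glucose concentration and inhibitor applications (IAA blocks
#' glycolysis at glyceraldehyde-3-phosphate dehydrogenase; 6-AN blocks the
#' pentose phosphate pathway at glucose-6-phosphate dehydrogenase). The first
#' event, at t = 0, defines the baseline condition; imaging samples are taken
#' every `sample_interval_s` seconds.
#'
#' @param events A data frame with columns `time_min` (minutes from recording
#'   start), `glucose_mM` (extracellular glucose, mM), `iaa` and `six_an`
#'   (logical inhibitor flags). Event times must be strictly increasing,
#'   start at 0, and lie within `[0, duration_min]`.
#' @param duration_min Total recording duration in minutes.
#' @param sample_interval_s Imaging sample interval in seconds (default 15).
#'
#' @return An object of class `fret_protocol`.
#' @export
#' @examples
#' p <- protocol(
#'   events = tibble::tibble(
#'     time_min = c(0, 10), glucose_mM = c(2.5, 0.2),
#'     iaa = FALSE, six_an = FALSE
#'   ),
#'   duration_min = 35
#' )
#' protocol_event_time(p)
protocol <- function(events, duration_min, sample_interval_s = 15) {
  events <- as_tibble(events)
  required <- c("time_min", "glucose_mM", "iaa", "six_an")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("`events` lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(events) < 1) abort("`events` must contain at least one event")
  if (events$time_min[1] != 0) abort("first event must be at time 0 (baseline condition)")
  if (any(diff(events$time_min) <= 0)) abort("event times must be strictly increasing")
  if (any(events$time_min < 0) || any(events$time_min > duration_min)) {
    abort("event times must lie within [0, duration_min]")
  }
  if (any(events$glucose_mM < 0)) abort("extracellular glucose must be non-negative")
  if (!is.logical(events$iaa) || !is.logical(events$six_an)) {
    abort("`iaa` and `six_an` must be logical")
  }
  if (duration_min <= 0) abort("`duration_min` must be positive")
  if (sample_interval_s <= 0) abort("`sample_interval_s` must be positive")
  structure(
    list(
      events = events[required],
      duration_min = as.numeric(duration_min),
      sample_interval_s = as.numeric(sample_interval_s)
    ),
    class = "fret_protocol"
  )
}

#' @export
print.fret_protocol <- function(x, ...) {
  cat(sprintf(
    "<fret_protocol> %.0f min, sampled every %.0f s\n",
    x$duration_min, x$sample_interval_s
  ))
  print(x$events)
  invisible(x)
}

#' Query a protocol at given times
#'
#' `protocol_glucose()` returns the extracellular glucose concentration at
#' times `t_min` (step function, left-continuous from the event onwards).
#' `protocol_onset()` returns the first time an inhibitor is on (`Inf` if
#' never). `protocol_event_time()` returns the time of the first condition
#' change after baseline, i.e. the stimulus time used to anchor baseline and
#' analysis windows. `protocol_times()` returns the imaging sample grid in
#' minutes.
#'
#' @param protocol A [protocol()] object.
#' @param t_min Numeric vector of times in minutes.
#' @param drug `"iaa"` or `"six_an"`.
#' @return Numeric vector (`protocol_glucose`, `protocol_times`) or scalar.
#' @export
protocol_glucose <- function(protocol, t_min) {
  stopifnot(inherits(protocol, "fret_protocol"))
  idx <- findInterval(t_min, protocol$events$time_min)
  idx[idx < 1] <- 1L
  protocol$events$glucose_mM[idx]
}

#' @rdname protocol_glucose
#' @export
protocol_onset <- function(protocol, drug = c("iaa", "six_an")) {
  stopifnot(inherits(protocol, "fret_protocol"))
  drug <- match.arg(drug)
  on <- protocol$events$time_min[protocol$events[[drug]]]
  if (length(on) == 0) Inf else min(on)
}

#' @rdname protocol_glucose
#' @export
protocol_event_time <- function(protocol) {
  stopifnot(inherits(protocol, "fret_protocol"))
  if (nrow(protocol$events) < 2) {
    return(protocol$duration_min)
  }
  protocol$events$time_min[2]
}

#' @rdname protocol_glucose
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "fret_protocol"))
  seq(0, protocol$duration_min, by = protocol$sample_interval_s / 60)
}

#' Standard superfusion protocols
#'
#' The five protocol designs used throughout: each has a 10 min control
#' baseline at 2.5 mM extracellular glucose before the event.
#'
#' * `step10`: step from 2.5 to 10 mM glucose for 50 min (glucose uptake).
#' * `restriction`: step from 2.5 to 0.2 mM for 25 min (glucose elimination).
#' * `iaa`: 200 uM IAA for 35 min at constant 2.5 mM glucose (glycolysis
#'   inhibition).
#' * `sixan`: 6-AN for 35 min (pentose phosphate pathway inhibition).
#' * `combined`: IAA and 6-AN applied simultaneously for 30 min.
#'
#' @return A named list of [protocol()] objects.
#' @export
#' @examples
#' names(make_paper_protocols())
make_paper_protocols <- function() {
  ev <- function(t, glc, iaa = FALSE, six = FALSE) {
    tibble(time_min = t, glucose_mM = glc, iaa = iaa, six_an = six)
  }
  base <- ev(0, 2.5)
  list(
    step10 = protocol(bind_rows(base, ev(10, 10)), duration_min = 60),
    restriction = protocol(bind_rows(base, ev(10, 0.2)), duration_min = 35),
    iaa = protocol(bind_rows(base, ev(10, 2.5, iaa = TRUE)), duration_min = 45),
    sixan = protocol(bind_rows(base, ev(10, 2.5, six = TRUE)), duration_min = 45),
    combined = protocol(bind_rows(base, ev(10, 2.5, iaa = TRUE, six = TRUE)),
      duration_min = 40
    )
  )
}
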