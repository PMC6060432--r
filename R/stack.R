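#' Two-channel fluorescence stack
#'
#' Container for a donor (CFP) / acceptor (YFP) time-lapse: two numeric
#' arrays of dimension height x width x frames with a shared timestamp
#' vector in seconds. Intensities must be non-negative where defined; `NA`
#' marks pixels invalidated by registration (left the field of view).
#'
#' @param donor,acceptor Numeric arrays `h x w x n` with equal dimensions.
#' @param time_s Strictly increasing numeric vector of frame timestamps in
#'   seconds, one per frame.
#' @return An object of class `two_channel_stack`.
#' @export
two_channel_stack <- function(donor, acceptor, time_s) {
  if (length(dim(donor)) != 3 || !identical(dim(donor), dim(acceptor))) {
    abort("`donor` and `acceptor` must be h x w x n arrays of equal dimension")
  }
  n <- dim(donor)[3]
  if (length(time_s) != n) abort("one timestamp per frame required")
  if (n > 1 && any(diff(time_s) <= 0)) abort("timestamps must be strictly increasing")
  if (any(donor < 0, na.rm = TRUE) || any(acceptor < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative")
  }
  structure(list(donor = donor, acceptor = acceptor, time_s = as.numeric(time_s)),
    class = "two_channel_stack"
  )
}

#' @export
print.two_channel_stack <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf(
    "<two_channel_stack> %d x %d px, %d frames, %.0f-%.0f s\n",
    d[1], d[2], d[3], min(x$time_s), max(x$time_s)
  ))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [two_channel_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "two_channel_stack"))
  dim(stack$donor)[3]
}

#' Write / read a two-channel movie as multi-page TIFF plus JSON sidecar
#'
#' `write_movie()` stores the donor and acceptor channels as 32-bit
#' multi-page TIFFs (`<name>_donor.tif`, `<name>_acceptor.tif`). Because the
#' TIFF writer stores values in `[0, 1]`, each channel is divided by a scale
#' factor recorded in the sidecar `<name>.json` together with the timestamps;
#' `read_movie()` undoes the scaling. `NA` pixels are written as zeros.
#'
#' @param stack A [two_channel_stack()].
#' @param dir Output directory (created if missing).
#' @param name Basename for the three files.
#' @return `write_movie()` returns the sidecar path invisibly;
#'   `read_movie()` returns a [two_channel_stack()].
#' @export
write_movie <- function(stack, dir, name = "movie") {
  stopifnot(inherits(stack, "two_channel_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_channel <- function(arr, path) {
    arr[is.na(arr)] <- 0
    scale <- max(arr, 1e-12)
    pages <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    scale
  }
  s_d <- write_channel(stack$donor, file.path(dir, paste0(name, "_donor.tif")))
  s_a <- write_channel(stack$acceptor, file.path(dir, paste0(name, "_acceptor.tif")))
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(
      timestamps_s = stack$time_s,
      scale = list(donor = s_d, acceptor = s_a)
    ),
    sidecar,
    auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}

#' @rdname write_movie
#' @export
read_movie <- function(dir, name = "movie") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
    simplifyVector = TRUE
  )
  read_channel <- function(path, scale) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * scale
    arr
  }
  two_channel_stack(
    donor = read_channel(
      file.path(dir, paste0(name, "_donor.tif")), meta$scale$donor
    ),
    acceptor = read_channel(
      file.path(dir, paste0(name, "_acceptor.tif")), meta$scale$acceptor
    ),
    time_s = meta$timestamps_s
  )
}

#' Write / read trace tables as CSV
#'
#' Plain-text interchange for per-cell traces: columns `time_min`, `cell_id`
#' and one value column (`R` for ratio traces, `value` for relative traces).
#'
#' @param traces A trace tibble.
#' @param path CSV file path.
#' @return `read_traces()` returns a tibble.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
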