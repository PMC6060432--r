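#' Somatic ROI with nucleus exclusion
#'
#' The sensor is absent from nuclei, so somatic ROIs exclude the manually
#' delineated nucleus: the measured region is the cytosolic mask
#' `soma & !nucleus`, which must be non-empty.
#'
#' @param soma,nucleus Logical matrices of equal dimension; `nucleus` must be
#'   contained in `soma`. `nucleus` defaults to empty.
#' @param cell_id Cell identifier.
#' @return An object of class `roi_mask` with elements `soma`, `nucleus`,
#'   `cytosol`, `cell_id`.
#' @export
roi_mask <- function(soma, nucleus = NULL, cell_id = "cell_1") {
  if (!is.logical(soma)) abort("`soma` must be a logical matrix")
  if (is.null(nucleus)) nucleus <- array(FALSE, dim = dim(soma))
  if (!is.logical(nucleus) || !identical(dim(soma), dim(nucleus))) {
    abort("`nucleus` must be a logical matrix of the same dimension as `soma`")
  }
  if (any(nucleus & !soma)) abort("nucleus must be contained in soma")
  cytosol <- soma & !nucleus
  if (!any(cytosol)) abort("cytosolic mask (soma minus nucleus) is empty")
  structure(list(soma = soma, nucleus = nucleus, cytosol = cytosol, cell_id = cell_id),
    class = "roi_mask"
  )
}

#' Pixelwise ratio images from a registered stack
#'
#' Divides the acceptor (YFP) by the donor (CFP) channel pixel by pixel.
#' Pixels whose donor intensity is at or below the floor are undefined (`NA`)
#' and excluded from any downstream ROI mean; this guards against division by
#' near-zero background. The default floor is 1% of each donor frame's 99th
#' percentile intensity.
#'
#' @param stack A registered [two_channel_stack()].
#' @param floor Non-negative intensity threshold, or `NULL` for the default.
#' @return An object of class `ratio_stack`: list with `ratio` (array
#'   `h x w x n`, `NA` where undefined) and `time_s`.
#' @export
ratio_stack <- function(stack, floor = NULL) {
  stopifnot(inherits(stack, "two_channel_stack"))
  if (!is.null(floor) && floor < 0) abort("`floor` must be >= 0")
  n <- n_frames(stack)
  ratio <- array(NA_real_, dim = dim(stack$donor))
  for (f in seq_len(n)) {
    d <- stack$donor[, , f]
    a <- stack$acceptor[, , f]
    fl <- if (is.null(floor)) {
      0.01 * quantile(d, 0.99, na.rm = TRUE, names = FALSE)
    } else {
      floor
    }
    ok <- !is.na(d) & !is.na(a) & d > fl
    r <- matrix(NA_real_, nrow(d), ncol(d))
    r[ok] <- a[ok] / d[ok]
    ratio[, , f] <- r
  }
  structure(list(ratio = ratio, time_s = stack$time_s), class = "ratio_stack")
}

#' Extract a per-cell ratio trace from ratio images
#'
#' The mean ratio over the defined pixels of the cytosolic mask, at each time
#' point. Frames in which no cytosolic pixel is defined yield `NA` (missing,
#' never interpolated).
#'
#' @param rstack A [ratio_stack()].
#' @param roi A [roi_mask()] (or, for `extract_traces()`, a list of them).
#' @return A tibble with columns `cell_id`, `time_min`, `R`.
#' @export
extract_trace <- function(rstack, roi) {
  stopifnot(inherits(rstack, "ratio_stack"), inherits(roi, "roi_mask"))
  n <- dim(rstack$ratio)[3]
  cyto <- roi$cytosol
  vals <- vapply(seq_len(n), function(f) {
    px <- rstack$ratio[, , f][cyto]
    px <- px[!is.na(px)]
    if (length(px) == 0) NA_real_ else mean(px)
  }, numeric(1))
  tibble(
    cell_id = roi$cell_id,
    time_min = rstack$time_s / 60,
    R = vals
  )
}

#' @rdname extract_trace
#' @param rois A list of [roi_mask()] objects.
#' @export
extract_traces <- function(rstack, rois) {
  purrr::map_dfr(rois, function(roi) extract_trace(rstack, roi))
}
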