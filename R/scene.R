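# Deterministic substreams: every stochastic corruption draws from its own
# named stream derived from the scene's single integer seed, so adding or
# removing one corruption never perturbs the draws of another.
substream_seed <- function(seed, name) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed, name, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  code
}

ellipse_mask <- function(width, height, ellipse) {
  # ellipse = c(cx, cy, rx, ry), 0-based pixel-center coordinates
  x <- matrix(rep(seq_len(width) - 1, each = height), nrow = height)
  y <- matrix(rep(seq_len(height) - 1, times = width), nrow = height)
  ((x - ellipse[1]) / ellipse[3])^2 + ((y - ellipse[2]) / ellipse[4])^2 <= 1
}

#' One cell of a synthetic scene
#'
#' @param soma,nucleus Ellipses `c(cx, cy, rx, ry)` in 0-based pixel-center
#'   coordinates; the nucleus must lie strictly inside the soma.
#' @param cell_id Identifier matched against the ground-truth trace table.
#' @return A `scene_cell` list.
#' @export
scene_cell <- function(soma, nucleus, cell_id) {
  stopifnot(length(soma) == 4, length(nucleus) == 4)
  structure(list(soma = soma, nucleus = nucleus, cell_id = cell_id),
    class = "scene_cell"
  )
}

#' Synthetic movie scene description
#'
#' Describes the geometry and corruption model of a rendered two-channel
#' movie: cell ellipses, per-channel photon noise and linear photobleaching,
#' an x-y stage-drift path, and transient focus artifacts. A single integer
#' seed fixes all stochastic draws via named substreams.
#'
#' Photon noise is modeled as Gaussian with a standard deviation of
#' `noise_sd * sqrt(intensity)`, adequate at camera-count scales and
#' analytically convenient. A focus artifact dims the donor frame by the
#' factor `artifact_dim`, producing the sharp single-frame ratio spikes that
#' the five-point median filter is designed to remove.
#'
#' @param width,height Image size in pixels.
#' @param cells List of [scene_cell()] objects; somata must not overlap and
#'   each nucleus must lie strictly inside its soma.
#' @param background Background intensity (both channels).
#' @param cell_intensity Donor intensity inside a soma.
#' @param nucleus_ratio Acceptor/donor ratio rendered inside nuclei, where
#'   the sensor is absent.
#' @param noise_sd Length-2 vector `c(donor, acceptor)`: photon-noise scale
#'   per channel (0 disables).
#' @param bleach Length-2 vector `c(donor, acceptor)`: linear intensity drift
#'   rate as fraction per minute (frame intensity is multiplied by
#'   `1 - rate * t_min`, floored at 0).
#' @param drift `NULL`, or a data frame with columns `dx`, `dy` giving the
#'   per-frame translation path in pixels (recycled row-wise is not allowed:
#'   one row per frame).
#' @param artifact_prob Probability per frame of a transient focus artifact.
#' @param artifact_dim Donor dimming factor applied on artifact frames.
#' @param roi_margin_px Margin between the painted cell border and the
#'   ground-truth measurement ROI (default 1 px): the ROI ellipse is shrunk
#'   and the excluded nucleus grown by this amount, the way a manual
#'   delineation avoids boundary pixels that registration resampling mixes
#'   with the surround.
#' @param seed Integer seed fixing all stochastic draws.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(width = 64, height = 64, cells,
                         background = 20, cell_intensity = 100,
                         nucleus_ratio = 1.0,
                         noise_sd = c(0, 0), bleach = c(0, 0),
                         drift = NULL, artifact_prob = 0,
                         artifact_dim = 0.7, roi_margin_px = 1, seed = 1L) {
  if (length(cells) < 1) abort("at least one cell required")
  if (!all(vapply(cells, inherits, logical(1), "scene_cell"))) {
    abort("`cells` must be a list of scene_cell objects")
  }
  soma_masks <- lapply(cells, function(cl) ellipse_mask(width, height, cl$soma))
  overlap <- Reduce(`+`, lapply(soma_masks, function(m) m * 1))
  if (any(overlap > 1)) abort("somata must not overlap")
  for (i in seq_along(cells)) {
    nuc <- ellipse_mask(width, height, cells[[i]]$nucleus)
    if (any(nuc & !soma_masks[[i]])) abort("each nucleus must lie inside its soma")
    if (!any(soma_masks[[i]] & !nuc)) abort("cytosolic region must be non-empty")
  }
  if (length(noise_sd) != 2 || length(bleach) != 2) {
    abort("`noise_sd` and `bleach` must have length 2 (donor, acceptor)")
  }
  if (artifact_prob < 0 || artifact_prob > 1) abort("`artifact_prob` in [0, 1]")
  structure(
    list(
      width = width, height = height, cells = cells,
      background = background, cell_intensity = cell_intensity,
      nucleus_ratio = nucleus_ratio,
      noise_sd = as.numeric(noise_sd), bleach = as.numeric(bleach),
      drift = if (is.null(drift)) NULL else as_tibble(drift),
      artifact_prob = artifact_prob, artifact_dim = artifact_dim,
      roi_margin_px = roi_margin_px,
      seed = as.integer(seed)
    ),
    class = "scene_params"
  )
}

#' Render a synthetic two-channel movie
#'
#' Paints each cell's ground-truth ratio series into acceptor/donor frame
#' pairs, then applies, in order: photobleaching, focus artifacts, x-y stage
#' drift, and photon noise. Noise-free and drift-free, the acceptor/donor
#' mean over each cytosolic ROI equals the cell's ground-truth ratio exactly.
#' All injected corruptions are returned as ground truth so downstream
#' recovery can be tested against them.
#'
#' @param scene A [scene_params()] object.
#' @param traces Tibble with columns `cell_id`, `time_min`, `ratio`: one
#'   ground-truth sensor-ratio series per scene cell, all on the same time
#'   grid.
#' @return A list with elements `stack` (a [two_channel_stack()]) and `truth`
#'   (list: `traces`, `rois` (a list of [roi_mask()]), `shifts` (tibble
#'   `frame, dx, dy`), `artifact_frames`, `bleach`, `scene`).
#' @export
#' @examples
#' sc <- scene_params(
#'   width = 32, height = 32,
#'   cells = list(scene_cell(c(15, 15, 8, 6), c(15, 15, 3, 2), "c1"))
#' )
#' tr <- tibble::tibble(cell_id = "c1", time_min = c(0, 0.25), ratio = 1.2)
#' mv <- render_movie(sc, tr)
#' n_frames(mv$stack)
render_movie <- function(scene, traces) {
  stopifnot(inherits(scene, "scene_params"))
  traces <- as_tibble(traces)
  ids <- vapply(scene$cells, function(cl) as.character(cl$cell_id), character(1))
  if (!setequal(unique(traces$cell_id), ids)) {
    abort("`traces` must contain exactly one series per scene cell")
  }
  wide <- tidyr::pivot_wider(traces,
    id_cols = "time_min", names_from = "cell_id",
    values_from = "ratio"
  )
  wide <- arrange(wide, .data$time_min)
  t_min <- wide$time_min
  n <- length(t_min)
  h <- scene$height
  w <- scene$width

  soma <- lapply(scene$cells, function(cl) ellipse_mask(w, h, cl$soma))
  nuc <- lapply(scene$cells, function(cl) ellipse_mask(w, h, cl$nucleus))
  m <- scene$roi_margin_px
  rois <- lapply(seq_along(scene$cells), function(i) {
    cl <- scene$cells[[i]]
    roi_soma <- ellipse_mask(
      w, h, c(cl$soma[1:2], pmax(cl$soma[3:4] - m, 0.5))
    ) & soma[[i]]
    roi_nuc <- (ellipse_mask(w, h, cl$nucleus + c(0, 0, m, m)) | nuc[[i]]) & roi_soma
    roi_mask(roi_soma, roi_nuc, cell_id = ids[i])
  })

  base_donor <- matrix(scene$background, h, w)
  for (i in seq_along(soma)) base_donor[soma[[i]]] <- scene$cell_intensity

  drift <- scene$drift
  if (is.null(drift)) {
    drift <- tibble(dx = rep(0, n), dy = rep(0, n))
  }
  if (nrow(drift) != n) abort("drift path must have one row per frame")

  artifact_frames <- integer(0)
  if (scene$artifact_prob > 0) {
    artifact_frames <- with_substream(
      scene$seed, "artifact",
      which(runif(n) < scene$artifact_prob)
    )
  }

  donor <- array(0, dim = c(h, w, n))
  acceptor <- array(0, dim = c(h, w, n))
  for (f in seq_len(n)) {
    d <- base_donor
    a <- matrix(scene$background, h, w)
    for (i in seq_along(soma)) {
      cyto <- soma[[i]] & !nuc[[i]]
      a[cyto] <- wide[[ids[i]]][f] * scene$cell_intensity
      a[nuc[[i]]] <- scene$nucleus_ratio * scene$cell_intensity
    }
    d <- d * max(0, 1 - scene$bleach[1] * t_min[f])
    a <- a * max(0, 1 - scene$bleach[2] * t_min[f])
    if (f %in% artifact_frames) d <- d * scene$artifact_dim
    if (drift$dx[f] != 0 || drift$dy[f] != 0) {
      d <- shift_image(d, drift$dx[f], drift$dy[f], fill = scene$background)
      a <- shift_image(a, drift$dx[f], drift$dy[f], fill = scene$background)
    }
    donor[, , f] <- d
    acceptor[, , f] <- a
  }

  if (any(scene$noise_sd > 0)) {
    donor <- with_substream(
      scene$seed, "noise_donor",
      donor + rnorm(length(donor), sd = scene$noise_sd[1] * sqrt(pmax(donor, 0)))
    )
    acceptor <- with_substream(
      scene$seed, "noise_acceptor",
      acceptor + rnorm(length(acceptor), sd = scene$noise_sd[2] * sqrt(pmax(acceptor, 0)))
    )
    donor[donor < 0] <- 0
    acceptor[acceptor < 0] <- 0
  }

  list(
    stack = two_channel_stack(donor, acceptor, time_s = t_min * 60),
    truth = list(
      traces = traces,
      rois = rois,
      shifts = tibble(frame = seq_len(n), dx = drift$dx, dy = drift$dy),
      artifact_frames = artifact_frames,
      bleach = scene$bleach,
      scene = scene
    )
  )
}

#' Lay out non-overlapping cells on a grid
#'
#' Convenience scene builder: places `n_cells` elliptical somata (with
#' nuclei) on a regular grid with mild seeded jitter in size, and returns a
#' [scene_params()] covering them.
#'
#' @param n_cells Number of cells.
#' @param seed Integer seed (shared with the scene).
#' @param spacing_px Grid pitch in pixels.
#' @param ... Passed on to [scene_params()].
#' @return A `scene_params` object whose cells are named `cell_1 ...`.
#' @export
make_grid_scene <- function(n_cells, seed = 1L, spacing_px = 18, ...) {
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  margin <- 12
  width <- ncol_grid * spacing_px + 2 * margin
  height <- nrow_grid * spacing_px + 2 * margin
  sizes <- with_substream(
    seed, "cell_geometry",
    matrix(runif(2 * n_cells, 5.0, 6.5), ncol = 2)
  )
  cells <- lapply(seq_len(n_cells), function(i) {
    row <- (i - 1) %/% ncol_grid
    col <- (i - 1) %% ncol_grid
    cx <- margin + col * spacing_px + spacing_px / 2
    cy <- margin + row * spacing_px + spacing_px / 2
    scene_cell(
      soma = c(cx, cy, sizes[i, 1], sizes[i, 2]),
      nucleus = c(cx, cy, sizes[i, 1] * 0.4, sizes[i, 2] * 0.4),
      cell_id = paste0("cell_", i)
    )
  })
  scene_params(width = width, height = height, cells = cells, seed = seed, ...)
}
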