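#' Translate an image by a (possibly fractional) shift
#'
#' Returns the image with its content moved by `(dx, dy)` pixels (positive =
#' right/down), resampled bilinearly for fractional shifts. Pixels whose
#' source falls outside the field are set to `fill`.
#'
#' @param img Numeric matrix (rows = y, columns = x).
#' @param dx,dy Shift in pixels along columns (x) and rows (y).
#' @param fill Value for pixels leaving the field (default `NA`).
#' @return A matrix of the same dimension.
#' @export
shift_image <- function(img, dx, dy, fill = NA_real_) {
  h <- nrow(img)
  w <- ncol(img)
  # source coordinates: out[i, j] = img[i - dy, j - dx]
  yi <- seq_len(h) - dy
  xj <- seq_len(w) - dx
  y0 <- floor(yi)
  fy <- yi - y0
  x0 <- floor(xj)
  fx <- xj - x0

  gather <- function(rows, cols) {
    ok_r <- rows >= 1 & rows <= h
    ok_c <- cols >= 1 & cols <= w
    r <- pmin(pmax(rows, 1L), h)
    c <- pmin(pmax(cols, 1L), w)
    m <- img[r, c, drop = FALSE]
    m[!ok_r, ] <- NA_real_
    m[, !ok_c] <- NA_real_
    m
  }
  wy <- matrix(fy, h, w)
  wx <- matrix(fx, h, w, byrow = TRUE)
  out <- gather(y0, x0) * (1 - wy) * (1 - wx) +
    gather(y0 + 1, x0) * wy * (1 - wx) +
    gather(y0, x0 + 1) * (1 - wy) * wx +
    gather(y0 + 1, x0 + 1) * wy * wx
  out[is.na(out)] <- fill
  out
}

hann2d <- function(h, w) {
  hv <- if (h > 1) 0.5 * (1 - cos(2 * pi * (seq_len(h) - 1) / (h - 1))) else 1
  wv <- if (w > 1) 0.5 * (1 - cos(2 * pi * (seq_len(w) - 1) / (w - 1))) else 1
  outer(hv, wv)
}

#' Estimate the translation between two images by phase correlation
#'
#' Computes the normalized cross-power spectrum of the two images and locates
#' its correlation peak; the peak position gives the shift `(dx, dy)` such
#' that `img` matches `ref` translated by that amount. The peak is refined to
#' subpixel precision per axis with the two-point estimator of Foroosh et
#' al. (the phase-correlation peak of a fractionally shifted image is a
#' sampled sinc whose two largest samples determine the fraction). Images are
#' Hann-windowed before the FFT to suppress wrap-around edge energy.
#'
#' @param ref,img Numeric matrices of equal dimension; `NA`s are replaced by
#'   the image median before estimation.
#' @param subpixel Refine the integer peak parabolically (default `TRUE`).
#' @param window Apply a Hann window before the FFT (default `TRUE`).
#' @return Named numeric vector `c(dx, dy)`.
#' @export
phase_correlate <- function(ref, img, subpixel = TRUE, window = TRUE) {
  stopifnot(identical(dim(ref), dim(img)))
  fill_na <- function(m) {
    if (anyNA(m)) m[is.na(m)] <- median(m, na.rm = TRUE)
    m
  }
  a <- fill_na(ref)
  b <- fill_na(img)
  if (window) {
    win <- hann2d(nrow(a), ncol(a))
    a <- a * win
    b <- b * win
  }
  cp <- Conj(fft(a)) * fft(b)
  cp <- cp / pmax(Mod(cp), 1e-15)
  r <- Re(fft(cp, inverse = TRUE)) / length(cp)
  h <- nrow(r)
  w <- ncol(r)
  peak <- arrayInd(which.max(r), dim(r))
  i0 <- peak[1]
  j0 <- peak[2]

  wrap <- function(i, n) ((i - 1) %% n) + 1
  refine <- function(cm, c0, cp_) {
    # two-point sinc-peak estimator: the larger neighbour fixes the side
    delta <- if (cp_ >= cm) cp_ / (cp_ + c0) else -cm / (cm + c0)
    if (!is.finite(delta)) {
      return(0)
    }
    max(min(delta, 0.5), -0.5)
  }
  di <- i0 - 1
  dj <- j0 - 1
  if (subpixel) {
    di <- di + refine(r[wrap(i0 - 1, h), j0], r[i0, j0], r[wrap(i0 + 1, h), j0])
    dj <- dj + refine(r[i0, wrap(j0 - 1, w)], r[i0, j0], r[i0, wrap(j0 + 1, w)])
  }
  if (di > h / 2) di <- di - h
  if (dj > w / 2) dj <- dj - w
  c(dx = dj, dy = di)
}

#' Register a two-channel stack by translation
#'
#' Estimates a per-frame translation against a reference frame by phase
#' correlation on the donor + acceptor sum image (channel-independent
#' geometry, better signal-to-noise), and applies the inverse shift
#' identically to both channels with bilinear interpolation. Pixels that
#' leave the field of view become `NA` and are excluded from downstream ROI
#' means. An all-zero (blank) frame is flagged and carries the shift of the
#' previous frame.
#'
#' @param stack A [two_channel_stack()] with at least two frames.
#' @param reference Index of the reference frame (default 1).
#' @return A list with `stack` (the aligned [two_channel_stack()]) and
#'   `shifts`, a tibble with columns `frame`, `dx`, `dy`, `flagged` giving
#'   the estimated displacement of each frame relative to the reference.
#' @export
register_stack <- function(stack, reference = 1L) {
  stopifnot(inherits(stack, "two_channel_stack"))
  n <- n_frames(stack)
  if (n < 2) abort("registration needs at least 2 frames")
  if (reference < 1 || reference > n) abort("`reference` out of range")

  ref_img <- stack$donor[, , reference] + stack$acceptor[, , reference]
  dx <- numeric(n)
  dy <- numeric(n)
  flagged <- logical(n)
  prev <- c(0, 0)
  for (f in seq_len(n)) {
    if (f == reference) {
      dx[f] <- 0
      dy[f] <- 0
      prev <- c(0, 0)
      next
    }
    frame <- stack$donor[, , f] + stack$acceptor[, , f]
    if (all(is.na(frame)) || max(frame, na.rm = TRUE) <= 0) {
      flagged[f] <- TRUE
      dx[f] <- prev[1]
      dy[f] <- prev[2]
      next
    }
    d <- phase_correlate(ref_img, frame)
    dx[f] <- d[["dx"]]
    dy[f] <- d[["dy"]]
    prev <- c(dx[f], dy[f])
  }

  donor <- stack$donor
  acceptor <- stack$acceptor
  for (f in seq_len(n)) {
    if (dx[f] == 0 && dy[f] == 0) next
    donor[, , f] <- shift_image(stack$donor[, , f], -dx[f], -dy[f])
    acceptor[, , f] <- shift_image(stack$acceptor[, , f], -dx[f], -dy[f])
  }
  list(
    stack = two_channel_stack(donor, acceptor, stack$time_s),
    shifts = tibble(frame = seq_len(n), dx = dx, dy = dy, flagged = flagged)
  )
}
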