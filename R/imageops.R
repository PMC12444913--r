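#' Gaussian blur
#'
#' Separable Gaussian filter. The `radius_px` argument is interpreted as the
#' standard deviation sigma in pixels, with the kernel truncated at 4 sigma;
#' borders are handled by symmetric reflection, which conserves total
#' intensity exactly for a normalised kernel.
#'
#' @param plane an `image_plane` or numeric matrix.
#' @param radius_px Gaussian sigma in pixels (> 0).
#' @return Blurred image of the same kind and shape as the input.
#' @export
gaussian_blur <- function(plane, radius_px) {
  if (!is.numeric(radius_px) || length(radius_px) != 1 || radius_px <= 0)
    stop("gaussian_blur: radius_px must be a positive scalar")
  x <- plane_pixels(plane)
  h <- as.integer(ceiling(4 * radius_px))
  k <- stats::dnorm(-h:h, sd = radius_px)
  k <- k / sum(k)
  out <- blur_axis(blur_axis(x, k, rows = TRUE), k, rows = FALSE)
  plane_like(plane, out)
}

# Apply a 1-D kernel along rows (rows = TRUE) or columns via a banded
# operator matrix with reflective (edge-repeating) index folding.
blur_axis <- function(x, k, rows = TRUE) {
  n <- if (rows) nrow(x) else ncol(x)
  h <- (length(k) - 1L) / 2L
  B <- matrix(0, n, n)
  idx <- seq_len(n)
  for (d in -h:h) {
    j <- reflect_index(idx + d, n)
    B[cbind(idx, j)] <- B[cbind(idx, j)] + k[d + h + 1L]
  }
  if (rows) B %*% x else x %*% t(B)
}

# Symmetric reflection with edge repetition: 0 -> 1, -1 -> 2, n+1 -> n, ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  i <- ((i - 1L) %% p + p) %% p          # 0 .. 2n-1
  ifelse(i < n, i + 1L, p - i)
}

# 256-bin histogram over [min, max]; returns counts and bin edges.
intensity_histogram <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[2] - rng[1] <= max(1e-12, 1e-9 * max(abs(rng))))
    stop("degenerate input: image is constant, no threshold exists")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), nbins)
  counts <- tabulate(bin, nbins)
  list(counts = counts, edges = edges,
       centers = (edges[-1] + edges[-(nbins + 1L)]) / 2)
}

#' Otsu threshold
#'
#' Threshold on the 256-equal-width-bin histogram spanning `[min, max]` of the
#' image that maximises the between-class variance. The foreground mask is the
#' set of pixels strictly above the returned value.
#'
#' @param plane an `image_plane` or numeric matrix with at least two distinct
#'   values.
#' @return Threshold intensity (upper edge of the last background bin).
#' @export
threshold_otsu <- function(plane) {
  x <- plane_pixels(plane)
  hg <- intensity_histogram(x)
  cnt <- hg$counts
  n <- sum(cnt)
  w <- cumsum(cnt)                       # pixels in bins 1..k
  mu <- cumsum(cnt * hg$centers)
  mu_t <- mu[length(mu)]
  k <- seq_len(length(cnt) - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, length(k))
  sb[valid] <- (mu_t * w0[valid] / n - mu[k][valid])^2 /
    (w0[valid] / n * w1[valid] / n)
  best <- which.max(sb)
  hg$edges[best + 1L]
}

#' Triangle threshold
#'
#' Geometric triangle method on the 256-bin histogram: a chord is drawn from
#' the histogram peak to the farthest non-empty bin on the longer-tail side,
#' and the threshold is the bin maximising the perpendicular distance to that
#' chord. The returned value is the centre of that bin; the foreground is the
#' tail side (pixels strictly above the threshold when the tail is on the
#' right, strictly below when on the left).
#'
#' @inheritParams threshold_otsu
#' @return Threshold intensity.
#' @export
threshold_triangle <- function(plane) {
  x <- plane_pixels(plane)
  hg <- intensity_histogram(x)
  cnt <- hg$counts
  peak <- which.max(cnt)
  nz <- which(cnt > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  right <- (hi - peak) >= (peak - lo)    # longer-tail side; ties -> right
  tail_bin <- if (right) hi else lo
  if (tail_bin == peak) return(hg$centers[peak])
  span <- if (right) peak:tail_bin else tail_bin:peak
  # distance of (bin, count) to the peak-tail chord
  x1 <- peak; y1 <- cnt[peak]; x2 <- tail_bin; y2 <- cnt[tail_bin]
  d <- abs((y2 - y1) * span - (x2 - x1) * cnt[span] + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  hg$centers[span[which.max(d)]]
}

#' Mean threshold
#'
#' Arithmetic mean of all pixel intensities, the classic parameter-free
#' global threshold used to separate immunopositive processes from neuropil.
#'
#' @inheritParams threshold_otsu
#' @return Mean intensity.
#' @export
threshold_mean <- function(plane) {
  mean(plane_pixels(plane))
}

#' Prominence-based maxima detection
#'
#' Finds intensity maxima in the sense of the classic particle-counting
#' "noise tolerance" rule: a local maximum is reported iff no strictly higher
#' pixel is reachable from it along a path that never descends more than
#' `prominence` below its value. Equal-valued maxima within one tolerance
#' region merge to a single point at the plateau centroid (snapped to the
#' nearest plateau pixel, row-major tie-break); maxima whose plateau touches
#' the image border are suppressed, so a constant image yields none.
#'
#' In `mode = "segmented"` every pixel is additionally assigned to exactly
#' one maximum by flood descent from the maxima (watershed-style), producing
#' the label grid used to split touching synapses.
#'
#' @param plane an `image_plane` or numeric matrix.
#' @param prominence non-negative noise tolerance, in intensity units.
#' @param mode `"points"` or `"segmented"`.
#' @return A list of class `maxima_result` with `points` (n x 2 matrix of
#'   row/col pixel coordinates), `segments` (integer label matrix or `NULL`),
#'   and `prominence`.
#' @export
find_maxima <- function(plane, prominence, mode = c("points", "segmented")) {
  mode <- match.arg(mode)
  if (!is.numeric(prominence) || length(prominence) != 1 || prominence < 0)
    stop("find_maxima: prominence must be a non-negative scalar")
  x <- plane_pixels(plane)
  res <- cpp_find_maxima(x, prominence)
  pts <- res$points
  colnames(pts) <- c("row", "col")
  segments <- NULL
  if (mode == "segmented") {
    segments <- if (nrow(pts) > 0) cpp_flood_segments(x, pts)
                else matrix(0L, nrow(x), ncol(x))
  }
  structure(list(points = pts, segments = segments, prominence = prominence),
            class = "maxima_result")
}

#' @export
print.maxima_result <- function(x, ...) {
  cat(sprintf("<maxima_result> %d maxima (prominence %g)%s\n",
              nrow(x$points), x$prominence,
              if (is.null(x$segments)) "" else ", segmented"))
  invisible(x)
}

# Offsets and heights of a ball (spherical cap) structuring element.
ball_element <- function(radius_px) {
  r <- ceiling(radius_px)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= radius_px^2
  g <- g[keep, , drop = FALSE]
  list(dr = as.integer(g$dr), dc = as.integer(g$dc),
       h = sqrt(radius_px^2 - g$dr^2 - g$dc^2))
}

#' Rolling-ball background estimate
#'
#' Morphological implementation of the rolling-ball background: the
#' background is the grayscale opening of the image with a ball (spherical
#' cap) structuring element of the given radius, i.e. the upper envelope of
#' the ball rolled along the underside of the intensity surface. The estimate
#' never exceeds the image, is exact on constants, and is equivariant to
#' adding a constant.
#'
#' @param plane an `image_plane` or numeric matrix.
#' @param radius_px ball radius in pixels (>= 1).
#' @return Background image of the same kind and shape.
#' @export
rolling_ball_background <- function(plane, radius_px = 7) {
  if (!is.numeric(radius_px) || length(radius_px) != 1 || radius_px < 1)
    stop("rolling_ball_background: radius_px must be >= 1")
  x <- plane_pixels(plane)
  el <- ball_element(radius_px)
  er <- cpp_gray_morph(x, el$dr, el$dc, el$h, 0L)
  bg <- cpp_gray_morph(er, el$dr, el$dc, el$h, 1L)
  plane_like(plane, bg)
}

#' Subtract the rolling-ball background, clipped at zero
#'
#' Convenience wrapper: `max(plane - background, 0)` pixelwise. Negative
#' fluorescence is unphysical, so residuals below the background estimate are
#' clipped.
#' @inheritParams rolling_ball_background
#' @param background optional precomputed background (defaults to
#'   [rolling_ball_background()] of the input).
#' @export
subtract_background <- function(plane, radius_px = 7, background = NULL) {
  x <- plane_pixels(plane)
  bg <- if (is.null(background)) plane_pixels(rolling_ball_background(x, radius_px))
        else plane_pixels(background)
  plane_like(plane, pmax(x - bg, 0))
}

# Offsets of a Euclidean disc of the given radius.
disc_offsets <- function(radius_px) {
  r <- ceiling(radius_px)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius_px^2, , drop = FALSE]
}

#' Binary dilation with a Euclidean disc
#'
#' @param mask logical matrix.
#' @param px disc radius in pixels (>= 1).
#' @return Logical matrix: all pixels within Euclidean distance `px` of the
#'   input mask.
#' @export
dilate_mask <- function(mask, px) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)), px >= 1)
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  off <- disc_offsets(px)
  for (t in seq_len(nrow(off))) {
    di <- off$dr[t]; dj <- off$dc[t]
    si <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 - dj):min(nc, nc - dj)
    out[si, sj] <- out[si, sj] | m[si + di, sj + dj]
  }
  out
}

#' Integer translation registration by cross-correlation
#'
#' Returns the integer shift `(dy, dx)` that maximises the circular
#' cross-correlation of the two (mean-subtracted) images, i.e. `moving` is
#' the reference translated by `dy` rows down and `dx` columns right;
#' applying the negative shift to `moving` maximises its overlap with
#' `reference`. Shifts are reported in `(-n/2, n/2]`.
#'
#' @param reference,moving `image_plane`s or matrices of identical shape.
#' @return Named integer vector `c(dy, dx)`.
#' @export
register_translation <- function(reference, moving) {
  r <- plane_pixels(reference); m <- plane_pixels(moving)
  if (!all(dim(r) == dim(m)))
    stop("register_translation: images must have the same shape")
  r0 <- r - mean(r); m0 <- m - mean(m)
  if (all(r0 == 0) || all(m0 == 0)) {
    warning("register_translation: featureless image, returning (0, 0)")
    return(c(dy = 0L, dx = 0L))
  }
  cc <- Re(stats::fft(Conj(stats::fft(r0)) * stats::fft(m0), inverse = TRUE))
  best <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(k, n) { s <- k - 1L; if (s > n / 2) s - n else s }
  c(dy = as.integer(wrap(best[1], nrow(r))),
    dx = as.integer(wrap(best[2], ncol(r))))
}

#' Apply an integer translation (inverse of a measured shift)
#'
#' Shifts the image by `(dy, dx)` with zero fill, so
#' `shift_image(moving, -register_translation(ref, moving))` aligns `moving`
#' onto `ref`.
#' @param plane image or matrix.
#' @param shift integer `c(dy, dx)`.
#' @export
shift_image <- function(plane, shift) {
  x <- plane_pixels(plane)
  dy <- as.integer(shift[1]); dx <- as.integer(shift[2])
  out <- matrix(0, nrow(x), ncol(x))
  src_r <- seq_len(nrow(x)) - dy
  src_c <- seq_len(ncol(x)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(x)
  ok_c <- src_c >= 1 & src_c <= ncol(x)
  out[ok_r, ok_c] <- x[src_r[ok_r], src_c[ok_c]]
  plane_like(plane, out)
}
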