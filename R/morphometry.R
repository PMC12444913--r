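#' Per-object geometry of a label map
#'
#' Area (pixel count times squared pixel size), intensity-free pixel
#' centroid in micrometres (x right, y down, pixel centre of pixel `(r, c)`
#' at `((c - 0.5) px, (r - 0.5) px)`), and the aspect ratio of the ellipse
#' matched to the region's second central moments. Axis lengths are
#' `4 * sqrt(eigenvalue)` of the moment matrix (so a solid ellipse reproduces
#' its own axes); a per-pixel variance of 1/12 is added to each coordinate so
#' that discrete rectangles reproduce their exact side ratio and single
#' pixels have AR 1.
#'
#' @param labels a `label_map`, or integer matrix (then `pixel_size_nm` is
#'   required).
#' @param pixel_size_nm physical pixel size.
#' @return data.frame with one row per label: `label, area_um2,
#'   centroid_x_um, centroid_y_um, major_um, minor_um, aspect_ratio,
#'   touches_border`.
#' @export
region_properties <- function(labels, pixel_size_nm = NULL) {
  if (inherits(labels, "label_map")) {
    pixel_size_nm <- labels$pixel_size_nm
    lab <- labels$labels
  } else {
    if (is.null(pixel_size_nm)) stop("pixel_size_nm required")
    lab <- labels
  }
  k <- n_labels(lab)
  empty <- data.frame(label = integer(), area_um2 = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      major_um = numeric(), minor_um = numeric(),
                      aspect_ratio = numeric(), touches_border = logical())
  if (k == 0L) return(empty)
  px_um <- pixel_size_nm / 1000
  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(lab) + 1L
  c <- (idx - 1L) %/% nrow(lab) + 1L
  n <- tabulate(l, k)
  sr <- rowsum_vec(r, l, k); sc <- rowsum_vec(c, l, k)
  srr <- rowsum_vec(r * r, l, k); scc <- rowsum_vec(c * c, l, k)
  src <- rowsum_vec(r * c, l, k)
  mr <- sr / n; mc <- sc / n
  vrr <- srr / n - mr^2 + 1 / 12
  vcc <- scc / n - mc^2 + 1 / 12
  vrc <- src / n - mr * mc
  tr <- vrr + vcc
  det <- vrr * vcc - vrc^2
  disc <- sqrt(pmax((tr / 2)^2 - det, 0))
  lam1 <- tr / 2 + disc
  lam2 <- pmax(tr / 2 - disc, 1e-12)
  border <- border_labels(lab)
  data.frame(
    label = seq_len(k),
    area_um2 = n * px_um^2,
    centroid_x_um = (mc - 0.5) * px_um,
    centroid_y_um = (mr - 0.5) * px_um,
    major_um = 4 * sqrt(lam1) * px_um,
    minor_um = 4 * sqrt(lam2) * px_um,
    aspect_ratio = sqrt(lam1 / lam2),
    touches_border = seq_len(k) %in% border
  )
}

rowsum_vec <- function(x, group, k) {
  out <- numeric(k)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s
  out
}

#' Classify synapse orientation from the fitted-ellipse aspect ratio
#'
#' In ultrathin sections a synapse cut edge-on ("side view") appears as an
#' elongated bar while one cut flat ("en face") appears round or oval; the
#' empirical boundary is AR 2.7, with `AR >= threshold` classified side-view.
#'
#' @param AR aspect ratio(s), all `>= 1`.
#' @param threshold classification boundary (default 2.7).
#' @return Character vector, `"side_view"` or `"en_face"`.
#' @export
classify_view <- function(AR, threshold = 2.7) {
  if (any(AR < 1)) stop("classify_view: aspect ratio must be >= 1")
  ifelse(AR >= threshold, "side_view", "en_face")
}

#' Nearest-neighbour distances between synapse centroids
#'
#' For each point, the Euclidean distance to its closest other point.
#'
#' @param centroids two-column matrix/data.frame of (x, y) coordinates in
#'   micrometres.
#' @return Numeric vector of per-point NNDs (empty, with a warning, for
#'   fewer than two points).
#' @export
nearest_neighbor_distances <- function(centroids) {
  p <- as.matrix(centroids)
  n <- nrow(p)
  if (n < 2) {
    warning("nearest_neighbor_distances: fewer than 2 points")
    return(numeric(0))
  }
  # chunked squared-distance computation keeps memory bounded for large n
  nnd2 <- rep(Inf, n)
  s2 <- rowSums(p^2)
  chunk <- max(1L, floor(2e6 / n))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    d2 <- outer(s2[rows], s2, "+") - 2 * p[rows, , drop = FALSE] %*% t(p)
    d2[cbind(seq_along(rows), rows)] <- Inf
    nnd2[rows] <- pmin(nnd2[rows], apply(d2, 1, min))
  }
  sqrt(pmax(nnd2, 0))
}

#' Border-corrected mean nearest-neighbour distance
#'
#' Points whose distance to the nearest field border is smaller than their
#' NND are dropped from the mean (their true nearest neighbour may lie
#' outside the field), removing the upward edge bias of the naive mean.
#'
#' @param centroids two-column (x, y) um matrix.
#' @param field_um field dimensions `c(width_um, height_um)`; the window is
#'   `[0, width] x [0, height]`.
#' @return Mean NND in micrometres (`NA` when no point qualifies).
#' @export
mean_nnd <- function(centroids, field_um) {
  p <- as.matrix(centroids)
  d <- nearest_neighbor_distances(p)
  if (length(d) == 0) return(NA_real_)
  db <- pmin(p[, 1], field_um[1] - p[, 1], p[, 2], field_um[2] - p[, 2])
  keep <- d <= db
  if (!any(keep)) return(NA_real_)
  mean(d[keep])
}

#' Synapse count, density and mean NND of one field
#'
#' Density is the label count divided by the analyzable area; the analyzable
#' mask (when given) excludes cell bodies, fractures and blood vessels from
#' the denominator and defaults to the full imaged area. The mean NND is
#' border-corrected and computed from non-border-truncated labels.
#'
#' @param labels a `label_map`.
#' @param analyzable_mask optional logical matrix of analyzable pixels.
#' @param field_id provenance string.
#' @return One-row data.frame: `field_id, analyzable_area_um2, synapse_count,
#'   density_per_um2, mean_nnd_um`.
#' @export
field_density <- function(labels, analyzable_mask = NULL, field_id = NA_character_) {
  stopifnot(inherits(labels, "label_map"))
  px_um <- labels$pixel_size_nm / 1000
  npx <- if (is.null(analyzable_mask)) length(labels$labels)
         else sum(analyzable_mask)
  if (!is.null(analyzable_mask) &&
      !all(dim(analyzable_mask) == dim(labels$labels)))
    stop("field_density: mask shape mismatch")
  area <- npx * px_um^2
  if (area <= 0) stop("field_density: zero analyzable area")
  count <- n_labels(labels)
  props <- region_properties(labels)
  inner <- props[!props$touches_border, , drop = FALSE]
  field_w <- ncol(labels$labels) * px_um
  field_h <- nrow(labels$labels) * px_um
  m_nnd <- if (nrow(inner) >= 2)
    mean_nnd(inner[, c("centroid_x_um", "centroid_y_um")], c(field_w, field_h))
  else NA_real_
  data.frame(field_id = field_id, analyzable_area_um2 = area,
             synapse_count = count, density_per_um2 = count / area,
             mean_nnd_um = m_nnd)
}
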