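#' Segment PSD-95-positive synaptic puncta
#'
#' The synapse mask is the intersection of two binary masks computed on the
#' Gaussian-blurred PSD-95 channel: (i) the Otsu-threshold mask and (ii) the
#' maxima-segmented particle partition, whose watershed boundaries split
#' merged masks of nearby synapses. The intersection is relabelled as
#' 8-connected components that never cross a segment boundary, so each label
#' lies within exactly one maxima segment. A particle only exists around an
#' accepted intensity maximum, so components that contain no maximum point
#' (threshold slices through structureless noise) are discarded.
#'
#' Thresholding operates on the raw (not background-subtracted) blurred
#' channel; intensity measurements downstream use background-subtracted
#' images instead.
#'
#' @param psd95 PSD-95 `image_plane` (or matrix; then `pixel_size_nm` is
#'   required).
#' @param maxima_prominence noise tolerance for maxima splitting, in the
#'   blurred image's intensity units. No universal value exists; it is chosen
#'   once per experiment and shared across subjects.
#' @param blur_radius_px Gaussian sigma in pixels (default 2).
#' @param min_area_px discard components smaller than this many pixels
#'   (default 2; single-pixel specks are threshold artefacts).
#' @param pixel_size_nm required when `psd95` is a bare matrix.
#' @return A `label_map` of kind `"synapse"`.
#' @export
psd95_synapse_labels <- function(psd95, maxima_prominence, blur_radius_px = 2,
                                 min_area_px = 2L, pixel_size_nm = NULL) {
  px_nm <- plane_pixel_size(psd95, pixel_size_nm)
  x <- plane_pixels(psd95)
  b <- plane_pixels(gaussian_blur(x, blur_radius_px))
  thr <- tryCatch(threshold_otsu(b), error = function(e) NULL)
  if (is.null(thr)) {
    warning("constant image: returning empty synapse label map")
    return(label_map(matrix(0L, nrow(x), ncol(x)), px_nm, "synapse"))
  }
  otsu_mask <- b > thr
  fm <- find_maxima(b, maxima_prominence, mode = "segmented")
  segs <- fm$segments
  mask <- otsu_mask & segs > 0L
  lab <- cpp_label_components(mask, segs)
  # particles exist only around accepted maxima
  if (nrow(fm$points) > 0) {
    keep <- unique(lab[fm$points])
    lab[!(lab %in% keep)] <- 0L
  } else {
    lab[] <- 0L
  }
  lab <- drop_small_labels(lab, min_area_px)
  label_map(lab, px_nm, "synapse")
}

drop_small_labels <- function(lab, min_area_px) {
  if (min_area_px <= 1L || n_labels(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes < min_area_px)
  if (length(small)) lab[lab %in% small] <- 0L
  lab
}

#' Segment PV-immunopositive cell bodies
#'
#' Triangle-threshold mask of the Gaussian-blurred PV channel, kept as
#' 8-connected components of at least `min_area_um2`, minus any regions
#' listed in an exclusion annotation (the scriptable stand-in for manual mask
#' revision). Exclusion ids refer to labels of the pre-exclusion map.
#'
#' @param pv PV-channel `image_plane` (or matrix with `pixel_size_nm`).
#' @param min_area_um2 minimum soma area in square micrometres (default 50).
#' @param exclusions optional integer vector of region ids, or path to a CSV
#'   with a `region_id` column.
#' @param blur_radius_px Gaussian sigma in pixels (default 2).
#' @param pixel_size_nm required for bare matrices.
#' @return A `label_map` of kind `"soma"`.
#' @export
soma_labels <- function(pv, min_area_um2 = 50, exclusions = NULL,
                        blur_radius_px = 2, pixel_size_nm = NULL) {
  px_nm <- plane_pixel_size(pv, pixel_size_nm)
  x <- plane_pixels(pv)
  b <- plane_pixels(gaussian_blur(x, blur_radius_px))
  thr <- threshold_triangle(b)
  mask <- b > thr
  lab <- cpp_label_components(mask)
  px_area_um2 <- (px_nm / 1000)^2
  min_px <- ceiling(min_area_um2 / px_area_um2)
  lab <- drop_small_labels(lab, min_px)
  lab <- relabel_contiguous(lab)
  if (!is.null(exclusions)) {
    ids <- if (is.character(exclusions))
      utils::read.csv(exclusions)$region_id else as.integer(exclusions)
    lab[lab %in% ids] <- 0L
  }
  label_map(lab, px_nm, "soma")
}

#' Neuropil background mask for the PV-soma analysis
#'
#' Mask of PV-negative neuropil: pixels at or below the mean threshold of the
#' unfiltered PV image. By construction it is disjoint from the PV-positive
#' (above-mean) mask; its mean intensity is the background subtracted from
#' somatic PV measurements.
#'
#' @param pv PV-channel `image_plane` or matrix.
#' @return Logical matrix.
#' @export
neuropil_background_mask <- function(pv) {
  x <- plane_pixels(pv)
  x <= threshold_mean(x)
}

#' Segment synapses from the summed PSD-95 + AMPAR + GluN1 fluorescence
#'
#' PSD-95 alone is too weak at synapses on PV-positive dendrites, so the
#' synapse mask for the PV-dendrite experiment is built from the pixelwise
#' sum of the three postsynaptic channels, with the identical
#' threshold-plus-maxima-splitting procedure as [psd95_synapse_labels()].
#'
#' @param psd95,ampar,glun1 congruent registered `image_plane`s or matrices.
#' @inheritParams psd95_synapse_labels
#' @return A `label_map` of kind `"synapse"`.
#' @export
summed_channel_labels <- function(psd95, ampar, glun1, maxima_prominence,
                                  blur_radius_px = 2, min_area_px = 2L,
                                  pixel_size_nm = NULL) {
  px_nm <- plane_pixel_size(psd95, pixel_size_nm)
  a <- plane_pixels(psd95); b <- plane_pixels(ampar); c <- plane_pixels(glun1)
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(c)))
    stop("summed_channel_labels: channels must have identical shape")
  psd95_synapse_labels(a + b + c, maxima_prominence,
                       blur_radius_px = blur_radius_px,
                       min_area_px = min_area_px, pixel_size_nm = px_nm)
}

#' Retain synapses with sufficient integrated PSD-95 fluorescence
#'
#' Keeps labels whose background-subtracted PSD-95 integral exceeds
#' `min_integral` (default 10 AU, the ">10 integrated PSD-95 fluorescence"
#' inclusion rule) and relabels contiguously.
#'
#' @param labels a `label_map`.
#' @param psd95 PSD-95 channel (`image_plane` or matrix), congruent with
#'   `labels`.
#' @param min_integral inclusion threshold on the integral (strictly greater
#'   retained).
#' @param background optional precomputed background image; defaults to the
#'   rolling-ball background (radius 7 px) of `psd95`.
#' @return Filtered `label_map`.
#' @export
filter_by_psd95_integral <- function(labels, psd95, min_integral = 10,
                                     background = NULL) {
  stopifnot(inherits(labels, "label_map"))
  x <- plane_pixels(psd95)
  if (!all(dim(x) == dim(labels$labels)))
    stop("filter_by_psd95_integral: shape mismatch")
  if (n_labels(labels) == 0L) return(labels)
  if (is.null(background)) background <- rolling_ball_background(x, 7)
  ints <- per_synapse_intensity(labels, x, background)
  drop <- ints$label[ints$integral <= min_integral]
  lab <- labels$labels
  lab[lab %in% drop] <- 0L
  label_map(lab, labels$pixel_size_nm, labels$kind)
}

#' Dendrite annotation
#'
#' One annotated dendrite: an ordered polyline in micrometre coordinates
#' (x right, y down, origin at the field's top-left corner), a raster mask,
#' and flags for PV immunopositivity and for thick myelinated axons (which
#' are excluded from synapse-density measurements).
#'
#' @param dendrite_id identifier string.
#' @param polyline two-column matrix/data.frame of (x_um, y_um) vertices.
#' @param mask logical matrix covering the dendrite.
#' @param pv_positive,is_myelinated_axon flags.
#' @return An object of class `dendrite_annotation`.
#' @export
dendrite_annotation <- function(dendrite_id, polyline, mask,
                                pv_positive = TRUE, is_myelinated_axon = FALSE) {
  polyline <- as.matrix(polyline)
  stopifnot(nrow(polyline) >= 1, ncol(polyline) == 2)
  structure(list(dendrite_id = dendrite_id, polyline = polyline, mask = mask,
                 pv_positive = pv_positive,
                 is_myelinated_axon = is_myelinated_axon),
            class = "dendrite_annotation")
}

#' Length of a dendrite annotation in micrometres
#'
#' Cumulative polyline length. If the polyline has a single vertex, the
#' length is estimated from the mask as the extent of its pixels projected
#' on the principal axis.
#' @param dendrite a `dendrite_annotation`.
#' @param pixel_size_nm pixel size, needed only for the mask fallback.
#' @export
dendrite_length_um <- function(dendrite, pixel_size_nm = NULL) {
  pl <- dendrite$polyline
  if (nrow(pl) >= 2) {
    return(sum(sqrt(rowSums(diff(pl)^2))))
  }
  if (is.null(pixel_size_nm)) stop("pixel_size_nm required for mask fallback")
  idx <- which(dendrite$mask, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  ctr <- scale(idx, scale = FALSE)
  v <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)$vectors[, 1]
  proj <- ctr %*% v
  diff(range(proj)) * pixel_size_nm / 1000
}

#' Read dendrite annotations from a polyline CSV
#'
#' Expected columns: `dendrite_id, vertex_index, x_um, y_um, pv_positive,
#' is_myelinated_axon`. Masks are rasterised from the polyline with the given
#' half-width.
#'
#' @param path CSV path.
#' @param dim_px image dimensions `c(nrow, ncol)`.
#' @param pixel_size_nm pixel size.
#' @param halfwidth_um half-width of the rasterised dendrite mask
#'   (default 0.5 um).
#' @return List of `dendrite_annotation`s.
#' @export
read_dendrite_annotations <- function(path, dim_px, pixel_size_nm,
                                      halfwidth_um = 0.5) {
  d <- utils::read.csv(path)
  lapply(split(d, d$dendrite_id), function(g) {
    g <- g[order(g$vertex_index), ]
    pl <- cbind(x_um = g$x_um, y_um = g$y_um)
    dendrite_annotation(
      dendrite_id = as.character(g$dendrite_id[1]), polyline = pl,
      mask = polyline_mask(pl, dim_px, pixel_size_nm, halfwidth_um),
      pv_positive = as.logical(g$pv_positive[1]),
      is_myelinated_axon = as.logical(g$is_myelinated_axon[1]))
  })
}

# Rasterise a tube of the given half-width around a polyline (um coords).
polyline_mask <- function(polyline, dim_px, pixel_size_nm, halfwidth_um) {
  px_um <- pixel_size_nm / 1000
  # pixel centres in um
  nr <- dim_px[1]; nc <- dim_px[2]
  mask <- matrix(FALSE, nr, nc)
  # sample the polyline densely, then mark discs around samples
  pts <- polyline
  if (nrow(pts) >= 2) {
    seglen <- sqrt(rowSums(diff(pts)^2))
    dense <- lapply(seq_len(nrow(pts) - 1), function(k) {
      nstep <- max(2L, ceiling(seglen[k] / (px_um / 2)))
      t <- seq(0, 1, length.out = nstep)
      cbind(pts[k, 1] + t * (pts[k + 1, 1] - pts[k, 1]),
            pts[k, 2] + t * (pts[k + 1, 2] - pts[k, 2]))
    })
    pts <- do.call(rbind, dense)
  }
  rad_px <- halfwidth_um / px_um
  r <- ceiling(rad_px)
  for (k in seq_len(nrow(pts))) {
    cc <- pts[k, 1] / px_um + 0.5   # col index of point
    rr <- pts[k, 2] / px_um + 0.5
    ri <- max(1, floor(rr - r)):min(nr, ceiling(rr + r))
    ci <- max(1, floor(cc - r)):min(nc, ceiling(cc + r))
    if (length(ri) == 0 || length(ci) == 0) next
    sub <- outer((ri - rr)^2, (ci - cc)^2, "+") <= rad_px^2
    mask[ri, ci] <- mask[ri, ci] | sub
  }
  mask
}
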