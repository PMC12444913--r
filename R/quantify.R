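#' Background-subtracted per-synapse intensities
#'
#' Mean and sum of `max(channel - background, 0)` over each label's pixels.
#' The background normally comes from [rolling_ball_background()]; clipping
#' at zero reflects that negative fluorescence is unphysical.
#'
#' @param labels a `label_map`.
#' @param channel intensity image (`image_plane` or matrix) congruent with
#'   `labels`.
#' @param background background image of the same shape.
#' @return data.frame `label, mean, integral` with one row per label.
#' @export
per_synapse_intensity <- function(labels, channel, background) {
  stopifnot(inherits(labels, "label_map"))
  ch <- plane_pixels(channel); bg <- plane_pixels(background)
  lab <- labels$labels
  if (!all(dim(ch) == dim(lab)) || !all(dim(bg) == dim(lab)))
    stop("per_synapse_intensity: shape mismatch")
  k <- n_labels(labels)
  if (k == 0L)
    return(data.frame(label = integer(), mean = numeric(), integral = numeric()))
  diff <- pmax(ch - bg, 0)
  idx <- lab > 0L
  l <- lab[idx]
  n <- tabulate(l, k)
  s <- rowsum_vec(diff[idx], l, k)
  data.frame(label = seq_len(k), mean = s / n, integral = s)
}

#' Normalise paired-channel intensities to the PSD-95 population mean
#'
#' Divides each synapse's paired-channel mean intensity by the population
#' mean of PSD-95 mean intensities within the same immunoreaction, absorbing
#' labelling-efficiency differences between reactions. The result is the
#' "normalized mean intensity" used for all group comparisons of synaptic
#' protein content.
#'
#' @param records data.frame of synapse records with at least the columns
#'   named by `value_col`, `psd95_col` and `by`.
#' @param value_col paired-channel mean-intensity column (default
#'   `"channel_mean"`).
#' @param psd95_col PSD-95 mean-intensity column (default `"psd95_mean"`).
#' @param by grouping column defining one reaction (default `"reaction"`).
#' @return `records` with an added `normalized_mean` column.
#' @export
normalize_to_psd95 <- function(records, value_col = "channel_mean",
                               psd95_col = "psd95_mean", by = "reaction") {
  stopifnot(all(c(value_col, psd95_col, by) %in% names(records)))
  pop <- tapply(records[[psd95_col]], records[[by]], mean)
  if (any(pop == 0)) stop("normalize_to_psd95: zero PSD-95 population mean")
  records$normalized_mean <-
    records[[value_col]] / as.numeric(pop[as.character(records[[by]])])
  records
}

#' Count Munc13-1 nanoclusters per synapse
#'
#' Detects intensity peaks in the Munc13-1 channel with [find_maxima()]
#' (point output, one shared prominence for all subjects of an experiment)
#' and counts the peaks falling inside each synaptic mask dilated by
#' `dilate_px` (the dilation admits presynaptic active zones of side-view
#' synapses, which sit just outside the postsynaptic mask). Where dilated
#' masks overlap, a peak is assigned to the label whose nondilated boundary
#' is nearest.
#'
#' @param munc Munc13-1 `image_plane` or matrix (STED scale, ~20 nm/px).
#' @param labels nondilated synapse `label_map`.
#' @param dilate_px dilation radius in pixels (default 3).
#' @param prominence shared maxima noise tolerance.
#' @return data.frame `label, nanocluster_count`.
#' @export
count_nanoclusters <- function(munc, labels, dilate_px = 3L, prominence) {
  stopifnot(inherits(labels, "label_map"))
  x <- plane_pixels(munc)
  lab <- labels$labels
  if (!all(dim(x) == dim(lab))) stop("count_nanoclusters: shape mismatch")
  k <- n_labels(labels)
  counts <- integer(k)
  if (k > 0L) {
    pts <- find_maxima(x, prominence, mode = "points")$points
    if (nrow(pts) > 0) {
      assign <- assign_points_to_labels(pts, lab, dilate_px)
      tab <- tabulate(assign[assign > 0L], k)
      counts <- tab
    }
  }
  data.frame(label = seq_len(k), nanocluster_count = counts)
}

# Assign each (row, col) point to the label with the nearest pixel within
# Euclidean distance dilate_px (0 = unassigned). Points inside a label keep
# that label.
assign_points_to_labels <- function(points, lab, dilate_px) {
  nr <- nrow(lab); nc <- ncol(lab)
  r <- ceiling(dilate_px)
  vapply(seq_len(nrow(points)), function(t) {
    i <- points[t, 1]; j <- points[t, 2]
    if (lab[i, j] > 0L) return(lab[i, j])
    ri <- max(1, i - r):min(nr, i + r)
    ci <- max(1, j - r):min(nc, j + r)
    sub <- lab[ri, ci, drop = FALSE]
    d2 <- outer((ri - i)^2, (ci - j)^2, "+")
    ok <- sub > 0L & d2 <= dilate_px^2
    if (!any(ok)) return(0L)
    sub[ok][which.min(d2[ok])]
  }, integer(1))
}

#' Spearman correlation between nanocluster count and synaptic area
#'
#' Pooled over en-face synapses, the nanocluster count scales with synapse
#' area; this reports the Spearman rank correlation of that relationship.
#'
#' @param records data.frame with `nanocluster_count`, `area_um2` and
#'   optionally `view` (only `"en_face"` rows are used when present).
#' @return A `correlation_result` (see [spearman_cor()]).
#' @export
nanocluster_area_correlation <- function(records) {
  if (!is.null(records$view)) records <- records[records$view == "en_face", ]
  if (nrow(records) < 3) stop("nanocluster_area_correlation: need n >= 3")
  spearman_cor(records$area_um2, records$nanocluster_count)
}

#' Peak-aligned lateral intensity profiles across a side-view synapse
#'
#' Averages each registered channel inside a rectangular box laid across the
#' synaptic cleft (long axis perpendicular to the PSD-95 bar), producing a
#' 1-D profile per channel, peak-normalised, with the signed offset of each
#' channel's peak from the reference (PSD-95) peak. Sampling uses bilinear
#' interpolation at pixel-size steps, so offsets are integer multiples of
#' the pixel size.
#'
#' @param planes named list of congruent `image_plane`s/matrices, including
#'   the reference channel.
#' @param center box centre `(x_um, y_um)`.
#' @param direction unit-vector `(dx, dy)` of the box's long axis (positive
#'   offsets point along it).
#' @param box_length_nm,box_width_nm box dimensions (defaults 860 x 175 nm).
#' @param reference name of the reference channel (default `"PSD95"`).
#' @param pixel_size_nm required if `planes` holds bare matrices.
#' @return data.frame `channel, offset_nm, peak_position_nm` with the
#'   peak-normalised profiles in `attr(, "profiles")` (positions x channels)
#'   and positions in `attr(, "positions_nm")`.
#' @export
peak_aligned_profile <- function(planes, center, direction,
                                 box_length_nm = 860, box_width_nm = 175,
                                 reference = "PSD95", pixel_size_nm = NULL) {
  stopifnot(is.list(planes), reference %in% names(planes))
  px_nm <- plane_pixel_size(planes[[1]], pixel_size_nm)
  u <- direction / sqrt(sum(direction^2))
  v <- c(-u[2], u[1])                     # across-box unit vector
  half_l <- box_length_nm / 2000          # um
  half_w <- box_width_nm / 2000
  step <- px_nm / 1000
  tpos <- seq(-half_l, half_l, by = step)
  spos <- seq(-half_w, half_w, by = step)
  dims <- dim(plane_pixels(planes[[1]]))
  # sample grid in um
  gx <- outer(tpos * u[1], spos * v[1], "+") + center[1]
  gy <- outer(tpos * u[2], spos * v[2], "+") + center[2]
  if (min(gx) < 0 || min(gy) < 0 || max(gx) > dims[2] * step ||
      max(gy) > dims[1] * step)
    stop("peak_aligned_profile: box exceeds image bounds")
  profiles <- sapply(planes, function(p) {
    x <- plane_pixels(p)
    vals <- bilinear_sample(x, gx, gy, px_nm)
    rowMeans(matrix(vals, nrow = length(tpos)))
  })
  prof_norm <- profiles
  peaks <- integer(ncol(profiles))
  for (ch in seq_len(ncol(profiles))) {
    p <- profiles[, ch]
    if (max(p) <= min(p)) {
      warning(sprintf("peak_aligned_profile: flat channel '%s', peak undefined",
                      colnames(profiles)[ch]))
      prof_norm[, ch] <- NA_real_
      peaks[ch] <- NA_integer_
    } else {
      prof_norm[, ch] <- p / max(p)
      peaks[ch] <- which.max(p)
    }
  }
  pos_nm <- tpos * 1000
  ref_peak <- peaks[match(reference, colnames(profiles))]
  out <- data.frame(
    channel = colnames(profiles),
    offset_nm = round(pos_nm[peaks] - pos_nm[ref_peak]),
    peak_position_nm = round(pos_nm[peaks]))
  attr(out, "profiles") <- prof_norm
  attr(out, "positions_nm") <- pos_nm
  out
}

# Bilinear interpolation of matrix x (image convention: pixel (r, c) centre
# at ((c - .5) px, (r - .5) px) um) at um coordinates (gx, gy).
bilinear_sample <- function(x, gx, gy, pixel_size_nm) {
  px_um <- pixel_size_nm / 1000
  cf <- gx / px_um + 0.5                  # fractional col index
  rf <- gy / px_um + 0.5
  c0 <- pmin(pmax(floor(cf), 1), ncol(x)); c1 <- pmin(c0 + 1, ncol(x))
  r0 <- pmin(pmax(floor(rf), 1), nrow(x)); r1 <- pmin(r0 + 1, nrow(x))
  wc <- pmin(pmax(cf - c0, 0), 1); wr <- pmin(pmax(rf - r0, 0), 1)
  x[cbind(c(r0), c(c0))] * (1 - wr) * (1 - wc) +
    x[cbind(c(r1), c(c0))] * wr * (1 - wc) +
    x[cbind(c(r0), c(c1))] * (1 - wr) * wc +
    x[cbind(c(r1), c(c1))] * wr * wc
}

#' Receptor/PSD-95 ratios and synapse densities on PV-positive dendrites
#'
#' Computes, for one field, per-synapse receptor/PSD-95 integral ratios and
#' the assignment of synapses to annotated PV-positive dendrites ("on PV"
#' means at least `min_overlap_px` shared pixels with a PV dendrite mask;
#' myelinated-axon annotations are ignored). Per-dendrite synapse counts and
#' linear densities (synapses per micrometre of polyline length) are
#' returned alongside.
#'
#' Normalisation to the surrounding (non-PV) population is subject-scoped,
#' so it is performed afterwards by [normalize_pv_ratios()] on the combined
#' records of all of a subject's fields.
#'
#' @param labels synapse `label_map` (from [summed_channel_labels()] +
#'   [filter_by_psd95_integral()]).
#' @param dendrites list of `dendrite_annotation`s.
#' @param channels named list of receptor channel images (e.g. `AMPAR`,
#'   `GluN1`, `GluN2B`).
#' @param psd95 PSD-95 channel image.
#' @param min_overlap_px pixel-overlap rule for "on a PV dendrite"
#'   (default 1).
#' @param background_radius_px rolling-ball radius for intensity backgrounds.
#' @return List with `synapses` (per-synapse ratios, `on_pv_dendrite`,
#'   `dendrite_id`) and `dendrites` (`dendrite_id, length_um, synapse_count,
#'   synapses_per_um`).
#' @export
pv_dendrite_metrics <- function(labels, dendrites, channels, psd95,
                                min_overlap_px = 1L,
                                background_radius_px = 7) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  k <- n_labels(labels)
  use <- Filter(function(d) d$pv_positive && !d$is_myelinated_axon, dendrites)
  psd_bg <- rolling_ball_background(plane_pixels(psd95), background_radius_px)
  psd_int <- per_synapse_intensity(labels, psd95, psd_bg)
  syn <- data.frame(label = seq_len(k), psd95_integral = psd_int$integral)
  for (nm in names(channels)) {
    bg <- rolling_ball_background(plane_pixels(channels[[nm]]),
                                  background_radius_px)
    ints <- per_synapse_intensity(labels, channels[[nm]], bg)
    syn[[paste0(tolower(nm), "_integral")]] <- ints$integral
    syn[[paste0(tolower(nm), "_ratio")]] <- ints$integral / psd_int$integral
  }
  # overlap counts synapse x dendrite
  syn$on_pv_dendrite <- FALSE
  syn$dendrite_id <- NA_character_
  best_overlap <- integer(k)
  dend_rows <- lapply(use, function(d) {
    if (dendrite_length_um(d, labels$pixel_size_nm) <= 0) {
      warning(sprintf("dendrite %s has zero length, skipped", d$dendrite_id))
      return(NULL)
    }
    ov <- tabulate(lab[d$mask & lab > 0L], k)
    hit <- which(ov >= min_overlap_px)
    upgrade <- hit[ov[hit] > best_overlap[hit]]
    best_overlap[upgrade] <<- ov[upgrade]
    syn$on_pv_dendrite[hit] <<- TRUE
    syn$dendrite_id[upgrade] <<- d$dendrite_id
    len <- dendrite_length_um(d, labels$pixel_size_nm)
    data.frame(dendrite_id = d$dendrite_id, length_um = len,
               synapse_count = length(hit),
               synapses_per_um = length(hit) / len)
  })
  dend <- do.call(rbind, dend_rows)
  if (is.null(dend))
    dend <- data.frame(dendrite_id = character(), length_um = numeric(),
                       synapse_count = integer(), synapses_per_um = numeric())
  list(synapses = syn, dendrites = dend)
}

#' Normalise PV-synapse receptor ratios to the surrounding population
#'
#' Divides each PV-dendrite synapse's receptor/PSD-95 ratio by the mean
#' ratio of all non-PV synapses of the same subject (mean-of-ratios;
#' `method = "ratio_of_means"` divides the two populations' integral-ratio
#' means instead). The result is the "normalized synaptic receptor density":
#' 1 means PV synapses match the surrounding population.
#'
#' @param synapses combined per-synapse table of one subject (rows from
#'   [pv_dendrite_metrics()]`$synapses` across fields).
#' @param ratio_cols names of the ratio columns to normalise (default: all
#'   `*_ratio` columns).
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return `synapses` with added `normalized_<channel>_density` columns for
#'   PV rows (`NA` for non-PV rows).
#' @export
normalize_pv_ratios <- function(synapses, ratio_cols = NULL,
                                method = c("mean_of_ratios", "ratio_of_means")) {
  method <- match.arg(method)
  if (is.null(ratio_cols))
    ratio_cols <- grep("_ratio$", names(synapses), value = TRUE)
  non_pv <- synapses[!synapses$on_pv_dendrite, , drop = FALSE]
  if (nrow(non_pv) == 0) stop("normalize_pv_ratios: no non-PV synapses")
  for (rc in ratio_cols) {
    ref <- if (method == "mean_of_ratios") mean(non_pv[[rc]])
    else {
      ch_col <- sub("_ratio$", "_integral", rc)
      sum(non_pv[[ch_col]]) / sum(non_pv$psd95_integral)
    }
    out_col <- paste0("normalized_", sub("_ratio$", "", rc), "_density")
    synapses[[out_col]] <- ifelse(synapses$on_pv_dendrite,
                                  synapses[[rc]] / ref, NA_real_)
  }
  synapses
}

#' Background-subtracted somatic PV intensities and soma density
#'
#' Per-soma mean of the raw (unfiltered) PV channel minus the scalar mean
#' over the neuropil background mask, plus the areal density of PV somata.
#'
#' @param pv PV `image_plane` or matrix.
#' @param somata soma `label_map`.
#' @param background_mask logical matrix from [neuropil_background_mask()].
#' @return List with `somata` (data.frame `soma_id, area_um2,
#'   mean_intensity_bgsub`), `background_mean`, and `soma_density_per_um2`.
#' @export
somatic_pv_metrics <- function(pv, somata, background_mask) {
  stopifnot(inherits(somata, "label_map"))
  x <- plane_pixels(pv)
  lab <- somata$labels
  if (!all(dim(x) == dim(lab))) stop("somatic_pv_metrics: shape mismatch")
  if (!any(background_mask)) stop("somatic_pv_metrics: empty background mask")
  bg <- mean(x[background_mask])
  k <- n_labels(somata)
  px_um <- somata$pixel_size_nm / 1000
  if (k == 0L) {
    df <- data.frame(soma_id = integer(), area_um2 = numeric(),
                     mean_intensity_bgsub = numeric())
  } else {
    idx <- lab > 0L
    l <- lab[idx]
    n <- tabulate(l, k)
    s <- rowsum_vec(x[idx], l, k)
    df <- data.frame(soma_id = seq_len(k), area_um2 = n * px_um^2,
                     mean_intensity_bgsub = s / n - bg)
  }
  list(somata = df, background_mean = bg,
       soma_density_per_um2 = k / (length(lab) * px_um^2))
}
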