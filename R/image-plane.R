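#' Single-channel image plane with physical pixel size
#'
#' The raster currency of the pipeline: one 2-D fluorescence channel in
#' arbitrary intensity units (AU), together with its physical pixel size and
#' provenance (channel label, field, subject, condition). All image operators
#' accept either an `image_plane` or a bare numeric matrix; when given an
#' `image_plane` they return one with the metadata carried over.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size_nm physical edge length of one pixel, in nanometres.
#' @param channel channel label, e.g. `"PSD95"`, `"Munc13-1"`.
#' @param field_id,subject_id,condition provenance strings.
#' @return An object of class `image_plane`.
#' @export
image_plane <- function(pixels, pixel_size_nm, channel = "unknown",
                        field_id = NA_character_, subject_id = NA_character_,
                        condition = NA_character_) {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), nrow(pixels) > 0, ncol(pixels) > 0)
  if (!all(is.finite(pixels))) stop("image_plane: intensities must be finite")
  if (any(pixels < 0)) stop("image_plane: intensities must be >= 0")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 || pixel_size_nm <= 0)
    stop("image_plane: pixel_size_nm must be a positive scalar")
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm, channel = channel,
         field_id = field_id, subject_id = subject_id, condition = condition),
    class = "image_plane"
  )
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %s  %d x %d px @ %g nm/px  [%g, %g] AU\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_plane <- function(x) dim(x$pixels)

# Extract the pixel matrix from an image_plane or pass a matrix through.
plane_pixels <- function(x) {
  if (inherits(x, "image_plane")) x$pixels else as.matrix(x)
}

# Rebuild the same container kind as `template` around new pixels.
plane_like <- function(template, pixels) {
  if (inherits(template, "image_plane")) {
    out <- template
    out$pixels <- pixels
    out
  } else {
    pixels
  }
}

plane_pixel_size <- function(x, pixel_size_nm = NULL) {
  if (!is.null(pixel_size_nm)) return(pixel_size_nm)
  if (inherits(x, "image_plane")) return(x$pixel_size_nm)
  stop("pixel_size_nm is required when the input is a bare matrix")
}

#' Integer-labelled segmentation of one field
#'
#' @param labels integer matrix; 0 is background, positive values index
#'   objects. Labels are relabelled to contiguous `1..K` in scan order.
#' @param pixel_size_nm physical pixel size in nanometres.
#' @param kind one of `"synapse"`, `"soma"`, `"dendrite"`.
#' @return An object of class `label_map` with fields `labels`,
#'   `pixel_size_nm`, `kind`.
#' @export
label_map <- function(labels, pixel_size_nm, kind = c("synapse", "soma", "dendrite")) {
  kind <- match.arg(kind)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) stop("label_map: labels must be >= 0")
  labels <- relabel_contiguous(labels)
  structure(list(labels = labels, pixel_size_nm = pixel_size_nm, kind = kind),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map:%s> %d x %d px @ %g nm/px, %d objects\n",
              x$kind, nrow(x$labels), ncol(x$labels), x$pixel_size_nm,
              n_labels(x)))
  invisible(x)
}

#' Number of objects in a label map
#' @param x a `label_map` or integer matrix.
#' @export
n_labels <- function(x) {
  m <- if (inherits(x, "label_map")) x$labels else x
  if (all(m == 0L)) 0L else max(m)
}

# Map arbitrary positive labels to contiguous 1..K preserving first-occurrence
# (column-major scan) order.
relabel_contiguous <- function(labels) {
  pos <- labels[labels > 0L]
  if (length(pos) == 0L) return(labels)
  u <- unique(pos)
  if (length(u) == max(labels) && all(sort(u) == seq_along(u))) return(labels)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  labels[labels > 0L] <- map[pos]
  labels
}

#' Labels of objects touching the field border
#'
#' Objects truncated by the image border have biased areas and centroids;
#' they are flagged here and excluded from area and nearest-neighbour
#' statistics downstream.
#' @param labels a `label_map` or integer matrix.
#' @return Integer vector of border-touching label ids.
#' @export
border_labels <- function(labels) {
  m <- if (inherits(labels, "label_map")) labels$labels else labels
  b <- c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)])
  sort(unique(b[b > 0L]))
}

#' Read one channel from a TIFF file
#'
#' TIFF metadata in postmortem-tissue archives is unreliable, so the physical
#' pixel size is supplied explicitly (normally from the cohort's sidecar
#' `metadata.csv`), never read from tags.
#'
#' @param path TIFF file path (first page is read).
#' @param pixel_size_nm physical pixel size in nanometres.
#' @param intensity_scale factor the stored `[0, 1]` float values are
#'   multiplied by to recover AU intensities (recorded in the cohort's
#'   sidecar metadata by [write_image_plane()]).
#' @param ... further provenance fields passed to [image_plane()].
#' @return An [image_plane()].
#' @export
read_image_plane <- function(path, pixel_size_nm, intensity_scale = 1, ...) {
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  image_plane(px * intensity_scale, pixel_size_nm = pixel_size_nm, ...)
}

#' Write an image plane (or matrix) to a 32-bit float TIFF
#'
#' Float TIFF storage is defined on `[0, 1]`, so intensities are divided by a
#' scale factor on write; the factor is returned (and recorded in cohort
#' metadata) so [read_image_plane()] can restore the AU values.
#' @param x an `image_plane` or numeric matrix.
#' @param path output file path.
#' @param intensity_scale divisor applied before writing; the default is the
#'   smallest power of two not below the image maximum.
#' @return Invisibly, the scale used.
#' @export
write_image_plane <- function(x, path, intensity_scale = NULL) {
  px <- plane_pixels(x)
  if (is.null(intensity_scale))
    intensity_scale <- 2^max(0, ceiling(log2(max(px, 1))))
  storage.mode(px) <- "double"
  tiff::writeTIFF(px / intensity_scale, path, bits.per.sample = 32)
  invisible(intensity_scale)
}

#' Write a label map as 16-bit TIFF
#' @param x a `label_map`.
#' @param path output file path.
#' @export
write_label_map <- function(x, path) {
  m <- x$labels
  if (max(m) > 65535L) stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16)
  invisible(path)
}
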