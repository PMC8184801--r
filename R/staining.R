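#' Region of interest in pixel coordinates
#'
#' A rectangular ROI described by its top-left corner and size, either
#' directly in pixels or in micrometres with a calibration. Origins are
#' 0-based (package-wide convention).
#'
#' @param y0,x0 top-left corner (0-based).
#' @param height,width extents (> 0).
#' @param unit "px" or "um".
#' @param pixel_size_um required when `unit = "um"`.
#' @return a `RegionOfInterest` with pixel fields `y0`, `x0`, `height`,
#'   `width` (all integer pixels).
#' @export
roi <- function(y0, x0, height, width, unit = c("px", "um"),
                pixel_size_um = NULL) {
  unit <- match.arg(unit)
  if (height <= 0 || width <= 0) abort("ROI size must be positive", "gliadyn_usage_error")
  if (unit == "um") {
    if (is.null(pixel_size_um)) {
      abort("pixel_size_um required for an ROI in micrometres", "gliadyn_calibration_error")
    }
    y0 <- y0 / pixel_size_um; x0 <- x0 / pixel_size_um
    height <- height / pixel_size_um; width <- width / pixel_size_um
  }
  structure(list(y0 = as.integer(round(y0)), x0 = as.integer(round(x0)),
                 height = as.integer(round(height)), width = as.integer(round(width))),
            class = "RegionOfInterest")
}

roi_slice <- function(image, r) {
  ys <- (r$y0 + 1L):(r$y0 + r$height)
  xs <- (r$x0 + 1L):(r$x0 + r$width)
  if (min(ys) < 1L || max(ys) > nrow(image) || min(xs) < 1L || max(xs) > ncol(image)) {
    abort("ROI falls outside the image", "gliadyn_usage_error")
  }
  image[ys, xs]
}

#' Area fraction of staining above a threshold
#'
#' The percentage of pixels strictly above `threshold` within an ROI (or the
#' whole image), i.e. the area of staining normalized to region area. The
#' threshold is an explicit argument, or Otsu when `threshold = "otsu"`; the
#' value used is always recorded.
#'
#' @param image 2D numeric matrix.
#' @param threshold numeric intensity, or "otsu".
#' @param roi a `RegionOfInterest` or NULL for the whole image.
#' @return an `AreaFractionResult`: list with `percent_covered`,
#'   `threshold_used`, `n_pixels`, `roi`.
#' @export
area_fraction <- function(image, threshold, roi = NULL) {
  vals <- if (is.null(roi)) image else roi_slice(image, roi)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(vals) else threshold
  stopifnot(is.numeric(thr), length(thr) == 1L)
  structure(list(percent_covered = 100 * mean(vals > thr),
                 threshold_used = thr,
                 n_pixels = length(vals),
                 roi = roi),
            class = "AreaFractionResult")
}

# Deterministic placement of n square ROIs abutting the bounding box of the
# infusion edge, at the four compass directions (N, S, W, E, then corners for
# n > 4). ROIs that would leave the image are shifted inward; the shift is
# recorded.
place_edge_rois <- function(edge_mask, side_px, n_rois, image_dim) {
  idx <- which(edge_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("empty infusion edge mask", "gliadyn_usage_error")
  ylo <- min(idx[, 1L]) - 1L; yhi <- max(idx[, 1L]) - 1L
  xlo <- min(idx[, 2L]) - 1L; xhi <- max(idx[, 2L]) - 1L
  ymid <- as.integer(round((ylo + yhi) / 2 - side_px / 2))
  xmid <- as.integer(round((xlo + xhi) / 2 - side_px / 2))
  anchors <- list(
    N = c(yhi + 1L, xmid), S = c(ylo - side_px, xmid),
    W = c(ymid, xhi + 1L), E = c(ymid, xlo - side_px),
    NE = c(yhi + 1L, xlo - side_px), NW = c(yhi + 1L, xhi + 1L),
    SE = c(ylo - side_px, xlo - side_px), SW = c(ylo - side_px, xhi + 1L))
  # note: "N" here means toward larger y (below the box in image coordinates);
  # labels are placement ids, not anatomical directions
  out <- list()
  for (k in seq_len(n_rois)) {
    a <- anchors[[((k - 1L) %% length(anchors)) + 1L]]
    y0 <- a[1L]; x0 <- a[2L]
    y0s <- min(max(y0, 0L), image_dim[1L] - side_px)
    x0s <- min(max(x0, 0L), image_dim[2L] - side_px)
    if (y0s < 0L || x0s < 0L) {
      abort("ROI larger than the image", "gliadyn_usage_error")
    }
    r <- roi(y0s, x0s, side_px, side_px)
    attr(r, "shifted") <- (y0s != y0) || (x0s != x0)
    attr(r, "placement") <- names(anchors)[((k - 1L) %% length(anchors)) + 1L]
    out[[k]] <- r
  }
  out
}

#' Mean puncta coverage in fixed ROIs at the infusion edge
#'
#' Places `n_rois` square ROIs of side `roi_size_um` deterministically at the
#' compass positions abutting the bounding box of the infusion edge, computes
#' the per-ROI area fraction of puncta signal above `threshold`, and returns
#' their mean (one value per infusion site). ROIs that would leave the image
#' are shifted inward, never clipped; shifts are flagged per ROI.
#'
#' @param image 2D numeric puncta image.
#' @param infusion_edge_mask logical mask of the infusion edge (non-empty).
#' @param threshold intensity threshold or "otsu".
#' @param roi_size_um ROI side length in micrometres (default 200).
#' @param n_rois number of ROIs (default 4).
#' @param pixel_size_um calibration, micrometres per pixel.
#' @return list with `mean_pct`, `per_roi_pct`, `rois`, `threshold_used`.
#' @export
puncta_coverage <- function(image, infusion_edge_mask, threshold,
                            roi_size_um = 200, n_rois = 4L, pixel_size_um) {
  check_calibration(pixel_size_um, 1, 1, 16L)
  side_px <- as.integer(round(roi_size_um / pixel_size_um))
  rois <- place_edge_rois(infusion_edge_mask, side_px, n_rois, dim(image))
  thr <- if (identical(threshold, "otsu")) otsu_threshold(image) else threshold
  per <- vapply(rois, function(r) area_fraction(image, thr, r)$percent_covered,
                numeric(1))
  list(mean_pct = mean(per), per_roi_pct = per, rois = rois,
       threshold_used = thr,
       shifted = vapply(rois, function(r) isTRUE(attr(r, "shifted")), logical(1)))
}

#' Fraction of labeled cells containing signal
#'
#' The uptake read-out: the percentage of labeled cells (e.g. IBA1-positive
#' microglia) whose footprint overlaps the signal mask (e.g. labeled
#' amyloid-beta) by at least `min_overlap_px` pixels.
#'
#' @param cell_label_image integer label image (0 = background, cells numbered
#'   from 1; ids need not be consecutive).
#' @param signal_mask logical mask, same shape.
#' @param min_overlap_px minimum overlapping pixels for a cell to count
#'   (default 1).
#' @return list with `percent_positive`, `n_cells`, `n_positive`,
#'   `positive_ids`.
#' @export
uptake_fraction <- function(cell_label_image, signal_mask, min_overlap_px = 1L) {
  stopifnot(all(dim(cell_label_image) == dim(signal_mask)))
  ids <- sort(unique(cell_label_image[cell_label_image > 0]))
  if (length(ids) == 0L) abort("no labeled cells", "gliadyn_usage_error")
  ov <- table(factor(cell_label_image[signal_mask & cell_label_image > 0], levels = ids))
  pos <- ids[as.numeric(ov) >= min_overlap_px]
  list(percent_positive = 100 * length(pos) / length(ids),
       n_cells = length(ids), n_positive = length(pos), positive_ids = pos)
}

# shift a 3D array by integer offsets, zero fill
shift3d <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(0, d)
  zs <- seq_len(d[1L]); ys <- seq_len(d[2L]); xs <- seq_len(d[3L])
  z_to <- zs + dz; y_to <- ys + dy; x_to <- xs + dx
  okz <- z_to >= 1L & z_to <= d[1L]
  oky <- y_to >= 1L & y_to <= d[2L]
  okx <- x_to >= 1L & x_to <= d[3L]
  out[z_to[okz], y_to[oky], x_to[okx]] <- a[zs[okz], ys[oky], xs[okx]]
  out
}

#' Microglial coverage of the plaque surface
#'
#' Both stacks are floored at `intensity_floor` (voxels below it removed as
#' background). The plaque surface is the set of plaque foreground voxels with
#' at least one background 6-neighbor; a surface voxel counts as covered when
#' microglia foreground lies within `contact_radius_px` (Chebyshev metric).
#' The score is 100 x covered / surface voxels.
#'
#' @param plaque_stack,microglia_stack co-registered 3D arrays (Z, Y, X) of
#'   identical shape.
#' @param intensity_floor voxels strictly below this are background
#'   (default 500, the standard background cut for these acquisitions).
#' @param contact_radius_px Chebyshev contact distance in voxels (default 1).
#' @return list with `percent_covered`, `n_surface_voxels`,
#'   `n_covered_voxels`, `intensity_floor`.
#' @export
plaque_surface_coverage <- function(plaque_stack, microglia_stack,
                                    intensity_floor = 500,
                                    contact_radius_px = 1L) {
  stopifnot(all(dim(plaque_stack) == dim(microglia_stack)),
            length(dim(plaque_stack)) == 3L)
  fg_p <- plaque_stack >= intensity_floor
  if (!any(fg_p)) abort("plaque empty after intensity floor", "gliadyn_segmentation_error")
  fg_m <- microglia_stack >= intensity_floor
  # surface: plaque voxels with a background 6-neighbor (image border counts
  # as background)
  interior <- fg_p
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    interior <- interior & shift3d(fg_p, o[1L], o[2L], o[3L])
  }
  surface <- fg_p & !interior
  # Chebyshev dilation of the microglia foreground
  near <- fg_m
  if (contact_radius_px > 0L && any(fg_m)) {
    r <- as.integer(contact_radius_px)
    acc <- array(FALSE, dim(fg_m))
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      acc <- acc | shift3d(fg_m, dz, dy, dx)
    }
    near <- acc
  }
  n_surf <- sum(surface)
  n_cov <- sum(surface & near)
  list(percent_covered = 100 * n_cov / n_surf,
       n_surface_voxels = n_surf, n_covered_voxels = n_cov,
       intensity_floor = intensity_floor,
       contact_radius_px = as.integer(contact_radius_px))
}

#' Ordinary least-squares helper for coverage relationships
#'
#' Convenience wrapper relating one staining read-out to another (e.g. plaque
#' surface coverage against plaque burden) by simple linear regression.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `slope`, `intercept`, `r_squared`, and the `lm` fit.
#' @export
coverage_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = s$r.squared, fit = fit)
}
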