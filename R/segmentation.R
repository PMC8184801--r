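#' Otsu threshold
#'
#' Histogram threshold minimizing the weighted intra-class intensity variance
#' (equivalently maximizing the between-class variance). Foreground is defined
#' strictly: pixels with intensity greater than the returned threshold. For
#' images whose integer range already fits 256 values the histogram is exact;
#' wider (e.g. 16-bit) data are binned into `nbins` equal-width bins unless
#' `exact = TRUE`, in which case every distinct value is a candidate.
#'
#' The returned threshold is the midpoint between the largest background-class
#' value and the smallest foreground-class value, so `image > threshold`
#' reproduces the minimizing split exactly and the threshold lies strictly
#' between the two classes. Ties are broken toward the smallest threshold.
#'
#' @param image numeric array of intensities.
#' @param nbins number of histogram bins for wide-range data (default 256).
#' @param exact if TRUE, use every distinct intensity as a candidate split.
#' @return the threshold, a scalar intensity.
#' @export
otsu_threshold <- function(image, nbins = 256L, exact = FALSE) {
  x <- as.numeric(image)
  ux <- unique(x)
  if (length(ux) < 2L) {
    abort("Otsu threshold undefined for a constant image", "gliadyn_degenerate_error")
  }
  integral <- all(x == round(x))
  if (exact || (integral && (max(x) - min(x)) < nbins)) {
    vals <- sort(ux)
    cnt <- as.numeric(table(factor(x, levels = vals)))
    vmin <- vals; vmax <- vals
  } else {
    lo <- min(x); hi <- max(x)
    w <- (hi - lo) / nbins
    b <- pmin(nbins - 1L, floor((x - lo) / w))
    cnt <- tabulate(b + 1L, nbins)
    # attained extremes per bin, so the returned threshold splits the data
    # exactly as the binning does
    vmin <- vapply(seq_len(nbins) - 1L, function(k) {
      in_bin <- b == k
      if (any(in_bin)) min(x[in_bin]) else NA_real_
    }, numeric(1))
    vmax <- vapply(seq_len(nbins) - 1L, function(k) {
      in_bin <- b == k
      if (any(in_bin)) max(x[in_bin]) else NA_real_
    }, numeric(1))
    keep <- !is.na(vmax)
    vmin <- vmin[keep]; vmax <- vmax[keep]; cnt <- cnt[keep]
    vals <- vmax
  }
  n <- sum(cnt)
  csum <- cumsum(cnt)
  s0 <- cumsum(cnt * vals)
  stot <- s0[length(s0)]
  # between-class variance for the split after bin i (background = bins 1..i);
  # maximizing it is exactly minimizing the weighted intra-class variance
  i <- seq_len(length(vals) - 1L)
  w0 <- csum[i]; w1 <- n - w0
  m0 <- s0[i] / w0
  m1 <- (stot - s0[i]) / w1
  sigma_b <- (w0 / n) * (w1 / n) * (m0 - m1)^2
  best <- i[which.max(sigma_b)]
  (vmax[best] + vmin[best + 1L]) / 2
}

#' Segment the infusion site from a red-channel image
#'
#' The mask chain used throughout the dynamics read-outs: Otsu binarize
#' (foreground strictly above threshold), remove 8-connected components
#' smaller than `min_feature_area_px`, then dilate with a Euclidean disc of
#' `dilation_radius_px` to smooth the border and absorb the dim diffusion
#' gradient around the bolus. All parameters are recorded in the result.
#'
#' @param image 2D numeric matrix (typically a sum projection of the infusion
#'   channel).
#' @param min_feature_area_px components below this area are discarded
#'   (default 64).
#' @param dilation_radius_px disc radius for the smoothing dilation
#'   (default 3).
#' @param allow_empty if FALSE (default), an empty mask after cleanup is an
#'   error.
#' @param threshold optional externally supplied threshold; default is Otsu.
#' @return an `InfusionMask`: list with `mask` (logical), `threshold_used`,
#'   `min_feature_area_px`, `dilation_radius_px`.
#' @export
segment_infusion <- function(image, min_feature_area_px = 64L,
                             dilation_radius_px = 3L, allow_empty = FALSE,
                             threshold = NULL) {
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  mask <- image > threshold
  mask <- remove_small_components(mask, min_feature_area_px)
  mask <- dilate_mask(mask, dilation_radius_px)
  if (!any(mask) && !allow_empty) {
    abort("segmentation produced an empty mask (try lowering min_feature_area_px)",
          "gliadyn_segmentation_error")
  }
  structure(list(mask = mask,
                 threshold_used = threshold,
                 min_feature_area_px = as.integer(min_feature_area_px),
                 dilation_radius_px = as.integer(dilation_radius_px),
                 erosion_radius_px = NA_integer_),
            class = "InfusionMask")
}

#' @export
print.InfusionMask <- function(x, ...) {
  cat(sprintf("InfusionMask: %d foreground px | threshold %.4g, min area %d px, dilation %d px\n",
              sum(x$mask), x$threshold_used, x$min_feature_area_px,
              x$dilation_radius_px))
  invisible(x)
}

#' Infusion volume from a 3D stack by voxel counting
#'
#' Otsu-binarizes the stack, keeps the largest 26-connected component (plus,
#' optionally, every component at least `min_feature_area_px` voxels), and
#' converts the voxel count with a user-supplied voxel volume. The voxel
#' volume is a calibration input and is never derived from pixel sizes here.
#'
#' @param stack3d 3D array (Z, Y, X).
#' @param voxel_volume_um3 volume per voxel in cubic micrometres (> 0).
#' @param min_feature_area_px minimum voxel count for secondary components
#'   when `keep_all_large = TRUE` (default 64).
#' @param keep_all_large keep all sufficiently large components instead of
#'   only the largest (default FALSE).
#' @return a `VolumeEstimate`: list with `n_foreground_voxels`,
#'   `voxel_volume_um3`, `total_volume_um3` (exact product), and `mask`.
#' @export
infusion_volume <- function(stack3d, voxel_volume_um3,
                            min_feature_area_px = 64L, keep_all_large = FALSE) {
  stopifnot(length(dim(stack3d)) == 3L)
  if (!is.numeric(voxel_volume_um3) || voxel_volume_um3 <= 0) {
    abort("voxel_volume_um3 must be positive", "gliadyn_usage_error")
  }
  thr <- otsu_threshold(stack3d)
  fg <- stack3d > thr
  if (!any(fg)) abort("empty foreground after thresholding", "gliadyn_segmentation_error")
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- if (keep_all_large) which(sizes >= min_feature_area_px) else 1L
  mask <- array(lab %in% keep, dim(stack3d))
  n <- sum(mask)
  if (n == 0L) abort("no component survived the size filter", "gliadyn_segmentation_error")
  structure(list(n_foreground_voxels = n,
                 voxel_volume_um3 = voxel_volume_um3,
                 total_volume_um3 = n * voxel_volume_um3,
                 threshold_used = thr,
                 mask = mask),
            class = "VolumeEstimate")
}

#' @export
print.VolumeEstimate <- function(x, ...) {
  cat(sprintf("VolumeEstimate: %d voxels x %.4g um^3 = %.6g um^3\n",
              x$n_foreground_voxels, x$voxel_volume_um3, x$total_volume_um3))
  invisible(x)
}
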