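#' Baseline intensity statistics of the microglia channel
#'
#' Mean and population standard deviation of the green (microglia) channel at
#' a baseline frame, either within the infusion mask (the default, matching
#' the coverage definition) or over the whole frame. These statistics define
#' the detection threshold `mean + k * sd` used by both the coverage and the
#' distance series.
#'
#' @param green_frame 2D numeric matrix: one frame of the microglia-channel
#'   projection.
#' @param mask an `InfusionMask` (required when `region = "within_mask"`).
#' @param region "within_mask" or "whole_frame".
#' @param frame_index index of the baseline frame, recorded for provenance
#'   (default 1, i.e. t = 0).
#' @return a `BaselineStats`: list with `mean`, `sd` (population), `region`,
#'   `frame_index`.
#' @export
baseline_statistics <- function(green_frame, mask = NULL,
                                region = c("within_mask", "whole_frame"),
                                frame_index = 1L) {
  region <- match.arg(region)
  vals <- if (region == "within_mask") {
    if (is.null(mask) || !inherits(mask, "InfusionMask")) {
      abort("region = 'within_mask' requires an InfusionMask", "gliadyn_usage_error")
    }
    if (!any(mask$mask)) abort("empty mask region", "gliadyn_usage_error")
    green_frame[mask$mask]
  } else {
    as.numeric(green_frame)
  }
  structure(list(mean = mean(vals), sd = sd_pop(vals),
                 region = region, frame_index = as.integer(frame_index)),
            class = "BaselineStats")
}

# the detection rule shared by coverage and distance series
detection_threshold <- function(baseline, k, include_mean = TRUE) {
  if (include_mean) baseline$mean + k * baseline$sd else k * baseline$sd
}

#' Percent coverage of the infusion site by microglial processes over time
#'
#' Per frame, the percentage of infusion-mask pixels whose microglia-channel
#' intensity exceeds the detection threshold `baseline mean + k * baseline sd`
#' (the bare `k * sd` variant is selectable with `include_mean = FALSE`).
#'
#' @param proj a `Projection2D` (registered).
#' @param mask an `InfusionMask` with non-empty foreground.
#' @param baseline a `BaselineStats`; default: computed within the mask at the
#'   first frame.
#' @param k threshold multiplier (default 1.5).
#' @param include_mean if TRUE (default) the threshold is mean + k*sd.
#' @return a `CoverageSeries` data.frame: `t_min`, `coverage_pct`,
#'   `n_mask_px`, with the threshold rule in attributes.
#' @export
coverage_series <- function(proj, mask, baseline = NULL, k = 1.5,
                            include_mean = TRUE) {
  stopifnot(inherits(proj, "Projection2D"), inherits(mask, "InfusionMask"))
  if (!any(mask$mask)) abort("empty infusion mask", "gliadyn_usage_error")
  if (is.null(baseline)) {
    baseline <- baseline_statistics(projection_frame(proj, 1L, "microglia"), mask)
  }
  thr <- detection_threshold(baseline, k, include_mean)
  nt <- dim(proj$data)[1L]
  nmask <- sum(mask$mask)
  cov <- vapply(seq_len(nt), function(t) {
    g <- projection_frame(proj, t, "microglia")
    100 * sum(g[mask$mask] > thr) / nmask
  }, numeric(1))
  out <- data.frame(t_min = (seq_len(nt) - 1L) * proj$frame_interval_min,
                    coverage_pct = cov, n_mask_px = nmask)
  attr(out, "threshold_rule") <- list(k = k, include_mean = include_mean,
                                      baseline_mean = baseline$mean,
                                      baseline_sd = baseline$sd,
                                      baseline_region = baseline$region,
                                      baseline_frame = baseline$frame_index,
                                      threshold = thr)
  class(out) <- c("CoverageSeries", "data.frame")
  out
}

#' Euclidean distance map to the (eroded) infusion mask
#'
#' Erodes the infusion mask with a Euclidean disc, then computes the exact
#' Euclidean distance of every pixel to the nearest foreground pixel of the
#' eroded mask, converted to micrometres. Its level sets are the concentric
#' proximity bands around the infusion site; the map is zero exactly on the
#' eroded foreground.
#'
#' @param mask an `InfusionMask`.
#' @param erosion_radius_px disc radius for the preliminary erosion
#'   (default 2).
#' @param pixel_size_um in-plane calibration, micrometres per pixel.
#' @return a `DistanceMap`: list with `distances_um` (Y x X matrix),
#'   `erosion_radius_px`, `pixel_size_um`, `eroded_mask`.
#' @export
eroded_distance_map <- function(mask, erosion_radius_px = 2L, pixel_size_um) {
  stopifnot(inherits(mask, "InfusionMask"))
  check_calibration(pixel_size_um, 1, 1, 16L)
  er <- erode_mask(mask$mask, erosion_radius_px)
  if (!any(er)) {
    abort("erosion emptied the mask; use a smaller erosion_radius_px",
          "gliadyn_segmentation_error")
  }
  d_px <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - er), metric = "euclidean"))
  structure(list(distances_um = d_px * pixel_size_um,
                 erosion_radius_px = as.integer(erosion_radius_px),
                 pixel_size_um = pixel_size_um,
                 eroded_mask = er),
            class = "DistanceMap")
}

#' Mean microglia-to-infusion distance over time
#'
#' Per frame, every microglia-channel pixel above the detection threshold is
#' assigned its distance-map value (distance in micrometres to the edge of the
#' infusion site) and the mean is reported. Frames with no qualifying pixel
#' yield NA rather than 0, so they cannot bias approach-speed fits; the count
#' of such frames is recorded.
#'
#' @param proj a `Projection2D` (registered).
#' @param dmap a `DistanceMap` of matching Y x X shape.
#' @param baseline a `BaselineStats`; default: within-mask statistics of the
#'   first frame require `mask`.
#' @param mask `InfusionMask`, only needed when `baseline` is NULL.
#' @param k threshold multiplier (default 1.5).
#' @param include_mean threshold is mean + k*sd (TRUE, default) or bare k*sd.
#' @param exclude_inside if TRUE, pixels at distance 0 (inside the eroded
#'   mask) are not counted.
#' @return a `DistanceSeries` data.frame: `t_min`, `mean_distance_um`,
#'   `n_pixels_counted`.
#' @export
mean_distance_series <- function(proj, dmap, baseline = NULL, mask = NULL,
                                 k = 1.5, include_mean = TRUE,
                                 exclude_inside = FALSE) {
  stopifnot(inherits(proj, "Projection2D"), inherits(dmap, "DistanceMap"))
  g1 <- projection_frame(proj, 1L, "microglia")
  if (!all(dim(g1) == dim(dmap$distances_um))) {
    abort("projection and distance map shapes differ", "gliadyn_usage_error")
  }
  if (is.null(baseline)) {
    if (is.null(mask)) abort("need a baseline or a mask to derive one", "gliadyn_usage_error")
    baseline <- baseline_statistics(g1, mask)
  }
  thr <- detection_threshold(baseline, k, include_mean)
  nt <- dim(proj$data)[1L]
  res <- lapply(seq_len(nt), function(t) {
    g <- projection_frame(proj, t, "microglia")
    sel <- g > thr
    if (exclude_inside) sel <- sel & dmap$distances_um > 0
    n <- sum(sel)
    c(if (n == 0L) NA_real_ else mean(dmap$distances_um[sel]), n)
  })
  m <- do.call(rbind, res)
  n_missing <- sum(is.na(m[, 1L]))
  if (n_missing > 0L) {
    warning(sprintf("%d frame(s) had no qualifying pixels; recorded as NA", n_missing))
  }
  out <- data.frame(t_min = (seq_len(nt) - 1L) * proj$frame_interval_min,
                    mean_distance_um = m[, 1L], n_pixels_counted = as.integer(m[, 2L]))
  attr(out, "threshold_rule") <- list(k = k, include_mean = include_mean,
                                      threshold = thr,
                                      exclude_inside = exclude_inside,
                                      erosion_radius_px = dmap$erosion_radius_px)
  attr(out, "n_missing_frames") <- n_missing
  class(out) <- c("DistanceSeries", "data.frame")
  out
}

#' Least-squares approach speed from a distance series
#'
#' Ordinary least-squares slope of mean distance against time over a stated
#' frame window (typically the pre-contact interval). The approach speed is
#' the negated slope, in micrometres per minute.
#'
#' @param series a `DistanceSeries`.
#' @param frames integer indices of the frames to fit (default: all
#'   non-missing).
#' @return list with `slope_um_per_min`, `speed_um_per_min` (= -slope) and
#'   `n_frames`.
#' @export
fit_approach_speed <- function(series, frames = NULL) {
  stopifnot(inherits(series, "DistanceSeries"))
  if (is.null(frames)) frames <- seq_len(nrow(series))
  d <- series[frames, ]
  d <- d[!is.na(d$mean_distance_um), ]
  if (nrow(d) < 2L) abort("need at least two non-missing frames", "gliadyn_usage_error")
  fit <- stats::lm(mean_distance_um ~ t_min, data = d)
  slope <- unname(stats::coef(fit)[2L])
  list(slope_um_per_min = slope, speed_um_per_min = -slope, n_frames = nrow(d))
}

#' Red/green displacement composite
#'
#' The display used for time-lapse panels: the microglia channel at `t0`
#' mapped to red, at `t1` to green (yellow where they overlap), and the
#' infusion mask overlaid in white. Each channel is normalized by its own
#' maximum (deterministic, recorded in attributes).
#'
#' @param proj a `Projection2D`.
#' @param t0,t1 frame indices (1-based); `t0 == t1` is allowed.
#' @param mask an `InfusionMask` or NULL.
#' @return Y x X x 3 array in [0, 1] with attribute `normalization`.
#' @export
displacement_composite <- function(proj, t0, t1, mask = NULL) {
  stopifnot(inherits(proj, "Projection2D"))
  nt <- dim(proj$data)[1L]
  if (t0 < 1L || t0 > nt || t1 < 1L || t1 > nt) {
    abort("t0/t1 out of range", "gliadyn_usage_error")
  }
  r <- projection_frame(proj, t0, "microglia")
  g <- projection_frame(proj, t1, "microglia")
  mr <- max(r); mg <- max(g)
  r <- if (mr > 0) r / mr else r
  g <- if (mg > 0) g / mg else g
  out <- array(0, c(nrow(r), ncol(r), 3L))
  out[, , 1L] <- r
  out[, , 2L] <- g
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "InfusionMask"))
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[mask$mask] <- 1
      out[, , ch] <- plane
    }
  }
  attr(out, "normalization") <- list(max_t0 = mr, max_t1 = mg)
  out
}
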