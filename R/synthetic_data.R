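#' Simulation configuration for two-photon-like time-lapse movies
#'
#' Defines the acquisition geometry, the infusion blob, the microglia, their
#' approach kinetics and the noise model for \code{\link{generate_timelapse}}.
#' Defaults mirror the acquisition this pipeline targets (0.4 um/px in-plane,
#' 3 um z-step, one stack per minute) at a desk-testable matrix size
#' (8 x 256 x 256 x 20 frames rather than 11 x 1024 x 1024 x 80; the full
#' scale is reachable through `image_shape`).
#'
#' Intensity amplitudes are photon counts summed over z (the scale the sum
#' projection sees). Noise is Poisson shot noise on the per-slice signal,
#' scaled by `photon_gain`, plus optional additive Gaussian read noise;
#' `noise_gaussian_sd = 0` by default, the shot-noise-limited regime of
#' photon-counting PMTs.
#'
#' @param image_shape integer (T, Z, Y, X).
#' @param pixel_size_um,z_step_um,frame_interval_min acquisition calibration.
#' @param blob_center (z, y, x) in 0-based pixels; default: image center.
#' @param blob_radius_um radius of the infusion bolus.
#' @param blob_edge_sigma_px Gaussian falloff of the blob edge, pixels.
#' @param n_microglia number of cells on the initial ring.
#' @param soma_ring_radius_um initial distance of somata from the blob edge.
#' @param soma_radius_um soma disc radius.
#' @param process_speed_um_per_min approach speed of the cells/process tips.
#' @param process_count_per_cell processes per cell (first one points straight
#'   at the blob, the rest fan over `process_spread_deg`).
#' @param process_length_um process length (tips lead the soma by this much).
#' @param process_spread_deg full fan angle of the processes.
#' @param process_sigma_px Gaussian cross-section of process shafts, pixels.
#' @param tip_radius_um radius of the bright growth-cone disc at each tip.
#' @param arc_band_um width of the lamellipodial band deposited along the blob
#'   edge after contact.
#' @param amp_red,amp_soma,amp_shaft,amp_tip projected photon-count amplitudes.
#' @param photon_gain intensity units per detected photon.
#' @param noise_gaussian_sd additive Gaussian read-noise SD (intensity units).
#' @param shot_noise logical; FALSE yields the noiseless geometry.
#' @param bit_depth 8 or 16.
#' @param drift_per_frame c(dy, dx, theta): rigid drift added per frame
#'   (pixels, pixels, radians).
#' @param seed integer RNG seed; identical (config, seed) gives bit-identical
#'   output.
#' @param geometry_seed seed of the separate stream that draws the cell
#'   layout; `seed` drives only the noise, so two runs differing only in
#'   `seed` share an identical noiseless geometry.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(image_shape = c(T = 20L, Z = 8L, Y = 256L, X = 256L),
                              pixel_size_um = 0.4, z_step_um = 3,
                              frame_interval_min = 1,
                              blob_center = NULL,
                              blob_radius_um = 12,
                              blob_edge_sigma_px = 0.5,
                              n_microglia = 10L,
                              soma_ring_radius_um = 25,
                              soma_radius_um = 3,
                              process_speed_um_per_min = 1.5,
                              process_count_per_cell = 4L,
                              process_length_um = 8,
                              process_spread_deg = 50,
                              process_sigma_px = 0.8,
                              tip_radius_um = 1.2,
                              arc_band_um = 2,
                              amp_red = 240, amp_soma = 30,
                              amp_shaft = 16, amp_tip = 36,
                              photon_gain = 1,
                              noise_gaussian_sd = 0,
                              shot_noise = TRUE,
                              bit_depth = 16L,
                              drift_per_frame = c(dy = 0, dx = 0, theta = 0),
                              seed = 1L,
                              geometry_seed = 42L) {
  image_shape <- as.integer(image_shape)
  names(image_shape) <- c("T", "Z", "Y", "X")
  if (any(image_shape < 1L)) abort("all extents must be positive", "gliadyn_config_error")
  check_calibration(pixel_size_um, z_step_um, frame_interval_min, bit_depth)
  if (is.null(blob_center)) {
    blob_center <- c((image_shape["Z"] - 1) / 2,
                     (image_shape["Y"] - 1) / 2,
                     (image_shape["X"] - 1) / 2)
  }
  names(blob_center) <- c("z", "y", "x")
  r_px <- blob_radius_um / pixel_size_um
  if (blob_center["y"] - r_px < 0 || blob_center["y"] + r_px > image_shape["Y"] - 1 ||
      blob_center["x"] - r_px < 0 || blob_center["x"] + r_px > image_shape["X"] - 1) {
    abort("blob does not fit inside the image", "gliadyn_config_error")
  }
  if (soma_ring_radius_um <= 0) {
    abort("soma ring must lie outside the blob", "gliadyn_config_error")
  }
  if (process_speed_um_per_min < 0) {
    abort("process speed must be non-negative", "gliadyn_config_error")
  }
  if (soma_ring_radius_um - process_length_um <= tip_radius_um) {
    abort("processes start touching the blob: enlarge soma_ring_radius_um",
          "gliadyn_config_error")
  }
  ring_ext_px <- (blob_radius_um + soma_ring_radius_um + soma_radius_um) /
    pixel_size_um
  if (ring_ext_px > min(image_shape[c("Y", "X")] - 1) / 2) {
    abort("soma ring does not fit inside the image", "gliadyn_config_error")
  }
  cfg <- list(image_shape = image_shape, pixel_size_um = pixel_size_um,
              z_step_um = z_step_um, frame_interval_min = frame_interval_min,
              blob_center = blob_center, blob_radius_um = blob_radius_um,
              blob_edge_sigma_px = blob_edge_sigma_px,
              n_microglia = as.integer(n_microglia),
              soma_ring_radius_um = soma_ring_radius_um,
              soma_radius_um = soma_radius_um,
              process_speed_um_per_min = process_speed_um_per_min,
              process_count_per_cell = as.integer(process_count_per_cell),
              process_length_um = process_length_um,
              process_spread_deg = process_spread_deg,
              process_sigma_px = process_sigma_px,
              tip_radius_um = tip_radius_um,
              arc_band_um = arc_band_um,
              amp_red = amp_red, amp_soma = amp_soma,
              amp_shaft = amp_shaft, amp_tip = amp_tip,
              photon_gain = photon_gain,
              noise_gaussian_sd = noise_gaussian_sd,
              shot_noise = isTRUE(shot_noise),
              bit_depth = as.integer(bit_depth),
              drift_per_frame = stats::setNames(as.numeric(drift_per_frame),
                                                c("dy", "dx", "theta")),
              seed = as.integer(seed),
              geometry_seed = as.integer(geometry_seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

# ---- 2D intensity-field primitives (pixel coordinates, 0-based) -------------

new_field <- function(ny, nx) matrix(0, ny, nx)

crop_window <- function(ny, nx, ylo, yhi, xlo, xhi) {
  ys <- max(1L, floor(ylo) + 1L):min(ny, ceiling(yhi) + 1L)
  xs <- max(1L, floor(xlo) + 1L):min(nx, ceiling(xhi) + 1L)
  if (length(ys) == 0L || length(xs) == 0L || ys[1L] > ys[length(ys)] ||
      xs[1L] > xs[length(xs)]) return(NULL)
  list(ys = ys, xs = xs)
}

# soft-edged disc: amp inside radius, Gaussian falloff truncated at 3 sigma
field_disc <- function(field, cy, cx, r_px, amp, sigma_px) {
  ny <- nrow(field); nx <- ncol(field)
  ext <- r_px + 3 * sigma_px
  w <- crop_window(ny, nx, cy - ext, cy + ext, cx - ext, cx + ext)
  if (is.null(w)) return(field)
  dy <- (w$ys - 1) - cy
  dx <- (w$xs - 1) - cx
  d <- sqrt(outer(dy^2, dx^2, "+"))
  v <- ifelse(d <= r_px, amp,
              ifelse(d <= ext, amp * exp(-(d - r_px)^2 / (2 * sigma_px^2)), 0))
  field[w$ys, w$xs] <- pmax(field[w$ys, w$xs], v)
  field
}

# tube of Gaussian cross-section along a segment, truncated at 3 sigma
field_tube <- function(field, y0, x0, y1, x1, amp, sigma_px) {
  ny <- nrow(field); nx <- ncol(field)
  ext <- 3 * sigma_px
  w <- crop_window(ny, nx, min(y0, y1) - ext, max(y0, y1) + ext,
                   min(x0, x1) - ext, max(x0, x1) + ext)
  if (is.null(w)) return(field)
  gy <- matrix((w$ys - 1), length(w$ys), length(w$xs))
  gx <- matrix((w$xs - 1), length(w$ys), length(w$xs), byrow = TRUE)
  vy <- y1 - y0; vx <- x1 - x0
  len2 <- vy^2 + vx^2
  tpar <- if (len2 == 0) matrix(0, nrow(gy), ncol(gy)) else
    pmin(1, pmax(0, ((gy - y0) * vy + (gx - x0) * vx) / len2))
  d <- sqrt((gy - (y0 + tpar * vy))^2 + (gx - (x0 + tpar * vx))^2)
  v <- ifelse(d <= ext, amp * exp(-d^2 / (2 * sigma_px^2)), 0)
  field[w$ys, w$xs] <- pmax(field[w$ys, w$xs], v)
  field
}

# hard annular arc: band [r_in, r_out], angles within half_ang of ang_c
field_arc <- function(field, cy, cx, r_in, r_out, ang_c, half_ang, amp) {
  ny <- nrow(field); nx <- ncol(field)
  w <- crop_window(ny, nx, cy - r_out, cy + r_out, cx - r_out, cx + r_out)
  if (is.null(w)) return(field)
  gy <- matrix((w$ys - 1), length(w$ys), length(w$xs))
  gx <- matrix((w$xs - 1), length(w$ys), length(w$xs), byrow = TRUE)
  d <- sqrt((gy - cy)^2 + (gx - cx)^2)
  ang <- atan2(gy - cy, gx - cx)
  dang <- abs(((ang - ang_c + pi) %% (2 * pi)) - pi)
  v <- ifelse(d >= r_in & d <= r_out & dang <= half_ang, amp, 0)
  field[w$ys, w$xs] <- pmax(field[w$ys, w$xs], v)
  field
}

apply_tf_point <- function(y, x, tf, cy, cx) {
  y <- unname(y); x <- unname(x); cy <- unname(cy); cx <- unname(cx)
  ct <- cos(tf$theta); st <- sin(tf$theta)
  py <- y - cy; px <- x - cx
  c(y = ct * py - st * px + cy + tf$dy,
    x = st * py + ct * px + cx + tf$dx)
}

# render the green (microglia) photon field for one frame, given the cell
# layout and elapsed time; tf drifts the whole scene (identity for truth)
render_green <- function(cfg, cells, minutes, tf) {
  px <- cfg$pixel_size_um
  ny <- cfg$image_shape["Y"]; nx <- cfg$image_shape["X"]
  icy <- (ny - 1) / 2; icx <- (nx - 1) / 2
  bc <- cfg$blob_center
  r_blob <- cfg$blob_radius_um / px
  field <- new_field(ny, nx)
  d0 <- cfg$soma_ring_radius_um - cfg$process_length_um
  adv <- cfg$process_speed_um_per_min * minutes
  pre <- min(adv, d0)
  extra <- max(0, adv - d0)
  bc_t <- apply_tf_point(bc["y"], bc["x"], tf, icy, icx)
  for (cell in cells) {
    r_soma_um <- cfg$blob_radius_um + cfg$soma_ring_radius_um - pre
    sy <- bc["y"] + (r_soma_um / px) * sin(cell$phi)
    sx <- bc["x"] + (r_soma_um / px) * cos(cell$phi)
    p <- apply_tf_point(sy, sx, tf, icy, icx)
    sy <- p["y"]; sx <- p["x"]
    inward <- cell$phi + pi + tf$theta
    field <- field_disc(field, sy, sx, cfg$soma_radius_um / px,
                        cfg$amp_soma, 0.7)
    for (j in seq_along(cell$alphas)) {
      dir <- inward + cell$alphas[j]
      L <- cell$lengths[j] / px
      base_y <- sy + (cfg$soma_radius_um / px) * sin(dir)
      base_x <- sx + (cfg$soma_radius_um / px) * cos(dir)
      tip_y <- sy + L * sin(dir)
      tip_x <- sx + L * cos(dir)
      field <- field_tube(field, base_y, base_x, tip_y, tip_x,
                          cfg$amp_shaft, cfg$process_sigma_px)
      field <- field_disc(field, tip_y, tip_x, cfg$tip_radius_um / px,
                          cfg$amp_tip, 0.7)
    }
    if (extra > 0) {
      r_arc_um <- cfg$blob_radius_um - cfg$arc_band_um / 2
      half_ang <- min(pi, extra / r_arc_um)
      field <- field_arc(field, bc_t["y"], bc_t["x"],
                         (cfg$blob_radius_um - cfg$arc_band_um) / px, r_blob,
                         cell$phi + tf$theta, half_ang, cfg$amp_tip)
    }
  }
  field
}

render_red <- function(cfg, tf) {
  ny <- cfg$image_shape["Y"]; nx <- cfg$image_shape["X"]
  icy <- (ny - 1) / 2; icx <- (nx - 1) / 2
  bc <- apply_tf_point(cfg$blob_center["y"], cfg$blob_center["x"], tf, icy, icx)
  field_disc(new_field(ny, nx), bc["y"], bc["x"],
             cfg$blob_radius_um / cfg$pixel_size_um, cfg$amp_red,
             cfg$blob_edge_sigma_px)
}

# distribute a projected photon field over z slices and quantize
slice_noiseless <- function(field, nz) round(field / nz)

add_noise <- function(lambda_slice, cfg) {
  n <- length(lambda_slice)
  x <- if (cfg$shot_noise) {
    stats::rpois(n, lambda_slice / cfg$photon_gain) * cfg$photon_gain
  } else {
    round(lambda_slice)
  }
  if (cfg$noise_gaussian_sd > 0) {
    x <- x + stats::rnorm(n, 0, cfg$noise_gaussian_sd)
  }
  matrix(pmin(2^cfg$bit_depth - 1, pmax(0, round(x))),
         nrow(lambda_slice), ncol(lambda_slice))
}

#' Generate a two-channel time-lapse movie with ground truth
#'
#' The red channel holds a static soft-edged infusion blob; the green channel
#' holds microglia (soma + process fan + bright growth cones) that advance
#' toward the blob edge at the configured speed, halt at contact, and then
#' deposit a laterally spreading lamellipodial band along the edge. Optional
#' rigid drift is applied per frame to the whole scene. Noise is
#' Poisson (+ optional Gaussian), clipped to the bit depth.
#'
#' Ground truth is computed from the noiseless, drift-free geometry: the blob
#' footprint is its half-maximum set, the green support is every pixel with
#' non-zero noiseless signal, coverage is the percentage of footprint pixels
#' under green support, and mean distance is the average Euclidean distance
#' (um) of green-support pixels to the footprint.
#'
#' @param config a `SimulationConfig`.
#' @return list with `stack` (a `TimeLapseStack`) and `truth` (a
#'   `SimulationTruth`: per-frame `true_coverage_pct` and
#'   `true_mean_distance_um`, `process_speed_um_per_min`, `blob_volume_um3`,
#'   `applied_transforms`, `first_contact_frame`, `blob_mask`).
#' @export
generate_timelapse <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  sh <- cfg$image_shape
  # cell layout: fixed for the whole movie, drawn from the geometry stream so
  # that the noise seed leaves the noiseless scene untouched
  cells <- with_local_seed(cfg$geometry_seed, {
    lapply(seq_len(cfg$n_microglia), function(i) {
      phi <- 2 * pi * (i - 1) / cfg$n_microglia +
        stats::runif(1, -0.25, 0.25) * 2 * pi / cfg$n_microglia
      m <- cfg$process_count_per_cell
      spread <- cfg$process_spread_deg * pi / 180
      alphas <- if (m == 1L) 0 else
        c(0, setdiff(seq(-spread / 2, spread / 2, length.out = m), 0)[seq_len(m - 1L)])
      lengths <- cfg$process_length_um *
        c(1, if (m > 1L) stats::runif(m - 1L, 0.7, 1) else numeric())
      list(phi = phi, alphas = alphas, lengths = lengths)
    })
  })
  with_local_seed(cfg$seed, {
    drift <- rigid_transform(cfg$drift_per_frame["dy"], cfg$drift_per_frame["dx"],
                             cfg$drift_per_frame["theta"])
    has_drift <- abs(drift$dy) + abs(drift$dx) + abs(drift$theta) > 0
    ident <- rigid_transform(0, 0, 0)
    data <- array(0, unname(c(sh["T"], sh["Z"], 2L, sh["Y"], sh["X"])))
    red0 <- render_red(cfg, ident)
    blob_mask <- red0 > max(red0) / 2
    dmap_px <- EBImage::imageData(
      EBImage::distmap(EBImage::Image(1 - blob_mask), metric = "euclidean"))
    cov <- numeric(sh["T"]); mdist <- numeric(sh["T"])
    support <- array(FALSE, unname(c(sh["T"], sh["Y"], sh["X"])))
    tfs <- data.frame(t = seq_len(sh["T"]) - 1L, dy_px = 0, dx_px = 0, theta_rad = 0)
    cum <- ident
    red_slice0 <- slice_noiseless(red0, sh["Z"])
    for (f in seq_len(sh["T"])) {
      minutes <- (f - 1) * cfg$frame_interval_min
      green0 <- render_green(cfg, cells, minutes, ident)
      gslice0 <- slice_noiseless(green0, sh["Z"])
      sup <- gslice0 > 0
      support[f, , ] <- sup
      nb <- sum(blob_mask)
      cov[f] <- 100 * sum(sup & blob_mask) / nb
      mdist[f] <- if (any(sup)) mean(dmap_px[sup]) * cfg$pixel_size_um else NA_real_
      if (f > 1L && has_drift) cum <- compose_rigid(drift, cum)
      tfs$dy_px[f] <- cum$dy; tfs$dx_px[f] <- cum$dx; tfs$theta_rad[f] <- cum$theta
      if (has_drift && f > 1L) {
        rslice <- slice_noiseless(render_red(cfg, cum), sh["Z"])
        gslice <- slice_noiseless(render_green(cfg, cells, minutes, cum), sh["Z"])
      } else {
        rslice <- red_slice0
        gslice <- gslice0
      }
      for (z in seq_len(sh["Z"])) {
        data[f, z, 1L, , ] <- add_noise(rslice, cfg)
        data[f, z, 2L, , ] <- add_noise(gslice, cfg)
      }
    }
    d0 <- cfg$soma_ring_radius_um - cfg$process_length_um
    t_contact <- if (cfg$process_speed_um_per_min > 0)
      d0 / cfg$process_speed_um_per_min else Inf
    fc <- which((seq_len(sh["T"]) - 1) * cfg$frame_interval_min >= t_contact)
    voxel_um3 <- cfg$pixel_size_um^2 * cfg$z_step_um
    truth <- structure(list(
      true_coverage_pct = cov,
      true_mean_distance_um = mdist,
      process_speed_um_per_min = cfg$process_speed_um_per_min,
      blob_volume_um3 = sum(red_slice0 > 0) * sh["Z"] * voxel_um3,
      applied_transforms = tfs,
      first_contact_frame = if (length(fc)) min(fc) else NA_integer_,
      blob_mask = blob_mask,
      green_support = support
    ), class = "SimulationTruth")
    stack <- timelapse_stack(data, c(infusion = 1L, microglia = 2L),
                             cfg$pixel_size_um, cfg$z_step_um,
                             cfg$frame_interval_min, cfg$bit_depth)
    list(stack = stack, truth = truth)
  })
}

#' Generate a 3D infusion volume stack with analytic ground truth
#'
#' A single-channel Z x Y x X stack holding an ellipsoidal (default spherical)
#' bolus of known analytic volume, a stated number of small bright specks for
#' testing the small-component removal, and optional shot noise.
#'
#' @param shape integer c(Z, Y, X) (Z >= 3).
#' @param pixel_size_um,z_step_um calibration (defaults 0.8 and 5, the volume
#'   acquisition calibration).
#' @param radius_um sphere radius in micrometres (0 gives an empty stack and
#'   volume 0).
#' @param center 0-based (z, y, x) voxel coordinates; default: stack center.
#' @param amplitude bolus intensity (default 600).
#' @param n_specks number of 1-3 voxel bright specks (default 6).
#' @param shot_noise add Poisson noise (default TRUE).
#' @param bit_depth 8 or 16.
#' @param seed RNG seed.
#' @return list with `stack3d` (array with calibration attributes) and `truth`
#'   (list: `blob_volume_um3` = (4/3) pi r^3, `n_blob_voxels`, `center`,
#'   `radius_um`, `n_specks`).
#' @export
generate_volume_stack <- function(shape = c(Z = 24L, Y = 96L, X = 96L),
                                  pixel_size_um = 0.8, z_step_um = 5,
                                  radius_um = 10, center = NULL,
                                  amplitude = 600, n_specks = 6L,
                                  shot_noise = TRUE, bit_depth = 16L,
                                  seed = 1L) {
  shape <- as.integer(shape)
  if (shape[1L] < 3L) abort("need Z >= 3", "gliadyn_config_error")
  check_calibration(pixel_size_um, z_step_um, 1, bit_depth)
  if (is.null(center)) center <- (shape - 1) / 2
  with_local_seed(seed, {
    z_um <- ((seq_len(shape[1L]) - 1) - center[1L]) * z_step_um
    y_um <- ((seq_len(shape[2L]) - 1) - center[2L]) * pixel_size_um
    x_um <- ((seq_len(shape[3L]) - 1) - center[3L]) * pixel_size_um
    d2 <- outer(outer(z_um^2, y_um^2, "+"), x_um^2, "+")
    blob <- d2 <= radius_um^2
    lam <- array(0, shape)
    lam[blob] <- amplitude
    # bright specks well away from the bolus
    if (n_specks > 0L) {
      far <- which(d2 > (radius_um + 6 * max(pixel_size_um, z_step_um))^2)
      pick <- far[sample.int(length(far), min(n_specks, length(far)))]
      for (p in pick) {
        lam[p] <- amplitude
        extra <- sample.int(3L, 1L) - 1L
        if (extra > 0L) {
          co <- arrayInd(p, shape)
          for (e in seq_len(extra)) {
            nb <- pmin(shape, pmax(1L, co + sample(c(-1L, 0L, 1L), 3L, TRUE)))
            lam[nb[1L], nb[2L], nb[3L]] <- amplitude
          }
        }
      }
    }
    x <- if (shot_noise) array(stats::rpois(length(lam), lam), shape) else lam
    x <- array(pmin(2^bit_depth - 1, pmax(0, round(x))), shape)
    attr(x, "pixel_size_um") <- pixel_size_um
    attr(x, "z_step_um") <- z_step_um
    attr(x, "bit_depth") <- bit_depth
    list(stack3d = x,
         truth = list(blob_volume_um3 = 4 / 3 * pi * radius_um^3,
                      n_blob_voxels = sum(blob),
                      center = center, radius_um = radius_um,
                      n_specks = as.integer(n_specks)))
  })
}

#' Generate random filament tracings with known morphometry
#'
#' Each cell is a rooted tree grown from a soma placed on a ring around the
#' infusion center: primary processes leave the soma with a configurable
#' orientation bias toward the infusion site, extend in jittered steps and
#' branch stochastically. Total length, branch-point count (non-root nodes
#' with >= 2 children; root with >= 3) and the facing side of every process
#' tip are recorded during construction.
#'
#' @param n_cells number of cells (>= 1).
#' @param infusion_center_um c(y, x) of the infusion site, micrometres.
#' @param seed RNG seed.
#' @param orientation_bias in [0, 1]: probability that a primary process
#'   points into the infusion-facing half-plane (1 = all tips facing).
#' @param n_processes primary processes per cell.
#' @param n_segments segments per primary process.
#' @param step_um mean segment length.
#' @param branch_prob probability of a side branch at each interior node.
#' @param ring_radius_um range (min, max) of soma distances from the center.
#' @return list of `FilamentTracing`; attribute `truth` holds per-cell
#'   `total_length_um`, `n_branch_points`, `tips_facing`, `tips_total`.
#' @export
generate_filament_set <- function(n_cells, infusion_center_um = c(0, 0),
                                  seed = 1L, orientation_bias = 0.7,
                                  n_processes = 4L, n_segments = 3L,
                                  step_um = 6, branch_prob = 0.35,
                                  ring_radius_um = c(30, 60)) {
  stopifnot(n_cells >= 1L, orientation_bias >= 0, orientation_bias <= 1)
  cy <- infusion_center_um[1L]; cx <- infusion_center_um[2L]
  with_local_seed(seed, {
    tracings <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    for (ci in seq_len(n_cells)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rr <- stats::runif(1, ring_radius_um[1L], ring_radius_um[2L])
      sx <- cx + rr * cos(ang); sy <- cy + rr * sin(ang)
      facing <- atan2(cy - sy, cx - sx)
      nodes <- data.frame(id = 1L, type = 1L, x = sx, y = sy, z = 0,
                          radius = 3, parent = -1L)
      nid <- 1L
      nchildren <- c(0L)
      total_len <- 0
      tips_facing <- 0L; tips_total <- 0L
      add_node <- function(parent_id, x, y, z) {
        nid <<- nid + 1L
        nodes[nrow(nodes) + 1L, ] <<- list(nid, 3L, x, y, z, 0.5, parent_id)
        nchildren <<- c(nchildren, 0L)
        prow <- match(parent_id, nodes$id)
        nchildren[prow] <<- nchildren[prow] + 1L
        p <- nodes[prow, ]
        total_len <<- total_len + sqrt((x - p$x)^2 + (y - p$y)^2 + (z - p$z)^2)
        nid
      }
      grow <- function(parent_id, dir, nseg, allow_branch) {
        prow <- match(parent_id, nodes$id)
        px <- nodes$x[prow]; py <- nodes$y[prow]; pz <- nodes$z[prow]
        cur <- parent_id
        for (s in seq_len(nseg)) {
          dir <- dir + stats::runif(1, -10, 10) * pi / 180
          len <- step_um * stats::runif(1, 0.7, 1.3)
          px <- px + len * cos(dir); py <- py + len * sin(dir)
          pz <- pz + stats::runif(1, -1, 1)
          cur <- add_node(cur, px, py, pz)
          if (allow_branch && s < nseg && stats::runif(1) < branch_prob) {
            side <- dir + sample(c(-1, 1), 1L) * stats::runif(1, 30, 60) * pi / 180
            grow(cur, side, 1L + stats::rbinom(1L, 1L, 0.5), FALSE)
          }
        }
        dir
      }
      for (p in seq_len(n_processes)) {
        into_facing <- stats::runif(1) < orientation_bias
        dir0 <- if (into_facing) {
          facing + stats::runif(1, -15, 15) * pi / 180
        } else {
          facing + pi + stats::runif(1, -75, 75) * pi / 180
        }
        tipdir <- grow(1L, dir0, n_segments, TRUE)
        tips_total <- tips_total + 1L
        # facing test on the actual tip position, not the nominal direction
        tip <- nodes[nrow(nodes), ]
        if ((tip$x - sx) * cos(facing) + (tip$y - sy) * sin(facing) > 0) {
          tips_facing <- tips_facing + 1L
        }
      }
      root_bp <- as.integer(nchildren[1L] >= 3L)
      nbp <- sum(nchildren[-1L] >= 2L) + root_bp
      tracings[[ci]] <- filament_tracing(nodes)
      truth[[ci]] <- list(total_length_um = total_len, n_branch_points = nbp,
                          tips_facing = tips_facing, tips_total = tips_total,
                          soma_um = c(y = sy, x = sx))
    }
    attr(tracings, "truth") <- truth
    tracings
  })
}

#' Generate staining fixtures with known ground truth
#'
#' Four kinds of noiseless fixtures for the staining metrics:
#' \describe{
#'   \item{area_fraction}{2D image with an exactly known percentage of pixels
#'     above threshold.}
#'   \item{puncta}{puncta field around a circular infusion footprint plus its
#'     edge mask; truth holds the per-ROI and mean coverage recomputed by
#'     direct pixel counting over the four deterministic edge ROIs.}
#'   \item{uptake}{cell label image plus a signal mask overlapping a known
#'     subset of cells.}
#'   \item{plaque3d}{paired 3D stacks: a voxel sphere plaque and a microglia
#'     half-shell; truth holds the contact fraction from an independent
#'     neighbor scan.}
#' }
#'
#' @param kind one of "area_fraction", "puncta", "uptake", "plaque3d".
#' @param params named list of kind-specific parameters (all have defaults).
#' @param seed RNG seed.
#' @return list with the image(s)/masks and a `truth` list.
#' @export
generate_stain_image <- function(kind, params = list(), seed = 1L) {
  if (!kind %in% c("area_fraction", "puncta", "uptake", "plaque3d")) {
    abort(sprintf("unknown stain fixture kind '%s'", kind), "gliadyn_usage_error")
  }
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  with_local_seed(seed, switch(kind,
    area_fraction = {
      dm <- p("dim", c(100L, 100L)); target <- p("target_pct", 25)
      fgv <- p("fg_value", 200); bgv <- p("bg_value", 10)
      n <- prod(dm); k <- round(target / 100 * n)
      img <- matrix(bgv, dm[1L], dm[2L])
      img[sample.int(n, k)] <- fgv
      list(image = img,
           truth = list(percent = 100 * k / n, threshold = (fgv + bgv) / 2))
    },
    puncta = {
      dm <- p("dim", c(512L, 512L)); px <- p("pixel_size_um", 2)
      r_um <- p("infusion_radius_um", 60); density <- p("density", 0.08)
      punc_r <- p("puncta_radius_px", 1L); amp <- p("amplitude", 180)
      roi_um <- p("roi_size_um", 200); n_rois <- p("n_rois", 4L)
      cyx <- (dm - 1) / 2
      gy <- matrix(seq_len(dm[1L]) - 1, dm[1L], dm[2L])
      gx <- matrix(seq_len(dm[2L]) - 1, dm[1L], dm[2L], byrow = TRUE)
      d <- sqrt((gy - cyx[1L])^2 + (gx - cyx[2L])^2)
      infusion <- d <= r_um / px
      edge <- infusion & d > r_um / px - 2
      img <- matrix(0, dm[1L], dm[2L])
      n_punc <- round(density * sum(!infusion) / max(1, (2 * punc_r + 1)^2))
      cand <- which(!infusion)
      ctr <- cand[sample.int(length(cand), n_punc)]
      co <- arrayInd(ctr, dm)
      for (i in seq_len(nrow(co))) {
        ys <- max(1L, co[i, 1L] - punc_r):min(dm[1L], co[i, 1L] + punc_r)
        xs <- max(1L, co[i, 2L] - punc_r):min(dm[2L], co[i, 2L] + punc_r)
        img[ys, xs] <- amp
      }
      img[infusion] <- 0
      thr <- amp / 2
      side <- as.integer(round(roi_um / px))
      rois <- place_edge_rois(edge, side, n_rois, dm)
      per <- vapply(rois, function(r) {
        sub <- img[(r$y0 + 1L):(r$y0 + r$height), (r$x0 + 1L):(r$x0 + r$width)]
        100 * sum(sub > thr) / length(sub)
      }, numeric(1))
      list(image = img, edge_mask = edge, pixel_size_um = px,
           threshold = thr,
           truth = list(mean_pct = mean(per), per_roi_pct = per))
    },
    uptake = {
      n_cells <- p("n_cells", 10L); n_pos <- p("n_positive", 4L)
      dm <- p("dim", c(256L, 256L)); cr <- p("cell_radius_px", 6L)
      stopifnot(n_pos <= n_cells)
      labels <- matrix(0L, dm[1L], dm[2L])
      signal <- matrix(FALSE, dm[1L], dm[2L])
      ngrid <- ceiling(sqrt(n_cells))
      pitch <- floor((dm - 4 * cr) / ngrid)
      pos_ids <- sample.int(n_cells, n_pos)
      for (i in seq_len(n_cells)) {
        gyx <- c((i - 1) %/% ngrid, (i - 1) %% ngrid)
        cy <- 2 * cr + gyx[1L] * pitch[1L] + sample.int(3L, 1L)
        cx <- 2 * cr + gyx[2L] * pitch[2L] + sample.int(3L, 1L)
        yy <- pmax(1L, cy - cr):pmin(dm[1L], cy + cr)
        xx <- pmax(1L, cx - cr):pmin(dm[2L], cx + cr)
        dd <- outer((yy - cy)^2, (xx - cx)^2, "+") <= cr^2
        block <- labels[yy, xx]; block[dd] <- i
        labels[yy, xx] <- block
        if (i %in% pos_ids) {
          sr <- max(2L, cr %/% 2L)
          sy <- cy + 1L; sx <- cx - 1L
          yy2 <- pmax(1L, sy - sr):pmin(dm[1L], sy + sr)
          xx2 <- pmax(1L, sx - sr):pmin(dm[2L], sx + sr)
          dd2 <- outer((yy2 - sy)^2, (xx2 - sx)^2, "+") <= sr^2
          sblock <- signal[yy2, xx2]; sblock[dd2] <- TRUE
          signal[yy2, xx2] <- sblock
        }
      }
      list(cell_label_image = labels, signal_mask = signal,
           truth = list(percent = 100 * n_pos / n_cells,
                        positive_ids = sort(pos_ids)))
    },
    plaque3d = {
      dm <- p("dim", c(24L, 48L, 48L)); r <- p("radius_px", 8)
      amp <- p("amplitude", 800); floor_i <- p("intensity_floor", 500)
      shell_frac <- p("shell_fraction", 0.5)
      ctr <- (dm - 1) / 2
      zz <- (seq_len(dm[1L]) - 1) - ctr[1L]
      yy <- (seq_len(dm[2L]) - 1) - ctr[2L]
      xx <- (seq_len(dm[3L]) - 1) - ctr[3L]
      d2 <- outer(outer(zz^2, yy^2, "+"), xx^2, "+")
      plaque_mask <- d2 <= r^2
      surf <- plaque_mask & !(
        shift3d(plaque_mask, 1, 0, 0) & shift3d(plaque_mask, -1, 0, 0) &
        shift3d(plaque_mask, 0, 1, 0) & shift3d(plaque_mask, 0, -1, 0) &
        shift3d(plaque_mask, 0, 0, 1) & shift3d(plaque_mask, 0, 0, -1))
      # shell: voxels just outside the plaque, restricted to x above the plane
      # splitting the surface voxels at the requested fraction
      shell <- d2 > r^2 & d2 <= (r + 1.8)^2
      gx <- array(rep(xx, each = dm[1L] * dm[2L]), dm)
      cut <- stats::quantile(gx[surf], probs = 1 - shell_frac, names = FALSE)
      micro_mask <- shell & gx >= cut
      plaque <- array(0, dm); plaque[plaque_mask] <- amp
      micro <- array(0, dm); micro[micro_mask] <- amp
      # independent neighbor scan for the truth contact fraction
      nearm <- micro_mask
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        nearm <- nearm | shift3d(micro_mask, dz, dy, dx)
      }
      list(plaque_stack = plaque, microglia_stack = micro,
           intensity_floor = floor_i,
           truth = list(percent = 100 * sum(surf & nearm) / sum(surf),
                        nominal_percent = 100 * shell_frac,
                        n_surface_voxels = sum(surf)))
    }
  ))
}

#' Smooth textured synthetic frame
#'
#' A band-limited random field (uniform noise smoothed with a Gaussian),
#' rescaled to [0, amplitude]. Used as the reference scene for registration
#' benchmarks: it has structure at the scales drift estimation relies on,
#' without the rotational symmetry of a bare bolus.
#'
#' @param n side length in pixels.
#' @param seed RNG seed.
#' @param smooth_sigma_px Gaussian smoothing sigma (default 3).
#' @param amplitude intensity range (default 100).
#' @return n x n numeric matrix.
#' @export
synthetic_texture <- function(n = 256L, seed = 1L, smooth_sigma_px = 3,
                              amplitude = 100) {
  with_local_seed(seed, {
    x <- matrix(stats::runif(n * n), n, n)
    x <- gaussian_blur(x, smooth_sigma_px)
    (x - min(x)) / (max(x) - min(x)) * amplitude
  })
}
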