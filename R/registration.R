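#' Rigid in-plane transforms
#'
#' A rigid transform rotates image content by `theta` radians about the image
#' center and then translates it by (`dy`, `dx`) pixels (y increases downward,
#' x rightward). `rigid_transform` builds one; `invert_rigid` and
#' `compose_rigid` give the group operations; `apply_rigid` resamples an image
#' under the transform with bilinear interpolation, filling out-of-frame
#' pixels with 0.
#'
#' @param dy,dx translation in pixels (real-valued).
#' @param theta rotation in radians about the image center.
#' @return `rigid_transform`: a `RigidTransform` object.
#' @export
rigid_transform <- function(dy = 0, dx = 0, theta = 0) {
  stopifnot(is.finite(dy), is.finite(dx), is.finite(theta))
  structure(list(dy = unname(dy), dx = unname(dx), theta = unname(theta)),
            class = "RigidTransform")
}

#' @rdname rigid_transform
#' @param tf,a,b `RigidTransform` objects.
#' @export
invert_rigid <- function(tf) {
  ct <- cos(-tf$theta); st <- sin(-tf$theta)
  # forward: p' = R(theta) (p - c) + c + t  =>  inverse rotation -theta,
  # translation -R(-theta) t
  rigid_transform(dy = -(ct * tf$dy - st * tf$dx),
                  dx = -(st * tf$dy + ct * tf$dx),
                  theta = -tf$theta)
}

#' @rdname rigid_transform
#' @export
compose_rigid <- function(a, b) {
  # apply b first, then a
  ct <- cos(a$theta); st <- sin(a$theta)
  rigid_transform(dy = ct * b$dy - st * b$dx + a$dy,
                  dx = st * b$dy + ct * b$dx + a$dx,
                  theta = a$theta + b$theta)
}

#' @rdname rigid_transform
#' @param img 2D numeric matrix (Y rows, X columns).
#' @export
apply_rigid <- function(img, tf) {
  ny <- nrow(img); nx <- ncol(img)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  gy <- matrix(seq_len(ny), ny, nx)
  gx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  # inverse map each output pixel to its source location
  ct <- cos(-tf$theta); st <- sin(-tf$theta)
  py <- gy - cy - tf$dy
  px <- gx - cx - tf$dx
  sy <- ct * py - st * px + cy
  sx <- st * py + ct * px + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    out <- numeric(length(yy))
    out[ok] <- img[cbind(yy[ok], xx[ok])]
    out
  }
  v <- (1 - fy) * (1 - fx) * val(y0, x0) +
       (1 - fy) * fx       * val(y0, x0 + 1) +
       fy       * (1 - fx) * val(y0 + 1, x0) +
       fy       * fx       * val(y0 + 1, x0 + 1)
  matrix(v, ny, nx)
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat(sprintf("RigidTransform: dy=%.4g px, dx=%.4g px, theta=%.4g rad\n",
              x$dy, x$dx, x$theta))
  invisible(x)
}

hann_window <- function(ny, nx) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
  outer(wy, wx)
}

fft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k > n / 2, k - n, k)
}

# Phase correlation between two equal-shape images. Returns the translation
# (dy, dx) that `moving` carries relative to `reference` (i.e. moving ~
# reference shifted by (dy, dx)) plus the correlation peak height. Images are
# Hann-windowed to suppress wrap-around edge artifacts; sub-pixel refinement
# evaluates the correlation surface around the integer peak by matrix DFT at
# `upsample`-fold resolution.
phase_correlate <- function(reference, moving, subpixel = TRUE, upsample = 50L) {
  stopifnot(all(dim(reference) == dim(moving)))
  ny <- nrow(reference); nx <- ncol(reference)
  w <- hann_window(ny, nx)
  f1 <- stats::fft((reference - mean(reference)) * w)
  f2 <- stats::fft((moving - mean(moving)) * w)
  cp <- f1 * Conj(f2)
  cp <- cp / (Mod(cp) + 1e-12)
  # Gaussian low-pass on the whitened cross-power: microscopy frames carry
  # little signal in the upper spectrum, where whitening would otherwise let
  # noise dominate the peak
  fr2 <- outer(fft_freqs(ny)^2, fft_freqs(nx)^2, "+")
  cp <- cp * exp(-fr2 / (max(ny, nx) / 8)^2)
  r <- Re(stats::fft(cp, inverse = TRUE)) / (ny * nx)
  pk <- arrayInd(which.max(r), dim(r))
  peak <- r[pk]
  # wrap-around index -> signed peak location; the peak sits at (-dy, -dx)
  sy <- pk[1L] - 1L; if (sy > ny / 2) sy <- sy - ny
  sx <- pk[2L] - 1L; if (sx > nx / 2) sx <- sx - nx
  if (subpixel) {
    us <- as.integer(upsample)
    gy <- sy + seq(-1, 1, by = 1 / us)
    gx <- sx + seq(-1, 1, by = 1 / us)
    uy <- fft_freqs(ny); ux <- fft_freqs(nx)
    ey <- exp(2i * pi * outer(gy, uy) / ny)
    ex <- exp(2i * pi * outer(ux, gx) / nx)
    cc <- Re(ey %*% cp %*% ex)
    best <- arrayInd(which.max(cc), dim(cc))
    sy <- gy[best[1L]]; sx <- gx[best[2L]]
    peak <- cc[best] / (ny * nx)
  }
  list(dy = -sy, dx = -sx, peak = peak)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  sz <- 2L * ceiling(3 * sigma) + 1L
  EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma, radius = sz))
}

#' Estimate the rigid transform between two frames
#'
#' Finds the rotation + translation that `moving` carries relative to
#' `reference`, i.e. the transform T with `moving ~ apply_rigid(reference, T)`.
#' Translation comes from Hann-windowed phase correlation with matrix-DFT
#' sub-pixel refinement around the integer peak; rotation from a bounded
#' coarse search over +/- `max_theta` scored by the phase-correlation peak
#' height, followed by golden-section refinement scored by masked normalized
#' cross-correlation of the fully aligned frame.
#' Both images are lightly smoothed (1 px Gaussian) before correlation to tame
#' shot noise.
#'
#' @param reference,moving 2D numeric matrices of identical shape,
#'   non-constant.
#' @param max_theta rotation search bound in radians (default 5 degrees).
#' @param theta_step coarse search step in radians.
#' @return a `RigidTransform`.
#' @export
estimate_rigid <- function(reference, moving, max_theta = 5 * pi / 180,
                           theta_step = 0.5 * pi / 180) {
  if (length(unique(as.numeric(reference))) < 2L ||
      length(unique(as.numeric(moving))) < 2L) {
    abort("constant image: rigid transform is undefined", "gliadyn_degenerate_error")
  }
  stopifnot(all(dim(reference) == dim(moving)))
  ref <- gaussian_blur(reference, 1)
  mov <- gaussian_blur(moving, 1)
  # coarse rotation search scored by the phase-correlation peak height
  # (translation-invariant); refinement scored by masked normalized
  # cross-correlation of the fully aligned image, which is smooth in theta
  # where the raw peak height is not
  coarse_score <- function(theta) {
    un <- if (theta == 0) mov else apply_rigid(mov, rigid_transform(0, 0, -theta))
    phase_correlate(ref, un, subpixel = FALSE)$peak
  }
  ny <- nrow(ref); nx <- ncol(ref)
  mar_y <- max(4L, ceiling(0.15 * ny)); mar_x <- max(4L, ceiling(0.15 * nx))
  cy <- (mar_y + 1L):(ny - mar_y); cx <- (mar_x + 1L):(nx - mar_x)
  # un-rotating first means phase correlation sees the translation rotated by
  # -theta; rotate it back before composing the full transform
  tf_at <- function(theta, pc) {
    ct <- cos(theta); st <- sin(theta)
    rigid_transform(dy = ct * pc$dy - st * pc$dx,
                    dx = st * pc$dy + ct * pc$dx,
                    theta = theta)
  }
  fine_score <- function(theta) {
    un <- if (theta == 0) mov else apply_rigid(mov, rigid_transform(0, 0, -theta))
    pc <- phase_correlate(ref, un, subpixel = TRUE, upsample = 10L)
    aligned <- apply_rigid(mov, invert_rigid(tf_at(theta, pc)))
    stats::cor(as.numeric(aligned[cy, cx]), as.numeric(ref[cy, cx]))
  }
  if (max_theta > 0) {
    grid <- seq(-max_theta, max_theta, by = theta_step)
    if (!0 %in% grid) grid <- sort(c(grid, 0))
    sc <- vapply(grid, coarse_score, numeric(1))
    i <- which.max(sc)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- fine_score(x1); f2 <- fine_score(x2)
    for (it in seq_len(25L)) {
      if (b - a < 2e-4) break
      if (f1 < f2) {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- fine_score(x2)
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- fine_score(x1)
      }
    }
    theta <- (a + b) / 2
    if (abs(theta) < 5e-5) theta <- 0
    # rotationally near-symmetric content (e.g. a centered bolus) leaves theta
    # unidentified and the line search wandering on noise: keep 0 unless the
    # rotation buys a real NCC improvement
    if (theta != 0 && fine_score(theta) - fine_score(0) < 1e-4) theta <- 0
  } else {
    theta <- 0
  }
  un <- if (theta == 0) mov else apply_rigid(mov, rigid_transform(0, 0, -theta))
  pc <- phase_correlate(ref, un, subpixel = TRUE)
  ct <- cos(theta); st <- sin(theta)
  rigid_transform(dy = ct * pc$dy - st * pc$dx,
                  dx = st * pc$dy + ct * pc$dx,
                  theta = theta)
}

#' Register a time series to a reference frame
#'
#' Per frame, the drift transform is estimated on the infusion channel's sum
#' projection against the reference frame (the infusion bolus is static, so it
#' anchors the registration), then the inverse is applied identically to every
#' channel and z-plane of that frame. All frames are registered directly to
#' the reference, not successively, so estimation errors do not accumulate.
#' Out-of-frame pixels are filled with 0.
#'
#' @param stack a `TimeLapseStack`.
#' @param reference_frame index of the reference frame (default 1, i.e. t=0).
#' @param max_theta rotation search bound in radians.
#' @return list with `stack` (registered `TimeLapseStack`) and `transforms`
#'   (data.frame t, dy_px, dx_px, theta_rad: the drift each frame carried).
#' @export
register_series <- function(stack, reference_frame = 1L,
                            max_theta = 5 * pi / 180) {
  stopifnot(inherits(stack, "TimeLapseStack"))
  d <- dim(stack$data)
  if (reference_frame < 1L || reference_frame > d[1L]) {
    abort("reference_frame out of range", "gliadyn_usage_error")
  }
  ich <- stack$channel_roles[["infusion"]]
  proj <- function(t) apply(stack$data[t, , ich, , , drop = FALSE], c(4L, 5L), sum)
  ref <- proj(reference_frame)
  out <- stack$data
  tfs <- data.frame(t = seq_len(d[1L]) - 1L, dy_px = 0, dx_px = 0, theta_rad = 0)
  maxv <- 2^stack$bit_depth - 1
  for (t in seq_len(d[1L])) {
    if (t == reference_frame) next
    tf <- estimate_rigid(ref, proj(t), max_theta = max_theta)
    tfs$dy_px[t] <- tf$dy; tfs$dx_px[t] <- tf$dx; tfs$theta_rad[t] <- tf$theta
    inv <- invert_rigid(tf)
    if (abs(inv$dy) + abs(inv$dx) + abs(inv$theta) == 0) next
    for (z in seq_len(d[2L])) for (ch in seq_len(d[3L])) {
      plane <- matrix(stack$data[t, z, ch, , ], d[4L], d[5L])
      out[t, z, ch, , ] <- pmin(maxv, pmax(0, apply_rigid(plane, inv)))
    }
  }
  reg <- stack
  reg$data <- out
  list(stack = reg, transforms = tfs)
}

#' Sum-based XY projection of a time-lapse stack
#'
#' Collapses each frame and channel to 2D by summing intensities along z.
#' Values are kept as reals with no clipping, so total intensity per frame and
#' channel is conserved exactly.
#'
#' @param stack a `TimeLapseStack`.
#' @return a `Projection2D`: list with `data` (T x C x Y x X array) and the
#'   inherited calibration.
#' @export
sum_projection <- function(stack) {
  stopifnot(inherits(stack, "TimeLapseStack"))
  data <- apply(stack$data, c(1L, 3L, 4L, 5L), sum)
  structure(list(data = data,
                 channel_roles = stack$channel_roles,
                 pixel_size_um = stack$pixel_size_um,
                 frame_interval_min = stack$frame_interval_min),
            class = "Projection2D")
}

#' Extract one channel frame from a projection
#'
#' @param proj a `Projection2D`.
#' @param t frame index (1-based).
#' @param channel channel index or role name ("infusion"/"microglia").
#' @return 2D numeric matrix.
#' @export
projection_frame <- function(proj, t, channel = "microglia") {
  stopifnot(inherits(proj, "Projection2D"))
  ch <- if (is.character(channel)) proj$channel_roles[[channel]] else channel
  matrix(proj$data[t, ch, , ], dim(proj$data)[3L], dim(proj$data)[4L])
}
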