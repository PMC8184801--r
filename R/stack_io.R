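#' Construct a two-channel time-lapse stack
#'
#' The raw substrate of the dynamics pipeline: a T x Z x C x Y x X array of
#' non-negative integer intensities with the acquisition calibration attached.
#' Channel roles name which channel carries the infused amyloid bolus
#' ("infusion", the red detector in the original acquisition) and which the
#' microglial reporter ("microglia", green).
#'
#' @param data 5-D numeric array ordered T, Z, C, Y, X.
#' @param channel_roles named integer vector with entries `infusion` and
#'   `microglia` giving distinct channel indices.
#' @param pixel_size_um in-plane pixel size, micrometres (> 0).
#' @param z_step_um spacing between z planes, micrometres (> 0).
#' @param frame_interval_min time between stacks, minutes (> 0).
#' @param bit_depth 8 or 16.
#' @return object of class `TimeLapseStack`.
#' @export
timelapse_stack <- function(data, channel_roles = c(infusion = 1L, microglia = 2L),
                            pixel_size_um, z_step_um, frame_interval_min,
                            bit_depth = 16L) {
  if (length(dim(data)) != 5L) {
    abort("data must be a 5-D array ordered T, Z, C, Y, X", "gliadyn_usage_error")
  }
  check_calibration(pixel_size_um, z_step_um, frame_interval_min, bit_depth)
  nc <- dim(data)[3L]
  roles <- c("infusion", "microglia")
  if (!all(roles %in% names(channel_roles))) {
    abort("channel_roles must name both 'infusion' and 'microglia'",
          "gliadyn_usage_error")
  }
  ch <- as.integer(channel_roles[roles])
  if (anyNA(ch) || any(ch < 1L) || any(ch > nc) || ch[1L] == ch[2L]) {
    abort("channel roles must map to distinct, in-range channel indices",
          "gliadyn_usage_error")
  }
  if (min(data) < 0 || max(data) > 2^bit_depth - 1) {
    abort("intensities outside the declared bit depth", "gliadyn_usage_error")
  }
  structure(list(
    data = data,
    channel_roles = stats::setNames(ch, roles),
    pixel_size_um = as.numeric(pixel_size_um),
    z_step_um = as.numeric(z_step_um),
    frame_interval_min = as.numeric(frame_interval_min),
    bit_depth = as.integer(bit_depth)
  ), class = "TimeLapseStack")
}

check_calibration <- function(pixel_size_um, z_step_um, frame_interval_min,
                              bit_depth) {
  vals <- c(pixel_size_um, z_step_um, frame_interval_min)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    abort("calibration values must all be positive and finite",
          "gliadyn_calibration_error")
  }
  if (!bit_depth %in% c(8L, 16L)) {
    abort("bit_depth must be 8 or 16", "gliadyn_calibration_error")
  }
  invisible(TRUE)
}

#' @export
print.TimeLapseStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "TimeLapseStack: T=%d Z=%d C=%d Y=%d X=%d | %.3g um/px, %.3g um z-step, %.3g min/frame, %d-bit\n",
    d[1], d[2], d[3], d[4], d[5],
    x$pixel_size_um, x$z_step_um, x$frame_interval_min, x$bit_depth))
  invisible(x)
}

#' Write a time-lapse stack as multi-page TIFF plus calibration sidecar
#'
#' Pages are written T-major, then Z, then C; the sidecar JSON records the
#' dimensions, the page order, the calibration and the channel roles, so the
#' reader can normalize any declared order back to T, Z, C, Y, X.
#'
#' @param stack a `TimeLapseStack`.
#' @param path output TIFF path.
#' @param sidecar_path output JSON path (default: `path` + ".json").
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(stack, "TimeLapseStack"))
  d <- dim(stack$data)
  scale <- 2^stack$bit_depth - 1
  pages <- vector("list", d[1L] * d[2L] * d[3L])
  i <- 1L
  for (t in seq_len(d[1L])) for (z in seq_len(d[2L])) for (c in seq_len(d[3L])) {
    pages[[i]] <- matrix(stack$data[t, z, c, , ], d[4L], d[5L]) / scale
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  write_json_file(list(
    axis_order = "TZCYX",
    page_order = c("T", "Z", "C"),
    shape = list(T = d[1L], Z = d[2L], C = d[3L], Y = d[4L], X = d[5L]),
    pixel_size_um = stack$pixel_size_um,
    z_step_um = stack$z_step_um,
    frame_interval_min = stack$frame_interval_min,
    bit_depth = stack$bit_depth,
    channel_roles = as.list(stack$channel_roles)
  ), sidecar_path)
  invisible(path)
}

#' Read a time-lapse stack from TIFF plus sidecar
#'
#' The sidecar declares the page nesting order and the calibration; the axis
#' order of the result is always normalized to T, Z, C, Y, X. Missing
#' calibration is an error: distances are never silently assumed to be in
#' pixel units.
#'
#' @param path TIFF path.
#' @param sidecar_path JSON sidecar path (default: `path` + ".json").
#' @param calibration optional named list overriding/standing in for the
#'   sidecar (`pixel_size_um`, `z_step_um`, `frame_interval_min`,
#'   `bit_depth`, `shape`, `channel_roles`).
#' @return a `TimeLapseStack`.
#' @export
read_stack <- function(path, sidecar_path = paste0(path, ".json"),
                       calibration = NULL) {
  meta <- if (!is.null(calibration)) calibration
          else if (file.exists(sidecar_path)) jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
          else abort(sprintf("no calibration: sidecar '%s' missing and none passed", sidecar_path),
                     "gliadyn_calibration_error")
  need <- c("pixel_size_um", "z_step_um", "frame_interval_min", "bit_depth", "shape")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(paste0("calibration sidecar missing field(s): ", paste(miss, collapse = ", ")),
          "gliadyn_calibration_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sh <- meta$shape
  dT <- as.integer(sh$T); dZ <- as.integer(sh$Z); dC <- as.integer(sh$C)
  dY <- as.integer(sh$Y); dX <- as.integer(sh$X)
  if (length(pages) != dT * dZ * dC) {
    abort("page count does not match sidecar shape", "gliadyn_format_error")
  }
  porder <- if (!is.null(meta$page_order)) unlist(meta$page_order) else c("T", "Z", "C")
  sizes <- c(T = dT, Z = dZ, C = dC)[porder]
  data <- array(0, c(dT, dZ, dC, dY, dX))
  idx <- as.matrix(expand.grid(lapply(rev(sizes), seq_len)))[, rev(seq_along(sizes)), drop = FALSE]
  colnames(idx) <- porder
  for (i in seq_along(pages)) {
    data[idx[i, "T"], idx[i, "Z"], idx[i, "C"], , ] <- pages[[i]]
  }
  roles <- if (!is.null(meta$channel_roles)) {
    stats::setNames(as.integer(unlist(meta$channel_roles[c("infusion", "microglia")])),
                    c("infusion", "microglia"))
  } else if (dC >= 2L) c(infusion = 1L, microglia = 2L)
  else abort("channel roles unresolvable for a single-channel stack",
             "gliadyn_calibration_error")
  timelapse_stack(data, roles, meta$pixel_size_um, meta$z_step_um,
                  meta$frame_interval_min, meta$bit_depth)
}

#' Write / read a single-channel 3D (Z, Y, X) stack
#'
#' Used for the infusion-volume stacks. Calibration travels in the same
#' sidecar layout as the time-lapse writer.
#'
#' @param stack3d 3D array ordered Z, Y, X.
#' @param path TIFF path.
#' @param pixel_size_um,z_step_um,bit_depth calibration.
#' @param sidecar_path JSON path.
#' @return `path` invisibly (writer); 3D array with calibration attributes
#'   (reader).
#' @export
write_volume_stack <- function(stack3d, path, pixel_size_um, z_step_um,
                               bit_depth = 16L,
                               sidecar_path = paste0(path, ".json")) {
  stopifnot(length(dim(stack3d)) == 3L)
  scale <- 2^bit_depth - 1
  pages <- lapply(seq_len(dim(stack3d)[1L]),
                  function(z) matrix(stack3d[z, , ], dim(stack3d)[2L], dim(stack3d)[3L]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  write_json_file(list(
    axis_order = "ZYX",
    shape = list(Z = dim(stack3d)[1L], Y = dim(stack3d)[2L], X = dim(stack3d)[3L]),
    pixel_size_um = pixel_size_um, z_step_um = z_step_um, bit_depth = bit_depth
  ), sidecar_path)
  invisible(path)
}

#' @rdname write_volume_stack
#' @export
read_volume_stack <- function(path, sidecar_path = paste0(path, ".json")) {
  if (!file.exists(sidecar_path)) {
    abort("volume stack sidecar missing", "gliadyn_calibration_error")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, c(length(pages), dim(pages[[1L]])))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
  attr(out, "pixel_size_um") <- meta$pixel_size_um
  attr(out, "z_step_um") <- meta$z_step_um
  attr(out, "bit_depth") <- meta$bit_depth
  out
}

#' Construct a filament tracing
#'
#' A rooted tree of 3D nodes with SWC semantics: one root (soma, parent -1),
#' every other node points at an existing parent, no cycles. Coordinates are
#' micrometres; y increases downward, x rightward (the package-wide
#' convention).
#'
#' @param nodes data.frame with columns id, type, x, y, z, radius, parent.
#' @return object of class `FilamentTracing` with fields `nodes` and `soma`
#'   (the root id).
#' @export
filament_tracing <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    abort("nodes must have columns id, type, x, y, z, radius, parent",
          "gliadyn_format_error")
  }
  if (anyDuplicated(nodes$id)) abort("duplicate node ids", "gliadyn_format_error")
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L) {
    abort("tracing must have exactly one root (parent -1)", "gliadyn_format_error")
  }
  known <- c(-1, nodes$id)
  bad <- which(!(nodes$parent %in% known))
  if (length(bad)) {
    abort(sprintf("node %d (line %d) references missing parent id %d",
                  nodes$id[bad[1L]], bad[1L], nodes$parent[bad[1L]]),
          "gliadyn_format_error")
  }
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")])))) {
    abort("node coordinates must be finite", "gliadyn_format_error")
  }
  # acyclicity + connectivity: walk each node up to the root
  pmap <- stats::setNames(nodes$parent, as.character(nodes$id))
  for (i in seq_len(nrow(nodes))) {
    cur <- nodes$id[i]; steps <- 0L
    while (cur != -1) {
      cur <- pmap[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > nrow(nodes)) {
        abort(sprintf("cycle detected at node id %d (line %d)", nodes$id[i], i),
              "gliadyn_format_error")
      }
    }
  }
  structure(list(nodes = nodes, soma = nodes$id[roots]), class = "FilamentTracing")
}

#' Read / write SWC filament tracings
#'
#' Plain 7-column SWC: id, type, x, y, z, radius, parent; `#` comments allowed.
#' Coordinates are taken as micrometres.
#'
#' @param path SWC file path.
#' @return `read_swc`: a `FilamentTracing`. `write_swc`: `path`, invisibly.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) abort("SWC file has no data lines", "gliadyn_format_error")
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nbad <- which(lengths(fields) != 7L)
  if (length(nbad)) {
    abort(sprintf("SWC line %d does not have 7 columns", which(keep)[nbad[1L]]),
          "gliadyn_format_error")
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  nodes <- data.frame(id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
                      x = m[, 3L], y = m[, 4L], z = m[, 5L],
                      radius = m[, 6L], parent = as.integer(m[, 7L]))
  filament_tracing(nodes)
}

#' @rdname read_swc
#' @param tracing a `FilamentTracing`.
#' @export
write_swc <- function(tracing, path) {
  stopifnot(inherits(tracing, "FilamentTracing"))
  n <- tracing$nodes
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   n$id, n$type, n$x, n$y, n$z, n$radius, n$parent)
  writeLines(c("# SWC filament tracing (coordinates in um)", lines), path)
  invisible(path)
}

#' Write a per-timepoint series as CSV with units in the headers
#'
#' @param df data.frame, one row per timepoint.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
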