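#' Branch statistics of a filament tracing
#'
#' Total process length is the sum of Euclidean parent-child edge lengths over
#' all nodes (3D). A branch point is any non-root node with at least two
#' children; the root (soma) counts as a branch point only with at least three
#' children, since its first two children are the two ends of a single passing
#' process rather than a bifurcation.
#'
#' @param tracing a `FilamentTracing`.
#' @return list with `total_length_um` and `n_branch_points`.
#' @export
branch_statistics <- function(tracing) {
  stopifnot(inherits(tracing, "FilamentTracing"))
  n <- tracing$nodes
  if (nrow(n) == 1L) return(list(total_length_um = 0, n_branch_points = 0L))
  idx <- match(n$parent, n$id)
  child <- which(n$parent != -1)
  p <- idx[child]
  seg <- sqrt((n$x[child] - n$x[p])^2 + (n$y[child] - n$y[p])^2 +
              (n$z[child] - n$z[p])^2)
  nchildren <- tabulate(p, nbins = nrow(n))
  root_row <- which(n$parent == -1)
  nbp <- sum(nchildren[-root_row] >= 2L) + as.integer(nchildren[root_row] >= 3L)
  list(total_length_um = sum(seg), n_branch_points = nbp)
}

#' Orient tracings toward the infusion site
#'
#' Translates each tracing so its soma sits at the origin and rotates it
#' in-plane so the soma-to-infusion-center direction maps onto the +x axis;
#' z is untouched. The transform is a rigid isometry, so all inter-node
#' distances are preserved exactly. Tracings whose soma coincides with the
#' infusion center have no defined facing direction; they are skipped and
#' reported in the `skipped` attribute.
#'
#' @param tracings list of `FilamentTracing` objects.
#' @param infusion_center_um infusion-site center as c(y, x) in micrometres
#'   (same frame as the tracing coordinates).
#' @return list of oriented `FilamentTracing` objects (attribute `skipped`
#'   holds indices of degenerate tracings that were dropped).
#' @export
orient_tracings <- function(tracings, infusion_center_um) {
  stopifnot(is.list(tracings), length(infusion_center_um) == 2L)
  cy <- infusion_center_um[1L]; cx <- infusion_center_um[2L]
  out <- list(); skipped <- integer()
  for (i in seq_along(tracings)) {
    tr <- tracings[[i]]
    stopifnot(inherits(tr, "FilamentTracing"))
    srow <- match(tr$soma, tr$nodes$id)
    sx <- tr$nodes$x[srow]; sy <- tr$nodes$y[srow]
    vx <- cx - sx; vy <- cy - sy
    if (vx == 0 && vy == 0) { skipped <- c(skipped, i); next }
    phi <- atan2(vy, vx)
    ct <- cos(-phi); st <- sin(-phi)
    px <- tr$nodes$x - sx; py <- tr$nodes$y - sy
    tr$nodes$x <- ct * px - st * py
    tr$nodes$y <- st * px + ct * py
    out[[length(out) + 1L]] <- tr
  }
  attr(out, "skipped") <- skipped
  out
}

# All grid cells a 2D segment passes through (supercover traversal).
# Bins are indexed by center: cell (i, j) covers
# [i*bin - bin/2, i*bin + bin/2) x (same in x); i runs over y, j over x.
supercover_cells <- function(x0, y0, x1, y1, bin) {
  to_idx <- function(v) floor(v / bin + 0.5)
  i0 <- to_idx(y0); j0 <- to_idx(x0)
  i1 <- to_idx(y1); j1 <- to_idx(x1)
  cells <- matrix(c(i0, j0), 1L, 2L)
  if (i0 == i1 && j0 == j1) return(cells)
  dx <- x1 - x0; dy <- y1 - y0
  # parametric crossings of the cell boundaries along each axis
  tx <- if (j0 != j1) {
    bnd <- if (j1 > j0) (seq(j0, j1 - 1L) + 0.5) * bin else (seq(j0, j1 + 1L) - 0.5) * bin
    (bnd - x0) / dx
  } else numeric()
  ty <- if (i0 != i1) {
    bnd <- if (i1 > i0) (seq(i0, i1 - 1L) + 0.5) * bin else (seq(i0, i1 + 1L) - 0.5) * bin
    (bnd - y0) / dy
  } else numeric()
  ts <- sort(unique(pmin(1, pmax(0, c(tx, ty)))))
  ts <- ts[ts > 0 & ts < 1]
  # midpoints of the sub-intervals give one interior point per visited cell
  mids <- (c(0, ts) + c(ts, 1)) / 2
  px <- x0 + mids * dx; py <- y0 + mids * dy
  unique(cbind(to_idx(py), to_idx(px)))
}

#' Rasterize oriented tracings into an infusion-oriented heatmap
#'
#' Each tracing's edges are traced (in-plane, supercover traversal so thin
#' diagonal processes leave no gaps) into a square grid centered on the soma
#' origin of the oriented frame; each tracing increments a cell at most once,
#' so cell counts are numbers of overlapping microglia processes. Quadrant
#' percentages of the occupied cells are attached (see
#' \code{\link{quadrant_coverage}}).
#'
#' @param oriented list of oriented `FilamentTracing` objects (see
#'   \code{\link{orient_tracings}}).
#' @param bin_size_um cell size in micrometres (default 1).
#' @param extent_um half-width of the grid in micrometres (default 60); the
#'   grid has an odd number of cells so that a cell center sits at the origin.
#' @return a `HeatmapGrid`: list with `grid` (counts, rows = y, cols = x),
#'   `bin_size_um`, `centers_um`, `quadrant_pct`.
#' @export
projection_heatmap <- function(oriented, bin_size_um = 1, extent_um = 60) {
  if (length(oriented) < 1L) abort("need at least one tracing", "gliadyn_usage_error")
  nh <- floor(extent_um / bin_size_um)
  centers <- seq(-nh, nh) * bin_size_um
  ncell <- 2L * nh + 1L
  grid <- matrix(0, ncell, ncell)
  any_in <- FALSE
  for (tr in oriented) {
    n <- tr$nodes
    idx <- match(n$parent, n$id)
    child <- which(n$parent != -1)
    seen <- matrix(FALSE, ncell, ncell)
    for (k in child) {
      p <- idx[k]
      cells <- supercover_cells(n$x[p], n$y[p], n$x[k], n$y[k], bin_size_um)
      ii <- cells[, 1L] + nh + 1L
      jj <- cells[, 2L] + nh + 1L
      ok <- ii >= 1L & ii <= ncell & jj >= 1L & jj <= ncell
      if (any(ok)) seen[cbind(ii[ok], jj[ok])] <- TRUE
    }
    if (nrow(n) == 1L) {
      cells <- supercover_cells(n$x[1], n$y[1], n$x[1], n$y[1], bin_size_um)
      ii <- cells[1L] + nh + 1L; jj <- cells[2L] + nh + 1L
      if (ii >= 1L && ii <= ncell && jj >= 1L && jj <= ncell) seen[ii, jj] <- TRUE
    }
    if (any(seen)) any_in <- TRUE
    grid <- grid + seen
  }
  if (!any_in) abort("extent too small: no node rasterized into the grid",
                     "gliadyn_usage_error")
  hm <- structure(list(grid = grid, bin_size_um = bin_size_um,
                       centers_um = centers, quadrant_pct = NULL),
                  class = "HeatmapGrid")
  hm$quadrant_pct <- quadrant_coverage(hm)
  hm
}

#' Per-quadrant share of occupied heatmap cells
#'
#' The percentage of all occupied (process-containing) cells that fall in each
#' quadrant of the oriented frame. Quadrants follow the oriented coordinates
#' (y downward): Q1 = (+x, +y), Q2 = (-x, +y), Q3 = (-x, -y), Q4 = (+x, -y);
#' the infusion-facing side is +x (quadrants 1 and 4). Cells whose center lies
#' exactly on an axis are split 0.5/0.5 between the adjacent quadrants (0.25
#' each at the origin), so symmetric patterns land on exact values. The four
#' percentages sum to 100.
#'
#' @param hm a `HeatmapGrid`.
#' @return named numeric vector of four percentages (Q1..Q4).
#' @export
quadrant_coverage <- function(hm) {
  stopifnot(inherits(hm, "HeatmapGrid"))
  occ <- which(hm$grid > 0, arr.ind = TRUE)
  if (nrow(occ) == 0L) abort("empty heatmap grid", "gliadyn_usage_error")
  y <- hm$centers_um[occ[, 1L]]
  x <- hm$centers_um[occ[, 2L]]
  wq <- matrix(0, nrow(occ), 4L)
  for (r in seq_len(nrow(occ))) {
    xs <- if (x[r] > 0) 1L else if (x[r] < 0) -1L else 0L
    ys <- if (y[r] > 0) 1L else if (y[r] < 0) -1L else 0L
    qx <- if (xs == 0L) c(1L, -1L) else xs
    qy <- if (ys == 0L) c(1L, -1L) else ys
    combs <- expand.grid(qx = qx, qy = qy)
    w <- 1 / nrow(combs)
    for (m in seq_len(nrow(combs))) {
      q <- if (combs$qx[m] > 0 && combs$qy[m] > 0) 1L
           else if (combs$qx[m] < 0 && combs$qy[m] > 0) 2L
           else if (combs$qx[m] < 0 && combs$qy[m] < 0) 3L
           else 4L
      wq[r, q] <- wq[r, q] + w
    }
  }
  tot <- colSums(wq)
  stats::setNames(100 * tot / sum(tot), c("Q1", "Q2", "Q3", "Q4"))
}

#' Write a heatmap grid as 16-bit TIFF plus quadrant CSV
#'
#' @param hm a `HeatmapGrid`.
#' @param tiff_path output TIFF (counts scaled to the 16-bit range by the
#'   maximum count).
#' @param csv_path output CSV of quadrant percentages.
#' @return `tiff_path`, invisibly.
#' @export
write_heatmap <- function(hm, tiff_path, csv_path = NULL) {
  stopifnot(inherits(hm, "HeatmapGrid"))
  mx <- max(hm$grid)
  img <- if (mx > 0) hm$grid / mx else hm$grid
  tiff::writeTIFF(img, tiff_path, bits.per.sample = 16L)
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(quadrant = names(hm$quadrant_pct),
                                pct_occupied = as.numeric(hm$quadrant_pct)),
                     csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(tiff_path)
}
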