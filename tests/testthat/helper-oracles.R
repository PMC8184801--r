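# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# exhaustive Otsu: try every candidate split and minimize the weighted
# intra-class variance computed directly from the two groups
oracle_otsu <- function(x) {
  x <- as.numeric(x)
  vals <- sort(unique(x))
  cands <- (vals[-length(vals)] + vals[-1]) / 2  # midpoints between splits
  pvar <- function(v) if (length(v) == 0L) 0 else mean((v - mean(v))^2)
  icv <- vapply(cands, function(t) {
    bg <- x[x <= t]; fg <- x[x > t]
    (length(bg) * pvar(bg) + length(fg) * pvar(fg)) / length(x)
  }, numeric(1))
  cands[which.min(icv)]
}

# all-pairs Euclidean distance transform (distance to nearest TRUE pixel)
oracle_edt <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    out[r, cc] <- sqrt(min((fg[, 1] - r)^2 + (fg[, 2] - cc)^2))
  }
  out
}

# set dilation with a Euclidean disc
oracle_dilate <- function(mask, radius) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  fg <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    yy <- fg[, 1] + offs$dy[k]; xx <- fg[, 2] + offs$dx[k]
    ok <- yy >= 1 & yy <= nrow(mask) & xx >= 1 & xx <= ncol(mask)
    out[cbind(yy[ok], xx[ok])] <- TRUE
  }
  out
}

# dense-sampling rasterization of a segment onto the heatmap grid (bins
# indexed by center, matching projection_heatmap's convention)
oracle_raster_cells <- function(x0, y0, x1, y1, bin, n_samples = 1000000L) {
  tt <- seq(0, 1, length.out = n_samples)
  px <- x0 + tt * (x1 - x0); py <- y0 + tt * (y1 - y0)
  cells <- unique(cbind(floor(py / bin + 0.5), floor(px / bin + 0.5)))
  cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
}

# brute-force edge-length sum and branch-point count from a node table
oracle_branch_stats <- function(nodes) {
  len <- 0; nch <- integer(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    if (nodes$parent[i] == -1) next
    p <- which(nodes$id == nodes$parent[i])
    len <- len + sqrt(sum((c(nodes$x[i], nodes$y[i], nodes$z[i]) -
                           c(nodes$x[p], nodes$y[p], nodes$z[p]))^2))
    nch[p] <- nch[p] + 1L
  }
  root <- which(nodes$parent == -1)
  bp <- sum(nch[-root] >= 2L) + as.integer(nch[root] >= 3L)
  list(total_length_um = len, n_branch_points = bp)
}

# smooth textured frame for registration tests
mk_texture <- function(n = 128, seed = 1, amplitude = 100) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  x <- matrix(stats::runif(n * n), n, n)
  x <- EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = 3))
  (x - min(x)) / (max(x) - min(x)) * amplitude
}

# small, fast simulation configuration used by several suites
small_sim_config <- function(...) {
  defaults <- list(image_shape = c(T = 8L, Z = 2L, Y = 160L, X = 160L),
                   blob_radius_um = 8, soma_ring_radius_um = 16,
                   process_length_um = 6, soma_radius_um = 2,
                   n_microglia = 6L, process_speed_um_per_min = 1.5)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

random_tracing <- function(seed, n_nodes = 20L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nodes <- data.frame(id = 1L, type = 1L, x = stats::runif(1, -20, 20),
                      y = stats::runif(1, -20, 20), z = 0, radius = 2,
                      parent = -1L)
  for (i in 2:n_nodes) {
    p <- nodes$id[sample.int(nrow(nodes), 1L)]
    pr <- which(nodes$id == p)
    nodes[i, ] <- list(i, 3L, nodes$x[pr] + stats::runif(1, -5, 5),
                       nodes$y[pr] + stats::runif(1, -5, 5),
                       nodes$z[pr] + stats::runif(1, -1, 1), 0.5, p)
  }
  filament_tracing(nodes)
}
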