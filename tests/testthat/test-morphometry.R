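path_tracing <- function(coords) {
  # coords: matrix with columns x, y, z; simple unbranched path
  n <- nrow(coords)
  filament_tracing(data.frame(id = seq_len(n), type = c(1L, rep(3L, n - 1L)),
                              x = coords[, 1], y = coords[, 2], z = coords[, 3],
                              radius = 1, parent = c(-1L, seq_len(n - 1L))))
}

test_that("branch statistics match hand-built fixtures", {
  tr <- path_tracing(cbind(c(0, 1, 2), 0, 0))
  bs <- branch_statistics(tr)
  expect_equal(bs$total_length_um, 2)
  expect_identical(bs$n_branch_points, 0L)

  y <- filament_tracing(data.frame(
    id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 0, -1, 1), y = c(0, 1, 2, 2), z = 0, radius = 1,
    parent = c(-1L, 1L, 2L, 2L)))
  expect_identical(branch_statistics(y)$n_branch_points, 1L)

  single <- filament_tracing(data.frame(id = 1L, type = 1L, x = 0, y = 0,
                                        z = 0, radius = 1, parent = -1L))
  expect_identical(branch_statistics(single)$total_length_um, 0)
})

test_that("branch statistics equal the brute-force oracle on random trees", {
  for (s in 1:30) {
    tr <- random_tracing(s, n_nodes = sample(5:40, 1))
    bs <- branch_statistics(tr)
    or <- oracle_branch_stats(tr$nodes)
    expect_equal(bs$total_length_um, or$total_length_um)
    expect_identical(bs$n_branch_points, or$n_branch_points)
  }
})

test_that("generator filament truth matches the edge-sum oracle", {
  fs <- generate_filament_set(6, c(10, -5), seed = 8)
  tr <- attr(fs, "truth")
  for (i in seq_along(fs)) {
    or <- oracle_branch_stats(fs[[i]]$nodes)
    expect_equal(tr[[i]]$total_length_um, or$total_length_um)
    expect_identical(tr[[i]]$n_branch_points, or$n_branch_points)
  }
})

test_that("orientation maps the facing direction onto +x and preserves distances", {
  # soma directly left of the center: already facing +x
  tr <- path_tracing(cbind(c(-10, -8), c(0, 0), c(0, 0)))
  o <- orient_tracings(list(tr), c(0, 0))[[1]]
  expect_equal(o$nodes$x, c(0, 2))
  expect_equal(o$nodes$y, c(0, 0), tolerance = 1e-12)

  # soma directly above the center (smaller y): facing is +y in image coords
  tr2 <- path_tracing(cbind(c(0, 0), c(-10, -7), c(0, 0)))
  o2 <- orient_tracings(list(tr2), c(0, 0))[[1]]
  expect_equal(o2$nodes$x, c(0, 3), tolerance = 1e-12)
  expect_equal(o2$nodes$y, c(0, 0), tolerance = 1e-12)

  for (s in 1:10) {
    tr <- random_tracing(s)
    o <- orient_tracings(list(tr), c(5, 5))[[1]]
    d_in <- dist(as.matrix(tr$nodes[, c("x", "y", "z")]))
    d_out <- dist(as.matrix(o$nodes[, c("x", "y", "z")]))
    expect_lt(max(abs(d_in - d_out)), 1e-9)
  }
})

test_that("degenerate soma at the infusion center is skipped, not rotated", {
  tr <- path_tracing(cbind(c(0, 1), c(0, 0), c(0, 0)))
  o <- orient_tracings(list(tr), c(0, 0))
  expect_identical(length(o), 0L)
  expect_identical(attr(o, "skipped"), 1L)
})

test_that("heatmap rasterization matches the dense-sampling oracle", {
  # single straight process along +x stays on the y = 0 row
  tr <- path_tracing(cbind(c(0, 10), c(0, 0), c(0, 0)))
  hm <- projection_heatmap(list(tr), 1, 15)
  occ <- which(hm$grid > 0, arr.ind = TRUE)
  expect_true(all(hm$centers_um[occ[, 1]] == 0))
  expect_true(all(hm$centers_um[occ[, 2]] >= 0))

  set.seed(77)
  for (i in 1:20) {
    a <- runif(4, -12, 12)
    cells <- gliadyn:::supercover_cells(a[1], a[2], a[3], a[4], 1)
    oc <- oracle_raster_cells(a[1], a[2], a[3], a[4], 1)
    cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
    expect_identical(unname(cells), unname(oc))
  }
})

test_that("quadrant percentages sum to 100 and respect symmetry", {
  right <- path_tracing(cbind(c(2, 10), c(2, 10), c(0, 0)))  # strictly Q1
  hm <- projection_heatmap(list(right), 1, 15)
  expect_equal(unname(hm$quadrant_pct), c(100, 0, 0, 0))

  cross <- lapply(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), function(d)
    path_tracing(cbind(c(0, 10 * d[1]), c(0, 10 * d[2]), c(0, 0))))
  hmx <- projection_heatmap(cross, 1, 15)
  expect_equal(unname(hmx$quadrant_pct), rep(25, 4))
  expect_equal(sum(hmx$quadrant_pct), 100, tolerance = 1e-9)

  set.seed(3)
  rnd <- lapply(1:5, random_tracing)
  hmr <- projection_heatmap(rnd, 2, 60)
  expect_equal(sum(hmr$quadrant_pct), 100, tolerance = 1e-9)
})

test_that("orientation bias shows up as facing-quadrant dominance", {
  for (s in 1:10) {
    fs <- generate_filament_set(8, c(0, 0), seed = 100 + s,
                                orientation_bias = 0.9)
    ori <- orient_tracings(fs, c(0, 0))
    hm <- projection_heatmap(ori, 2, 120)
    facing <- hm$quadrant_pct[["Q1"]] + hm$quadrant_pct[["Q4"]]
    expect_gt(facing, 100 - facing)
  }
})

test_that("empty-extent and empty-grid cases error cleanly", {
  tr <- path_tracing(cbind(c(500, 510), c(500, 500), c(0, 0)))
  expect_error(projection_heatmap(list(tr), 1, 10), class = "gliadyn_usage_error")
})
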