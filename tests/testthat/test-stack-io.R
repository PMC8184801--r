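test_that("stack write/read round-trip is bit-identical with calibration", {
  cfg <- small_sim_config(image_shape = c(T = 2L, Z = 3L, Y = 64L, X = 64L),
                          blob_radius_um = 4, soma_ring_radius_um = 6,
                          process_length_um = 3, soma_radius_um = 1.5,
                          tip_radius_um = 1, n_microglia = 3L, seed = 5)
  tl <- generate_timelapse(cfg)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(tl$stack, path)
  back <- read_stack(path)
  expect_identical(back$data, tl$stack$data)
  expect_identical(back$pixel_size_um, tl$stack$pixel_size_um)
  expect_identical(back$z_step_um, tl$stack$z_step_um)
  expect_identical(back$frame_interval_min, tl$stack$frame_interval_min)
  expect_identical(back$channel_roles, tl$stack$channel_roles)
})

test_that("degenerate T=1, Z=1 stacks survive the round trip", {
  data <- array(sample(0:255, 2 * 16 * 16, TRUE), c(1, 1, 2, 16, 16))
  st <- timelapse_stack(data, pixel_size_um = 0.4, z_step_um = 3,
                        frame_interval_min = 1, bit_depth = 8L)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_identical(dim(back$data), dim(data))
  expect_identical(back$data, data + 0)
})

test_that("missing calibration is an explicit error, never a silent default", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), path)
  expect_error(read_stack(path), class = "gliadyn_calibration_error")
  expect_error(read_stack(path, calibration = list(pixel_size_um = 0.4)),
               class = "gliadyn_calibration_error")
})

test_that("axis normalization honors the declared page order and conserves voxels", {
  set.seed(9)
  dT <- 2L; dZ <- 2L; dC <- 2L
  arr <- array(sample(0:255, dT * dZ * dC * 8 * 8, TRUE), c(dT, dZ, dC, 8, 8))
  # write pages nested C-major, then T, then Z, and declare that order
  pages <- list()
  for (c in seq_len(dC)) for (t in seq_len(dT)) for (z in seq_len(dZ)) {
    pages[[length(pages) + 1L]] <- matrix(arr[t, z, c, , ], 8, 8) / 255
  }
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(page_order = c("C", "T", "Z"),
                            shape = list(T = dT, Z = dZ, C = dC, Y = 8, X = 8),
                            pixel_size_um = 0.4, z_step_um = 3,
                            frame_interval_min = 1, bit_depth = 8,
                            channel_roles = list(infusion = 1, microglia = 2)),
                       side, auto_unbox = TRUE)
  back <- read_stack(path)
  expect_identical(back$data, arr + 0)
  expect_identical(sum(back$data), sum(arr) + 0)
})

test_that("SWC files parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 2 -1", "2 3 1 0 0 0.5 1", "3 3 2 0 0 0.5 2"),
             path)
  tr <- read_swc(path)
  expect_identical(nrow(tr$nodes), 3L)
  expect_identical(tr$soma, 1L)

  writeLines(c("1 1 0 0 0 2 -1", "2 3 1 0 0 0.5 7"), path)
  expect_error(read_swc(path), class = "gliadyn_format_error")

  for (s in 1:5) {
    tr <- random_tracing(s)
    write_swc(tr, path)
    back <- read_swc(path)
    expect_equal(back$nodes$x, tr$nodes$x, tolerance = 1e-7)
    expect_identical(back$nodes$id, tr$nodes$id)
    expect_identical(back$nodes$parent, tr$nodes$parent)
    # canonicalized files are a fixed point of write/read
    write_swc(back, path)
    expect_identical(read_swc(path)$nodes, back$nodes)
  }
})

test_that("tracings with cycles or multiple roots are rejected", {
  nodes <- data.frame(id = 1:2, type = 3L, x = 0, y = 0, z = 0, radius = 1,
                      parent = c(2L, 1L))
  expect_error(filament_tracing(nodes), class = "gliadyn_format_error")
  nodes2 <- data.frame(id = 1:2, type = 1L, x = 0, y = 0, z = 0, radius = 1,
                       parent = c(-1L, -1L))
  expect_error(filament_tracing(nodes2), class = "gliadyn_format_error")
})

test_that("volume stacks round-trip with calibration attributes", {
  gv <- generate_volume_stack(shape = c(6L, 24L, 24L), radius_um = 4,
                              n_specks = 2L, seed = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume_stack(gv$stack3d, path, 0.8, 5)
  back <- read_volume_stack(path)
  expect_equal(back[, , ], gv$stack3d[, , ], ignore_attr = TRUE)
  expect_identical(attr(back, "pixel_size_um"), 0.8)
})
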