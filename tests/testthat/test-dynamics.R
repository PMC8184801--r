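mask_from <- function(m) {
  structure(list(mask = m, threshold_used = 0, min_feature_area_px = 1L,
                 dilation_radius_px = 0L, erosion_radius_px = NA_integer_),
            class = "InfusionMask")
}

proj_from <- function(frames, px = 0.4, dt = 1) {
  # frames: list of green matrices; an all-zero infusion channel is added
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  data <- array(0, c(length(frames), 2L, ny, nx))
  for (t in seq_along(frames)) data[t, 2L, , ] <- frames[[t]]
  structure(list(data = data, channel_roles = c(infusion = 1L, microglia = 2L),
                 pixel_size_um = px, frame_interval_min = dt),
            class = "Projection2D")
}

test_that("baseline statistics use the population SD over the stated region", {
  g <- matrix(7, 8, 8)
  m <- mask_from(matrix(TRUE, 8, 8))
  b <- baseline_statistics(g, m)
  expect_identical(c(b$mean, b$sd), c(7, 0))

  g2 <- matrix(c(0, 10), 8, 8)
  b2 <- baseline_statistics(g2, m)
  expect_identical(c(b2$mean, b2$sd), c(5, 5))

  set.seed(4)
  g3 <- matrix(rnorm(64), 8, 8)
  sel <- matrix(FALSE, 8, 8); sel[2:5, 3:7] <- TRUE
  b3 <- baseline_statistics(g3, mask_from(sel))
  expect_equal(b3$mean, mean(g3[sel]))
  expect_equal(b3$sd, sqrt(mean((g3[sel] - mean(g3[sel]))^2)))
})

test_that("coverage hits 0 and 100 at the extremes and is monotone in k", {
  m <- mask_from(matrix(c(TRUE, FALSE), 10, 10))
  frames <- list(matrix(0, 10, 10), matrix(100, 10, 10))
  pr <- proj_from(frames)
  base <- structure(list(mean = 1, sd = 2, region = "within_mask",
                         frame_index = 1L), class = "BaselineStats")
  cs <- coverage_series(pr, m, baseline = base)
  expect_identical(cs$coverage_pct, c(0, 100))

  set.seed(5)
  noisy <- proj_from(list(matrix(runif(100, 0, 10), 10, 10)))
  covs <- vapply(c(0.5, 1, 1.5, 2, 3), function(k)
    coverage_series(noisy, m, baseline = base, k = k)$coverage_pct, numeric(1))
  expect_true(all(diff(covs) <= 0))
})

test_that("coverage ignores intensity changes outside the mask", {
  m <- mask_from(matrix(c(TRUE, FALSE), 10, 10))
  set.seed(6)
  g <- matrix(runif(100, 0, 10), 10, 10)
  g2 <- g
  g2[!m$mask] <- sample(g2[!m$mask])  # relabel outside pixels
  base <- structure(list(mean = 2, sd = 1, region = "within_mask",
                         frame_index = 1L), class = "BaselineStats")
  c1 <- coverage_series(proj_from(list(g)), m, baseline = base)$coverage_pct
  c2 <- coverage_series(proj_from(list(g2)), m, baseline = base)$coverage_pct
  expect_identical(c1, c2)
})

test_that("distance map is the exact EDT of the eroded mask, in microns", {
  m <- matrix(FALSE, 9, 9); m[3, 3] <- TRUE
  dm <- eroded_distance_map(mask_from(m), 0, 0.4)
  expect_identical(dm$distances_um[3, 3], 0)
  expect_equal(dm$distances_um[6, 7], 5 * 0.4)  # 3-4-5 triangle

  set.seed(12)
  for (i in 1:25) {
    n <- sample(5:32, 1); k <- sample(5:32, 1)
    mm <- matrix(runif(n * k) < 0.08, n, k)
    if (!any(mm)) mm[1, 1] <- TRUE
    dm <- eroded_distance_map(mask_from(mm), 0, 1)
    expect_lt(max(abs(dm$distances_um - oracle_edt(mm))), 1e-9)
  }
})

test_that("erosion radius is honored and over-erosion raises an error", {
  m <- matrix(FALSE, 21, 21)
  m[7:15, 7:15] <- TRUE
  dm <- eroded_distance_map(mask_from(m), 2, 1)
  er <- dm$distances_um == 0
  expect_true(all(which(er) %in% which(m)))
  expect_lt(sum(er), sum(m))
  expect_error(eroded_distance_map(mask_from(m), 8, 1),
               class = "gliadyn_segmentation_error")
})

test_that("mean distance series averages the qualifying pixels' distances", {
  m <- matrix(FALSE, 9, 9); m[3, 3] <- TRUE
  dmap <- eroded_distance_map(mask_from(m), 0, 0.4)
  g <- matrix(0, 9, 9); g[6, 7] <- 50
  base <- structure(list(mean = 0, sd = 1, region = "within_mask",
                         frame_index = 1L), class = "BaselineStats")
  ds <- mean_distance_series(proj_from(list(g)), dmap, baseline = base)
  expect_equal(ds$mean_distance_um, 2.0)
  expect_identical(ds$n_pixels_counted, 1L)

  gin <- matrix(0, 9, 9); gin[3, 3] <- 50
  ds2 <- mean_distance_series(proj_from(list(gin)), dmap, baseline = base,
                              exclude_inside = FALSE)
  expect_identical(ds2$mean_distance_um, 0)

  expect_warning(
    ds3 <- mean_distance_series(proj_from(list(matrix(0, 9, 9))), dmap,
                                baseline = base),
    "no qualifying"
  )
  expect_true(is.na(ds3$mean_distance_um))
})

test_that("noiseless pipeline reproduces simulation truth (closure)", {
  cfg <- small_sim_config(shot_noise = FALSE, seed = 41)
  tl <- generate_timelapse(cfg)
  pr <- sum_projection(tl$stack)
  m <- segment_infusion(projection_frame(pr, 1, "infusion"),
                        min_feature_area_px = 32, dilation_radius_px = 0)
  cs <- coverage_series(pr, m)
  expect_lt(max(abs(cs$coverage_pct - tl$truth$true_coverage_pct)), 2)
  dm <- eroded_distance_map(m, 0, cfg$pixel_size_um)
  ds <- mean_distance_series(pr, dm, mask = m)
  expect_lt(max(abs(ds$mean_distance_um - tl$truth$true_mean_distance_um)), 0.2)
})

test_that("static scenes give a constant distance series", {
  cfg <- small_sim_config(process_speed_um_per_min = 0, shot_noise = FALSE,
                          seed = 42)
  tl <- generate_timelapse(cfg)
  pr <- sum_projection(tl$stack)
  m <- segment_infusion(projection_frame(pr, 1, "infusion"),
                        min_feature_area_px = 32, dilation_radius_px = 0)
  dm <- eroded_distance_map(m, 0, cfg$pixel_size_um)
  ds <- mean_distance_series(pr, dm, mask = m)
  expect_identical(max(ds$mean_distance_um) - min(ds$mean_distance_um), 0)
})

test_that("displacement composite is deterministic and color-faithful", {
  cfg <- small_sim_config(image_shape = c(T = 3L, Z = 2L, Y = 160L, X = 160L),
                          seed = 43)
  tl <- generate_timelapse(cfg)
  pr <- sum_projection(tl$stack)
  m <- segment_infusion(projection_frame(pr, 1, "infusion"),
                        min_feature_area_px = 32)
  c1 <- displacement_composite(pr, 1, 1, m)
  expect_identical(c1[, , 1], c1[, , 2])
  c2 <- displacement_composite(pr, 1, 3, m)
  expect_identical(c2, displacement_composite(pr, 1, 3, m))
  expect_true(all(c2[m$mask] == 1))
  # disjoint signals never co-light a pixel
  a <- matrix(0, 8, 8); a[1:4, ] <- 60
  b <- matrix(0, 8, 8); b[5:8, ] <- 60
  cc <- displacement_composite(proj_from(list(a, b)), 1, 2)
  expect_identical(sum(cc[, , 1] > 0.5 & cc[, , 2] > 0.5), 0L)
})
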