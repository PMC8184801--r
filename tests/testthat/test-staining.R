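test_that("area fraction counts pixels above threshold within the ROI", {
  img <- matrix(c(rep(10, 50), rep(90, 50)), 10, 10)
  expect_equal(area_fraction(img, 50)$percent_covered, 50)
  expect_equal(area_fraction(img, 1000)$percent_covered, 0)

  r <- roi(0, 5, 10, 5)  # the right half holds the bright columns
  expect_equal(area_fraction(img, 50, r)$percent_covered, 100)
  expect_error(area_fraction(img, 50, roi(5, 5, 20, 20)),
               class = "gliadyn_usage_error")

  af <- generate_stain_image("area_fraction", seed = 12)
  expect_identical(area_fraction(af$image, af$truth$threshold)$percent_covered,
                   af$truth$percent)
  # monotone non-increasing in threshold
  ths <- c(0, 5, 50, 150, 250)
  fr <- vapply(ths, function(t) area_fraction(af$image, t)$percent_covered,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("ROIs in micrometres map through the calibration", {
  r <- roi(10, 20, 100, 100, unit = "um", pixel_size_um = 2)
  expect_identical(c(r$y0, r$x0, r$height, r$width), c(5L, 10L, 50L, 50L))
  expect_error(roi(0, 0, 100, 100, unit = "um"),
               class = "gliadyn_calibration_error")
})

test_that("puncta coverage averages four deterministic edge ROIs", {
  pf <- generate_stain_image("puncta", seed = 13)
  res <- puncta_coverage(pf$image, pf$edge_mask, pf$threshold,
                         pixel_size_um = pf$pixel_size_um)
  expect_equal(res$mean_pct, pf$truth$mean_pct, tolerance = 1e-12)
  expect_equal(res$per_roi_pct, pf$truth$per_roi_pct, tolerance = 1e-12)
  expect_identical(length(res$per_roi_pct), 4L)

  zero <- puncta_coverage(matrix(0, nrow(pf$image), ncol(pf$image)),
                          pf$edge_mask, pf$threshold,
                          pixel_size_um = pf$pixel_size_um)
  expect_identical(zero$mean_pct, 0)

  # identical per-ROI values average to themselves; uniform density comes out
  # within one pixel's discretization of the nominal rate
  dens <- 0.05
  pf2 <- generate_stain_image("puncta", list(density = dens), seed = 14)
  res2 <- puncta_coverage(pf2$image, pf2$edge_mask, pf2$threshold,
                          pixel_size_um = pf2$pixel_size_um)
  nominal <- 100 * dens
  expect_lt(abs(res2$mean_pct - nominal), 0.35 * nominal)
})

test_that("edge ROIs are shifted inward rather than clipped", {
  edge <- matrix(FALSE, 90, 90); edge[40:60, 40:60] <- TRUE
  img <- matrix(0, 90, 90)
  res <- puncta_coverage(img, edge, 1, roi_size_um = 100, n_rois = 4L,
                         pixel_size_um = 2)
  for (r in res$rois) {
    expect_gte(r$y0, 0); expect_gte(r$x0, 0)
    expect_lte(r$y0 + r$height, 90)
    expect_lte(r$x0 + r$width, 90)
    expect_identical(c(r$height, r$width), c(50L, 50L))
  }
  expect_true(any(res$shifted))
})

test_that("uptake fraction counts cells overlapping signal", {
  up <- generate_stain_image("uptake", seed = 15)
  res <- uptake_fraction(up$cell_label_image, up$signal_mask)
  expect_identical(res$percent_positive, up$truth$percent)
  expect_identical(sort(res$positive_ids), up$truth$positive_ids)

  none <- uptake_fraction(up$cell_label_image,
                          matrix(FALSE, nrow(up$signal_mask), ncol(up$signal_mask)))
  expect_identical(none$percent_positive, 0)
  expect_error(uptake_fraction(matrix(0L, 4, 4), matrix(FALSE, 4, 4)),
               class = "gliadyn_usage_error")

  # invariant to relabeling of the cell ids
  relab <- up$cell_label_image
  relab[relab > 0] <- 100L + relab[relab > 0]
  res2 <- uptake_fraction(relab, up$signal_mask)
  expect_identical(res2$percent_positive, res$percent_positive)

  # brute-force per-cell recount
  ids <- setdiff(unique(as.vector(up$cell_label_image)), 0L)
  manual <- sum(vapply(ids, function(i)
    sum(up$cell_label_image == i & up$signal_mask) >= 1, logical(1)))
  expect_identical(res$n_positive, as.integer(manual))
})

test_that("plaque surface coverage spans 0 to 100 and matches fixtures", {
  pl <- generate_stain_image("plaque3d", seed = 16)
  res <- plaque_surface_coverage(pl$plaque_stack, pl$microglia_stack,
                                 pl$intensity_floor)
  expect_lt(abs(res$percent_covered - pl$truth$percent), 3)
  expect_lt(abs(res$percent_covered - pl$truth$nominal_percent), 10)

  none <- plaque_surface_coverage(pl$plaque_stack, array(0, dim(pl$plaque_stack)),
                                  pl$intensity_floor)
  expect_identical(none$percent_covered, 0)

  # microglia fully enclosing the plaque
  full <- plaque_surface_coverage(pl$plaque_stack, pl$plaque_stack,
                                  pl$intensity_floor, contact_radius_px = 1L)
  expect_identical(full$percent_covered, 100)

  expect_error(plaque_surface_coverage(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))),
               class = "gliadyn_segmentation_error")
})

test_that("coverage of exactly half the surface voxels scores exactly 50", {
  dm <- c(16L, 32L, 32L)
  ctr <- (dm - 1) / 2
  zz <- (seq_len(dm[1]) - 1) - ctr[1]
  yy <- (seq_len(dm[2]) - 1) - ctr[2]
  xx <- (seq_len(dm[3]) - 1) - ctr[3]
  d2 <- outer(outer(zz^2, yy^2, "+"), xx^2, "+")
  pm <- d2 <= 6^2
  plaque <- array(0, dm); plaque[pm] <- 800
  # surface voxels, then mark exactly half of them as microglia-contacted
  surf <- which(pm & !(gliadyn:::shift3d(pm, 1, 0, 0) & gliadyn:::shift3d(pm, -1, 0, 0) &
                       gliadyn:::shift3d(pm, 0, 1, 0) & gliadyn:::shift3d(pm, 0, -1, 0) &
                       gliadyn:::shift3d(pm, 0, 0, 1) & gliadyn:::shift3d(pm, 0, 0, -1)))
  stopifnot(length(surf) %% 2 == 0)
  half <- surf[seq_len(length(surf) / 2)]
  micro <- array(0, dm); micro[half] <- 800
  res <- plaque_surface_coverage(plaque, micro, 500, contact_radius_px = 0L)
  expect_identical(res$percent_covered, 50)
})

test_that("coverage is invariant to which disconnected component makes contact", {
  dm <- c(10L, 24L, 24L)
  plaque <- array(0, dm); plaque[4:7, 10:14, 10:14] <- 800
  mA <- array(0, dm); mA[4:7, 8:9, 10:14] <- 800     # touches one face
  mB <- array(0, dm); mB[4:7, 15:16, 10:14] <- 800   # mirror component
  both1 <- mA; both1[1, 1, 1] <- 800                  # far blob, no contact
  rA <- plaque_surface_coverage(plaque, mA, 500)
  rB <- plaque_surface_coverage(plaque, mB, 500)
  expect_identical(rA$percent_covered, rB$percent_covered)
})

test_that("regression helper returns OLS slope and intercept", {
  x <- 1:10
  y <- 2.5 * x + 1 + c(0.1, -0.1, 0, 0.05, -0.05, 0, 0.1, -0.1, 0, 0)
  fit <- coverage_regression(x, y)
  expect_equal(fit$slope, unname(coef(lm(y ~ x))[2]))
  expect_gt(fit$r_squared, 0.99)
})
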