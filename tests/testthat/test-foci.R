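test_that("segmentation finds exactly the rendered objects", {
  mask <- matrix(TRUE, 80, 80)
  # uniform image: no foci
  seg <- segment_foci(matrix(100, 80, 80), mask)
  expect_equal(seg$n_foci, 0)
  # three disjoint discs well above background
  img <- matrix(100, 80, 80)
  for (c0 in list(c(20, 20), c(20, 60), c(60, 40)))
    img[(row(img) - c0[1])^2 + (col(img) - c0[2])^2 <= 6^2] <- 1000
  seg <- segment_foci(img, mask)
  expect_equal(seg$n_foci, 3)
  # a disc below min_area_px is filtered out
  img2 <- matrix(100, 80, 80)
  img2[40, 40] <- 1000; img2[40, 41] <- 1000
  seg2 <- segment_foci(img2, mask, min_area_px = 5)
  expect_equal(seg2$n_foci, 0)
  expect_error(segment_foci(img, matrix(FALSE, 80, 80)), "empty")
})

test_that("shape factor oracles: disc near 1, square near pi/4", {
  for (r in c(10, 15, 25)) {
    sf <- shape_factor(make_disc(r))
    expect_gte(sf, 0.98)
    expect_lte(sf, 1.06)
  }
  expect_lt(abs(shape_factor(make_square(80)) - pi / 4), 0.02)
  # degenerate region is flagged, not silently scored
  m <- matrix(0, 10, 10); m[5, 5] <- 1
  expect_warning(sf <- shape_factor(m), "degenerate")
  expect_true(is.na(sf))
})

test_that("shape factor is invariant under translation and 90-degree rotation", {
  m <- matrix(0, 60, 60)
  m[20:35, 15:40] <- 1
  m[10:19, 22:30] <- 1   # an L-ish compound region
  sf <- shape_factor(m)
  shifted <- matrix(0, 60, 60)
  shifted[25:40, 18:43] <- 1
  shifted[15:24, 25:33] <- 1
  expect_equal(shape_factor(shifted), sf, tolerance = 1e-9)
  expect_equal(shape_factor(t(m)[ncol(m):1, ]), sf, tolerance = 1e-9)
  expect_lte(sf, 1.06)
})

test_that("intensity CV matches closed forms and scaling invariance", {
  mask <- matrix(TRUE, 10, 10)
  expect_equal(intensity_cv(matrix(7, 10, 10), mask)$cv, 0)
  # half 0, half 2m: mean m, SD m, cv 1
  img <- matrix(c(rep(0, 50), rep(12, 50)), 10, 10)
  expect_equal(intensity_cv(img, mask)$cv, 1)
  # multiplicative rescaling leaves cv unchanged
  img2 <- generate_nucleus_images(image_gen_params(n_images = 1, seed = 2))[[1]]
  cv1 <- intensity_cv(img2$image, img2$mask)$cv
  cv2 <- intensity_cv(img2$image * 3.7, img2$mask)$cv
  expect_equal(cv1, cv2, tolerance = 1e-12)
  expect_error(intensity_cv(matrix(0, 10, 10), mask), "mean")
})

test_that("cv decreases monotonically along the dispersal series", {
  im <- generate_nucleus_images(image_gen_params(n_images = 1, noise_sd = 0,
                                                 seed = 7))[[1]]
  series <- disperse_signal(im$image, c(0, 1, 2, 4, 8, 16))
  cvs <- vapply(series, function(s) intensity_cv(s, im$mask)$cv, 0)
  expect_true(all(diff(cvs) < 0))
  # focal vs uniformly spread signal with the same mask total
  uni <- im$image; uni[im$mask] <- mean(im$image[im$mask])
  expect_gt(cvs[1], intensity_cv(uni, im$mask)$cv)
})

test_that("treatment comparison separates dispersed from focal groups", {
  imgs <- generate_nucleus_images(image_gen_params(n_images = 12, seed = 20))
  cv_ctrl <- vapply(imgs[1:6], function(im)
    intensity_cv(im$image, im$mask)$cv, 0)
  cv_form <- vapply(imgs[7:12], function(im)
    intensity_cv(disperse_signal(im$image, 8)[[1]], im$mask)$cv, 0)
  expect_warning(cmp <- treatment_comparison(
    list(control = cv_ctrl, formamide = cv_form),
    min_cells_per_group = 200, n_boot = 500, seed = 1),
    "below 200")
  expect_true(all(cmp$groups$undersized))
  d <- cmp$differences
  expect_gt(d$diff_mean_cv, 0)          # control cv exceeds treated cv
  expect_gt(d$ci_lo, 0)                 # and the bootstrap CI excludes 0
  # identical groups: difference straddles zero
  cmp2 <- suppressWarnings(treatment_comparison(
    list(a = cv_ctrl, b = cv_ctrl), min_cells_per_group = 3,
    n_boot = 200, seed = 2))
  expect_equal(cmp2$differences$diff_mean_cv, 0)
})

test_that("measured foci recover the analytic ground truth", {
  imgs <- generate_nucleus_images(image_gen_params(n_images = 6, seed = 30))
  stats <- lapply(imgs, function(im) {
    seg <- segment_foci(im$image, im$mask)
    measure_foci(seg, im$image)
  })
  meas <- do.call(rbind, stats)
  truth <- do.call(rbind, lapply(imgs, `[[`, "truth"))
  expect_equal(nrow(meas), nrow(truth))      # every focus found, none split
  expect_lt(abs(mean(meas$shape_factor) - mean(truth$shape_factor)), 0.04)
  expect_lt(abs(mean(meas$area_px) / mean(truth$area_px) - 1), 0.12)
})
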