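test_that("background-only and circular-focus cases are exact", {
  p0 <- image_gen_params(n_foci = 0, noise_sd = 0, n_images = 1, seed = 1)
  im <- generate_nucleus_images(p0)[[1]]
  expect_true(all(im$image == 500))
  expect_equal(nrow(im$truth), 0)

  pc <- image_gen_params(n_foci = 1, focus_aspect_log_sd = 0, noise_sd = 0,
                         n_images = 1, seed = 2)
  im <- generate_nucleus_images(pc)[[1]]
  expect_equal(im$truth$shape_factor, 1, tolerance = 1e-12)
  expect_equal(im$truth$a, im$truth$b)
})

test_that("ground-truth mean shape factor matches the aspect calibration", {
  # many foci across images; analytic truth, no segmentation involved
  p <- image_gen_params(n_images = 40, seed = 3)
  truth <- do.call(rbind, lapply(generate_nucleus_images(p), `[[`, "truth"))
  expect_gt(nrow(truth), 400)
  expect_lt(abs(mean(truth$shape_factor) - 0.93),
            3 * sd(truth$shape_factor) / sqrt(nrow(truth)) + 0.005)
})

test_that("foci lie inside the mask and generation is seed-reproducible", {
  p <- image_gen_params(n_images = 2, seed = 9)
  imgs <- generate_nucleus_images(p)
  for (im in imgs) {
    lab <- im$image > 1000   # foci pixels (no-noise threshold is generous)
    expect_true(all(im$mask[lab]))
  }
  expect_identical(generate_nucleus_images(p), generate_nucleus_images(p))
})

test_that("impossible placements are rejected with a diagnostic", {
  p <- image_gen_params(image_size_px = 32, n_foci = 40, focus_radius_px = 6,
                        n_images = 1, seed = 1)
  expect_error(generate_nucleus_images(p), "could not place focus")
})

test_that("dispersal preserves integrated signal while flattening it", {
  im <- generate_nucleus_images(image_gen_params(n_images = 1, noise_sd = 0,
                                                 seed = 5))[[1]]
  series <- disperse_signal(im$image, c(0, 3, 6))
  tot <- vapply(series, sum, 0)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 0.02)
  expect_gt(max(series[[1]]), max(series[[3]]))
})
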