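test_that("per-cell thresholds follow mean + k_sd * SD of filament pixels", {
  # zero variance: threshold equals the common intensity
  filt <- matrix(0, 30, 30)
  skel <- matrix(FALSE, 30, 30)
  skel[10, 5:25] <- TRUE
  filt[skel] <- 100
  tm <- calibrate_thresholds(fake_processed(filt, skel), grid = c(1, 1))
  expect_equal(tm$thresholds[1, 1], 100)

  # sampled normal intensities: mean + 1.8 sd
  set.seed(21)
  filt2 <- matrix(0, 120, 120)
  skel2 <- matrix(FALSE, 120, 120)
  skel2[sample.int(120 * 120, 1e4)] <- TRUE
  vals <- rnorm(sum(skel2), 50, 10)
  filt2[skel2] <- vals
  tm2 <- calibrate_thresholds(fake_processed(filt2, skel2), grid = c(1, 1))
  expect_equal(tm2$thresholds[1, 1], mean(vals) + 1.8 * sd(vals))
  expect_equal(tm2$thresholds[1, 1], 68, tolerance = 0.02)
  expect_equal(tm2$k_sd, 1.8)
})

test_that("sparse grid cells inherit the whole-image threshold", {
  filt <- matrix(0, 60, 60)
  skel <- matrix(FALSE, 60, 60)
  skel[10, 5:55] <- TRUE            # all filament pixels in the top band
  filt[skel] <- rep(c(90, 100, 110), length.out = sum(skel))
  tm <- calibrate_thresholds(fake_processed(filt, skel), grid = c(3, 3))
  vals <- filt[skel]
  global <- mean(vals) + 1.8 * sd(vals)
  expect_equal(tm$thresholds[3, 1], global)   # empty bottom cell
  expect_equal(tm$thresholds[2, 2], global)
  expect_error(calibrate_thresholds(
    fake_processed(matrix(0, 20, 20), matrix(FALSE, 20, 20))),
    "no filament pixels")
})

test_that("classification weighs the bundled fraction by intensity", {
  filt <- matrix(0, 40, 40)
  skel <- matrix(FALSE, 40, 40)
  skel[10, 1:10] <- TRUE; skel[30, 1:10] <- TRUE
  filt[10, 1:10] <- 50    # 0.5x threshold
  filt[30, 1:10] <- 300   # 3x threshold
  tm <- structure(list(n_rows = 1L, n_cols = 1L,
                       thresholds = matrix(100, 1, 1), k_sd = 1.8,
                       frame_index = 0L), class = "grid_threshold_map")
  res <- classify_frame(fake_processed(filt, skel), tm)
  expect_equal(res$fraction_bundled, 3 / 3.5, tolerance = 1e-12)
  expect_equal(res$n_bundled_pixels, 10L)
  expect_false(any(res$bundled_mask & res$single_mask))
  expect_equal(res$bundled_mask | res$single_mask, skel)

  # all pixels far above threshold
  filt[skel] <- 300
  expect_equal(classify_frame(fake_processed(filt, skel), tm)$fraction_bundled, 1)

  # empty mask
  expect_warning(
    r0 <- classify_frame(fake_processed(matrix(0, 40, 40),
                                        matrix(FALSE, 40, 40)), tm),
    "empty")
  expect_equal(r0$fraction_bundled, 0)
})

test_that("raising a cell threshold never increases the bundled fraction", {
  set.seed(22)
  for (i in 1:5) {
    filt <- matrix(0, 30, 30)
    skel <- matrix(runif(900) < 0.2, 30, 30)
    filt[skel] <- runif(sum(skel), 0, 200)
    base <- matrix(runif(9, 50, 150), 3, 3)
    tm <- structure(list(n_rows = 3L, n_cols = 3L, thresholds = base,
                         k_sd = 1.8, frame_index = 0L),
                    class = "grid_threshold_map")
    f0 <- classify_frame(fake_processed(filt, skel), tm)$fraction_bundled
    cell <- sample.int(9, 1)
    tm$thresholds[cell] <- tm$thresholds[cell] * 1.5
    f1 <- classify_frame(fake_processed(filt, skel), tm)$fraction_bundled
    expect_lte(f1, f0)
    expect_gte(f0, 0); expect_lte(f0, 1)
  }
})

test_that("bleach model fits recover the generating parameters", {
  t <- seq(0, 300, 10)
  fe <- fit_bleach_model(t, 200 * exp(-0.01 * t))
  expect_equal(fe$model_type, "exponential")
  expect_equal(fe$params[["decay_rate"]], 0.01, tolerance = 0.1)
  expect_equal(fe$correction(0), 1)

  fl <- fit_bleach_model(t, 200 - 0.2 * t)
  expect_equal(fl$model_type, "linear")
  expect_equal(fl$params[["slope"]], -0.2, tolerance = 0.05)

  fc <- fit_bleach_model(t, rep(150, length(t)))
  expect_equal(fc$model_type, "constant")
  expect_equal(fc$correction(c(0, 100, 250)), c(1, 1, 1))
})

test_that("the 1.8-SD two-sided normal coverage matches the error function", {
  skip_if_not_installed("pracma")
  expect_equal(normal_coverage(1.8), pracma::erf(1.8 / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(round(100 * normal_coverage(1.8)), 93)
})

test_that("stack-level bleach calibration tracks a known decay", {
  spec <- scene_spec(image_shape = c(192L, 192L), n_filaments = 8L,
                     length_distribution = list(type = "exponential", mean_um = 4),
                     curvature_px = 2, noise_sd = 2, bleach_rate = 0.002,
                     frame_interval_s = 10, n_frames = 20L, rng_seed = 4)
  sc <- render_scene(spec)
  fit <- calibrate_bleaching(sc$stack, n_sample = 10L)
  t_end <- sc$stack$frames[[20]]$time_s
  expect_equal(fit$correction(t_end), exp(-0.002 * t_end), tolerance = 0.1)
  # constant-intensity series yields a constant correction
  spec0 <- scene_spec(image_shape = c(160L, 160L), n_filaments = 5L,
                      length_distribution = list(type = "fixed", length_um = 4),
                      noise_sd = 0, bleach_rate = 0, frame_interval_s = 10,
                      n_frames = 4L, rng_seed = 2)
  sc0 <- render_scene(spec0)
  fit0 <- calibrate_bleaching(sc0$stack, n_sample = 4L)
  expect_equal(fit0$correction(30), 1, tolerance = 1e-6)
})

test_that("run_kinetics reports a flat curve on a stationary series", {
  spec <- scene_spec(image_shape = c(160L, 160L), n_filaments = 5L,
                     length_distribution = list(type = "fixed", length_um = 4),
                     noise_sd = 0, bleach_rate = 0, frame_interval_s = 10,
                     n_frames = 4L, rng_seed = 2)
  sc <- render_scene(spec)
  kin <- run_kinetics(sc$stack, bleach_model = "none")
  expect_equal(diff(range(kin$results$fraction_bundled)), 0, tolerance = 1e-9)
  expect_lt(max(kin$results$fraction_bundled), 0.1)
  # report interval thins the summary table
  kin2 <- run_kinetics(sc$stack, bleach_model = "none", report_interval_s = 20)
  expect_equal(kin2$results$time_s, c(0, 20))
})

test_that("single-frame stacks fall back to a constant correction", {
  spec <- scene_spec(image_shape = c(160L, 160L), n_filaments = 5L,
                     length_distribution = list(type = "fixed", length_um = 4),
                     noise_sd = 0, n_frames = 1L, rng_seed = 2)
  sc <- render_scene(spec)
  expect_warning(kin <- run_kinetics(sc$stack), "constant correction")
  expect_equal(kin$bleach$model_type, "constant")
})
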