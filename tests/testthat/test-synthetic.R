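test_that("fixed seeds reproduce scenes bit-exactly", {
  sp <- scene_spec(image_shape = c(96L, 96L), n_filaments = 4L, rng_seed = 9,
                   length_distribution = list(type = "exponential", mean_um = 3),
                   n_frames = 2L)
  a <- render_scene(sp)
  b <- render_scene(sp)
  expect_identical(a$stack$frames[[1]]$pixels, b$stack$frames[[1]]$pixels)
  expect_identical(a$stack$frames[[2]]$pixels, b$stack$frames[[2]]$pixels)
  expect_identical(a$truth$lengths_um, b$truth$lengths_um)
  # a different seed gives a different scene
  sp2 <- scene_spec(image_shape = c(96L, 96L), n_filaments = 4L, rng_seed = 10,
                    length_distribution = list(type = "exponential", mean_um = 3),
                    n_frames = 2L)
  expect_false(identical(render_scene(sp2)$stack$frames[[1]]$pixels,
                         a$stack$frames[[1]]$pixels))
})

test_that("straight filaments rasterize with exact pixel counts", {
  sp <- scene_spec(image_shape = c(96L, 96L), n_filaments = 1L,
                   length_distribution = list(type = "fixed", length_um = 5),
                   curvature_px = 0, orientation_deg = 0,
                   psf_sigma_px = 0, noise_sd = 0, rng_seed = 1)
  sc <- render_scene(sp)
  expect_equal(nrow(sc$truth$paths[[1]]), 51L)
  expect_equal(sum(sc$stack$frames[[1]]$pixels > 0), 51L)
  expect_equal(sc$truth$lengths_um[1], 5)
})

test_that("exponential length sampling matches its target mean", {
  sp <- scene_spec(image_shape = c(512L, 512L), n_filaments = 50L,
                   length_distribution = list(type = "exponential", mean_um = 7),
                   psf_sigma_px = 0, noise_sd = 0, rng_seed = 17)
  sc <- render_scene(sp)
  m <- mean(sc$truth$lengths_um)
  se <- sd(sc$truth$lengths_um) / sqrt(50)
  expect_lt(abs(m - 7), 2 * se + 0.2)  # digitization adds ~0.1 um jitter
})

test_that("scene validation rejects impossible geometry and events", {
  expect_error(render_scene(
    scene_spec(image_shape = c(64L, 64L), n_filaments = 1L,
               length_distribution = list(type = "fixed", length_um = 50),
               rng_seed = 1)),
    "longer than the usable image diagonal")
  expect_error(scene_spec(bundle_events = list(
    list(time_s = -5, filament_ids = 1L, multiplier = 2))),
    "before t = 0")
  expect_error(make_bundling_series(
    scene_spec(n_frames = 3L, bundle_events = list(
      list(time_s = 0, filament_ids = 1L, multiplier = 2)))),
    "precede")
})

test_that("crossing fixtures produce the expected error topology", {
  fx <- make_crossing_fixture(c(0, 90), c(8, 8))
  proc <- preprocess(fx$image)
  objs <- label_objects(proc$skeleton)
  errs <- Filter(function(o) o$is_error, objs)
  expect_length(errs, 1L)
  expect_equal(nrow(errs[[1]]$endpoints), 4L)

  fx3 <- make_crossing_fixture(c(0, 60, 120), c(8, 8, 8))
  objs3 <- label_objects(preprocess(fx3$image)$skeleton)
  errs3 <- Filter(function(o) o$is_error, objs3)
  expect_gte(sum(vapply(errs3, function(o) nrow(o$branch_points), integer(1))),
             2L)

  single <- render_scene(scene_spec(image_shape = c(160L, 160L),
                                    n_filaments = 1L, rng_seed = 3,
                                    length_distribution = list(type = "fixed",
                                                               length_um = 5)))
  objs1 <- label_objects(preprocess(single$stack$frames[[1]])$skeleton)
  expect_false(any(vapply(objs1, `[[`, logical(1), "is_error")))

  expect_error(make_crossing_fixture(c(10), 5), "at least 2")
  expect_error(make_crossing_fixture(c(10, 190), c(5, 5)), "parallel")
})

test_that("bundling-series ground truth follows the event schedule", {
  base <- scene_spec(image_shape = c(128L, 128L), n_filaments = 4L,
                     length_distribution = list(type = "fixed", length_um = 3),
                     curvature_px = 0, psf_sigma_px = 1, noise_sd = 0,
                     frame_interval_s = 10, n_frames = 15L, rng_seed = 6)
  # no events: identically zero
  null_tr <- make_bundling_series(base)$truth$fraction_curve
  expect_equal(null_tr, rep(0, 15))

  # all filaments doubled at t = 100 s: step 0 -> 1
  all2 <- base; all2$bundle_events <- list(
    list(time_s = 100, filament_ids = 1:4, multiplier = 2))
  tr <- make_bundling_series(all2)$truth$fraction_curve
  expect_equal(tr[1:10], rep(0, 10))
  expect_equal(tr[11:15], rep(1, 5))

  # half the polymer doubled: plateau at the intensity-weighted fraction
  half <- base; half$bundle_events <- list(
    list(time_s = 50, filament_ids = 1:2, multiplier = 2))
  res <- make_bundling_series(half)
  wb <- sum(vapply(res$truth$paths[1:2], function(p)
    filametrics:::measure_path_px(p) + 1, numeric(1)))
  ws <- sum(vapply(res$truth$paths[3:4], function(p)
    filametrics:::measure_path_px(p) + 1, numeric(1)))
  expect_equal(res$truth$fraction_curve[15], 2 * wb / (2 * wb + ws),
               tolerance = 1e-9)
})
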