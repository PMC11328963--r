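small_scene <- function(seed, n_blobs = 2) {
  scene_spec(width = 96, height = 96, n_blobs = n_blobs,
             semi_axis_range = c(7, 13), seed = seed)
}

test_that("scene generation is deterministic and respects its contract", {
  empty <- generate_scene(small_scene(1, n_blobs = 0))
  expect_equal(mask_area(empty$truth), 0)

  a <- generate_scene(small_scene(5))
  b <- generate_scene(small_scene(5))
  expect_identical(unclass(a$truth), unclass(b$truth))
  expect_identical(a$image, b$image)
  expect_identical(a$blobs, b$blobs)

  # blobs never touch the border and stay separate regions
  for (s in 1:10) {
    sc <- generate_scene(small_scene(s))
    t_m <- unclass(sc$truth)
    expect_false(any(t_m[1, ]) || any(t_m[96, ]) || any(t_m[, 1]) || any(t_m[, 96]))
    expect_equal(n_regions(label_components(sc$truth, 8)), 2)
  }

  expect_error(generate_scene(scene_spec(width = 40, height = 40, n_blobs = 50,
                                         semi_axis_range = c(8, 10), seed = 1)),
               "infeasible packing")
})

test_that("a single-lobe elliptical blob ties to the region measurements", {
  spec <- scene_spec(width = 220, height = 220, n_blobs = 1,
                     semi_axis_range = c(40, 40), axis_ratio_range = c(0.5, 0.5),
                     lobes_range = c(1, 1), rotation_range = c(0, 0), seed = 9)
  sc <- generate_scene(spec)
  props <- measure_regions(sc$truth)
  expect_equal(nrow(props), 1)
  expect_lt(abs(props$eccentricity - sqrt(1 - 0.5^2)), 0.02)
  expect_lt(abs(props$area_px - pi * 40 * 20) / (pi * 40 * 20), 0.02)
})

test_that("corruption bookkeeping always equals recomputed confusion", {
  sc <- generate_scene(small_scene(3))
  zero <- corrupt_prediction(sc$truth, corruption_spec(seed = 1))
  expect_true(mask_content_equal(zero$pred, sc$truth))
  expect_equal(zero$confusion$fp + zero$confusion$fn, 0)

  withr::with_seed(59, {
    for (k in 1:100) {
      sc <- generate_scene(small_scene(k))
      spec <- corruption_spec(boundary_radius = sample(-2:2, 1),
                              speckle_fp_count = sample(0:5, 1),
                              miss_probability = stats::runif(1, 0, 0.5),
                              seed = k + 1000)
      out <- corrupt_prediction(sc$truth, spec)
      expect_identical(out$confusion, confusion(out$pred, sc$truth))
    }
  })
})

test_that("erosion of a disk removes close to the analytic ring", {
  truth <- disk_mask(40)
  out <- corrupt_prediction(truth, corruption_spec(boundary_radius = -2, seed = 1))
  ring <- pi * (40^2 - 38^2)
  expect_equal(out$confusion$fp, 0)
  expect_lt(abs(out$confusion$fn - ring) / ring, 0.10)
})

test_that("miss_probability at 1 removes every blob", {
  sc <- generate_scene(small_scene(12, n_blobs = 3))
  out <- corrupt_prediction(sc$truth, corruption_spec(miss_probability = 1, seed = 2))
  expect_equal(mask_area(out$pred), 0)
  expect_equal(out$confusion$fn, mask_area(sc$truth))
})

test_that("annotation completeness: endpoints exact, middle binomial", {
  sc <- generate_scene(small_scene(21))
  out <- corrupt_prediction(sc$truth,
                            corruption_spec(boundary_radius = 2,
                                            speckle_fp_count = 3, seed = 3))
  none <- derive_annotation(out$pred, sc$truth, completeness = 0, seed = 1)
  expect_equal(sum(none$green) + sum(none$red), 0)

  full <- derive_annotation(out$pred, sc$truth, completeness = 1, seed = 1)
  expect_true(mask_content_equal(apply_correction(out$pred, full), sc$truth))

  fp_total <- sum(unclass(out$pred) & !unclass(sc$truth))
  fracs <- vapply(1:100, function(s) {
    ann <- derive_annotation(out$pred, sc$truth, completeness = 0.5, seed = s)
    sum(ann$green) / fp_total
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.05)
})

test_that("training sequences decay as specified", {
  # tau -> infinity: corruption constant, rolling dice flat (same seeds
  # per frame would still vary scenes; check the corruption magnitudes directly)
  ts_inf <- trajectory_spec(n_images = 30, scene = small_scene(1), tau = 1e9, seed = 7)
  ts_zero <- trajectory_spec(n_images = 15, scene = small_scene(1),
                             initial = corruption_spec(), tau = 8, seed = 7)
  seq0 <- generate_training_sequence(ts_zero)
  log0 <- evaluate_sequence(seq0)
  expect_true(all(log0$dice == 1))
  expect_equal(stopping_index(log0, stopping_rule(10, 0.95)), 9L)

  seq_inf <- generate_training_sequence(ts_inf)
  expect_equal(nrow(seq_inf), 30)
  # same master seed twice -> bit-identical sequence
  seq_inf2 <- generate_training_sequence(ts_inf)
  expect_identical(seq_inf$tp, seq_inf2$tp)
  expect_true(all(purrr::map2_lgl(seq_inf$pred, seq_inf2$pred, mask_content_equal)))

  # with decay, late-sequence error mass is far below early-sequence
  ts <- trajectory_spec(n_images = 40, scene = small_scene(1), tau = 6, seed = 13)
  sq <- generate_training_sequence(ts)
  err <- sq$fp + sq$fn
  expect_lt(mean(err[31:40]), mean(err[1:10]) / 4)
})

test_that("trajectory bookkeeping matches corrective metrics at completeness 1", {
  ts <- trajectory_spec(n_images = 20, scene = small_scene(2), tau = 5,
                        completeness = 1, seed = 23)
  sq <- generate_training_sequence(ts)
  log <- evaluate_sequence(sq)
  for (i in seq_len(nrow(sq))) {
    cc <- sq[i, c("tp", "fp", "fn", "tn")]
    expect_equal(log$dice[i], dice(cc))
    expect_equal(log$precision[i], precision(cc))
  }
})

test_that("laser frames meet their geometric contract", {
  lf <- generate_laser_frame(50, seed = 3)
  cal <- calibrate_from_lasers(lf)
  expect_lt(abs(cal$px_per_cm - 50) / 50, 0.01)
  centers <- attr(lf, "centers")
  expect_equal(laser_distance(c(centers$x[1], centers$y[1]),
                              c(centers$x[2], centers$y[2])), 250)

  tiny <- generate_laser_frame(10, dot_radius = 1, seed = 5)
  cal_tiny <- calibrate_from_lasers(tiny, min_region_px = 1)
  expect_equal(cal_tiny$status, "ok")

  expect_error(generate_laser_frame(500, width = 100, height = 60, seed = 1),
               "infeasible geometry")
})

test_that("simulate_dataset writes the directory convention and manifest", {
  dir <- withr::local_tempdir()
  ts <- trajectory_spec(n_images = 4, scene = small_scene(3), tau = 4, seed = 31)
  manifest <- simulate_dataset(dir, ts, laser_px_per_cm = 25)
  for (s in c("images", "truths", "predictions", "annotations", "lasers"))
    expect_length(list.files(file.path(dir, s), pattern = "\\.png$"), 4)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 4)

  # written masks decode to the in-memory sequence
  sq <- generate_training_sequence(ts)
  back <- read_mask(file.path(dir, "predictions", "img_0002.png"))
  expect_true(mask_content_equal(back, sq$pred[[3]]))
  ann_back <- read_annotation(file.path(dir, "annotations", "img_0001.png"))
  expect_identical(ann_back$green, sq$ann[[2]]$green)
})
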