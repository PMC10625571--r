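test_that("segment_length_px does plane geometry", {
  expect_equal(segment_length_px(pixel_segment(0, 0, 3, 4, "width_right")), 5)
  expect_equal(segment_length_px(pixel_segment(7, 7, 7, 7, "columella")), 0)
  expect_equal(segment_length_px(pixel_segment(10.5, 2, 10.5, 14, "height_left")), 12)
})

test_that("measure_annotations maps roles at the calibrated scale", {
  ann <- annotation_set(list(
    pixel_segment(0, 0, 100, 0, "calibrator"),     # 100 px -> 0.05 mm/px at 5 mm
    pixel_segment(0, 10, 172, 10, "width_right")   # 172 px -> 8.6 mm
  ))
  m <- measure_annotations(ann, spec = marker_spec(5))
  v <- measurement_values(m)
  expect_equal(v[["width_right_mm"]], 8.6)
  expect_true(is.na(v[["width_left_mm"]]))
  expect_true(is.na(v[["height_right_mm"]]))

  # unilateral: only left-side segments present -> right side absent
  left_only <- annotation_set(list(
    pixel_segment(0, 0, 100, 0, "calibrator"),
    pixel_segment(0, 0, 140, 0, "width_left"),
    pixel_segment(0, 0, 0, 196, "height_left")
  ))
  lv <- measurement_values(measure_annotations(left_only, spec = marker_spec(5)))
  expect_equal(lv[["width_left_mm"]], 7)
  expect_equal(lv[["height_left_mm"]], 9.8)
  expect_true(all(is.na(lv[c("width_right_mm", "height_right_mm", "columella_mm")])))
})

test_that("measurement guards: missing calibrator, implausible values", {
  no_cal <- annotation_set(list(pixel_segment(0, 0, 50, 0, "width_right")))
  expect_error(measure_annotations(no_cal), class = "nariform_missing_calibrator")

  # a 10 px calibrator on a 5 mm marker makes everything 0.5 mm/px: 172 px
  # would be 86 mm, far beyond any nare
  huge <- annotation_set(list(
    pixel_segment(0, 0, 10, 0, "calibrator"),
    pixel_segment(0, 0, 172, 0, "width_right")
  ))
  expect_error(measure_annotations(huge), class = "nariform_implausible_value")
  expect_error(annotation_set(list(
    pixel_segment(0, 0, 1, 0, "columella"),
    pixel_segment(0, 0, 2, 0, "columella")
  )), class = "nariform_invalid_params")
})

test_that("average_replicates means per role and enforces the protocol", {
  reps <- lapply(c(8.5, 8.6, 8.7), function(w)
    nostril_measurements(width_right_mm = w, height_right_mm = 12))
  avg <- average_replicates(reps)
  expect_equal(measurement_values(avg)[["width_right_mm"]], 8.6)
  expect_equal(measurement_values(avg)[["height_right_mm"]], 12)

  same <- replicate(3, nostril_measurements(width_left_mm = 7.1), simplify = FALSE)
  expect_equal(measurement_values(average_replicates(same))[["width_left_mm"]], 7.1)

  expect_error(average_replicates(reps[1:2]), class = "nariform_replicate_count_mismatch")
  expect_equal(measurement_values(average_replicates(reps[1:2], n_required = 2))[["width_right_mm"]],
               8.55)

  mixed <- list(nostril_measurements(width_right_mm = 8.5, height_right_mm = 12),
                nostril_measurements(width_right_mm = 8.6),
                nostril_measurements(width_right_mm = 8.7, height_right_mm = 12))
  expect_error(average_replicates(mixed), class = "nariform_role_mismatch")
})

test_that("measurements scale linearly and are rigid-motion invariant", {
  set.seed(23)
  segs <- list(
    pixel_segment(10, 10, 110, 35, "calibrator"),
    pixel_segment(50, 80, 120, 130, "width_right"),
    pixel_segment(200, 80, 260, 150, "width_left"),
    pixel_segment(60, 60, 80, 170, "height_right"),
    pixel_segment(220, 60, 230, 175, "height_left"),
    pixel_segment(140, 110, 190, 112, "columella")
  )
  ann <- annotation_set(segs)
  sc1 <- structure(list(mm_per_px = 0.06, source = "from_segment"), class = "scale_factor")
  sc2 <- structure(list(mm_per_px = 0.12, source = "from_segment"), class = "scale_factor")
  v1 <- measurement_values(measure_annotations(ann, sc1))
  v2 <- measurement_values(measure_annotations(ann, sc2))
  expect_equal(v2, 2 * v1)

  for (i in 1:10) {
    th <- runif(1, 0, 2 * pi); tx <- runif(1, -50, 50); ty <- runif(1, -50, 50)
    moved <- annotation_set(lapply(segs, transform_segment,
                                   theta = th, ox = 100, oy = 100, tx = tx, ty = ty))
    expect_equal(measurement_values(measure_annotations(moved, sc1)), v1,
                 tolerance = 1e-9)
  }
})

test_that("annotation JSON round-trips segments and marker size", {
  ann <- annotation_set(list(
    pixel_segment(1.25, 2.5, 101.25, 2.5, "calibrator"),
    pixel_segment(10, 20, 80.5, 21.5, "width_right")
  ), image_id = "img-007")
  p <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, p, marker_mm = 5)
  back <- read_annotations(p)
  expect_equal(back$marker_mm, 5)
  expect_equal(back$annotations$image_id, "img-007")
  expect_equal(back$annotations$segments$calibrator$p2, ann$segments$calibrator$p2)
  expect_equal(measurement_values(measure_annotations(back$annotations, spec = marker_spec(5))),
               measurement_values(measure_annotations(ann, spec = marker_spec(5))))
})
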