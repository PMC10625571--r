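bbox_wh <- function(mesh, side) {
  bb <- nariform:::mesh_bbox(mesh, attr(mesh, "parts")[[side]]$vidx)
  c(width = unname(bb[2, 1] - bb[1, 1]), height = unname(bb[2, 2] - bb[1, 2]),
    depth = unname(bb[2, 3] - bb[1, 3]))
}

test_that("default template matches its construction contract", {
  tm <- build_template()
  expect_equal(bbox_wh(tm, "left"), c(width = 8.6, height = 12.5, depth = 12),
               tolerance = 1e-6)
  expect_equal(bbox_wh(tm, "right"), c(width = 8.6, height = 12.5, depth = 12),
               tolerance = 1e-6)
  expect_equal(retainer_gap_mm(tm), 6.8, tolerance = 1e-6)
  val <- validate_mesh(tm)
  expect_true(val$ok)
  expect_equal(val$n_components, 3L)  # two crura + bridge, each closed
})

test_that("outer bounding box is pinned regardless of angular resolution", {
  lo <- build_template(template_params(segments = 8))
  hi <- build_template(template_params(segments = 96))
  expect_equal(bbox_wh(lo, "left"), bbox_wh(hi, "left"), tolerance = 1e-6)
  expect_equal(bbox_wh(lo, "right"), bbox_wh(hi, "right"), tolerance = 1e-6)
  expect_true(validate_mesh(lo)$ok)
  expect_true(validate_mesh(hi)$ok)
})

test_that("template parameter validation rejects impossible geometry", {
  expect_error(template_params(wall_mm = 4.3), class = "nariform_invalid_params")
  expect_error(template_params(wall_mm = 5), class = "nariform_invalid_params")
  expect_error(template_params(segments = 10), class = "nariform_invalid_params")
  expect_error(template_params(nominal_width_mm = -1), class = "nariform_invalid_params")
})

test_that("plan_reshape computes per-side factors and handles absence", {
  params <- template_params()
  nominal <- nostril_measurements(height_right_mm = 12.5, height_left_mm = 12.5,
                                  width_right_mm = 8.6, width_left_mm = 8.6,
                                  columella_mm = 6.8)
  id <- plan_reshape(nominal, params)
  expect_identical(c(id$fx_left, id$fy_left, id$fx_right, id$fy_right), rep(1, 4))

  m <- nostril_measurements(width_right_mm = 6.45)
  p <- plan_reshape(m, params)
  expect_equal(p$fx_right, 0.75)
  expect_identical(p$fy_right, 1)

  # unilateral: right side absent keeps exact unit factors
  uni <- nostril_measurements(width_left_mm = 7, height_left_mm = 9.8)
  pu <- plan_reshape(uni, params)
  expect_identical(c(pu$fx_right, pu$fy_right), c(1, 1))
  expect_equal(pu$fx_left, 7 / 8.6)
  expect_equal(pu$columella_target_mm, params$nominal_columella_mm)

  # overcorrection is additive in mm before the factor
  oc <- plan_reshape(nostril_measurements(width_right_mm = 6.45),
                     params, overcorrect = list(right = c(2.15, 0)))
  expect_equal(oc$fx_right, 1)
  expect_error(plan_reshape(nostril_measurements(width_right_mm = 1),
                            params, overcorrect = list(right = c(-2, 0))),
               class = "nariform_non_positive_measurement")
})

test_that("identity reshape reproduces the template vertices", {
  params <- template_params()
  tm <- build_template(params)
  id <- plan_reshape(nostril_measurements(
    height_right_mm = 12.5, height_left_mm = 12.5,
    width_right_mm = 8.6, width_left_mm = 8.6, columella_mm = 6.8), params)
  out <- apply_reshape(tm, id)
  expect_lt(max(abs(out$vertices - tm$vertices)), 1e-12)
  expect_identical(out$faces, tm$faces)
})

test_that("one-sided reshape leaves the other crus and z extents alone", {
  tm <- build_template()
  plan <- plan_reshape(nostril_measurements(width_left_mm = 2 * 8.6))
  out <- apply_reshape(tm, plan)
  expect_equal(bbox_wh(out, "left")[["width"]], 17.2, tolerance = 1e-9)
  expect_equal(bbox_wh(out, "left")[["height"]], 12.5, tolerance = 1e-9)
  expect_equal(bbox_wh(out, "right"), bbox_wh(tm, "right"), tolerance = 1e-9)
  expect_equal(bbox_wh(out, "left")[["depth"]], 12, tolerance = 1e-9)
})

test_that("columella target sets the inter-crus gap", {
  tm <- build_template()
  plan <- plan_reshape(nostril_measurements(columella_mm = 5.8))
  out <- apply_reshape(tm, plan)
  expect_equal(retainer_gap_mm(out), 5.8, tolerance = 1e-6)
})

test_that("reshaped crura meet the dimensional contract and stay watertight", {
  set.seed(31)
  tm <- build_template()
  for (i in 1:8) {
    m <- nostril_measurements(
      height_right_mm = runif(1, 7, 14), height_left_mm = runif(1, 7, 14),
      width_right_mm = runif(1, 5, 11), width_left_mm = runif(1, 5, 11),
      columella_mm = runif(1, 4, 8))
    plan <- plan_reshape(m, attr(tm, "params"))
    out <- apply_reshape(tm, plan)
    v <- measurement_values(m)
    expect_equal(bbox_wh(out, "right")[["width"]], v[["width_right_mm"]], tolerance = 1e-6)
    expect_equal(bbox_wh(out, "right")[["height"]], v[["height_right_mm"]], tolerance = 1e-6)
    expect_equal(bbox_wh(out, "left")[["width"]], v[["width_left_mm"]], tolerance = 1e-6)
    expect_equal(bbox_wh(out, "left")[["height"]], v[["height_left_mm"]], tolerance = 1e-6)
    expect_equal(retainer_gap_mm(out), v[["columella_mm"]], tolerance = 1e-6)
    val <- validate_mesh(out)
    expect_true(val$watertight && val$consistently_wound && val$positive_volume)
    expect_equal(val$degenerate_face_count, 0L)
  }
})

test_that("uniform cross-section scaling scales each crus volume by s^2", {
  tm <- build_template()
  base <- validate_mesh(tm)$component_volumes_mm3
  for (s in c(0.6, 1.7)) {
    plan <- plan_reshape(nostril_measurements(
      width_right_mm = s * 8.6, height_right_mm = s * 12.5,
      width_left_mm = s * 8.6, height_left_mm = s * 12.5,
      columella_mm = 6.8, sanity_max_mm = 100), template_params())
    out <- apply_reshape(tm, plan)
    vols <- validate_mesh(out)$component_volumes_mm3
    # the two largest components are the crura (the bridge is unchanged)
    expect_equal(sort(vols, decreasing = TRUE)[1:2],
                 s^2 * sort(base, decreasing = TRUE)[1:2], tolerance = 1e-6)
  }
})

test_that("a symmetric retainer is mirror-symmetric about the mid-sagittal plane", {
  tm <- build_template()
  v <- tm$vertices
  key <- function(mat) sort(apply(round(mat, 9), 1, paste, collapse = "|"))
  mirrored <- v
  mirrored[, 1] <- -mirrored[, 1]
  expect_identical(key(mirrored), key(v))
})
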