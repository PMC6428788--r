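test_that("tube between two squares has 8 vertices and 8 triangles", {
  stack <- circle_stack(n = 64)
  mesh <- build_endo_mesh(stack, points_per_slice = 4)
  expect_equal(nrow(mesh$vertices), 8)
  expect_equal(nrow(mesh$faces), 8)
  expect_true(all(mesh$faces >= 1 & mesh$faces <= 8))
})

test_that("ring resampling preserves the circumference of a circle", {
  stack <- circle_stack(r_endo = 20, n = 1440)
  mesh <- build_endo_mesh(stack, points_per_slice = 360)
  ring <- mesh$vertices[1:360, 1:2]
  expect_equal(cartoplan:::polyline_perimeter(ring), 2 * pi * 20, tolerance = 0.01 / (2 * pi * 20))
})

test_that("open and self-intersecting contours are rejected with the slice named", {
  arc <- circle_pts(15, 720)[1:360, ]  # open half circle
  stack <- structure(list(slices = list(
    list(z = 0, endo = arc, epi = circle_pts(25, 720)),
    list(z = 10, endo = circle_pts(15, 720), epi = circle_pts(25, 720)))),
    class = "contour_stack")
  expect_error(build_endo_mesh(stack), "slice 0.*not closed")

  bow <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 5, -2, 2, 6, 8, 6, 3, -1), ncol = 2)
  expect_error(contour_stack(list(list(z = 0, endo = bow, epi = circle_pts(40, 64)))),
               "self-intersecting")
})

test_that("wall thickness is exact for concentric circles", {
  stack <- circle_stack(r_endo = 20, r_epi = 30)
  mesh <- build_endo_mesh(stack)
  wt <- wall_thickness(stack, mesh)
  expect_equal(wt, rep(10, length(wt)), tolerance = 1e-4)
})

test_that("wall thickness matches brute-force ray casting on an ellipse-in-circle toy", {
  stack <- contour_stack(list(
    list(z = 0, endo = ellipse_pts(16, 12), epi = circle_pts(25)),
    list(z = 10, endo = ellipse_pts(16, 12), epi = circle_pts(25))))
  mesh <- build_endo_mesh(stack, points_per_slice = 60)
  wt <- wall_thickness(stack, mesh)
  set.seed(13)
  for (i in sample(60, 12)) {
    t_brute <- brute_ray_hit(mesh$vertices[i, 1:2], mesh$normals[i, 1:2],
                             stack$slices[[1]]$epi)
    expect_equal(wt[i], t_brute, tolerance = 0.02)
  }
})

test_that("transmurality hits the trivial extremes", {
  ph <- generate_phantom(toy_phantom_spec(n_slices = 3, noise_sd = 0, seed = 14))
  geometry <- ph$volume[c("dim", "spacing", "origin", "orientation")]
  stack <- ph$truth$contours
  mesh <- build_endo_mesh(stack)
  none <- array(FALSE, geometry$dim)
  expect_true(all(transmurality(stack, mesh, none, geometry) == 0))
  all_scar <- ph$truth$myo_mask
  tm <- transmurality(stack, mesh, all_scar, geometry)
  expect_true(all(tm >= 90))  # full chord through scar, minus voxel edge effects
  expect_gt(mean(tm), 97)
  expect_true(all(tm <= 100))
})

test_that("maps are invariant under in-plane rigid motion", {
  ph <- generate_phantom(toy_phantom_spec(n_slices = 3, noise_sd = 0, seed = 15))
  geometry <- ph$volume[c("dim", "spacing", "origin", "orientation")]
  seg <- fwhm_segment(ph$volume$data, ph$truth$myo_mask)
  map0 <- endo_surface_map(ph$truth$contours, seg, geometry)

  ang <- 36  # multiple of the 3-degree vertex spacing: vertices correspond by index shift
  R <- rotation_about_z(ang); tr <- c(12, -7, 4)
  stack2 <- contour_stack(lapply(ph$truth$contours$slices, function(s) list(
    z = s$z + tr[3],
    endo = t(R[1:2, 1:2] %*% t(s$endo)) + rep(tr[1:2], each = nrow(s$endo)),
    epi = t(R[1:2, 1:2] %*% t(s$epi)) + rep(tr[1:2], each = nrow(s$epi)))))
  geometry2 <- geometry
  geometry2$orientation <- R %*% geometry$orientation
  geometry2$origin <- as.numeric(R %*% geometry$origin) + tr
  map2 <- endo_surface_map(stack2, seg, geometry2)

  shift <- ang / 3
  N <- map0$points_per_slice
  for (sl in 0:2) {
    i0 <- which(map0$slice_index == sl)
    i2 <- which(map2$slice_index == sl)
    # vertex at angle a in map0 corresponds to angle a + 36 in map2
    reord <- ((seq_len(N) - 1 - shift) %% N) + 1
    expect_equal(map2$wall_thickness[i2], map0$wall_thickness[i0][reord], tolerance = 1e-6)
    expect_equal(map2$transmurality[i2], map0$transmurality[i0][reord], tolerance = 1e-6)
  }
})

test_that("populated maps have no missing scalars and bounded transmurality", {
  ph <- generate_phantom(phantom_spec(seed = 16, n_slices = 4))
  geometry <- ph$volume[c("dim", "spacing", "origin", "orientation")]
  seg <- fwhm_segment(ph$volume$data, ph$truth$myo_mask)
  map <- endo_surface_map(ph$truth$contours, seg, geometry)
  expect_false(anyNA(map$transmurality))
  expect_false(anyNA(map$wall_thickness))
  expect_true(all(map$transmurality >= 0 & map$transmurality <= 100))
  expect_true(all(map$wall_thickness > 0))
})
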