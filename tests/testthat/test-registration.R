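asym_cloud <- function(n = 600) {
  # anisotropic, non-symmetric blob: distinct principal axes
  set.seed(30)
  cbind(rnorm(n, sd = 9), rnorm(n, sd = 4), rnorm(n, sd = 1.5)) +
    outer(rnorm(n)^2, c(0.4, 0.1, 0))
}

test_that("rigid transforms compose, invert and preserve distances", {
  tf <- rigid_transform(rotation_about_z(25) %*% rotation_about_x(10), c(3, -8, 5))
  pts <- matrix(rnorm(60), ncol = 3)
  back <- transform_points(invert_transform(tf), transform_points(tf, pts))
  expect_equal(back, pts, tolerance = 1e-9)
  d0 <- dist(pts); d1 <- dist(transform_points(tf, pts))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  expect_identical(transform_points(rigid_transform(), pts), pts)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
})

test_that("coarse alignment recovers translations and rotations", {
  cl <- asym_cloud()
  tf <- coarse_align(cl, cl + rep(c(5, -3, 2), each = nrow(cl)))
  expect_equal(tf$translation, c(5, -3, 2), tolerance = 1e-6)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-6)

  tf_id <- coarse_align(cl, cl)
  expect_equal(rotation_angle(tf_id), 0, tolerance = 1e-6)

  R <- rotation_about_z(30)
  tf_rot <- coarse_align(cl, t(R %*% t(cl)))
  err <- rotation_angle(compose_transforms(invert_transform(rigid_transform(R)), tf_rot))
  expect_lt(err, 0.5)

  flat <- cbind(cl[, 1:2], 0)
  expect_warning(tf_flat <- coarse_align(flat, flat + rep(c(1, 2, 0), each = nrow(cl))),
                 "degenerate")
  expect_equal(tf_flat$translation, c(1, 2, 0), tolerance = 1e-9)
})

test_that("ICP recovers a known transform exactly without noise", {
  cl <- asym_cloud()
  expect_error(icp_refine(cl, rbind(cl, NA)), "non-finite")

  same <- icp_refine(cl, cl, trim_fraction = 0)
  expect_lt(same$rms, 1e-9)
  expect_lt(rotation_angle(same$transform), 1e-6)

  tf_true <- rigid_transform(rotation_about_z(10), c(5, -3, 2))
  moved <- transform_points(tf_true, cl)
  fit <- icp_refine(cl, moved, init = coarse_align(cl, moved), trim_fraction = 0)
  err <- compose_transforms(invert_transform(tf_true), fit$transform)
  expect_lt(rotation_angle(err), 0.1)
  expect_lt(sqrt(sum(err$translation^2)), 0.05)
})

test_that("trimmed RMS is non-increasing across ICP iterations", {
  ph <- generate_phantom(phantom_spec(seed = 31, n_slices = 4, noise_sd = 0))
  cloud <- generate_ra_cloud(ph$truth, rigid_transform(rotation_about_z(15), c(8, 2, -5)),
                             noise_sd = 0.5, keep_fraction = 0.7, seed = 2,
                             points_per_slice = 150)
  src <- do.call(rbind, lapply(ph$truth$contours$slices, function(s)
    cbind(cartoplan:::resample_closed_polyline(s$epi, 150), s$z)))
  fit <- icp_refine(src, cloud$points, init = coarse_align(src, cloud$points))
  expect_true(all(diff(fit$rms_trace) <= 1e-9))
})

test_that("two-stage registration recovers transforms of phantom clouds", {
  ph <- generate_phantom(phantom_spec(seed = 32, noise_sd = 0))
  src <- do.call(rbind, lapply(ph$truth$contours$slices, function(s)
    cbind(cartoplan:::resample_closed_polyline(s$epi, 320), s$z)))
  for (s in 1:3) {
    set.seed(500 + s)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    tf_true <- rigid_transform(cartoplan:::rotation_axis_angle(ax, runif(1, 5, 25)),
                               runif(3, -30, 30))
    cloud <- generate_ra_cloud(ph$truth, tf_true, noise_sd = 0.5,
                               keep_fraction = 0.7, seed = s)
    reg <- register_to_ra(src, cloud$points)
    err <- compose_transforms(invert_transform(tf_true), reg$transform)
    expect_lt(rotation_angle(err), 2)
    expect_lt(sqrt(sum(err$translation^2)), 1)
  }
})

test_that("apply_transform moves plans and maps coherently", {
  ph <- generate_phantom(phantom_spec(seed = 33, n_slices = 4))
  geometry <- ph$volume[c("dim", "spacing", "origin", "orientation")]
  seg <- fwhm_segment(ph$volume$data, ph$truth$myo_mask)
  map <- endo_surface_map(ph$truth$contours, seg, geometry)
  plan <- assign_targets(map, planner_config(
    n_targets = 8, sector_split = c(septal = 4, anterior = 4),
    septal_direction = ph$truth$septal_direction))
  tf <- rigid_transform(rotation_about_y(20), c(1, 2, 3))

  plan_id <- apply_transform(plan, rigid_transform())
  expect_identical(plan_id$targets, plan$targets)

  moved <- apply_transform(plan, tf)
  back <- apply_transform(moved, invert_transform(tf))
  expect_equal(as.matrix(back$targets[, c("x", "y", "z")]),
               as.matrix(plan$targets[, c("x", "y", "z")]), tolerance = 1e-9)
  d0 <- dist(as.matrix(plan$targets[, c("x", "y", "z")]))
  d1 <- dist(as.matrix(moved$targets[, c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  # scalars untouched
  expect_identical(moved$targets$needle_depth, plan$targets$needle_depth)

  map_moved <- apply_transform(map, tf)
  expect_equal(map_moved$transmurality, map$transmurality)
  expect_equal(dim(map_moved$vertices), dim(map$vertices))
})
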