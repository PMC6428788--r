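# Ring with an analytic transmurality profile: 20% at angle 0 falling
# linearly to 1% at +30 degrees (the border zone is exactly [0, 30]),
# rising into dense scar (> 20%) for negative angles.
band_map <- function(r = 20, n = 720) {
  stack <- circle_stack(r_endo = r, r_epi = r + 10, n = n)
  map <- build_endo_mesh(stack, points_per_slice = n)
  map$wall_thickness <- rep(10, nrow(map$vertices))
  map$transmurality <- pmin(100, pmax(0, 20 - (19 / 30) * map$angle))
  list(map = map, stack = stack)
}

test_that("signed border-zone distance matches the analytic circle cases", {
  bm <- band_map()
  cfg <- planner_config(septal_direction = c(0, -1))
  at <- function(deg) c(20 * cos(deg * pi / 180), 20 * sin(deg * pi / 180), 0)

  expect_equal(as.numeric(signed_ibz_distance(bm$map, at(15), cfg)), 0)
  d_remote <- signed_ibz_distance(bm$map, at(60), cfg)
  expect_equal(as.numeric(d_remote), 20 * 30 * pi / 180, tolerance = 1e-3)
  d_infarct <- signed_ibz_distance(bm$map, at(-15), cfg)
  expect_equal(as.numeric(d_infarct), -20 * 15 * pi / 180, tolerance = 1e-3)
  map_noband <- bm$map
  map_noband$transmurality <- rep(50, length(map_noband$transmurality))
  expect_error(signed_ibz_distance(map_noband, at(0), cfg), "no slice")
})

test_that("signed distance agrees with exhaustive arc search on random toys", {
  cfg <- planner_config(septal_direction = c(0, -1))
  set.seed(50)
  worst <- 0
  n_done <- 0
  while (n_done < 100) {
    r <- runif(1, 15, 30)
    N <- 360
    stack <- circle_stack(r_endo = r, r_epi = r + 8, n = 720)
    map <- build_endo_mesh(stack, points_per_slice = N)
    # random piecewise-linear profile with knots on the vertex angles
    knots <- sort(sample(0:(N - 1), sample(4:9, 1)))
    vals <- runif(length(knots), 0, 45)
    Tv <- approx(c(knots, knots[1] + N), c(vals, vals[1]),
                 xout = seq(0, N - 1) + 0, rule = 2)$y
    map$transmurality <- Tv[((round(map$angle / (360 / N)) %% N) + 1)]
    map$wall_thickness <- rep(10, nrow(map$vertices))
    inband <- map$transmurality[1:N] >= 1 & map$transmurality[1:N] <= 20
    if (!any(inband)) next
    q <- c((r + runif(1, -4, 4)) * cos(runif(1, 0, 2 * pi)),
           (r + runif(1, -4, 4)) * sin(runif(1, 0, 2 * pi)), 0)
    got <- as.numeric(signed_ibz_distance(map, q, cfg))
    ring <- map$vertices[1:N, 1:2]
    want <- brute_ibz_distance(ring, map$transmurality[1:N], q[1:2], 1, 20)
    if (abs(got - want) > worst) worst <- abs(got - want)
    expect_equal(got, want, tolerance = 0.05, label = sprintf("toy %d", n_done))
    n_done <- n_done + 1
  }
  expect_lt(worst, 0.05)
})

test_that("an injection on a slice without border zone falls back to the nearest one", {
  bm <- band_map(n = 360)
  # wipe the band from slice 0
  map <- bm$map
  map$transmurality[map$slice_index == 0] <- 0
  cfg <- planner_config(septal_direction = c(0, -1))
  d <- signed_ibz_distance(map, c(20, 0, 0), cfg)  # z = 0 -> slice 0, band only on slice 1
  expect_equal(attr(d, "slice_index"), 1L)
  expect_equal(attr(d, "out_of_plane_mm"), 10)
})

test_that("injection depth is the perpendicular distance, signed into the wall", {
  stack <- circle_stack()
  expect_equal(injection_depth(stack, c(23, 0, 0)), 3, tolerance = 1e-4)
  expect_equal(injection_depth(stack, c(20, 0, 0)), 0, tolerance = 1e-4)
  expect_warning(d <- injection_depth(stack, c(10, 0, 0)), "blood-pool")
  expect_equal(d, -10, tolerance = 1e-3)
})

test_that("per-animal summaries weight animals, not injections", {
  r <- data.frame(animal_id = c("a", "a", "a", "b"),
                  distance_to_ibz = c(1, 2, 3, 10), depth = c(1, 1, 1, 5))
  s <- per_animal_summary(r)
  expect_equal(s$mean_distance, c(2, 10))
  expect_equal(s$n, c(3L, 1L))
  # grand mean = mean of animal means, not pooled
  expect_equal(mean(s$mean_distance), 6)
  expect_false(mean(s$mean_distance) == mean(r$distance_to_ibz))
  expect_equal(nrow(per_animal_summary(r[0, ])), 0)
})

test_that("injections planted on planned targets score near zero distance", {
  ph <- generate_phantom(phantom_spec(seed = 55))
  geometry <- ph$volume[c("dim", "spacing", "origin", "orientation")]
  seg <- fwhm_segment(ph$volume$data, ph$truth$myo_mask)
  map <- endo_surface_map(ph$truth$contours, seg, geometry)
  cfg <- planner_config(septal_direction = ph$truth$septal_direction)
  plan <- assign_targets(map, cfg)
  inj <- data.frame(animal_id = rep(c("p1", "p2"), each = 8),
                    x = plan$targets$x, y = plan$targets$y, z = plan$targets$z)
  scored <- evaluate_injections(map, ph$truth$contours, cfg, inj)
  s <- per_animal_summary(scored)
  expect_true(all(abs(s$mean_distance) < 1))
  expect_true(all(abs(scored$depth) < 0.2))   # targets sit on the endocardium

  # planted at needle depth along the wall normal: measured depth matches
  nrm <- map$normals[plan$targets$vertex, ]
  inj2 <- data.frame(animal_id = "p3",
                     x = plan$targets$x + nrm[, 1] * plan$targets$needle_depth,
                     y = plan$targets$y + nrm[, 2] * plan$targets$needle_depth,
                     z = plan$targets$z)
  scored2 <- evaluate_injections(map, ph$truth$contours, cfg, inj2)
  expect_equal(scored2$depth, plan$targets$needle_depth, tolerance = 0.1)
})
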