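# A small map with hand-set scalars: 2 rings of 12 vertices on circles.
toy_map <- function(T, WT) {
  stack <- circle_stack(r_endo = 20, r_epi = 32, n = 96)
  mesh <- build_endo_mesh(stack, points_per_slice = 12)
  mesh$transmurality <- rep_len(T, 24)
  mesh$wall_thickness <- rep_len(WT, 24)
  mesh
}

test_that("vertex classification follows the border-zone and danger rules", {
  cfg <- planner_config(septal_direction = c(1, 0))
  cases <- data.frame(T = c(25, 10, 10, 0, 20, 1, 10, 10),
                      WT = c(8, 4, 8, 8, 8, 8, 5, 4.999),
                      zone = c("danger", "danger", "ibz", "neutral",
                               "ibz", "ibz", "neutral", "danger"))
  for (i in seq_len(nrow(cases))) {
    m <- toy_map(cases$T[i], cases$WT[i])
    z <- classify_vertices(m, cfg)
    got <- if (1 %in% z$ibz) "ibz" else if (1 %in% z$danger) "danger" else "neutral"
    expect_equal(got, cases$zone[i], label = sprintf("T=%g WT=%g", cases$T[i], cases$WT[i]))
    expect_length(intersect(z$ibz, z$danger), 0)
  }
  expect_error(classify_vertices(build_endo_mesh(circle_stack(n = 64), 8), cfg),
               "not populated")
})

test_that("targets satisfy the border-zone predicate with half-wall needle depth", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  geometry <- ph$volume[c("dim", "spacing", "origin", "orientation")]
  seg <- fwhm_segment(ph$volume$data, ph$truth$myo_mask)
  map <- endo_surface_map(ph$truth$contours, seg, geometry)
  cfg <- planner_config(septal_direction = ph$truth$septal_direction)
  plan <- assign_targets(map, cfg)
  tg <- plan$targets
  expect_equal(nrow(tg), 16)
  expect_equal(as.vector(table(tg$sector)[c("septal", "anterior")]), c(8L, 8L))
  expect_true(all(tg$transmurality >= 1 & tg$transmurality <= 20))
  expect_true(all(tg$wall_thickness > 5))
  expect_equal(tg$needle_depth, 0.5 * tg$wall_thickness)
  # deterministic
  plan2 <- assign_targets(map, cfg)
  expect_identical(plan$targets, plan2$targets)
  # plan JSON round trip keeps exact coordinates
  f <- tempfile(fileext = ".json")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_equal(back$targets$x, tg$x, tolerance = 1e-12)
  expect_equal(back$targets$needle_depth, tg$needle_depth, tolerance = 1e-12)
})

test_that("an explicit needle-depth example: half of an 8 mm wall is 4 mm", {
  m <- toy_map(10, 8)
  cfg <- planner_config(n_targets = 2, sector_split = c(septal = 1, anterior = 1),
                        septal_direction = c(1, 0))
  plan <- assign_targets(m, cfg)
  expect_equal(plan$targets$needle_depth, c(4, 4))
})

test_that("with one target per sector the sector seed rule picks the angular centre", {
  m <- toy_map(10, 8)
  cfg <- planner_config(n_targets = 2, sector_split = c(septal = 1, anterior = 1),
                        septal_direction = c(1, 0))
  plan <- assign_targets(m, cfg)
  # whole ring is IBZ: seeds are the vertices nearest 0 deg (septal) and 180 deg
  expect_equal(sort(abs(cartoplan:::wrap_angle(plan$targets$angle - c(0, 180)))), c(0, 0),
               tolerance = 1e-6)
})

test_that("greedy spread achieves the factor-2 dispersion bound (brute force)", {
  ph <- generate_phantom(phantom_spec(seed = 21))
  geometry <- ph$volume[c("dim", "spacing", "origin", "orientation")]
  seg <- fwhm_segment(ph$volume$data, ph$truth$myo_mask)
  map <- endo_surface_map(ph$truth$contours, seg, geometry)
  cfg <- planner_config(septal_direction = ph$truth$septal_direction)
  z <- classify_vertices(map, cfg)
  sectors <- cartoplan:::vertex_sectors(map, cfg)
  members <- z$ibz[sectors[z$ibz] == "septal"]
  members <- members[seq_len(min(12, length(members)))]
  k <- 4
  chosen <- cartoplan:::farthest_point_sample(map$vertices, members, members[1], k)
  mindist <- function(set) min(dist(map$vertices[set, , drop = FALSE]))
  combos <- utils::combn(members, k)
  best <- max(apply(combos, 2, mindist))
  expect_gte(mindist(chosen), best / 2)
})

test_that("a sector deficit is reported as an error with the shortfall", {
  m <- toy_map(c(10, rep(0, 23)), 8)  # single IBZ vertex, on the septal side
  cfg <- planner_config(n_targets = 4, sector_split = c(septal = 2, anterior = 2),
                        septal_direction = c(1, 0))
  expect_error(assign_targets(m, cfg), "deficit")
})

test_that("planner config rejects inconsistent settings", {
  expect_error(planner_config(septal_direction = NULL), "required")
  expect_error(planner_config(transmurality_low = 30, transmurality_high = 20,
                              septal_direction = c(1, 0)), "transmurality")
  expect_error(planner_config(n_targets = 10, sector_split = c(septal = 4, anterior = 4),
                              septal_direction = c(1, 0)), "sum")
  expect_error(planner_config(needle_depth_fraction = 0, septal_direction = c(1, 0)),
               "needle_depth_fraction")
})
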