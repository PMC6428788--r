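# Shared toy geometries and independent brute-force oracles.

circle_pts <- function(r, n = 720, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ellipse_pts <- function(a, b, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

# concentric-circle contour stack
circle_stack <- function(r_endo = 20, r_epi = 30, zs = c(0, 10), n = 720) {
  contour_stack(lapply(zs, function(z)
    list(z = z, endo = circle_pts(r_endo, n), epi = circle_pts(r_epi, n))))
}

# circular toy phantom (no ellipticity/drift) for exact-geometry checks
toy_phantom_spec <- function(...) {
  phantom_spec(ellipticity = 0, center_drift = 0, endo_radius = 20, ...)
}

# Brute-force first ray/polyline crossing by dense sampling of the
# polyline (independent of the analytic segment intersection).
brute_ray_hit <- function(origin, dir, poly, n_dense = 400000, tol = 0.02) {
  poly <- rbind(poly, poly[1, ])
  seg_len <- sqrt(rowSums(diff(poly)^2))
  s <- c(0, cumsum(seg_len))
  total <- s[length(s)]
  sv <- seq(0, total, length.out = n_dense)
  idx <- findInterval(sv, s, rightmost.closed = TRUE)
  idx[idx >= nrow(poly)] <- nrow(poly) - 1L
  u <- (sv - s[idx]) / seg_len[idx]
  px <- poly[idx, 1] + u * (poly[idx + 1, 1] - poly[idx, 1])
  py <- poly[idx, 2] + u * (poly[idx + 1, 2] - poly[idx, 2])
  t_along <- (px - origin[1]) * dir[1] + (py - origin[2]) * dir[2]
  off <- abs((px - origin[1]) * dir[2] - (py - origin[2]) * dir[1])
  ok <- off < tol & t_along > 1e-6
  if (!any(ok)) return(NULL)
  min(t_along[ok])
}

# Exhaustive arc-length search for the signed border-zone distance on a
# densely resampled ring with linearly interpolated transmurality.
brute_ibz_distance <- function(ring, Tv, q, low, high, n_dense = 200000) {
  n <- nrow(ring)
  poly <- rbind(ring, ring[1, ])
  seg_len <- sqrt(rowSums(diff(poly)^2))
  s <- c(0, cumsum(seg_len))
  L <- s[n + 1]
  sv <- seq(0, L, length.out = n_dense + 1)[-(n_dense + 1)]
  idx <- findInterval(sv, s, rightmost.closed = TRUE)
  idx[idx > n] <- n
  u <- (sv - s[idx]) / seg_len[idx]
  px <- poly[idx, 1] + u * (poly[idx + 1, 1] - poly[idx, 1])
  py <- poly[idx, 2] + u * (poly[idx + 1, 2] - poly[idx, 2])
  Tnext <- c(Tv[-1], Tv[1])
  Td <- Tv[idx] + u * (Tnext[idx] - Tv[idx])
  inband <- Td >= low & Td <= high
  if (!any(inband)) stop("toy has no band")
  i0 <- which.min((px - q[1])^2 + (py - q[2])^2)
  if (inband[i0]) return(0)
  d_fwd <- (sv[inband] - sv[i0]) %% L
  d_bwd <- (sv[i0] - sv[inband]) %% L
  d <- pmin(d_fwd, d_bwd)
  j <- which.min(d)
  i_star <- which(inband)[j]
  # sample adjacent to the band entry on the path from i0
  step <- if (d_fwd[j] <= d_bwd[j]) -1 else 1
  i_adj <- ((i_star - 1 + step) %% n_dense) + 1
  sgn <- if (Td[i_adj] > high) -1 else 1
  sgn * d[j]
}

# per-group synthetic injection records (animal means structure)
synth_records <- function(group, n_animals, inj_per_animal, mean_dist,
                          between_sd = 1, within_sd = 3) {
  do.call(rbind, lapply(seq_len(n_animals), function(a) {
    mu <- rnorm(1, mean_dist, between_sd)
    data.frame(animal_id = sprintf("%s%02d", group, a), group = group,
               distance_to_ibz = rnorm(inj_per_animal, mu, within_sd),
               depth = abs(rnorm(inj_per_animal, 3, 1)))
  }))
}
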