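#' Build the endocardial surface mesh
#'
#' Resamples every endocardial contour to `points_per_slice` vertices at
#' equal arc-length spacing, starting at the crossing of the in-slice
#' ray at angle 0 from the contour centroid, and triangulates adjacent
#' rings by index correspondence. Per-vertex scalar fields (infarct
#' transmurality, wall thickness) are initialised to `NA` and filled by
#' [endo_surface_map()].
#'
#' @param stack a [contour_stack()] (at least 2 slices).
#' @param points_per_slice vertices per ring; the default 120 gives 3
#'   degrees of angular resolution.
#' @return Object of class `endo_map`: `vertices` (n x 3, mm), `faces`
#'   (m x 3, 1-based), per-vertex `slice_index` (0-based), `angle`
#'   (degrees CCW from +x about the slice centroid), outward in-slice
#'   unit `normals` (n x 3, z = 0), `transmurality` (%), `wall_thickness`
#'   (mm), plus ring bookkeeping (`ring_z`, `centroids`).
#' @export
build_endo_mesh <- function(stack, points_per_slice = 120) {
  stopifnot(inherits(stack, "contour_stack"))
  ns <- length(stack$slices)
  if (ns < 2) stop("need at least 2 slices to build a surface")
  N <- as.integer(points_per_slice)
  verts <- matrix(NA_real_, ns * N, 3)
  normals <- matrix(NA_real_, ns * N, 3)
  angle <- numeric(ns * N)
  slice_index <- integer(ns * N)
  centroids <- matrix(NA_real_, ns, 2)
  ring_z <- numeric(ns)
  for (i in seq_len(ns)) {
    s <- stack$slices[[i]]
    check_contour_closed(s$endo, i - 1, "endocardial")
    check_contour_closed(s$epi, i - 1, "epicardial")
    ctr <- polygon_centroid(s$endo)
    ring <- resample_closed_polyline(s$endo, N, center = ctr, start_angle_deg = 0)
    idx <- (i - 1) * N + seq_len(N)
    verts[idx, ] <- cbind(ring, s$z)
    centroids[i, ] <- ctr
    ring_z[i] <- s$z
    angle[idx] <- wrap_angle(rad2deg(atan2(ring[, 2] - ctr[2], ring[, 1] - ctr[1])))
    slice_index[idx] <- i - 1L
    # outward normal from the two neighbouring ring vertices (central
    # difference), sign-oriented away from the centroid
    nxt <- ring[c(2:N, 1), ] - ring[c(N, 1:(N - 1)), ]
    nrm <- cbind(nxt[, 2], -nxt[, 1])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    flip <- rowSums(nrm * (ring - rep(ctr, each = N))) < 0
    nrm[flip, ] <- -nrm[flip, ]
    normals[idx, ] <- cbind(nrm, 0)
  }
  faces <- matrix(NA_integer_, 2 * N * (ns - 1), 3)
  fi <- 0L
  for (i in seq_len(ns - 1)) {
    a <- (i - 1) * N + seq_len(N)
    b <- a %% N + (i - 1) * N + 1L     # next vertex on same ring
    au <- a + N; bu <- b + N           # ring above
    faces[fi + seq_len(N), ] <- cbind(a, b, au)
    faces[fi + N + seq_len(N), ] <- cbind(b, bu, au)
    fi <- fi + 2L * N
  }
  structure(list(vertices = verts, faces = faces, normals = normals,
                 slice_index = slice_index, angle = angle,
                 transmurality = rep(NA_real_, ns * N),
                 wall_thickness = rep(NA_real_, ns * N),
                 points_per_slice = N, n_slices = ns,
                 ring_z = ring_z, centroids = centroids),
            class = "endo_map")
}

# A contour is delivered as an ordered point list with implicit closure;
# an excessively long closing edge betrays an open (unclosed) trace.
#' @keywords internal
check_contour_closed <- function(p, slice0, what) {
  p <- strip_closure(p)
  seg <- polyline_segments(p)
  closing <- seg$len[length(seg$len)]
  if (closing > 5 * stats::median(seg$len[-length(seg$len)]))
    stop(sprintf("slice %d: %s contour is not closed (gap of %.2f mm)",
                 slice0, what, closing))
  invisible(TRUE)
}

#' @export
print.endo_map <- function(x, ...) {
  cat(sprintf("endo_map: %d vertices (%d slices x %d), %d faces; transmurality %s\n",
              nrow(x$vertices), x$n_slices, x$points_per_slice, nrow(x$faces),
              if (all(is.na(x$transmurality))) "unset" else
                sprintf("%.1f-%.1f%%", min(x$transmurality), max(x$transmurality))))
  invisible(x)
}

# Wall chords -----------------------------------------------------------

# For every mesh vertex, cast the outward in-slice normal ray against the
# epicardial contour of its slice; fall back to the centroid ray when the
# normal ray misses. Returns the chord length (= wall thickness) and the
# unit chord direction per vertex.
#' @keywords internal
wall_chords <- function(stack, mesh) {
  n <- nrow(mesh$vertices)
  wt <- numeric(n)
  dirs <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    sl <- mesh$slice_index[i] + 1L
    epi <- stack$slices[[sl]]$epi
    v <- mesh$vertices[i, 1:2]
    d <- mesh$normals[i, 1:2]
    hit <- ray_polyline_intersection(v, d, epi)
    if (is.null(hit)) {
      ctr <- mesh$centroids[sl, ]
      d <- v - ctr
      d <- d / sqrt(sum(d^2))
      hit <- ray_polyline_intersection(v, d, epi)
      if (is.null(hit))
        stop(sprintf("slice %d, angle %.1f deg: wall chord misses the epicardial contour",
                     mesh$slice_index[i], mesh$angle[i]))
    }
    wt[i] <- hit$t
    dirs[i, ] <- d
  }
  list(wt = wt, dirs = dirs)
}

#' Per-vertex wall thickness
#'
#' Wall thickness at each mesh vertex, measured perpendicular to the
#' endocardial contour: the distance from the vertex along its outward
#' in-slice normal to the first crossing of the epicardial contour. If
#' the normal ray misses the epicardial polyline (possible for strongly
#' non-convex contours), the ray from the endocardial centroid through
#' the vertex is used instead; if that also misses, an error names the
#' slice and angle.
#'
#' @param stack a [contour_stack()].
#' @param mesh an `endo_map` built from the same stack.
#' @return Numeric vector of wall thickness (mm) per vertex.
#' @export
wall_thickness <- function(stack, mesh) wall_chords(stack, mesh)$wt

#' Per-vertex infarct transmurality
#'
#' Infarct transmurality at each mesh vertex: the percentage of the
#' endo-to-epi wall chord (the same perpendicular chord used for wall
#' thickness) that runs through segmented scar. The chord is sampled at
#' steps of at most a quarter pixel and each sample is classified by the
#' scar voxel it falls in; samples outside the grid count as non-scar.
#'
#' @param stack a [contour_stack()].
#' @param mesh an `endo_map` built from the same stack.
#' @param scar a [fwhm_segment()] result (or any logical array matching
#'   the volume grid).
#' @param geometry the voxel geometry of the scar grid (`dim`, `spacing`,
#'   `origin`, `orientation`).
#' @return Numeric vector of transmurality (%) per vertex, in `[0, 100]`.
#' @export
transmurality <- function(stack, mesh, scar, geometry) {
  mask <- if (inherits(scar, "scar_seg")) scar$scar_mask else scar
  stopifnot(all(dim(mask) == geometry$dim))
  ch <- wall_chords(stack, mesh)
  step <- 0.25 * min(geometry$spacing[1:2])
  n <- nrow(mesh$vertices)
  out <- numeric(n)
  # sample all chords in one batch: midpoint rule along each chord; the
  # tiny offset keeps the sample count stable when the chord length is
  # an exact multiple of the step (rigid-motion invariance)
  counts <- pmax(1L, ceiling(ch$wt / step - 1e-9))
  total <- sum(counts)
  vid <- rep.int(seq_len(n), counts)
  tfrac <- (unlist(lapply(counts, function(m) (seq_len(m) - 0.5) / m)))
  tlen <- tfrac * ch$wt[vid]
  pts <- cbind(mesh$vertices[vid, 1] + tlen * ch$dirs[vid, 1],
               mesh$vertices[vid, 2] + tlen * ch$dirs[vid, 2],
               mesh$vertices[vid, 3])
  ijk <- mm_to_voxel(geometry, pts)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= geometry$dim[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= geometry$dim[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= geometry$dim[3]
  hit <- logical(total)
  lin <- ijk[ok, 1] + (ijk[ok, 2] - 1) * geometry$dim[1] +
    (ijk[ok, 3] - 1) * geometry$dim[1] * geometry$dim[2]
  hit[ok] <- mask[lin]
  100 * as.numeric(tapply(hit, vid, mean))
}

#' Endocardial surface map with scalar fields
#'
#' Convenience wrapper building the endocardial mesh and populating the
#' per-vertex wall-thickness and transmurality fields; after it returns,
#' no vertex holds `NA`.
#'
#' @inheritParams transmurality
#' @param points_per_slice vertices per ring.
#' @return A fully populated `endo_map`.
#' @export
endo_surface_map <- function(stack, scar = NULL, geometry = NULL,
                             points_per_slice = 120) {
  mesh <- build_endo_mesh(stack, points_per_slice)
  mesh$wall_thickness <- wall_thickness(stack, mesh)
  mesh$transmurality <- if (is.null(scar)) rep(0, nrow(mesh$vertices))
    else transmurality(stack, mesh, scar, geometry)
  mesh
}
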