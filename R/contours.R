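#' Stack of endocardial and epicardial contours
#'
#' The geometric backbone of the pipeline: one pair of closed planar
#' contours per short-axis slice, in patient coordinates (mm). Slices are
#' ordered apex to base with strictly increasing z. Each contour is an
#' ordered polyline of at least 8 points; the closing edge from the last
#' point back to the first is implicit (a repeated first point is
#' tolerated and stripped). The endocardial contour must lie strictly
#' inside the epicardial contour of the same slice, and neither may
#' self-intersect.
#'
#' @param slices list of slices, each a list with fields `z` (mm),
#'   `endo` and `epi` (n x 2 matrices, mm).
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(slices) {
  stopifnot(is.list(slices), length(slices) >= 1)
  zs <- vapply(slices, function(s) as.numeric(s$z), numeric(1))
  if (any(diff(zs) <= 0)) stop("slice z positions must be strictly increasing")
  slices <- lapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    endo <- strip_closure(as.matrix(s$endo))
    epi <- strip_closure(as.matrix(s$epi))
    for (nm in c("endo", "epi")) {
      p <- if (nm == "endo") endo else epi
      if (ncol(p) != 2 || nrow(p) < 8)
        stop(sprintf("slice %d: %s contour needs >= 8 two-column points", i - 1, nm))
      if (polyline_self_intersects(p))
        stop(sprintf("slice %d: %s contour is self-intersecting", i - 1, nm))
    }
    if (!all(points_in_polygon(epi, endo)))
      stop(sprintf("slice %d: endocardial contour is not inside the epicardial contour", i - 1))
    list(z = as.numeric(s$z), endo = endo, epi = epi)
  })
  structure(list(slices = slices), class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  zs <- vapply(x$slices, `[[`, numeric(1), "z")
  cat(sprintf("contour_stack: %d slices, z = %.1f .. %.1f mm\n",
              length(x$slices), min(zs), max(zs)))
  invisible(x)
}

#' @export
length.contour_stack <- function(x) length(x$slices)

#' Read and write contour stacks as JSON
#'
#' Contours are exchanged as a JSON array of slices, each with `z` and
#' ordered `endo` / `epi` `[x, y]` lists in mm — the format the phantom
#' writes and the planning pipeline reads.
#'
#' @param path file path.
#' @param stack a `contour_stack`.
#' @return `read_contours` returns a `contour_stack`;
#'   `write_contours` returns `path` invisibly.
#' @export
read_contours <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  contour_stack(lapply(raw, function(s)
    list(z = s$z, endo = matrix(unlist(s$endo), ncol = 2, byrow = is.list(s$endo)),
         epi = matrix(unlist(s$epi), ncol = 2, byrow = is.list(s$epi)))))
}

#' @rdname read_contours
#' @export
write_contours <- function(stack, path) {
  out <- lapply(stack$slices, function(s)
    list(z = s$z, endo = unname(s$endo), epi = unname(s$epi)))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Rasterize the myocardium between contours
#'
#' Builds a per-slice binary myocardial mask on a voxel grid: pixels whose
#' centres fall inside the epicardial polygon but outside the endocardial
#' polygon (even-odd rule). Each contour slice is matched to the nearest
#' voxel plane of the grid.
#'
#' @param stack a `contour_stack`.
#' @param geometry volume geometry, a list with `dim` (nx, ny, nz),
#'   `spacing` (mm), `origin` (mm, centre of voxel `[0,0,0]`) and
#'   `orientation` (3x3 direction cosines), as returned by
#'   [read_lge_series()].
#' @return Logical array of `geometry$dim`.
#' @export
rasterize_myocardium <- function(stack, geometry) {
  dm <- geometry$dim
  mask <- array(FALSE, dm)
  centers <- voxel_plane_coords(geometry)
  zs <- voxel_plane_z(geometry)
  for (s in stack$slices) {
    k <- which.min(abs(zs - s$z))
    inside <- points_in_polygon(s$epi, centers) & !points_in_polygon(s$endo, centers)
    mask[, , k] <- mask[, , k] | matrix(inside, dm[1], dm[2])
  }
  mask
}

# x/y coordinates (mm) of in-plane voxel centres of slice k = 1 (all
# slices share them for axis-aligned geometries).
#' @keywords internal
voxel_plane_coords <- function(geometry) {
  stopifnot(max(abs(geometry$orientation - diag(3))) < 1e-6)
  xs <- geometry$origin[1] + (seq_len(geometry$dim[1]) - 1) * geometry$spacing[1]
  ys <- geometry$origin[2] + (seq_len(geometry$dim[2]) - 1) * geometry$spacing[2]
  cbind(rep(xs, times = geometry$dim[2]), rep(ys, each = geometry$dim[1]))
}

#' @keywords internal
voxel_plane_z <- function(geometry) {
  geometry$origin[3] + (seq_len(geometry$dim[3]) - 1) * geometry$spacing[3]
}

# Map mm points (n x 3) to 1-based voxel indices; general orientation.
#' @keywords internal
mm_to_voxel <- function(geometry, pts) {
  pts <- matrix(pts, ncol = 3)
  A <- geometry$orientation %*% diag(geometry$spacing)
  ijk <- t(solve(A, t(pts) - geometry$origin))
  round(ijk) + 1
}
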