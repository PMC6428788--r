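#' Specification of a synthetic LGE left-ventricle phantom
#'
#' Defines the geometry, scar and signal model of the synthetic
#' short-axis LGE volume used to exercise the full planning pipeline with
#' known ground truth. The left ventricle is a stack of short-axis
#' annuli, apex to base: the endocardial contour of slice `k` is the oval
#' `r(theta) = R_k (1 + e cos 2 theta)` around a slice centre that drifts
#' quadratically toward the base, and the epicardial contour is its exact
#' outward offset at distance `wall_thickness`, so the true perpendicular
#' wall thickness is the nominal value everywhere. A small ellipticity
#' `e` and the centre drift are kept on by default: a perfectly circular,
#' straight tube has no identifiable in-plane orientation, which would
#' make rigid registration of the epicardial surface ill-posed.
#'
#' The scar is an angular wedge `scar_theta_range` occupying, at angle
#' theta, the innermost `transmurality_profile(theta, slice)` fraction of
#' the endo-to-epi chord. The default profile is triangular: fully
#' transmural at the wedge centre, falling linearly to 0 at the wedge
#' edges, identical on every slice — so the 1–20% border zone is a thin
#' angular band on each side of the wedge. The wedge straddles the
#' antero-septal junction and `septal_direction` points to the middle of
#' the septal half, mirroring an antero-septal infarct.
#'
#' @param n_slices number of short-axis slices (apex to base).
#' @param slice_spacing slice separation, mm.
#' @param endo_radius endocardial reference radius, mm; scalar or one
#'   value per slice (apex to base).
#' @param wall_thickness myocardial wall thickness, mm; scalar or per
#'   slice.
#' @param scar_theta_range angular extent `[theta1, theta2)` of the scar
#'   wedge, degrees counter-clockwise from +x.
#' @param transmurality_profile `function(theta_deg, slice_index)`
#'   returning the scar fraction of the wall chord in `[0, 1]`; `NULL`
#'   for the default triangular profile.
#' @param remote_intensity,scar_intensity signal of remote and infarcted
#'   myocardium, a.u.
#' @param noise_sd standard deviation of additive Gaussian noise, a.u.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param seed integer seed making the phantom reproducible.
#' @param ellipticity relative cos(2 theta) modulation of the endocardial
#'   radius.
#' @param center_drift total in-plane drift (mm, along +y) of the slice
#'   centres from apex to base, applied quadratically.
#' @param n_contour_points points per exported truth contour.
#' @param background_fraction background (incl. blood pool) intensity as
#'   a fraction of `remote_intensity`; kept below 1 so the myocardium is
#'   the bright structure within its mask.
#' @param margin grid margin around the epicardium, mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 10,
                         slice_spacing = 5,
                         endo_radius = seq(16, 22, length.out = n_slices),
                         wall_thickness = 10,
                         scar_theta_range = c(-30, 30),
                         transmurality_profile = NULL,
                         remote_intensity = 100,
                         scar_intensity = 300,
                         noise_sd = 10,
                         pixel_spacing = 0.8,
                         seed = 1,
                         ellipticity = 0.12,
                         center_drift = 3,
                         n_contour_points = 720,
                         background_fraction = 0.3,
                         margin = 5) {
  if (n_slices < 2) stop("need at least 2 slices")
  if (slice_spacing <= 0 || pixel_spacing <= 0) stop("spacings must be positive")
  endo_radius <- rep_len(endo_radius, n_slices)
  wall_thickness <- rep_len(wall_thickness, n_slices)
  if (any(endo_radius <= 0) || any(wall_thickness <= 0))
    stop("radii and wall thickness must be positive")
  if (diff(scar_theta_range) < 0 || diff(scar_theta_range) > 360)
    stop("scar_theta_range must be an interval no wider than 360 degrees")
  if (scar_intensity <= remote_intensity)
    stop("scar_intensity must exceed remote_intensity")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (ellipticity < 0 || ellipticity > 0.3) stop("ellipticity must be in [0, 0.3]")
  wedge_center <- mean(scar_theta_range)
  half_width <- diff(scar_theta_range) / 2
  if (is.null(transmurality_profile)) {
    transmurality_profile <- function(theta_deg, slice_index) {
      if (half_width == 0) return(rep(0, length(theta_deg)))
      pmax(0, 1 - abs(wrap_angle(theta_deg - wedge_center)) / half_width)
    }
  }
  probe <- transmurality_profile(seq(-180, 180, by = 5), 0L)
  if (any(probe < -1e-12) || any(probe > 1 + 1e-12))
    stop("transmurality_profile must stay within [0, 1]")
  structure(list(n_slices = as.integer(n_slices), slice_spacing = slice_spacing,
                 endo_radius = endo_radius, wall_thickness = wall_thickness,
                 scar_theta_range = scar_theta_range,
                 transmurality_profile = transmurality_profile,
                 remote_intensity = remote_intensity,
                 scar_intensity = scar_intensity,
                 noise_sd = noise_sd, pixel_spacing = pixel_spacing,
                 seed = as.integer(seed), ellipticity = ellipticity,
                 center_drift = center_drift,
                 n_contour_points = as.integer(n_contour_points),
                 background_fraction = background_fraction, margin = margin),
            class = "phantom_spec")
}

# Per-slice analytic geometry -------------------------------------------

#' @keywords internal
phantom_slice_center <- function(spec, k) {
  # k is 0-based apex -> base
  u <- if (spec$n_slices > 1) k / (spec$n_slices - 1) else 0
  c(0, spec$center_drift * u^2)
}

# Endocardial curve p(theta), its tangent and outward normal.
#' @keywords internal
phantom_endo_curve <- function(spec, k, theta_rad) {
  R <- spec$endo_radius[k + 1]
  e <- spec$ellipticity
  ctr <- phantom_slice_center(spec, k)
  r <- R * (1 + e * cos(2 * theta_rad))
  rp <- -2 * e * R * sin(2 * theta_rad)
  px <- ctr[1] + r * cos(theta_rad)
  py <- ctr[2] + r * sin(theta_rad)
  tx <- rp * cos(theta_rad) - r * sin(theta_rad)
  ty <- rp * sin(theta_rad) + r * cos(theta_rad)
  tl <- sqrt(tx^2 + ty^2)
  list(p = cbind(px, py), n = cbind(ty / tl, -tx / tl), r = r)
}

# Closest-curve coordinates (theta, signed normal distance) of in-plane
# points q for slice k, by Newton iteration on the analytic curve. Exact
# up to the iteration tolerance (~1e-10 mm).
#' @keywords internal
phantom_curve_coords <- function(spec, k, q) {
  R <- spec$endo_radius[k + 1]
  e <- spec$ellipticity
  ctr <- phantom_slice_center(spec, k)
  qx <- q[, 1] - ctr[1]; qy <- q[, 2] - ctr[2]
  th <- atan2(qy, qx)
  for (i in 1:25) {
    r <- R * (1 + e * cos(2 * th)); rp <- -2 * e * R * sin(2 * th); rpp <- -4 * e * R * cos(2 * th)
    ct <- cos(th); st <- sin(th)
    px <- r * ct; py <- r * st
    dx <- qx - px; dy <- qy - py
    tx <- rp * ct - r * st; ty <- rp * st + r * ct
    txp <- rpp * ct - 2 * rp * st - r * ct
    typ <- rpp * st + 2 * rp * ct - r * st
    g <- -(dx * tx + dy * ty)
    gp <- tx^2 + ty^2 - (dx * txp + dy * typ)
    step <- g / gp
    th <- th - step
    if (max(abs(step)) < 1e-12) break
  }
  r <- R * (1 + e * cos(2 * th)); rp <- -2 * e * R * sin(2 * th)
  ct <- cos(th); st <- sin(th)
  tx <- rp * ct - r * st; ty <- rp * st + r * ct
  tl <- sqrt(tx^2 + ty^2)
  nx <- ty / tl; ny <- -tx / tl
  s <- (qx - r * ct) * nx + (qy - r * st) * ny  # signed distance, + outward
  list(theta_deg = wrap_angle(rad2deg(th)), s = s)
}

#' Generate a synthetic LGE phantom
#'
#' Builds the voxel intensity volume and exact ground truth for a
#' [phantom_spec()]: myocardial voxels take `remote_intensity`, scar
#' voxels (the innermost `transmurality_profile` fraction of each wall
#' chord inside the wedge) take `scar_intensity`, everything else a
#' background below the remote signal; zero-mean Gaussian noise of sd
#' `noise_sd` is added and intensities are rounded to non-negative
#' integers, as magnitude MR images are stored. Identical spec and seed
#' give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `lv_phantom` with elements
#'   \describe{
#'     \item{volume}{`lge_volume`: intensity array plus geometry
#'       (`spacing`, `origin`, `orientation`, patient mm).}
#'     \item{truth}{ground truth: `contours` (a [contour_stack()]),
#'       logical `scar_mask` and `myo_mask`, `transmurality_true` and
#'       `wall_thickness_true` (slice x angle grids, percent and mm),
#'       `angle_grid_deg`, `septal_direction`, and the profile function.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ns <- spec$n_slices
  h <- spec$pixel_spacing

  # grid extent from the analytic contours
  rmax <- max(spec$endo_radius) * (1 + spec$ellipticity) + max(spec$wall_thickness)
  lo <- -rmax - spec$margin
  hi <- rmax + spec$margin + max(0, spec$center_drift)
  nxy <- ceiling((hi - lo) / h)
  origin <- c(lo + h / 2, lo + h / 2, 0)
  geometry <- list(dim = c(nxy, nxy, ns), spacing = c(h, h, spec$slice_spacing),
                   origin = origin, orientation = diag(3))

  xs <- origin[1] + (seq_len(nxy) - 1) * h
  ys <- origin[2] + (seq_len(nxy) - 1) * h
  px <- rep(xs, times = nxy)
  py <- rep(ys, each = nxy)

  th1 <- spec$scar_theta_range[1]
  width <- diff(spec$scar_theta_range)

  data <- array(0, geometry$dim)
  myo <- array(FALSE, geometry$dim)
  scar <- array(FALSE, geometry$dim)
  contours <- vector("list", ns)
  theta_grid <- seq(0, 359, by = 1)
  trans_true <- matrix(0, ns, length(theta_grid))
  wt_true <- matrix(0, ns, length(theta_grid))

  for (k in 0:(ns - 1)) {
    WT <- spec$wall_thickness[k + 1]
    ctr <- phantom_slice_center(spec, k)
    # coarse radial gate to keep the Newton solve small
    rr <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
    Rk <- spec$endo_radius[k + 1]
    cand <- which(rr >= Rk * (1 - spec$ellipticity) - h &
                  rr <= Rk * (1 + spec$ellipticity) + WT + h)
    cc <- phantom_curve_coords(spec, k, cbind(px[cand], py[cand]))
    in_myo <- cc$s >= 0 & cc$s <= WT
    frac <- spec$transmurality_profile(cc$theta_deg, k)
    in_wedge <- wrap_width(cc$theta_deg - th1) < width
    in_scar <- in_myo & in_wedge & cc$s <= frac * WT
    sl_myo <- matrix(FALSE, nxy, nxy); sl_myo[cand[in_myo]] <- TRUE
    sl_scar <- matrix(FALSE, nxy, nxy); sl_scar[cand[in_scar]] <- TRUE
    myo[, , k + 1] <- sl_myo
    scar[, , k + 1] <- sl_scar

    th <- deg2rad(seq(0, 360, length.out = spec$n_contour_points + 1)[-(spec$n_contour_points + 1)])
    ec <- phantom_endo_curve(spec, k, th)
    contours[[k + 1]] <- list(z = k * spec$slice_spacing,
                              endo = ec$p, epi = ec$p + WT * ec$n)

    fgrid <- spec$transmurality_profile(theta_grid, k)
    in_w <- wrap_width(theta_grid - th1) < width
    trans_true[k + 1, ] <- 100 * fgrid * in_w
    wt_true[k + 1, ] <- WT
  }

  sl <- matrix(0, nxy, nxy)
  intensity <- array(spec$background_fraction * spec$remote_intensity, geometry$dim)
  intensity[myo] <- spec$remote_intensity
  intensity[scar] <- spec$scar_intensity
  intensity <- withr::with_seed(spec$seed, {
    intensity + stats::rnorm(length(intensity), 0, spec$noise_sd)
  })
  data <- array(pmax(0L, as.integer(round(intensity))), geometry$dim)

  volume <- structure(c(list(data = data), geometry), class = "lge_volume")
  wedge_center <- mean(spec$scar_theta_range)
  septal_angle <- wedge_center - 90
  truth <- list(contours = contour_stack(contours),
                scar_mask = scar, myo_mask = myo,
                transmurality_true = trans_true,
                wall_thickness_true = wt_true,
                angle_grid_deg = theta_grid,
                septal_direction = c(cos(deg2rad(septal_angle)), sin(deg2rad(septal_angle))),
                profile = spec$transmurality_profile)
  structure(list(volume = volume, truth = truth, spec = spec), class = "lv_phantom")
}

# angular offset wrapped into [0, 360)
#' @keywords internal
wrap_width <- function(a) a %% 360

#' @export
print.lv_phantom <- function(x, ...) {
  cat(sprintf("lv_phantom: %d slices, grid %d x %d, pixel %.2f mm, %d scar voxels\n",
              x$spec$n_slices, x$volume$dim[1], x$volume$dim[2],
              x$spec$pixel_spacing, sum(x$truth$scar_mask)))
  invisible(x)
}

#' Sample an interventional epicardial point cloud from phantom truth
#'
#' Emulates the epicardial surface reconstructed from a rotational
#' angiography roll scan: epicardial surface points are sampled from the
#' phantom truth contours, moved by a known rigid transform (the unknown
#' the registration stage must recover), jittered with isotropic
#' Gaussian noise and randomly thinned to `keep_fraction` to mimic
#' partial coverage.
#'
#' @param truth the `truth` element of a [generate_phantom()] result (or
#'   any list with a `contours` [contour_stack()]).
#' @param transform a [rigid_transform()] applied to the points.
#' @param noise_sd isotropic jitter sd, mm.
#' @param keep_fraction fraction of points kept, in `(0, 1]`.
#' @param seed integer seed.
#' @param points_per_slice epicardial samples per slice before thinning;
#'   the default mirrors the dense surface a rotational-angiography
#'   reconstruction yields.
#' @return List of class `ra_cloud`: `points` (n x 3 mm) and
#'   `transform_true` (the applied transform, for validation).
#' @export
generate_ra_cloud <- function(truth, transform = rigid_transform(),
                              noise_sd = 0.5, keep_fraction = 1,
                              seed = 1, points_per_slice = 400) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  pts <- do.call(rbind, lapply(truth$contours$slices, function(s) {
    epi <- resample_closed_polyline(s$epi, points_per_slice)
    cbind(epi, s$z)
  }))
  if (round(keep_fraction * nrow(pts)) < 10)
    stop("keep_fraction leaves fewer than 10 points")
  pts <- transform_points(transform, pts)
  pts <- withr::with_seed(seed, {
    p <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd), ncol = 3)
    keep <- sort(sample.int(nrow(p), round(keep_fraction * nrow(p))))
    p[keep, , drop = FALSE]
  })
  structure(list(points = pts, transform_true = transform), class = "ra_cloud")
}

#' Write phantom artifacts to disk
#'
#' Writes the intensity volume and scar mask as NIfTI, the truth
#' contours as JSON, and optionally the volume as a DICOM series.
#'
#' @param phantom an `lv_phantom`.
#' @param dir output directory (created if needed).
#' @param dicom also export the volume as a DICOM series.
#' @return Invisibly, the named vector of written paths.
#' @export
write_phantom <- function(phantom, dir, dicom = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(volume = file.path(dir, "lge.nii.gz"),
             scar = file.path(dir, "scar_truth.nii.gz"),
             contours = file.path(dir, "contours.json"),
             septal = file.path(dir, "septal_direction.json"))
  write_volume_nifti(phantom$volume, paths[["volume"]])
  mask_vol <- phantom$volume
  mask_vol$data <- array(as.integer(phantom$truth$scar_mask), dim(phantom$truth$scar_mask))
  write_volume_nifti(mask_vol, paths[["scar"]])
  write_contours(phantom$truth$contours, paths[["contours"]])
  jsonlite::write_json(list(septal_direction = phantom$truth$septal_direction),
                       paths[["septal"]], digits = NA)
  if (dicom) {
    ddir <- file.path(dir, "dicom")
    write_dicom_series(phantom$volume, ddir, series_description = "synthetic LGE phantom")
    paths <- c(paths, dicom = ddir)
  }
  invisible(paths)
}
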