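# Injection-accuracy endpoints: signed along-contour distance of a
# retrieved injection to the infarct border zone, and perpendicular
# injection depth. Distances are measured per slice along the 2-D
# endocardial contour, matching measurement on short-axis histology
# slices; no 3-D geodesic across slices is attempted. Sign convention:
# negative = the injection sits on the infarct side of the border zone
# (beyond the upper transmurality bound), positive = on the remote side
# (below the lower bound); 0 = inside the zone.

# In-band arc intervals of a ring. Given ordered ring vertices with arc
# positions and transmurality values (linear in between), returns the
# merged circular intervals [s_lo, s_hi] where low <= T <= high, with
# the bound that clips each endpoint ("low"/"high") for the sign rule.
#' @keywords internal
band_intervals <- function(arc, L, T, low, high) {
  n <- length(arc)
  nxt <- c(2:n, 1)
  iv <- list()
  for (j in seq_len(n)) {
    T1 <- T[j]; T2 <- T[nxt[j]]
    l1 <- arc[j]
    l2 <- if (j < n) arc[nxt[j]] else L
    seg <- l2 - l1
    # u-interval of low <= T1 + u (T2 - T1) <= high on [0, 1]
    if (T1 == T2) {
      if (T1 < low || T1 > high) next
      u <- c(0, 1); cl <- c(NA, NA)
    } else {
      ulo <- (low - T1) / (T2 - T1); uhi <- (high - T1) / (T2 - T1)
      u <- sort(c(ulo, uhi))
      cl <- if (ulo < uhi) c("low", "high") else c("high", "low")
      keep_lo <- max(u[1], 0); keep_hi <- min(u[2], 1)
      if (keep_lo >= keep_hi) next
      cl <- c(if (u[1] < 0) NA else cl[1], if (u[2] > 1) NA else cl[2])
      u <- c(keep_lo, keep_hi)
    }
    iv[[length(iv) + 1]] <- list(s = l1 + u * seg, clip = cl)
  }
  if (!length(iv)) return(list())
  # merge intervals that touch (shared vertex inside the band)
  iv <- iv[order(vapply(iv, function(x) x$s[1], numeric(1)))]
  merged <- list(iv[[1]])
  for (x in iv[-1]) {
    last <- merged[[length(merged)]]
    if (x$s[1] - last$s[2] < 1e-9) {
      merged[[length(merged)]] <- list(s = c(last$s[1], max(last$s[2], x$s[2])),
                                       clip = c(last$clip[1], x$clip[2]))
    } else merged[[length(merged) + 1]] <- x
  }
  # circular wrap: merge last into first if they touch across s = 0/L
  if (length(merged) > 1) {
    first <- merged[[1]]; last <- merged[[length(merged)]]
    if (first$s[1] < 1e-9 && L - last$s[2] < 1e-9) {
      merged[[1]] <- list(s = c(last$s[1] - L, first$s[2]),
                          clip = c(last$clip[1], first$clip[2]))
      merged[[length(merged)]] <- NULL
    }
  }
  merged
}

#' Signed along-contour distance of an injection to the border zone
#'
#' Projects the injection onto the endocardial ring of its slice
#' (closest point) and measures the minimal arc length along the ring to
#' the infarct border zone, the arc where transmurality lies within the
#' planner band. Transmurality between ring vertices is interpolated
#' linearly, so the zone boundary is located sub-vertex. The distance is
#' 0 when the projection falls inside the zone, negative when the
#' nearest zone boundary is an upper-bound crossing (the injection sits
#' on the dense-scar side) and positive at a lower-bound crossing (the
#' remote side). If the injection's slice has no border zone, the
#' nearest slice that has one is used and the out-of-plane offset is
#' reported in the `out_of_plane_mm` attribute.
#'
#' @param map a populated `endo_map`.
#' @param position length-3 injection position (mm), or length-2 with
#'   `slice_index` given.
#' @param cfg a [planner_config()] (supplies the band).
#' @param slice_index optional 0-based slice; default: nearest ring z.
#' @return Signed distance (mm) with attributes `slice_index` (used
#'   slice) and `out_of_plane_mm`.
#' @export
signed_ibz_distance <- function(map, position, cfg, slice_index = NULL) {
  N <- map$points_per_slice
  has_band <- vapply(seq_len(map$n_slices), function(i) {
    T <- map$transmurality[(i - 1) * N + seq_len(N)]
    any(T >= cfg$transmurality_low & T <= cfg$transmurality_high)
  }, logical(1))
  if (!any(has_band)) stop("no slice carries an infarct border zone")
  if (is.null(slice_index)) {
    stopifnot(length(position) == 3)
    slice_index <- which.min(abs(map$ring_z - position[3])) - 1L
  }
  zi <- slice_index + 1L
  if (!has_band[zi]) zi <- which(has_band)[which.min(abs(map$ring_z[has_band] - map$ring_z[zi]))]
  oop <- abs(map$ring_z[zi] - if (length(position) == 3) position[3] else map$ring_z[slice_index + 1L])
  idx <- (zi - 1) * N + seq_len(N)
  ring <- map$vertices[idx, 1:2, drop = FALSE]
  T <- map$transmurality[idx]
  seg <- polyline_segments(ring)
  arc <- c(0, cumsum(seg$len))[seq_len(N)]
  L <- sum(seg$len)
  proj <- closest_point_on_polyline(ring, position[1:2])
  s0 <- proj$s
  iv <- band_intervals(arc, L, T, cfg$transmurality_low, cfg$transmurality_high)
  if (!length(iv)) stop("selected slice has no border zone arc")   # cannot happen after has_band
  best <- Inf; best_sign <- 1
  for (x in iv) {
    slo <- x$s[1] %% L; shi <- x$s[2] %% L
    inside <- if (slo <= shi) (s0 >= slo - 1e-9 && s0 <= shi + 1e-9)
              else (s0 >= slo - 1e-9 || s0 <= shi + 1e-9)
    if (inside) { best <- 0; break }
    for (side in 1:2) {
      se <- x$s[side] %% L
      d <- min((s0 - se) %% L, (se - s0) %% L)
      if (d < best) {
        best <- d
        # sign from the bound that clips this endpoint; an unclipped
        # endpoint (band running through the ring start) defaults remote
        best_sign <- if (identical(x$clip[side], "high")) -1 else 1
      }
    }
  }
  structure(best * ifelse(best == 0, 1, best_sign),
            slice_index = zi - 1L, out_of_plane_mm = oop)
}

#' Perpendicular injection depth
#'
#' Distance from the endocardial contour of the injection's slice to
#' the injection point, measured perpendicular to the contour (the
#' point-to-polyline distance). Depth is positive into the wall; an
#' injection on the blood-pool side of the contour is reported with a
#' negative depth and a warning.
#'
#' @param stack a [contour_stack()].
#' @param position length-3 position (mm), or length-2 with
#'   `slice_index`.
#' @param slice_index optional 0-based slice; default nearest slice z.
#' @return Depth in mm (negative = inside the blood pool).
#' @export
injection_depth <- function(stack, position, slice_index = NULL) {
  zs <- vapply(stack$slices, `[[`, numeric(1), "z")
  if (is.null(slice_index)) {
    stopifnot(length(position) == 3)
    slice_index <- which.min(abs(zs - position[3])) - 1L
  }
  endo <- stack$slices[[slice_index + 1L]]$endo
  d <- closest_point_on_polyline(endo, position[1:2])$dist
  # points within 0.01 mm of the contour count as on it: below any
  # measurement precision, and robust to which side of a polygon edge
  # an exactly-on-contour point falls
  if (d > 0.01 && points_in_polygon(endo, matrix(position[1:2], 1))) {
    warning("injection lies on the blood-pool side of the endocardium")
    d <- -d
  }
  d
}

#' Read retrieved injection positions
#'
#' CSV with columns `animal_id`, `x`, `y`, `z` (mm), optional `group`
#' (e.g. comparator vs planned) and optional 0-based `slice_index`.
#'
#' @param path CSV path.
#' @return A data frame of injection records.
#' @export
read_injections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "x", "y", "z")
  if (nrow(df) && !all(need %in% names(df)))
    stop("injections CSV needs columns: ", paste(need, collapse = ", "))
  df
}

#' Evaluate a set of injections against a map
#'
#' Computes the signed border-zone distance and perpendicular depth for
#' every injection record.
#'
#' @param map a populated `endo_map`.
#' @param stack the matching [contour_stack()].
#' @param cfg a [planner_config()].
#' @param injections data frame from [read_injections()].
#' @return The input data frame with `distance_to_ibz`, `depth` and
#'   `out_of_plane_mm` columns appended.
#' @export
evaluate_injections <- function(map, stack, cfg, injections) {
  n <- nrow(injections)
  dist <- depth <- oop <- numeric(n)
  for (i in seq_len(n)) {
    pos <- as.numeric(injections[i, c("x", "y", "z")])
    si <- if ("slice_index" %in% names(injections)) injections$slice_index[i] else NULL
    d <- signed_ibz_distance(map, pos, cfg, slice_index = si)
    dist[i] <- as.numeric(d)
    oop[i] <- attr(d, "out_of_plane_mm")
    depth[i] <- injection_depth(stack, pos, slice_index = si)
  }
  cbind(injections, distance_to_ibz = dist, depth = depth, out_of_plane_mm = oop)
}

#' Per-animal summary of repeated injections
#'
#' Repeated measurements are reduced to one mean per animal before any
#' group comparison, so animals -- not injections -- are the unit of
#' analysis. The grand mean of a group is therefore the mean of animal
#' means, not the pooled injection mean.
#'
#' @param records data frame with `animal_id`, `distance_to_ibz`,
#'   `depth` and optionally `group`.
#' @return One row per animal: `animal_id`, `group` (if present), `n`,
#'   `mean_distance`, `mean_depth`.
#' @export
per_animal_summary <- function(records) {
  if (!nrow(records))
    return(data.frame(animal_id = character(0), n = integer(0),
                      mean_distance = numeric(0), mean_depth = numeric(0)))
  ids <- unique(records$animal_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    r <- records[records$animal_id == id, ]
    data.frame(animal_id = id,
               group = if ("group" %in% names(r)) r$group[1] else NA_character_,
               n = nrow(r),
               mean_distance = mean(r$distance_to_ibz),
               mean_depth = mean(r$depth))
  }))
  rownames(out) <- NULL
  if (all(is.na(out$group))) out$group <- NULL
  out
}
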