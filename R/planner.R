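#' Planner configuration
#'
#' Operating thresholds of the injection planner. The infarct border
#' zone (IBZ) is the region with transmurality between
#' `transmurality_low` and `transmurality_high` (both inclusive, per the
#' 1–20% convention) and wall thickness strictly above `wt_min`; regions
#' with transmurality above `transmurality_high` (dense scar) or wall
#' thickness strictly below `wt_min` (perforation risk) are danger
#' zones. A wall of exactly `wt_min` is neither. Targets are split
#' between the septal and anterior sides of the infarct per
#' `sector_split`, and the needle extension at each target is
#' `needle_depth_fraction` of the local wall thickness (half, following
#' the convention that the needle is set to half the wall thickness
#' measured on MRI).
#'
#' `septal_direction` must be supplied by the user (the phantom emits
#' it): it is the in-slice unit vector pointing into the middle of the
#' septal side, and vertices within 90 degrees of it are labelled
#' septal, the rest anterior.
#'
#' @param transmurality_low,transmurality_high IBZ transmurality band, %.
#' @param wt_min minimum wall thickness for injection, mm.
#' @param n_targets total number of targets.
#' @param sector_split named integer vector, targets per sector; must sum
#'   to `n_targets`.
#' @param needle_depth_fraction needle depth as a fraction of local wall
#'   thickness, in `(0, 1]`.
#' @param septal_direction in-slice unit 2-vector toward the septum.
#' @return An object of class `planner_config`.
#' @export
planner_config <- function(transmurality_low = 1, transmurality_high = 20,
                           wt_min = 5, n_targets = 16,
                           sector_split = c(septal = 8, anterior = 8),
                           needle_depth_fraction = 0.5,
                           septal_direction) {
  if (missing(septal_direction) || is.null(septal_direction))
    stop("septal_direction is required (the phantom truth supplies one)")
  stopifnot(length(septal_direction) == 2)
  septal_direction <- septal_direction / sqrt(sum(septal_direction^2))
  if (!(transmurality_low >= 0 && transmurality_low < transmurality_high &&
        transmurality_high <= 100))
    stop("need 0 <= transmurality_low < transmurality_high <= 100")
  if (wt_min <= 0) stop("wt_min must be positive")
  if (needle_depth_fraction <= 0 || needle_depth_fraction > 1)
    stop("needle_depth_fraction must be in (0, 1]")
  if (sum(sector_split) != n_targets)
    stop("sector_split must sum to n_targets")
  if (is.null(names(sector_split)) || any(!nzchar(names(sector_split))))
    stop("sector_split must be named")
  structure(list(transmurality_low = transmurality_low,
                 transmurality_high = transmurality_high,
                 wt_min = wt_min, n_targets = as.integer(n_targets),
                 sector_split = sector_split,
                 needle_depth_fraction = needle_depth_fraction,
                 septal_direction = septal_direction),
            class = "planner_config")
}

#' Classify mesh vertices into border zone, danger zone and neutral
#'
#' Applies the IBZ and danger-zone predicates to a populated surface
#' map. IBZ: `low <= T <= high` and `WT > wt_min`. Danger: `T > high` or
#' `WT < wt_min`. Everything else (including `T` below the band floor
#' and walls of exactly `wt_min`) is neutral. The two sets are disjoint
#' by construction.
#'
#' @param map a populated `endo_map`.
#' @param cfg a [planner_config()].
#' @return List with integer vertex indices `ibz` and `danger` (1-based).
#' @export
classify_vertices <- function(map, cfg) {
  if (anyNA(map$transmurality) || anyNA(map$wall_thickness))
    stop("map scalars are not populated; run endo_surface_map() first")
  T <- map$transmurality; WT <- map$wall_thickness
  ibz <- which(T >= cfg$transmurality_low & T <= cfg$transmurality_high &
                 WT > cfg$wt_min)
  danger <- which(T > cfg$transmurality_high | WT < cfg$wt_min)
  list(ibz = ibz, danger = danger)
}

# Sector label per vertex: septal when the vertex direction lies within
# 90 degrees of septal_direction (boundary inclusive), anterior otherwise.
#' @keywords internal
vertex_sectors <- function(map, cfg) {
  a <- deg2rad(map$angle)
  d <- cbind(cos(a), sin(a))
  dp <- d %*% cfg$septal_direction
  ifelse(dp >= -1e-12, "septal", "anterior")
}

#' Assign injection targets in the infarct border zone
#'
#' Selects `n_targets` injection targets from the IBZ vertices, split
#' between the septal and anterior sectors. Within each sector, targets
#' are spread by greedy farthest-point sampling under the 3-D Euclidean
#' metric, seeded at the IBZ vertex whose in-slice angle is closest to
#' the sector's angular centre; the greedy rule is deterministic (ties
#' break toward the lowest vertex index), achieves the classic factor-2
#' dispersion bound, and matches the intent of "equally distributed"
#' targets without requiring a stated placement algorithm. Needle depth
#' per target is `needle_depth_fraction` times the local wall thickness.
#'
#' @param map a populated `endo_map`.
#' @param cfg a [planner_config()].
#' @return Object of class `target_plan`: data frame `targets` (vertex,
#'   position, slice, angle, sector, wall thickness, transmurality,
#'   needle depth), vertex index sets `ibz_vertices` and
#'   `danger_vertices`, and the `config`.
#' @export
assign_targets <- function(map, cfg) {
  zones <- classify_vertices(map, cfg)
  sectors <- vertex_sectors(map, cfg)
  septal_angle <- rad2deg(atan2(cfg$septal_direction[2], cfg$septal_direction[1]))
  chosen <- integer(0)
  for (sec in names(cfg$sector_split)) {
    want <- cfg$sector_split[[sec]]
    members <- zones$ibz[sectors[zones$ibz] == sec]
    if (length(members) < want)
      stop(sprintf("sector '%s': only %d IBZ vertices for %d requested targets (deficit %d); lower n_targets or widen the band",
                   sec, length(members), want, want - length(members)))
    center <- if (sec == "septal") septal_angle else septal_angle + 180
    off <- abs(wrap_angle(map$angle[members] - center))
    seedv <- members[order(off, members)[1]]
    chosen <- c(chosen, farthest_point_sample(map$vertices, members, seedv, want))
  }
  t_idx <- chosen
  targets <- data.frame(vertex = t_idx,
                        x = map$vertices[t_idx, 1],
                        y = map$vertices[t_idx, 2],
                        z = map$vertices[t_idx, 3],
                        slice_index = map$slice_index[t_idx],
                        angle = map$angle[t_idx],
                        sector = sectors[t_idx],
                        wall_thickness = map$wall_thickness[t_idx],
                        transmurality = map$transmurality[t_idx],
                        needle_depth = cfg$needle_depth_fraction * map$wall_thickness[t_idx],
                        row.names = NULL)
  structure(list(targets = targets, ibz_vertices = zones$ibz,
                 danger_vertices = zones$danger, config = cfg),
            class = "target_plan")
}

# Greedy k-dispersion: start from seed, repeatedly add the candidate
# farthest from the chosen set (ties -> lowest index).
#' @keywords internal
farthest_point_sample <- function(vertices, candidates, seed_vertex, k) {
  chosen <- seed_vertex
  pool <- setdiff(candidates, seed_vertex)
  mind <- sqrt(rowSums((vertices[pool, , drop = FALSE] -
                          matrix(vertices[seed_vertex, ], length(pool), 3, byrow = TRUE))^2))
  while (length(chosen) < k) {
    best <- pool[order(-mind, pool)[1]]
    chosen <- c(chosen, best)
    if (length(chosen) == k) break
    keep <- pool != best
    pool <- pool[keep]; mind <- mind[keep]
    d <- sqrt(rowSums((vertices[pool, , drop = FALSE] -
                         matrix(vertices[best, ], length(pool), 3, byrow = TRUE))^2))
    mind <- pmin(mind, d)
  }
  chosen
}

#' @export
print.target_plan <- function(x, ...) {
  cat(sprintf("target_plan: %d targets (%s), %d IBZ / %d danger vertices\n",
              nrow(x$targets),
              paste(sprintf("%s %d", names(table(x$targets$sector)),
                            table(x$targets$sector)), collapse = ", "),
              length(x$ibz_vertices), length(x$danger_vertices)))
  invisible(x)
}

#' Read and write target plans as JSON
#'
#' The plan JSON holds exact millimetre coordinates and is the
#' authoritative record of a plan; it contains no timestamps, so
#' rerunning a pipeline with the same configuration and seed reproduces
#' it byte for byte.
#'
#' @param plan a `target_plan`.
#' @param path file path.
#' @return `read_plan` returns a `target_plan` (without the original
#'   `planner_config` closure fields beyond what JSON can carry).
#' @export
write_plan <- function(plan, path) {
  cfg <- plan$config
  out <- list(targets = plan$targets,
              ibz_vertices = plan$ibz_vertices,
              danger_vertices = plan$danger_vertices,
              config = list(transmurality_low = cfg$transmurality_low,
                            transmurality_high = cfg$transmurality_high,
                            wt_min = cfg$wt_min, n_targets = cfg$n_targets,
                            sector_split = as.list(cfg$sector_split),
                            needle_depth_fraction = cfg$needle_depth_fraction,
                            septal_direction = cfg$septal_direction))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  raw <- jsonlite::fromJSON(path)
  cfg <- raw$config
  structure(list(targets = raw$targets,
                 ibz_vertices = as.integer(raw$ibz_vertices),
                 danger_vertices = as.integer(raw$danger_vertices),
                 config = planner_config(cfg$transmurality_low, cfg$transmurality_high,
                                         cfg$wt_min, cfg$n_targets,
                                         unlist(cfg$sector_split),
                                         cfg$needle_depth_fraction,
                                         unlist(cfg$septal_direction))),
            class = "target_plan")
}
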