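#' Pipeline configuration
#'
#' Assembles (and validates) the configuration of a full planning run:
#' input paths, planner thresholds, segmentation options, registration
#' options, phantom parameters and the global seed. Every field has a
#' default, so a configuration resolves without any file; values can
#' come from a YAML or JSON file via `config_file` with individual
#' overrides on top.
#'
#' When `paths$image` is `NULL`, the run is a self-contained phantom
#' run: the synthetic volume, contours and septal direction are
#' generated (and written) instead of read.
#'
#' @param config_file optional YAML/JSON file of settings.
#' @param paths list: `image`, `contours`, `septal`, `ra_cloud`
#'   (all optional inputs) and `out_dir`.
#' @param planner list of [planner_config()] arguments
#'   (`septal_direction` may be omitted when the phantom supplies it).
#' @param scarseg list: `min_component_px`, `reference`, `scope`.
#' @param registration list: `max_iter`, `tol`, `trim_fraction`.
#' @param phantom list of [phantom_spec()] arguments.
#' @param points_per_slice mesh resolution.
#' @param seed integer seed for every stochastic element of the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config_file = NULL, paths = list(), planner = list(),
                            scarseg = list(), registration = list(),
                            phantom = list(), points_per_slice = 120, seed = 1) {
  base <- list(paths = list(image = NULL, contours = NULL, septal = NULL,
                            ra_cloud = NULL, out_dir = "cartoplan_out"),
               planner = list(), scarseg = list(min_component_px = 5,
                                                reference = "min", scope = "slice"),
               registration = list(max_iter = 100, tol = 1e-4, trim_fraction = 0.2,
                                   source_points_per_slice = 240),
               phantom = list(), points_per_slice = points_per_slice, seed = seed)
  if (!is.null(config_file)) {
    ext <- tolower(tools::file_ext(config_file))
    filed <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(config_file)
             else jsonlite::fromJSON(config_file, simplifyVector = TRUE)
    base <- modify_list_deep(base, filed)
  }
  cfg <- modify_list_deep(base, list(paths = paths, planner = planner,
                                     scarseg = scarseg, registration = registration,
                                     phantom = phantom))
  if (!missing(seed) || is.null(cfg$seed)) cfg$seed <- seed
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' @keywords internal
modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && length(new[[nm]]) == 0) next  # empty override: keep defaults
    if (is.list(new[[nm]]) && is.list(base[[nm]]) && !is.null(names(new[[nm]])))
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}

# stable hash of the configuration for provenance records
#' @keywords internal
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(strip_functions(unclass(config)),
                              auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' @keywords internal
strip_functions <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.list(x)) return(lapply(x, strip_functions))
  x
}

#' Run the full planning pipeline
#'
#' Executes scar segmentation, surface mapping, target planning and
#' export in order, writing every artifact under
#' `config$paths$out_dir`: the phantom inputs (for a phantom run), the
#' endocardial mesh as PLY with per-vertex transmurality and wall
#' thickness, the plan JSON (byte-stable across reruns of the same
#' configuration and seed), one DICOM treatment series plus JSON
#' sidecar per target, a run manifest with the configuration hash and,
#' when an interventional cloud is supplied, the registration result
#' and the transformed plan.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the `plan`, `map`, `stack`,
#'   `scar`, `geometry`, optional `registration`, and `artifacts`
#'   (paths).
#' @export
run_plan <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$paths
  # validate inputs before writing anything
  phantom_run <- is.null(p$image)
  if (!phantom_run) {
    if (!file.exists(p$image) && !dir.exists(p$image))
      stop(sprintf("stage input: image path '%s' does not exist", p$image))
    if (is.null(p$contours) || !file.exists(p$contours))
      stop(sprintf("stage input: contours path '%s' does not exist",
                   p$contours %||% "<missing>"))
  }
  out <- p$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()

  if (phantom_run) {
    spec <- do.call(phantom_spec, modify_list_deep(list(seed = config$seed),
                                                   config$phantom))
    phantom <- generate_phantom(spec)
    artifacts$phantom <- write_phantom(phantom, file.path(out, "phantom"))
    volume <- phantom$volume
    stack <- phantom$truth$contours
    septal <- phantom$truth$septal_direction
  } else {
    volume <- read_lge_series(p$image)
    stack <- read_contours(p$contours)
    septal <- config$planner$septal_direction
    if (!is.null(p$septal))
      septal <- unlist(jsonlite::fromJSON(p$septal)$septal_direction)
    if (is.null(septal))
      stop("stage planner: septal_direction must come from the config or a septal file")
  }
  geometry <- volume[c("dim", "spacing", "origin", "orientation")]

  myo <- with_stage("segment-scar", rasterize_myocardium(stack, geometry))
  scar <- with_stage("segment-scar",
    fwhm_segment(volume$data, myo,
                 min_component_px = config$scarseg$min_component_px,
                 reference = config$scarseg$reference,
                 scope = config$scarseg$scope))
  map <- with_stage("map",
    endo_surface_map(stack, scar, geometry, config$points_per_slice))
  pl_args <- config$planner
  pl_args$septal_direction <- septal
  cfg <- do.call(planner_config, pl_args)
  plan <- with_stage("plan", assign_targets(map, cfg))

  hash <- config_hash(config)
  artifacts$mesh <- file.path(out, "endo_mesh.ply")
  write_ply(map$vertices, artifacts$mesh, faces = map$faces,
            vertex_props = data.frame(transmurality = map$transmurality,
                                      wall_thickness = map$wall_thickness))
  artifacts$plan <- file.path(out, "plan.json")
  write_plan(plan, artifacts$plan)
  artifacts$thresholds <- file.path(out, "fwhm_thresholds.csv")
  utils::write.csv(data.frame(slice_index = seq_along(scar$threshold_used) - 1L,
                              threshold = scar$threshold_used),
                   artifacts$thresholds, row.names = FALSE)
  artifacts$dicom <- file.path(out, "treatment_datasets")
  with_stage("export-dicom",
    write_treatment_datasets(plan, map, geometry, artifacts$dicom,
                             config_hash = hash))

  registration <- NULL
  if (!is.null(p$ra_cloud)) {
    cloud <- if (grepl("\\.ply$", p$ra_cloud)) read_ply(p$ra_cloud)$vertices
             else read_cloud_csv(p$ra_cloud)
    source_pts <- do.call(rbind, lapply(stack$slices, function(s)
      cbind(resample_closed_polyline(s$epi, config$registration$source_points_per_slice), s$z)))
    registration <- with_stage("register",
      register_to_ra(source_pts, cloud,
                     max_iter = config$registration$max_iter,
                     tol = config$registration$tol,
                     trim_fraction = config$registration$trim_fraction))
    plan_ra <- apply_transform(plan, registration$transform)
    artifacts$plan_registered <- file.path(out, "plan_registered.json")
    write_plan(plan_ra, artifacts$plan_registered)
  }

  manifest <- list(config_hash = hash,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = config$seed,
                   n_targets = nrow(plan$targets),
                   registration_rms_mm = if (is.null(registration)) NULL else registration$rms)
  artifacts$manifest <- file.path(out, "run_manifest.json")
  jsonlite::write_json(manifest, artifacts$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(plan = plan, map = map, stack = stack, scar = scar,
                 geometry = geometry, registration = registration,
                 artifacts = artifacts))
}

#' @keywords internal
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Evaluate retrieved injections against a plan
#'
#' Computes per-injection signed border-zone distance and depth,
#' per-animal means and — when two groups are present — the unpaired
#' t-test comparisons on the animal means, writing each table as CSV
#' under the run's output directory. An empty injections file produces
#' empty outputs and a warning, not an error.
#'
#' @param run a [run_plan()] result (or a list with `map`, `stack` and
#'   the planner config in `plan$config`).
#' @param injections_csv CSV of retrieved injections
#'   ([read_injections()] format).
#' @param out_dir output directory; defaults alongside the run.
#' @return Invisibly, list with `per_injection`, `per_animal`,
#'   `comparison` (or NULL).
#' @export
run_evaluate <- function(run, injections_csv, out_dir = "cartoplan_eval") {
  injections <- read_injections(injections_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!nrow(injections)) {
    warning("no injections in input; writing empty outputs")
    empty <- injections
    utils::write.csv(empty, file.path(out_dir, "per_injection.csv"), row.names = FALSE)
    utils::write.csv(per_animal_summary(empty), file.path(out_dir, "per_animal.csv"),
                     row.names = FALSE)
    return(invisible(list(per_injection = empty,
                          per_animal = per_animal_summary(empty),
                          comparison = NULL)))
  }
  per_inj <- evaluate_injections(run$map, run$stack, run$plan$config, injections)
  per_animal <- per_animal_summary(per_inj)
  comparison <- NULL
  if ("group" %in% names(per_animal) && length(unique(per_animal$group)) == 2 &&
      all(table(per_animal$group) >= 2)) {
    gs <- unique(per_animal$group)
    a <- per_animal[per_animal$group == gs[1], ]
    b <- per_animal[per_animal$group == gs[2], ]
    comparison <- do.call(rbind, lapply(c("mean_distance", "mean_depth"), function(v) {
      r <- ttest_from_samples(a[[v]], b[[v]])
      data.frame(endpoint = v, group1 = gs[1], group2 = gs[2],
                 mean1 = mean(a[[v]]), sd1 = stats::sd(a[[v]]),
                 mean2 = mean(b[[v]]), sd2 = stats::sd(b[[v]]),
                 t = r$statistic, df = r$df, p = r$p)
    }))
    utils::write.csv(comparison, file.path(out_dir, "group_comparison.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(per_inj, file.path(out_dir, "per_injection.csv"), row.names = FALSE)
  utils::write.csv(per_animal, file.path(out_dir, "per_animal.csv"), row.names = FALSE)
  invisible(list(per_injection = per_inj, per_animal = per_animal,
                 comparison = comparison))
}
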