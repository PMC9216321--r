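#' Run configuration for the pipeline commands
#'
#' A run configuration is a plain named list (serializable to JSON) that
#' fully determines a pipeline run together with its seeds. The pipeline
#' commands [cmd_phantom()], [cmd_field()], [cmd_curve()], [cmd_simulate()],
#' [cmd_calibrate()] and [cmd_select()] each take such a configuration (or a
#' path to its JSON file) and are idempotent given identical inputs and
#' seeds; field libraries are cached in the output directory keyed by the
#' parameters they depend on.
#'
#' @param out_dir output directory
#' @param seed integer master seed
#' @param ... overrides merged over the defaults (nested lists are merged
#'   shallowly per top-level key)
#' @return the configuration list
#' @export
default_run_config <- function(out_dir = "magrecruit_run", seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    phantom = list(length = 0.18, outer_radius = 0.065, bone_radius = 0.012,
                   fat_thickness = 0.008, skin_thickness = 0.002,
                   voxel_pitch = 0.002),
    coils = list(
      round = list(type = "circular", mean_radius = 0.045, n_turns = 10,
                   turn_spacing = 0.0015, n_segments = 64),
      racetrack = list(type = "racetrack", straight_length = 0.08,
                       end_radius = 0.04, n_turns = 8, turn_spacing = 0.0015,
                       n_segments = 64),
      figure_eight = list(type = "figure_eight", wing_radius = 0.035,
                          n_turns = 9, turn_spacing = 0.0015,
                          n_segments = 64),
      saddle = list(type = "saddle", arc_radius = 0.07, arc_angle = 140,
                    axial_length = 0.13, n_turns = 6, turn_spacing = 0.002,
                    n_segments = 128)
    ),
    distances_mm = c(0, 5, 10, 15),
    placement = list(azimuth_deg = 0, z_centre = 0.12, rotation_deg = 5,
                     z_centre_saddle = 0.09),
    drive = list(frequency = 5000, peak_current = 3000),
    solver = list(method = "cg", tol = 1e-8),
    apl_coil = "saddle",
    design = list(
      conditions = data.frame(
        coil = c("round", "round", "saddle", "saddle"),
        distance_mm = c(0, 10, 5, 10), stringsAsFactors = FALSE),
      amplitudes = seq(0.1, 1, length.out = 15),
      missing_prob = 0),
    population = list(n_subjects = 10, e_th = 65, force_median = 3e5,
                      force_sdlog = 0.25, apl0_sd = 0.003, noise_cv = 0.1),
    models = c("1A", "1B", "2A", "2B")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    # shallow per-key merge; data.frames (e.g. design$conditions) are
    # replaced wholesale, never merged element-wise
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) &&
        !is.data.frame(cfg[[nm]]) && !is.data.frame(dots[[nm]])) {
      for (k in names(dots[[nm]])) cfg[[nm]][[k]] <- dots[[nm]][[k]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' @rdname default_run_config
#' @param path JSON file written by [write_run_config()]
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$design$conditions))
    cfg$design$conditions <- as.data.frame(cfg$design$conditions)
  cfg
}

#' @rdname default_run_config
#' @param config a configuration list
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

as_config <- function(config) {
  if (is.character(config)) read_run_config(config) else config
}

make_coil_from_config <- function(cc) {
  switch(cc$type,
    circular = make_circular_coil(cc$mean_radius, cc$n_turns,
                                  cc$turn_spacing, cc$n_segments),
    racetrack = make_racetrack_coil(cc$straight_length, cc$end_radius,
                                    cc$n_turns, cc$turn_spacing,
                                    cc$n_segments),
    figure_eight = make_figure_eight_coil(cc$wing_radius, cc$n_turns,
                                          turn_spacing = cc$turn_spacing,
                                          n_segments = cc$n_segments),
    saddle = make_saddle_coil(cc$arc_radius, cc$arc_angle, cc$axial_length,
                              cc$n_turns, cc$turn_spacing, cc$n_segments),
    stop("unknown coil type: ", cc$type))
}

config_phantom <- function(config) {
  p <- config$phantom
  build_cylindrical_phantom(phantom_spec(
    length = p$length, outer_radius = p$outer_radius,
    bone_radius = p$bone_radius, fat_thickness = p$fat_thickness,
    skin_thickness = p$skin_thickness, voxel_pitch = p$voxel_pitch))
}

# content key for the field-library cache
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Pipeline commands
#'
#' Thin command layer over the package functions, suitable for scripting a
#' whole study from a single JSON configuration. `cmd_phantom` writes the
#' labelled anatomy; `cmd_field` solves and caches the field library;
#' `cmd_curve` writes predicted recruitment curves per (coil, distance);
#' `cmd_simulate` writes a synthetic observation table with its ground
#' truth; `cmd_calibrate` fits the requested model variants and writes one
#' JSON per fit; `cmd_select` writes the BIC ranking.
#'
#' @param config a configuration list from [default_run_config()] or the
#'   path to its JSON file
#' @return the created object, invisibly (commands also write files under
#'   `config$out_dir`)
#' @export
cmd_phantom <- function(config) {
  config <- as_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  anatomy <- config_phantom(config)
  write_anatomy(anatomy, file.path(config$out_dir, "anatomy.nii.gz"))
  message("anatomy: ", paste(dim(anatomy$labels), collapse = "x"),
          " voxels -> ", file.path(config$out_dir, "anatomy.nii.gz"))
  invisible(anatomy)
}

#' @rdname cmd_phantom
#' @export
cmd_field <- function(config) {
  config <- as_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  key <- config_hash(config[c("phantom", "coils", "distances_mm",
                              "placement", "drive", "solver")])
  cache <- file.path(config$out_dir, paste0("field_library_", key, ".rds"))
  if (file.exists(cache)) {
    message("field library cache hit: ", cache)
    return(invisible(readRDS(cache)))
  }
  anatomy <- config_phantom(config)
  coils <- lapply(config$coils, make_coil_from_config)
  pl <- config$placement
  placements <- lapply(names(coils), function(cn) {
    zc <- if (cn == config$apl_coil && !is.null(pl$z_centre_saddle))
      pl$z_centre_saddle else pl$z_centre
    coil_placement(pl$azimuth_deg, zc, 0, pl$rotation_deg)
  })
  names(placements) <- names(coils)
  lib <- build_field_library(
    anatomy, coils, distances_mm = config$distances_mm,
    placement = placements,
    drive = pulse_drive(config$drive$frequency, config$drive$peak_current),
    config = solver_config(config$solver$method, config$solver$tol),
    keep_fields = FALSE)
  saveRDS(lib, cache)
  message("field library: ", length(lib$entries), " entries -> ", cache)
  invisible(lib)
}

#' @rdname cmd_phantom
#' @export
cmd_curve <- function(config) {
  config <- as_config(config)
  lib <- cmd_field(config)
  spec <- recruitment_model_spec("cross_section",
                                 apl_coil = config$apl_coil)
  params <- parameter_set(e_th = config$population$e_th,
                          force_scale = c(S01 = config$population$force_median))
  amplitudes <- config$design$amplitudes
  curves <- list()
  for (cn in lib$coils)
    for (d in lib$distances[[cn]])
      curves[[entry_key(cn, d)]] <-
        recruitment_curve(spec, params, lib, cn, d, amplitudes)
  path <- file.path(config$out_dir, "curves.csv")
  write_curves(curves, path)
  message("recruitment curves -> ", path)
  invisible(curves)
}

#' @rdname cmd_phantom
#' @export
cmd_simulate <- function(config) {
  config <- as_config(config)
  lib <- cmd_field(config)
  pop_cfg <- config$population
  pspec <- population_spec(pop_cfg$n_subjects, pop_cfg$e_th,
                           pop_cfg$force_median, pop_cfg$force_sdlog,
                           pop_cfg$apl0_sd, pop_cfg$noise_cv,
                           seed = config$seed)
  population <- generate_population(pspec)
  design <- design_spec(config$design$conditions, config$design$amplitudes,
                        config$design$missing_prob)
  gen_model <- model_by_name(config$gen_model %||% "1A",
                             apl_coil = config$apl_coil)
  obs <- generate_observations(population, design, gen_model, lib,
                               seed = config$seed + 1L,
                               e_th = pop_cfg$e_th,
                               noise_cv = pop_cfg$noise_cv)
  path <- file.path(config$out_dir, "observations.csv")
  write_observations(obs, path)
  message("observations: ", nrow(obs), " records -> ", path)
  invisible(obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname cmd_phantom
#' @export
cmd_calibrate <- function(config) {
  config <- as_config(config)
  lib <- cmd_field(config)
  obs_path <- file.path(config$out_dir, "observations.csv")
  obs <- if (file.exists(obs_path)) read_observations(obs_path)
         else cmd_simulate(config)
  fits <- list()
  for (mn in config$models) {
    spec <- model_by_name(mn, apl_coil = config$apl_coil)
    fit <- fit_model(spec, obs, lib, fit_control(seed = config$seed))
    write_fit_result(fit, file.path(config$out_dir,
                                    paste0("fit_", mn, ".json")))
    fits[[mn]] <- fit
    message("model ", mn, ": L = ", round(fit$logLik, 2),
            ", BIC = ", round(fit$bic, 2))
  }
  invisible(fits)
}

#' @rdname cmd_phantom
#' @export
cmd_select <- function(config) {
  config <- as_config(config)
  paths <- file.path(config$out_dir, paste0("fit_", config$models, ".json"))
  if (!all(file.exists(paths))) {
    missing <- paths[!file.exists(paths)]
    stop("missing fit result(s); run cmd_calibrate first. Expected: ",
         paste(missing, collapse = ", "))
  }
  fits <- lapply(paths, jsonlite::fromJSON)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, logLik = f$logLik, k = f$k, n = f$n,
               bic = f$bic, e_th = f$e_th, stringsAsFactors = FALSE)))
  tab <- tab[order(tab$bic, tab$k), ]
  rownames(tab) <- NULL
  jsonlite::write_json(tab, file.path(config$out_dir, "ranking.json"),
                       auto_unbox = TRUE, digits = NA)
  message("ranking -> ", file.path(config$out_dir, "ranking.json"))
  tab
}
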