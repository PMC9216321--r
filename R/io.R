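#' Write / read a labelled anatomy as NIfTI plus JSON sidecar
#'
#' The label grid is stored as an integer NIfTI image with the voxel pitch
#' in the header (millimetres, the NIfTI convention); region and muscle
#' compartment metadata (tissue classes, pennation angles, fiber axes,
#' extensor membership) go to a JSON sidecar next to the image.
#'
#' @param anatomy an [anatomy_volume()]
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `read_anatomy` returns an [anatomy_volume()]
#' @export
write_anatomy <- function(anatomy, path) {
  img <- RNifti::asNifti(anatomy$labels,
                         pixdim = anatomy$voxel_pitch * 1000)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(origin_m = anatomy$origin,
                            voxel_pitch_m = anatomy$voxel_pitch,
                            regions = anatomy$regions,
                            compartments = anatomy$compartments),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_anatomy
#' @export
read_anatomy <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::fromJSON(sub("\\.nii(\\.gz)?$", ".json", path))
  anatomy_volume(array(as.integer(img), dim = dim(img)),
                 voxel_pitch = side$voxel_pitch_m,
                 origin = side$origin_m,
                 regions = side$regions,
                 compartments = side$compartments)
}

#' Write / read a coil winding as CSV polylines plus JSON metadata
#'
#' @param winding a [coil_winding()]
#' @param path output CSV path (`loop_id`, `vertex_index`, `x`, `y`, `z` in
#'   metres); metadata goes to a `.json` next to it
#' @return `read_coil` returns a [coil_winding()]
#' @export
write_coil <- function(winding, path) {
  rows <- do.call(rbind, lapply(seq_along(winding$loops), function(i) {
    v <- winding$loops[[i]]
    data.frame(loop_id = i, vertex_index = seq_len(nrow(v)),
               x = v[, 1], y = v[, 2], z = v[, 3])
  }))
  write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(list(topology = winding$topology,
                            frame = winding$frame, turns = winding$turns,
                            meta = winding$meta),
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coil
#' @export
read_coil <- function(path) {
  rows <- read.csv(path)
  meta <- jsonlite::fromJSON(sub("\\.csv$", ".json", path))
  loops <- lapply(split(rows, rows$loop_id), function(d) {
    d <- d[order(d$vertex_index), ]
    unname(as.matrix(d[, c("x", "y", "z")]))
  })
  coil_winding(unname(loops), topology = meta$topology, frame = meta$frame,
               meta = meta$meta)
}

#' Write / read an observation table as CSV
#'
#' Missing forces are written as blank cells; on reading, rows with blank
#' force are dropped (missing records carry no information for the
#' likelihood).
#'
#' @param observations an [observation_table()]
#' @param path CSV path
#' @return `read_observations` returns an [observation_table()]
#' @export
write_observations <- function(observations, path) {
  write.csv(as.data.frame(observations), path, row.names = FALSE, na = "")
  gt <- attr(observations, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(gt, sub("\\.csv$", "_truth.json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- df[!is.na(df$force_N), , drop = FALSE]
  observation_table(df)
}

#' Write a field solution's magnitude volume as NIfTI
#'
#' @param solution a `field_solution` from [solve_field()]
#' @param path output `.nii`/`.nii.gz` path
#' @export
write_field_magnitude <- function(solution, path) {
  E <- solution$Emag
  E[!solution$body] <- 0
  img <- RNifti::asNifti(E, pixdim = solution$pitch * 1000)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a full field solution as NIfTI volumes plus diagnostics JSON
#'
#' Writes `phi.nii.gz`, `Emag.nii.gz` and the three field components
#' `E_x/E_y/E_z.nii.gz` (zero outside the body) plus `diagnostics.json`
#' (solver method, iterations, residuals) into a directory.
#'
#' @param solution a `field_solution` from [solve_field()]
#' @param dir output directory (created if needed)
#' @export
write_field_solution <- function(solution, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- solution$pitch * 1000
  wr <- function(vol, name) {
    vol[!solution$body] <- 0
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = px),
                       file.path(dir, name))
  }
  wr(solution$phi, "phi.nii.gz")
  wr(solution$Emag, "Emag.nii.gz")
  for (a in 1:3)
    wr(solution$E[, , , a], paste0("E_", c("x", "y", "z")[a], ".nii.gz"))
  jsonlite::write_json(solution$diagnostics,
                       file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write / read a field library as NIfTI volumes with a JSON manifest
#'
#' Each entry's unit-amplitude field magnitude goes to
#' `<coil>_<distance>mm.nii.gz`; the manifest records coils, distances and
#' the drive normalization. Reading requires the anatomy the library was
#' built on (the threshold profiles are reconstructed from it), and the
#' library must have been written with its field volumes retained
#' (`keep_fields = TRUE`).
#'
#' @param library a `field_library` built with `keep_fields = TRUE`
#' @param dir output directory
#' @return `read_field_library` returns a `field_library`
#' @export
write_field_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (key in names(library$entries)) {
    e <- library$entries[[key]]
    if (is.null(e$Emag))
      stop("library was built with keep_fields = FALSE; nothing to write")
    fn <- paste0(e$coil, "_", e$distance_mm, "mm.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(e$Emag), file.path(dir, fn))
    files[[key]] <- list(coil = e$coil, distance_mm = e$distance_mm,
                         file = fn)
  }
  jsonlite::write_json(list(coils = library$coils,
                            distances = library$distances,
                            drive = library$drive, entries = files),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_field_library
#' @param anatomy the [anatomy_volume()] the library was built on
#' @param slice_pitch plane spacing for the reconstructed section scan (m)
#' @export
read_field_library <- function(dir, anatomy, slice_pitch = NULL) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  volumes <- list()
  for (e in man$entries) {
    img <- RNifti::readNifti(file.path(dir, e$file))
    volumes[[e$coil]][[as.character(e$distance_mm)]] <-
      array(as.numeric(img), dim = dim(img))
  }
  lib <- field_library_from_volumes(anatomy, volumes, slice_pitch)
  lib$drive <- man$drive
  lib
}

#' Write a fit result as JSON
#'
#' @param fit a `recruit_fit`
#' @param path output JSON path
#' @export
write_fit_result <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$model_name, logLik = fit$logLik, k = fit$k, n = fit$n,
         bic = fit$bic,
         e_th = fit$params$e_th, noise_scale = fit$params$noise_scale,
         force_scale = as.list(fit$params$force_scale),
         apl0 = as.list(fit$params$apl0),
         diagnostics = fit$diagnostics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write recruitment curves as CSV
#'
#' @param curves a `recruitment_curve` or list of them
#' @param path output CSV path (`coil`, `distance_mm`, `amplitude`,
#'   `force_N`)
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "recruitment_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cu)
    data.frame(coil = attr(cu, "coil"), distance_mm = attr(cu, "distance_mm"),
               amplitude = cu$amplitude, force_N = cu$force_N)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
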