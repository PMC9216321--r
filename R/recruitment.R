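#' Recruitment model specification
#'
#' Identifies one of the four candidate force-recruitment models by its force
#' basis and whether the per-subject distance offset of the conforming
#' (saddle/APL-type) coil is enabled:
#' model 1A = cross-section basis, no shift; 1B = cross-section + shift;
#' 2A = volume basis, no shift; 2B = volume + shift.
#'
#' @param force_basis `"cross_section"` (activated pennation-corrected
#'   cross-sectional area, `F = f_i * A_eff`) or `"volume"` (activated
#'   volume, `F = v_i * V_eff`)
#' @param apl_shift logical; allow a per-subject effective-distance offset
#'   for the conforming coil
#' @param apl_coil name of the coil the offset applies to
#' @param slice_pitch plane spacing of the cross-section scan (m); default
#'   the voxel pitch
#' @return an object of class `recruitment_model_spec`
#' @export
recruitment_model_spec <- function(force_basis = c("cross_section", "volume"),
                                   apl_shift = FALSE, apl_coil = "saddle",
                                   slice_pitch = NULL) {
  force_basis <- match.arg(force_basis)
  structure(list(force_basis = force_basis, apl_shift = apl_shift,
                 apl_coil = apl_coil, slice_pitch = slice_pitch),
            class = "recruitment_model_spec")
}

#' @rdname recruitment_model_spec
#' @param name `"1A"`, `"1B"`, `"2A"` or `"2B"`
#' @export
model_by_name <- function(name, apl_coil = "saddle", slice_pitch = NULL) {
  switch(toupper(name),
    "1A" = recruitment_model_spec("cross_section", FALSE, apl_coil, slice_pitch),
    "1B" = recruitment_model_spec("cross_section", TRUE, apl_coil, slice_pitch),
    "2A" = recruitment_model_spec("volume", FALSE, apl_coil, slice_pitch),
    "2B" = recruitment_model_spec("volume", TRUE, apl_coil, slice_pitch),
    stop("unknown model name: ", name))
}

#' @exportS3Method base::print
print.recruitment_model_spec <- function(x, ...) {
  nm <- model_name(x)
  cat(sprintf("recruitment model %s: %s basis, distance shift %s\n", nm,
              x$force_basis, if (x$apl_shift) "on" else "off"))
  invisible(x)
}

model_name <- function(spec) {
  paste0(if (spec$force_basis == "cross_section") "1" else "2",
         if (spec$apl_shift) "B" else "A")
}

#' Parameter set of a recruitment model
#'
#' @param e_th threshold electric-field magnitude (V/m), shared across
#'   subjects
#' @param force_scale named numeric, one entry per subject: force per area
#'   `f_i` (N/m^2, cross-section basis) or force per volume `v_i` (N/m^3,
#'   volume basis)
#' @param apl0 named numeric, per-subject effective-distance offset of the
#'   conforming coil (m); 0 when the shift is disabled
#' @param noise_scale observation noise standard deviation (N)
#' @return an object of class `parameter_set`
#' @export
parameter_set <- function(e_th, force_scale, apl0 = NULL, noise_scale = 1) {
  stopifnot(e_th > 0, all(force_scale >= 0), noise_scale > 0)
  if (is.null(names(force_scale)))
    names(force_scale) <- paste0("S", seq_along(force_scale))
  if (is.null(apl0)) apl0 <- setNames(rep(0, length(force_scale)),
                                      names(force_scale))
  structure(list(e_th = e_th, force_scale = force_scale, apl0 = apl0,
                 noise_scale = noise_scale), class = "parameter_set")
}

#' Supra-threshold activation mask
#'
#' The local threshold condition of the recruitment model: a voxel is active
#' when the induced field magnitude at output fraction `x` strictly exceeds
#' the threshold, `x * ||E_unit(r)|| > E_th`, restricted to the extensor
#' muscle compartments. The comparison is strict (the tie set has measure
#' zero; strictness fixes the convention for exact tests).
#'
#' @param E_unit 3D array of unit-amplitude field magnitude (V/m at x = 1)
#' @param anatomy an [anatomy_volume()]
#' @param e_th threshold field (V/m)
#' @param x output fraction in `[0, 1]`
#' @return logical 3D array
#' @export
supra_threshold_mask <- function(E_unit, anatomy, e_th, x) {
  stopifnot(e_th > 0, x >= 0)
  if (!identical(dim(E_unit), dim(anatomy$labels)))
    stop("field grid does not match the anatomy grid")
  ext <- anatomy$labels %in% extensor_ids(anatomy)
  m <- array(FALSE, dim(anatomy$labels))
  if (x > 0) {
    v <- x * E_unit > e_th
    v[is.na(v)] <- FALSE
    m <- v & array(ext, dim(anatomy$labels))
  }
  m
}

#' Pennation-tilted section scan geometry
#'
#' Precomputes, for every extensor muscle compartment, the nearest-voxel
#' sampling of planes perpendicular to that muscle's pennation-tilted fiber
#' axis: planes are spaced `slice_pitch` apart along the axis and rasterised
#' at voxel-pitch resolution; each raster pixel is mapped to the voxel
#' containing it (kept only if that voxel belongs to the muscle). The
#' mapping depends only on the anatomy, so it is shared across coils and
#' reused by the field library.
#'
#' @param anatomy an [anatomy_volume()]
#' @param slice_pitch plane spacing (m); default `min(voxel_pitch)`
#' @return list of per-muscle profiles: `planes` (list of integer voxel
#'   index vectors), `pixel_area` (m^2)
#' @export
section_profiles <- function(anatomy, slice_pitch = NULL) {
  p <- anatomy$voxel_pitch
  if (is.null(slice_pitch)) slice_pitch <- min(p)
  d <- dim(anatomy$labels)
  ax <- voxel_axes(anatomy)
  comp <- anatomy$compartments[anatomy$compartments$extensor, , drop = FALSE]
  raster_pitch <- min(p)
  out <- list()
  for (r in seq_len(nrow(comp))) {
    id <- comp$id[r]
    vox <- which(anatomy$labels == id)
    if (!length(vox)) {
      out[[comp$name[r]]] <- list(planes = list(), pixel_area = raster_pitch^2)
      next
    }
    ijk <- arrayInd(vox, d)
    centers <- cbind(ax$x[ijk[, 1]], ax$y[ijk[, 2]], ax$z[ijk[, 3]])
    u <- c(comp$axis_x[r], comp$axis_y[r], comp$axis_z[r])
    u <- u / sqrt(sum(u^2))
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- c(u[2] * ref[3] - u[3] * ref[2], u[3] * ref[1] - u[1] * ref[3],
            u[1] * ref[2] - u[2] * ref[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    s <- centers %*% u
    a <- centers %*% e1
    b <- centers %*% e2
    s_planes <- seq(min(s), max(s), by = slice_pitch)
    a_grid <- seq(min(a), max(a), by = raster_pitch)
    b_grid <- seq(min(b), max(b), by = raster_pitch)
    ab <- cbind(rep(a_grid, times = length(b_grid)),
                rep(b_grid, each = length(a_grid)))
    base <- ab[, 1, drop = FALSE] %*% rbind(e1) + ab[, 2, drop = FALSE] %*% rbind(e2)
    planes <- vector("list", length(s_planes))
    for (k in seq_along(s_planes)) {
      pts <- base + matrix(s_planes[k] * u, nrow(base), 3, byrow = TRUE)
      i <- floor((pts[, 1] - anatomy$origin[1]) / p[1]) + 1
      j <- floor((pts[, 2] - anatomy$origin[2]) / p[2]) + 1
      kk <- floor((pts[, 3] - anatomy$origin[3]) / p[3]) + 1
      ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & kk >= 1 & kk <= d[3]
      lin <- i[ok] + (j[ok] - 1) * d[1] + (kk[ok] - 1) * d[1] * d[2]
      lin <- lin[anatomy$labels[lin] == id]
      planes[[k]] <- as.integer(lin)
    }
    out[[comp$name[r]]] <- list(planes = planes, pixel_area = raster_pitch^2)
  }
  out
}

#' Activated effective cross-section
#'
#' For each extensor muscle, scans the planes perpendicular to that muscle's
#' pennation-tilted fiber axis and takes the plane with the largest
#' supra-threshold intersection area; the contributions of the muscles are
#' summed over the extensor group (parallel fiber recruitment sums across
#' muscles).
#'
#' @param mask logical 3D activation mask (see [supra_threshold_mask()])
#' @param anatomy an [anatomy_volume()]
#' @param profiles optional precomputed [section_profiles()]
#' @param slice_pitch plane spacing (m) when `profiles` is not supplied
#' @return effective cross-sectional area `A_eff` (m^2)
#' @export
effective_cross_section <- function(mask, anatomy, profiles = NULL,
                                    slice_pitch = NULL) {
  if (is.null(profiles)) profiles <- section_profiles(anatomy, slice_pitch)
  total <- 0
  mv <- as.vector(mask)
  for (pr in profiles) {
    if (!length(pr$planes)) next
    counts <- vapply(pr$planes, function(idx)
      if (length(idx)) sum(mv[idx]) else 0L, numeric(1))
    total <- total + max(counts) * pr$pixel_area
  }
  total
}

#' Activated effective volume
#'
#' Supra-threshold voxel count times the voxel volume, over the extensor
#' group (the mask is already restricted to it).
#'
#' @inheritParams effective_cross_section
#' @return activated volume `V_eff` (m^3)
#' @export
effective_volume <- function(mask, anatomy) {
  sum(mask) * voxel_volume(anatomy)
}

# ---- field library ---------------------------------------------------------

# exact step-function representation of count(values > t):
# breaks = sorted unique values; for t in [breaks[i], breaks[i+1]) the count
# equals count(values > breaks[i]); n0 is the count for t < breaks[1]
step_counts <- function(breaks, values) {
  n <- length(values)
  if (!n) return(rep(0, length(breaks)))
  n - findInterval(breaks, sort(values))
}

step_lookup <- function(t, breaks, counts, n0) {
  i <- findInterval(t, breaks)
  ifelse(i == 0L, n0, counts[pmax(i, 1L)])
}

#' Build a field library over coils and lift distances
#'
#' Runs the full field pipeline (placement, Biot-Savart, finite-volume
#' solve) for every coil at every lift distance and stores, per (coil,
#' distance), the unit-amplitude field-magnitude volume together with
#' precomputed threshold profiles: exact step functions of the
#' supra-threshold plane areas (per muscle, max over planes) and of the
#' supra-threshold extensor volume, so that `A_eff` and `V_eff` can be
#' evaluated for any threshold in microseconds during calibration.
#'
#' @param anatomy an [anatomy_volume()]
#' @param coils named list of unplaced [coil_winding()]s
#' @param distances_mm numeric vector of lift distances in mm (default
#'   `c(0, 5, 10, 15)`), or a named list giving a vector per coil
#' @param placement base [coil_placement()], or a named list with one
#'   placement per coil (the `lift` is overridden by the distances)
#' @param drive a [pulse_drive()] at full output (`x = 1`)
#' @param config a [solver_config()]
#' @param table a [tissue_table()]
#' @param slice_pitch plane spacing for the section scan (m)
#' @param keep_fields keep the full `Emag` arrays in the library (needed for
#'   mask-level work; the calibration path only needs the profiles)
#' @return an object of class `field_library`
#' @export
build_field_library <- function(anatomy, coils,
                                distances_mm = c(0, 5, 10, 15),
                                placement = coil_placement(),
                                drive = pulse_drive(),
                                config = solver_config(),
                                table = default_tissue_table(),
                                slice_pitch = NULL, keep_fields = TRUE) {
  stopifnot(is.list(coils), !is.null(names(coils)))
  if (!is.list(distances_mm))
    distances_mm <- setNames(rep(list(sort(distances_mm)), length(coils)),
                             names(coils))
  profiles <- section_profiles(anatomy, slice_pitch)
  ext <- which(anatomy$labels %in% extensor_ids(anatomy))
  entries <- list()
  for (cn in names(coils)) {
    ds <- sort(distances_mm[[cn]])
    if (any(duplicated(ds))) stop("duplicate distances for coil ", cn)
    for (d_mm in ds) {
      pl <- if (inherits(placement, "coil_placement")) placement
            else placement[[cn]]
      pl$lift <- d_mm / 1000
      placed <- place_coil(coils[[cn]], pl, anatomy)
      sol <- solve_field(anatomy, placed, drive, config, table)
      entries[[entry_key(cn, d_mm)]] <-
        library_entry(cn, d_mm, sol$Emag, anatomy, profiles, ext, keep_fields)
    }
  }
  structure(list(entries = entries,
                 coils = names(coils),
                 distances = lapply(distances_mm, sort),
                 profiles = profiles,
                 voxel_volume = voxel_volume(anatomy),
                 anatomy_dim = dim(anatomy$labels),
                 drive = unclass(drive)),
            class = "field_library")
}

#' Assemble a field library from precomputed field volumes
#'
#' Lower-level companion of [build_field_library()] for field-magnitude
#' volumes obtained elsewhere (an external solver, or constructed in tests):
#' takes unit-amplitude `||E||` arrays keyed by coil and distance and
#' precomputes the same threshold profiles.
#'
#' @param anatomy an [anatomy_volume()]
#' @param volumes nested named list: `volumes[[coil]][[as.character(d_mm)]]`
#'   is a 3D `||E||` array on the anatomy grid (V/m at full output)
#' @param slice_pitch plane spacing for the section scan (m)
#' @param keep_fields keep the `Emag` arrays in the entries
#' @return a `field_library`
#' @export
field_library_from_volumes <- function(anatomy, volumes, slice_pitch = NULL,
                                       keep_fields = TRUE) {
  profiles <- section_profiles(anatomy, slice_pitch)
  ext <- which(anatomy$labels %in% extensor_ids(anatomy))
  entries <- list()
  distances <- list()
  for (cn in names(volumes)) {
    ds <- sort(as.numeric(names(volumes[[cn]])))
    distances[[cn]] <- ds
    for (d_mm in ds) {
      Emag <- volumes[[cn]][[as.character(d_mm)]]
      if (!identical(dim(Emag), dim(anatomy$labels)))
        stop("field volume grid mismatch for ", cn, " at ", d_mm, " mm")
      entries[[entry_key(cn, d_mm)]] <-
        library_entry(cn, d_mm, Emag, anatomy, profiles, ext, keep_fields)
    }
  }
  structure(list(entries = entries, coils = names(volumes),
                 distances = distances, profiles = profiles,
                 voxel_volume = voxel_volume(anatomy),
                 anatomy_dim = dim(anatomy$labels), drive = NULL),
            class = "field_library")
}

entry_key <- function(coil, d_mm) paste0(coil, "@", format(d_mm))

# precompute the exact threshold step functions for one field volume
library_entry <- function(coil, d_mm, Emag, anatomy, profiles, ext_idx,
                          keep_fields) {
  ev <- as.vector(Emag)
  muscles <- list()
  for (mn in names(profiles)) {
    pr <- profiles[[mn]]
    if (!length(pr$planes)) next
    vals <- sort(unique(unlist(lapply(pr$planes, function(idx) ev[idx]))))
    mx <- rep(0, length(vals))
    n0 <- 0
    for (idx in pr$planes) {
      if (!length(idx)) next
      v <- ev[idx]
      mx <- pmax(mx, step_counts(vals, v))
      n0 <- max(n0, length(v))
    }
    muscles[[mn]] <- list(breaks = vals, max_counts = mx, n0 = n0,
                          pixel_area = pr$pixel_area)
  }
  vol_vals <- sort(ev[ext_idx])
  e <- list(coil = coil, distance_mm = d_mm, muscles = muscles,
            vol_values = vol_vals)
  if (keep_fields) e$Emag <- Emag
  e
}

#' @exportS3Method base::print
print.field_library <- function(x, ...) {
  cat("field_library:", length(x$entries), "entries on a",
      paste(x$anatomy_dim, collapse = " x "), "grid\n")
  for (cn in x$coils)
    cat("  ", cn, ": d =", paste(x$distances[[cn]], collapse = ", "), "mm\n")
  invisible(x)
}

# A_eff(t): sum over muscles of max-plane supra-threshold area at field
# threshold t (V/m, unit amplitude)
a_eff_entry <- function(entry, t) {
  total <- 0
  for (m in entry$muscles)
    total <- total + step_lookup(t, m$breaks, m$max_counts, m$n0) * m$pixel_area
  total
}

# V_eff(t): supra-threshold extensor volume at threshold t
v_eff_entry <- function(entry, t, vox_vol) {
  v <- entry$vol_values
  (length(v) - findInterval(t, v)) * vox_vol
}

# basis value g(t) at (coil, effective distance), linearly interpolated
# between the bracketing library distances; errors outside the span
basis_value <- function(library, spec, coil, d_eff_mm, t) {
  ds <- library$distances[[coil]]
  if (is.null(ds)) stop("coil not in the field library: ", coil)
  tol <- 1e-9
  if (d_eff_mm < ds[1] - tol || d_eff_mm > ds[length(ds)] + tol)
    stop(sprintf(
      "effective distance %.2f mm outside the library range [%g, %g] for coil %s (no extrapolation)",
      d_eff_mm, ds[1], ds[length(ds)], coil))
  d_eff_mm <- min(max(d_eff_mm, ds[1]), ds[length(ds)])
  i <- findInterval(d_eff_mm, ds)
  i <- min(max(i, 1L), length(ds) - if (length(ds) > 1) 1L else 0L)
  g_at <- function(d_mm) {
    e <- library$entries[[entry_key(coil, d_mm)]]
    if (spec$force_basis == "cross_section") a_eff_entry(e, t)
    else v_eff_entry(e, t, library$voxel_volume)
  }
  if (length(ds) == 1L || abs(d_eff_mm - ds[i]) < tol) return(g_at(ds[i]))
  if (abs(d_eff_mm - ds[i + 1]) < tol) return(g_at(ds[i + 1]))
  w <- (d_eff_mm - ds[i]) / (ds[i + 1] - ds[i])
  (1 - w) * g_at(ds[i]) + w * g_at(ds[i + 1])
}

#' Predict the noiseless force response
#'
#' Model mean of the recruitment model: `f_i * A_eff` (cross-section basis)
#' or `v_i * V_eff` (volume basis) at threshold `E_th / x`, where for the
#' conforming coil with the shift enabled the effective distance is
#' `d + APL0_i`, resolved by linear interpolation between the two bracketing
#' library distances.
#'
#' @param spec a [recruitment_model_spec()]
#' @param params a [parameter_set()]
#' @param library a [build_field_library()]
#' @param coil coil name
#' @param d_mm nominal coil-skin distance (mm)
#' @param x output fraction(s) in `[0, 1]` (vectorized)
#' @param subject subject id (name into the parameter vectors)
#' @return predicted force(s) in newtons (noiseless model mean)
#' @export
predict_force <- function(spec, params, library, coil, d_mm, x, subject) {
  fi <- params$force_scale[[subject]]
  if (is.null(fi) || is.na(fi)) stop("no force scale for subject ", subject)
  d_eff <- d_mm
  if (spec$apl_shift && identical(coil, spec$apl_coil)) {
    a0 <- params$apl0[[subject]]
    if (!is.null(a0) && !is.na(a0)) d_eff <- d_mm + a0 * 1000
  }
  vapply(x, function(xi) {
    if (xi <= 0 || fi <= 0) return(0)
    fi * basis_value(library, spec, coil, d_eff, params$e_th / xi)
  }, numeric(1))
}

#' Recruitment curve of a coil condition
#'
#' Evaluates the noiseless force over an amplitude grid and reports the
#' threshold amplitude (first nonzero force) and the saturation amplitude
#' (first amplitude reaching 99% of the full-output force) as attributes.
#'
#' @inheritParams predict_force
#' @param amplitudes numeric vector of output fractions
#' @return a `data.frame` (class `recruitment_curve`) with columns
#'   `amplitude` and `force_N`; attributes `threshold_amplitude`,
#'   `saturation_amplitude`, `coil`, `distance_mm`
#' @export
recruitment_curve <- function(spec, params, library, coil, d_mm, amplitudes,
                              subject = names(params$force_scale)[1]) {
  amplitudes <- sort(amplitudes)
  f <- predict_force(spec, params, library, coil, d_mm, amplitudes, subject)
  f_full <- predict_force(spec, params, library, coil, d_mm, 1, subject)
  thr <- amplitudes[which(f > 0)[1]]
  sat <- amplitudes[which(f >= 0.99 * f_full)[1]]
  out <- data.frame(amplitude = amplitudes, force_N = f)
  attr(out, "threshold_amplitude") <- if (length(thr)) thr else NA_real_
  attr(out, "saturation_amplitude") <- if (length(sat)) sat else NA_real_
  attr(out, "coil") <- coil
  attr(out, "distance_mm") <- d_mm
  class(out) <- c("recruitment_curve", "data.frame")
  out
}
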