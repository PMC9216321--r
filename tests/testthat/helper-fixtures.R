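# shared fixtures, built in code; expensive objects are cached per session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

# homogeneous or radially layered conducting cylinder along z
cylinder_anatomy <- function(R = 0.03, Lz = 0.06, pitch = 0.002,
                             layered = FALSE, fat_frac = 0.3) {
  n <- ceiling(2 * R / pitch) + 2L
  nz <- ceiling(Lz / pitch) + 2L
  ax <- ((seq_len(n)) - 0.5 - n / 2) * pitch
  r2 <- outer(ax^2, ax^2, "+")
  sl <- array(0L, c(n, n))
  sl[r2 < R^2] <- if (layered) 2L else 4L
  if (layered) sl[r2 < ((1 - fat_frac) * R)^2] <- 4L
  lab <- array(0L, c(n, n, nz))
  for (k in 2:(nz - 1)) lab[, , k] <- sl
  regions <- data.frame(id = c(2L, 4L), name = c("fat", "muscle"),
                        tissue = c("fat", "muscle"))
  anatomy_volume(lab, rep(pitch, 3),
                 origin = c(-n / 2 * pitch, -n / 2 * pitch, -nz / 2 * pitch),
                 regions = regions)
}

# uniform axial dB/dt imposed as dA/dt = dBdt * (-y/2, x/2, 0)
uniform_axial_dAdt <- function(anatomy, dBdt = 1) {
  d <- dim(anatomy$labels)
  ax <- voxel_axes(anatomy)
  X <- array(rep(ax$x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax$y, each = d[1]), times = d[3]), d)
  dA <- array(0, c(d, 3))
  dA[, , , 1] <- -Y / 2 * dBdt
  dA[, , , 2] <- X / 2 * dBdt
  dA
}

# solve the imposed-drive problem on an anatomy, returning fields + system
solve_imposed <- function(anatomy, dAdt, config = solver_config()) {
  sigma <- conductivity_volume(anatomy)
  f <- assemble_source(sigma, dAdt, anatomy$voxel_pitch)
  sys <- assemble_operator(sigma, anatomy$voxel_pitch)
  sol <- solve_potential(sys, f, config, sigma = sigma)
  E <- electric_field(sol$phi, dAdt, sys$body, anatomy$voxel_pitch)
  Emag <- sqrt(E[, , , 1]^2 + E[, , , 2]^2 + E[, , , 3]^2)
  list(phi = sol$phi, E = E, Emag = Emag, dAdt = dAdt, body = sys$body,
       sigma = sigma, system = sys, f = f, pitch = anatomy$voxel_pitch,
       iterations = sol$iterations, residual = sol$residual)
}

# axis-aligned cuboid muscle (single extensor compartment), 1-voxel padding
cuboid_muscle_anatomy <- function(nx = 10, ny = 8, nz = 30, pitch = 0.001,
                                  pennation_deg = 0) {
  lab <- array(0L, c(nx + 2L, ny + 2L, nz + 2L))
  lab[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- 1L
  regions <- data.frame(id = 1L, name = "cuboid", tissue = "muscle")
  pen <- pennation_deg * pi / 180
  comp <- data.frame(id = 1L, name = "cuboid", pennation_deg = pennation_deg,
                     axis_x = sin(pen), axis_y = 0, axis_z = cos(pen),
                     extensor = TRUE)
  anatomy_volume(lab, rep(pitch, 3), origin = c(0, 0, 0), regions = regions,
                 compartments = comp)
}

# library over a cuboid muscle with prescribed field volumes
cuboid_library <- function(anatomy, fields) {
  field_library_from_volumes(anatomy, fields)
}

# coarse calibration library: small phantom (thicker skin so a 4 mm grid
# resolves every layer), two coils at two distances each; cheap enough for
# unit tests of the calibration machinery
unit_library <- function() {
  cached("unit_library", function() {
    wedges <- default_muscle_wedges()
    an <- build_cylindrical_phantom(phantom_spec(
      length = 0.12, outer_radius = 0.052, bone_radius = 0.012,
      fat_thickness = 0.008, skin_thickness = 0.004,
      muscle_wedges = wedges, voxel_pitch = 0.004))
    coils <- list(round = make_circular_coil(0.04, 4, 0.002, 64),
                  saddle = make_saddle_coil(0.056, 140, 0.09, 3, 0.002, 64))
    placements <- list(round = coil_placement(0, 0.08, 0, 5),
                       saddle = coil_placement(0, 0.06, 0, 5))
    build_field_library(an, coils,
                        distances_mm = list(round = c(0, 10),
                                            saddle = c(0, 5, 10)),
                        placement = placements, keep_fields = TRUE)
  })
}

unit_design <- function(amplitudes = seq(0.1, 1, length.out = 12),
                        missing_prob = 0) {
  design_spec(data.frame(coil = c("round", "round", "saddle"),
                         distance_mm = c(0, 10, 5),
                         stringsAsFactors = FALSE),
              amplitudes = amplitudes, missing_prob = missing_prob)
}

# full-resolution study library used by the acceptance suite (2 mm pitch,
# 2 mm skin, four coils); built once per session
study_library <- function() {
  cached("study_library", function() {
    an <- build_cylindrical_phantom(phantom_spec(
      length = 0.18, outer_radius = 0.065, voxel_pitch = 0.002))
    coils <- list(
      round = make_circular_coil(0.045, 10, 0.0015, 64),
      saddle = make_saddle_coil(0.07, 140, 0.13, 6, 0.002, 128),
      figure_eight = make_figure_eight_coil(0.035, 9, turn_spacing = 0.0015,
                                            n_segments = 64))
    placements <- list(round = coil_placement(0, 0.12, 0, 5),
                       saddle = coil_placement(0, 0.09, 0, 5),
                       figure_eight = coil_placement(0, 0.12, 0, 5))
    build_field_library(an, coils,
                        distances_mm = list(round = c(0, 10),
                                            saddle = c(0, 5, 10, 15),
                                            figure_eight = 0),
                        placement = placements, keep_fields = FALSE)
  })
}

study_design <- function(amplitudes = seq(0.1, 1, length.out = 15),
                         missing_prob = 0) {
  design_spec(data.frame(coil = c("round", "round", "saddle", "saddle"),
                         distance_mm = c(0, 10, 5, 10),
                         stringsAsFactors = FALSE),
              amplitudes = amplitudes, missing_prob = missing_prob)
}
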