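#' Labelled voxel anatomy
#'
#' Container for a labelled voxel volume: an integer label grid (0 =
#' background/air), the voxel pitch in metres, the position of the grid
#' origin (lower corner of voxel `[1,1,1]`), a region table mapping label ids
#' to tissue classes, and per-muscle compartment metadata (pennation angle,
#' fiber axis, extensor-group membership). Voxel `[i,j,k]` spans the
#' half-open box `[origin + (i-1)*pitch, origin + i*pitch)` along each axis.
#'
#' @param labels integer 3D array of region ids; 0 is background
#' @param voxel_pitch numeric length-3, voxel edge lengths (m)
#' @param origin numeric length-3, coordinates of the grid corner (m)
#' @param regions `data.frame` with columns `id`, `name`, `tissue`
#' @param compartments `data.frame` with columns `id`, `name`,
#'   `pennation_deg`, `axis_x`, `axis_y`, `axis_z`, `extensor` (one row per
#'   muscle region; the fiber axis is a unit vector)
#' @return an object of class `anatomy_volume`
#' @export
anatomy_volume <- function(labels, voxel_pitch, origin = c(0, 0, 0),
                           regions, compartments = NULL) {
  stopifnot(length(dim(labels)) == 3)
  voxel_pitch <- rep_len(as.numeric(voxel_pitch), 3)
  if (any(voxel_pitch <= 0)) stop("voxel pitch must be > 0")
  labels <- array(as.integer(labels), dim = dim(labels))
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0L]
  if (!all(ids %in% regions$id))
    stop("labels present in the grid but missing from the region table: ",
         paste(setdiff(ids, regions$id), collapse = ", "))
  # background must pad every face so that boundary stencils never wrap
  d <- dim(labels)
  faces <- c(labels[1, , ], labels[d[1], , ], labels[, 1, ], labels[, d[2], ],
             labels[, , 1], labels[, , d[3]])
  if (any(faces != 0L))
    stop("anatomy must have at least one background voxel on every face")
  if (is.null(compartments)) {
    compartments <- data.frame(id = integer(), name = character(),
                               pennation_deg = numeric(), axis_x = numeric(),
                               axis_y = numeric(), axis_z = numeric(),
                               extensor = logical())
  }
  structure(list(labels = labels, voxel_pitch = voxel_pitch,
                 origin = as.numeric(origin), regions = regions,
                 compartments = compartments),
            class = "anatomy_volume")
}

#' @exportS3Method base::print
print.anatomy_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat("anatomy_volume:", paste(d, collapse = " x "), "voxels, pitch",
      paste(signif(x$voxel_pitch * 1e3, 4), collapse = " x "), "mm\n")
  tab <- table(factor(x$labels, levels = c(0L, x$regions$id),
                      labels = c("background", x$regions$name)))
  for (nm in names(tab)) cat(sprintf("  %-18s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' @rdname anatomy_volume
#' @param anatomy an `anatomy_volume`
#' @return `voxel_volume` returns the volume of one voxel in m^3
#' @export
voxel_volume <- function(anatomy) prod(anatomy$voxel_pitch)

#' Voxel-centre coordinate axes
#'
#' @param anatomy an `anatomy_volume`
#' @return list with numeric vectors `x`, `y`, `z` of voxel-centre
#'   coordinates (m)
#' @export
voxel_axes <- function(anatomy) {
  d <- dim(anatomy$labels)
  p <- anatomy$voxel_pitch
  o <- anatomy$origin
  list(x = o[1] + (seq_len(d[1]) - 0.5) * p[1],
       y = o[2] + (seq_len(d[2]) - 0.5) * p[2],
       z = o[3] + (seq_len(d[3]) - 0.5) * p[3])
}

#' Extensor-group region ids
#' @param anatomy an `anatomy_volume`
#' @return integer vector of region ids in the extensor group
#' @export
extensor_ids <- function(anatomy) {
  anatomy$compartments$id[anatomy$compartments$extensor]
}

#' Default quadriceps / flexor wedge layout
#'
#' Angular layout of the muscle compartments of the cylindrical thigh
#' phantom. The four quadriceps heads occupy the anterior half (azimuth
#' measured from +x, the anterior direction) and carry their physiological
#' pennation angles with respect to the femur axis: +10 deg rectus femoris,
#' +8 deg vastus lateralis, -8 deg vastus intermedius, +15 deg vastus
#' medialis. The posterior half is filled by flexor/adductor wedges that are
#' anatomically present but carry no force parameter (not in the extensor
#' group). The angular extents are free parameters of the phantom; the
#' defaults are plausible, not subject-specific.
#'
#' @return `data.frame` with columns `name`, `extent_deg`, `pennation_deg`,
#'   `extensor`
#' @export
default_muscle_wedges <- function() {
  data.frame(
    name = c("rectus_femoris", "vastus_lateralis", "vastus_intermedius",
             "vastus_medialis", "biceps_femoris", "semitendinosus",
             "semimembranosus", "adductor_group"),
    extent_deg = c(50, 45, 40, 45, 60, 40, 40, 40),
    pennation_deg = c(10, 8, -8, 15, 0, 0, 0, 0),
    extensor = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Specification of the cylindrical thigh phantom
#'
#' Concentric tissue layout along the femur (z) axis: bone core, muscle
#' annulus split into angular wedges, subcutaneous fat, and an
#' approximately 2 mm skin surface layer.
#'
#' @param length phantom extent along the femur axis (m)
#' @param outer_radius outer skin radius (m)
#' @param bone_radius femur radius (m)
#' @param fat_thickness subcutaneous fat layer (m)
#' @param skin_thickness skin layer (m), default 0.002
#' @param muscle_wedges `data.frame` as [default_muscle_wedges()]; extents
#'   must sum to 360 degrees
#' @param voxel_pitch isotropic voxel edge (m)
#' @param start_angle_deg azimuth (deg from +x) where the first wedge starts
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(length = 0.40, outer_radius = 0.07,
                         bone_radius = 0.012, fat_thickness = 0.008,
                         skin_thickness = 0.002,
                         muscle_wedges = default_muscle_wedges(),
                         voxel_pitch = 0.002, start_angle_deg = -90) {
  stopifnot(length > 0, outer_radius > 0, voxel_pitch > 0,
            bone_radius >= 0, fat_thickness >= 0, skin_thickness >= 0)
  if (bone_radius + fat_thickness + skin_thickness > outer_radius)
    stop("layer thicknesses exceed the outer radius: no room for muscle")
  if (abs(sum(muscle_wedges$extent_deg) - 360) > 1e-6)
    stop("muscle wedge extents must partition 360 degrees")
  structure(list(length = length, outer_radius = outer_radius,
                 bone_radius = bone_radius, fat_thickness = fat_thickness,
                 skin_thickness = skin_thickness,
                 muscle_wedges = muscle_wedges, voxel_pitch = voxel_pitch,
                 start_angle_deg = start_angle_deg),
            class = "phantom_spec")
}

#' Build the labelled cylindrical thigh phantom
#'
#' Deterministic concentric assignment by voxel-centre position: bone core,
#' muscle wedges, fat annulus, skin shell, background. The femur axis is the
#' z axis through (x, y) = (0, 0); the grid is padded with one background
#' voxel on every face. Each muscle wedge becomes its own region with a
#' fiber axis obtained by tilting the femur axis by the wedge's pennation
#' angle within the wedge's radial plane (signed angles tilt toward/away
#' from the outward radial direction).
#'
#' @param spec a [phantom_spec()]
#' @return an [anatomy_volume()]
#' @export
build_cylindrical_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  p <- spec$voxel_pitch
  layers <- c(bone = spec$bone_radius, fat = spec$fat_thickness,
              skin = spec$skin_thickness,
              muscle = spec$outer_radius - spec$bone_radius -
                spec$fat_thickness - spec$skin_thickness)
  thin <- layers[layers > 0 & layers < p]
  if (length(thin))
    stop("voxel pitch ", p, " m exceeds layer thickness of: ",
         paste(names(thin), collapse = ", "),
         " - the layer would vanish; reduce the pitch")

  nr <- ceiling(spec$outer_radius / p) + 1L   # +1 voxel background padding
  nx <- 2L * nr + 1L
  nz <- as.integer(ceiling(spec$length / p) + 2L)
  origin <- c(-(nx / 2) * p, -(nx / 2) * p, -p)

  ax_x <- origin[1] + (seq_len(nx) - 0.5) * p
  ax_z <- origin[3] + (seq_len(nz) - 0.5) * p

  # region table: fixed single-tissue regions + one region per muscle wedge
  w <- spec$muscle_wedges
  regions <- data.frame(
    id = seq_len(3L + nrow(w)),
    name = c("bone", "fat", "skin", w$name),
    tissue = c("bone", "fat", "skin", rep("muscle", nrow(w))),
    stringsAsFactors = FALSE
  )
  muscle_ids <- regions$id[-(1:3)]

  r_musc <- spec$outer_radius - spec$fat_thickness - spec$skin_thickness
  r_fat <- spec$outer_radius - spec$skin_thickness

  # wedge boundaries in [0, 360)
  edges <- spec$start_angle_deg + c(0, cumsum(w$extent_deg))

  xy <- expand.grid(x = ax_x, y = ax_x)
  r2 <- xy$x^2 + xy$y^2
  theta <- (atan2(xy$y, xy$x) * 180 / pi - spec$start_angle_deg) %% 360
  wedge <- findInterval(theta, cumsum(w$extent_deg) - 1e-9) + 1L
  wedge[wedge > nrow(w)] <- nrow(w)  # numerical guard at exactly 360

  slice <- integer(nx * nx)
  in_body <- r2 < spec$outer_radius^2
  slice[in_body] <- 3L                               # skin
  slice[r2 < r_fat^2] <- 2L                          # fat
  sel <- r2 < r_musc^2
  slice[sel] <- muscle_ids[wedge[sel]]               # muscle wedges
  if (spec$bone_radius > 0) slice[r2 < spec$bone_radius^2] <- 1L

  labels <- array(0L, dim = c(nx, nx, nz))
  in_z <- ax_z > 0 & ax_z < spec$length
  for (k in which(in_z)) labels[, , k] <- slice

  # fiber axes: femur axis tilted by the pennation angle in the radial plane
  mid <- spec$start_angle_deg + cumsum(w$extent_deg) - w$extent_deg / 2
  pen <- w$pennation_deg * pi / 180
  er <- cbind(cos(mid * pi / 180), sin(mid * pi / 180), 0)
  axis <- cbind(sin(pen) * er[, 1], sin(pen) * er[, 2], cos(pen))
  compartments <- data.frame(
    id = muscle_ids, name = w$name, pennation_deg = w$pennation_deg,
    axis_x = axis[, 1], axis_y = axis[, 2], axis_z = axis[, 3],
    extensor = w$extensor, stringsAsFactors = FALSE
  )

  anatomy_volume(labels, voxel_pitch = c(p, p, p), origin = origin,
                 regions = regions, compartments = compartments)
}

#' Conductivity volume from a labelled anatomy
#'
#' Voxelwise lookup of electrical conductivity: each region's tissue class is
#' looked up in the tissue table; background maps to exactly 0 S/m.
#'
#' @param anatomy an [anatomy_volume()]
#' @param table a [tissue_table()]; default [default_tissue_table()]
#' @return numeric 3D array of conductivities (S/m), same dim as the labels
#' @export
conductivity_volume <- function(anatomy, table = default_tissue_table()) {
  tissues <- anatomy$regions$tissue
  missing <- setdiff(unique(tissues), table$label)
  if (length(missing))
    stop("tissue class(es) missing from the tissue table: ",
         paste(missing, collapse = ", "))
  sigma_by_id <- numeric(max(anatomy$regions$id) + 1L)   # index = id + 1
  sigma_by_id[anatomy$regions$id + 1L] <-
    table$conductivity_S_per_m[match(tissues, table$label)]
  sig <- sigma_by_id[anatomy$labels + 1L]
  array(sig, dim = dim(anatomy$labels))
}
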