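#' Coil windings
#'
#' A coil winding is an ordered set of closed 3D polyline loops, one loop per
#' physical turn (multi-turn coils are represented with each individual turn,
#' not collapsed to a single equivalent loop). Vertex order defines the
#' circulation sense; consecutive vertices are joined by straight segments and
#' the last vertex closes back to the first.
#'
#' @param loops list of numeric `n x 3` matrices of loop vertices (m); the
#'   closing segment from the last to the first vertex is implicit
#' @param topology character tag (`"circular"`, `"racetrack"`,
#'   `"figure_eight"`, `"saddle"`, ...)
#' @param frame `"planar"` (built in the z = 0 plane, normal +z) or
#'   `"cylindrical"` (built conforming to a cylinder about the z axis)
#' @param meta list of builder parameters (kept for serialization)
#' @return an object of class `coil_winding`; `turns` equals the number of
#'   loops
#' @export
coil_winding <- function(loops, topology = "custom", frame = "planar",
                         meta = list()) {
  stopifnot(is.list(loops), length(loops) >= 1)
  for (lp in loops) {
    stopifnot(is.matrix(lp), ncol(lp) == 3, nrow(lp) >= 3)
    seg <- rbind(diff(lp), lp[1, ] - lp[nrow(lp), ])
    if (any(sqrt(rowSums(seg^2)) <= 0)) stop("zero-length segment in loop")
  }
  structure(list(loops = loops, turns = length(loops), topology = topology,
                 frame = frame, meta = meta),
            class = "coil_winding")
}

#' @exportS3Method base::print
print.coil_winding <- function(x, ...) {
  nseg <- sum(vapply(x$loops, nrow, 1L))
  cat("coil_winding:", x$topology, "-", x$turns, "turn(s),", nseg,
      "segments\n")
  invisible(x)
}

# all straight segments of a winding: list(starts, ends, cur) with unit
# signed current per segment (sign from vertex order)
coil_segments <- function(winding) {
  starts <- ends <- NULL
  for (lp in winding$loops) {
    nxt <- rbind(lp[-1, , drop = FALSE], lp[1, , drop = FALSE])
    starts <- rbind(starts, lp)
    ends <- rbind(ends, nxt)
  }
  list(starts = starts, ends = ends, cur = rep(1, nrow(starts)))
}

#' Sinusoidal pulse drive
#'
#' Drive parameters of the stimulator: sinusoid frequency, peak coil current
#' per turn, and the dimensionless stimulator-output fraction `x` in [0, 1].
#' All induced fields are evaluated at the sinusoid's peak slew rate, so the
#' peak of `dA/dt` is `2*pi*frequency` times the peak vector potential, and
#' every field scales linearly in `peak_current * output_fraction`.
#'
#' @param frequency sinusoid frequency (Hz), default 5000
#' @param peak_current peak current per turn (A)
#' @param output_fraction stimulator output fraction `x` in [0, 1]
#' @return an object of class `pulse_drive`
#' @export
pulse_drive <- function(frequency = 5000, peak_current = 3000,
                        output_fraction = 1) {
  # a negative peak current flips the drive polarity (fields negate)
  stopifnot(frequency > 0, is.finite(peak_current),
            output_fraction >= 0, output_fraction <= 1)
  structure(list(frequency = frequency, peak_current = peak_current,
                 output_fraction = output_fraction), class = "pulse_drive")
}

#' Parametric coil builders
#'
#' Build multi-turn windings of the four studied coil topologies as closed
#' polyline loops: a flat circular coil, a flat racetrack (stadium) coil, a
#' flat figure-of-eight coil with counter-circulating wings, and a saddle
#' coil conforming to a cylinder about the z axis. Flat coils are built in
#' the z = 0 plane with their centre at the origin and normal +z; use
#' [place_coil()] to pose them against an anatomy.
#'
#' @param mean_radius mean turn radius (m)
#' @param n_turns number of turns (each modelled as its own loop)
#' @param turn_spacing radial spacing between adjacent turns (m)
#' @param n_segments polygon segments per turn (>= 64)
#' @return a [coil_winding()]
#' @export
make_circular_coil <- function(mean_radius, n_turns = 1,
                               turn_spacing = 0.002, n_segments = 128) {
  stopifnot(mean_radius > 0, n_turns >= 1, n_segments >= 64)
  radii <- mean_radius + (seq_len(n_turns) - (n_turns + 1) / 2) * turn_spacing
  if (any(radii <= 0)) stop("turn spacing too large for the mean radius")
  ang <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  loops <- lapply(radii, function(r) cbind(r * cos(ang), r * sin(ang), 0))
  coil_winding(loops, "circular", meta = list(mean_radius = mean_radius,
               n_turns = n_turns, turn_spacing = turn_spacing))
}

#' @rdname make_circular_coil
#' @param straight_length length of the two straight sections (m); 0
#'   degenerates to a circular turn
#' @param end_radius radius of the semicircular ends (m)
#' @export
make_racetrack_coil <- function(straight_length, end_radius, n_turns = 1,
                                turn_spacing = 0.002, n_segments = 128) {
  stopifnot(straight_length >= 0, end_radius > 0, n_turns >= 1,
            n_segments >= 64)
  radii <- end_radius + (seq_len(n_turns) - (n_turns + 1) / 2) * turn_spacing
  if (any(radii <= 0)) stop("turn spacing too large for the end radius")
  L <- straight_length
  stadium <- function(R) {
    P <- 2 * L + 2 * pi * R
    s <- P * (seq_len(n_segments) - 1) / n_segments
    q <- pi * R / 2  # quarter arc
    pt <- matrix(0, n_segments, 3)
    for (i in seq_len(n_segments)) {
      si <- s[i]
      if (si < q) {                      # right semicircle, upper quarter
        a <- si / R
        pt[i, 1:2] <- c(L / 2 + R * cos(a), R * sin(a))
      } else if (si < q + L) {           # top straight, rightward to leftward
        pt[i, 1:2] <- c(L / 2 - (si - q), R)
      } else if (si < 3 * q + L) {       # left semicircle
        a <- pi / 2 + (si - q - L) / R
        pt[i, 1:2] <- c(-L / 2 + R * cos(a), R * sin(a))
      } else if (si < 3 * q + 2 * L) {   # bottom straight
        pt[i, 1:2] <- c(-L / 2 + (si - 3 * q - L), -R)
      } else {                           # right semicircle, lower quarter
        a <- -pi / 2 + (si - 3 * q - 2 * L) / R
        pt[i, 1:2] <- c(L / 2 + R * cos(a), R * sin(a))
      }
    }
    pt
  }
  loops <- lapply(radii, stadium)
  coil_winding(loops, "racetrack", meta = list(straight_length = L,
               end_radius = end_radius, n_turns = n_turns,
               turn_spacing = turn_spacing))
}

#' @rdname make_circular_coil
#' @param wing_radius radius of each wing (m)
#' @param wing_separation centre-to-centre wing distance (m); the default
#'   `2 * wing_radius` makes the wings tangent
#' @export
make_figure_eight_coil <- function(wing_radius, n_turns = 1,
                                   wing_separation = 2 * wing_radius,
                                   turn_spacing = 0.002, n_segments = 128) {
  stopifnot(wing_radius > 0, wing_separation > 0, n_turns >= 1,
            n_segments >= 64)
  radii <- wing_radius + (seq_len(n_turns) - (n_turns + 1) / 2) * turn_spacing
  if (any(radii <= 0)) stop("turn spacing too large for the wing radius")
  ang <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  right <- lapply(radii, function(r)
    cbind(wing_separation / 2 + r * cos(ang), r * sin(ang), 0))
  # left wing clockwise: opposite circulation, so induced currents add
  # under the wings' meeting line
  left <- lapply(radii, function(r)
    cbind(-wing_separation / 2 + r * cos(-ang), r * sin(-ang), 0))
  coil_winding(c(right, left), "figure_eight",
               meta = list(wing_radius = wing_radius,
                           wing_separation = wing_separation,
                           n_turns = n_turns, turn_spacing = turn_spacing))
}

#' @rdname make_circular_coil
#' @param arc_radius cylinder radius the saddle conforms to (m)
#' @param arc_angle azimuthal extent of the saddle (degrees)
#' @param axial_length axial extent of the saddle (m)
#' @export
make_saddle_coil <- function(arc_radius, arc_angle, axial_length, n_turns = 1,
                             turn_spacing = 0.002, n_segments = 128) {
  stopifnot(arc_radius > 0, arc_angle > 0, arc_angle <= 360,
            axial_length > 0, n_turns >= 1, n_segments >= 64)
  half <- arc_angle / 2 * pi / 180
  n_arc <- max(16L, as.integer(round(n_segments * 0.4)))
  n_leg <- max(4L, as.integer(round(n_segments * 0.1)))
  one <- function(R) {
    a_lo <- seq(-half, half, length.out = n_arc + 1)       # arc at z = -h/2
    a_hi <- rev(a_lo)                                      # arc at z = +h/2
    h <- axial_length / 2
    z_up <- seq(-h, h, length.out = n_leg + 1)
    z_dn <- rev(z_up)
    v <- rbind(
      cbind(R * cos(a_lo), R * sin(a_lo), -h),                 # lower arc ->
      cbind(R * cos(half), R * sin(half), z_up[-1]),           # leg up
      cbind(R * cos(a_hi[-1]), R * sin(a_hi[-1]), h),          # upper arc <-
      cbind(R * cos(-half), R * sin(-half), z_dn[-c(1, n_leg + 1)])  # leg down
    )
    v
  }
  radii <- arc_radius + (seq_len(n_turns) - 1) * turn_spacing
  loops <- lapply(radii, one)
  coil_winding(loops, "saddle", frame = "cylindrical",
               meta = list(arc_radius = arc_radius, arc_angle = arc_angle,
                           axial_length = axial_length, n_turns = n_turns,
                           turn_spacing = turn_spacing))
}

#' Signed area vector of a closed polyline loop
#'
#' Half the sum of consecutive cross products (Newell's formula); its
#' direction is the loop normal by the right-hand rule and its length the
#' enclosed area. Used to check circulation senses.
#'
#' @param vertices `n x 3` matrix of loop vertices
#' @return numeric length-3 area vector (m^2)
#' @export
loop_area_vector <- function(vertices) {
  v <- vertices
  w <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  0.5 * colSums(cbind(v[, 2] * w[, 3] - v[, 3] * w[, 2],
                      v[, 3] * w[, 1] - v[, 1] * w[, 3],
                      v[, 1] * w[, 2] - v[, 2] * w[, 1]))
}

#' Coil placement against the phantom surface
#'
#' A placement poses a winding against the skin of a cylindrical anatomy:
#' contact point given by azimuth (degrees from +x) and axial position,
#' lifted by `lift` metres along the outward surface normal, and laterally
#' rotated about the femur-parallel axis through the contact point.
#'
#' @param azimuth_deg azimuth of the contact point (deg from +x)
#' @param z_centre axial position of the coil centre (m)
#' @param lift coil-skin distance d (m); defaults used in the study are 0,
#'   0.005, 0.010 and 0.015
#' @param rotation_deg lateral rotation (deg, default 5, outward)
#' @return an object of class `coil_placement`
#' @export
coil_placement <- function(azimuth_deg = 0, z_centre = 0.28, lift = 0,
                           rotation_deg = 5) {
  stopifnot(is.finite(lift), lift >= 0)
  structure(list(azimuth_deg = azimuth_deg, z_centre = z_centre, lift = lift,
                 rotation_deg = rotation_deg), class = "coil_placement")
}

# outer body radius of an anatomy (max voxel-centre radius of non-background
# voxels in the mid slice, plus half a pitch)
anatomy_surface_radius <- function(anatomy) {
  d <- dim(anatomy$labels)
  ax <- voxel_axes(anatomy)
  k <- which(apply(anatomy$labels != 0L, 3, any))
  if (!length(k)) stop("anatomy has no body voxels")
  mid <- k[ceiling(length(k) / 2)]
  sl <- anatomy$labels[, , mid] != 0L
  r <- sqrt(outer(ax$x^2, ax$y^2, "+"))
  max(r[sl]) + max(anatomy$voxel_pitch[1:2]) / 2
}

#' Place a coil winding against an anatomy
#'
#' Applies a rigid transform only (all intra-winding distances are
#' preserved): flat coils are laid tangent on the skin surface with their
#' normal along the outward surface normal and their local x axis along the
#' femur axis; cylindrical (saddle) windings are rotated about the femur
#' axis to the target azimuth. The winding is then translated by the lift
#' distance along the outward normal at the contact point and laterally
#' rotated by `rotation_deg` about the femur-parallel axis through the
#' contact point.
#'
#' @param winding a [coil_winding()]
#' @param placement a [coil_placement()]
#' @param anatomy an [anatomy_volume()] providing the surface
#' @return the transformed [coil_winding()]
#' @export
place_coil <- function(winding, placement, anatomy) {
  stopifnot(inherits(winding, "coil_winding"),
            inherits(placement, "coil_placement"))
  ax <- voxel_axes(anatomy)
  zr <- range(ax$z[apply(anatomy$labels != 0L, 3, any)])
  if (placement$z_centre < zr[1] || placement$z_centre > zr[2])
    stop("contact point outside the phantom surface (z = ",
         placement$z_centre, " not in [", signif(zr[1], 3), ", ",
         signif(zr[2], 3), "])")
  R_surf <- anatomy_surface_radius(anatomy)
  th <- placement$azimuth_deg * pi / 180
  er <- c(cos(th), sin(th), 0)
  et <- c(-sin(th), cos(th), 0)
  contact <- R_surf * er + c(0, 0, placement$z_centre)

  transform <- function(v) {
    if (winding$frame == "planar") {
      # local frame -> (z_global, -e_theta, e_r); coil normal becomes e_r
      Rm <- cbind(c(0, 0, 1), -et, er)
      v <- v %*% t(Rm)
      v <- sweep(v, 2, contact + placement$lift * er, "+")
    } else {
      # cylindrical winding: rotate about z to azimuth, shift axially, lift
      Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
      v <- v %*% t(Rz)
      v <- sweep(v, 2, c(0, 0, placement$z_centre) + placement$lift * er, "+")
    }
    if (placement$rotation_deg != 0) {
      rho <- placement$rotation_deg * pi / 180
      Rz <- matrix(c(cos(rho), sin(rho), 0, -sin(rho), cos(rho), 0, 0, 0, 1), 3)
      v <- sweep(sweep(v, 2, contact, "-") %*% t(Rz), 2, contact, "+")
    }
    v
  }
  out <- winding
  out$loops <- lapply(winding$loops, transform)
  out$meta$placement <- unclass(placement)
  out
}

#' Magnetic vector potential and peak slew field of a winding
#'
#' Biot-Savart summation over all straight segments of the winding:
#' `A = (mu0 / 4 pi) * I * sum_segments integral dl / |r - r'|`, with
#' per-turn current `I = peak_current * output_fraction`. For the sinusoidal
#' drive the peak of `dA/dt` is `2 pi f * A`; the returned `dAdt` is that
#' peak (in V/m), the source term of the eddy-current solve via
#' `E = -dA/dt - grad phi`.
#'
#' @param winding a [coil_winding()]
#' @param drive a [pulse_drive()]
#' @param points `n x 3` matrix of evaluation points (m)
#' @param guard minimum allowed point-wire distance (m); points closer than
#'   this raise an error (singular kernel). Set 0 to disable the check.
#' @return list with `A` (`n x 3`, V s/m) and `dAdt` (`n x 3`, V/m)
#' @export
vector_potential <- function(winding, drive, points, guard = 1e-3) {
  points <- as_points(points)
  seg <- coil_segments(winding)
  if (guard > 0) {
    dmin <- bs_min_distance(points, seg$starts, seg$ends)
    if (any(dmin < guard))
      stop(sum(dmin < guard), " evaluation point(s) within the ", guard,
           " m wire guard radius (singular kernel)")
  }
  I_eff <- drive$peak_current * drive$output_fraction
  A <- bs_vector_potential(points, seg$starts, seg$ends, seg$cur) *
    (MU0 / (4 * pi)) * I_eff
  list(A = A, dAdt = 2 * pi * drive$frequency * A)
}

#' Magnetic flux density of a winding
#'
#' Biot-Savart summation for `B` over all straight segments, with the same
#' drive scaling and linearity contract as [vector_potential()].
#'
#' @inheritParams vector_potential
#' @return `n x 3` matrix of B (tesla)
#' @export
flux_density <- function(winding, drive, points, guard = 1e-3) {
  points <- as_points(points)
  seg <- coil_segments(winding)
  if (guard > 0) {
    dmin <- bs_min_distance(points, seg$starts, seg$ends)
    if (any(dmin < guard))
      stop(sum(dmin < guard), " evaluation point(s) within the ", guard,
           " m wire guard radius (singular kernel)")
  }
  I_eff <- drive$peak_current * drive$output_fraction
  bs_flux_density(points, seg$starts, seg$ends, seg$cur) *
    (MU0 / (4 * pi)) * I_eff
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3)
  points
}
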