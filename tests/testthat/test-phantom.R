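test_that("tissue table carries the six tissue classes and a zero-conductivity background", {
  tab <- default_tissue_table()
  expect_setequal(tab$label, c("background", "skin", "fat", "muscle",
                               "vessel", "nerve", "bone"))
  expect_identical(tab$conductivity_S_per_m[tab$label == "background"], 0)
  expect_equal(tab$conductivity_S_per_m[tab$label == "muscle"], 0.34)
  expect_equal(tab$conductivity_S_per_m[tab$label == "fat"], 0.024)
  expect_equal(tab$conductivity_S_per_m[tab$label == "skin"], 2.0e-4)
  expect_true(all(tab$conductivity_S_per_m >= 0))
})

test_that("conductivity lookup is voxelwise and rejects unknown tissue classes", {
  an <- cylinder_anatomy(R = 0.02, Lz = 0.03, pitch = 0.002, layered = TRUE)
  sig <- conductivity_volume(an)
  muscle_id <- an$regions$id[an$regions$tissue == "muscle"]
  fat_id <- an$regions$id[an$regions$tissue == "fat"]
  expect_true(all(sig[an$labels == muscle_id] == 0.34))
  expect_true(all(sig[an$labels == fat_id] == 0.024))
  expect_true(all(sig[an$labels == 0L] == 0))
  an2 <- an
  an2$regions$tissue[1] <- "cartilage"
  expect_error(conductivity_volume(an2), "cartilage")
})

test_that("per-tissue voxel counts of the cylindrical phantom match analytic annulus volumes within 3%", {
  spec <- phantom_spec(length = 0.4, outer_radius = 0.07, bone_radius = 0.01,
                       fat_thickness = 0.01, skin_thickness = 0.002,
                       voxel_pitch = 0.002)
  an <- build_cylindrical_phantom(spec)
  vv <- voxel_volume(an)
  counts <- table(factor(an$regions$tissue[an$labels],
                         levels = unique(an$regions$tissue)))
  vol <- function(r_out, r_in) pi * (r_out^2 - r_in^2) * spec$length
  r_musc <- 0.07 - 0.01 - 0.002
  expected <- c(bone = vol(0.01, 0), muscle = vol(r_musc, 0.01),
                fat = vol(0.07 - 0.002, r_musc), skin = vol(0.07, 0.07 - 0.002))
  for (tis in names(expected))
    expect_equal(counts[[tis]] * vv, expected[[tis]],
                 tolerance = 0.03, label = paste(tis, "volume"))
})

test_that("skin shell is about two voxels thick along a radial ray at 1 mm pitch", {
  an <- build_cylindrical_phantom(phantom_spec(
    length = 0.02, outer_radius = 0.03, bone_radius = 0.005,
    fat_thickness = 0.005, skin_thickness = 0.002, voxel_pitch = 0.001))
  d <- dim(an$labels)
  mid_k <- ceiling(d[3] / 2)
  j0 <- ceiling(d[2] / 2)
  ray <- an$regions$tissue[an$labels[(ceiling(d[1] / 2)):d[1], j0, mid_k]]
  n_skin <- sum(ray == "skin", na.rm = TRUE)
  expect_gte(n_skin, 1)
  expect_lte(n_skin, 3)
})

test_that("degenerate single-tissue phantom labels every interior voxel muscle", {
  w <- data.frame(name = "muscle_all", extent_deg = 360, pennation_deg = 0,
                  extensor = TRUE)
  an <- build_cylindrical_phantom(phantom_spec(
    length = 0.02, outer_radius = 0.02, bone_radius = 0, fat_thickness = 0,
    skin_thickness = 0, muscle_wedges = w, voxel_pitch = 0.002))
  inside <- an$labels != 0L
  expect_true(all(an$regions$tissue[an$labels[inside]] == "muscle"))
  ax <- voxel_axes(an)
  d <- dim(an$labels)
  X <- array(rep(ax$x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax$y, each = d[1]), times = d[3]), d)
  Z <- array(rep(ax$z, each = d[1] * d[2]), d)
  interior <- sqrt(X^2 + Y^2) < 0.02 & Z > 0 & Z < 0.02
  expect_true(all(an$labels[interior] != 0L))
})

test_that("labels along any outward radial ray follow bone, muscle, fat, skin, background", {
  an <- build_cylindrical_phantom(phantom_spec(
    length = 0.03, outer_radius = 0.04, bone_radius = 0.008,
    fat_thickness = 0.006, skin_thickness = 0.002, voxel_pitch = 0.002))
  d <- dim(an$labels)
  mid_k <- ceiling(d[3] / 2)
  ci <- ceiling(d[1] / 2)
  cj <- ceiling(d[2] / 2)
  order_of <- c(background = 99, bone = 1, muscle = 2, fat = 3, skin = 4)
  for (ang in seq(0, 2 * pi, length.out = 13)[-13]) {
    rr <- seq(0, 0.045, by = 0.001)
    ii <- pmin(pmax(round(ci + rr * cos(ang) / 0.002), 1), d[1])
    jj <- pmin(pmax(round(cj + rr * sin(ang) / 0.002), 1), d[2])
    lab <- an$labels[cbind(ii, jj, mid_k)]
    tis <- ifelse(lab == 0L, "background", an$regions$tissue[lab])
    expect_true(!is.unsorted(order_of[tis]),
                label = paste("radial ordering at angle", round(ang, 2)))
  }
})

test_that("label partition and background padding hold", {
  an <- build_cylindrical_phantom(phantom_spec(
    length = 0.02, outer_radius = 0.02, bone_radius = 0.005,
    fat_thickness = 0.003, skin_thickness = 0.002, voxel_pitch = 0.001))
  tab <- table(an$labels)
  expect_identical(sum(tab), length(an$labels))
  d <- dim(an$labels)
  expect_true(all(an$labels[c(1, d[1]), , ] == 0L))
  expect_true(all(an$labels[, c(1, d[2]), ] == 0L))
  expect_true(all(an$labels[, , c(1, d[3])] == 0L))
})

test_that("per-tissue volume fractions converge with the voxel pitch", {
  mk <- function(p) build_cylindrical_phantom(phantom_spec(
    length = 0.04, outer_radius = 0.04, bone_radius = 0.01,
    fat_thickness = 0.008, skin_thickness = 0.004, voxel_pitch = p))
  frac <- function(an) {
    tis <- an$regions$tissue[an$labels]
    tab <- table(factor(tis, levels = c("bone", "muscle", "fat", "skin")))
    tab / sum(tab)
  }
  f4 <- frac(mk(0.004))
  f2 <- frac(mk(0.002))
  f1 <- frac(mk(0.001))
  # halving the pitch should at least halve-ish the deviation
  expect_lt(max(abs(f1 - f2)), max(abs(f2 - f4)) * 0.9)
})

test_that("a voxel pitch coarser than a layer is rejected with a clear message", {
  expect_error(build_cylindrical_phantom(phantom_spec(
    length = 0.05, outer_radius = 0.04, skin_thickness = 0.002,
    voxel_pitch = 0.005)), "skin")
})

test_that("quadriceps wedges carry the physiological pennation angles and extensor flags", {
  an <- build_cylindrical_phantom(phantom_spec(
    length = 0.03, outer_radius = 0.05, voxel_pitch = 0.002))
  comp <- an$compartments
  expect_equal(comp$pennation_deg[comp$name == "rectus_femoris"], 10)
  expect_equal(comp$pennation_deg[comp$name == "vastus_lateralis"], 8)
  expect_equal(comp$pennation_deg[comp$name == "vastus_intermedius"], -8)
  expect_equal(comp$pennation_deg[comp$name == "vastus_medialis"], 15)
  expect_identical(sum(comp$extensor), 4L)
  # fiber axes are unit vectors tilted by the pennation angle off the femur axis
  for (r in seq_len(nrow(comp))) {
    u <- c(comp$axis_x[r], comp$axis_y[r], comp$axis_z[r])
    expect_equal(sum(u^2), 1, tolerance = 1e-12)
    expect_equal(acos(u[3]) * 180 / pi, abs(comp$pennation_deg[r]),
                 tolerance = 1e-8)
  }
})
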