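# cuboid muscle with a prescribed field: geometry oracles have closed forms

test_that("threshold mask uses a strict inequality and is monotone in amplitude", {
  an <- cuboid_muscle_anatomy(3, 1, 1, pitch = 0.001)
  E <- array(0, dim(an$labels))
  E[2:4, 2, 2] <- c(50, 65, 80)
  m <- supra_threshold_mask(E, an, e_th = 65, x = 1)
  expect_identical(as.vector(m[2:4, 2, 2]), c(FALSE, FALSE, TRUE))
  expect_false(any(supra_threshold_mask(E, an, 65, 0)))
  # uniform 100 V/m, threshold 65, x = 0.7: all muscle voxels active
  E2 <- array(100, dim(an$labels))
  m2 <- supra_threshold_mask(E2, an, 65, 0.7)
  expect_identical(sum(m2), sum(an$labels == 1L))
  # setwise monotone in x
  for (x_lo in c(0.2, 0.5, 0.8)) {
    m_lo <- supra_threshold_mask(E, an, 65, x_lo)
    m_hi <- supra_threshold_mask(E, an, 65, x_lo + 0.2)
    expect_true(all(m_hi[m_lo]))
  }
  # only the amplitude-to-threshold ratio matters (exact duality)
  expect_identical(supra_threshold_mask(E, an, 65, 0.9),
                   supra_threshold_mask(E, an, 65 * 3, 0.9 * 3))
})

test_that("effective cross-section of a fully active cuboid equals width times height", {
  nx <- 10; ny <- 8; nz <- 30; p <- 0.001
  an <- cuboid_muscle_anatomy(nx, ny, nz, pitch = p)
  mask <- an$labels == 1L
  a_eff <- effective_cross_section(mask, an)
  expect_equal(a_eff, nx * ny * p^2, tolerance = nx * p * p / (nx * ny * p^2))
  # only the proximal half active: some full plane is still fully active
  half <- mask
  half[, , 1:(nz %/% 2)] <- FALSE
  expect_equal(effective_cross_section(half, an), a_eff)
  # empty muscle contributes zero
  expect_identical(effective_cross_section(array(FALSE, dim(an$labels)), an), 0)
})

test_that("pennation tilt scales the maximal section by 1/cos(theta)", {
  nx <- 40; ny <- 12; nz <- 60; p <- 0.001
  theta <- 20
  an0 <- cuboid_muscle_anatomy(nx, ny, nz, pitch = p, pennation_deg = 0)
  an1 <- cuboid_muscle_anatomy(nx, ny, nz, pitch = p, pennation_deg = theta)
  mask <- an0$labels == 1L
  a0 <- effective_cross_section(mask, an0)
  a1 <- effective_cross_section(mask, an1)
  # the tilted cut leaves the cuboid through the long faces, so the area
  # grows by the secant of the tilt while it stays fully interior
  expect_equal(a1 / a0, 1 / cos(theta * pi / 180), tolerance = 0.03)
})

test_that("effective volume is the supra-threshold voxel count times the voxel volume", {
  an <- cuboid_muscle_anatomy(10, 10, 100, pitch = 0.001)
  mask <- an$labels == 1L
  expect_identical(effective_volume(mask, an), 10 * 10 * 100 * 1e-9)
  expect_identical(effective_volume(array(FALSE, dim(an$labels)), an), 0)
})

test_that("library threshold profiles agree exactly with the mask-level computation", {
  an <- cuboid_muscle_anatomy(8, 6, 20, pitch = 0.001)
  set.seed(11)
  E <- array(0, dim(an$labels))
  E[an$labels == 1L] <- runif(sum(an$labels == 1L), 20, 120)
  lib <- cuboid_library(an, list(test = list("0" = E)))
  entry <- lib$entries[["test@0"]]
  for (t in c(10, 40.5, 70.2, 119, 150)) {
    mask <- supra_threshold_mask(E, an, e_th = t, x = 1)
    expect_equal(magrecruit:::a_eff_entry(entry, t),
                 effective_cross_section(mask, an), tolerance = 1e-12)
    expect_equal(magrecruit:::v_eff_entry(entry, t, lib$voxel_volume),
                 effective_volume(mask, an), tolerance = 1e-12)
  }
})

test_that("uniform-field force prediction reproduces the closed-form product", {
  # uniform 100 V/m over a 50 cm^2 extensor section; threshold 65 V/m at
  # x = 0.7 -> fully active; f_i = 30 N/cm^2 gives 1500 N
  p <- 0.001
  an <- cuboid_muscle_anatomy(100, 50, 30, pitch = p)  # 100 x 50 mm section
  E <- array(0, dim(an$labels))
  E[an$labels == 1L] <- 100
  lib <- cuboid_library(an, list(uni = list("0" = E)))
  spec <- recruitment_model_spec("cross_section")
  par <- parameter_set(e_th = 65, force_scale = c(S01 = 30 * 1e4))
  f <- predict_force(spec, par, lib, "uni", 0, 0.7, "S01")
  expect_equal(f, 1500, tolerance = 0.03)
  expect_identical(predict_force(spec, par, lib, "uni", 0, 0.5, "S01"), 0)
  par0 <- parameter_set(65, c(S01 = 0))
  expect_identical(predict_force(spec, par0, lib, "uni", 0, 0.9, "S01"), 0)
})

test_that("distance-offset interpolation hits the library endpoints exactly", {
  an <- cuboid_muscle_anatomy(8, 6, 20, pitch = 0.001)
  set.seed(3)
  E0 <- array(0, dim(an$labels)); E5 <- array(0, dim(an$labels))
  sel <- an$labels == 1L
  E0[sel] <- runif(sum(sel), 50, 150)
  E5[sel] <- 0.7 * E0[sel]
  lib <- cuboid_library(an, list(apl = list("0" = E0, "5" = E5)))
  spec <- recruitment_model_spec("cross_section", apl_shift = TRUE,
                                 apl_coil = "apl")
  par5 <- parameter_set(65, c(S01 = 1), apl0 = c(S01 = 0.005))
  par0 <- parameter_set(65, c(S01 = 1), apl0 = c(S01 = 0))
  x <- 0.8
  expect_equal(predict_force(spec, par5, lib, "apl", 0, x, "S01"),
               predict_force(spec, par0, lib, "apl", 5, x, "S01"),
               tolerance = 1e-12)
  # midway offset is the average of the bracketing entries
  par_mid <- parameter_set(65, c(S01 = 1), apl0 = c(S01 = 0.0025))
  expect_equal(predict_force(spec, par_mid, lib, "apl", 0, x, "S01"),
               0.5 * (predict_force(spec, par0, lib, "apl", 0, x, "S01") +
                      predict_force(spec, par0, lib, "apl", 5, x, "S01")),
               tolerance = 1e-12)
  # no extrapolation outside the library span
  par_out <- parameter_set(65, c(S01 = 1), apl0 = c(S01 = 0.010))
  expect_error(predict_force(spec, par_out, lib, "apl", 0, x, "S01"),
               "outside")
})

test_that("recruitment curves are monotone with sensible threshold and saturation metadata", {
  an <- cuboid_muscle_anatomy(10, 8, 25, pitch = 0.001)
  set.seed(5)
  E <- array(0, dim(an$labels))
  sel <- an$labels == 1L
  E[sel] <- runif(sum(sel), 30, 200)
  lib <- cuboid_library(an, list(c1 = list("0" = E)))
  spec <- recruitment_model_spec("cross_section")
  par <- parameter_set(65, c(S01 = 3e5))
  amps <- seq(0.05, 1, by = 0.05)
  cu <- recruitment_curve(spec, par, lib, "c1", 0, amps)
  expect_true(all(diff(cu$force_N) >= 0))
  thr <- attr(cu, "threshold_amplitude")
  expect_true(all(cu$force_N[cu$amplitude < thr] == 0))
  expect_gt(cu$force_N[cu$amplitude == thr], 0)
  sat <- attr(cu, "saturation_amplitude")
  expect_gte(max(cu$force_N), 0.99 * cu$force_N[length(amps)])
  expect_true(sat <= 1)
  # all amplitudes below threshold: an all-zero curve
  cu0 <- recruitment_curve(spec, parameter_set(1e4, c(S01 = 3e5)), lib,
                           "c1", 0, amps)
  expect_true(all(cu0$force_N == 0))
})
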