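test_that("source term vanishes for homogeneous conductivity and orthogonal steps", {
  d <- c(8, 8, 8)
  sigma <- array(0.3, d)
  dAdt <- array(0, c(d, 3))
  dAdt[, , , 2] <- 1.5
  f <- assemble_source(sigma, dAdt, rep(0.002, 3))
  inner <- 2:7  # away from the grid faces, where the padding step appears
  expect_true(all(f[inner, inner, inner] == 0))
  # sigma step along x only, drive purely along y: contraction is zero
  sigma2 <- sigma
  sigma2[5:8, , ] <- 0.05
  f2 <- assemble_source(sigma2, dAdt, rep(0.002, 3))
  expect_true(all(f2[inner, inner, inner] == 0))
  expect_error(assemble_source(sigma, dAdt[, , 1:4, , drop = FALSE],
                               rep(0.002, 3)), "match")
})

test_that("source term of a single-voxel conductivity bump matches the hand-computed stencil", {
  d <- c(7, 7, 7)
  h <- 0.001
  sigma <- array(0.2, d)
  sigma[4, 4, 4] <- 0.5
  dAdt <- array(0, c(d, 3))
  dAdt[, , , 1] <- 2
  dAdt[, , , 2] <- -1
  dAdt[, , , 3] <- 0.5
  f <- assemble_source(sigma, dAdt, rep(h, 3))
  step <- (0.5 - 0.2) / (2 * h)
  # neighbours of the bump see the step through the central difference
  expect_equal(f[3, 4, 4], 2 * step)     # d(sigma)/dx > 0 at x-lower nb
  expect_equal(f[5, 4, 4], -2 * step)
  expect_equal(f[4, 3, 4], -1 * step)
  expect_equal(f[4, 5, 4], 1 * step)
  expect_equal(f[4, 4, 3], 0.5 * step)
  expect_equal(f[4, 4, 5], -0.5 * step)
  expect_equal(f[4, 4, 4], 0)            # symmetric differences cancel
})

test_that("operator reduces to the scaled 7-point Laplacian on a homogeneous cube", {
  d <- c(3, 3, 3)
  h <- 0.002
  sigma <- array(0, c(5, 5, 5))
  sigma[2:4, 2:4, 2:4] <- 1
  sys <- assemble_operator(sigma, rep(h, 3))
  centre <- sys$index[3, 3, 3]
  row <- sys$L[centre, ]
  # face conductance sigma * V / h^2 = h for unit sigma and cubic cells
  expect_equal(row[centre], -6 * h, tolerance = 1e-12)
  nbs <- c(sys$index[2, 3, 3], sys$index[4, 3, 3], sys$index[3, 2, 3],
           sys$index[3, 4, 3], sys$index[3, 3, 2], sys$index[3, 3, 4])
  expect_equal(as.numeric(row[nbs]), rep(h, 6), tolerance = 1e-12)
})

test_that("operator is symmetric with zero row sums and a constant null space", {
  an <- cylinder_anatomy(R = 0.015, Lz = 0.03, pitch = 0.003, layered = TRUE)
  sigma <- conductivity_volume(an)
  sys <- assemble_operator(sigma, an$voxel_pitch)
  L <- sys$L
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-15)
  expect_identical(Matrix::nnzero(L - Matrix::t(L)), 0L)
  ones <- rep(1, nrow(L))
  expect_lt(max(abs(as.numeric(L %*% ones))), 1e-15)
  set.seed(1)
  u <- rnorm(nrow(L)); v <- rnorm(nrow(L))
  expect_equal(sum(u * as.numeric(L %*% v)), sum(v * as.numeric(L %*% u)),
               tolerance = 1e-9)
  expect_error(assemble_operator(array(0, c(4, 4, 4)), rep(0.001, 3)),
               "empty")
})

test_that("zero source yields zero potential and the solve is linear", {
  an <- cylinder_anatomy(R = 0.015, Lz = 0.03, pitch = 0.003, layered = TRUE)
  sigma <- conductivity_volume(an)
  sys <- assemble_operator(sigma, an$voxel_pitch)
  sol0 <- solve_potential(sys, array(0, dim(sigma)), solver_config())
  expect_true(all(sol0$phi == 0))
  dAdt <- array(0, c(dim(sigma), 3))
  dAdt[, , , 1] <- 1
  f <- assemble_source(sigma, dAdt, an$voxel_pitch)
  s1 <- solve_potential(sys, f, solver_config(tol = 1e-10))
  s3 <- solve_potential(sys, 3 * f, solver_config(tol = 1e-10))
  expect_equal(s3$phi, 3 * s1$phi, tolerance = 1e-6)
})

test_that("Gauss-Seidel and conjugate gradients agree on a small layered problem", {
  an <- cylinder_anatomy(R = 0.015, Lz = 0.03, pitch = 0.002, layered = TRUE)
  sigma <- conductivity_volume(an)
  dAdt <- array(0, c(dim(sigma), 3))
  dAdt[, , , 1] <- 1
  dAdt[, , , 3] <- 0.5
  f <- assemble_source(sigma, dAdt, an$voxel_pitch)
  sys <- assemble_operator(sigma, an$voxel_pitch)
  cg <- solve_potential(sys, f, solver_config("cg", 1e-9))
  gs <- solve_potential(sys, f, solver_config("gauss_seidel", 1e-9),
                        sigma = sigma)
  scale <- max(abs(cg$phi))
  expect_lt(max(abs(cg$phi - gs$phi)) / scale, 1e-8 * 10)
})

test_that("induced field matches the axisymmetric closed form on the conducting cylinder", {
  an <- cylinder_anatomy(R = 0.024, Lz = 0.048, pitch = 0.002)
  sol <- solve_imposed(an, uniform_axial_dAdt(an, dBdt = 1))
  ax <- voxel_axes(an)
  d <- dim(an$labels)
  X <- array(rep(ax$x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax$y, each = d[1]), times = d[3]), d)
  Z <- array(rep(ax$z, each = d[1] * d[2]), d)
  rr <- sqrt(X^2 + Y^2)
  interior <- sol$body & rr > 2 * 0.002 & rr < 0.8 * 0.024 &
    abs(Z) < 0.35 * 0.048
  rel <- abs(sol$Emag - rr / 2) / (rr / 2)
  expect_lt(max(rel[interior]), 0.05)
})

test_that("a radially layered conductivity leaves the azimuthal field unchanged", {
  an_h <- cylinder_anatomy(R = 0.024, Lz = 0.048, pitch = 0.002)
  an_l <- cylinder_anatomy(R = 0.024, Lz = 0.048, pitch = 0.002,
                           layered = TRUE)
  sol_h <- solve_imposed(an_h, uniform_axial_dAdt(an_h))
  sol_l <- solve_imposed(an_l, uniform_axial_dAdt(an_l))
  ax <- voxel_axes(an_h)
  d <- dim(an_h$labels)
  X <- array(rep(ax$x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax$y, each = d[1]), times = d[3]), d)
  rr <- sqrt(X^2 + Y^2)
  # compare away from the staircase rings of the two material interfaces
  away <- sol_h$body & rr > 2 * 0.002 & rr < 0.024 - 2 * 0.002 &
    abs(rr - 0.7 * 0.024) > 4 * 0.002
  rel <- abs(sol_l$Emag - sol_h$Emag) / pmax(rr / 2, 1e-9)
  expect_lt(max(rel[away]), 0.05)
})

test_that("electric field is gauge invariant under the potential reference", {
  an <- cylinder_anatomy(R = 0.015, Lz = 0.03, pitch = 0.003, layered = TRUE)
  dAdt <- array(0, c(dim(an$labels), 3))
  dAdt[, , , 1] <- 1
  sol <- solve_imposed(an, dAdt)
  phi_shift <- sol$phi
  phi_shift[sol$body] <- phi_shift[sol$body] + 12.34
  E1 <- electric_field(sol$phi, dAdt, sol$body, an$voxel_pitch)
  E2 <- electric_field(phi_shift, dAdt, sol$body, an$voxel_pitch)
  expect_equal(E2[!is.na(E2)], E1[!is.na(E1)], tolerance = 1e-9)
})

test_that("continuity residual is tiny when converged and large for an unsolved potential", {
  an <- cylinder_anatomy(R = 0.015, Lz = 0.03, pitch = 0.002, layered = TRUE)
  dAdt <- array(0, c(dim(an$labels), 3))
  dAdt[, , , 1] <- 1
  dAdt[, , , 3] <- 0.25
  sol <- solve_imposed(an, dAdt, solver_config(tol = 1e-10))
  sigma <- conductivity_volume(an)
  res_conv <- divergence_residual(sigma, sol, an$voxel_pitch)
  expect_lt(res_conv, 1e-6)
  unsolved <- sol
  unsolved$phi <- array(0, dim(sol$phi))
  unsolved$E <- electric_field(unsolved$phi, dAdt, sol$body, an$voxel_pitch)
  res_bad <- divergence_residual(sigma, unsolved, an$voxel_pitch)
  expect_gt(res_bad, res_conv * 100)
  # homogeneous cylinder with azimuthal drive: analytic divergence is zero
  an_h <- cylinder_anatomy(R = 0.015, Lz = 0.03, pitch = 0.003)
  sol_h <- solve_imposed(an_h, uniform_axial_dAdt(an_h))
  expect_lt(divergence_residual(conductivity_volume(an_h), sol_h,
                                an_h$voxel_pitch), 1e-6)
})
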