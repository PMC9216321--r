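#' Solver configuration for the scalar-potential solve
#'
#' @param method `"cg"` (Jacobi-preconditioned conjugate gradients on the
#'   sparse operator, the default) or `"gauss_seidel"` (plain sweeps, the
#'   method used historically for this formulation; practical on small grids)
#' @param tol relative residual tolerance `||L phi - f|| / ||f||`
#' @param max_iter iteration cap (CG iterations or Gauss-Seidel sweeps)
#' @return an object of class `solver_config`
#' @export
solver_config <- function(method = c("cg", "gauss_seidel"), tol = 1e-8,
                          max_iter = NULL) {
  method <- match.arg(method)
  stopifnot(tol > 0)
  if (is.null(max_iter)) max_iter <- if (method == "cg") 20000L else 100000L
  structure(list(method = method, tol = tol, max_iter = as.integer(max_iter)),
            class = "solver_config")
}

# shift a 3D array by one voxel along an axis, zero-filling the exposed face
shift3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(0, d)
  idx <- lapply(d, seq_len)
  src <- idx
  n <- d[axis]
  if (by == 1L) {        # out[i] = a[i+1]
    idx[[axis]] <- seq_len(n - 1L)
    src[[axis]] <- 2:n
  } else {               # out[i] = a[i-1]
    idx[[axis]] <- 2:n
    src[[axis]] <- seq_len(n - 1L)
  }
  out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Source term of the decoupled eddy-current formulation
#'
#' The right-hand side of `div(sigma grad phi) = -dA/dt . grad sigma`:
#' second-order central differences of the conductivity contracted with the
#' peak slew field, `f = dAdt_x (sigma_{i+1}-sigma_{i-1})/(2 dx) + ...`.
#' The grid must carry a zero-conductivity background padding layer so the
#' stencil is defined everywhere; `f` vanishes wherever `sigma` is locally
#' homogeneous.
#'
#' @param sigma 3D conductivity array (S/m)
#' @param dAdt 4D array `[nx, ny, nz, 3]` of the peak `dA/dt` (V/m)
#' @param pitch numeric length-3 voxel pitch (m)
#' @return 3D array `f` (the source, A/m^3 scale `sigma`/m x V/m)
#' @export
assemble_source <- function(sigma, dAdt, pitch) {
  d <- dim(sigma)
  if (!identical(as.integer(dim(dAdt)), as.integer(c(d, 3L))))
    stop("dAdt grid does not match the sigma grid")
  pitch <- rep_len(pitch, 3)
  f <- array(0, d)
  for (a in 1:3) {
    ds <- (shift3(sigma, a, 1L) - shift3(sigma, a, -1L)) / (2 * pitch[a])
    f <- f + dAdt[, , , a] * ds
  }
  f
}

#' Conservative finite-volume operator
#'
#' Assembles the 7-point face-flux discretization of
#' `phi -> div(sigma grad phi) * V` over the conducting body (voxels with
#' `sigma > 0`): face conductances are `harm(sigma_c, sigma_nb) * V / h^2`
#' with the harmonic mean of the adjacent cell conductivities (exact for
#' layered media; a face against `sigma = 0` carries zero flux, which
#' realises the natural Neumann boundary condition). The operator is
#' symmetric, its rows sum to zero, and its null space is the constant
#' vector (pure-Neumann problem).
#'
#' @param sigma 3D conductivity array (S/m), `>= 0`, zero outside the body
#' @param pitch numeric length-3 voxel pitch (m)
#' @return an `fvm_system`: list with the sparse operator `L`
#'   (`Matrix::dgCMatrix`, body voxels only), the logical `body` mask, the
#'   integer `index` map grid -> body row, `dims` and `pitch`
#' @export
assemble_operator <- function(sigma, pitch) {
  d <- dim(sigma)
  pitch <- rep_len(as.numeric(pitch), 3)
  if (any(sigma < 0)) stop("sigma must be >= 0")
  body <- sigma > 0
  nb <- sum(body)
  if (nb == 0) stop("empty conducting region (all sigma == 0)")
  index <- array(0L, d)
  index[body] <- seq_len(nb)
  V <- prod(pitch)

  ii <- jj <- integer(0)
  xx <- numeric(0)
  diag_acc <- numeric(nb)
  for (a in 1:3) {
    s_hi <- shift3(sigma, a, 1L)
    g <- 2 * sigma * s_hi / (sigma + s_hi + (sigma + s_hi == 0))
    g <- g * V / pitch[a]^2
    hi <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    idx[[a]] <- seq_len(d[a] - 1L)
    hi[idx[[1]], idx[[2]], idx[[3]]] <- TRUE      # faces to the +a neighbour
    sel <- hi & g > 0
    from <- index[sel]
    idx_to <- which(sel)                           # linear index of cell c
    stride <- c(1L, d[1], d[1] * d[2])[a]
    to <- index[idx_to + stride]
    gg <- g[sel]
    ii <- c(ii, from, to)
    jj <- c(jj, to, from)
    xx <- c(xx, gg, gg)
    diag_acc[from] <- diag_acc[from] + gg
    diag_acc[to] <- diag_acc[to] + gg
  }
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(nb)), j = c(jj, seq_len(nb)),
                            x = c(xx, -diag_acc), dims = c(nb, nb))
  structure(list(L = L, body = body, index = index, dims = d, pitch = pitch),
            class = "fvm_system")
}

# matrix-free application of the same operator (diagnostics)
apply_operator <- function(sigma, phi, pitch) {
  d <- dim(sigma)
  pitch <- rep_len(pitch, 3)
  V <- prod(pitch)
  out <- array(0, d)
  for (a in 1:3) {
    for (by in c(1L, -1L)) {
      s_nb <- shift3(sigma, a, by)
      p_nb <- shift3(phi, a, by)
      g <- 2 * sigma * s_nb / (sigma + s_nb + (sigma + s_nb == 0))
      g <- g * V / pitch[a]^2
      out <- out + g * (p_nb - phi)
    }
  }
  out[sigma <= 0] <- 0
  out
}

#' Solve the pure-Neumann scalar-potential problem
#'
#' Solves `L phi = -f V` over the conducting body with the operator of
#' [assemble_operator()]. The right-hand side is projected onto the range of
#' the operator by mean subtraction (null-space compatibility) and the
#' returned potential is gauge-fixed to zero mean over the body; any other
#' reference yields identical electric fields.
#'
#' @param system an `fvm_system` from [assemble_operator()]
#' @param f 3D source array from [assemble_source()] (or a body-length
#'   vector of the assembled right-hand side `-f*V`)
#' @param config a [solver_config()]
#' @param sigma the conductivity array (required for
#'   `method = "gauss_seidel"`, which runs matrix-free on the grid)
#' @return list with `phi` (3D array, volts, 0 outside the body),
#'   `iterations`, `residual` (achieved relative residual)
#' @export
solve_potential <- function(system, f, config = solver_config(),
                            sigma = NULL) {
  stopifnot(inherits(system, "fvm_system"))
  V <- prod(system$pitch)
  if (is.array(f)) {
    if (!identical(dim(f), system$dims)) stop("source grid mismatch")
    rhs <- -f[system$body] * V
  } else rhs <- f
  nb <- length(rhs)
  rhs <- rhs - mean(rhs)
  rhs_norm <- sqrt(sum(rhs^2))
  phi_grid <- array(0, system$dims)

  if (rhs_norm == 0) {
    return(list(phi = phi_grid, iterations = 0L, residual = 0))
  }

  if (config$method == "gauss_seidel") {
    if (is.null(sigma))
      stop("gauss_seidel needs the sigma array (matrix-free sweeps)")
    rhs_full <- array(0, system$dims)
    rhs_full[system$body] <- rhs
    res <- gs_solve(as.numeric(sigma), as.numeric(rhs_full),
                    as.integer(system$dims), as.numeric(system$pitch),
                    config$tol, config$max_iter, 50L)
    phi <- array(res$phi, system$dims)[system$body]
    it <- res$iterations
    rel <- res$residual
  } else {
    A <- -system$L                      # SPD on the complement of constants
    b <- -rhs
    M <- Matrix::diag(A)
    M[M <= 0] <- 1
    x <- numeric(nb)
    r <- b
    z <- r / M
    p <- z
    rz <- sum(r * z)
    bn <- sqrt(sum(b^2))
    rel <- 1
    it <- 0L
    while (it < config$max_iter) {
      it <- it + 1L
      Ap <- as.numeric(A %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      rel <- sqrt(sum(r^2)) / bn
      if (rel <= config$tol) break
      z <- r / M
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
    # true residual (recurrence residual can drift)
    rel <- sqrt(sum((as.numeric(A %*% x) - b)^2)) / bn
    phi <- x
  }
  if (rel > config$tol * 10)
    stop(sprintf(
      "potential solve did not converge: relative residual %.3e after %d iterations (tolerance %.1e)",
      rel, it, config$tol))
  phi <- phi - mean(phi)                # gauge: zero mean over the body
  phi_grid[system$body] <- phi
  list(phi = phi_grid, iterations = it, residual = rel)
}

#' Induced electric field from potential and slew field
#'
#' `E = -dA/dt - grad phi`, with central differences for the gradient where
#' both neighbours are inside the conducting body and one-sided differences
#' at the body surface. The field is only meaningful over the body; voxels
#' outside are set to `NA`.
#'
#' @param phi 3D potential array (V), zero/any gauge outside the body
#' @param dAdt 4D `[dims, 3]` peak slew field (V/m)
#' @param body logical 3D array marking conducting voxels
#' @param pitch numeric length-3 voxel pitch (m)
#' @return 4D array `[dims, 3]` of E (V/m), `NA` outside the body
#' @export
electric_field <- function(phi, dAdt, body, pitch) {
  d <- dim(phi)
  pitch <- rep_len(pitch, 3)
  if (!identical(as.integer(dim(dAdt)), as.integer(c(d, 3L))))
    stop("dAdt grid does not match the phi grid")
  E <- array(NA_real_, c(d, 3))
  bodyn <- array(0, d)
  bodyn[body] <- 1
  for (a in 1:3) {
    hi_in <- shift3(bodyn, a, 1L) > 0
    lo_in <- shift3(bodyn, a, -1L) > 0
    p_hi <- shift3(phi, a, 1L)
    p_lo <- shift3(phi, a, -1L)
    grad <- array(0, d)
    both <- hi_in & lo_in
    grad[both] <- (p_hi[both] - p_lo[both]) / (2 * pitch[a])
    fwd <- hi_in & !lo_in
    grad[fwd] <- (p_hi[fwd] - phi[fwd]) / pitch[a]
    bwd <- !hi_in & lo_in
    grad[bwd] <- (phi[bwd] - p_lo[bwd]) / pitch[a]
    comp <- -dAdt[, , , a] - grad
    comp[!body] <- NA_real_
    E[, , , a] <- comp
  }
  E
}

#' Current-continuity residual of a field solution
#'
#' Discrete continuity diagnostic of the decoupled scheme: in this
#' formulation the statement `div(sigma E) = 0` discretizes to
#' `L phi + f V = 0` (the `dA/dt` part of `sigma E` enters through the
#' assembled source `f`), so the diagnostic is `||L phi + f V|| / V`
#' normalized by `||sigma E|| / mean(pitch)`. For a converged solve it is
#' bounded by a constant times the solver tolerance; for an unsolved
#' potential it is large.
#'
#' @param sigma 3D conductivity array (S/m)
#' @param solution a `field_solution` (see [solve_field()]) or a list with
#'   `phi` (3D), `dAdt` (4D) and `E` (4D)
#' @param pitch voxel pitch (m); taken from the solution if present
#' @return scalar normalized residual (dimensionless)
#' @export
divergence_residual <- function(sigma, solution, pitch = solution$pitch) {
  pitch <- rep_len(pitch, 3)
  V <- prod(pitch)
  f <- assemble_source(sigma, solution$dAdt, pitch)
  mis <- apply_operator(sigma, solution$phi, pitch) + f * V
  body <- sigma > 0
  # null-space component is not an error: project it out
  mis_b <- mis[body] - mean(mis[body])
  num <- sqrt(sum(mis_b^2)) / V
  sE <- solution$E
  for (a in 1:3) sE[, , , a] <- sE[, , , a] * sigma
  den <- sqrt(sum(sE[!is.na(sE)]^2)) / mean(pitch)
  if (den == 0) return(0)
  num / den
}

#' Solve the induced-field problem for a placed coil
#'
#' Convenience wrapper chaining the full decoupled quasi-static solve on an
#' anatomy: evaluates the Biot-Savart `dA/dt` of the winding at every voxel
#' centre, assembles source and operator, solves for the scalar potential,
#' and returns `E = -dA/dt - grad phi` over the conducting body.
#'
#' @param anatomy an [anatomy_volume()]
#' @param winding a placed [coil_winding()]
#' @param drive a [pulse_drive()]
#' @param config a [solver_config()]
#' @param table a [tissue_table()]
#' @return a `field_solution`: list with `phi` (3D, V), `E` (4D, V/m, `NA`
#'   outside the body), `Emag` (3D, V/m), `dAdt` (4D), `body` mask, `pitch`
#'   and `diagnostics` (iterations, residual, continuity residual)
#' @export
solve_field <- function(anatomy, winding, drive, config = solver_config(),
                        table = default_tissue_table()) {
  sigma <- conductivity_volume(anatomy, table)
  d <- dim(sigma)
  ax <- voxel_axes(anatomy)
  pts <- cbind(rep(ax$x, times = d[2] * d[3]),
               rep(rep(ax$y, each = d[1]), times = d[3]),
               rep(ax$z, each = d[1] * d[2]))
  va <- vector_potential(winding, drive, pts, guard = 0)
  dAdt <- array(va$dAdt, c(d, 3))
  f <- assemble_source(sigma, dAdt, anatomy$voxel_pitch)
  system <- assemble_operator(sigma, anatomy$voxel_pitch)
  sol <- solve_potential(system, f, config, sigma = sigma)
  E <- electric_field(sol$phi, dAdt, system$body, anatomy$voxel_pitch)
  Emag <- sqrt(E[, , , 1]^2 + E[, , , 2]^2 + E[, , , 3]^2)
  out <- list(phi = sol$phi, E = E, Emag = Emag, dAdt = dAdt,
              body = system$body, pitch = anatomy$voxel_pitch,
              diagnostics = list(method = config$method,
                                 iterations = sol$iterations,
                                 residual = sol$residual))
  class(out) <- "field_solution"
  out$diagnostics$continuity <- divergence_residual(sigma, out)
  out
}

#' @exportS3Method base::print
print.field_solution <- function(x, ...) {
  cat("field_solution:", paste(dim(x$phi), collapse = " x "), "grid,",
      sum(x$body), "body voxels\n")
  cat(sprintf("  solver: %s, %d iterations, residual %.2e, continuity %.2e\n",
              x$diagnostics$method, x$diagnostics$iterations,
              x$diagnostics$residual, x$diagnostics$continuity))
  cat(sprintf("  ||E|| over body: median %.3g, max %.3g V/m\n",
              median(x$Emag[x$body]), max(x$Emag[x$body])))
  invisible(x)
}
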