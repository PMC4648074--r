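# Iterative solution of the discretized linearized Poisson-Boltzmann
# equation: red-black Gauss-Seidel with successive over-relaxation.

#' Boundary condition specification
#'
#' @param kind `"zero"` (potential clamped to 0 at the grid faces) or
#'   `"quasi_coulombic"` (faces set from the screened two-center dipole
#'   formula).
#' @param periodic logical 3-vector; axes with `TRUE` wrap around instead of
#'   carrying fixed values.
#' @return a `boundary_spec`
#' @export
boundary_spec <- function(kind = c("zero", "quasi_coulombic"),
                          periodic = c(FALSE, FALSE, FALSE)) {
  kind <- match.arg(kind)
  periodic <- rep_len(as.logical(periodic), 3L)
  structure(list(kind = kind, periodic = periodic), class = "boundary_spec")
}

#' Convergence specification
#'
#' Iteration stops as soon as any criterion is met: root-mean-square change
#' below `rmsc`, maximum change below `maxc`, or `maxit` sweeps.
#'
#' @param rmsc threshold on the rms change per iteration, kT/e (default 1e-4)
#' @param maxc threshold on the maximum change per iteration, kT/e
#'   (default 1e-4)
#' @param maxit maximum number of sweeps (default 500)
#' @return a `convergence_spec`
#' @export
convergence_spec <- function(rmsc = 1e-4, maxc = 1e-4, maxit = 500L) {
  stopifnot(rmsc > 0, maxc > 0, maxit >= 1)
  structure(list(rmsc = rmsc, maxc = maxc, maxit = as.integer(maxit)),
            class = "convergence_spec")
}

#' Root-mean-square and maximum change between two potential grids
#'
#' `rmsc` is `sqrt(mean((new - old)^2))` over all grid nodes; `maxc` is the
#' largest absolute per-node change.
#'
#' @param phi_new,phi_old arrays of identical dimensions
#' @return a scalar, kT/e
#' @export
rmsc <- function(phi_new, phi_old) {
  if (!identical(dim(phi_new), dim(phi_old)))
    stop("potential grids have different dimensions")
  sqrt(mean((phi_new - phi_old)^2))
}

#' @rdname rmsc
#' @export
maxc <- function(phi_new, phi_old) {
  if (!identical(dim(phi_new), dim(phi_old)))
    stop("potential grids have different dimensions")
  max(abs(phi_new - phi_old))
}

# Cyclic shift by -1 along `ax`: element i of the result is a[i-1] (wrapped).
shift_down_cyc <- function(a, ax) {
  n <- dim(a)[ax]
  idx <- lapply(dim(a), seq_len)
  idx[[ax]] <- c(n, seq_len(n - 1L))
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# sum_k eps_k + (kappa0 h)^2 per node (wrap indexing; values at fixed
# boundary nodes are never used).
stencil_diag <- function(maps) {
  h <- maps$grid$h
  maps$eps_x + shift_down_cyc(maps$eps_x, 1) +
    maps$eps_y + shift_down_cyc(maps$eps_y, 2) +
    maps$eps_z + shift_down_cyc(maps$eps_z, 3) +
    maps$kappa2 * h^2
}

# Logical array: nodes updated by the iteration (faces of non-periodic axes
# are fixed).
update_mask <- function(grid, bc) {
  np <- grid$npoints
  m <- array(TRUE, dim = np)
  for (ax in 1:3) {
    if (bc$periodic[ax]) next
    idx <- lapply(np, seq_len)
    idx[[ax]] <- c(1L, np[ax])
    m[idx[[1]], idx[[2]], idx[[3]]] <- FALSE
  }
  m
}

#' Fixed boundary values for the grid faces
#'
#' For `kind = "zero"` all fixed faces are 0. For
#' `kind = "quasi_coulombic"` the faces carry the screened two-center
#' formula
#' `phi(x) = f * [c+ exp(-d+/lambda)/(d+ eps) + c- exp(-d-/lambda)/(d- eps)]`
#' in kT/e, where `c+`/`c-` are the total positive/negative charge of the
#' solute, `d+`/`d-` the distances to the respective charge centroids,
#' `lambda` the Debye length (infinite without salt) and `f` the Coulomb
#' conversion factor at the given temperature. Periodic axes carry no fixed
#' values.
#'
#' @param bc a [boundary_spec()]
#' @param atoms an [atom_set()]
#' @param grid a `grid_spec`
#' @param eps_solvent solvent dielectric constant
#' @param debye_length Debye screening length, Angstrom (`Inf` for no salt)
#' @param temperature temperature, K
#' @return list with `values` (array, nonzero only on fixed faces) and
#'   `fixed` (logical array of fixed nodes)
#' @export
apply_boundary <- function(bc, atoms, grid, eps_solvent,
                           debye_length = Inf, temperature = 273.15) {
  fixed <- !update_mask(grid, bc)
  vals <- array(0, dim = grid$npoints)
  if (bc$kind == "quasi_coulombic" && any(fixed)) {
    qp <- atoms$charge[atoms$charge > 0]
    qn <- atoms$charge[atoms$charge < 0]
    if (length(qp) == 0 && length(qn) == 0) {
      warning("quasi-Coulombic boundary with an uncharged solute; ",
              "falling back to zero boundary")
    } else {
      beta <- beta_length(temperature)
      idx <- which(fixed)
      sub <- arrayInd(idx, grid$npoints)
      pts <- cbind(grid_axis(grid, 1)[sub[, 1]],
                   grid_axis(grid, 2)[sub[, 2]],
                   grid_axis(grid, 3)[sub[, 3]])
      phi <- numeric(length(idx))
      for (sgn in c(1, -1)) {
        qs <- if (sgn > 0) qp else qn
        if (length(qs) == 0) next
        sel <- if (sgn > 0) atoms$charge > 0 else atoms$charge < 0
        ctr <- colSums(atom_coords(atoms)[sel, , drop = FALSE] * qs) / sum(qs)
        d <- sqrt(rowSums(sweep(pts, 2, ctr, "-")^2))
        d <- pmax(d, 1e-6)
        damp <- if (is.finite(debye_length)) exp(-d / debye_length) else 1
        phi <- phi + beta * sum(qs) * damp / (d * eps_solvent)
      }
      vals[idx] <- phi
    }
  }
  list(values = vals, fixed = fixed)
}

#' Single-point stencil evaluation
#'
#' Evaluates the update formula for one interior node: the full form
#' `(sum_k eps_k phi_k + 4 pi q0 beta / h) / (sum_k eps_k + (kappa0 h)^2)`,
#' or, with `fast = TRUE`, the uniform 7-point stencil (mean of the six
#' neighbors; with salt, denominator `6 + (kappa0 h)^2 / eps0`). The two
#' forms agree wherever the local dielectric is uniform and the node is
#' uncharged.
#'
#' @param phi potential array, kT/e
#' @param maps a `region_maps`
#' @param idx integer 3-vector of the node (must be interior)
#' @param temperature temperature, K
#' @param fast use the uniform stencil
#' @return the updated potential at the node, kT/e
#' @export
stencil_update <- function(phi, maps, idx, temperature = 273.15,
                           fast = FALSE) {
  np <- maps$grid$npoints
  if (any(idx <= 1L) || any(idx >= np))
    stop("stencil_update requires an interior node")
  i <- idx[1]; j <- idx[2]; k <- idx[3]
  nb <- c(phi[i - 1, j, k], phi[i + 1, j, k],
          phi[i, j - 1, k], phi[i, j + 1, k],
          phi[i, j, k - 1], phi[i, j, k + 1])
  h <- maps$grid$h
  k2h2 <- maps$kappa2[i, j, k] * h^2
  if (fast) {
    eps0 <- maps$eps_x[i, j, k]
    return(sum(nb) / (6 + k2h2 / eps0))
  }
  eps <- c(maps$eps_x[i - 1, j, k], maps$eps_x[i, j, k],
           maps$eps_y[i, j - 1, k], maps$eps_y[i, j, k],
           maps$eps_z[i, j, k - 1], maps$eps_z[i, j, k])
  src <- 4 * pi * maps$charge[i, j, k] * beta_length(temperature) / h
  (sum(eps * nb) + src) / (sum(eps) + k2h2)
}

#' Estimate the spectral radius of the Jacobi iteration operator
#'
#' Matrix-free power iteration with a deterministic smooth start vector
#' (product of half-sine profiles along non-periodic axes), using the
#' diagonally weighted Rayleigh quotient. Falls back to the uniform-grid
#' Laplacian closed form (mean of the per-axis cosines) with a warning when
#' the iteration does not settle.
#'
#' @param maps a `region_maps`
#' @param bc a [boundary_spec()]
#' @param max_iter iteration cap (default 500)
#' @param tol relative tolerance on successive estimates (default 1e-7)
#' @return the spectral radius estimate, in [0, 1) for assembled maps
#' @export
estimate_spectral_radius <- function(maps, bc = boundary_spec("zero"),
                                     max_iter = 500L, tol = 1e-7) {
  grid <- maps$grid
  np <- grid$npoints
  diag <- stencil_diag(maps)
  upd <- update_mask(grid, bc)
  prof <- function(ax) {
    n <- np[ax]
    if (bc$periodic[ax]) rep(1, n) else sin(pi * (seq_len(n) - 1) / (n - 1))
  }
  x <- outer(outer(prof(1), prof(2)), prof(3))
  dim(x) <- np
  x[!upd] <- 0
  nx <- sqrt(sum(x^2))
  if (nx == 0) return(0)
  x <- x / nx
  lam <- 0
  for (it in seq_len(max_iter)) {
    y <- pb_jacobi_apply(x, maps$eps_x, maps$eps_y, maps$eps_z,
                         diag, upd, bc$periodic)
    lam_new <- sum(x * diag * y) / sum(x * diag * x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(0)
    x <- y / ny
    if (it > 1 && abs(lam_new - lam) <= tol * max(abs(lam_new), 1e-12))
      return(lam_new)
    lam <- lam_new
  }
  warning("spectral-radius power iteration did not settle; ",
          "using the uniform-grid closed form")
  mean(vapply(1:3, function(ax) {
    n <- if (bc$periodic[ax]) np[ax] else np[ax] - 2L
    cos(pi / (n + 1))
  }, 0))
}

#' Optimal SOR relaxation factor
#'
#' For a Jacobi spectral radius `lambda` the standard SOR optimum is
#' `omega = 2 / (1 + sqrt(1 - lambda^2))`. The variant
#' `"radius_as_squared"` treats the supplied value as the squared radius,
#' `omega = 2 / (1 + sqrt(1 - lambda))`.
#'
#' @param lambda Jacobi spectral radius, in [0, 1)
#' @param variant `"jacobi"` (default) or `"radius_as_squared"`
#' @return omega in [1, 2)
#' @export
optimal_omega <- function(lambda, variant = c("jacobi", "radius_as_squared")) {
  variant <- match.arg(variant)
  if (lambda < 0 || lambda >= 1)
    stop("spectral radius must lie in [0, 1)")
  if (variant == "jacobi") 2 / (1 + sqrt(1 - lambda^2))
  else 2 / (1 + sqrt(1 - lambda))
}

#' Solve the discretized linearized Poisson-Boltzmann equation
#'
#' Red-black Gauss-Seidel with successive over-relaxation on the 7-point
#' stencil. Newly computed values are used within the same sweep. The
#' initial guess is zero everywhere except the fixed boundary faces.
#' Iteration stops as soon as the rms change, the maximum change, or the
#' sweep count criterion fires.
#'
#' @param maps a `region_maps` (from [build_region_maps()] or
#'   [assign_region_maps()])
#' @param bc a [boundary_spec()]
#' @param conv a [convergence_spec()]
#' @param omega relaxation factor in (0, 2), or `"auto"` to derive it from
#'   the estimated Jacobi spectral radius
#' @param temperature temperature, K (sets the charge-to-potential scale)
#' @param debye_length Debye length for quasi-Coulombic boundary values,
#'   Angstrom; `NULL` derives it from the screening map
#' @return a `solver_result`: list with `potential` (array, kT/e),
#'   `iterations`, `rmsc_history`, `maxc_history`, `omega`, `converged`,
#'   `criterion`, `grid`, `bc`
#' @export
sor_solve <- function(maps, bc = boundary_spec("zero"),
                      conv = convergence_spec(), omega = "auto",
                      temperature = 273.15, debye_length = NULL) {
  grid <- maps$grid
  h <- grid$h
  if (identical(omega, "auto")) {
    lam <- estimate_spectral_radius(maps, bc)
    lam <- min(max(lam, 0), 1 - 1e-9)
    omega <- optimal_omega(lam)
  }
  if (!(omega > 0 && omega < 2)) stop("omega must lie in (0, 2)")

  if (is.null(debye_length)) {
    k2 <- max(maps$kappa2) / maps$eps_out
    debye_length <- if (k2 > 0) 1 / sqrt(k2) else Inf
  }
  bvals <- apply_boundary(bc, maps$atoms, grid, maps$eps_out,
                          debye_length, temperature)
  phi <- array(0, dim = grid$npoints)
  phi[bvals$fixed] <- bvals$values[bvals$fixed]
  upd <- !bvals$fixed
  diag <- stencil_diag(maps)
  src <- 4 * pi * maps$charge * beta_length(temperature) / h

  rh <- numeric(conv$maxit)
  mh <- numeric(conv$maxit)
  criterion <- "maxit"
  it <- 0L
  while (it < conv$maxit) {
    it <- it + 1L
    res <- pb_sor_sweep(phi, maps$eps_x, maps$eps_y, maps$eps_z,
                        diag, src, upd, bc$periodic, omega)
    if (!all(is.finite(res)))
      stop("solver produced non-finite values at sweep ", it,
           " (omega = ", format(omega), ")")
    rh[it] <- res[1]; mh[it] <- res[2]
    if (it > 20 && rh[it] > 10 * rh[it - 20] && rh[it] > conv$rmsc)
      stop("solver diverging (rmsc grew 10-fold over 20 sweeps) ",
           "at omega = ", format(omega))
    if (rh[it] <= conv$rmsc) { criterion <- "rmsc"; break }
    if (mh[it] <= conv$maxc) { criterion <- "maxc"; break }
  }
  structure(list(
    potential = phi,
    iterations = it,
    rmsc_history = rh[seq_len(it)],
    maxc_history = mh[seq_len(it)],
    omega = omega,
    converged = criterion != "maxit",
    criterion = criterion,
    grid = grid,
    bc = bc
  ), class = "solver_result")
}

#' @exportS3Method base::print
print.solver_result <- function(x, ...) {
  cat(sprintf(
    "solver_result: %s after %d sweeps (omega = %.4f, criterion: %s)\n",
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$omega, x$criterion))
  n <- x$iterations
  cat(sprintf("  final rmsc = %.3e, maxc = %.3e kT/e\n",
              x$rmsc_history[n], x$maxc_history[n]))
  invisible(x)
}

#' Sample the potential at arbitrary positions
#'
#' Trilinear interpolation of the grid potential; exact for fields that are
#' affine in x, y and z.
#'
#' @param phi potential array, kT/e
#' @param grid a `grid_spec`
#' @param points n x 3 matrix (or 3-vector) of positions, Angstrom
#' @return numeric vector of potentials in input order, kT/e
#' @export
sample_potential <- function(phi, grid, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  np <- grid$npoints
  u <- grid_frac_index(points, grid)
  bad <- which(apply(u, 1, function(v)
    any(v < 1 - 1e-9) || any(v > np + 1e-9)))
  if (length(bad) > 0)
    stop("point(s) outside the grid: index ", paste(bad, collapse = ", "))
  u <- pmin(pmax(u, 1), matrix(rep(np, each = nrow(u)), ncol = 3))
  i0 <- pmin(floor(u), matrix(rep(np - 1L, each = nrow(u)), ncol = 3))
  f <- u - i0
  out <- numeric(nrow(u))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    out <- out + w * phi[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out
}
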