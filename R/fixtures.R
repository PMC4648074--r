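# Synthetic solutes and independent oracles. Every numerical module is
# testable against these without external data.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Born ion fixture
#'
#' A single spherical ion: the standard validation system for
#' finite-difference continuum-electrostatics solvers, with closed-form
#' solvation energy ([born_energy_analytic()]) and exterior potential
#' ([dh_sphere_potential()]).
#'
#' @param q charge, e
#' @param R radius, Angstrom
#' @param center position of the ion, Angstrom
#' @return an [atom_set()] with one atom
#' @export
make_born_ion <- function(q = 1, R = 2, center = c(0, 0, 0)) {
  stopifnot(R > 0)
  atom_set(matrix(center, 1, 3), radius = R, charge = q,
           elety = "ION", resid = "BRN")
}

#' Two-atom dumbbell fixture
#'
#' Two spheres along x, centered at the origin: the minimal solute with a
#' reentrant molecular surface when the separation admits no probe between
#' the atoms.
#'
#' @param r1,r2 radii, Angstrom
#' @param separation center-center distance, Angstrom
#' @param charges length-2 charge vector, e
#' @return an [atom_set()] with two atoms
#' @export
make_dumbbell <- function(r1 = 2, r2 = 2, separation = 5,
                          charges = c(0, 0)) {
  stopifnot(separation >= 0)
  atom_set(rbind(c(-separation / 2, 0, 0), c(separation / 2, 0, 0)),
           radius = c(r1, r2), charge = rep_len(charges, 2),
           elety = c("A1", "A2"), resid = "DMB")
}

#' Random small-molecule fixture
#'
#' `n_atoms` atoms with radii uniform in [1, 2] Angstrom, positions uniform
#' in a ball of radius 10 Angstrom, and charges uniform in [-1, 1] e
#' shifted so that the total charge is the nearest integer. Deterministic
#' for a given seed.
#'
#' @param n_atoms number of atoms
#' @param seed integer seed
#' @return an [atom_set()]
#' @export
make_random_molecule <- function(n_atoms = 20, seed = 1) {
  stopifnot(n_atoms >= 1)
  with_local_seed(seed, {
    # uniform in a ball: direction times radius^(1/3)
    dir <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    pos <- dir * 10 * stats::runif(n_atoms)^(1 / 3)
    radius <- stats::runif(n_atoms, 1, 2)
    charge <- stats::runif(n_atoms, -1, 1)
    charge <- charge - (sum(charge) - round(sum(charge))) / n_atoms
    atom_set(pos, radius, charge,
             elety = sprintf("C%d", seq_len(n_atoms)), resid = "RND")
  })
}

#' Brute-force probe-accessibility oracle for midpoint classification
#'
#' Independent arbiter for the probe reclassification: a midpoint is
#' outside the solvent-excluded surface iff some probe-center position on a
#' fine search grid lies outside every probe-extended atom sphere and
#' within `probe_radius` of the midpoint. Intended for small fixtures only.
#'
#' @param midpoints n x 3 matrix of midpoint positions, Angstrom
#' @param atoms an [atom_set()]
#' @param probe_radius probe radius, Angstrom
#' @param search_resolution spacing of the probe-center search grid,
#'   Angstrom
#' @return logical vector: TRUE where the midpoint is inside the
#'   solvent-excluded region
#' @export
brute_force_probe_oracle <- function(midpoints, atoms, probe_radius,
                                     search_resolution) {
  if (is.null(dim(midpoints))) midpoints <- matrix(midpoints, ncol = 3)
  ctr <- atom_coords(atoms)
  ext <- atoms$radius + probe_radius
  # relative probe-center offsets within the probe sphere
  g <- seq(-probe_radius, probe_radius, by = search_resolution)
  off <- as.matrix(expand.grid(x = g, y = g, z = g))
  off <- off[rowSums(off^2) <= probe_radius^2 + 1e-12, , drop = FALSE]
  tol <- 1e-9
  vapply(seq_len(nrow(midpoints)), function(m) {
    x <- midpoints[m, ]
    # deterministic candidates: the continuous optimum on each extended
    # sphere (keeps the oracle exact for convex solutes, where the search
    # grid alone can narrowly miss a touching probe position)
    rad <- t(vapply(seq_len(nrow(ctr)), function(a) {
      v <- x - ctr[a, ]
      dv <- sqrt(sum(v^2))
      if (dv < tol) v <- c(1, 0, 0) else v <- v / dv
      ctr[a, ] + ext[a] * v
    }, numeric(3)))
    keep <- sqrt(rowSums(sweep(rad, 2, x, "-")^2)) <= probe_radius + tol
    cand <- rbind(sweep(off, 2, x, "+"), rad[keep, , drop = FALSE])
    ok <- rep(TRUE, nrow(cand))
    for (a in seq_len(nrow(ctr))) {
      d2 <- rowSums(sweep(cand, 2, ctr[a, ], "-")^2)
      ok <- ok & (d2 >= ext[a]^2 - tol)
      if (!any(ok)) break
    }
    !any(ok)   # no accessible probe position => inside the SES region
  }, TRUE)
}

#' Direct dense solution of the discretized system
#'
#' Assembles the sparse linear system implied by the 7-point stencil
#' explicitly (one equation per updated node, fixed boundary values moved
#' to the right-hand side, periodic axes wrapped) and solves it by direct
#' sparse linear algebra. Completely independent of the iterative sweep
#' code; reference for [sor_solve()] on small grids.
#'
#' @param maps a `region_maps`
#' @param bc a [boundary_spec()]
#' @param temperature temperature, K
#' @param boundary_values optional array of fixed face values (defaults to
#'   the values [apply_boundary()] produces)
#' @return potential array, kT/e, including the fixed boundary values
#' @export
dense_system_oracle <- function(maps, bc = boundary_spec("zero"),
                                temperature = 273.15,
                                boundary_values = NULL) {
  grid <- maps$grid
  np <- grid$npoints
  h <- grid$h
  if (prod(np) > 15^3)
    stop("dense_system_oracle is intended for small grids only")
  if (is.null(boundary_values)) {
    k2 <- max(maps$kappa2) / maps$eps_out
    dl <- if (k2 > 0) 1 / sqrt(k2) else Inf
    boundary_values <- apply_boundary(bc, maps$atoms, grid, maps$eps_out,
                                      dl, temperature)$values
  }
  upd <- update_mask(grid, bc)
  unk <- which(upd)
  id <- array(NA_integer_, dim = np)
  id[unk] <- seq_along(unk)
  nunk <- length(unk)
  sub <- arrayInd(unk, np)

  eps_arr <- list(maps$eps_x, maps$eps_y, maps$eps_z)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  rhs <- 4 * pi * maps$charge[unk] * beta_length(temperature) / h
  diag_v <- maps$kappa2[unk] * h^2

  for (ax in 1:3) {
    for (side in c(-1L, 1L)) {
      nb <- sub
      nb[, ax] <- nb[, ax] + side
      wrap <- rep(FALSE, nunk)
      if (bc$periodic[ax]) {
        wrap <- nb[, ax] < 1L | nb[, ax] > np[ax]
        nb[, ax] <- ((nb[, ax] - 1L) %% np[ax]) + 1L
      }
      # midpoint between the node and this neighbor: own-axis index of the
      # lower of the two (wrap midpoint = np[ax] for the periodic seam)
      mi <- sub
      if (side == -1L) {
        mi[, ax] <- mi[, ax] - 1L
        if (bc$periodic[ax])
          mi[, ax] <- ((mi[, ax] - 1L) %% np[ax]) + 1L
      }
      eps <- eps_arr[[ax]][mi]
      diag_v <- diag_v + eps
      nb_id <- id[nb]
      fixed_nb <- is.na(nb_id)
      if (any(fixed_nb))
        rhs[fixed_nb] <- rhs[fixed_nb] +
          eps[fixed_nb] * boundary_values[nb[fixed_nb, , drop = FALSE]]
      keep <- !fixed_nb
      rows <- c(rows, which(keep))
      cols <- c(cols, nb_id[keep])
      vals <- c(vals, -eps[keep])
    }
  }
  A <- Matrix::sparseMatrix(i = c(rows, seq_len(nunk)),
                            j = c(cols, seq_len(nunk)),
                            x = c(vals, diag_v),
                            dims = c(nunk, nunk))
  x <- as.numeric(Matrix::solve(A, rhs))
  phi <- boundary_values
  phi[unk] <- x
  phi
}

#' Random region maps for solver cross-checks
#'
#' Seeded random dielectric midpoint maps (uniform in [1, 80]), random
#' sparse charges and random non-negative screening values on a small
#' grid: a stress fixture with no geometric structure, used to compare the
#' iterative solver against [dense_system_oracle()].
#'
#' @param npoints grid points per axis
#' @param h grid spacing, Angstrom
#' @param seed integer seed
#' @param salt logical: include random screening values
#' @return a `region_maps`
#' @export
make_random_maps <- function(npoints = 9, h = 1, seed = 1, salt = TRUE) {
  with_local_seed(seed, {
    np <- rep(as.integer(npoints), 3)
    grid <- structure(list(origin = -(np - 1) / 2 * h, h = h, npoints = np,
                           edge = (npoints - 1) * h, filling = NA),
                      class = "grid_spec")
    charge <- array(0, dim = np)
    ncharge <- 5L
    idx <- sample(which(array(TRUE, np) &
                          update_mask(grid, boundary_spec("zero"))), ncharge)
    charge[idx] <- stats::runif(ncharge, -1, 1)
    atoms <- atom_set(matrix(0, 1, 3), radius = 0.5, charge = sum(charge))
    structure(list(
      eps_x = array(stats::runif(prod(np), 1, 80), dim = np),
      eps_y = array(stats::runif(prod(np), 1, 80), dim = np),
      eps_z = array(stats::runif(prod(np), 1, 80), dim = np),
      kappa2 = if (salt) array(stats::runif(prod(np), 0, 0.1), dim = np)
               else array(0, dim = np),
      charge = charge,
      region = array("external", dim = np),
      atoms = atoms,
      grid = grid,
      eps_in = 2, eps_out = 80
    ), class = "region_maps")
  })
}
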