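#' Build a uniform cubic grid around a solute
#'
#' The grid is a cube centered on the center of the solute's van der Waals
#' bounding box. Exactly two of `filling`, `spacing` and `npoints` must be
#' given; the third is derived. `filling` is the percentage of the box edge
#' occupied by the largest dimension of the solute's van der Waals bounding
#' box. When the derived point count is fractional it is rounded up to the
#' next odd integer and the spacing is recomputed so that the box edge is
#' preserved.
#'
#' @param atoms an [atom_set()]
#' @param filling percentage of the box edge filled by the solute (default
#'   convention: 80)
#' @param spacing grid spacing h, Angstrom (default convention: 1)
#' @param npoints number of grid points per axis (odd integer)
#' @return a `grid_spec`: list with `origin` (3-vector, Angstrom), `h`
#'   (Angstrom), `npoints` (3 odd integers), `edge` (Angstrom)
#' @examples
#' ion <- atom_set(matrix(0, 1, 3), radius = 2, charge = 1)
#' build_grid(ion, filling = 50, spacing = 1)$npoints # 9 9 9
#' @export
build_grid <- function(atoms, filling = NULL, spacing = NULL, npoints = NULL) {
  given <- !c(is.null(filling), is.null(spacing), is.null(npoints))
  if (sum(given) != 2L)
    stop("exactly two of 'filling', 'spacing' and 'npoints' must be given")
  bb <- bounding_box(atoms)
  extent <- max(bb$max - bb$min)
  center <- (bb$max + bb$min) / 2

  if (!is.null(npoints)) {
    npoints <- as.integer(npoints)
    if (npoints < 3L || npoints %% 2L == 0L)
      stop("'npoints' must be an odd integer >= 3")
  }
  if (!is.null(filling)) {
    if (filling <= 0) stop("'filling' must be positive")
    if (filling >= 100)
      warning("filling >= 100%: the solute touches or exceeds the box; ",
              "exterior-dependent boundary conditions will be inaccurate")
  }

  if (is.null(npoints)) {
    edge <- extent / (filling / 100)
    np <- ceiling(edge / spacing - 1e-9) + 1
    if (np %% 2 == 0) np <- np + 1
    npoints <- as.integer(np)
    spacing <- edge / (npoints - 1)
  } else if (is.null(spacing)) {
    edge <- extent / (filling / 100)
    spacing <- edge / (npoints - 1)
  } else {
    edge <- spacing * (npoints - 1)
    filling <- 100 * extent / edge
  }

  structure(list(
    origin  = center - edge / 2,
    h       = spacing,
    npoints = rep(as.integer(npoints), 3L),
    edge    = edge,
    filling = filling
  ), class = "grid_spec")
}

#' @exportS3Method base::print
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d points, h = %.4f A, edge = %.2f A\n",
              x$npoints[1], x$npoints[2], x$npoints[3], x$h, x$edge))
  cat(sprintf("  origin: (%.3f, %.3f, %.3f) A\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Node coordinates along one grid axis
#' @param grid a `grid_spec`
#' @param axis 1, 2 or 3
#' @return numeric vector of world coordinates, Angstrom
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$npoints[axis]) - 1) * grid$h
}

# Continuous (1-based) grid coordinates of world positions.
grid_frac_index <- function(points, grid) {
  sweep(sweep(points, 2, grid$origin, "-"), 2, rep(grid$h, 3), "/") + 1
}

#' Spread atomic point charges onto the grid
#'
#' Trilinear (cloud-in-cell) assignment: each atomic charge is distributed
#' over the eight nodes of its enclosing grid cell with weights given by the
#' trilinear shape function. Total grid charge equals the molecular charge
#' to machine precision.
#'
#' @param atoms an [atom_set()]
#' @param grid a `grid_spec`
#' @return 3-d array of per-node charges, e
#' @export
spread_charges <- function(atoms, grid) {
  np <- grid$npoints
  q <- array(0, dim = np)
  u <- grid_frac_index(atom_coords(atoms), grid)
  bad <- which(apply(u, 1, function(v)
    any(v < 1 - 1e-9) || any(v > np - 1e-9 + 1)))
  if (length(bad) > 0)
    stop("atom(s) outside the grid: index ", paste(bad, collapse = ", "))
  i0 <- pmin(pmax(floor(u), 1), matrix(rep(np - 1, each = nrow(u)), ncol = 3))
  f <- u - i0
  for (a in seq_len(nrow(u))) {
    ii <- i0[a, ]; ff <- f[a, ]
    wx <- c(1 - ff[1], ff[1]); wy <- c(1 - ff[2], ff[2]); wz <- c(1 - ff[3], ff[3])
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- wx[dx + 1] * wy[dy + 1] * wz[dz + 1]
      if (w != 0)
        q[ii[1] + dx, ii[2] + dy, ii[3] + dz] <-
          q[ii[1] + dx, ii[2] + dy, ii[3] + dz] + atoms$charge[a] * w
    }
  }
  q
}

#' Squared Debye-Hueckel screening parameter
#'
#' Computes kappa^2 = 8 pi N_A e^2 I_s / (1000 eps k_B T) in Angstrom^-2.
#' 1/kappa is the Debye screening length of the electrolyte. On the grid,
#' solvent points carry the modified value eps_solvent * kappa^2 (see
#' [assign_region_maps()]).
#'
#' @param ionic_strength ionic strength, mol/L
#' @param temperature temperature, K
#' @param eps_solvent relative dielectric constant of the solvent
#' @return kappa^2 in Angstrom^-2
#' @examples
#' 1 / sqrt(compute_kappa2(0.1, 298.15, 80)) # Debye length ~ 9.7 A
#' @export
compute_kappa2 <- function(ionic_strength, temperature, eps_solvent) {
  if (ionic_strength < 0) stop("'ionic_strength' must be >= 0")
  stopifnot(temperature > 0, eps_solvent > 0)
  pc <- physical_constants()
  n_ions <- pc$N_A * ionic_strength * 1e-27    # number density, A^-3
  8 * pi * n_ions * beta_length(temperature) / eps_solvent
}

#' Define an implicit membrane slab
#'
#' A planar low-dielectric slab in the xy-plane between `zmin` and `zmax`,
#' standing in for a lipid bilayer. Within the slab the solvent dielectric
#' is replaced by `eps_mem` and mobile ions are excluded (kappa = 0); solute
#' interior points keep the solute dielectric.
#'
#' @param zmin,zmax slab extent along z, Angstrom
#' @param eps_mem relative dielectric constant of the membrane (typically 2-3)
#' @return a `membrane_slab` object
#' @export
membrane_slab <- function(zmin, zmax, eps_mem) {
  if (!(zmin < zmax)) stop("membrane slab requires zmin < zmax")
  if (eps_mem <= 0) stop("membrane dielectric must be > 0")
  structure(list(zmin = zmin, zmax = zmax, eps_mem = eps_mem),
            class = "membrane_slab")
}

#' Derive a membrane slab from an atom selection
#'
#' Selects atoms by residue and atom name (e.g. the phosphorus atoms of a
#' POPC bilayer), splits the selection at its median z into an upper and a
#' lower leaflet, and uses the mean z of each leaflet as `zmax` and `zmin`.
#'
#' @param atoms an [atom_set()] with `resid` and `elety` columns
#' @param residue_name residue name of the membrane atoms
#' @param atom_name atom name within the residue
#' @param eps_mem membrane dielectric constant
#' @param min_separation smallest credible leaflet separation, Angstrom
#'   (default 10; lipid bilayers are several times thicker). Selections
#'   whose leaflet means are closer than this are rejected as
#'   single-leaflet input.
#' @return a [membrane_slab()]
#' @export
membrane_from_selection <- function(atoms, residue_name, atom_name, eps_mem,
                                    min_separation = 10) {
  if (is.null(atoms$resid) || is.null(atoms$elety))
    stop("atom set lacks residue/atom names needed for membrane selection")
  sel <- atoms$resid == residue_name & atoms$elety == atom_name
  if (!any(sel)) stop("membrane selection is empty")
  z <- atoms$z[sel]
  med <- stats::median(z)
  upper <- z > med
  lower <- !upper
  if (!any(upper) || !any(lower))
    stop("membrane selection has atoms in only one leaflet")
  zmin <- mean(z[lower])
  zmax <- mean(z[upper])
  if (zmax - zmin < min_separation)
    stop(sprintf(paste("membrane selection looks like a single leaflet:",
                       "leaflet means %.1f A apart (< %.1f A)"),
                 zmax - zmin, min_separation))
  membrane_slab(zmin = zmin, zmax = zmax, eps_mem = eps_mem)
}

#' Assemble dielectric, screening and charge maps
#'
#' Populates the region maps consumed by the solver: the dielectric constant
#' on the three staggered midpoint half-grids, the modified screening map
#' eps_out * kappa^2 at grid points, and the per-node charge map. Mobile
#' ions are excluded (kappa = 0) from the solute interior, from the
#' ion-exclusion (Stern) layer within `radius + ion_radius` of any atom
#' center, and from the membrane slab. Within the slab, midpoints outside
#' the solute take `eps_mem`; solute midpoints keep `eps_in`.
#'
#' The midpoint arrays have the full grid dimensions: `eps_x[i, j, k]` is
#' the midpoint between nodes `i` and `i + 1` along x, with index
#' `i = npoints` describing the wrap-around midpoint used only by periodic
#' boundaries (and carrying the ambient dielectric).
#'
#' @param classification a `point_classification` from [classify_points()]
#' @param midmap a `midpoint_map` (final, probe-reclassified)
#' @param atoms the [atom_set()] (needed for the ion-exclusion layer)
#' @param grid a `grid_spec`
#' @param eps_in,eps_out solute / solvent dielectric constants
#' @param kappa2 squared screening parameter from [compute_kappa2()],
#'   Angstrom^-2
#' @param ion_radius Stern-layer ion radius, Angstrom (default 2)
#' @param membrane optional [membrane_slab()]
#' @return a `region_maps` object: list with `eps_x`, `eps_y`, `eps_z`,
#'   `kappa2` (modified, per node), `charge`, `region`, `grid`
#' @export
assign_region_maps <- function(classification, midmap, atoms, grid,
                               eps_in, eps_out, kappa2 = 0,
                               ion_radius = 2.0, membrane = NULL) {
  if (eps_in <= 0 || eps_out <= 0) stop("dielectric constants must be > 0")
  np <- grid$npoints
  h <- grid$h
  zax <- grid_axis(grid, 3)

  if (!is.null(membrane) &&
      (membrane$zmax < zax[1] || membrane$zmin > zax[np[3]] + h))
    warning("membrane slab lies entirely outside the grid")
  eps_mid <- list()
  for (ax in 1:3) {
    e <- array(eps_out, dim = np)
    if (!is.null(membrane)) {
      # z-coordinate of each midpoint on this half-grid
      zmid <- if (ax == 3) zax + h / 2 else zax
      in_slab <- zmid >= membrane$zmin & zmid <= membrane$zmax
      if (any(in_slab)) {
        idx <- slice.index(e, 3)
        e[in_slab[idx]] <- membrane$eps_mem
      }
    }
    ins <- midmap$inside[[ax]]   # dims np - unit along ax
    di <- dim(ins)
    e[seq_len(di[1]), seq_len(di[2]), seq_len(di[3])][ins] <- eps_in
    eps_mid[[ax]] <- e
  }

  # screening map: eps_out * kappa2 on solvent nodes, 0 elsewhere
  k2 <- array(eps_out * kappa2, dim = np)
  k2[classification$label != "external"] <- 0
  if (kappa2 > 0) {
    # ion-exclusion layer: nodes within (radius + ion_radius) of any atom
    k2[exclusion_mask(atoms, grid, ion_radius)] <- 0
    if (!is.null(membrane)) {
      zin <- zax >= membrane$zmin & zax <= membrane$zmax
      if (any(zin)) k2[zin[slice.index(k2, 3)]] <- 0
    }
  }

  structure(list(
    eps_x = eps_mid[[1]], eps_y = eps_mid[[2]], eps_z = eps_mid[[3]],
    kappa2 = k2,
    charge = spread_charges(atoms, grid),
    region = classification$label,
    atoms = atoms,
    grid = grid,
    eps_in = eps_in, eps_out = eps_out,
    membrane = membrane
  ), class = "region_maps")
}

# Logical node mask: within (radius + extra) of any atom center.
exclusion_mask <- function(atoms, grid, extra) {
  np <- grid$npoints
  mask <- array(FALSE, dim = np)
  ax <- lapply(1:3, function(a) grid_axis(grid, a))
  for (i in seq_len(nrow(atoms))) {
    r <- atoms$radius[i] + extra
    if (r <= 0) next
    ctr <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    rng <- lapply(1:3, function(a) {
      which(abs(ax[[a]] - ctr[a]) <= r)
    })
    if (any(vapply(rng, length, 1L) == 0)) next
    dx2 <- (ax[[1]][rng[[1]]] - ctr[1])^2
    dy2 <- (ax[[2]][rng[[2]]] - ctr[2])^2
    dz2 <- (ax[[3]][rng[[3]]] - ctr[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    mask[rng[[1]], rng[[2]], rng[[3]]] <-
      mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] | (d2 < r^2)
  }
  mask
}

#' @exportS3Method base::print
print.region_maps <- function(x, ...) {
  tab <- table(x$region)
  cat("region_maps on", paste(x$grid$npoints, collapse = " x "), "grid\n")
  cat(sprintf("  eps_in = %g, eps_out = %g%s\n", x$eps_in, x$eps_out,
              if (!is.null(x$membrane))
                sprintf(", membrane [%.1f, %.1f] eps %g",
                        x$membrane$zmin, x$membrane$zmax, x$membrane$eps_mem)
              else ""))
  cat(sprintf("  nodes: %d internal, %d boundary, %d external\n",
              tab["internal"], tab["boundary"], tab["external"]))
  cat(sprintf("  total grid charge: %+.4f e\n", sum(x$charge)))
  invisible(x)
}

#' Build all region maps for a solute in one call
#'
#' Convenience driver: van der Waals midpoint classification, probe
#' reclassification to the solvent-excluded surface, point classification,
#' and map assembly.
#'
#' @inheritParams assign_region_maps
#' @param atoms an [atom_set()]
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water)
#' @return a `region_maps` object (with the final `midmap` attached)
#' @export
build_region_maps <- function(atoms, grid, eps_in = 2, eps_out = 80,
                              kappa2 = 0, probe_radius = 1.4,
                              ion_radius = 2.0, membrane = NULL) {
  mid <- classify_midpoints_vdw(atoms, grid)
  mid <- reclassify_probe(mid, atoms, probe_radius)
  cls <- classify_points(mid)
  maps <- assign_region_maps(cls, mid, atoms, grid, eps_in, eps_out,
                             kappa2, ion_radius, membrane)
  maps$midmap <- mid
  maps$probe_radius <- probe_radius
  maps
}

#' Region maps for the uniform reference state
#'
#' Same grid and charges as `maps`, but a uniform dielectric `eps_in`
#' everywhere and no salt. Used as the second solve of the
#' reference-subtraction solvation energy, which cancels the grid
#' self-energy.
#'
#' @param maps a `region_maps` object
#' @return a `region_maps` object for the homogeneous system
#' @export
homogeneous_reference_maps <- function(maps) {
  np <- maps$grid$npoints
  out <- maps
  out$eps_x <- array(maps$eps_in, dim = np)
  out$eps_y <- array(maps$eps_in, dim = np)
  out$eps_z <- array(maps$eps_in, dim = np)
  out$kappa2 <- array(0, dim = np)
  out$eps_out <- maps$eps_in
  out$membrane <- NULL
  out
}
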