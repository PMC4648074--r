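# High-level drivers tying gridding, surface, solver and energy together.

#' Load the solute described by a parameter set
#'
#' Uses the PQR input when given, otherwise PDB plus radius/charge tables.
#'
#' @param params a `pb_params` list
#' @return an [atom_set()]
#' @export
load_solute <- function(params) {
  if (!is.null(params$pqr)) return(read_pqr(params$pqr))
  if (is.null(params$pdb))
    stop("no structure input: set in(pqr, ...) or in(pdb, ...)")
  if (is.null(params$siz))
    stop("radius table in(siz, ...) is necessary with pdb input")
  if (is.null(params$crg))
    stop("charge table in(crg, ...) is necessary with pdb input")
  read_structure(params$pdb, params$siz, params$crg)
}

# Resolve the two chosen box parameters into a grid.
grid_from_params <- function(atoms, params) {
  set <- params$box_set
  if (length(set) == 0) set <- c("filling", "spacing")
  if (length(set) == 1)
    set <- unique(c(set, if ("spacing" %in% set) "filling" else "spacing"))
  build_grid(atoms,
             filling = if ("filling" %in% set) params$filling,
             spacing = if ("spacing" %in% set) params$spacing,
             npoints = if ("gridS" %in% set) params$gridS)
}

#' Assemble grid, surface classification and region maps from parameters
#'
#' @param atoms an [atom_set()]
#' @param params a `pb_params` list (see [pb_params()])
#' @return list with `grid`, `maps`, `bc`, `conv`, `kappa2`
#' @export
pb_setup <- function(atoms, params = pb_params()) {
  grid <- grid_from_params(atoms, params)
  kappa2 <- if (params$salt > 0)
    compute_kappa2(params$salt, params$temp, params$epsOut) else 0
  membrane <- params$membrane
  if (is.null(membrane) && !is.null(params$memsel))
    membrane <- membrane_from_selection(atoms, params$memsel$resid,
                                        params$memsel$elety,
                                        params$memsel$eps_mem)
  maps <- build_region_maps(atoms, grid,
                            eps_in = params$epsIn, eps_out = params$epsOut,
                            kappa2 = kappa2, probe_radius = params$probe,
                            ion_radius = params$ion, membrane = membrane)
  kind <- if (params$bc == 2L) "quasi_coulombic" else "zero"
  list(grid = grid, maps = maps,
       bc = boundary_spec(kind, params$pb),
       conv = convergence_spec(params$rmsc, params$maxc, params$maxit),
       kappa2 = kappa2)
}

#' Run the full potential calculation
#'
#' @param atoms an [atom_set()]
#' @param params a `pb_params` list
#' @param omega relaxation factor or `"auto"`
#' @return a `solver_result` with the assembled `maps` attached
#' @export
pb_solve <- function(atoms, params = pb_params(), omega = "auto") {
  su <- pb_setup(atoms, params)
  res <- sor_solve(su$maps, su$bc, su$conv, omega, params$temp)
  res$maps <- su$maps
  res
}

#' Solvation free energy of a solute
#'
#' Runs the reference-subtraction method and, optionally, the
#' induced-boundary-charge method on the same heterogeneous solve.
#'
#' @param atoms an [atom_set()]
#' @param params a `pb_params` list
#' @param methods character vector among `"reference"` and `"induced"`
#' @param omega relaxation factor or `"auto"`
#' @return named list of `energy_result` objects (plus `setup`)
#' @export
pb_solvation <- function(atoms, params = pb_params(),
                         methods = c("reference", "induced"),
                         omega = "auto") {
  su <- pb_setup(atoms, params)
  out <- list()
  ref <- solvation_energy_reference(su$maps, NULL, su$bc, su$conv, omega,
                                    params$temp)
  if ("reference" %in% methods) out$reference <- ref
  if ("induced" %in% methods) {
    cls <- structure(list(label = su$maps$region, grid = su$grid),
                     class = "point_classification")
    surf <- project_boundary_points(cls, su$maps$midmap, atoms,
                                    params$probe, su$grid)
    out$induced <- solvation_energy_induced(
      surf, ref$components$heterogeneous$potential, su$maps$charge,
      su$grid, params$epsIn, params$temp)
    out$surface <- surf
  }
  out$setup <- su
  out
}
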