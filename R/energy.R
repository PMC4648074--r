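# Electrostatic solvation free energy: reference-state subtraction and
# induced boundary charges.

energy_result <- function(method, kT_value, temperature, components = NULL) {
  structure(list(
    method = method,
    kcal = kT_value * kT_kcal(temperature),
    kT = kT_value,
    temperature = temperature,
    components = components
  ), class = "energy_result")
}

#' @exportS3Method base::print
print.energy_result <- function(x, ...) {
  cat(sprintf("energy_result (%s): %.4f kcal/mol (%.4f kT at %.2f K)\n",
              x$method, x$kcal, x$kT, x$temperature))
  invisible(x)
}

#' Grid charge-potential interaction energy
#'
#' One half of the sum over all grid nodes of charge times potential. This
#' includes the (grid-dependent) self-energy of the spread charges; it is
#' physically meaningful only in differences between solves on the same
#' grid with the same charge map.
#'
#' @param phi potential array, kT/e
#' @param charge per-node charge array, e
#' @param temperature temperature, K
#' @return energy in kcal/mol (scalar, with attribute `kT`)
#' @export
grid_interaction_energy <- function(phi, charge, temperature = 273.15) {
  if (!identical(dim(phi), dim(charge)))
    stop("potential and charge maps have different dimensions")
  e_kT <- 0.5 * sum(charge * phi)
  structure(e_kT * kT_kcal(temperature), kT = e_kT)
}

#' Solvation free energy by reference-state subtraction
#'
#' Solves the system twice on the identical grid and charge map: once with
#' the heterogeneous dielectric/screening maps and once with a uniform
#' dielectric `eps_in` and no salt. The difference of the two
#' charge-potential sums is the electrostatic solvation free energy; the
#' grid self-energy cancels exactly because charge spreading and grid are
#' identical. For the quasi-Coulombic boundary the homogeneous solve uses
#' `eps_in` as its solvent dielectric, consistent with its own analytic
#' far field.
#'
#' @param maps_het heterogeneous `region_maps`
#' @param maps_hom homogeneous reference maps (from
#'   [homogeneous_reference_maps()]); derived automatically when `NULL`
#' @param bc a [boundary_spec()]
#' @param conv a [convergence_spec()]
#' @param omega relaxation factor or `"auto"`
#' @param temperature temperature, K
#' @return an `energy_result` (method `"reference_subtraction"`) with the
#'   two solves in `components`
#' @export
solvation_energy_reference <- function(maps_het, maps_hom = NULL,
                                       bc = boundary_spec("quasi_coulombic"),
                                       conv = convergence_spec(),
                                       omega = "auto",
                                       temperature = 273.15) {
  if (is.null(maps_hom)) maps_hom <- homogeneous_reference_maps(maps_het)
  if (!identical(maps_het$grid$npoints, maps_hom$grid$npoints) ||
      !isTRUE(all.equal(maps_het$grid$h, maps_hom$grid$h)))
    stop("heterogeneous and homogeneous solves must share one grid")
  if (!isTRUE(all.equal(maps_het$charge, maps_hom$charge)))
    stop("heterogeneous and homogeneous solves must share one charge map")
  sol_het <- sor_solve(maps_het, bc, conv, omega, temperature)
  sol_hom <- sor_solve(maps_hom, bc, conv, omega, temperature)
  e_het <- grid_interaction_energy(sol_het$potential, maps_het$charge,
                                   temperature)
  e_hom <- grid_interaction_energy(sol_hom$potential, maps_hom$charge,
                                   temperature)
  energy_result("reference_subtraction",
                attr(e_het, "kT") - attr(e_hom, "kT"), temperature,
                components = list(heterogeneous = sol_het,
                                  homogeneous = sol_hom,
                                  grid_energy_het_kcal = as.numeric(e_het),
                                  grid_energy_hom_kcal = as.numeric(e_hom)))
}

#' Solvation free energy from induced boundary charges
#'
#' Computes the polarization charge induced at each dielectric-boundary
#' node from the local stencil residual of the converged heterogeneous
#' potential,
#' `q_ind(b) = h/(4 pi f) * (6 phi_b - sum_k phi_k) - q_b / eps_in`
#' (f is the Coulomb factor at the given temperature), places it at the
#' node's projection onto the molecular surface, and sums the Coulomb
#' interaction with the real (spread) charges:
#' `G_W = 1/2 * f * sum_b q_ind(b) sum_p q_p / dist(b_s, p)`.
#' In a homogeneous dielectric the residual, and hence the energy, is
#' exactly zero. Pairs closer than `h/2` are floored to `h/2` (with a
#' warning).
#'
#' @param surface a `surface_point_set` from [project_boundary_points()]
#' @param phi converged heterogeneous potential array, kT/e
#' @param charge per-node charge array, e
#' @param grid a `grid_spec`
#' @param eps_in solute dielectric constant
#' @param temperature temperature, K
#' @return an `energy_result` (method `"induced_charge"`)
#' @export
solvation_energy_induced <- function(surface, phi, charge, grid,
                                     eps_in, temperature = 273.15) {
  np <- grid$npoints
  beta <- beta_length(temperature)
  h <- grid$h
  if (nrow(surface) == 0)
    return(energy_result("induced_charge", 0, temperature))
  i <- surface$i; j <- surface$j; k <- surface$k
  if (any(i <= 1 | i >= np[1] | j <= 1 | j >= np[2] | k <= 1 | k >= np[3]))
    stop("boundary nodes touch the grid faces; enlarge the box")
  nb_sum <- phi[cbind(i - 1, j, k)] + phi[cbind(i + 1, j, k)] +
            phi[cbind(i, j - 1, k)] + phi[cbind(i, j + 1, k)] +
            phi[cbind(i, j, k - 1)] + phi[cbind(i, j, k + 1)]
  q_ind <- h / (4 * pi * beta) * (6 * phi[cbind(i, j, k)] - nb_sum) -
    charge[cbind(i, j, k)] / eps_in

  cp <- which(charge != 0)
  if (length(cp) == 0)
    return(energy_result("induced_charge", 0, temperature))
  sub <- arrayInd(cp, np)
  p_pos <- cbind(grid_axis(grid, 1)[sub[, 1]],
                 grid_axis(grid, 2)[sub[, 2]],
                 grid_axis(grid, 3)[sub[, 3]])
  q_p <- charge[cp]
  bs <- cbind(surface$sx, surface$sy, surface$sz)
  floored <- 0L
  s <- numeric(nrow(bs))
  for (pp in seq_len(nrow(p_pos))) {
    d <- sqrt(rowSums(sweep(bs, 2, p_pos[pp, ], "-")^2))
    small <- d < h / 2
    if (any(small)) { floored <- floored + sum(small); d[small] <- h / 2 }
    s <- s + q_p[pp] / d
  }
  if (floored > 0)
    warning(floored, " surface-charge pair(s) closer than h/2; ",
            "distance floored")
  energy_result("induced_charge", 0.5 * beta * sum(q_ind * s), temperature,
                components = list(n_boundary = nrow(bs),
                                  total_induced_charge = sum(q_ind)))
}

#' Analytic Born solvation energy
#'
#' Closed-form continuum result for a single ion of charge `q` and radius
#' `R` transferred from a medium of dielectric `eps_in` into `eps_out`
#' (no salt): `-f/2 * q^2/R * (1/eps_in - 1/eps_out)` kcal/mol.
#'
#' @param q ion charge, e
#' @param R ion radius, Angstrom
#' @param eps_in,eps_out dielectric constants
#' @return energy in kcal/mol
#' @export
born_energy_analytic <- function(q, R, eps_in = 2, eps_out = 80) {
  -physical_constants()$f_C_kcal / 2 * q^2 / R * (1 / eps_in - 1 / eps_out)
}

#' Analytic screened potential outside a Born ion
#'
#' Debye-Hueckel solution for a sphere of radius `R` carrying a central
#' charge `q`, surrounded by an ion-exclusion shell of thickness
#' `ion_radius`: for `r >= a = R + ion_radius`,
#' `phi(r) = f q exp(-kappa (r - a)) / (eps_out r (1 + kappa a))` in kT/e.
#' Without salt this reduces to the Coulomb potential `f q / (eps_out r)`.
#'
#' @param r radial distance(s), Angstrom
#' @param q charge, e
#' @param R ion radius, Angstrom
#' @param eps_out solvent dielectric
#' @param kappa inverse Debye length, Angstrom^-1 (`sqrt(compute_kappa2())`)
#' @param ion_radius Stern-layer thickness, Angstrom
#' @param temperature temperature, K
#' @return potential(s) in kT/e
#' @export
dh_sphere_potential <- function(r, q, R, eps_out = 80, kappa = 0,
                                ion_radius = 2, temperature = 273.15) {
  a <- R + ion_radius
  beta <- beta_length(temperature)
  beta * q * exp(-kappa * pmax(r - a, 0)) / (eps_out * r * (1 + kappa * a))
}
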