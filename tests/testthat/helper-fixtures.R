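# Shared builders for the test suite. Everything is generated in code; no
# stored data.

# Uniform-dielectric maps on a bare grid (no solute geometry), for solver
# tests that need full control over eps/kappa/charge.
uniform_maps <- function(npoints = 9, h = 1, eps = 80, kappa2 = 0,
                         charge_at = NULL, q = 1) {
  np <- rep(as.integer(npoints), 3L)
  grid <- structure(list(origin = -(np - 1) / 2 * h, h = h, npoints = np,
                         edge = (npoints - 1) * h, filling = NA),
                    class = "grid_spec")
  charge <- array(0, dim = np)
  if (!is.null(charge_at)) charge[charge_at[1], charge_at[2], charge_at[3]] <- q
  atoms <- atom_set(matrix(0, 1, 3), radius = 0.5, charge = q)
  structure(list(
    eps_x = array(eps, np), eps_y = array(eps, np), eps_z = array(eps, np),
    kappa2 = array(kappa2, np), charge = charge,
    region = array("external", np),
    atoms = atoms, grid = grid, eps_in = eps, eps_out = eps
  ), class = "region_maps")
}

# Toy 3-atom PDB + DelPhi-style .siz/.crg fixture written to a temp dir.
write_toy_pdb_fixture <- function(dir = tempfile("toy")) {
  dir.create(dir)
  pdb <- file.path(dir, "toy.pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  O   ALA A   1       0.000   2.000   0.000  1.00  0.00           O",
    "END"), pdb)
  siz <- file.path(dir, "toy.siz")
  writeLines(c("atom__res_radius",
               "N    ALA  1.55",
               "CA   ALA  2.00",
               "O         1.40"), siz)   # O: wildcard residue
  crg <- file.path(dir, "toy.crg")
  writeLines(c("atom__resnumbc_charge",
               "N    ALA  -0.30",
               "CA   ALA   0.10",
               "O          -0.55"), crg)
  list(pdb = pdb, siz = siz, crg = crg, dir = dir,
       radius = c(1.55, 2.00, 1.40), charge = c(-0.30, 0.10, -0.55))
}

# Dense sample of the solvent-excluded surface of two equal spheres:
# convex sphere patches plus the reentrant torus traced by probes on the
# seam circle. Independent geometric construction used as projection oracle.
sample_dumbbell_ses <- function(c1, c2, r, p) {
  ext <- r + p
  th <- seq(0, pi, length.out = 200)
  ph <- seq(0, 2 * pi, length.out = 400)
  sph <- cbind(rep(cos(th), each = length(ph)),
               rep(sin(th), each = length(ph)) * cos(ph),
               rep(sin(th), each = length(ph)) * sin(ph))
  pts <- list()
  for (c0 in list(c1, c2)) {
    other <- if (identical(c0, c1)) c2 else c1
    vdw <- sweep(sph * r, 2, c0, "+")
    sas <- sweep(sph * ext, 2, c0, "+")
    keep <- sqrt(rowSums(sweep(sas, 2, other, "-")^2)) >= ext
    pts[[length(pts) + 1L]] <- vdw[keep, , drop = FALSE]
  }
  # reentrant torus: probe centers on the intersection circle of the two
  # extended spheres
  D <- sqrt(sum((c2 - c1)^2))
  u <- (c2 - c1) / D
  a <- D / 2                      # equal radii
  rho <- sqrt(ext^2 - a^2)
  e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ang <- seq(0, 2 * pi, length.out = 400)
  tor <- list()
  for (al in ang) {
    s <- c1 + a * u + rho * (cos(al) * e1 + sin(al) * e2)
    t1 <- (c1 - s) / ext; t2 <- (c2 - s) / ext   # unit, toward tangent pts
    for (tt in seq(0, 1, length.out = 25)) {
      w <- (1 - tt) * t1 + tt * t2
      w <- w / sqrt(sum(w^2))
      tor[[length(tor) + 1L]] <- s + p * w
    }
  }
  rbind(do.call(rbind, pts), do.call(rbind, tor))
}

# World coordinates of all midpoints on half-grid `ax` (test-side copy).
all_midpoints <- function(grid, ax) {
  dims <- grid$npoints
  dims[ax] <- dims[ax] - 1L
  sub <- arrayInd(seq_len(prod(dims)), dims)
  axes <- lapply(1:3, function(al) {
    v <- fdpb::grid_axis(grid, al)
    if (al == ax) v[-length(v)] + grid$h / 2 else v
  })
  cbind(axes[[1]][sub[, 1]], axes[[2]][sub[, 2]], axes[[3]][sub[, 3]])
}
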