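test_that("stencil_update reproduces the discretized equation literally", {
  set.seed(7)
  m <- uniform_maps(5, h = 0.8)
  m$eps_x[] <- runif(length(m$eps_x), 1, 80)
  m$eps_y[] <- runif(length(m$eps_y), 1, 80)
  m$eps_z[] <- runif(length(m$eps_z), 1, 80)
  m$kappa2[] <- runif(length(m$kappa2), 0, 1)
  m$charge[] <- runif(length(m$charge), -1, 1)
  phi <- array(rnorm(prod(m$grid$npoints)), dim = m$grid$npoints)
  idx <- c(3, 3, 3)
  # literal arithmetic oracle
  h <- m$grid$h
  beta <- fdpb:::beta_length(298.15)
  eps <- c(m$eps_x[2, 3, 3], m$eps_x[3, 3, 3],
           m$eps_y[3, 2, 3], m$eps_y[3, 3, 3],
           m$eps_z[3, 3, 2], m$eps_z[3, 3, 3])
  nb <- c(phi[2, 3, 3], phi[4, 3, 3], phi[3, 2, 3], phi[3, 4, 3],
          phi[3, 3, 2], phi[3, 3, 4])
  want <- (sum(eps * nb) + 4 * pi * m$charge[3, 3, 3] * beta / h) /
    (sum(eps) + m$kappa2[3, 3, 3] * h^2)
  expect_equal(stencil_update(phi, m, idx, 298.15), want, tolerance = 1e-14)
})

test_that("uniform fast stencil agrees with the full formula", {
  m <- uniform_maps(5, h = 1, eps = 40, kappa2 = 0.3)
  phi <- array(seq_len(125) / 10, dim = c(5, 5, 5))
  full <- stencil_update(phi, m, c(3, 3, 3))
  fast <- stencil_update(phi, m, c(3, 3, 3), fast = TRUE)
  expect_equal(full, fast, tolerance = 1e-14)
  # without salt and charge: arithmetic mean of the six neighbors
  m0 <- uniform_maps(5, h = 1, eps = 40, kappa2 = 0)
  nb_mean <- mean(c(phi[2, 3, 3], phi[4, 3, 3], phi[3, 2, 3],
                    phi[3, 4, 3], phi[3, 3, 2], phi[3, 3, 4]))
  expect_equal(stencil_update(phi, m0, c(3, 3, 3)), nb_mean)
  # fixed point: all neighbors at v
  phi[] <- 3.7
  expect_equal(stencil_update(phi, m0, c(3, 3, 3)), 3.7)
})

test_that("rmsc and maxc match their definitions", {
  a <- array(0, dim = c(4, 4, 4))
  expect_equal(rmsc(a, a), 0)
  expect_equal(maxc(a, a), 0)
  b <- a; b[2, 3, 1] <- 0.5
  expect_equal(rmsc(b, a), 0.5 / sqrt(64))
  expect_equal(maxc(b, a), 0.5)
  set.seed(5)
  x <- array(rnorm(64), dim = c(4, 4, 4))
  y <- array(rnorm(64), dim = c(4, 4, 4))
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  expect_equal(rmsc(x, y), sqrt(s / 64))
  expect_equal(maxc(x, y), max(abs(x - y)))
  expect_error(rmsc(a, array(0, c(3, 3, 3))), "dimensions")
})

test_that("one omega=1 sweep equals a hand-written red-black Gauss-Seidel", {
  m <- make_random_maps(7, h = 1, seed = 9)
  bc <- boundary_spec("zero")
  diag <- fdpb:::stencil_diag(m)
  upd <- fdpb:::update_mask(m$grid, bc)
  beta <- fdpb:::beta_length(273.15)
  src <- 4 * pi * m$charge * beta / m$grid$h
  np <- m$grid$npoints

  set.seed(2)
  start <- array(rnorm(prod(np)), dim = np)
  start[!upd] <- 0

  # reference sweep in plain R: color 0 then color 1, in-place
  ref <- start
  for (color in 0:1) {
    for (k in 1:np[3]) for (j in 1:np[2]) for (i in 1:np[1]) {
      if (!upd[i, j, k]) next
      if ((i + j + k - 3) %% 2 != color) next
      num <- src[i, j, k] +
        m$eps_x[i - 1, j, k] * ref[i - 1, j, k] +
        m$eps_x[i, j, k] * ref[i + 1, j, k] +
        m$eps_y[i, j - 1, k] * ref[i, j - 1, k] +
        m$eps_y[i, j, k] * ref[i, j + 1, k] +
        m$eps_z[i, j, k - 1] * ref[i, j, k - 1] +
        m$eps_z[i, j, k] * ref[i, j, k + 1]
      ref[i, j, k] <- num / diag[i, j, k]
    }
  }
  phi <- start + 0   # force a fresh copy for the in-place C sweep
  fdpb:::pb_sor_sweep(phi, m$eps_x, m$eps_y, m$eps_z, diag, src, upd,
                      bc$periodic, 1.0)
  expect_equal(phi, ref, tolerance = 1e-14)
})

test_that("SOR solution matches the dense direct solve on random maps", {
  bc <- boundary_spec("zero")
  cv <- convergence_spec(1e-12, 1e-12, 5000)
  for (seed in 1:5) {
    m <- make_random_maps(if (seed %% 2) 9 else 11, h = 1, seed = seed)
    direct <- dense_system_oracle(m, bc)
    sol <- sor_solve(m, bc, cv, omega = "auto")
    expect_lt(max(abs(sol$potential - direct)), 1e-8)
  }
})

test_that("trivial and degenerate solves behave as fixed points", {
  m <- uniform_maps(7, eps = 80)
  sol <- sor_solve(m, boundary_spec("zero"))
  expect_equal(sol$iterations, 1L)
  expect_true(sol$converged)
  expect_equal(sol$criterion, "rmsc")
  expect_true(all(sol$potential == 0))
})

test_that("quasi-Coulombic boundary values follow the screened formula", {
  g <- structure(list(origin = c(-30, -30, -30), h = 30, npoints = rep(3L, 3),
                      edge = 60, filling = NA), class = "grid_spec")
  at <- atom_set(matrix(0, 1, 3), 1, 1)   # +1 e at the box center
  bv <- apply_boundary(boundary_spec("quasi_coulombic"), at, g, 80,
                       debye_length = 9.63, temperature = 298.15)
  beta <- fdpb:::beta_length(298.15)
  want <- beta * exp(-30 / 9.63) / (30 * 80)
  expect_equal(bv$values[1, 2, 2], want, tolerance = 1e-12)

  # no salt: pure Coulomb limit
  bv0 <- apply_boundary(boundary_spec("quasi_coulombic"), at, g, 80,
                        debye_length = Inf, temperature = 298.15)
  expect_equal(bv0$values[1, 2, 2], beta / (30 * 80))

  # all-negative molecule: negative boundary everywhere
  atn <- atom_set(rbind(c(0, 0, 0), c(1, 0, 0)), 1, c(-0.5, -0.7))
  bvn <- apply_boundary(boundary_spec("quasi_coulombic"), atn, g, 80,
                        temperature = 298.15)
  expect_true(all(bvn$values[bvn$fixed] < 0))

  # uncharged solute: fall back to zero with a warning
  at0 <- atom_set(matrix(0, 1, 3), 1, 0)
  expect_warning(
    bvz <- apply_boundary(boundary_spec("quasi_coulombic"), at0, g, 80),
    "uncharged")
  expect_true(all(bvz$values == 0))
})

test_that("spectral radius estimate matches closed form and hand algebra", {
  m <- uniform_maps(15, eps = 80)
  lam <- estimate_spectral_radius(m)
  expect_equal(lam, cos(pi / 14), tolerance = 1e-6)

  # 3^3 grid, zero boundary: one unknown with no unknown neighbors -> 0
  m3 <- uniform_maps(3, eps = 80)
  expect_equal(estimate_spectral_radius(m3), 0)

  # salt strictly decreases the radius (diagonal grows)
  ms <- uniform_maps(15, eps = 80, kappa2 = 1)
  expect_lt(estimate_spectral_radius(ms), lam)
})

test_that("optimal omega has the textbook limits and variants", {
  expect_equal(optimal_omega(0), 1)
  expect_gt(optimal_omega(1 - 1e-10), 1.99)
  expect_lt(optimal_omega(0.999), 2)
  expect_error(optimal_omega(1), "spectral radius")
  expect_error(optimal_omega(-0.1), "spectral radius")
  expect_equal(optimal_omega(0.25, variant = "radius_as_squared"),
               2 / (1 + sqrt(0.75)))
  expect_equal(optimal_omega(0.5), 2 / (1 + sqrt(0.75)))
})

test_that("computed omega converges no slower than plain Gauss-Seidel", {
  m <- uniform_maps(15, eps = 80, charge_at = c(8, 8, 8))
  cv <- convergence_spec(1e-6, 1e-10, 5000)
  s1 <- sor_solve(m, boundary_spec("zero"), cv, omega = 1,
                  temperature = 298.15)
  s2 <- sor_solve(m, boundary_spec("zero"), cv, omega = "auto",
                  temperature = 298.15)
  expect_true(s1$converged && s2$converged)
  expect_lte(s2$iterations, s1$iterations)
})

test_that("all-periodic solutions shift cyclically with the solute", {
  db <- make_dumbbell(1.5, 1.5, 4, charges = c(1, -1))
  np <- 17L; h <- 1
  mk <- function(shift) {
    grid <- structure(list(origin = c(-8, -8, -8), h = h,
                           npoints = rep(np, 3L), edge = 16, filling = NA),
                      class = "grid_spec")
    at <- db; at$x <- at$x + shift
    k2 <- compute_kappa2(0.1, 298.15, 80)
    build_region_maps(at, grid, 2, 80, k2, 1.4, 2)
  }
  bc <- boundary_spec("zero", periodic = c(TRUE, TRUE, TRUE))
  cv <- convergence_spec(1e-12, 1e-12, 10000)
  s0 <- sor_solve(mk(0), bc, cv, omega = 1.6, temperature = 298.15)
  s1 <- sor_solve(mk(1), bc, cv, omega = 1.6, temperature = 298.15)
  shifted <- s0$potential[c(np, seq_len(np - 1)), , ]
  expect_lt(max(abs(s1$potential - shifted)), 1e-8)
})

test_that("mixed lateral-periodic + quasi-Coulombic boundaries solve", {
  db <- atom_set(rbind(c(0, 0, -2), c(0, 0, 2)), radius = 2,
                 charge = c(1, 1))
  g <- build_grid(db, filling = 50, spacing = 1)
  maps <- build_region_maps(db, g, 2, 80, 0, 1.4, 2)
  bc <- boundary_spec("quasi_coulombic", periodic = c(TRUE, TRUE, FALSE))
  sol <- sor_solve(maps, bc, convergence_spec(1e-8, 1e-8, 2000),
                   temperature = 298.15)
  expect_true(sol$converged)
  np <- g$npoints
  # z faces carry the fixed screened-Coulomb values, x/y faces are free
  bv <- apply_boundary(bc, db, g, 80, Inf, 298.15)
  expect_equal(sol$potential[, , 1], bv$values[, , 1])
  expect_true(all(bv$values[, , 1] > 0))   # net positive solute
  expect_false(isTRUE(all.equal(sol$potential[1, , ],
                                bv$values[1, , ])))
})

test_that("potential sampling is trilinear-exact", {
  g <- structure(list(origin = c(0, 0, 0), h = 1, npoints = rep(5L, 3),
                      edge = 4, filling = NA), class = "grid_spec")
  phi <- array(2.5, dim = c(5, 5, 5))
  pts <- rbind(c(1.3, 2.7, 0.2), c(0, 0, 0), c(4, 4, 4))
  expect_equal(sample_potential(phi, g, pts), rep(2.5, 3))

  # affine field reproduced exactly at arbitrary points
  ax <- fdpb::grid_axis(g, 1)
  f <- function(x, y, z) 1 + 2 * x - 3 * y + 0.5 * z
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    phi[i, j, k] <- f(ax[i], ax[j], ax[k])
  set.seed(3)
  pts <- matrix(runif(30, 0, 4), ncol = 3)
  expect_equal(sample_potential(phi, g, pts),
               f(pts[, 1], pts[, 2], pts[, 3]), tolerance = 1e-12)
  # node-coincident points return the stored value
  expect_equal(sample_potential(phi, g, c(2, 3, 1)), phi[3, 4, 2])
  expect_error(sample_potential(phi, g, c(9, 0, 0)), "index 1")
})
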