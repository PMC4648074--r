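test_that("vdW midpoint classification matches a brute-force scan", {
  at <- make_born_ion(0, 1.5)
  g <- build_grid(at, filling = 50, spacing = 1)
  mid <- classify_midpoints_vdw(at, g)
  ctr <- (g$npoints[1] + 1) / 2
  # x-midpoint at distance 0.5 from the center: inside
  expect_true(mid$inside[[1]][ctr, ctr, ctr])
  # y-midpoint at distance sqrt(1.5^2 + 0.25) = 1.58 > 1.5: outside
  expect_false(mid$inside[[2]][ctr, ctr + 1, ctr])

  # 20 random atoms: per-atom sub-box equals global all-midpoints scan
  mol <- make_random_molecule(20, seed = 4)
  g2 <- build_grid(mol, filling = 80, spacing = 1.5)
  mid2 <- classify_midpoints_vdw(mol, g2)
  ctrm <- atom_coords(mol)
  for (ax in 1:3) {
    pts <- all_midpoints(g2, ax)
    ins <- rep(FALSE, nrow(pts))
    for (a in seq_len(nrow(mol)))
      ins <- ins | sqrt(rowSums(sweep(pts, 2, ctrm[a, ], "-")^2)) <
        mol$radius[a]
    expect_identical(as.vector(mid2$inside[[ax]]), ins)
  }
})

test_that("node classification follows the six-midpoint rule", {
  at <- make_born_ion(0, 1.5)
  g <- build_grid(at, filling = 30, spacing = 1)
  np <- g$npoints

  # no solute: every node external
  empty <- classify_midpoints_vdw(atom_set(matrix(0, 1, 3), 0, 0), g)
  cls <- classify_points(empty)
  expect_true(all(cls$label == "external"))

  # a single inside midpoint flips exactly its two flanking nodes
  empty$inside[[1]][4, 4, 4] <- TRUE
  cls <- classify_points(empty)
  expect_equal(sum(cls$label == "boundary"), 2L)
  expect_equal(cls$label[4, 4, 4], "boundary")
  expect_equal(cls$label[5, 4, 4], "boundary")

  # random midpoint map: labels equal a direct 6-neighbor check
  mid <- classify_midpoints_vdw(at, g)
  set.seed(42)
  for (ax in 1:3)
    mid$inside[[ax]][] <- stats::runif(length(mid$inside[[ax]])) < 0.3
  cls <- classify_points(mid)
  ins <- mid$inside
  for (trial in 1:200) {
    i <- sample(np[1], 1); j <- sample(np[2], 1); k <- sample(np[3], 1)
    vals <- c(if (i > 1) ins[[1]][i - 1, j, k],
              if (i < np[1]) ins[[1]][i, j, k],
              if (j > 1) ins[[2]][i, j - 1, k],
              if (j < np[2]) ins[[2]][i, j, k],
              if (k > 1) ins[[3]][i, j, k - 1],
              if (k < np[3]) ins[[3]][i, j, k])
    want <- if (all(vals)) "internal" else
      if (!any(vals)) "external" else "boundary"
    expect_identical(cls$label[i, j, k], want)
  }
})

test_that("sas_depth handles single spheres, signs and overlap seams", {
  at <- make_born_ion(0, 2)
  expect_equal(sas_depth(c(2.5, 0, 0), at, 1.4), 0.9)
  expect_lt(sas_depth(c(5, 0, 0), at, 1.4), 0)
  expect_equal(sas_depth(c(0, 0, 0), at, 1.4), 3.4)

  # two-sphere neck: depth equals the distance to a densely sampled union
  # boundary within 1e-3
  db <- make_dumbbell(2, 2, 5)
  p <- 1.4
  ext <- 2 + p
  # dense sample of the SAS (union of the two extended spheres)
  th <- seq(0, pi, length.out = 600)
  ph <- seq(0, 2 * pi, length.out = 1200)
  sph <- cbind(rep(cos(th), each = length(ph)),
               rep(sin(th), each = length(ph)) * cos(ph),
               rep(sin(th), each = length(ph)) * sin(ph))
  surf <- rbind(sweep(sph * ext, 2, c(-2.5, 0, 0), "+"),
                sweep(sph * ext, 2, c(2.5, 0, 0), "+"))
  d1 <- sqrt(rowSums(sweep(surf, 2, c(-2.5, 0, 0), "-")^2))
  d2 <- sqrt(rowSums(sweep(surf, 2, c(2.5, 0, 0), "-")^2))
  surf <- surf[d1 >= ext - 1e-9 & d2 >= ext - 1e-9, ]   # union boundary
  for (q in list(c(0, 1.0, 0), c(0.3, 2.0, 0.2), c(0, 2.8, 0))) {
    true_d <- min(sqrt(rowSums(sweep(surf, 2, q, "-")^2)))
    inside <- min(d_at <- c(sqrt(sum((q - c(-2.5, 0, 0))^2)),
                            sqrt(sum((q - c(2.5, 0, 0))^2)))) < ext
    expect_equal(sas_depth(q, db, p), (if (inside) 1 else -1) * true_d,
                 tolerance = 2e-3)
  }
})

test_that("probe reclassification is convex-exact, monotone and terminating", {
  at <- make_born_ion(1, 2)
  g <- build_grid(at, filling = 40, spacing = 0.5)
  vdw <- classify_midpoints_vdw(at, g)

  # probe 0 is a no-op
  expect_identical(reclassify_probe(vdw, at, 0)$inside, vdw$inside)
  # convexity identity: a single sphere never flips, for any probe
  for (p in c(0.5, 1.4, 3)) {
    out <- reclassify_probe(vdw, at, p)
    expect_identical(out$inside, vdw$inside)
  }

  # probe-size monotonicity on the dumbbell: inside sets nest
  db <- make_dumbbell(2, 2, 5)
  g2 <- build_grid(db, filling = 60, spacing = 0.5)
  vdw2 <- classify_midpoints_vdw(db, g2)
  prev <- NULL
  for (p in c(0.6, 1.0, 1.4, 2.0)) {
    cur <- reclassify_probe(vdw2, db, p)
    if (!is.null(prev))
      for (ax in 1:3) expect_true(all(cur$inside[[ax]] >= prev$inside[[ax]]))
    for (ax in 1:3)   # one-directional: never unflips the vdW set
      expect_true(all(cur$inside[[ax]] >= vdw2$inside[[ax]]))
    prev <- cur
  }
})

test_that("reclassified midpoints agree with the brute-force probe oracle", {
  db <- make_dumbbell(2, 2, 5)
  h <- 1.0
  g <- build_grid(db, spacing = h, filling = 60)
  vdw <- classify_midpoints_vdw(db, g)
  mid <- reclassify_probe(vdw, db, 1.4)
  n_tot <- 0; n_dis <- 0
  for (ax in 1:3) {
    idx <- which(!vdw$inside[[ax]])
    pts <- all_midpoints(g, ax)[idx, , drop = FALSE]
    dep <- sas_depth(pts, db, 1.4)
    cand <- which(dep > 0)   # only midpoints under the SAS can flip
    orc <- brute_force_probe_oracle(pts[cand, , drop = FALSE], db, 1.4,
                                    h / 4)
    ours <- mid$inside[[ax]][idx[cand]]
    n_tot <- n_tot + length(cand)
    n_dis <- n_dis + sum(orc != ours)
  }
  expect_lt(n_dis / n_tot, 0.05)
  # flipped set is symmetric about the midplane between the atoms
  flips <- which(mid$inside[[2]] & !vdw$inside[[2]])
  sub <- arrayInd(flips, dim(mid$inside[[2]]))
  xs <- fdpb::grid_axis(g, 1)[sub[, 1]]
  expect_setequal(round(xs, 9), round(-xs, 9))
  expect_gt(length(flips), 0)
})

test_that("boundary projection lands on the molecular surface", {
  at <- make_born_ion(1, 2)
  g <- build_grid(at, filling = 40, spacing = 0.5)
  mid <- reclassify_probe(classify_midpoints_vdw(at, g), at, 1.4)
  cls <- classify_points(mid)
  surf <- project_boundary_points(cls, mid, at, 1.4, g)
  expect_gt(nrow(surf), 0)
  # convex region: |b_s - c| = r exactly, b_s collinear with b and c
  r_s <- sqrt(surf$sx^2 + surf$sy^2 + surf$sz^2)
  expect_equal(r_s, rep(2, nrow(surf)), tolerance = 1e-12)
  cross <- abs(surf$bx * surf$sy - surf$by * surf$sx)
  expect_lt(max(cross / pmax(r_s, 1)), 1e-9)

  # two-atom fixture: every b_s within h of a densely sampled SES
  db <- make_dumbbell(2, 2, 5)
  h <- 0.5
  g2 <- build_grid(db, spacing = h, filling = 60)
  mid2 <- reclassify_probe(classify_midpoints_vdw(db, g2), db, 1.4)
  cls2 <- classify_points(mid2)
  surf2 <- project_boundary_points(cls2, mid2, db, 1.4, g2)
  ses <- sample_dumbbell_ses(c1 = c(-2.5, 0, 0), c2 = c(2.5, 0, 0),
                             r = 2, p = 1.4)
  for (row in seq_len(nrow(surf2))) {
    bs <- c(surf2$sx[row], surf2$sy[row], surf2$sz[row])
    expect_lt(min(sqrt(rowSums(sweep(ses, 2, bs, "-")^2))), h)
  }
})
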