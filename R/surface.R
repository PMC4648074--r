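# Molecular-surface-aware classification of the grid.
#
# Midpoints of the three staggered half-grids are classified against the van
# der Waals surface, then reclassified iteratively against the
# solvent-excluded surface traced by a spherical probe; grid nodes are
# labeled internal/boundary/external from their six adjacent midpoints.

# World coordinates of midpoints on half-grid `ax`: the midpoint [i, j, k]
# sits between nodes i and i+1 along `ax` (dims: np - unit vector along ax).
midpoint_axis <- function(grid, ax, along) {
  v <- grid_axis(grid, along)
  if (along == ax) v[-length(v)] + grid$h / 2 else v
}

mid_dims <- function(grid, ax) {
  d <- grid$npoints
  d[ax] <- d[ax] - 1L
  d
}

#' Classify midpoints against the van der Waals surface
#'
#' A midpoint is inside the solute iff it lies strictly within the van der
#' Waals sphere of at least one atom. The scan is per-atom over the atom's
#' bounding sub-box.
#'
#' @param atoms an [atom_set()]
#' @param grid a `grid_spec`
#' @return a `midpoint_map`: list with `inside` (list of three logical
#'   arrays, x-, y-, z-half-grids) and `grid`
#' @export
classify_midpoints_vdw <- function(atoms, grid) {
  inside <- lapply(1:3, function(ax) array(FALSE, dim = mid_dims(grid, ax)))
  for (ax in 1:3) {
    axes <- lapply(1:3, function(al) midpoint_axis(grid, ax, al))
    for (i in seq_len(nrow(atoms))) {
      r <- atoms$radius[i]
      if (r <= 0) next
      ctr <- c(atoms$x[i], atoms$y[i], atoms$z[i])
      rng <- lapply(1:3, function(al) which(abs(axes[[al]] - ctr[al]) < r))
      if (any(vapply(rng, length, 1L) == 0)) next
      d2 <- outer(outer((axes[[1]][rng[[1]]] - ctr[1])^2,
                        (axes[[2]][rng[[2]]] - ctr[2])^2, "+"),
                  (axes[[3]][rng[[3]]] - ctr[3])^2, "+")
      inside[[ax]][rng[[1]], rng[[2]], rng[[3]]] <-
        inside[[ax]][rng[[1]], rng[[2]], rng[[3]], drop = FALSE] |
        (d2 < r^2)
    }
  }
  structure(list(inside = inside, grid = grid), class = "midpoint_map")
}

# Pad a half-grid array back to full node dims with `fill` on the missing
# top slice along `ax`.
pad_hi <- function(a, ax, np, fill) {
  out <- array(fill, dim = np)
  d <- dim(a)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  out
}

# Shift a full-dims array by +1 along `ax`, filling the vacated slice.
shift_up <- function(a, ax, fill) {
  np <- dim(a)
  idx <- lapply(np, seq_len)
  src <- idx; src[[ax]] <- seq_len(np[ax] - 1L)
  dst <- idx; dst[[ax]] <- 1L + seq_len(np[ax] - 1L)
  out <- array(fill, dim = np)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Classify grid nodes from the midpoint map
#'
#' A node is `internal` if all of its adjacent midpoints are inside the
#' solute, `external` if all are outside, and `boundary` otherwise. Nodes on
#' the grid faces use only their existing midpoints.
#'
#' @param midmap a `midpoint_map`
#' @return a `point_classification`: list with `label` (character array,
#'   `"internal"`/`"boundary"`/`"external"`) and `grid`
#' @export
classify_points <- function(midmap) {
  grid <- midmap$grid
  np <- grid$npoints
  n_in <- array(0L, dim = np)
  n_tot <- array(0L, dim = np)
  for (ax in 1:3) {
    ins <- pad_hi(midmap$inside[[ax]], ax, np, NA)   # midpoint above node
    lo <- shift_up(ins, ax, NA)                      # midpoint below node
    n_in <- n_in + (!is.na(ins) & ins) + (!is.na(lo) & lo)
    n_tot <- n_tot + (!is.na(ins)) + (!is.na(lo))
  }
  label <- array("boundary", dim = np)
  label[n_in == 0L] <- "external"
  label[n_in == n_tot] <- "internal"
  structure(list(label = label, grid = grid), class = "point_classification")
}

#' Signed depth below the solvent-accessible surface
#'
#' The solvent-accessible surface (SAS) is the boundary of the union of the
#' probe-extended atom spheres (radius + probe). The depth of a point is its
#' distance to that union boundary, positive inside (below) the SAS and
#' negative outside. Overlapping extended spheres are handled by
#' nearest-point projection with rejection: the candidate nearest point on
#' sphere i is discarded when it falls strictly inside another extended
#' sphere (exact for pairwise overlaps). If every candidate is rejected the
#' depth falls back to the maximal single-sphere penetration.
#'
#' @param points n x 3 matrix (or 3-vector) of query positions, Angstrom
#' @param atoms an [atom_set()]
#' @param probe_radius probe radius, Angstrom
#' @return numeric vector of signed depths, Angstrom
#' @export
sas_depth <- function(points, atoms, probe_radius) {
  sas_nearest(points, atoms, probe_radius)$depth
}

# Depth plus the surviving candidate atom (NA when all candidates were
# rejected, i.e. the nearest SAS point lies on an intersection seam).
sas_nearest <- function(points, atoms, probe_radius) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  m <- nrow(points)
  n <- nrow(atoms)
  ctr <- atom_coords(atoms)
  ext <- atoms$radius + probe_radius
  d <- matrix(0, m, n)
  for (j in seq_len(n))
    d[, j] <- sqrt(rowSums(sweep(points, 2, ctr[j, ], "-")^2))
  pen <- sweep(-d, 2, ext, "+")            # (ext_j - d_j): >0 => inside j
  inside_any <- apply(pen, 1, max) > 0
  cand_dist <- abs(pen)                    # distance to sphere j's surface
  alive <- matrix(TRUE, m, n)
  tol <- 1e-9
  for (j in seq_len(n)) {
    dj <- pmax(d[, j], 1e-12)
    # candidate point on extended sphere j
    cand <- ctr[rep(j, m), , drop = FALSE] +
      sweep(points - ctr[rep(j, m), , drop = FALSE], 1, ext[j] / dj, "*")
    for (l in seq_len(n)) {
      if (l == j) next
      dl <- sqrt(rowSums(sweep(cand, 2, ctr[l, ], "-")^2))
      alive[, j] <- alive[, j] & (dl >= ext[l] - tol)
    }
  }
  cand_dist[!alive] <- Inf
  best <- max.col(-cand_dist, ties.method = "first")
  best_dist <- cand_dist[cbind(seq_len(m), best)]
  rejected <- !is.finite(best_dist)
  depth <- ifelse(inside_any, 1, -1) * best_dist
  # all radial candidates rejected: the nearest SAS point lies on an
  # intersection seam; measure the distance to the seam circle (exact for
  # pairwise overlaps), falling back to the deepest single-sphere
  # penetration only when no overlap circle exists
  for (p_i in which(rejected)) {
    ord <- order(-pen[p_i, ])
    top <- utils::head(ord, 4L)
    dmin <- Inf
    for (a1 in seq_along(top)) for (a2 in seq_along(top)) {
      if (a2 <= a1) next
      s <- circle_nearest_point(points[p_i, ], ctr[top[a1], ],
                                ctr[top[a2], ], ext[top[a1]], ext[top[a2]])
      if (is.null(s)) next
      ok <- TRUE
      for (l in seq_len(n)) {
        if (l %in% top[c(a1, a2)]) next
        if (sum((s - ctr[l, ])^2) < (ext[l] - tol)^2) { ok <- FALSE; break }
      }
      if (ok) dmin <- min(dmin, sqrt(sum((points[p_i, ] - s)^2)))
    }
    depth[p_i] <- if (is.finite(dmin)) sign(depth[p_i]) * dmin
                  else max(pen[p_i, ])
  }
  list(depth = depth, atom = ifelse(rejected, NA_integer_, best),
       dist = d, pen = pen)
}

# Midpoints adjacent to any TRUE node in `nodes` on half-grid `ax`:
# midpoint [i,...] flanks nodes i and i+1 along ax.
mids_adjacent_to <- function(nodes, ax, grid) {
  np <- grid$npoints
  idx <- lapply(np, seq_len)
  lo <- idx; lo[[ax]] <- seq_len(np[ax] - 1L)
  hi <- idx; hi[[ax]] <- 1L + seq_len(np[ax] - 1L)
  nodes[lo[[1]], lo[[2]], lo[[3]]] | nodes[hi[[1]], hi[[2]], hi[[3]]]
}

#' Reclassify midpoints against the solvent-excluded surface
#'
#' Starting from the van der Waals classification, outside midpoints
#' adjacent to boundary nodes are examined: a midpoint whose depth below the
#' solvent-accessible surface is at least the probe radius cannot be touched
#' by any probe sphere and is flipped to inside. Node labels are then
#' recomputed and the pass repeats until no midpoint flips. Flips are
#' one-directional (outside to inside), so the iteration terminates. A probe
#' radius of zero leaves the map unchanged (the molecular surface equals the
#' van der Waals surface).
#'
#' @param midmap a `midpoint_map` (van der Waals classification)
#' @param atoms an [atom_set()]
#' @param probe_radius probe radius, Angstrom
#' @return the reclassified `midpoint_map` (with attribute `passes`)
#' @export
reclassify_probe <- function(midmap, atoms, probe_radius) {
  stopifnot(probe_radius >= 0)
  if (probe_radius == 0) return(midmap)
  grid <- midmap$grid
  passes <- 0L
  repeat {
    cls <- classify_points(midmap)
    bnd <- cls$label == "boundary"
    if (!any(bnd)) break
    flipped_any <- FALSE
    for (ax in 1:3) {
      cand <- mids_adjacent_to(bnd, ax, grid) & !midmap$inside[[ax]]
      if (!any(cand)) next
      ci <- which(cand)
      sub <- arrayInd(ci, dim(cand))
      pts <- cbind(midpoint_axis(grid, ax, 1)[sub[, 1]],
                   midpoint_axis(grid, ax, 2)[sub[, 2]],
                   midpoint_axis(grid, ax, 3)[sub[, 3]])
      depth <- sas_depth(pts, atoms, probe_radius)
      flip <- depth >= probe_radius
      if (any(flip)) {
        midmap$inside[[ax]][ci[flip]] <- TRUE
        flipped_any <- TRUE
      }
    }
    passes <- passes + 1L
    if (!flipped_any) break
  }
  attr(midmap, "passes") <- passes
  midmap
}

#' Project boundary grid nodes onto the molecular surface
#'
#' Every node labeled `boundary` is projected to a point on the
#' solvent-excluded surface. Where the nearest point of the
#' solvent-accessible surface lies on a single extended sphere (convex
#' region) the projection is direct, along the line to that atom's center,
#' onto its van der Waals sphere. Where the nearest SAS point lies on an
#' intersection seam of two extended spheres (reentrant region) the node is
#' first projected onto the seam circle and then moved back by the probe
#' radius toward the node, landing on the reentrant probe patch.
#'
#' @param classification a `point_classification`
#' @param midmap the final `midpoint_map` (unused directly; kept for
#'   interface symmetry)
#' @param atoms an [atom_set()]
#' @param probe_radius probe radius, Angstrom
#' @param grid a `grid_spec`
#' @return a `surface_point_set`: data frame with node indices `i, j, k`,
#'   node coordinates `bx, by, bz`, surface points `sx, sy, sz`, and the
#'   generating atom index `atom`
#' @export
project_boundary_points <- function(classification, midmap, atoms,
                                    probe_radius, grid) {
  bnd <- which(classification$label == "boundary")
  sub <- arrayInd(bnd, dim(classification$label))
  if (nrow(sub) == 0) {
    return(structure(data.frame(i = integer(), j = integer(), k = integer(),
                                bx = numeric(), by = numeric(), bz = numeric(),
                                sx = numeric(), sy = numeric(), sz = numeric(),
                                atom = integer()),
                     class = c("surface_point_set", "data.frame")))
  }
  b <- cbind(grid_axis(grid, 1)[sub[, 1]],
             grid_axis(grid, 2)[sub[, 2]],
             grid_axis(grid, 3)[sub[, 3]])
  nr <- sas_nearest(b, atoms, probe_radius)
  ctr <- atom_coords(atoms)
  ext <- atoms$radius + probe_radius
  bs <- matrix(NA_real_, nrow(b), 3)
  gen <- integer(nrow(b))
  n_ties <- 0L
  for (p in seq_len(nrow(b))) {
    j <- nr$atom[p]
    if (!is.na(j)) {
      # convex-adjacent: direct projection onto atom j's vdW sphere
      v <- b[p, ] - ctr[j, ]
      dv <- sqrt(sum(v^2))
      if (dv < 1e-12) { v <- c(1, 0, 0); dv <- 1 }
      if (sum(abs(nr$dist[p, ] - nr$dist[p, j]) < 1e-12) > 1L) n_ties <- n_ties + 1L
      bs[p, ] <- ctr[j, ] + atoms$radius[j] * v / dv
      gen[p] <- j
    } else {
      # reentrant: nearest SAS point on a two-sphere seam circle
      ord <- order(abs(nr$pen[p, ]))
      top <- utils::head(ord, 4L)
      best <- NULL; best_d <- Inf
      for (a1 in seq_along(top)) for (a2 in seq_along(top)) {
        if (a2 <= a1) next
        s <- circle_nearest_point(b[p, ], ctr[top[a1], ], ctr[top[a2], ],
                                  ext[top[a1]], ext[top[a2]])
        if (is.null(s)) next
        ds <- sqrt(sum((b[p, ] - s)^2))
        if (ds < best_d) { best_d <- ds; best <- s }
      }
      if (is.null(best)) {
        # degenerate: fall back to direct projection on deepest atom
        j <- ord[1]
        v <- b[p, ] - ctr[j, ]
        dv <- max(sqrt(sum(v^2)), 1e-12)
        bs[p, ] <- ctr[j, ] + atoms$radius[j] * v / dv
        gen[p] <- j
      } else {
        u <- b[p, ] - best
        du <- max(sqrt(sum(u^2)), 1e-12)
        bs[p, ] <- best + probe_radius * u / du
        gen[p] <- ord[1]
      }
    }
  }
  if (n_ties > 0)
    message(sprintf(
      "project_boundary_points: %d node(s) equidistant from several atoms; lowest atom index used",
      n_ties))
  structure(data.frame(i = sub[, 1], j = sub[, 2], k = sub[, 3],
                       bx = b[, 1], by = b[, 2], bz = b[, 3],
                       sx = bs[, 1], sy = bs[, 2], sz = bs[, 3],
                       atom = gen),
            class = c("surface_point_set", "data.frame"))
}

# Nearest point to x on the intersection circle of spheres (c1, R1), (c2, R2);
# NULL when the spheres do not intersect.
circle_nearest_point <- function(x, c1, c2, R1, R2) {
  u <- c2 - c1
  D <- sqrt(sum(u^2))
  if (D < 1e-12 || D > R1 + R2 || D < abs(R1 - R2)) return(NULL)
  u <- u / D
  a <- (D^2 + R1^2 - R2^2) / (2 * D)
  rho2 <- R1^2 - a^2
  if (rho2 <= 0) return(NULL)
  cc <- c1 + a * u
  w <- x - cc
  w_perp <- w - sum(w * u) * u
  nw <- sqrt(sum(w_perp^2))
  if (nw < 1e-12) {
    # pick any direction perpendicular to the axis
    e <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w_perp <- e - sum(e * u) * u
    nw <- sqrt(sum(w_perp^2))
  }
  cc + sqrt(rho2) * w_perp / nw
}
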