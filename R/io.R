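# Structure, parameter and map input/output.
#
# Structures come either as PDB plus DelPhi-style .siz/.crg lookup tables,
# or as PQR with per-record charge and radius. Potentials are written in
# the OpenDX scalar-field dialect understood by the common molecular
# viewers.

strip_comments <- function(lines) {
  lines <- sub("[#!].*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

# DelPhi-convention lookup tables: whitespace-separated
# "atom-name [residue-name] value"; a missing residue name is a wildcard.
read_delphi_table <- function(path) {
  lines <- strip_comments(readLines(path))
  rows <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    val <- suppressWarnings(as.numeric(tok[length(tok)]))
    if (is.na(val)) next          # header line such as "atom__res_radius"
    rows[[length(rows) + 1L]] <- data.frame(
      elety = toupper(tok[1]),
      resid = if (length(tok) >= 3) toupper(tok[2]) else "*",
      value = val, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no usable entries in table: ", path)
  do.call(rbind, rows)
}

lookup_table <- function(tab, elety, resid, what, strict) {
  n <- length(elety)
  out <- rep(NA_real_, n)
  key_exact <- paste(toupper(elety), toupper(resid))
  tab_exact <- paste(tab$elety, tab$resid)
  m <- match(key_exact, tab_exact)
  out[!is.na(m)] <- tab$value[m[!is.na(m)]]
  wild <- tab[tab$resid == "*", , drop = FALSE]
  miss <- is.na(out)
  if (any(miss) && nrow(wild) > 0) {
    m2 <- match(toupper(elety[miss]), wild$elety)
    out[miss][!is.na(m2)] <- wild$value[m2[!is.na(m2)]]
  }
  miss <- is.na(out)
  if (any(miss)) {
    desc <- unique(paste(elety[miss], resid[miss]))
    if (strict)
      stop("no ", what, " for atom(s): ", paste(desc, collapse = ", "))
    message("assigning ", what, " 0 to unmatched atom(s): ",
            paste(desc, collapse = ", "))
    out[miss] <- 0
  }
  out
}

#' Read a structure from PDB with radius and charge tables
#'
#' Atom radii and charges are matched by atom name and residue name against
#' DelPhi-convention `.siz` and `.crg` tables (whitespace-separated, blank
#' residue = wildcard). In strict mode unmatched atoms are an error; in
#' permissive mode they get radius 0 (never generating inside midpoints)
#' and charge 0, with a message.
#'
#' @param pdb path to a PDB file
#' @param siz path to the radius table
#' @param crg path to the charge table
#' @param strict error on unmatched atoms (default TRUE)
#' @return an [atom_set()]
#' @export
read_structure <- function(pdb, siz, crg, strict = TRUE) {
  for (f in c(pdb, siz, crg)) if (!file.exists(f)) stop("no such file: ", f)
  s <- bio3d::read.pdb(pdb, verbose = FALSE)
  at <- s$atom
  radius <- lookup_table(read_delphi_table(siz), at$elety, at$resid,
                         "radius", strict)
  charge <- lookup_table(read_delphi_table(crg), at$elety, at$resid,
                         "charge", strict)
  atom_set(cbind(at$x, at$y, at$z), radius, charge,
           elety = at$elety, resid = at$resid)
}

#' Read a PQR structure
#'
#' Whitespace-delimited PQR records (`ATOM`/`HETATM`): serial, atom name,
#' residue name, optional chain, residue number, x, y, z, charge, radius.
#'
#' @param path path to the PQR file
#' @return an [atom_set()]
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rec <- grep("^(ATOM|HETATM)", lines)
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  rows <- lapply(rec, function(li) {
    tok <- strsplit(trimws(lines[li]), "[[:space:]]+")[[1]]
    if (length(tok) < 10)
      stop("unparseable PQR record at line ", li, " of ", path)
    has_chain <- length(tok) >= 11 &&
      is.na(suppressWarnings(as.numeric(tok[5])))
    o <- if (has_chain) 1L else 0L
    num <- suppressWarnings(as.numeric(tok[(6 + o - 1):(10 + o)]))
    if (any(is.na(num)))
      stop("unparseable PQR record at line ", li, " of ", path)
    list(elety = tok[3], resid = tok[4],
         x = num[2], y = num[3], z = num[4],
         charge = num[5], radius = as.numeric(tok[10 + o]))
  })
  xs <- vapply(rows, function(r) r$x, 0)
  atom_set(cbind(xs,
                 vapply(rows, function(r) r$y, 0),
                 vapply(rows, function(r) r$z, 0)),
           radius = vapply(rows, function(r) r$radius, 0),
           charge = vapply(rows, function(r) r$charge, 0),
           elety = vapply(rows, function(r) r$elety, ""),
           resid = vapply(rows, function(r) r$resid, ""))
}

#' Write an atom set as PQR
#'
#' @param atoms an [atom_set()]
#' @param path output path
#' @export
write_pqr <- function(atoms, path) {
  elety <- if (!is.null(atoms$elety)) atoms$elety else
    sprintf("A%d", seq_len(nrow(atoms)))
  resid <- if (!is.null(atoms$resid)) atoms$resid else "MOL"
  resid <- rep_len(resid, nrow(atoms))
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s %4d    %8.3f %8.3f %8.3f %8.4f %7.4f",
    seq_len(nrow(atoms)), elety, resid, 1L,
    atoms$x, atoms$y, atoms$z, atoms$charge, atoms$radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Default parameter set
#'
#' All pipeline parameters with their default conventions: `filling` 80
#' percent, `spacing` 1 Angstrom, grid size derived, `rmsc` and `maxc`
#' 1e-4, `maxit` 500, `epsIn` 2.0, `epsOut` 80.0, `salt` 0 mol/L, `temp`
#' 273.15 K, zero boundary conditions, no periodicity, no membrane, probe
#' radius 1.4 Angstrom (water), Stern-layer ion radius 2.0 Angstrom.
#'
#' @return a `pb_params` list
#' @export
pb_params <- function() {
  structure(list(
    pdb = NULL, siz = NULL, crg = NULL, pqr = NULL, sph = NULL,
    filling = 80, spacing = 1.0, gridS = NULL,
    rmsc = 1e-4, maxc = 1e-4, maxit = 500L,
    epsIn = 2.0, epsOut = 80.0, salt = 0.0, temp = 273.15,
    bc = 1L, pb = c(FALSE, FALSE, FALSE),
    membrane = NULL, memsel = NULL,
    probe = 1.4, ion = 2.0,
    box_set = character(0)   # which of filling/spacing/gridS were given
  ), class = "pb_params")
}

#' Read a key-value parameter file
#'
#' Accepts `key = value` and `key(sub, value)` lines, `#`/`!` comments and
#' the bare keyword `nomem`. Unset keys take the defaults of
#' [pb_params()]; an empty file reproduces them exactly. Recognized keys:
#' `in(pdb|siz|crg|pqr|sph, path)`, `filling`, `spacing`, `gridS`, `rmsc`,
#' `maxc`, `maxit`, `epsIn`, `epsOut`, `salt`, `temp`, `bc`, `pb`,
#' `probe`, `ion`, `nomem`, `mem = zmin,zmax,eps` and
#' `memsel = res,atom,eps` (membrane slab from an atom selection). At most
#' two of `filling`, `spacing`, `gridS` may be set.
#'
#' @param path path to the parameter file
#' @return a `pb_params` list
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- pb_params()
  lines <- strip_comments(readLines(path))
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z]+)\\(([^,]+),(.+)\\)$", ln))[[1]]
    if (length(m) == 4) {
      key <- tolower(trimws(m[2])); sub <- tolower(trimws(m[3]))
      val <- trimws(m[4])
      if (key != "in") stop("unknown parameter: ", ln)
      if (sub == "tpr")
        stop("tpr input is not supported; use pdb+siz+crg or pqr")
      if (!sub %in% c("pdb", "siz", "crg", "pqr", "sph"))
        stop("unknown input kind: ", sub)
      p[[sub]] <- val
      next
    }
    if (tolower(ln) == "nomem") { p$membrane <- NULL; p$memsel <- NULL; next }
    kv <- regmatches(ln, regexec("^([A-Za-z]+)[[:space:]]*=[[:space:]]*(.+)$",
                                 ln))[[1]]
    if (length(kv) != 3) stop("unparseable parameter line: ", ln)
    key <- tolower(kv[2]); val <- trimws(kv[3])
    num <- function() {
      x <- suppressWarnings(as.numeric(val))
      if (is.na(x)) stop("numeric value expected in: ", ln)
      x
    }
    switch(key,
      filling = { p$filling <- num(); p$box_set <- c(p$box_set, "filling") },
      spacing = { p$spacing <- num(); p$box_set <- c(p$box_set, "spacing") },
      grids   = { p$gridS <- as.integer(num())
                  p$box_set <- c(p$box_set, "gridS") },
      rmsc = { p$rmsc <- num() },
      maxc = { p$maxc <- num() },
      maxit = { p$maxit <- as.integer(num()) },
      epsin = { p$epsIn <- num() },
      epsout = { p$epsOut <- num() },
      salt = { p$salt <- num() },
      temp = { p$temp <- num() },
      probe = { p$probe <- num() },
      ion = { p$ion <- num() },
      bc = {
        b <- as.integer(num())
        if (!b %in% c(1L, 2L)) stop("bc must be 1 or 2")
        p$bc <- b
      },
      pb = {
        ch <- strsplit(tolower(val), "")[[1]]
        if (!all(ch %in% c("x", "y", "z")))
          stop("pb must be a combination of x, y, z")
        p$pb <- c("x", "y", "z") %in% ch
      },
      mem = {
        v <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
        if (length(v) != 3 || any(is.na(v)))
          stop("mem expects 'zmin,zmax,eps': ", ln)
        p$membrane <- membrane_slab(v[1], v[2], v[3])
      },
      memsel = ,
      tprmem = {
        v <- trimws(strsplit(val, ",")[[1]])
        if (length(v) != 3) stop("membrane selection expects 'res,atom,eps'")
        p$memsel <- list(resid = v[1], elety = v[2],
                         eps_mem = as.numeric(v[3]))
      },
      stop("unknown parameter: ", key)
    )
  }
  p$box_set <- unique(p$box_set)
  if (length(p$box_set) > 2)
    stop("at most two of 'filling', 'spacing' and 'gridS' may be set")
  p
}

#' Write a potential grid in OpenDX format
#'
#' Scalar-field dialect (gridpositions / gridconnections / data follows)
#' readable by PyMOL, VMD and Chimera; data ordered with z fastest.
#'
#' @param phi potential array, kT/e
#' @param grid a `grid_spec`
#' @param path output path
#' @export
write_potential_dx <- function(phi, grid, path) {
  np <- grid$npoints
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# electrostatic potential, kT/e",
    sprintf("object 1 class gridpositions counts %d %d %d",
            np[1], np[2], np[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$h),
    sprintf("delta 0.000000 %.6f 0.000000", grid$h),
    sprintf("delta 0.000000 0.000000 %.6f", grid$h),
    sprintf("object 2 class gridconnections counts %d %d %d",
            np[1], np[2], np[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(np))), con)
  v <- as.vector(aperm(phi, c(3, 2, 1)))   # z fastest
  n3 <- (length(v) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(v[seq_len(n3)], nrow = 3)
    writeLines(apply(m, 2, function(r) paste(sprintf("%.6e", r),
                                             collapse = " ")), con)
  }
  if (n3 < length(v))
    writeLines(paste(sprintf("%.6e", v[(n3 + 1):length(v)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX potential grid written by [write_potential_dx()]
#' @param path path to the DX file
#' @return list with `phi` (array) and `grid` (a `grid_spec`)
#' @export
read_potential_dx <- function(path) {
  lines <- readLines(path)
  cl <- grep("class gridpositions counts", lines, value = TRUE)[1]
  np <- as.integer(strsplit(sub(".*counts ", "", cl), " ")[[1]])
  org <- as.numeric(strsplit(sub("^origin ", "",
                                 grep("^origin", lines, value = TRUE)[1]),
                             " ")[[1]])
  d1 <- as.numeric(strsplit(sub("^delta ", "",
                                grep("^delta", lines, value = TRUE)[1]),
                            " ")[[1]])
  start <- grep("data follows", lines)[1] + 1L
  stopifnot(!is.na(start))
  end <- grep("^attribute", lines)[1] - 1L
  v <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "[[:space:]]+")))
  stopifnot(length(v) == prod(np))
  phi <- aperm(array(v, dim = rev(np)), c(3, 2, 1))
  grid <- structure(list(origin = org, h = d1[1], npoints = np,
                         edge = (np[1] - 1) * d1[1], filling = NA),
                    class = "grid_spec")
  list(phi = phi, grid = grid)
}

#' Write a potential profile along a path
#'
#' Two-column text: cumulative arc length (Angstrom) and potential (kT/e).
#'
#' @param values potentials, kT/e
#' @param points n x 3 matrix of path positions, Angstrom
#' @param path output path
#' @export
write_profile <- function(values, points, path) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(length(values) == nrow(points))
  arc <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  writeLines(c("# arc_length_A potential_kT_per_e",
               sprintf("%.4f %.6f", arc, values)), path)
  invisible(path)
}

#' Write a plain-text solver/energy report
#'
#' Key-value lines: grid parameters, iteration diagnostics and energies.
#'
#' @param result a `solver_result`
#' @param energies optional named list of `energy_result` objects
#' @param path output path
#' @export
write_report <- function(result, energies = NULL, path) {
  np <- result$grid$npoints
  n <- result$iterations
  lines <- c(
    sprintf("grid_points = %d %d %d", np[1], np[2], np[3]),
    sprintf("spacing_A = %.6f", result$grid$h),
    sprintf("omega = %.6f", result$omega),
    sprintf("iterations = %d", n),
    sprintf("converged = %s", result$converged),
    sprintf("criterion = %s", result$criterion),
    sprintf("final_rmsc = %.6e", result$rmsc_history[n]),
    sprintf("final_maxc = %.6e", result$maxc_history[n]))
  for (nm in names(energies)) {
    e <- energies[[nm]]
    lines <- c(lines,
               sprintf("energy_%s_kcal_per_mol = %.6f", nm, e$kcal),
               sprintf("energy_%s_kT = %.6f", nm, e$kT))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write surface points for visual inspection
#'
#' As PDB pseudo-atoms and/or a plain xyz table.
#'
#' @param surface a `surface_point_set`
#' @param path output path
#' @param format `"pdb"` or `"xyz"`
#' @export
write_surface_points <- function(surface, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "pdb") {
    lines <- sprintf(
      "ATOM  %5d  S   SRF A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(surface)) %% 100000L, seq_len(nrow(surface)) %% 10000L,
      surface$sx, surface$sy, surface$sz)
    writeLines(c(lines, "END"), path)
  } else {
    writeLines(c("# x y z atom",
                 sprintf("%.4f %.4f %.4f %d",
                         surface$sx, surface$sy, surface$sz, surface$atom)),
               path)
  }
  invisible(path)
}
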