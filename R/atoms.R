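#' Construct an atom set
#'
#' The solute model used throughout the package: atom positions, van der
#' Waals radii and partial charges. An `atom_set` is a data frame with
#' columns `x`, `y`, `z` (Angstrom), `radius` (Angstrom), `charge`
#' (elementary charges) and optional `elety` (atom name) and `resid`
#' (residue name) columns used for parameter matching and membrane atom
#' selections.
#'
#' @param positions numeric matrix (n x 3) of atom centers, Angstrom
#' @param radius numeric vector of van der Waals radii, Angstrom (recycled)
#' @param charge numeric vector of partial charges, e (recycled)
#' @param elety optional character vector of atom names
#' @param resid optional character vector of residue names
#' @return an object of class `atom_set` (a data frame)
#' @examples
#' ion <- atom_set(matrix(0, 1, 3), radius = 2, charge = 1)
#' total_charge(ion)
#' @export
atom_set <- function(positions, radius, charge,
                     elety = NULL, resid = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  if (n == 0L) stop("atom_set must contain at least one atom")
  if (!all(is.finite(positions))) stop("atom positions must be finite")
  radius <- rep_len(as.numeric(radius), n)
  charge <- rep_len(as.numeric(charge), n)
  if (any(radius < 0)) stop("atom radii must be >= 0")
  df <- data.frame(
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    radius = radius, charge = charge,
    stringsAsFactors = FALSE
  )
  if (!is.null(elety)) df$elety <- rep_len(as.character(elety), n)
  if (!is.null(resid)) df$resid <- rep_len(as.character(resid), n)
  class(df) <- c("atom_set", "data.frame")
  df
}

#' @exportS3Method base::print
print.atom_set <- function(x, ...) {
  cat(sprintf("atom_set: %d atoms, total charge %+.4f e\n",
              nrow(x), total_charge(x)))
  bb <- bounding_box(x)
  cat(sprintf("  vdW bounding box: [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] A\n",
              bb$min[1], bb$max[1], bb$min[2], bb$max[2], bb$min[3], bb$max[3]))
  NextMethod()
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param atoms an `atom_set`
#' @return n x 3 numeric matrix
#' @export
atom_coords <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

#' Total charge of an atom set
#' @param atoms an `atom_set`
#' @return sum of partial charges, e
#' @export
total_charge <- function(atoms) sum(atoms$charge)

#' Van der Waals bounding box of an atom set
#' @param atoms an `atom_set`
#' @return list with `min` and `max` 3-vectors (Angstrom), including radii
#' @export
bounding_box <- function(atoms) {
  xyz <- atom_coords(atoms)
  list(
    min = apply(xyz - atoms$radius, 2, min),
    max = apply(xyz + atoms$radius, 2, max)
  )
}
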