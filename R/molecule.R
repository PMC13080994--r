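#' Construct a rigid molecule
#'
#' Creates a molecule container from element symbols and Cartesian
#' coordinates. Geometric properties (total mass, van der Waals volume,
#' bounding radius and the canonical inertial frame) are computed
#' automatically. The canonical "standard orientation" places the center of
#' geometry at the origin and aligns the principal inertial axes with the
#' Cartesian axes (largest moment along x). The volume and radius are
#' computed in the standard orientation so they are invariant under rigid
#' motion of the input.
#'
#' @param symbols character vector of element symbols (length N).
#' @param coords N x 3 numeric matrix of Cartesian coordinates in Angstrom.
#' @param charges optional numeric vector of per-atom partial charges (e);
#'   defaults to all zero.
#' @param volume_spacing grid spacing (Angstrom) for the vdW volume
#'   estimator.
#' @return an object of class `cspkit_molecule` with fields `symbols`,
#'   `coords`, `masses`, `vdw_radii`, `charges`, `mass`, `volume`, `radius`
#'   and `frame` (3 x 3 rotation taking the standard orientation into the
#'   input orientation, applied as `coords = std %*% t(frame) + centroid`).
#' @export
molecule <- function(symbols, coords, charges = NULL, volume_spacing = 0.1) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3)
    stop("coords must be an N x 3 numeric matrix", call. = FALSE)
  n <- nrow(coords)
  if (n < 1) stop("molecule needs at least one atom", call. = FALSE)
  if (length(symbols) != n)
    stop("length(symbols) must match nrow(coords)", call. = FALSE)
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  masses <- element_masses(symbols)
  vdw <- element_vdw_radii(symbols)
  if (is.null(charges)) charges <- numeric(n)
  if (length(charges) != n) stop("charges must have one entry per atom", call. = FALSE)
  dimnames(coords) <- NULL

  std <- .standard_frame(coords, masses)
  mol <- structure(list(
    symbols = as.character(symbols),
    coords = coords,
    masses = masses,
    vdw_radii = vdw,
    charges = as.numeric(charges),
    mass = sum(masses),
    frame = std$frame,
    centroid = std$centroid,
    std_coords = std$std_coords
  ), class = "cspkit_molecule")
  mol$radius <- molecule_radius(mol)
  mol$volume <- molecule_volume(mol, grid_spacing = volume_spacing)
  mol
}

# Canonical inertial frame: eigenvectors of the mass-weighted inertia tensor
# about the (unweighted) center of geometry, eigenvalues sorted descending.
# Sign of each of the first two axes fixed by the third moment of the
# (unweighted) coordinates (fallback: first atom with a non-negligible
# component made non-negative); third axis = cross product (right-handed).
.standard_frame <- function(coords, masses) {
  n <- nrow(coords)
  centroid <- colMeans(coords)
  d <- sweep(coords, 2, centroid)
  if (n == 1) {
    return(list(frame = diag(3), centroid = centroid, std_coords = d))
  }
  scale <- sqrt(max(rowSums(d^2)))
  if (scale < 1e-9)
    stop("degenerate geometry: all atoms coincident", call. = FALSE)
  r2 <- rowSums(d^2)
  inertia <- diag(sum(masses * r2), 3) - t(d * masses) %*% d
  ev <- eigen(inertia, symmetric = TRUE)   # eigenvalues decreasing
  axes <- ev$vectors
  # sign convention: each axis flipped so the third moment of the
  # (unweighted) coordinates along it is non-negative; if that moment
  # vanishes (symmetric molecule), the first atom with a non-negligible
  # component is made non-negative. Axes where no rule decides (e.g. the
  # normal of a planar molecule: every component is zero) are left free
  # and used to enforce right-handedness; otherwise the last axis is
  # flipped. All rules depend only on intrinsic quantities, so the frame
  # is invariant under rigid motion of the input.
  decided <- logical(3)
  for (k in 1:3) {
    comp <- d %*% axes[, k]
    m3 <- sum(comp^3)
    if (abs(m3) > 1e-8 * scale^3) {
      if (m3 < 0) axes[, k] <- -axes[, k]
      decided[k] <- TRUE
    } else {
      j <- which(abs(comp) > 1e-6 * scale)
      if (length(j) > 0) {
        if (comp[j[1]] < 0) axes[, k] <- -axes[, k]
        decided[k] <- TRUE
      }
    }
  }
  if (det(axes) < 0) {
    k <- if (any(!decided)) which(!decided)[1] else 3L
    axes[, k] <- -axes[, k]
  }
  list(frame = axes, centroid = centroid, std_coords = d %*% axes)
}

#' Standardize a molecule
#'
#' Returns a copy of the molecule in its standard orientation (center of
#' geometry at the origin, principal inertial axes along the Cartesian axes,
#' moments non-increasing) together with the rigid motion mapping the
#' standardized copy back onto the input: `input = std %*% t(rotation) +
#' translation` (row-vector convention).
#'
#' @param mol a `cspkit_molecule`.
#' @return list with elements `molecule` (standardized), `rotation` (3 x 3,
#'   determinant +1) and `translation` (length-3).
#' @export
standardize <- function(mol) {
  stopifnot(inherits(mol, "cspkit_molecule"))
  std <- mol
  std$coords <- mol$std_coords
  std$frame <- diag(3)
  std$centroid <- c(0, 0, 0)
  std$std_coords <- mol$std_coords
  list(molecule = std, rotation = mol$frame, translation = mol$centroid)
}

#' Test whether a molecule is in standard orientation
#' @param mol a `cspkit_molecule`.
#' @param tol tolerance on the centroid norm and frame deviation.
#' @return logical.
#' @export
is_standardized <- function(mol, tol = 1e-7) {
  sqrt(sum(mol$centroid^2)) < tol &&
    max(abs(mol$frame - diag(3))) < tol
}

#' Van der Waals volume of a molecule
#'
#' Volume of the union of atomic van der Waals spheres, estimated by counting
#' points of a regular Cartesian grid (spacing `grid_spacing`, anchored at
#' the lower corner of the bounding box plus half a spacing) that fall inside
#' at least one sphere. Evaluated in the standard orientation, so the result
#' is deterministic and invariant under rigid motion of the input. This is
#' the volume calculator used consistently throughout the toolkit (packing
#' coefficients are only meaningful relative to a fixed calculator).
#'
#' @param mol a `cspkit_molecule`.
#' @param grid_spacing grid spacing in Angstrom (default 0.1).
#' @return volume in cubic Angstrom.
#' @export
molecule_volume <- function(mol, grid_spacing = 0.1) {
  stopifnot(inherits(mol, "cspkit_molecule"))
  if (!is.numeric(grid_spacing) || grid_spacing <= 0)
    stop("grid_spacing must be > 0", call. = FALSE)
  x <- mol$std_coords
  r <- mol$vdw_radii
  h <- grid_spacing
  # the fractional grid offset avoids grid points lying exactly on sphere
  # surfaces for molecules with lattice-aligned coordinates, which would
  # make the estimate sensitive to round-off in the standardized frame
  ofs <- 0.2971143 * h
  lo <- apply(x - r, 2, min) - h / 2
  hi <- apply(x + r, 2, max) + h
  gx <- seq(lo[1] + h / 2 + ofs, hi[1], by = h)
  gy <- seq(lo[2] + h / 2 + ofs, hi[2], by = h)
  gz <- seq(lo[3] + h / 2 + ofs, hi[3], by = h)
  inside <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
  dx2m <- outer(gx, x[, 1], function(g, c) (g - c)^2)
  dy2m <- outer(gy, x[, 2], function(g, c) (g - c)^2)
  dz2m <- outer(gz, x[, 3], function(g, c) (g - c)^2)
  for (i in seq_len(nrow(x))) {
    xi <- which(dx2m[, i] < r[i]^2)
    if (!length(xi)) next
    yi <- which(dy2m[, i] < r[i]^2)
    zi <- which(dz2m[, i] < r[i]^2)
    if (!length(yi) || !length(zi)) next
    sub <- outer(dx2m[xi, i], dy2m[yi, i], "+")
    for (k in seq_along(zi)) {
      hit <- sub + dz2m[zi[k], i] < r[i]^2
      inside[xi, yi, zi[k]] <- inside[xi, yi, zi[k]] | hit
    }
  }
  sum(inside) * h^3
}

#' Bounding radius of a molecule
#'
#' Maximum over atoms of (distance from the center of geometry + that atom's
#' van der Waals radius). Invariant under rigid motion.
#'
#' @param mol a `cspkit_molecule`.
#' @return radius in Angstrom.
#' @export
molecule_radius <- function(mol) {
  stopifnot(inherits(mol, "cspkit_molecule"))
  max(sqrt(rowSums(mol$std_coords^2)) + mol$vdw_radii)
}

#' @export
print.cspkit_molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms [%s], mass %.3f amu, V %.2f A^3, R %.2f A>\n",
              nrow(x$coords), paste(unique(x$symbols), collapse = ","),
              x$mass, x$volume, x$radius))
  invisible(x)
}
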