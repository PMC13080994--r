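#' @title Unit-cell geometry
#' @description Conversions between cell parameters (a, b, c, alpha, beta,
#'   gamma) and lattice vectors, and fractional/Cartesian coordinate
#'   transforms. The lattice matrix `T` holds the lattice vectors as rows in
#'   the lower-triangular convention: the a-vector lies along Cartesian x and
#'   the b-vector in the xy-plane, so every valid parameter set has a unique
#'   representative matrix and `det(T) = V_cell > 0`. Angles are degrees in
#'   the public API.
#' @name lattice
NULL

.deg2rad <- pi / 180

# cosines and the squared volume factor u = 1 - ca^2 - cb^2 - cg^2 + 2 ca cb cg
.cell_u <- function(alpha, beta, gamma) {
  ca <- cos(alpha * .deg2rad); cb <- cos(beta * .deg2rad); cg <- cos(gamma * .deg2rad)
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' Lattice vectors from cell parameters
#'
#' @param a,b,c cell lengths in Angstrom (> 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180); the
#'   triple must yield a positive cell volume.
#' @return 3 x 3 lower-triangular matrix with lattice vectors as rows.
#' @export
cell_to_vectors <- function(a, b, c, alpha, beta, gamma) {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be > 0", call. = FALSE)
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  u <- .cell_u(alpha, beta, gamma)
  if (u <= 1e-12)
    stop("impossible cell angles (non-positive volume): alpha=", alpha,
         " beta=", beta, " gamma=", gamma, call. = FALSE)
  ca <- cos(alpha * .deg2rad); cb <- cos(beta * .deg2rad)
  cg <- cos(gamma * .deg2rad); sg <- sin(gamma * .deg2rad)
  rbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * (ca - cb * cg) / sg, c * sqrt(u) / sg)
  )
}

#' Cell parameters from lattice vectors
#' @param T 3 x 3 matrix with lattice vectors as rows.
#' @return list with `lengths` (a, b, c) and `angles` (alpha, beta, gamma in
#'   degrees).
#' @export
vectors_to_cell <- function(T) {
  T <- as.matrix(T)
  lens <- sqrt(rowSums(T^2))
  if (any(lens <= 0)) stop("degenerate lattice vectors", call. = FALSE)
  ang <- function(i, j) acos(sum(T[i, ] * T[j, ]) / (lens[i] * lens[j])) / .deg2rad
  list(lengths = lens, angles = c(ang(2, 3), ang(1, 3), ang(1, 2)))
}

#' Construct a unit cell
#'
#' @inheritParams cell_to_vectors
#' @return object of class `cspkit_cell` with fields `lengths`, `angles`,
#'   `T` (lattice matrix, rows = lattice vectors), `Tinv` and `volume`.
#' @export
make_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  T <- cell_to_vectors(a, b, c, alpha, beta, gamma)
  structure(list(
    lengths = c(a, b, c),
    angles = c(alpha, beta, gamma),
    T = T,
    Tinv = solve(T),
    volume = det(T)
  ), class = "cspkit_cell")
}

#' Fractional to Cartesian coordinates
#' @param frac M x 3 fractional coordinates (rows).
#' @param cell a `cspkit_cell` (or 3 x 3 lattice matrix).
#' @return M x 3 Cartesian coordinates in Angstrom.
#' @export
frac_to_cart <- function(frac, cell) {
  T <- if (inherits(cell, "cspkit_cell")) cell$T else as.matrix(cell)
  matrix(as.numeric(frac), ncol = 3) %*% T
}

#' Cartesian to fractional coordinates
#' @param cart M x 3 Cartesian coordinates in Angstrom (rows).
#' @inheritParams frac_to_cart
#' @return M x 3 fractional coordinates.
#' @export
cart_to_frac <- function(cart, cell) {
  Tinv <- if (inherits(cell, "cspkit_cell")) cell$Tinv else solve(as.matrix(cell))
  matrix(as.numeric(cart), ncol = 3) %*% Tinv
}

#' Unit-cell volume
#' @inheritParams frac_to_cart
#' @return volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  if (inherits(cell, "cspkit_cell")) cell$volume else det(as.matrix(cell))
}

# derivatives of the lattice matrix T with respect to the six cell
# parameters; angles in DEGREES (public chart). Returns a list of six 3x3
# matrices in order a, b, c, alpha, beta, gamma.
.cell_jacobian <- function(a, b, c, alpha, beta, gamma) {
  d <- .deg2rad
  al <- alpha * d; be <- beta * d; ga <- gamma * d
  ca <- cos(al); sa <- sin(al)
  cb <- cos(be); sb <- sin(be)
  cg <- cos(ga); sg <- sin(ga)
  u <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  su <- sqrt(u)
  J <- vector("list", 6)
  zero <- matrix(0, 3, 3)
  # lengths: T rows are linear in a, b, c
  J[[1]] <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0))
  J[[2]] <- rbind(c(0, 0, 0), c(cg, sg, 0), c(0, 0, 0))
  J[[3]] <- rbind(c(0, 0, 0), c(0, 0, 0), c(cb, (ca - cb * cg) / sg, su / sg))
  # alpha (radians, then scaled by pi/180)
  Ja <- zero
  Ja[3, 2] <- c * (-sa) / sg
  Ja[3, 3] <- c * (sa * (ca - cb * cg)) / (su * sg)
  J[[4]] <- Ja * d
  # beta
  Jb <- zero
  Jb[3, 1] <- -c * sb
  Jb[3, 2] <- c * sb * cg / sg
  Jb[3, 3] <- c * (sb * (cb - ca * cg)) / (su * sg)
  J[[5]] <- Jb * d
  # gamma
  Jg <- zero
  Jg[2, 1] <- -b * sg
  Jg[2, 2] <- b * cg
  Jg[3, 2] <- c * (cb * sg^2 - (ca - cb * cg) * cg) / sg^2
  dudg <- 2 * sg * (cg - ca * cb)
  Jg[3, 3] <- c * (dudg / (2 * su) * sg - su * cg) / sg^2
  J[[6]] <- Jg * d
  J
}

#' @export
print.cspkit_cell <- function(x, ...) {
  cat(sprintf("<cell a=%.4f b=%.4f c=%.4f alpha=%.3f beta=%.3f gamma=%.3f V=%.3f A^3>\n",
              x$lengths[1], x$lengths[2], x$lengths[3],
              x$angles[1], x$angles[2], x$angles[3], x$volume))
  invisible(x)
}
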