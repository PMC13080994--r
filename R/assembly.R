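#' @title Crystal assembly from reduced parameters
#' @description The 12-parameter reduced crystal representation: six cell
#'   parameters, the fractional centroid of the canonical conformer inside
#'   the asymmetric unit, and an axis-angle rotation vector (|v| <= pi)
#'   taking the molecule's standard orientation into the crystal frame.
#'   Crystals are built by posing the rigid molecule, applying the space
#'   group's general-position operators to its fractional coordinates, and
#'   wrapping each symmetry image molecule-wise so its centroid lies in
#'   [0,1)^3.
#' @name assembly
NULL

#' Rotation matrix from an axis-angle rotation vector
#' @param v length-3 rotation vector (axis * angle, radians).
#' @return 3 x 3 rotation matrix (applied to column vectors).
#' @export
rotation_from_rotvec <- function(v) {
  th <- sqrt(sum(v^2))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  if (th < 1e-8) return(diag(3) + K + 0.5 * K %*% K)
  diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * K %*% K
}

#' Axis-angle rotation vector from a rotation matrix
#' @param R 3 x 3 rotation matrix (determinant +1).
#' @return length-3 rotation vector with norm <= pi.
#' @export
rotvec_from_rotation <- function(R) {
  tr <- sum(diag(R))
  th <- acos(max(-1, min(1, (tr - 1) / 2)))
  if (th < 1e-10) return(c(0, 0, 0))
  if (th < pi - 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
    return(ax * th)
  }
  # theta near pi: axis from the dominant column of R + I
  B <- R + diag(3)
  j <- which.max(colSums(B^2))
  ax <- B[, j] / sqrt(sum(B[, j]^2))
  # fix sign convention: first nonzero component positive
  k <- which(abs(ax) > 1e-8)[1]
  if (ax[k] < 0) ax <- -ax
  ax * th
}

# Gallego & Yezzi closed-form derivative of the Rodrigues map:
# dR/dv_i = (v_i [v]_x + [v x ((I - R) e_i)]_x) / th^2 %*% R
.rotation_jacobian <- function(v) {
  R <- rotation_from_rotvec(v)
  th2 <- sum(v^2)
  skew <- function(w) matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  J <- vector("list", 3)
  if (th2 < 1e-14) {
    for (i in 1:3) {
      e <- numeric(3); e[i] <- 1
      J[[i]] <- skew(e)
    }
    return(list(R = R, J = J))
  }
  K <- skew(v)
  ImR <- diag(3) - R
  for (i in 1:3) {
    e <- numeric(3); e[i] <- 1
    w <- c(v[2] * ImR[3, i] - v[3] * ImR[2, i],
           v[3] * ImR[1, i] - v[1] * ImR[3, i],
           v[1] * ImR[2, i] - v[2] * ImR[1, i])
    J[[i]] <- ((v[i] * K + skew(w)) / th2) %*% R
  }
  list(R = R, J = J)
}

# half-open box membership with a small boundary tolerance
.in_asym <- function(sg, p, tol = 1e-9) {
  all(p >= sg$asym_min - tol & p < sg$asym_max + tol)
}

#' Construct crystal parameters
#'
#' @param cell numeric length-6 vector `(a, b, c, alpha, beta, gamma)`
#'   (Angstrom / degrees) or a `cspkit_cell`.
#' @param centroid fractional centroid (x, y, z) of the canonical conformer;
#'   must lie inside the space group's asymmetric-unit box (half-open)
#'   unless `check = FALSE`.
#' @param rotvec axis-angle rotation vector (radians); re-branched to
#'   |v| <= pi.
#' @param sg space group (any key accepted by [get_spacegroup()]).
#' @param check validate centroid membership and cell-angle constraints of
#'   the crystal system (default TRUE).
#' @return object of class `cspkit_params`.
#' @export
crystal_parameters <- function(cell, centroid, rotvec, sg, check = TRUE) {
  sg <- get_spacegroup(sg)
  if (inherits(cell, "cspkit_cell")) cell <- c(cell$lengths, cell$angles)
  cell <- as.numeric(cell)
  if (length(cell) != 6) stop("cell must have 6 components", call. = FALSE)
  centroid <- as.numeric(centroid)
  rotvec <- as.numeric(rotvec)
  th <- sqrt(sum(rotvec^2))
  if (th > pi) {
    k <- floor((th + pi) / (2 * pi))
    rotvec <- rotvec * (1 - 2 * pi * k / th)
  }
  if (check) {
    cons <- .constrain_angles(sg, cell[4:6])
    if (max(abs(cons - cell[4:6])) > 1e-8)
      stop("cell angles violate the ", sg$system,
           " constraints of space group ", sg$symbol, call. = FALSE)
    if (!.in_asym(sg, centroid))
      stop("fractional centroid (", paste(signif(centroid, 6), collapse = ", "),
           ") outside the asymmetric unit of ", sg$symbol, call. = FALSE)
  }
  structure(list(cell = cell, centroid = centroid, rotvec = rotvec, sg = sg),
            class = "cspkit_params")
}

#' Flatten crystal parameters to a numeric 12-vector
#' @param params a `cspkit_params`.
#' @return numeric vector `(a,b,c,alpha,beta,gamma,x,y,z,v1,v2,v3)`.
#' @export
params_to_vector <- function(params) {
  c(params$cell, params$centroid, params$rotvec)
}

#' Rebuild crystal parameters from a numeric 12-vector
#' @param p numeric length-12 vector.
#' @param sg space group.
#' @param check passed to [crystal_parameters()].
#' @return a `cspkit_params`.
#' @export
vector_to_params <- function(p, sg, check = FALSE) {
  crystal_parameters(p[1:6], p[7:9], p[10:12], sg, check = check)
}

#' Pose a molecule from crystal parameters
#'
#' Rotates the standardized molecule by the rotation vector and translates
#' its center of geometry to the Cartesian image of the fractional centroid.
#'
#' @param mol a standardized `cspkit_molecule`.
#' @param params a `cspkit_params`.
#' @return N x 3 Cartesian coordinates.
#' @export
pose_molecule <- function(mol, params) {
  if (!is_standardized(mol))
    stop("pose_molecule requires a standardized molecule; call standardize()",
         call. = FALSE)
  cl <- make_cell(params$cell[1], params$cell[2], params$cell[3],
                  params$cell[4], params$cell[5], params$cell[6])
  R <- rotation_from_rotvec(params$rotvec)
  m <- as.numeric(matrix(params$centroid, 1, 3) %*% cl$T)
  mol$std_coords %*% t(R) + matrix(m, nrow(mol$std_coords), 3, byrow = TRUE)
}

#' Build a unit cell from crystal parameters
#'
#' Poses the canonical conformer, applies every general-position operator to
#' its fractional coordinates, and wraps each image molecule-wise so its
#' centroid lies in [0,1)^3. The result contains Z congruent copies.
#'
#' @param mol a standardized `cspkit_molecule`.
#' @param params a `cspkit_params`.
#' @param allow_outside allow a canonical centroid outside the asymmetric
#'   unit (used internally during optimization); default FALSE errors.
#' @return object of class `cspkit_crystal` with fields `cell`, `sg`,
#'   `mol`, `copies` (list of Z Cartesian N x 3 matrices),
#'   `frac_copies`, `wrap_shifts`, `canonical_index`, `params`.
#' @export
build_unit_cell <- function(mol, params, allow_outside = FALSE) {
  sg <- params$sg
  if (!allow_outside && !.in_asym(sg, params$centroid))
    stop("centroid outside asymmetric unit; set allow_outside = TRUE to build anyway",
         call. = FALSE)
  cl <- make_cell(params$cell[1], params$cell[2], params$cell[3],
                  params$cell[4], params$cell[5], params$cell[6])
  posed <- pose_molecule(mol, params)
  frac <- posed %*% cl$Tinv
  copies <- vector("list", sg$Z)
  frac_copies <- vector("list", sg$Z)
  wrap_shifts <- matrix(0, sg$Z, 3)
  for (k in seq_len(sg$Z)) {
    op <- sg$ops[[k]]
    fk <- frac %*% t(op$M) + matrix(op$t, nrow(frac), 3, byrow = TRUE)
    cen <- colMeans(fk)
    sh <- -floor(cen)
    fk <- fk + matrix(sh, nrow(fk), 3, byrow = TRUE)
    wrap_shifts[k, ] <- sh
    frac_copies[[k]] <- fk
    copies[[k]] <- fk %*% cl$T
  }
  structure(list(cell = cl, sg = sg, mol = mol, copies = copies,
                 frac_copies = frac_copies, wrap_shifts = wrap_shifts,
                 canonical_index = 1L, params = params),
            class = "cspkit_crystal")
}

#' Packing coefficient of a crystal
#'
#' `CP = V_mol * Z / V_cell`, the fraction of the unit-cell volume occupied
#' by molecular van der Waals volume.
#'
#' @param mol a `cspkit_molecule`.
#' @param params a `cspkit_params` (or a `cspkit_crystal`).
#' @return dimensionless packing coefficient.
#' @export
packing_coefficient <- function(mol, params) {
  if (inherits(params, "cspkit_crystal")) params <- params$params
  u <- .cell_u(params$cell[4], params$cell[5], params$cell[6])
  vcell <- prod(params$cell[1:3]) * sqrt(u)
  mol$volume * params$sg$Z / vcell
}

#' Carve a periodic cluster around the canonical molecule
#'
#' Tiles integer lattice translations of all symmetry copies within a bound
#' derived from the cutoff plus twice the molecule radius, and keeps every
#' image with at least one atom within `cutoff` of any atom of the central
#' (canonical) molecule. The central molecule itself is excluded from its
#' neighbor list.
#'
#' @param struct a `cspkit_crystal` from [build_unit_cell()].
#' @param cutoff distance cutoff in Angstrom (>= 0).
#' @param min_volume minimum admissible cell volume (guards against
#'   pathological cells).
#' @return object of class `cspkit_cluster`: `symbols`, `central` (N x 3),
#'   `neighbors` (list of `list(op, shift, coords)` where `shift` is the
#'   total fractional translation including molecule wrapping), `cell`,
#'   `sg`, `mol`, `cutoff`.
#' @export
build_cluster <- function(struct, cutoff, min_volume = 1.0) {
  stopifnot(inherits(struct, "cspkit_crystal"))
  if (cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  cl <- struct$cell
  if (cl$volume < min_volume)
    stop("pathological cell: volume ", signif(cl$volume, 4),
         " A^3 below threshold", call. = FALSE)
  mol <- struct$mol
  central <- struct$copies[[struct$canonical_index]]
  ccen <- colMeans(central)
  reach <- cutoff + 2 * mol$radius
  # interplanar spacings: distance between fractional planes f_i = 0, 1
  inv <- cl$Tinv
  spacing <- 1 / sqrt(colSums(inv^2))
  nmax <- ceiling(reach / spacing)
  neighbors <- list()
  cen_frac <- t(vapply(struct$frac_copies, colMeans, numeric(3)))
  for (k in seq_len(struct$sg$Z)) {
    fk <- struct$frac_copies[[k]]
    for (tx in -nmax[1]:nmax[1]) for (ty in -nmax[2]:nmax[2]) for (tz in -nmax[3]:nmax[3]) {
      if (k == struct$canonical_index && tx == 0 && ty == 0 && tz == 0) next
      tvec <- c(tx, ty, tz)
      mcen <- (cen_frac[k, ] + tvec) %*% cl$T
      if (sqrt(sum((mcen - ccen)^2)) > reach) next
      coords <- (fk + matrix(tvec, nrow(fk), 3, byrow = TRUE)) %*% cl$T
      d2 <- .min_cross_dist2(central, coords)
      if (d2 <= cutoff^2) {
        neighbors[[length(neighbors) + 1]] <- list(
          op = k, shift = struct$wrap_shifts[k, ] + tvec, coords = coords)
      }
    }
  }
  structure(list(symbols = mol$symbols, central = central,
                 neighbors = neighbors, cell = cl, sg = struct$sg,
                 mol = mol, cutoff = cutoff, params = struct$params),
            class = "cspkit_cluster")
}

# squared minimum distance between two coordinate sets
.min_cross_dist2 <- function(A, B) {
  cross <- -2 * A %*% t(B)
  cross <- cross + rowSums(A^2)
  cross <- sweep(cross, 2, rowSums(B^2), "+")
  min(cross)
}

#' Extract crystal parameters from a built cell
#'
#' Inverts [build_unit_cell()]: locates the copy whose (wrapped) centroid
#' lies in the asymmetric unit, verifies all copies are congruent to the
#' reference molecule (intramolecular distance matrix preserved), and
#' recovers the rotation vector by a proper orthogonal Procrustes (Kabsch)
#' fit against the standard orientation.
#'
#' @param struct a `cspkit_crystal`, or a list with fields `cell`
#'   (`cspkit_cell`) and `copies` (list of N x 3 Cartesian matrices or one
#'   single (Z N) x 3 block).
#' @param mol the standardized reference molecule.
#' @param sg the space group.
#' @param tol congruence tolerance in Angstrom.
#' @return a `cspkit_params` whose [build_unit_cell()] image reproduces the
#'   input cell up to symmetry-equivalent relabeling.
#' @export
extract_parameters <- function(struct, mol, sg, tol = 1e-6) {
  sg <- get_spacegroup(sg)
  cl <- struct$cell
  n <- nrow(mol$std_coords)
  copies <- struct$copies
  if (length(copies) == 1 && nrow(copies[[1]]) != n) {
    blk <- copies[[1]]
    if (nrow(blk) != n * sg$Z)
      stop("not homomolecular: atom count ", nrow(blk),
           " is not Z * N = ", sg$Z * n, call. = FALSE)
    copies <- lapply(seq_len(sg$Z), function(k) blk[((k - 1) * n + 1):(k * n), , drop = FALSE])
  }
  if (length(copies) != sg$Z)
    stop("expected Z = ", sg$Z, " molecule copies, got ", length(copies),
         call. = FALSE)
  dref <- dist(mol$std_coords)
  for (k in seq_along(copies)) {
    if (nrow(copies[[k]]) != n)
      stop("not homomolecular: copy ", k, " has ", nrow(copies[[k]]),
           " atoms, expected ", n, call. = FALSE)
    if (max(abs(dist(copies[[k]]) - dref)) > max(tol, 1e-8))
      stop("not homomolecular: copy ", k,
           " is not congruent to the reference molecule", call. = FALSE)
  }
  # candidate canonical copies: wrapped centroid inside the asymmetric unit
  best <- NULL
  for (k in seq_along(copies)) {
    X <- copies[[k]]
    cf <- colMeans(X %*% cl$Tinv)
    cen_frac <- cf - floor(cf + 1e-9)   # wrap; 1 - eps maps to ~0
    if (!.in_asym(sg, cen_frac)) next
    Xc <- sweep(X, 2, colMeans(X))
    fit <- .kabsch(mol$std_coords, Xc)
    if (fit$rmsd < tol * max(1, sqrt(mean(mol$std_coords^2)))) {
      best <- list(k = k, centroid = cen_frac, R = fit$R)
      break
    }
    if (is.null(best) || fit$rmsd < best$rmsd)
      best <- list(k = k, centroid = cen_frac, R = fit$R, rmsd = fit$rmsd)
  }
  if (is.null(best))
    stop("no molecule copy has its centroid in the asymmetric unit of ",
         sg$symbol, call. = FALSE)
  if (!is.null(best$rmsd) &&
      best$rmsd >= tol * max(1, sqrt(mean(mol$std_coords^2))))
    stop("asymmetric-unit copy cannot be expressed as a proper rotation of ",
         "the reference molecule (mirror image of a chiral conformer?)",
         call. = FALSE)
  cellpar <- c(cl$lengths, cl$angles)
  crystal_parameters(cellpar, best$centroid, rotvec_from_rotation(best$R),
                     sg, check = FALSE)
}

# proper Kabsch fit: rotation R (det +1) minimizing ||X - Y R^T||, rows are
# atoms, both sets centered
.kabsch <- function(Y, X) {
  C <- t(Y) %*% X
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  rmsd <- sqrt(mean(rowSums((X - Y %*% t(R))^2)))
  list(R = R, rmsd = rmsd)
}

#' Minimum intermolecular contact ratio of a crystal
#'
#' Smallest intermolecular atom-atom distance divided by the sum of the two
#' atoms' van der Waals radii, over a cluster carved at `cutoff`. Values
#' well below 1 indicate molecular overlap; random dense seeds typically
#' start far below 0.7.
#'
#' @param struct a `cspkit_crystal`.
#' @param cutoff carving cutoff in Angstrom.
#' @return the minimum ratio (Inf if the cluster has no neighbors).
#' @export
min_contact_ratio <- function(struct, cutoff = 4) {
  cluster <- build_cluster(struct, cutoff)
  if (length(cluster$neighbors) == 0) return(Inf)
  vdw <- cluster$mol$vdw_radii
  best <- Inf
  for (nb in cluster$neighbors) {
    D2 <- outer(rowSums(cluster$central^2), rowSums(nb$coords^2), "+") -
      2 * cluster$central %*% t(nb$coords)
    ratio <- sqrt(pmax(D2, 0)) / outer(vdw, vdw, "+")
    best <- min(best, min(ratio))
  }
  best
}

#' @export
print.cspkit_crystal <- function(x, ...) {
  cat(sprintf("<crystal: %s, Z = %d, %d atoms/molecule, V = %.2f A^3, CP = %.3f>\n",
              x$sg$symbol, x$sg$Z, nrow(x$copies[[1]]), x$cell$volume,
              packing_coefficient(x$mol, x)))
  invisible(x)
}

#' @export
print.cspkit_params <- function(x, ...) {
  cat(sprintf("<crystal parameters [%s]: a=%.3f b=%.3f c=%.3f al=%.2f be=%.2f ga=%.2f | x=(%.3f,%.3f,%.3f) | v=(%.3f,%.3f,%.3f)>\n",
              x$sg$symbol, x$cell[1], x$cell[2], x$cell[3], x$cell[4],
              x$cell[5], x$cell[6], x$centroid[1], x$centroid[2],
              x$centroid[3], x$rotvec[1], x$rotvec[2], x$rotvec[3]))
  invisible(x)
}
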