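#' @title Frozen cluster topology and analytic parameter gradients
#' @description During gradient optimization the cluster bookkeeping (which
#'   symmetry images and lattice translations are neighbors, and how each
#'   image molecule is wrapped) is frozen between periodic rebuilds. With
#'   the bookkeeping fixed, every image's atom positions are smooth
#'   closed-form functions of the 12 crystal parameters:
#'   `X_m = Y t(R) Tinv t(M_m) T + (x t(M_m) + s_m) T`, where `Y` are the
#'   standard-orientation coordinates, `R` the Rodrigues rotation, `T` the
#'   lattice matrix, `M_m` the symmetry rotation and `s_m` the frozen total
#'   fractional translation. Energies summed over central/neighbor atom
#'   pairs therefore have analytic gradients with respect to all 12
#'   parameters, assembled here by the chain rule.
#' @name topology
NULL

#' Freeze the cluster bookkeeping of a crystal
#'
#' Builds the crystal and carves a cluster (with a safety margin beyond the
#' interaction cutoff so pairs can flow in and out smoothly between
#' rebuilds), then records, for every kept image, the symmetry-rotation
#' matrix and total fractional translation. The returned topology evaluates
#' energies and analytic gradients at nearby parameter values without
#' rebuilding.
#'
#' @param mol standardized `cspkit_molecule`.
#' @param params `cspkit_params`.
#' @param pp `cspkit_pairparams` (supplies the interaction cutoff and pair
#'   tables).
#' @param margin extra carving distance in Angstrom beyond the interaction
#'   cutoff (default 1.5).
#' @return object of class `cspkit_topology`.
#' @export
freeze_topology <- function(mol, params, pp = pair_params(), margin = 1.5) {
  struct <- build_unit_cell(mol, params, allow_outside = TRUE)
  cluster <- build_cluster(struct, pp$cutoff + margin)
  images <- vector("list", length(cluster$neighbors) + 1)
  can <- struct$canonical_index
  images[[1]] <- list(Mt = t(struct$sg$ops[[can]]$M),
                      shift = struct$sg$ops[[can]]$t + struct$wrap_shifts[can, ])
  for (m in seq_along(cluster$neighbors)) {
    nb <- cluster$neighbors[[m]]
    images[[m + 1]] <- list(Mt = t(struct$sg$ops[[nb$op]]$M),
                            shift = struct$sg$ops[[nb$op]]$t + nb$shift)
  }
  n <- nrow(mol$std_coords)
  tab <- .pair_tables(pp, mol$symbols, mol$symbols, mol$charges, mol$charges)
  # stacked pair bookkeeping: neighbor-image atoms are concatenated into one
  # M x 3 block (image 2 first); pairs run over (central atom, stacked atom)
  nnb <- length(images) - 1
  ii1 <- rep(seq_len(n), times = n)   # central index, fastest
  jj1 <- rep(seq_len(n), each = n)    # within-image neighbor index
  iiB <- rep(ii1, times = max(nnb, 0))
  jjB <- rep(jj1, times = max(nnb, 0)) +
    rep((seq_len(max(nnb, 0)) - 1) * n, each = n * n)
  structure(list(
    Y = mol$std_coords,
    n_atoms = n,
    images = images,
    ii = iiB,
    jj = jjB,
    sigB = rep(tab$sig, times = max(nnb, 0)),
    epsB = rep(tab$eps, times = max(nnb, 0)),
    qqB = if (is.null(tab$qq)) NULL else rep(tab$qq, times = max(nnb, 0)),
    tab = tab,
    sg = params$sg,
    vmol = mol$volume,
    struct = struct
  ), class = "cspkit_topology")
}

# positions for a parameter vector: central molecule Xc (N x 3) and all
# neighbor-image atoms stacked into Xn (M x 3, image order as frozen).
# With gradient = TRUE also dXc / dXn, lists over the 12 parameters.
.topology_positions <- function(p, topo, gradient = FALSE) {
  Tm <- cell_to_vectors(p[1], p[2], p[3], p[4], p[5], p[6])
  Tinv <- solve(Tm)
  x <- matrix(p[7:9], 1, 3)
  rot <- .rotation_jacobian(p[10:12])
  G <- t(rot$R) %*% Tinv
  Y <- topo$Y
  n <- nrow(Y)
  nimg <- length(topo$images)
  nnb <- nimg - 1
  Ct <- vector("list", nimg)
  fx <- vector("list", nimg)
  Xn <- matrix(0, nnb * n, 3)
  for (m in seq_len(nimg)) {
    im <- topo$images[[m]]
    Ct[[m]] <- im$Mt %*% Tm
    fx[[m]] <- x %*% im$Mt + matrix(im$shift, 1, 3)
    Xm <- Y %*% (G %*% Ct[[m]]) +
      matrix(fx[[m]] %*% Tm, n, 3, byrow = TRUE)
    if (m == 1) Xc <- Xm else Xn[((m - 2) * n + 1):((m - 1) * n), ] <- Xm
  }
  if (!gradient) return(list(Xc = Xc, Xn = Xn))
  dT <- .cell_jacobian(p[1], p[2], p[3], p[4], p[5], p[6])
  dXc <- vector("list", 12)
  dXn <- vector("list", 12)
  Rt <- t(rot$R)
  for (k in 1:6) {
    dTinv <- -Tinv %*% dT[[k]] %*% Tinv
    dn <- matrix(0, nnb * n, 3)
    for (m in seq_len(nimg)) {
      im <- topo$images[[m]]
      dA <- Rt %*% dTinv %*% Ct[[m]] + (G %*% im$Mt) %*% dT[[k]]
      db <- fx[[m]] %*% dT[[k]]
      dm <- Y %*% dA + matrix(db, n, 3, byrow = TRUE)
      if (m == 1) dc <- dm else dn[((m - 2) * n + 1):((m - 1) * n), ] <- dm
    }
    dXc[[k]] <- dc
    dXn[[k]] <- dn
  }
  for (j in 1:3) {
    dn <- matrix(0, nnb * n, 3)
    for (m in seq_len(nimg)) {
      dm <- matrix(Ct[[m]][j, ], n, 3, byrow = TRUE)
      if (m == 1) dc <- dm else dn[((m - 2) * n + 1):((m - 1) * n), ] <- dm
    }
    dXc[[6 + j]] <- dc
    dXn[[6 + j]] <- dn
  }
  for (i in 1:3) {
    dGt <- t(rot$J[[i]]) %*% Tinv
    dn <- matrix(0, nnb * n, 3)
    for (m in seq_len(nimg)) {
      dm <- Y %*% (dGt %*% Ct[[m]])
      if (m == 1) dc <- dm else dn[((m - 2) * n + 1):((m - 1) * n), ] <- dm
    }
    dXc[[9 + i]] <- dc
    dXn[[9 + i]] <- dn
  }
  list(Xc = Xc, Xn = Xn, dXc = dXc, dXn = dXn)
}

# energy (and gradient) of one pair potential over a frozen topology
# potential: "lj", "soft" or "coul"
.topology_energy <- function(p, topo, pp, potential = "lj", gradient = TRUE) {
  grad <- numeric(12)
  if (length(topo$images) < 2)
    return(list(energy = 0, grad = if (gradient) grad else NULL))
  pos <- .topology_positions(p, topo, gradient = gradient)
  ii <- topo$ii; jj <- topo$jj
  D <- pos$Xc[ii, , drop = FALSE] - pos$Xn[jj, , drop = FALSE]
  r <- sqrt(rowSums(D^2))
  if (potential != "soft" && any(r < 1e-6)) {
    b <- which(r < 1e-6)[1]
    stop(sprintf("overlapping atoms: central atom %d and image atom %d, r = %.2e A",
                 ii[b], (jj[b] - 1) %% topo$n_atoms + 1, r[b]), call. = FALSE)
  }
  keep <- which(r < pp$cutoff)
  if (!length(keep))
    return(list(energy = 0, grad = if (gradient) grad else NULL))
  rk <- r[keep]
  uk <- switch(potential,
               lj = .lj_kernel(rk, topo$sigB[keep], topo$epsB[keep]),
               soft = .soft_kernel(rk, topo$sigB[keep], pp$soft_c, pp$soft_w),
               coul = .coul_kernel(rk, topo$qqB[keep]),
               stop("unknown potential: ", potential))
  env <- .envelope(rk, pp$cutoff, pp$taper)
  energy <- sum(uk$u * env$S)
  if (gradient) {
    w <- (uk$du * env$S + uk$u * env$dS) / pmax(rk, 1e-8)
    Dk <- D[keep, , drop = FALSE]
    iik <- ii[keep]; jjk <- jj[keep]
    wD <- Dk * w
    for (q in 1:12) {
      dD <- pos$dXc[[q]][iik, , drop = FALSE] -
        pos$dXn[[q]][jjk, , drop = FALSE]
      grad[q] <- sum(wD * dD)
    }
  }
  list(energy = energy, grad = if (gradient) grad else NULL)
}

# packing coefficient and gradient from a parameter vector
.cp_value_grad <- function(p, vmol, Z, gradient = TRUE) {
  u <- .cell_u(p[4], p[5], p[6])
  vcell <- p[1] * p[2] * p[3] * sqrt(u)
  cp <- vmol * Z / vcell
  if (!gradient) return(list(cp = cp, grad = NULL))
  d <- .deg2rad
  ca <- cos(p[4] * d); sa <- sin(p[4] * d)
  cb <- cos(p[5] * d); sb <- sin(p[5] * d)
  cg <- cos(p[6] * d); sgn <- sin(p[6] * d)
  du <- c(2 * sa * (ca - cb * cg), 2 * sb * (cb - ca * cg),
          2 * sgn * (cg - ca * cb)) * d
  g <- numeric(12)
  g[1:3] <- -cp / p[1:3]
  g[4:6] <- -cp * du / (2 * u)
  list(cp = cp, grad = g)
}
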