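#' @title Intermolecular pair potentials
#' @description Lennard-Jones, softened ("SiLU") repulsion and short-range
#'   electrostatic energies evaluated over the central-molecule /
#'   neighbor-molecule atom pairs of a carved cluster. All three potentials
#'   are multiplied by a smooth cosine taper envelope that switches the
#'   interaction off at the cutoff, keeping cluster energies smooth
#'   functions of the crystal parameters.
#' @name potentials
NULL

#' Nonbonded pair parameters
#'
#' Per-element Lennard-Jones parameters with a combining rule, the
#' interaction cutoff and taper width, and the softened-repulsion constants.
#' Defaults come from the packaged UFF table (`sigma = x_I / 2^(1/6)`,
#' `epsilon = D_I` in kcal/mol) with Lorentz-Berthelot combining
#' (arithmetic sigma, geometric epsilon).
#'
#' @param sigma named numeric vector of per-element sigma (Angstrom);
#'   default UFF.
#' @param epsilon named numeric vector of per-element epsilon (kcal/mol);
#'   default UFF.
#' @param cutoff interaction cutoff r_c in Angstrom (default 6).
#' @param taper width of the cosine switching region below the cutoff
#'   (Angstrom, default 1); set to 0 to disable switching.
#' @param soft_c prefactor of the softened repulsion (kcal/mol, default 1).
#' @param soft_w width w of the softened repulsion (Angstrom, default 0.5).
#' @param combine combining rule tag; only `"lorentz-berthelot"` is
#'   implemented.
#' @return object of class `cspkit_pairparams`.
#' @export
pair_params <- function(sigma = NULL, epsilon = NULL, cutoff = 6, taper = 1,
                        soft_c = 1, soft_w = 0.5,
                        combine = "lorentz-berthelot") {
  if (is.null(sigma)) {
    sigma <- .uff_table$x / 2^(1 / 6)
    names(sigma) <- .uff_table$symbol
  }
  if (is.null(epsilon)) {
    epsilon <- .uff_table$d
    names(epsilon) <- .uff_table$symbol
  }
  stopifnot(all(sigma > 0), all(epsilon > 0), cutoff > 0, taper >= 0,
            soft_w > 0, identical(combine, "lorentz-berthelot"))
  structure(list(sigma = sigma, epsilon = epsilon, cutoff = cutoff,
                 taper = taper, soft_c = soft_c, soft_w = soft_w,
                 combine = combine),
            class = "cspkit_pairparams")
}

# per-pair combined parameters for two symbol vectors; returns vectors over
# the flattened (i over A, j over B) pair grid, i varying fastest
.pair_tables <- function(pp, sym_a, sym_b, q_a = NULL, q_b = NULL) {
  sa <- pp$sigma[sym_a]; sb <- pp$sigma[sym_b]
  if (anyNA(sa) || anyNA(sb)) {
    bad <- unique(c(sym_a[is.na(sa)], sym_b[is.na(sb)]))
    stop("no nonbonded parameters for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ea <- pp$epsilon[sym_a]; eb <- pp$epsilon[sym_b]
  list(sig = as.numeric(outer(sa, sb, "+") / 2),
       eps = as.numeric(sqrt(outer(ea, eb))),
       qq = if (is.null(q_a) || is.null(q_b)) NULL else as.numeric(outer(q_a, q_b)))
}

# cosine taper envelope S(r) and derivative: 1 below r_on = r_c - taper,
# smooth half-cosine down to 0 at r_c
.envelope <- function(r, cutoff, taper) {
  S <- numeric(length(r))
  dS <- numeric(length(r))
  if (taper <= 0) {
    S[r < cutoff] <- 1
    return(list(S = S, dS = dS))
  }
  r_on <- cutoff - taper
  S[r <= r_on] <- 1
  mid <- r > r_on & r < cutoff
  u <- (r[mid] - r_on) / taper
  S[mid] <- 0.5 * (1 + cos(pi * u))
  dS[mid] <- -0.5 * pi / taper * sin(pi * u)
  list(S = S, dS = dS)
}

# raw pair kernels u(r) and du/dr
.lj_kernel <- function(r, sig, eps) {
  sr6 <- (sig / r)^6
  list(u = 4 * eps * (sr6^2 - sr6),
       du = -24 * eps / r * (2 * sr6^2 - sr6))
}

.silu <- function(x) x * stats::plogis(x)

.soft_kernel <- function(r, sig, cc, w) {
  x <- (sig - r) / w
  s <- stats::plogis(x)
  list(u = cc * x * s,
       du = -cc / w * s * (1 + x * (1 - s)))
}

.coul_kernel <- function(r, qq) {
  list(u = .coulomb_k * qq / r,
       du = -.coulomb_k * qq / r^2)
}

.check_overlap <- function(r, cluster, nb_index) {
  bad <- which(r < 1e-6)
  if (length(bad)) {
    n <- nrow(cluster$central)
    i <- (bad[1] - 1) %% n + 1
    j <- (bad[1] - 1) %/% n + 1
    stop(sprintf("overlapping atoms: central atom %d (%s) and neighbor %d atom %d (%s), r = %.2e A",
                 i, cluster$symbols[i], nb_index, j, cluster$symbols[j], r[bad[1]]),
         call. = FALSE)
  }
}

.cluster_energy <- function(cluster, pp, kernel, need_q = FALSE,
                            check_overlap = TRUE, decompose = FALSE) {
  stopifnot(inherits(cluster, "cspkit_cluster"),
            inherits(pp, "cspkit_pairparams"))
  per <- numeric(length(cluster$neighbors))
  A <- cluster$central
  qa <- cluster$mol$charges
  tab <- .pair_tables(pp, cluster$symbols, cluster$symbols,
                      if (need_q) qa else NULL, if (need_q) qa else NULL)
  for (m in seq_along(cluster$neighbors)) {
    B <- cluster$neighbors[[m]]$coords
    D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    r <- sqrt(pmax(as.numeric(D2), 0))
    if (check_overlap) .check_overlap(r, cluster, m)
    keep <- r < pp$cutoff
    if (!any(keep)) next
    uk <- kernel(r[keep], tab, keep)
    env <- .envelope(r[keep], pp$cutoff, pp$taper)
    per[m] <- sum(uk$u * env$S)
  }
  total <- sum(per)
  if (decompose) list(total = total, per_neighbor = per) else total
}

#' Lennard-Jones cluster energy
#'
#' Sum of tapered 12-6 Lennard-Jones energies over all central-molecule /
#' neighbor-molecule atom pairs within the cutoff. Intramolecular pairs are
#' excluded by construction (the central molecule is not in its own
#' neighbor list).
#'
#' @param cluster a `cspkit_cluster` from [build_cluster()]; carve with a
#'   cutoff at least as large as `pp$cutoff`.
#' @param pp a `cspkit_pairparams`.
#' @param decompose if TRUE, also return the per-neighbor-molecule
#'   decomposition.
#' @return energy in kcal/mol (or a list if `decompose = TRUE`).
#' @export
lj_energy <- function(cluster, pp = pair_params(), decompose = FALSE) {
  .cluster_energy(cluster, pp,
                  function(r, tab, keep) .lj_kernel(r, tab$sig[keep], tab$eps[keep]),
                  check_overlap = TRUE, decompose = decompose)
}

#' Softened-repulsion ("SiLU") cluster energy
#'
#' `U(r) = c * silu((sigma_ij - r) / w)` with `silu(x) = x / (1 + exp(-x))`,
#' tapered to zero at the cutoff. Finite at r = 0 and decaying for
#' r >> sigma, this potential lets severely overlapping random seeds slide
#' past one another during the first optimization stage.
#'
#' @inheritParams lj_energy
#' @return energy in kcal/mol (or a list if `decompose = TRUE`).
#' @export
soft_repulsion_energy <- function(cluster, pp = pair_params(), decompose = FALSE) {
  .cluster_energy(cluster, pp,
                  function(r, tab, keep) .soft_kernel(r, tab$sig[keep], pp$soft_c, pp$soft_w),
                  check_overlap = FALSE, decompose = decompose)
}

#' Short-range electrostatic cluster energy
#'
#' Tapered Coulomb sum `k q_i q_j / r` over intermolecular pairs within the
#' cutoff, with `k = 332.06371` kcal A / (mol e^2). Charges default to zero
#' (set them on the molecule, e.g. from an extended-XYZ charge column).
#'
#' @inheritParams lj_energy
#' @return energy in kcal/mol (or a list if `decompose = TRUE`).
#' @export
electrostatic_energy <- function(cluster, pp = pair_params(), decompose = FALSE) {
  .cluster_energy(cluster, pp,
                  function(r, tab, keep) .coul_kernel(r, tab$qq[keep]),
                  need_q = TRUE, check_overlap = TRUE, decompose = decompose)
}
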