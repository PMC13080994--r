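#' @title Two-stage gradient-based crystal structure search
#' @description Random crystal seeds are drawn at a target packing
#'   coefficient (random sampling at realistic densities produces "jammed"
#'   structures with severe intermolecular overlap). Each seed is relaxed in
#'   two stages: first on a softened-repulsion potential plus a squared
#'   density deviation and an auxiliary hinge keeping cell vectors short
#'   (the soft potential lets overlapping molecules slide past one another),
#'   then a short local refinement of the Lennard-Jones energy at the target
#'   density. Optimization uses adaptive per-parameter gradient descent
#'   (Adam) on the 12 crystal parameters with analytic gradients and
#'   periodically rebuilt (otherwise frozen) cluster bookkeeping.
#' @name search
NULL

#' Search configuration
#'
#' @param target_cp target packing coefficient, in (0, 1).
#' @param n_samples number of random seeds.
#' @param stage1_steps,stage2_steps optimizer steps per stage.
#' @param lr1,lr2 Adam learning rates per stage.
#' @param w_density weight of the squared packing-coefficient deviation
#'   (kcal/mol per unit CP^2).
#' @param w_cell weight of the cell-length hinge penalty (kcal/mol/A^2).
#' @param l_max maximum unpenalized cell length in Angstrom.
#' @param exclude_percentile samples with final LJ energy above this
#'   percentile are flagged excluded (default 94, i.e. worst 6 percent).
#' @param cutoff interaction cutoff in Angstrom.
#' @param rebuild_every rebuild the cluster bookkeeping every this many
#'   steps.
#' @param lr_decay2 apply a cosine learning-rate decay to zero over the
#'   stage-2 refinement so the final parameters settle tightly into the
#'   local minimum (default TRUE; stage 1 always runs at constant rate).
#' @param seed RNG seed; all randomness in [run_search()] flows from it.
#' @param soft_c,soft_w softened-repulsion constants (see [pair_params()]).
#' @param length_sd,angle_sd log-normal spread of the seeded cell lengths
#'   and normal spread (degrees) of free cell angles around 90.
#' @param rdf_rmax,rdf_bins binning of RDF profiles used for reference
#'   comparisons.
#' @return object of class `cspkit_config`.
#' @export
search_config <- function(target_cp = 0.65, n_samples = 64,
                          stage1_steps = 300, stage2_steps = 200,
                          lr1 = 0.01, lr2 = 0.003,
                          w_density = 100, w_cell = 1, l_max = 30,
                          exclude_percentile = 94, cutoff = 6,
                          rebuild_every = 25, seed = 1,
                          lr_decay2 = TRUE,
                          soft_c = 1, soft_w = 0.5,
                          length_sd = 0.25, angle_sd = 8,
                          rdf_rmax = 6, rdf_bins = 100) {
  stopifnot(target_cp > 0, target_cp < 1, n_samples >= 0,
            stage1_steps >= 0, stage2_steps >= 0,
            w_density >= 0, w_cell >= 0, l_max > 0)
  structure(as.list(environment()), class = "cspkit_config")
}

.config_pp <- function(cfg) {
  pair_params(cutoff = cfg$cutoff, soft_c = cfg$soft_c, soft_w = cfg$soft_w)
}

#' Read a search configuration from a YAML file
#'
#' Keys map 1:1 to the arguments of [search_config()]; missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return a `cspkit_config`.
#' @export
read_search_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(search_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(search_config, vals)
}

#' Draw a random crystal at a target packing coefficient
#'
#' Centroid uniform in the asymmetric unit, orientation uniform over
#' rotations (random unit quaternion), free cell angles normal around 90
#' degrees (resampled until the volume is valid; angles fixed by the
#' crystal system are set to 90), cell lengths log-normal around twice the
#' molecule radius, then the cell is rescaled isotropically so the packing
#' coefficient equals `target_cp` exactly.
#'
#' @param mol standardized `cspkit_molecule`.
#' @param sg space group (key accepted by [get_spacegroup()]).
#' @param target_cp target packing coefficient in (0, 1).
#' @param cfg optional `cspkit_config` controlling the sampling widths.
#' @return a `cspkit_params`.
#' @export
sample_random_crystal <- function(mol, sg, target_cp,
                                  cfg = search_config(target_cp = target_cp)) {
  stopifnot(target_cp > 0, target_cp < 1)
  sg <- get_spacegroup(sg)
  centroid <- sg$asym_min + stats::runif(3) * (sg$asym_max - sg$asym_min)
  # uniform rotation via random quaternion
  qn <- stats::rnorm(4)
  qn <- qn / sqrt(sum(qn^2))
  R <- .quat_to_rot(qn)
  rotvec <- rotvec_from_rotation(R)
  free <- .free_angle_mask(sg)
  repeat {
    angles <- c(90, 90, 90)
    if (any(free))
      angles[free] <- stats::rnorm(sum(free), 90, cfg$angle_sd)
    if (all(angles > 50) && all(angles < 130) &&
        .cell_u(angles[1], angles[2], angles[3]) > 0.05) break
  }
  lengths <- 2 * mol$radius * exp(stats::rnorm(3, 0, cfg$length_sd))
  vcell0 <- prod(lengths) * sqrt(.cell_u(angles[1], angles[2], angles[3]))
  scale <- (mol$volume * sg$Z / (target_cp * vcell0))^(1 / 3)
  lengths <- lengths * scale
  crystal_parameters(c(lengths, angles), centroid, rotvec, sg)
}

.quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# shared loss machinery: potential energy + density penalty (+ cell hinge
# for stage 1), evaluated on a frozen topology (built fresh when NULL)
.stage_eval <- function(mol, params, cfg, stage, topology = NULL,
                        gradient = FALSE) {
  if (inherits(params, "cspkit_params")) {
    p <- params_to_vector(params)
    sgp <- params$sg
  } else stop("params must be a cspkit_params", call. = FALSE)
  pp <- .config_pp(cfg)
  if (is.null(topology)) topology <- freeze_topology(mol, params, pp)
  pot <- if (stage == 1) "soft" else "lj"
  en <- .topology_energy(p, topology, pp, potential = pot, gradient = gradient)
  cpg <- .cp_value_grad(p, mol$volume, sgp$Z, gradient = gradient)
  loss <- en$energy + cfg$w_density * (cpg$cp - cfg$target_cp)^2
  grad <- NULL
  if (gradient)
    grad <- en$grad + cfg$w_density * 2 * (cpg$cp - cfg$target_cp) * cpg$grad
  if (stage == 1) {
    over <- pmax(0, p[1:3] - cfg$l_max)
    loss <- loss + cfg$w_cell * sum(over^2)
    if (gradient) grad[1:3] <- grad[1:3] + cfg$w_cell * 2 * over
  }
  list(loss = loss, grad = grad, topology = topology)
}

#' Stage-1 loss: softened repulsion + density + cell-length hinge
#'
#' `E_soft + w_density (CP - target)^2 + w_cell sum_k max(0, len_k -
#' l_max)^2`. Smooth in all 12 crystal parameters for fixed cluster
#' bookkeeping.
#'
#' @param mol standardized `cspkit_molecule`.
#' @param params `cspkit_params`.
#' @param cfg `cspkit_config`.
#' @param topology optional frozen `cspkit_topology` (built fresh if NULL).
#' @return scalar loss (kcal/mol).
#' @export
stage1_loss <- function(mol, params, cfg, topology = NULL) {
  .stage_eval(mol, params, cfg, 1, topology)$loss
}

#' Stage-2 loss: Lennard-Jones energy + density penalty
#' @inheritParams stage1_loss
#' @return scalar loss (kcal/mol).
#' @export
stage2_loss <- function(mol, params, cfg, topology = NULL) {
  .stage_eval(mol, params, cfg, 2, topology)$loss
}

#' Analytic gradient of the stage-1 loss
#' @inheritParams stage1_loss
#' @return numeric length-12 gradient with respect to
#'   `(a,b,c,alpha,beta,gamma,x,y,z,v1,v2,v3)` (Angstrom / degrees /
#'   fractional / radians).
#' @export
stage1_gradient <- function(mol, params, cfg, topology = NULL) {
  .stage_eval(mol, params, cfg, 1, topology, gradient = TRUE)$grad
}

#' Analytic gradient of the stage-2 loss
#' @inheritParams stage1_loss
#' @return numeric length-12 gradient.
#' @export
stage2_gradient <- function(mol, params, cfg, topology = NULL) {
  .stage_eval(mol, params, cfg, 2, topology, gradient = TRUE)$grad
}

# keep parameters in the valid chart: wrap centroid mod 1 (lattice
# translations are always proper isometries), re-branch the rotation
# vector to |v| <= pi, clamp angles to validity and the crystal system
.project_chart <- function(p, sg) {
  p[7:9] <- p[7:9] %% 1
  th <- sqrt(sum(p[10:12]^2))
  if (th > pi) {
    k <- floor((th + pi) / (2 * pi))
    p[10:12] <- p[10:12] * (1 - 2 * pi * k / th)
  }
  ang <- .constrain_angles(get_spacegroup(sg), p[4:6])
  ang <- pmin(pmax(ang, 50), 130)
  while (.cell_u(ang[1], ang[2], ang[3]) < 0.02) {
    ang <- 90 + 0.8 * (ang - 90)
  }
  p[4:6] <- ang
  p[1:3] <- pmax(p[1:3], 1)
  p
}

#' Optimize crystal parameters by adaptive gradient descent
#'
#' Adam updates on the 12-parameter vector with analytic gradients. The
#' cluster bookkeeping is rebuilt every `cfg$rebuild_every` steps and frozen
#' in between; at each rebuild the parameters are projected back into the
#' valid chart (centroid wrapped mod 1, rotation vector re-branched, angles
#' clamped to the crystal system and validity). A non-finite loss or
#' gradient aborts the run, returning the best parameters seen with
#' `converged = FALSE`.
#'
#' @param mol standardized `cspkit_molecule`.
#' @param params starting `cspkit_params`.
#' @param cfg `cspkit_config`.
#' @param stage 1 (softened repulsion) or 2 (Lennard-Jones).
#' @param steps,lr override the stage's step count / learning rate.
#' @param loss,gradient optional custom objective: functions of a
#'   `cspkit_params` returning a scalar and a length-12 gradient. When
#'   given, they replace the stage loss (any smooth function of the 12
#'   parameters can be optimized).
#' @return list with `params` (final), `loss_trace` (per-step loss),
#'   `converged` (final loss <= initial loss and all evaluations finite).
#' @export
optimize_crystal <- function(mol, params, cfg, stage = 1,
                             steps = NULL, lr = NULL,
                             loss = NULL, gradient = NULL) {
  custom <- !is.null(loss)
  if (custom && is.null(gradient))
    stop("a custom loss needs a matching gradient function", call. = FALSE)
  if (is.null(steps)) steps <- if (stage == 1) cfg$stage1_steps else cfg$stage2_steps
  if (is.null(lr)) lr <- if (stage == 1) cfg$lr1 else cfg$lr2
  sg <- params$sg
  p <- params_to_vector(params)
  if (steps == 0)
    return(list(params = params, loss_trace = numeric(0), converged = TRUE))
  mvec <- numeric(12); vvec <- numeric(12)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- rep(NA_real_, steps)
  topo <- NULL
  best_p <- p; best_loss <- Inf
  initial_loss <- NA_real_
  ok <- TRUE
  for (s in seq_len(steps)) {
    if ((s - 1) %% cfg$rebuild_every == 0) {
      p <- .project_chart(p, sg)
      if (!custom) {
        pr <- vector_to_params(p, sg)
        topo <- tryCatch(freeze_topology(mol, pr, .config_pp(cfg)),
                         error = function(e) NULL)
        if (is.null(topo)) { ok <- FALSE; break }
      }
    }
    pr <- vector_to_params(p, sg)
    ev <- if (custom)
      tryCatch(list(loss = loss(pr), grad = gradient(pr)),
               error = function(e) NULL)
    else
      tryCatch(.stage_eval(mol, pr, cfg, stage, topo, gradient = TRUE),
               error = function(e) NULL)
    if (is.null(ev) || !is.finite(ev$loss) || any(!is.finite(ev$grad))) {
      ok <- FALSE
      break
    }
    trace[s] <- ev$loss
    if (s == 1) initial_loss <- ev$loss
    if (ev$loss < best_loss) { best_loss <- ev$loss; best_p <- p }
    mvec <- b1 * mvec + (1 - b1) * ev$grad
    vvec <- b2 * vvec + (1 - b2) * ev$grad^2
    mhat <- mvec / (1 - b1^s)
    vhat <- vvec / (1 - b2^s)
    lr_s <- if (stage == 2 && isTRUE(cfg$lr_decay2))
      lr * 0.5 * (1 + cos(pi * (s - 1) / steps)) else lr
    p <- p - lr_s * mhat / (sqrt(vhat) + eps)
  }
  final_p <- if (ok) .project_chart(p, sg) else best_p
  final <- vector_to_params(final_p, sg)
  final_loss <- tryCatch(
    if (custom) loss(final) else
      .stage_eval(mol, final, cfg, stage, NULL, gradient = FALSE)$loss,
    error = function(e) Inf)
  if (is.finite(final_loss) && is.finite(best_loss) && final_loss > best_loss) {
    final <- vector_to_params(.project_chart(best_p, sg), sg)
    final_loss <- best_loss
  }
  converged <- ok && is.finite(final_loss) && is.finite(initial_loss) &&
    final_loss <= initial_loss + 1e-9
  list(params = final, loss_trace = trace[!is.na(trace)],
       converged = converged)
}

#' Refine a crystal to local convergence of the Lennard-Jones loss
#'
#' Runs repeated stage-2 refinement rounds until the loss change over a
#' round falls below `tol` (relative), or `max_rounds` is reached. A single
#' fixed-budget Adam run settles near, but not tightly into, a local
#' minimum; repeated decayed rounds converge it.
#'
#' @inheritParams stage1_loss
#' @param max_rounds maximum number of stage-2 rounds.
#' @param tol relative loss-change convergence tolerance per round.
#' @return list with `params`, `loss` (final round's last loss) and
#'   `converged`.
#' @export
refine_crystal <- function(mol, params, cfg, max_rounds = 6, tol = 1e-4) {
  converged <- FALSE
  loss <- NA_real_
  for (round in seq_len(max_rounds)) {
    out <- optimize_crystal(mol, params, cfg, stage = 2)
    params <- out$params
    lt <- out$loss_trace
    if (length(lt) >= 2) {
      loss <- lt[length(lt)]
      if (abs(lt[1] - loss) < tol * max(abs(loss), 1)) {
        converged <- out$converged
        break
      }
    }
  }
  list(params = params, loss = loss, converged = converged)
}

#' Run a two-stage crystal structure search
#'
#' Draws `cfg$n_samples` random seeds at the target packing coefficient,
#' relaxes each through stage 1 (softened repulsion) and stage 2
#' (Lennard-Jones refinement), and reports per-sample final parameters,
#' Lennard-Jones energy, packing coefficient and (optionally) the RDF earth
#' mover's distance to a reference crystal. Samples with final energy above
#' the configured percentile are flagged excluded; per-sample failures are
#' flagged, never fatal. Fully deterministic given `cfg$seed`.
#'
#' @param mol standardized `cspkit_molecule`.
#' @param sg space group (key accepted by [get_spacegroup()]).
#' @param cfg `cspkit_config`.
#' @param reference optional reference `cspkit_crystal` (or `cspkit_rdf`
#'   profile) for RDF-EMD reporting.
#' @return object of class `cspkit_search`: `table` (data.frame with one
#'   row per sample), `params` (list of final `cspkit_params`),
#'   `initial_params`, `config`.
#' @export
run_search <- function(mol, sg, cfg, reference = NULL) {
  sg <- get_spacegroup(sg)
  if (!is_standardized(mol)) mol <- standardize(mol)$molecule
  set.seed(cfg$seed)
  seeds <- lapply(seq_len(cfg$n_samples), function(i)
    sample_random_crystal(mol, sg, cfg$target_cp, cfg))
  pp <- .config_pp(cfg)
  ref_rdf <- NULL
  if (!is.null(reference)) {
    ref_rdf <- if (inherits(reference, "cspkit_rdf")) reference else
      compute_rdf(build_cluster(reference, cfg$cutoff),
                  r_max = cfg$rdf_rmax, n_bins = cfg$rdf_bins)
  }
  n <- cfg$n_samples
  res <- data.frame(sample = seq_len(n), converged = logical(n),
                    failed = logical(n), lj_energy = rep(NA_real_, n),
                    soft_energy = rep(NA_real_, n), cp = rep(NA_real_, n),
                    emd = rep(NA_real_, n))
  finals <- vector("list", n)
  for (i in seq_len(n)) {
    out <- tryCatch({
      s1 <- optimize_crystal(mol, seeds[[i]], cfg, stage = 1)
      s2 <- optimize_crystal(mol, s1$params, cfg, stage = 2)
      struct <- build_unit_cell(mol, s2$params, allow_outside = TRUE)
      cluster <- build_cluster(struct, cfg$cutoff)
      lj <- tryCatch(lj_energy(cluster, pp), error = function(e) Inf)
      soft <- soft_repulsion_energy(cluster, pp)
      emd <- if (is.null(ref_rdf)) NA_real_ else
        rdf_emd(compute_rdf(cluster, r_max = cfg$rdf_rmax,
                            n_bins = cfg$rdf_bins), ref_rdf)
      list(params = s2$params, lj = lj, soft = soft,
           cp = packing_coefficient(mol, s2$params), emd = emd,
           converged = s1$converged && s2$converged)
    }, error = function(e) NULL)
    if (is.null(out)) {
      res$failed[i] <- TRUE
      finals[[i]] <- seeds[[i]]
    } else {
      finals[[i]] <- out$params
      res$converged[i] <- out$converged
      res$lj_energy[i] <- out$lj
      res$soft_energy[i] <- out$soft
      res$cp[i] <- out$cp
      res$emd[i] <- out$emd
    }
  }
  ok <- is.finite(res$lj_energy)
  res$excluded <- res$failed
  if (any(ok)) {
    thresh <- stats::quantile(res$lj_energy[ok], cfg$exclude_percentile / 100,
                              names = FALSE, type = 7)
    res$excluded <- res$failed | !ok | res$lj_energy > thresh
  }
  pm <- t(vapply(finals, params_to_vector, numeric(12)))
  colnames(pm) <- c("a", "b", "c", "alpha", "beta", "gamma",
                    "x", "y", "z", "v1", "v2", "v3")
  structure(list(table = cbind(res, as.data.frame(pm)), params = finals,
                 initial_params = seeds, config = cfg),
            class = "cspkit_search")
}

#' Write a search result to CSV
#'
#' One row per sample: energies, packing coefficient, EMD, flags and the 12
#' final crystal parameters, printed with full precision so identical runs
#' produce bit-identical files.
#'
#' @param result a `cspkit_search`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_search_csv <- function(result, path) {
  tab <- result$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.12g", x))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cspkit_search <- function(x, ...) {
  tb <- x$table
  cat(sprintf("<crystal search: %d samples, %d retained, %d failed>\n",
              nrow(tb), sum(!tb$excluded), sum(tb$failed)))
  if (any(!tb$excluded))
    cat(sprintf("  LJ energy (retained): median %.3f, best %.3f kcal/mol; CP median %.3f\n",
                stats::median(tb$lj_energy[!tb$excluded]),
                min(tb$lj_energy[!tb$excluded]),
                stats::median(tb$cp[!tb$excluded])))
  invisible(x)
}
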