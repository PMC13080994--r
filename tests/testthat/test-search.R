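test_that("random seeds hit the target packing coefficient exactly", {
  mol <- generate_fixture("ring6")
  set.seed(61)
  for (num in c(1, 2, 14, 33)) {
    sg <- get_spacegroup(num)
    for (rep in 1:25) {
      pr <- sample_random_crystal(mol, sg, 0.62)
      expect_equal(packing_coefficient(mol, pr), 0.62, tolerance = 1e-8)
      expect_true(all(pr$centroid >= sg$asym_min & pr$centroid < sg$asym_max))
      expect_lte(sqrt(sum(pr$rotvec^2)), pi + 1e-12)
      # crystal-system angle constraints hold
      expect_equal(pr$cell[4:6], cspkit:::.constrain_angles(sg, pr$cell[4:6]),
                   tolerance = 1e-12)
    }
  }
  # RNG contract
  set.seed(7); a <- sample_random_crystal(mol, 33, 0.6)
  set.seed(7); b <- sample_random_crystal(mol, 33, 0.6)
  set.seed(8); c3 <- sample_random_crystal(mol, 33, 0.6)
  expect_identical(params_to_vector(a), params_to_vector(b))
  expect_false(isTRUE(all.equal(params_to_vector(a), params_to_vector(c3))))
})

test_that("stage losses vanish and grow as contracted", {
  mol <- generate_fixture("ring6")
  cfg <- search_config(target_cp = 0.4, l_max = 30, seed = 1)
  # far-apart molecules at the target density in a short cell: loss ~ 0
  iso <- crystal_parameters(
    c(rep((mol$volume / 0.4)^(1 / 3), 3), 90, 90, 90),
    c(0.2, 0.2, 0.2), c(0, 0, 0), 1, check = FALSE)
  # scale to hit CP exactly and push molecules out of soft range via P1 cell
  cp <- packing_coefficient(mol, iso)
  expect_equal(cp, 0.4, tolerance = 1e-6)
  # hinge: pushing one cell length beyond l_max strictly increases stage 1
  cfg2 <- search_config(target_cp = 0.4, l_max = 8, w_density = 0, seed = 1)
  big <- crystal_parameters(c(20, 20, 20, 90, 90, 90), c(0.2, 0.2, 0.2),
                            c(0, 0, 0), 1)
  bigger <- crystal_parameters(c(24, 20, 20, 90, 90, 90), c(0.2, 0.2, 0.2),
                               c(0, 0, 0), 1)
  expect_gt(stage1_loss(mol, bigger, cfg2), stage1_loss(mol, big, cfg2))
  # stage 2 equals the LJ energy when CP is on target
  cfg3 <- search_config(target_cp = packing_coefficient(mol, big), seed = 1)
  cl <- build_cluster(build_unit_cell(mol, big), cfg3$cutoff)
  expect_equal(stage2_loss(mol, big, cfg3),
               lj_energy(cl, cspkit:::.config_pp(cfg3)), tolerance = 1e-9)
})

test_that("analytic loss gradients match central differences", {
  mol <- generate_fixture("ring6")
  cfg <- search_config(target_cp = 0.5, seed = 1)
  set.seed(62)
  for (num in c(2, 33)) {
    for (rep in 1:3) {
      pr <- sample_random_crystal(mol, num, 0.5)
      topo <- freeze_topology(mol, pr, cspkit:::.config_pp(cfg))
      p0 <- params_to_vector(pr)
      for (stage in 1:2) {
        f <- function(p) cspkit:::.stage_eval(
          mol, vector_to_params(p, pr$sg), cfg, stage, topo)$loss
        ga <- if (stage == 1) stage1_gradient(mol, pr, cfg, topo) else
          stage2_gradient(mol, pr, cfg, topo)
        gn <- num_grad(f, p0)
        expect_lt(sqrt(sum((ga - gn)^2)) / sqrt(sum(gn^2)), 1e-4)
      }
    }
  }
})

test_that("loss decreases along a small descent step", {
  mol <- generate_fixture("ring6")
  cfg <- search_config(target_cp = 0.5, seed = 1)
  set.seed(63)
  pr <- sample_random_crystal(mol, 33, 0.5)
  topo <- freeze_topology(mol, pr, cspkit:::.config_pp(cfg))
  p0 <- params_to_vector(pr)
  g <- stage1_gradient(mol, pr, cfg, topo)
  h <- 1e-7 / max(abs(g))
  l0 <- stage1_loss(mol, pr, cfg, topo)
  l1 <- stage1_loss(mol, vector_to_params(p0 - h * g, pr$sg), cfg, topo)
  expect_lt(l1, l0)
})

test_that("a cubic single-atom crystal at its optimal spacing is stationary", {
  atom <- molecule("C", matrix(0, 1, 3))
  cfg <- search_config(target_cp = 0.5, w_density = 0, seed = 1)
  f <- function(a) stage2_loss(
    atom, crystal_parameters(c(a, a, a, 90, 90, 90), c(0.2, 0.2, 0.2),
                             c(0, 0, 0), 1), cfg)
  # locate the 1-D minimum of the cubic lattice energy precisely
  a_star <- stats::optimize(f, c(3.2, 5.5), tol = 1e-12)$minimum
  pr <- crystal_parameters(c(a_star, a_star, a_star, 90, 90, 90),
                           c(0.2, 0.2, 0.2), c(0, 0, 0), 1)
  g <- stage2_gradient(atom, pr, cfg)
  expect_lt(max(abs(g)), 1e-6)
})

test_that("the optimizer contracts a convex surrogate and honors zero steps", {
  mol <- generate_fixture("ring6")
  cfg <- search_config(target_cp = 0.55, seed = 1)
  set.seed(64)
  pr <- sample_random_crystal(mol, 33, 0.4)
  z <- optimize_crystal(mol, pr, cfg, steps = 0)
  expect_identical(params_to_vector(z$params), params_to_vector(pr))
  # quadratic surrogate in the packing coefficient converges to the target
  loss <- function(q) (packing_coefficient(mol, q) - 0.55)^2
  gradient <- function(q) {
    cg <- cspkit:::.cp_value_grad(params_to_vector(q), mol$volume, q$sg$Z)
    2 * (cg$cp - 0.55) * cg$grad
  }
  out <- optimize_crystal(mol, pr, cfg, steps = 200, lr = 0.01,
                          loss = loss, gradient = gradient)
  expect_lt(abs(packing_coefficient(mol, out$params) - 0.55), 1e-4)
  expect_true(out$converged)
  expect_lte(tail(out$loss_trace, 1), out$loss_trace[1])
})

test_that("stage 1 relieves the overlaps of jammed random seeds", {
  mol <- generate_fixture("ring6")
  cfg <- search_config(target_cp = 0.65, n_samples = 4, seed = 71,
                       stage1_steps = 200)
  set.seed(71)
  seeds <- lapply(1:4, function(i) sample_random_crystal(mol, 33, 0.65))
  before <- vapply(seeds, function(pr)
    min_contact_ratio(build_unit_cell(mol, pr)), numeric(1))
  after <- vapply(seeds, function(pr) {
    o <- optimize_crystal(mol, pr, cfg, stage = 1)
    min_contact_ratio(build_unit_cell(mol, o$params, allow_outside = TRUE))
  }, numeric(1))
  expect_lt(mean(before < 0.7 * 1), 1.01)   # jammed at init (sanity)
  expect_gt(mean(after), mean(before))
  expect_lt(sum(after < 0.7), sum(before < 0.7))
  # median soft-repulsion energy strictly decreases
  pp <- cspkit:::.config_pp(cfg)
  soft_of <- function(pr) soft_repulsion_energy(
    build_cluster(build_unit_cell(mol, pr, allow_outside = TRUE), 6), pp)
  s_before <- median(vapply(seeds, soft_of, numeric(1)))
  s_after <- median(vapply(seeds, function(pr)
    soft_of(optimize_crystal(mol, pr, cfg, stage = 1)$params), numeric(1)))
  expect_lt(s_after, s_before)
})

test_that("run_search is deterministic, flags excluded samples, and self-matches", {
  mol <- generate_fixture("ring6")
  cfg <- search_config(target_cp = 0.65, n_samples = 4, seed = 5,
                       stage1_steps = 150, stage2_steps = 100)
  empty <- run_search(mol, 33, search_config(target_cp = 0.65, n_samples = 0,
                                             seed = 1))
  expect_identical(nrow(empty$table), 0L)
  res <- run_search(mol, 33, cfg)
  expect_identical(nrow(res$table), 4L)
  expect_identical(sum(res$table$excluded) + sum(!res$table$excluded), 4L)
  # reference = one sample's own structure: that sample attains the
  # minimum RDF-EMD over the batch
  ref <- build_unit_cell(mol, res$params[[2]], allow_outside = TRUE)
  res2 <- run_search(mol, 33, cfg, reference = ref)
  expect_identical(which.min(res2$table$emd), 2L)
  expect_lt(res2$table$emd[2], 1e-9)
  # identical config -> bit-identical CSV
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_search_csv(run_search(mol, 33, cfg), f1)
  write_search_csv(run_search(mol, 33, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("search configs round-trip through YAML", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("target_cp: 0.7", "n_samples: 3", "stage1_steps: 10",
               "seed: 9"), tmp)
  cfg <- read_search_config(tmp)
  expect_equal(cfg$target_cp, 0.7)
  expect_identical(cfg$n_samples, 3L)
  expect_identical(cfg$stage1_steps, 10L)
  expect_equal(cfg$lr1, 0.01)  # defaults fill in
  writeLines(c("target_cp: 0.7", "bogus_key: 1"), tmp)
  expect_error(read_search_config(tmp), "bogus_key")
})
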