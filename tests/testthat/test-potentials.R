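test_that("LJ dimer reproduces the analytic minimum and the oracle", {
  pp <- pair_params(cutoff = 10, taper = 0)
  sig <- pp$sigma["C"]
  eps <- pp$epsilon["C"]
  cl <- pair_cluster(2^(1 / 6) * sig)
  expect_equal(lj_energy(cl, pp), -eps, tolerance = 1e-10,
               ignore_attr = TRUE)
  # repulsive inside, attractive outside the minimum
  expect_gt(lj_energy(pair_cluster(0.8 * sig), pp), 0)
  expect_lt(lj_energy(pair_cluster(1.5 * sig), pp), 0)
  # linearity in epsilon
  pp2 <- pair_params(epsilon = pp$epsilon * 2, cutoff = 10, taper = 0)
  expect_equal(lj_energy(cl, pp2), 2 * lj_energy(cl, pp), tolerance = 1e-12)
})

test_that("cluster energies match a brute-force double loop", {
  mol <- generate_fixture("ring6")
  set.seed(21)
  for (num in c(2, 33)) {
    pr <- sample_random_crystal(mol, num, 0.45)
    st <- build_unit_cell(mol, pr)
    pp <- pair_params()
    cl <- build_cluster(st, pp$cutoff)
    expect_equal(lj_energy(cl, pp), brute_lj(cl, pp), tolerance = 1e-10)
  }
  # isolated molecule: zero energy
  iso <- crystal_parameters(c(60, 60, 60, 90, 90, 90), c(0.3, 0.3, 0.3),
                            c(0, 0, 0), 1)
  cl0 <- build_cluster(build_unit_cell(mol, iso), 6)
  expect_identical(lj_energy(cl0), 0)
  expect_identical(soft_repulsion_energy(cl0), 0)
  expect_identical(electrostatic_energy(cl0), 0)
})

test_that("energies are invariant under rigid motion of the whole cluster", {
  mol <- generate_fixture("blob", 6)
  set.seed(22)
  pr <- sample_random_crystal(mol, 19, 0.4)
  cl <- build_cluster(build_unit_cell(mol, pr), 6)
  pp <- pair_params()
  e0 <- c(lj_energy(cl, pp), soft_repulsion_energy(cl, pp))
  R <- rand_rotation()
  tv <- c(3, -2, 7)
  move <- function(X) X %*% t(R) + matrix(tv, nrow(X), 3, byrow = TRUE)
  cl$central <- move(cl$central)
  cl$neighbors <- lapply(cl$neighbors, function(nb) {
    nb$coords <- move(nb$coords); nb
  })
  e1 <- c(lj_energy(cl, pp), soft_repulsion_energy(cl, pp))
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("soft repulsion has the silu closed form and a decreasing core", {
  pp <- pair_params(cutoff = 30, taper = 0, soft_c = 2, soft_w = 0.5)
  sig <- pp$sigma["C"]
  silu <- function(x) x / (1 + exp(-x))
  # finite at contact, equal to the closed form
  expect_equal(soft_repulsion_energy(pair_cluster(1e-7), pp),
               2 * silu((sig - 1e-7) / 0.5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # far tail is negligible
  expect_lt(abs(soft_repulsion_energy(pair_cluster(10 * sig), pp)), 1e-4 * 2)
  # numerically decreasing over the repulsive core [0, sigma + w]
  rs <- seq(0.01, sig + 0.5, length.out = 120)
  us <- vapply(rs, function(r) soft_repulsion_energy(pair_cluster(r), pp),
               numeric(1))
  expect_true(all(diff(us) < 0))
})

test_that("electrostatics follow Coulomb's law inside the envelope", {
  # +1/-1 pair: put both charges on one 2-atom molecule 50 A apart and
  # translate the neighbor image so exactly one opposite-sign pair is at 1 A
  mol <- molecule(c("N", "N"), rbind(c(0, 0, 0), c(50, 0, 0)),
                  charges = c(1, -1))
  cl <- structure(list(
    symbols = mol$symbols, central = mol$coords,
    neighbors = list(list(op = 1L, shift = c(0, 0, 0),
                          coords = mol$coords - matrix(c(51, 0, 0), 2, 3,
                                                       byrow = TRUE))),
    cell = make_cell(200, 200, 200), sg = get_spacegroup(1), mol = mol,
    cutoff = 7, params = NULL), class = "cspkit_cluster")
  pp <- pair_params(cutoff = 6, taper = 0)
  expect_equal(electrostatic_energy(cl, pp), -332.06371, tolerance = 1e-8)
  # all charges zero -> 0; pair beyond the cutoff -> 0
  cl0 <- pair_cluster(2.5)
  expect_identical(electrostatic_energy(cl0, pp), 0)
  expect_identical(lj_energy(pair_cluster(6.5), pp), 0)
})

test_that("overlapping atoms raise an error naming the pair", {
  pp <- pair_params()
  expect_error(lj_energy(pair_cluster(1e-8), pp), "overlapping atoms")
  expect_no_error(soft_repulsion_energy(pair_cluster(1e-8), pp))
})

test_that("per-molecule decomposition sums to the total", {
  mol <- generate_fixture("ring6")
  set.seed(23)
  pr <- sample_random_crystal(mol, 33, 0.5)
  cl <- build_cluster(build_unit_cell(mol, pr), 6)
  dec <- lj_energy(cl, decompose = TRUE)
  expect_length(dec$per_neighbor, length(cl$neighbors))
  expect_equal(sum(dec$per_neighbor), dec$total, tolerance = 1e-12)
  expect_equal(dec$total, lj_energy(cl), tolerance = 1e-12)
})

test_that("energy per molecule converges as the carving cutoff grows", {
  mol <- generate_fixture("ring6")
  set.seed(24)
  pr <- sample_random_crystal(mol, 33, 0.6)
  base <- optimize_crystal(mol, pr, search_config(target_cp = 0.6, seed = 1),
                           stage = 1, steps = 60)
  st <- build_unit_cell(mol, base$params, allow_outside = TRUE)
  pp <- pair_params()
  # carving beyond the interaction cutoff leaves the energy unchanged
  e1 <- lj_energy(build_cluster(st, 6), pp)
  e2 <- lj_energy(build_cluster(st, 9), pp)
  expect_equal(e1, e2, tolerance = 1e-9)
})
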