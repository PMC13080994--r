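test_that("posing is the identity at zero parameters and rotates correctly", {
  mol <- generate_fixture("ring6")
  p0 <- crystal_parameters(c(20, 20, 20, 90, 90, 90), c(0, 0, 0),
                           c(0, 0, 0), 1)
  expect_equal(pose_molecule(mol, p0), mol$std_coords, tolerance = 1e-12)
  # quarter turn about z maps an x offset to a y offset
  Rq <- rotation_from_rotvec(c(0, 0, pi / 2))
  expect_equal(as.numeric(Rq %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  m <- generate_fixture("blob", 4)
  pq <- crystal_parameters(c(30, 30, 30, 90, 90, 90), c(0, 0, 0),
                           c(0, 0, pi / 2), 1, check = FALSE)
  expect_equal(pose_molecule(m, pq), m$std_coords %*% t(Rq),
               tolerance = 1e-10)
  # centroid lands on the Cartesian image of the fractional centroid
  pc <- crystal_parameters(c(10, 12, 14, 90, 90, 90), c(0.2, 0.3, 0.4),
                           c(0.3, -0.2, 0.1), 1)
  expect_equal(colMeans(pose_molecule(mol, pc)),
               as.numeric(frac_to_cart(matrix(c(0.2, 0.3, 0.4), 1, 3),
                                       make_cell(10, 12, 14))),
               tolerance = 1e-10)
  # non-standardized molecules are rejected
  raw <- molecule(c("C", "C"), rbind(c(5, 0, 0), c(6.5, 0, 0)))
  expect_error(pose_molecule(raw, p0), "standardized")
})

test_that("unit cells have Z congruent copies placed by the operators", {
  mol <- generate_fixture("ring6")
  # P1: one copy identical to the posed molecule
  p1 <- crystal_parameters(c(9, 10, 11, 90, 90, 90), c(0.1, 0.2, 0.3),
                           c(0.4, 0.5, -0.6), 1)
  st1 <- build_unit_cell(mol, p1)
  expect_length(st1$copies, 1)
  expect_equal(st1$copies[[1]], pose_molecule(mol, p1), tolerance = 1e-10)
  # P-1 at centroid (1/4,1/4,1/4): inversion image centroid wraps to 3/4s
  p2 <- crystal_parameters(c(9, 10, 11, 85, 95, 100), c(0.25, 0.25, 0.25),
                           c(0.2, 0.1, 0.3), 2)
  st2 <- build_unit_cell(mol, p2)
  cen2 <- colMeans(st2$frac_copies[[2]])
  expect_equal(cen2, c(0.75, 0.75, 0.75), tolerance = 1e-9)
  # congruence and handedness across groups
  dref <- dist(mol$std_coords)
  for (key in c(33, 14, 61, 15)) {
    set.seed(key)
    pr <- sample_random_crystal(mol, key, 0.4)
    st <- build_unit_cell(mol, pr)
    expect_length(st$copies, st$sg$Z)
    for (k in seq_along(st$copies)) {
      expect_lt(max(abs(dist(st$copies[[k]]) - dref)), 1e-8)
      # chirality of each copy follows the operator determinant
      fit_sign <- det(cspkit:::.kabsch(
        mol$std_coords,
        sweep(st$copies[[k]], 2, colMeans(st$copies[[k]])))$R)
      expect_equal(fit_sign, 1)
      # mirror copies (det -1 ops) are congruent but not properly
      # superimposable unless the molecule is achiral; ring6 is planar,
      # so a proper fit always exists and centroids must obey the op
      cen <- colMeans(st$frac_copies[[k]]) %% 1
      img <- (st$sg$ops[[k]]$M %*% pr$centroid + st$sg$ops[[k]]$t) %% 1
      expect_equal(cen, as.numeric(img), tolerance = 1e-9)
    }
  }
  # centroid outside the asymmetric unit errors unless allowed
  bad <- crystal_parameters(c(9, 10, 11, 90, 90, 90), c(0.8, 0.2, 0.2),
                            c(0, 0, 0), 33, check = FALSE)
  expect_error(build_unit_cell(mol, bad), "asymmetric")
  expect_no_error(build_unit_cell(mol, bad, allow_outside = TRUE))
})

test_that("clusters match exhaustive enumeration and grow monotonically", {
  atom <- molecule("C", matrix(0, 1, 3))
  pr <- crystal_parameters(c(10, 10, 10, 90, 90, 90), c(0, 0, 0),
                           c(0, 0, 0), 1, check = FALSE)
  st <- build_unit_cell(atom, pr, allow_outside = TRUE)
  expect_length(build_cluster(st, 0)$neighbors, 0)
  cl <- build_cluster(st, 10.5)
  # oracle: enumerate a 5^3 translation block
  count <- 0
  for (tx in -2:2) for (ty in -2:2) for (tz in -2:2) {
    if (tx == 0 && ty == 0 && tz == 0) next
    if (sqrt(sum((c(tx, ty, tz) * 10)^2)) <= 10.5) count <- count + 1
  }
  expect_length(cl$neighbors, count)
  # monotone in the cutoff
  mol <- generate_fixture("ring6")
  set.seed(4)
  pr2 <- sample_random_crystal(mol, 33, 0.5)
  st2 <- build_unit_cell(mol, pr2)
  sizes <- vapply(c(2, 4, 6, 8), function(rc)
    length(build_cluster(st2, rc)$neighbors), integer(1))
  expect_true(all(diff(sizes) >= 0))
  # every neighbor really has an atom within the cutoff; tags are unique
  cl2 <- build_cluster(st2, 6)
  tags <- vapply(cl2$neighbors, function(nb)
    paste(nb$op, paste(nb$shift, collapse = ","), sep = "|"), character(1))
  expect_identical(anyDuplicated(tags), 0L)
  for (nb in cl2$neighbors) {
    d2 <- outer(rowSums(cl2$central^2), rowSums(nb$coords^2), "+") -
      2 * cl2$central %*% t(nb$coords)
    expect_lte(sqrt(max(0, min(d2))), 6)
  }
  expect_error(build_cluster(structure(list(cell = make_cell(0.5, 0.5, 0.5),
                                            sg = st2$sg, mol = mol),
                                       class = "cspkit_crystal"), 3),
               "pathological")
})

test_that("parameter extraction inverts building across all groups", {
  set.seed(12)
  mols <- list(generate_fixture("ring6"), generate_fixture("blob", 2))
  for (num in supported_spacegroups()$number) {
    for (rep in 1:3) {
      mol <- mols[[1 + (rep %% 2)]]
      pr <- sample_random_crystal(mol, num, stats::runif(1, 0.3, 0.6))
      st <- build_unit_cell(mol, pr)
      back <- extract_parameters(st, mol, num)
      st2 <- build_unit_cell(mol, back)
      err <- max(abs(unlist(st$copies) - unlist(st2$copies)))
      expect_lt(err, 1e-6)
      # recovered parameters match up to the axis-angle branch
      expect_equal(back$cell, pr$cell, tolerance = 1e-8)
      expect_equal(back$centroid, pr$centroid, tolerance = 1e-8)
    }
  }
  # trivial case: origin, standard orientation in P1
  mol <- mols[[1]]
  p0 <- crystal_parameters(c(9, 9, 9, 90, 90, 90), c(0, 0, 0), c(0, 0, 0), 1)
  back <- extract_parameters(build_unit_cell(mol, p0), mol, 1)
  expect_lt(max(abs(back$centroid)), 1e-9)
  expect_lt(max(abs(back$rotvec)), 1e-9)
})

test_that("non-homomolecular inputs are rejected by extraction", {
  mol <- generate_fixture("ring6")
  set.seed(9)
  pr <- sample_random_crystal(mol, 2, 0.4)
  st <- build_unit_cell(mol, pr)
  # delete one atom from one copy
  broken <- st
  broken$copies[[2]] <- broken$copies[[2]][-1, ]
  expect_error(extract_parameters(broken, mol, 2), "not homomolecular")
  # distort one copy
  bent <- st
  bent$copies[[2]][1, ] <- bent$copies[[2]][1, ] + 0.5
  expect_error(extract_parameters(bent, mol, 2), "not homomolecular")
})

test_that("packing coefficient follows CP = Vmol Z / Vcell", {
  mol <- generate_fixture("ring6")
  pr <- crystal_parameters(c(8, 9, 10, 90, 90, 90), c(0.05, 0.2, 0.3),
                           c(0, 0, 0), 33)
  cp <- packing_coefficient(mol, pr)
  expect_equal(cp, mol$volume * 4 / 720, tolerance = 1e-12)
  # algebraic identity CP * Vcell / Z == Vmol
  expect_equal(cp * 720 / 4, mol$volume, tolerance = 1e-10)
  # doubling all lengths divides CP by 8
  pr2 <- crystal_parameters(c(16, 18, 20, 90, 90, 90), c(0.05, 0.2, 0.3),
                            c(0, 0, 0), 33)
  expect_equal(packing_coefficient(mol, pr2), cp / 8, tolerance = 1e-12)
})

test_that("rotation vector conversions are exact inverses on both branches", {
  set.seed(77)
  for (rep in 1:50) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2)) * stats::runif(1, 0, pi - 1e-6)
    R <- rotation_from_rotvec(v)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(rotvec_from_rotation(R), v, tolerance = 1e-8)
  }
  # angle near pi still recovers a valid rotation
  v <- c(pi - 1e-9, 0, 0)
  R <- rotation_from_rotvec(v)
  expect_lt(max(abs(rotation_from_rotvec(rotvec_from_rotation(R)) - R)), 1e-6)
})
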