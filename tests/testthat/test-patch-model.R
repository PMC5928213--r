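# Patch geometry and the directional square-well pair interaction.

test_that("patch spanning angle follows the coverage relation", {
  expect_identical(patch_cos_half_angle(4, 0.7), 0.65)
  expect_equal(patch_cos_half_angle(2, 0.7), 0.3, tolerance = 1e-15)
  # full coverage with two polar patches: each spans a hemisphere
  expect_identical(patch_cos_half_angle(2, 1), 0)
  expect_error(patch_cos_half_angle(1, 1), "hemisphere")
  expect_error(patch_cos_half_angle(4, 0), "chi")
  expect_error(patch_cos_half_angle(4, 1.2), "chi")
})

test_that("reference patch frames are unit vectors with the right geometry", {
  dR <- reference_patch_directions("R")
  expect_equal(dR, rbind(c(0, 0, 1), c(0, 0, -1)))

  dP <- reference_patch_directions("P")
  expect_equal(nrow(dP), 4)
  expect_equal(rowSums(dP^2), rep(1, 4))
  dots <- tcrossprod(dP)
  expect_equal(dots[upper.tri(dots)], rep(-1 / 3, 6), tolerance = 1e-12)

  # rigid rotation preserves the pairwise dot products
  set.seed(1)
  q <- random_quaternion(1)[1, ]
  rot <- quat_rotate(q, dP)
  expect_equal(tcrossprod(rot), tcrossprod(dP), tolerance = 1e-12)
})

test_that("parameter validation rejects unphysical models", {
  expect_error(model_params(chi = 0), "chi")
  expect_error(model_params(chi = 1.5), "chi")
  expect_error(model_params(eps_PR = -0.1))
  expect_error(model_params(lam = 0))
  # three equatorial patches at high coverage overlap on the sphere
  expect_error(model_params(chi = 0.99, m_P = 3), "overlap")
  # the production parameter sets pass the disjoint-cap check
  expect_s3_class(model_params(), "patch_model")
  expect_s3_class(model_params(chi = 1, m_P = 2, m_R = 2), "patch_model")
})

test_that("bond criterion matches mutually facing patches", {
  p <- model_params()
  cfg <- two_particle_config("R", "R", r = 1.2, aligned = TRUE)
  expect_true(is_bonded(cfg, 1, 2, p))
  # bonded but zero well depth: geometry and energy are separate questions
  expect_identical(pair_energy(cfg, 1, 2, p), 0)

  # two-pole R particles always expose a patch along their axis, so the
  # non-bonded cases are a perpendicular axis or a turned-away P
  cfg_perp <- configuration(tibble::tibble(
    species = c("R", "R"), x = c(2, 3.2), y = c(2, 2), z = c(2, 2),
    qw = c(1, 1), qx = c(0, 0), qy = c(0, 0), qz = c(0, 0)),
    box_edge = 10)  # poles along z, separation along x
  expect_false(is_bonded(cfg_perp, 1, 2, p))

  cfg2 <- two_particle_config("P", "P", r = 1.2, aligned = FALSE)
  expect_false(is_bonded(cfg2, 1, 2, p))

  cfgP <- two_particle_config("P", "P", r = 1.2, aligned = TRUE)
  expect_true(is_bonded(cfgP, 1, 2, p))
  expect_identical(pair_energy(cfgP, 1, 2, p), -1)
})

test_that("randomized orientations agree with the all-patch-pairs oracle", {
  set.seed(42)
  p <- model_params(eps_PR = 0.7)
  for (k in 1:300) {
    r <- runif(1, 1.01, 1.6)
    sp <- sample(c("P", "R"), 2, replace = TRUE)
    q <- random_quaternion(2)
    cfg <- configuration(tibble::tibble(
      species = sp, x = c(2, 2 + r), y = c(2, 2), z = c(2, 2),
      qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4]
    ), box_edge = 10)
    oracle <- brute_force_bond_counts(cfg, p, energetic_only = FALSE)
    expect_identical(is_bonded(cfg, 1, 2, p), oracle$n_bonds[1] == 1L)
  }
})

test_that("pair energy takes only the overlap, well and zero values", {
  p <- model_params(eps_PR = 0.5)
  cfg <- two_particle_config("P", "P", r = 0.9)
  expect_identical(pair_energy(cfg, 1, 2, p), Inf)

  set.seed(8)
  vals <- replicate(200, {
    r <- runif(1, 0.8, 2.0)
    sp <- sample(c("P", "R"), 2, replace = TRUE)
    q <- random_quaternion(2)
    cfg <- configuration(tibble::tibble(
      species = sp, x = c(2, 2 + r), y = c(2, 2), z = c(2, 2),
      qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4]
    ), box_edge = 10)
    c(pair_energy(cfg, 1, 2, p), pair_energy(cfg, 2, 1, p))
  })
  # symmetry under particle interchange, exact
  expect_identical(vals[1, ], vals[2, ])
  expect_true(all(vals %in% c(Inf, -1, -0.5, 0)))
})

test_that("total energy matches hand-built fixtures and the oracle", {
  p <- model_params()
  single <- configuration(tibble::tibble(
    species = "P", x = 1, y = 1, z = 1, qw = 1, qx = 0, qy = 0, qz = 0),
    box_edge = 5)
  expect_identical(total_energy(single, p), 0)

  fx <- make_fixture("trimer_PPR")
  expect_identical(total_energy(fx$config, fx$params), -1.5)
  expect_identical(fx$expected$energy, -1.5)

  set.seed(11)
  prm <- model_params(eps_PR = 0.5)
  cfg <- random_configuration(35, 15, 5, prm)
  expect_identical(total_energy(cfg, prm), brute_force_energy(cfg, prm))
})

test_that("full patch coverage reduces to the isotropic square well", {
  p <- model_params(chi = 1, m_P = 2, m_R = 2, eps_PR = 0.5)
  set.seed(13)
  for (k in 1:200) {
    r <- runif(1, 1.01, 1.49)  # inside the well, away from the edges
    q <- random_quaternion(2)
    sp <- sample(c("P", "R"), 2, replace = TRUE)
    cfg <- configuration(tibble::tibble(
      species = sp, x = c(2, 2 + r), y = c(2, 2), z = c(2, 2),
      qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4]
    ), box_edge = 10)
    eps <- if (all(sp == "P")) 1 else if (all(sp == "R")) 0 else 0.5
    expect_identical(pair_energy(cfg, 1, 2, p), -eps)
    expect_true(is_bonded(cfg, 1, 2, p))
  }
  # outside the well the interaction vanishes for any orientation
  cfg <- two_particle_config("P", "P", r = 1.55)
  expect_identical(pair_energy(cfg, 1, 2, p), 0)
})

test_that("a global rotation leaves the total energy unchanged", {
  set.seed(17)
  p <- model_params(eps_PR = 1.0)
  # compact cluster well inside a large box so no interaction wraps
  n <- 8
  q <- random_quaternion(n)
  pos <- matrix(10 + runif(3 * n, -1.3, 1.3), ncol = 3)
  repeat {
    d <- as.matrix(dist(pos))
    bad <- which(d < 1.02 & upper.tri(d), arr.ind = TRUE)
    if (nrow(bad) == 0) break
    pos[bad[1, 2], ] <- 10 + runif(3, -1.3, 1.3)
  }
  cfg <- configuration(tibble::tibble(
    species = rep(c("P", "R"), each = n / 2),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4]
  ), box_edge = 40)
  u0 <- total_energy(cfg, p)
  expect_true(is.finite(u0))

  qg <- random_quaternion(1)[1, ]
  ctr <- c(10, 10, 10)
  newpos <- t(apply(pos, 1, function(v) ctr + quat_rotate(qg, v - ctr)))
  newq <- t(apply(q, 1, function(qi) quat_multiply(qg, qi)))
  cfg2 <- configuration(tibble::tibble(
    species = rep(c("P", "R"), each = n / 2),
    x = newpos[, 1], y = newpos[, 2], z = newpos[, 3],
    qw = newq[, 1], qx = newq[, 2], qy = newq[, 3], qz = newq[, 4]
  ), box_edge = 40)
  expect_identical(total_energy(cfg2, p), u0)
})

test_that("zero R-R well depth never contributes energy", {
  set.seed(19)
  p <- model_params(eps_PR = 0)  # only P-P interactions carry energy
  cfg <- random_configuration(0, 40, 4.5, p)
  expect_identical(total_energy(cfg, p), 0)
  expect_equal(nrow(bond_pairs(cfg, p)), 0)
})
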