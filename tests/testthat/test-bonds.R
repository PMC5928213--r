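# Bond-network statistics: partner counts, decomposition identities,
# clusters.

test_that("the trimer fixture decomposes by partner species", {
  fx <- make_fixture("trimer_PPR")
  counts <- count_bonds(fx$config, fx$params)
  # central P bonded to one P and one R; each neighbour has one bond
  expect_identical(counts$n_P_partners, c(1L, 1L, 1L))
  expect_identical(counts$n_R_partners, c(1L, 0L, 0L))
  expect_identical(counts$n_bonds, c(2L, 1L, 1L))

  cl <- extract_clusters(fx$config, fx$params)
  expect_identical(cl$cluster, rep(1L, 3))
  smry <- attr(cl, "summary")
  expect_identical(smry$size, 3L)
  expect_identical(smry$n_P, 2L)
  expect_identical(smry$n_R, 1L)
})

test_that("isolated particles form singleton clusters and zero bonds", {
  gas <- make_fixture("ideal_gas_box")
  counts <- count_bonds(gas$config, gas$params)
  expect_identical(sum(counts$n_bonds), 0L)
  cl <- extract_clusters(gas$config, gas$params)
  expect_identical(sort(unique(cl$cluster)), seq_len(nrow(counts)))
})

test_that("handshake lemma and oracle equivalence hold on random mixtures", {
  set.seed(53)
  for (k in 1:10) {
    p <- model_params(eps_PR = runif(1, 0.2, 1.5))
    cfg <- random_configuration(30, 15, 4.4, p)
    counts <- count_bonds(cfg, p)
    pairs <- bond_pairs(cfg, p)
    expect_identical(sum(counts$n_bonds), 2L * nrow(pairs))
    # reciprocity: P->R bonds equal R->P bonds
    expect_identical(
      sum(counts$n_R_partners[counts$species == "P"]),
      sum(counts$n_P_partners[counts$species == "R"]))
    expect_identical(counts, brute_force_bond_counts(cfg, p))
  }
})

test_that("geometric R-R contacts are excluded when the well depth is zero", {
  p <- model_params(eps_PR = 0.5)  # eps_RR = 0
  cfg <- two_particle_config("R", "R", r = 1.2, aligned = TRUE)
  expect_identical(nrow(bond_pairs(cfg, p, energetic_only = TRUE)), 0L)
  expect_identical(nrow(bond_pairs(cfg, p, energetic_only = FALSE)), 1L)
  # with an attractive R-R well the same contact counts
  p2 <- model_params(eps_PR = 0.5, eps_RR = 0.3)
  expect_identical(nrow(bond_pairs(cfg, p2, energetic_only = TRUE)), 1L)
})

test_that("cluster internal bonds account for every bond", {
  set.seed(59)
  p <- model_params(eps_PR = 1)
  cfg <- random_configuration(40, 20, 4.6, p)
  cl <- extract_clusters(cfg, p)
  pairs <- bond_pairs(cfg, p)
  # every bonded pair lies within one cluster, and the per-cluster bond
  # totals sum to the global bond count
  same <- cl$cluster[pairs$i] == cl$cluster[pairs$j]
  expect_true(all(same))
  per_cluster <- table(cl$cluster[pairs$i])
  expect_identical(sum(per_cluster), nrow(pairs))
})

test_that("the density-weighted bond average reproduces known arithmetic", {
  # rho_P = 0.6, rho_R = 0.2, n_bP = 6, n_bR = 4 -> n_b = 5.5
  n <- 40
  s <- tibble::tibble(
    cycle = seq_len(n),
    n_P_I = 2, n_R_I = 0, volume_I = 1000,
    energy_I = 0, n_PP_I = 0, n_PR_I = 0, n_RR_I = 0,
    n_P_II = 600, n_R_II = 200, volume_II = 1000,
    energy_II = 0, n_PP_II = 1400, n_PR_II = 800, n_RR_II = 0,
    rho_P_I = 0.002, rho_R_I = 0,
    rho_P_II = 0.6, rho_R_II = 0.2
  )
  rep <- bond_report(s, model_params(eps_PR = 1))
  expect_equal(rep$n_b, 5.5)
  expect_equal(rep$n_bP, 6)
  expect_equal(rep$n_bR, 4)
  expect_equal(rep$n_bPP, 2 * 1400 / 600)
  expect_equal(rep$n_bPR, 800 / 600)
  expect_equal(rep$r_fraction, 0.25)
})

test_that("bond decomposition identities hold exactly on every sample", {
  p <- model_params(eps_PR = 1)
  run <- cached_run("mix_small", {
    run_gibbs(p, n_P = 60, n_R = 30, temperature = 0.68, rho0 = 0.3,
              n_equil = 1500, n_collect = 3000, sample_stride = 25, seed = 61)
  })
  s <- run$samples
  for (box in c("I", "II")) {
    nP <- s[[paste0("n_P_", box)]]
    nR <- s[[paste0("n_R_", box)]]
    bPP <- s[[paste0("n_PP_", box)]]
    bPR <- s[[paste0("n_PR_", box)]]
    keep <- nP > 0 & nR > 0
    n_bP <- (2 * bPP[keep] + bPR[keep]) / nP[keep]
    n_bR <- bPR[keep] / nR[keep]
    n_bPP <- 2 * bPP[keep] / nP[keep]
    n_bPR <- bPR[keep] / nP[keep]
    n_b <- 2 * (bPP[keep] + bPR[keep]) / (nP[keep] + nR[keep])
    # population-weighted average of the species means (densities share the
    # volume, so weights reduce to counts)
    expect_equal(n_b, (nP[keep] * n_bP + nR[keep] * n_bR) /
                   (nP[keep] + nR[keep]), tolerance = 1e-12)
    expect_equal(n_bP, n_bPP + n_bPR, tolerance = 1e-12)
  }
})

test_that("bond report marks R statistics as undefined in pure P systems", {
  p <- model_params()
  run <- cached_run("pureP_small", {
    run_gibbs(p, n_P = 64, n_R = 0, temperature = 0.7, rho0 = 0.3,
              n_equil = 1000, n_collect = 2000, sample_stride = 25, seed = 67)
  })
  rep <- bond_report(run$samples, p)
  expect_true(is.na(rep$n_bR))
  expect_true(rep$n_b > 0)
  expect_equal(rep$n_b, rep$n_bP, tolerance = 1e-12)
})
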