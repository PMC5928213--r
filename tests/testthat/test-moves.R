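# Single-move semantics of the Gibbs-ensemble sampler (R-level move
# functions; the compiled run loop is exercised in test-engine.R).

make_dimer_state <- function(temperature = 0.7, r = 1.2) {
  box_I <- two_particle_config("P", "P", r = r, L = 6)
  box_II <- configuration(tibble::tibble(
    species = "P", x = 3, y = 3, z = 3, qw = 1, qx = 0, qy = 0, qz = 0),
    box_edge = 6)
  gibbs_state(box_I, box_II, temperature, model_params())
}

test_that("displacement obeys the Metropolis rule on a bonded dimer", {
  set.seed(23)
  state <- make_dimer_state(temperature = 0.7)
  expect_identical(state$energy_I, -1)

  n_break <- 0L; n_acc_break <- 0L; n_flat_acc <- 0L; n_flat <- 0L
  for (k in 1:6000) {
    res <- displacement_move(state, "I", max_translation = 0.45,
                             max_rotation = 2.5)
    if (is.finite(res$delta_U) && res$delta_U == 1) {
      n_break <- n_break + 1L
      if (res$accepted) n_acc_break <- n_acc_break + 1L
    }
    if (is.finite(res$delta_U) && res$delta_U == 0) {
      n_flat <- n_flat + 1L
      if (res$accepted) n_flat_acc <- n_flat_acc + 1L
    }
    if (!is.finite(res$delta_U)) expect_false(res$accepted)
    # state deliberately NOT updated: every attempt starts from the dimer
  }
  # zero-cost proposals always accepted
  expect_identical(n_flat_acc, n_flat)
  # bond-breaking proposals accepted at the Boltzmann rate within 3 s.e.
  p_target <- exp(-1 / 0.7)
  expect_gt(n_break, 500)
  se <- sqrt(p_target * (1 - p_target) / n_break)
  expect_lt(abs(n_acc_break / n_break - p_target), 3 * se)
})

test_that("moves reject hard-core overlaps outright", {
  set.seed(29)
  state <- make_dimer_state(r = 1.02)
  saw_overlap <- FALSE
  for (k in 1:300) {
    res <- displacement_move(state, "I", max_translation = 0.3,
                             max_rotation = 1)
    if (!is.finite(res$delta_U)) {
      saw_overlap <- TRUE
      expect_false(res$accepted)
    }
    state <- res$state
    expect_true(is.finite(state$energy_I))
  }
  expect_true(saw_overlap)
})

test_that("a single ideal particle shuttles between equal boxes evenly", {
  set.seed(31)
  p <- model_params(eps_PP = 0)
  box_I <- configuration(tibble::tibble(
    species = "P", x = 1, y = 1, z = 1, qw = 1, qx = 0, qy = 0, qz = 0),
    box_edge = 4)
  box_II <- configuration(tibble::tibble(
    species = character(), x = numeric(), y = numeric(), z = numeric(),
    qw = numeric(), qx = numeric(), qy = numeric(), qz = numeric()),
    box_edge = 4)
  state <- gibbs_state(box_I, box_II, 1, p)
  occ <- logical(2000)
  for (k in seq_along(occ)) {
    state <- exchange_move(state)$state
    occ[k] <- nrow(state$box_I$particles) == 1
  }
  # symmetric volumes: long-run occupancy 1/2 (the walk decorrelates every
  # accepted transfer, so binomial s.e. is conservative here)
  expect_lt(abs(mean(occ) - 0.5), 3 * sqrt(0.25 / length(occ)))
})

test_that("volume moves conserve the total volume and accept null proposals", {
  set.seed(37)
  state <- make_dimer_state()
  v_tot <- state$box_I$box_edge^3 + state$box_II$box_edge^3
  # a vanishing log-volume perturbation is an identity move
  res <- volume_move(state, max_ln_volume_change = 1e-14)
  expect_true(res$accepted)
  expect_equal(res$delta_U, 0)

  for (k in 1:150) {
    res <- volume_move(state, max_ln_volume_change = 0.3)
    state <- res$state
    expect_equal(state$box_I$box_edge^3 + state$box_II$box_edge^3, v_tot,
                 tolerance = 1e-12)
    expect_true(is.finite(state$energy_I) && is.finite(state$energy_II))
  }
})

test_that("move sequences keep the cached energies exact", {
  set.seed(41)
  p <- model_params(eps_PR = 0.5)
  box_I <- random_configuration(10, 5, 4, p)
  box_II <- random_configuration(10, 5, 4, p)
  state <- gibbs_state(box_I, box_II, 0.8, p)
  for (k in 1:200) {
    mv <- sample(c("d", "e", "v"), 1, prob = c(0.5, 0.4, 0.1))
    state <- switch(mv,
      d = displacement_move(state, sample(c("I", "II"), 1),
                            max_translation = 0.2, max_rotation = 0.5)$state,
      e = exchange_move(state)$state,
      v = volume_move(state, 0.05)$state)
  }
  expect_identical(state$energy_I, total_energy(state$box_I, p))
  expect_identical(state$energy_II, total_energy(state$box_II, p))
  tot <- state$totals
  expect_identical(sum(state$box_I$particles$species == "P") +
                     sum(state$box_II$particles$species == "P"),
                   as.integer(tot[["n_P"]]))
  expect_equal(state$box_I$box_edge^3 + state$box_II$box_edge^3,
               tot[["v_total"]], tolerance = 1e-10)
})
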