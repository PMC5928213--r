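# Phase labeling, binodal assembly and critical-point fitting.

test_that("phase labels are per-sample, invariant to box identity swaps", {
  s <- fake_samples(n = 80, nP_I = 20, nP_II = 150, seed = 2)
  # swap box identities in the second half of the stream
  half <- 41:80
  swapped <- s
  cols_I <- grep("_I$", names(s), value = TRUE)
  for (ci in cols_I) {
    cii <- sub("_I$", "_II", ci)
    swapped[half, c(ci, cii)] <- s[half, c(cii, ci)]
  }
  b1 <- binodal_point(s, 0.7)
  b2 <- binodal_point(swapped, 0.7)
  expect_equal(b1$rho_P_I, b2$rho_P_I, tolerance = 1e-12)
  expect_equal(b1$rho_P_II, b2$rho_P_II, tolerance = 1e-12)
  expect_true(b1$coexistence)
})

test_that("statistically identical boxes raise the no-coexistence signal", {
  s <- fake_samples(n = 80, nP_I = 85, nP_II = 85, noise = 4, seed = 3)
  expect_warning(b <- binodal_point(s, 0.85), "no coexistence")
  expect_false(b$coexistence)
})

test_that("noiseless synthetic binodals round-trip the generating law", {
  truth <- list(T_c = 0.75, rho_c = 0.30, A = -0.5, B = 1.1)
  bin <- synthetic_binodal(truth$T_c, truth$rho_c, truth$A, truth$B,
                           T_grid = seq(0.65, 0.74, by = 0.01))
  fit <- fit_critical_point(bin, prune = FALSE)
  expect_equal(fit$T_c, truth$T_c, tolerance = 1e-6)
  expect_equal(fit$rho_P_c, truth$rho_c, tolerance = 1e-6)
  expect_equal(fit$A, truth$A, tolerance = 1e-5)
  expect_equal(fit$B, truth$B, tolerance = 1e-5)
  # broom accessors expose the same estimates
  td <- tidy(fit)
  expect_identical(td$term, c("T_c", "rho_P_c", "A", "B"))
  expect_equal(td$estimate[1], fit$T_c)
  gl <- glance(fit)
  expect_identical(gl$exponent, 0.32)
})

test_that("pruning keeps the fit stable and records its trace", {
  bin <- synthetic_binodal(0.75, 0.30, -0.5, 1.1,
                           T_grid = seq(0.60, 0.74, by = 0.01))
  fit <- fit_critical_point(bin)
  expect_true(fit$converged)
  expect_gte(length(fit$included_temperatures), 4)
  expect_equal(fit$T_c, 0.75, tolerance = 1e-4)
  expect_true(all(diff(fit$trace$n_points) <= 0))
  expect_gt(fit$T_c, max(fit$included_temperatures))
  expect_gt(fit$B, 0)
})

test_that("fitting is robust to measurement noise across replicates", {
  errs <- vapply(1:30, function(k) {
    bin <- synthetic_binodal(0.75, 0.30, -0.5, 1.1,
                             T_grid = seq(0.63, 0.73, by = 0.01),
                             noise = 0.01, seed = 1000 + k)
    fit <- fit_critical_point(bin)
    abs(fit$T_c - 0.75)
  }, numeric(1))
  expect_lt(median(errs), 0.01)
})

test_that("degenerate width gives two identical branches", {
  bin <- synthetic_binodal(0.75, 0.30, -0.5, 0, T_grid = c(0.65, 0.7))
  expect_equal(bin$rho_P_I, bin$rho_P_II, tolerance = 1e-15)
  expect_equal(bin$rho_P_I, 0.30 - 0.5 * (bin$temperature - 0.75))
})

test_that("synthetic generation rejects grids at or above T_c", {
  expect_error(synthetic_binodal(0.75, 0.3, -0.5, 1, T_grid = c(0.7, 0.75)),
               "below T_c")
})

test_that("the critical fit demands enough coexisting points", {
  bin <- synthetic_binodal(0.75, 0.3, -0.5, 1.1, T_grid = c(0.70, 0.71, 0.72))
  expect_error(fit_critical_point(bin), "at least 4")
})

test_that("threshold ratio is unity against itself and guards its inputs", {
  s <- fake_samples(n = 60, nP_I = 25, nP_II = 140, seed = 5)
  b <- binodal_point(s, 0.7)
  r <- threshold_ratio(b, b)
  expect_equal(r$ratio, 1)
  b2 <- b; b2$temperature <- 0.68
  expect_error(threshold_ratio(b2, b), "same temperature")
  b3 <- b; b3$coexistence <- FALSE
  expect_error(threshold_ratio(b3, b), "no coexistence")
})

test_that("tie lines summarize the regulator's phase preference", {
  mk <- function(X, rR_I, rR_II) {
    s <- fake_samples(n = 60, nP_I = 25, nP_II = 140,
                      nR_I = rR_I * 320, nR_II = rR_II * 320, seed = 6)
    dplyr::mutate(binodal_point(s, 0.7), X = X)
  }
  bins <- dplyr::bind_rows(mk(0.2, 0.05, 0.01), mk(0.4, 0.02, 0.08))
  ties <- tie_lines(bins)
  expect_identical(ties$r_prefers, c("dilute", "dense"))
  expect_lt(ties$slope[1], 0)
  expect_gt(ties$slope[2], 0)
  # lever rule bookkeeping: dense arm denser than dilute arm
  expect_true(all(bins$rho_P_II > bins$rho_P_I))
})

test_that("plots build without evaluation errors", {
  bin <- synthetic_binodal(0.75, 0.3, -0.5, 1.1,
                           T_grid = seq(0.65, 0.73, by = 0.01),
                           noise = 0.005, seed = 9)
  fit <- fit_critical_point(bin, prune = FALSE)
  expect_s3_class(plot_binodal(bin), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
  ties <- dplyr::mutate(bin[1:2, ], X = c(0.1, 0.2))
  expect_s3_class(plot_tie_lines(tie_lines(ties)), "ggplot")
})
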