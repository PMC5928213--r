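# Coexistence analysis: per-sample phase labeling (the Gibbs boxes can swap
# identities over a run, so dilute/dense is assigned by total density per
# sample, never by box index), binodal points with block standard errors,
# and critical points from the law of rectilinear diameters with the 3D-Ising
# width exponent 0.32 held fixed.

CRITICAL_EXPONENT <- 0.32

# Split a samples tibble into per-sample dilute/dense records.
split_phases <- function(samples) {
  pick <- function(s, box) {
    tibble::tibble(
      cycle = s$cycle,
      n_P = s[[paste0("n_P_", box)]],
      n_R = s[[paste0("n_R_", box)]],
      volume = s[[paste0("volume_", box)]],
      energy = s[[paste0("energy_", box)]],
      n_PP = s[[paste0("n_PP_", box)]],
      n_PR = s[[paste0("n_PR_", box)]],
      n_RR = s[[paste0("n_RR_", box)]],
      rho_P = s[[paste0("rho_P_", box)]],
      rho_R = s[[paste0("rho_R_", box)]]
    )
  }
  a <- pick(samples, "I")
  b <- pick(samples, "II")
  dense_is_b <- (b$rho_P + b$rho_R) >= (a$rho_P + a$rho_R)
  swap <- function(lo, hi, cols = names(lo)) {
    out <- lo
    for (cc in cols) out[[cc]] <- ifelse(dense_is_b, lo[[cc]], hi[[cc]])
    out
  }
  list(dilute = swap(a, b), dense = swap(b, a))
}

#' Label the dilute and dense phases of a sample stream
#'
#' Per sample, the box with the lower total particle density is phase I
#' (dilute) and the other phase II (dense); averaged quantities are computed
#' after this labeling so that box-identity swaps during a run do not mix
#' the phases. Samples whose density gap falls below twice the pooled block
#' standard error are flagged as near-critical/unseparated.
#'
#' @param samples Samples tibble from [run_gibbs()].
#' @return Tibble with one row per sample: `cycle`, dilute-phase densities
#'   `rho_P_I`, `rho_R_I`, `rho_I`, dense-phase `rho_P_II`, `rho_R_II`,
#'   `rho_II`, and `separated` (logical flag).
#' @export
label_phases <- function(samples) {
  lab <- split_phases(samples)
  rho_I <- lab$dilute$rho_P + lab$dilute$rho_R
  rho_II <- lab$dense$rho_P + lab$dense$rho_R
  # near-critical flag: a sample is "separated" when the density gap exceeds
  # twice the pooled per-sample spread of the two labeled streams
  pooled_sd <- sqrt(sd(rho_I)^2 + sd(rho_II)^2)
  gap <- rho_II - rho_I
  sep <- if (is.na(pooled_sd)) rep(NA, length(gap)) else gap >= 2 * pooled_sd
  tibble::tibble(
    cycle = samples$cycle,
    rho_P_I = lab$dilute$rho_P, rho_R_I = lab$dilute$rho_R, rho_I = rho_I,
    rho_P_II = lab$dense$rho_P, rho_R_II = lab$dense$rho_R, rho_II = rho_II,
    separated = sep
  )
}

#' Coexistence densities at one temperature
#'
#' Averages the per-sample labeled phases into one binodal point with block
#' standard errors. If more than half of the samples are flagged as
#' unseparated the point is marked `coexistence = FALSE` (near- or
#' super-critical state point) and a warning is raised.
#'
#' @param samples Samples tibble from [run_gibbs()].
#' @param temperature Reduced temperature of the run.
#' @param n_blocks Blocks for the standard errors.
#' @return One-row tibble: `temperature`, `rho_P_I`, `rho_P_II`, `rho_R_I`,
#'   `rho_R_II` (with `*_se`), `rho_I`, `rho_II`, `coexistence`,
#'   `n_samples`.
#' @export
binodal_point <- function(samples, temperature, n_blocks = 10) {
  lab <- label_phases(samples)
  frac_bad <- mean(!lab$separated, na.rm = TRUE)
  coex <- !is.na(frac_bad) && frac_bad <= 0.5
  if (!coex) {
    warning("no coexistence at T = ", temperature,
            ": density gap below noise in ", round(100 * frac_bad),
            "% of samples")
  }
  out <- tibble::tibble(
    temperature = temperature,
    rho_P_I = mean(lab$rho_P_I), rho_P_I_se = block_se(lab$rho_P_I, n_blocks),
    rho_P_II = mean(lab$rho_P_II), rho_P_II_se = block_se(lab$rho_P_II, n_blocks),
    rho_R_I = mean(lab$rho_R_I), rho_R_I_se = block_se(lab$rho_R_I, n_blocks),
    rho_R_II = mean(lab$rho_R_II), rho_R_II_se = block_se(lab$rho_R_II, n_blocks),
    rho_I = mean(lab$rho_I), rho_II = mean(lab$rho_II),
    coexistence = coex,
    n_samples = nrow(lab)
  )
  out
}

# One joint fit at fixed point set: width law rho_II - rho_I = B (Tc - T)^0.32
# by nonlinear least squares with multistart over Tc, then the rectilinear
# diameter (rho_I + rho_II)/2 = rho_c + A (T - Tc) by linear regression.
fit_rectilinear_once <- function(tt, rI, rII, weights = NULL) {
  w <- rII - rI
  tmax <- max(tt)
  best <- NULL
  for (dT in c(0.005, 0.01, 0.02, 0.04, 0.08, 0.15)) {
    tc0 <- tmax + dT
    b0 <- stats::median(w / (tc0 - tt)^CRITICAL_EXPONENT)
    args <- list(
      w ~ B * (Tc - tt)^CRITICAL_EXPONENT,
      start = list(Tc = tc0, B = b0),
      lower = c(Tc = tmax + 1e-8, B = 1e-10),
      upper = c(Tc = tmax + 0.5, B = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (!is.null(weights)) args$weights <- weights
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-14) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    stop("critical-point width fit failed to converge for every start value")
  }
  cf <- coef(best$fit)
  tc <- unname(cf["Tc"]); b <- unname(cf["B"])
  dia <- lm(I((rI + rII) / 2) ~ I(tt - tc), weights = weights)
  list(T_c = tc, B = b,
       rho_P_c = unname(coef(dia)[1]), A = unname(coef(dia)[2]))
}

#' Fit the critical point of a binodal
#'
#' Simultaneous description of a binodal by the law of rectilinear diameters:
#' the phase-gap width follows `rho_P_II - rho_P_I = B * (T_c - T)^0.32`
#' (exponent fixed, never fitted) and the diameter follows
#' `(rho_P_I + rho_P_II)/2 = rho_P_c + A * (T - T_c)`. The width law is fit
#' first by nonlinear least squares with multistart over `T_c`, then the
#' diameter by linear regression at the fitted `T_c`.
#'
#' Points nearest the critical temperature are pruned iteratively (drop the
#' highest-T point, refit) until the fitted `T_c` moves by less than
#' `delta_tc_tol` between successive fits or `min_points` points remain; the
#' last fit is returned together with the pruning trace.
#'
#' @param binodal Tibble of binodal points (rows from [binodal_point()]):
#'   needs `temperature`, `rho_P_I`, `rho_P_II`; rows with
#'   `coexistence = FALSE` are dropped.
#' @param prune Apply the pruning loop (default TRUE).
#' @param delta_tc_tol Stability threshold on `|delta T_c|` between
#'   successive prunes.
#' @param min_points Minimum number of retained points.
#' @param weighted Weight points by `1 / rho_P_II_se^2` when available.
#' @return An object of class `critical_fit` with fields `T_c`, `rho_P_c`,
#'   `A`, `B`, `included_temperatures`, `trace` (tibble), `converged`,
#'   `exponent`, and the input `binodal`. Supports [tidy()], [glance()] and
#'   `ggplot2::autoplot()`.
#' @export
fit_critical_point <- function(binodal, prune = TRUE, delta_tc_tol = 0.002,
                               min_points = 4, weighted = FALSE) {
  b <- binodal
  if ("coexistence" %in% names(b)) b <- b[b$coexistence %in% TRUE, ]
  b <- b[order(b$temperature), ]
  if (nrow(b) < min_points) {
    stop("need at least ", min_points, " coexisting binodal points, got ",
         nrow(b))
  }
  wts <- NULL
  if (weighted && "rho_P_II_se" %in% names(b) && all(b$rho_P_II_se > 0)) {
    wts <- 1 / b$rho_P_II_se^2
  }

  trace <- list()
  fit_set <- function(d, w) {
    fit_rectilinear_once(d$temperature, d$rho_P_I, d$rho_P_II, w)
  }
  cur <- fit_set(b, wts)
  trace[[1]] <- c(n_points = nrow(b), cur[c("T_c", "rho_P_c", "A", "B")])
  converged <- !prune
  while (prune && nrow(b) > min_points) {
    keep <- -which.max(b$temperature)
    b2 <- b[keep, ]
    w2 <- if (is.null(wts)) NULL else wts[keep]
    nxt <- fit_set(b2, w2)
    trace[[length(trace) + 1]] <-
      c(n_points = nrow(b2), nxt[c("T_c", "rho_P_c", "A", "B")])
    stable <- abs(nxt$T_c - cur$T_c) < delta_tc_tol
    b <- b2; wts <- w2; cur <- nxt
    if (stable) {
      converged <- TRUE
      break
    }
  }
  trace <- dplyr::bind_rows(lapply(trace, function(r) {
    tibble::tibble(n_points = r[["n_points"]], T_c = r[["T_c"]],
                   rho_P_c = r[["rho_P_c"]], A = r[["A"]], B = r[["B"]])
  }))
  trace$step <- seq_len(nrow(trace))

  structure(list(
    T_c = cur$T_c, rho_P_c = cur$rho_P_c, A = cur$A, B = cur$B,
    included_temperatures = b$temperature,
    trace = trace, converged = converged,
    exponent = CRITICAL_EXPONENT, binodal = binodal
  ), class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  cat("<critical_fit> law of rectilinear diameters, exponent",
      x$exponent, "\n")
  cat(sprintf("  T_c = %.4f, rho_P_c = %.4f, A = %.4f, B = %.4f\n",
              x$T_c, x$rho_P_c, x$A, x$B))
  cat(sprintf("  %d temperatures retained (%s), pruning %s\n",
              length(x$included_temperatures),
              paste(signif(x$included_temperatures, 3), collapse = ", "),
              if (x$converged) "stable" else "not converged"))
  invisible(x)
}

#' Threshold-concentration ratio of a mixture relative to the pure system
#'
#' Ratio of the dilute-arm (threshold) P concentrations,
#' `rho_P_I(reference) / rho_P_I(mixture)`, at a common temperature below
#' both critical points. Values above 1 indicate the regulator promotes
#' phase separation (lower threshold), below 1 suppression.
#'
#' @param binodal_mix One-row binodal tibble for the mixture.
#' @param binodal_ref One-row binodal tibble for the reference (pure P) run
#'   at the same temperature.
#' @return One-row tibble: `temperature`, `ratio`, `ratio_se`.
#' @export
threshold_ratio <- function(binodal_mix, binodal_ref) {
  stopifnot(nrow(binodal_mix) == 1, nrow(binodal_ref) == 1)
  if (!isTRUE(all.equal(binodal_mix$temperature, binodal_ref$temperature))) {
    stop("threshold ratio requires both runs at the same temperature")
  }
  if (!isTRUE(binodal_mix$coexistence) || !isTRUE(binodal_ref$coexistence)) {
    stop("threshold ratio undefined: one of the runs shows no coexistence")
  }
  r <- binodal_ref$rho_P_I / binodal_mix$rho_P_I
  se <- r * sqrt((binodal_ref$rho_P_I_se / binodal_ref$rho_P_I)^2 +
                 (binodal_mix$rho_P_I_se / binodal_mix$rho_P_I)^2)
  tibble::tibble(temperature = binodal_mix$temperature, ratio = r,
                 ratio_se = se)
}

#' Tie lines across a composition grid at fixed temperature
#'
#' Connects the compositions `(rho_P_I, rho_R_I)` and `(rho_P_II, rho_R_II)`
#' of the coexisting phases for each regulator-to-protein ratio X. The slope
#' sign summarizes the regulator's partitioning: negative (higher R density
#' in the dilute phase) means R prefers the dilute phase, positive the dense
#' (droplet) phase.
#'
#' @param binodal Tibble of binodal points with an `X` column (one row per
#'   composition, all at the same temperature).
#' @return Tibble: `X`, endpoint densities with standard errors, `slope`,
#'   and `r_prefers` (`"dilute"` / `"dense"`).
#' @export
tie_lines <- function(binodal) {
  stopifnot("X" %in% names(binodal))
  if (any(!binodal$coexistence)) {
    stop("no coexistence at X = ",
         paste(binodal$X[!binodal$coexistence], collapse = ", "))
  }
  binodal |>
    dplyr::transmute(
      .data$X, .data$temperature,
      .data$rho_P_I, .data$rho_P_I_se, .data$rho_R_I, .data$rho_R_I_se,
      .data$rho_P_II, .data$rho_P_II_se, .data$rho_R_II, .data$rho_R_II_se,
      slope = (.data$rho_R_II - .data$rho_R_I) /
        (.data$rho_P_II - .data$rho_P_I),
      r_prefers = ifelse(.data$rho_R_II >= .data$rho_R_I, "dense", "dilute")
    )
}
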