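# broom-style accessors for fitted and simulated objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a critical-point fit
#'
#' @param x A `critical_fit` from [fit_critical_point()].
#' @param ... Unused.
#' @return Tibble with one row per fitted parameter (`T_c`, `rho_P_c`,
#'   `A`, `B`) and columns `term`, `estimate`.
#' @export
tidy.critical_fit <- function(x, ...) {
  tibble::tibble(
    term = c("T_c", "rho_P_c", "A", "B"),
    estimate = c(x$T_c, x$rho_P_c, x$A, x$B)
  )
}

#' One-row summary of a critical-point fit
#'
#' @inheritParams tidy.critical_fit
#' @return One-row tibble: estimates, the fixed width exponent, the number
#'   of retained temperatures, pruning steps and convergence flag.
#' @export
glance.critical_fit <- function(x, ...) {
  tibble::tibble(
    T_c = x$T_c, rho_P_c = x$rho_P_c, A = x$A, B = x$B,
    exponent = x$exponent,
    n_points = length(x$included_temperatures),
    n_pruned = nrow(x$trace) - 1L,
    converged = x$converged
  )
}

#' Tidy a Gibbs-ensemble run
#'
#' @param x A `gibbs_run` from [run_gibbs()].
#' @param ... Unused.
#' @return The samples tibble (one row per collected sample).
#' @export
tidy.gibbs_run <- function(x, ...) x$samples

#' One-row summary of a Gibbs-ensemble run
#'
#' @inheritParams tidy.gibbs_run
#' @return One-row tibble: state point, sample count and per-move acceptance
#'   rates.
#' @export
glance.gibbs_run <- function(x, ...) {
  acc <- setNames(x$acceptance$rate, paste0("acc_", x$acceptance$move))
  tibble::tibble(
    temperature = x$inputs$temperature,
    n_P = x$inputs$n_P, n_R = x$inputs$n_R,
    X = if (x$inputs$n_P > 0) x$inputs$n_R / x$inputs$n_P else NA_real_,
    rho0 = x$inputs$rho0,
    n_samples = nrow(x$samples),
    !!!as.list(acc)
  )
}
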