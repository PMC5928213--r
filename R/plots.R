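# ggplot2 figures for binodals, critical fits, tie lines and run traces.

#' Plot a binodal
#'
#' Coexistence P densities against temperature: the dilute arm
#' (`rho_P_I`) and dense arm (`rho_P_II`) with error bars when present.
#'
#' @param binodal Tibble of [binodal_point()] rows.
#' @return A ggplot object.
#' @export
plot_binodal <- function(binodal) {
  long <- tidyr::pivot_longer(binodal, c("rho_P_I", "rho_P_II"),
                              names_to = "arm", values_to = "rho")
  long$se <- ifelse(long$arm == "rho_P_I", binodal$rho_P_I_se[
    match(long$temperature, binodal$temperature)],
    binodal$rho_P_II_se[match(long$temperature, binodal$temperature)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rho, y = .data$temperature)) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$rho - .data$se, xmax = .data$rho + .data$se),
      height = 0, na.rm = TRUE) +
    ggplot2::labs(x = expression(rho[P] * sigma^3), y = "T") +
    ggplot2::theme_classic()
}

#' Plot a critical-point fit over its binodal
#'
#' The binodal points, the fitted coexistence curve from the
#' rectilinear-diameter and width laws, and the fitted critical point.
#'
#' @param object A `critical_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.critical_fit <- function(object, ...) {
  b <- object$binodal
  tt <- seq(min(b$temperature), object$T_c, length.out = 120)
  mid <- object$rho_P_c + object$A * (tt - object$T_c)
  w <- object$B * (object$T_c - tt)^object$exponent
  curve <- tibble::tibble(
    temperature = c(tt, rev(tt)),
    rho = c(mid - w / 2, rev(mid + w / 2))
  )
  plot_binodal(b) +
    ggplot2::geom_path(data = curve,
                       ggplot2::aes(x = .data$rho, y = .data$temperature),
                       linewidth = 0.4) +
    ggplot2::annotate("point", x = object$rho_P_c, y = object$T_c,
                      shape = 16, size = 2.5) +
    ggplot2::labs(subtitle = sprintf("T_c = %.3f, rho_c = %.3f",
                                     object$T_c, object$rho_P_c))
}

#' Plot tie lines in the composition plane
#'
#' Segments connecting the coexisting compositions `(rho_P, rho_R)` of the
#' two phases for each regulator-to-protein ratio X.
#'
#' @param ties Tibble from [tie_lines()].
#' @return A ggplot object.
#' @export
plot_tie_lines <- function(ties) {
  ggplot2::ggplot(ties) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$rho_P_I, y = .data$rho_R_I,
      xend = .data$rho_P_II, yend = .data$rho_R_II), colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(x = .data$rho_P_I, y = .data$rho_R_I),
                        shape = 1) +
    ggplot2::geom_point(ggplot2::aes(x = .data$rho_P_II, y = .data$rho_R_II),
                        shape = 16) +
    ggplot2::labs(x = expression(rho[P] * sigma^3),
                  y = expression(rho[R] * sigma^3)) +
    ggplot2::theme_classic()
}

#' Plot the density trace of a Gibbs-ensemble run
#'
#' Per-sample total density of both boxes over the collection stage; a
#' phase-separated run shows two well-separated branches.
#'
#' @param object A `gibbs_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gibbs_run <- function(object, ...) {
  s <- object$samples
  long <- tibble::tibble(
    cycle = rep(s$cycle, 2),
    box = rep(c("I", "II"), each = nrow(s)),
    rho = c((s$n_P_I + s$n_R_I) / s$volume_I,
            (s$n_P_II + s$n_R_II) / s$volume_II)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$rho,
                                     colour = .data$box)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "cycle", y = expression(rho * sigma^3),
                  colour = "box") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
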