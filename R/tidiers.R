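#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.guinier_result <- function(x, ...) {
  tibble::tibble(term = c("Rg", "I0"),
                 estimate = c(x$Rg, x$I0),
                 std.error = c(x$sigma_Rg, x$sigma_I0))
}

#' @export
glance.guinier_result <- function(x, ...) {
  tibble::tibble(Rg = x$Rg, sigma_Rg = x$sigma_Rg, I0 = x$I0,
                 sigma_I0 = x$sigma_I0, qmin_Rg = x$qmin_Rg,
                 qmax_Rg = x$qmax_Rg, window_start = x$window[1],
                 window_end = x$window[2], quality = x$quality,
                 r_squared = x$r_squared, aggregated = x$aggregated,
                 valid = x$valid, method = x$method)
}

#' @export
tidy.pddf <- function(x, ...) tibble::tibble(r = x$r, p = x$p)

#' @export
glance.pddf <- function(x, ...) {
  tibble::tibble(Dmax = x$Dmax, alpha = x$alpha, Rg = x$Rg_real,
                 I0 = x$I0_real, chi2_reduced = x$chi2_reduced,
                 log_evidence = x$log_evidence, status = x$status)
}

#' @export
tidy.cormap_outcome <- function(x, ...) {
  tibble::tibble(n = x$n, C = x$C, p_value = x$p_value, log_p = x$log_p,
                 equivalent = x$equivalent)
}

#' @export
glance.sas_invariants <- function(x, ...) {
  tibble::tibble(Q_p = x$Q_p, V_p = x$V_p, V_c = x$V_c, Q_R = x$Q_R,
                 mass_kda = x$mass_kda, mass_method = x$mass_method,
                 q_cut = x$q_cut)
}

#' @export
tidy.chromatogram <- function(x, ...) {
  total <- rowSums(x$M)
  total[!x$present] <- NA
  tibble::tibble(frame_id = x$frame_ids, total_intensity = total,
                 present = x$present)
}

#' @export
glance.fraction_result <- function(x, ...) {
  tibble::tibble(
    start = x$frame_range[1], end = x$frame_range[2], status = x$status,
    Rg = if (!is.null(x$guinier)) x$guinier$Rg else NA_real_,
    I0 = if (!is.null(x$guinier)) x$guinier$I0 else NA_real_,
    Dmax = if (!is.null(x$pddf)) x$pddf$Dmax else NA_real_,
    V_p = if (!is.null(x$invariants)) x$invariants$V_p else NA_real_,
    mass_kda = if (!is.null(x$invariants)) x$invariants$mass_kda else NA_real_)
}

#' Semi-logarithmic scattering-curve plot
#' @param object A [sas_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sas_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)[object$I > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (nm^-1)), y = "I (a.u.)") +
    ggplot2::theme_minimal()
}

#' Pair-distance distribution plot
#' @param object A `pddf`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pddf <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "r (nm)", y = "p(r)",
                  subtitle = sprintf("Dmax = %.2f nm, Rg = %.2f nm",
                                     object$Dmax, object$Rg_real)) +
    ggplot2::theme_minimal()
}

#' Total-scattering chromatogram plot
#' @param object A `chromatogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chromatogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$frame_id, y = .data$total_intensity)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "frame", y = "total scattering (a.u.)") +
    ggplot2::theme_minimal()
}

#' Guinier-fit diagnostic plot
#'
#' `ln I` against `q^2` with the fitted line and the fit window shaded.
#'
#' @param curve A [sas_curve()].
#' @param guinier A `guinier_result` for that curve.
#' @return A ggplot.
#' @export
plot_guinier <- function(curve, guinier) {
  qmax_show <- if (isTRUE(guinier$valid)) 2 * guinier$qmax_Rg / guinier$Rg else max(curve$q)
  df <- tibble::tibble(q2 = curve$q^2, lnI = log(pmax(curve$I, NA)))[curve$q <= qmax_show, ]
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q2, y = .data$lnI)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(q^2 ~ (nm^-2)), y = "ln I") +
    ggplot2::theme_minimal()
  if (isTRUE(guinier$valid)) {
    win_q2 <- curve$q[guinier$window[1]:(guinier$window[2] - 1L)]^2
    g <- g +
      ggplot2::annotate("rect", xmin = min(win_q2), xmax = max(win_q2),
                        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "seagreen") +
      ggplot2::geom_abline(intercept = log(guinier$I0),
                           slope = -guinier$Rg^2 / 3, color = "firebrick")
  }
  g
}

#' Dimensionless Kratky plot
#' @param curve A [sas_curve()].
#' @param guinier A `guinier_result`.
#' @return A ggplot.
#' @export
plot_kratky <- function(curve, guinier) {
  kr <- kratky_dimensionless(curve, guinier)
  ggplot2::ggplot(kr, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = sqrt(3), linetype = 3) +
    ggplot2::geom_hline(yintercept = 3 / exp(1), linetype = 3) +
    ggplot2::labs(x = expression(q * R[g]), y = expression((q * R[g])^2 * I / I[0])) +
    ggplot2::theme_minimal()
}

#' Four-panel SAS report
#'
#' The standard at-a-glance figure: log I(q) with the Guinier window and
#' the IFT back-transform overlaid, the Guinier diagnostic, the
#' dimensionless Kratky plot, and p(r).
#'
#' @param curve A [sas_curve()].
#' @param guinier A `guinier_result` (computed if missing).
#' @param pddf A `pddf` (computed if missing and the curve has sigma).
#' @return A list of four ggplots (classes combine them with e.g.
#'   patchwork); printed together when patchwork is installed.
#' @export
plot_sas_report <- function(curve, guinier = NULL, pddf = NULL) {
  if (is.null(guinier)) guinier <- auto_guinier(curve)
  if (is.null(pddf) && has_sigma(curve)) {
    pddf <- tryCatch(bift_auto(curve), error = function(e) NULL)
  }
  p1 <- autoplot.sas_curve(curve)
  if (!is.null(pddf)) {
    fit <- design_matrix(curve$q, pddf$r) %*% pddf$p
    p1 <- p1 + ggplot2::geom_line(
      data = tibble::tibble(q = curve$q, I = as.vector(fit)),
      ggplot2::aes(x = .data$q, y = .data$I), color = "firebrick")
  }
  panels <- list(curve = p1, guinier = plot_guinier(curve, guinier),
                 kratky = plot_kratky(curve, guinier),
                 pddf = if (!is.null(pddf)) autoplot.pddf(pddf) else NULL)
  panels[!vapply(panels, is.null, logical(1))]
}
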