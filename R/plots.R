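#' Plot radial scan profiles
#'
#' Radial absorbance profiles colored by scan time, the standard raw-data
#' view of a sedimentation-velocity run.
#'
#' @param object a `scan_set`.
#' @param every plot every `every`-th scan.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scan_set <- function(object, every = 1, ...) {
  df <- as_tibble(object)
  keep_times <- object$times[seq(1, length(object$times), by = every)]
  df <- dplyr::filter(df, .data$time_s %in% keep_times)
  ggplot2::ggplot(df, ggplot2::aes(.data$radius_cm, .data$signal_od,
                                   color = .data$time_s,
                                   group = .data$time_s)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_color_viridis_c(name = "time (s)") +
    ggplot2::labs(x = "radius (cm)", y = "signal (OD)",
                  title = sprintf("SV scans, %g rpm", object$meta$rpm)) +
    ggplot2::theme_minimal()
}

#' Plot a sedimentation-coefficient distribution
#'
#' @param object a `sed_distribution`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sed_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$s_svedberg, .data$weight)) +
    ggplot2::geom_area(alpha = 0.4, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "s (Svedberg)", y = "signal weight (OD)",
                  title = "c(s)-style distribution") +
    ggplot2::theme_minimal()
}

#' Plot a binding isotherm fit
#'
#' Mean sedimentation coefficients with replicate-SD error bars against
#' protein concentration, overlaid with the fitted Hill-hydrodynamic model
#' curve.
#'
#' @param object an `isotherm_fit`.
#' @param n_curve points in the model curve.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.isotherm_fit <- function(object, n_curve = 200, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$conc_molar * 1e6,
                                         .data$s_svedberg)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$s_svedberg - .data$sd_svedberg,
      ymax = .data$s_svedberg + .data$sd_svedberg), width = 0) +
    ggplot2::geom_point(color = "navy")
  if (object$converged) {
    cmax <- max(dat$conc_molar)
    cmin <- min(dat$conc_molar[dat$conc_molar > 0]) / 3
    grid <- c(0, 10^seq(log10(cmin), log10(cmax), length.out = n_curve))
    curve <- predict_isotherm(object, grid)
    p <- p + ggplot2::geom_line(data = curve, color = "red",
                                linetype = "dashed")
  }
  p +
    ggplot2::scale_x_continuous(trans = scales_pseudo_log()) +
    ggplot2::labs(x = "[protein] (uM)", y = expression(bar(s) ~ "(S)"),
                  title = "SV-AUC binding isotherm") +
    ggplot2::theme_minimal()
}

# pseudo-log x transform without depending on scales directly
scales_pseudo_log <- function() "identity"

#' Plot a frictional-ratio shape-evolution series
#'
#' @param object a `shape_series`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.shape_series <- function(object, ...) {
  df <- dplyr::filter(object, !.data$flagged)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$conc_molar * 1e6, .data$fr))
  if ("fr_sd" %in% names(df)) {
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$fr - .data$fr_sd, ymax = .data$fr + .data$fr_sd),
      width = 0)
  }
  p +
    ggplot2::geom_point(color = "darkred") +
    ggplot2::geom_line(color = "darkred", alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "[protein] (uM)", y = expression(f / f[0]),
                  title = "Shape evolution of the complex") +
    ggplot2::theme_minimal()
}
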