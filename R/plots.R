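#' Plot an interfacial-tension adsorption trace
#'
#' @param object An `ift_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ift_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$ift_mN_per_m)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "interfacial tension (mN/m)") +
    ggplot2::theme_minimal()
}

#' Plot an oscillatory strain/stress block
#'
#' Strain and (amplitude-normalized) stress on a common time axis, the raw
#' material of the phase-angle fit.
#'
#' @param object An `oscillation_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oscillation_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("strain_pct", "stress_Pa_m"),
    names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an amplitude sweep with its analysis landmarks
#'
#' Log-log storage/loss moduli versus strain amplitude; if an analysis is
#' supplied (or computable), the LVE plateau, yield point and flow point are
#' overlaid.
#'
#' @param object An `amplitude_sweep`.
#' @param analysis Optional one-row [analyze_sweep()] result; computed from
#'   the sweep when `TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.amplitude_sweep <- function(object, analysis = TRUE, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("gp_Pa_m", "gpp_Pa_m"),
    names_to = "modulus", values_to = "value")
  long$modulus <- factor(long$modulus, c("gp_Pa_m", "gpp_Pa_m"),
                         c("G'", "G''"))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(.data$strain_pct, .data$value,
                                    colour = .data$modulus)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "strain amplitude (%)",
                  y = "interfacial modulus (Pa·m)", colour = NULL) +
    ggplot2::theme_minimal()
  if (isTRUE(analysis)) analysis <- analyze_sweep(object)
  if (is.data.frame(analysis)) {
    if (isTRUE(analysis$yield_detected)) {
      p <- p + ggplot2::geom_vline(xintercept = analysis$gamma_y,
                                   linetype = "dashed", colour = "grey40")
    }
    if (isTRUE(analysis$flow_detected)) {
      p <- p + ggplot2::geom_vline(xintercept = analysis$gamma_f,
                                   linetype = "dotted", colour = "grey40")
    }
    p <- p + ggplot2::geom_hline(yintercept = analysis$gp_lve,
                                 linetype = "dotdash", colour = "grey70")
  }
  p
}

#' Plot a buildup (time-test) curve
#'
#' @param object A `buildup_curve` from [time_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.buildup_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("gp_Pa_m", "gpp_Pa_m"),
    names_to = "modulus", values_to = "value")
  long$modulus <- factor(long$modulus, c("gp_Pa_m", "gpp_Pa_m"),
                         c("G'", "G''"))
  ggplot2::ggplot(long, ggplot2::aes(.data$timestamp_s, .data$value,
                                     colour = .data$modulus)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "interfacial modulus (Pa·m)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a diameter concentration/intensity profile
#'
#' @param object A `diameter_profile`.
#' @param ref_conc Optional reference level (g/L) drawn when the profile is
#'   calibrated.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diameter_profile <- function(object, ref_conc = 0.5, ...) {
  unit <- attr(object, "value_unit", exact = TRUE) %||% "intensity"
  ylab <- if (unit == "g_per_L") "concentration (g/L)" else "intensity (counts)"
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$position_um, .data$value)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "position along diameter (µm)", y = ylab) +
    ggplot2::theme_minimal()
  if (unit == "g_per_L" && is.numeric(ref_conc)) {
    p <- p + ggplot2::geom_hline(yintercept = ref_conc, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot a droplet image as a raster
#'
#' @param object A [droplet_image()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.droplet_image <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$intensity)),
                    col = seq_len(ncol(object$intensity)))
  df$intensity <- as.vector(object$intensity)
  df$x_um <- (df$col - 1) * object$pixel_size_um
  df$y_um <- (df$row - 1) * object$pixel_size_um
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "µm", y = "µm", fill = "counts") +
    ggplot2::theme_minimal()
}
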