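#' Fit a fluorescence intensity-to-concentration calibration curve
#'
#' Ordinary least-squares line through calibration standards of known enzyme
#' concentration: `intensity = gain * conc + offset`. The gain must come out
#' positive for the curve to be usable.
#'
#' @param standards A data frame with columns `conc_g_per_L` and `intensity`
#'   (e.g. from [gen_calibration_standards()]); at least 2 distinct
#'   concentrations.
#' @return A `conc_calibration` object: `gain` (counts per g/L), `offset`
#'   (counts), `r_squared`, `n`. [tidy()] and [glance()] methods are
#'   available.
#' @examples
#' calibrate(gen_calibration_standards(gain = 850, noise_sd = 5, seed = 2))
#' @export
calibrate <- function(standards) {
  if (!all(c("conc_g_per_L", "intensity") %in% names(standards))) {
    stop_pickering("`standards` must have columns `conc_g_per_L` and `intensity`.",
                   "pickering_error_argument")
  }
  conc <- standards$conc_g_per_L
  intensity <- standards$intensity
  if (length(unique(conc)) < 2) {
    stop_pickering("Degenerate calibration: need at least 2 distinct concentrations.",
                   "pickering_error_degenerate_calibration")
  }
  fit <- lm(intensity ~ conc)
  # noise-free standards fit exactly; summary.lm warns about that
  fit_summary <- suppressWarnings(summary(fit))
  gain <- unname(coef(fit)[2])
  if (!is.finite(gain) || gain <= 0) {
    stop_pickering(
      sprintf("Unusable calibration curve: fitted gain = %.4g is not positive.", gain),
      "pickering_error_unusable_calibration"
    )
  }
  structure(
    list(gain = gain, offset = unname(coef(fit)[1]),
         r_squared = fit_summary$r.squared,
         gain_se = fit_summary$coefficients[2, 2],
         n = length(conc)),
    class = "conc_calibration"
  )
}

#' @export
print.conc_calibration <- function(x, ...) {
  cat(sprintf(
    "<conc_calibration> intensity = %.4g * conc + %.4g  (R^2 = %.4f, n = %d)\n",
    x$gain, x$offset, x$r_squared, x$n))
  invisible(x)
}

#' Convert an intensity profile to concentration units
#'
#' Inverts the calibration line, `conc = (intensity - offset) / gain`, and
#' clips negative concentrations to zero (recording the clipped fraction).
#'
#' @param profile A `diameter_profile` from [average_profile()] (or any data
#'   frame with `position_um` and `value` columns in intensity units).
#' @param curve A `conc_calibration` from [calibrate()].
#' @return The profile with `value` in g/L, attribute
#'   `value_unit = "g_per_L"` and attribute `clip_fraction` (fraction of
#'   positions whose pre-clip concentration was negative).
#' @export
to_concentration <- function(profile, curve) {
  if (!inherits(curve, "conc_calibration")) {
    stop_pickering("`curve` must be a `conc_calibration` from calibrate().",
                   "pickering_error_argument")
  }
  if (!all(c("position_um", "value") %in% names(profile))) {
    stop_pickering("`profile` must have columns `position_um` and `value`.",
                   "pickering_error_argument")
  }
  conc <- (profile$value - curve$offset) / curve$gain
  clip_fraction <- mean(conc < 0)
  profile$value <- pmax(conc, 0)
  attr(profile, "value_unit") <- "g_per_L"
  attr(profile, "clip_fraction") <- clip_fraction
  if (!inherits(profile, "diameter_profile")) {
    class(profile) <- c("diameter_profile", class(profile))
  }
  profile
}

# Sub-sample refinement of a sampled peak: vertex of the parabola through
# the maximum sample and its two neighbours. Counteracts the attenuation of
# a smooth maximum by 1-pixel sampling. Falls back to the sample when the
# parabola is degenerate or the vertex leaves the bracketing interval.
.refine_peak <- function(pos, val, i) {
  out <- list(pos = pos[i], val = val[i])
  if (i <= 1L || i >= length(val)) return(out)
  y <- val[(i - 1):(i + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom >= 0) return(out)
  d <- 0.5 * (y[1] - y[3]) / denom
  if (abs(d) > 1) return(out)
  step <- pos[i + 1] - pos[i]
  list(pos = pos[i] + d * step, val = y[2] - 0.25 * (y[1] - y[3]) * d)
}

# Linear-interpolated crossings of `level` between consecutive samples,
# returned as positions. Includes exact touches.
.level_crossings <- function(pos, val, level) {
  d <- val - level
  out <- pos[d == 0]
  s <- d[-length(d)] * d[-1]
  idx <- which(s < 0)
  if (length(idx) > 0) {
    f <- d[idx] / (d[idx] - d[idx + 1])
    out <- c(out, pos[idx] + f * (pos[idx + 1] - pos[idx]))
  }
  sort(unique(out))
}

# Thickness of one interfacial peak: distance between the outermost
# ref-level crossings on either side of the peak position, searched within
# the half-profile. NA when a side never drops below the level.
.side_thickness <- function(pos, val, peak_pos, peak_val, level) {
  if (peak_val < level) return(NA_real_)
  if (peak_val == level) return(0)
  cross <- .level_crossings(pos, val, level)
  lower <- cross[cross < peak_pos]
  upper <- cross[cross > peak_pos]
  if (length(lower) == 0 || length(upper) == 0) return(NA_real_)
  # outermost crossings bounding the peak region
  max(upper) - min(lower)
}

#' Measure droplet metrics from a calibrated diameter profile
#'
#' Extracts the per-droplet quantities of the high-resolution image
#' analysis from the representative concentration profile across the
#' droplet:
#' \itemize{
#'   \item \strong{diameter} — distance between the two interfacial
#'     concentration maxima (one per side of the centre);
#'   \item \strong{interface concentration} — mean of the two peak values;
#'   \item \strong{interface thickness} — width of each peak at the fixed
#'     `ref_conc` level (outermost level crossings around the peak, linear
#'     interpolation between samples), averaged over the two sides;
#'   \item \strong{bulk concentration} — mean over the `bulk_window_px`
#'     samples nearest the droplet centre.
#' }
#' The reference level is an absolute calibrated concentration (the initial
#' enzyme concentration of the preparation, 0.5 g/L by default), not a
#' relative half-max width.
#'
#' @param profile A calibrated `diameter_profile` (value unit g/L), see
#'   [to_concentration()].
#' @param ref_conc Concentration level defining the interface thickness, g/L.
#' @param bulk_window_px Number of central samples averaged for the bulk
#'   concentration.
#' @param refine_peaks Refine each side's peak position and height by the
#'   vertex of a parabola through the maximum sample and its neighbours
#'   (standard sub-sample peak interpolation; compensates the attenuation of
#'   a smooth maximum by pixel-step sampling). The boundary checks and level
#'   crossings always use the sampled profile.
#' @return A one-row `droplet_metrics` tibble: `diameter_um`,
#'   `interface_conc_g_per_L`, `interface_thickness_um`,
#'   `bulk_conc_g_per_L`, side-resolved peak positions and thicknesses, and
#'   quality flags (`thickness_flagged` when a side's thickness is undefined
#'   or zero at the level boundary).
#' @export
measure_droplet <- function(profile, ref_conc = 0.5, bulk_window_px = 10,
                            refine_peaks = TRUE) {
  check_number(ref_conc, "ref_conc", lower = 0, strict_lower = TRUE)
  unit <- attr(profile, "value_unit", exact = TRUE)
  if (is.null(unit) || unit != "g_per_L") {
    stop_pickering("`profile` must be calibrated to g/L first (see to_concentration()).",
                   "pickering_error_uncalibrated")
  }
  pos <- profile$position_um
  val <- profile$value
  ok <- is.finite(val)
  pos <- pos[ok]
  val <- val[ok]

  bulk_idx <- order(abs(pos), pos)[seq_len(min(bulk_window_px, length(pos)))]
  bulk <- mean(val[bulk_idx])

  sides <- list(left = pos < 0, right = pos > 0)
  peaks <- purrr::map(sides, function(m) {
    if (!any(m)) return(NULL)
    i_side <- which.max(val[m])
    refined <- if (refine_peaks) {
      .refine_peak(pos[m], val[m], i_side)
    } else {
      list(pos = pos[m][i_side], val = val[m][i_side])
    }
    # sampled maximum retained for the boundary/qualification logic
    list(pos = pos[m][i_side], val = val[m][i_side],
         pos_refined = refined$pos, val_refined = refined$val)
  })
  qualifying <- vapply(peaks, function(p) {
    !is.null(p) && p$val >= ref_conc && p$val > bulk
  }, logical(1))
  if (sum(qualifying) < 2) {
    stop_pickering(
      sprintf("No resolvable interface: fewer than two side peaks reach the %.3g g/L level above the bulk.",
              ref_conc),
      "pickering_error_no_interface"
    )
  }

  th <- purrr::map2_dbl(peaks, sides, function(p, m) {
    .side_thickness(pos[m], val[m], p$pos, p$val, ref_conc)
  })
  thickness_flagged <- any(is.na(th)) || any(th == 0, na.rm = TRUE)

  out <- tibble(
    diameter_um = peaks$right$pos_refined - peaks$left$pos_refined,
    interface_conc_g_per_L = (peaks$left$val_refined +
                                peaks$right$val_refined) / 2,
    interface_thickness_um = mean(th, na.rm = TRUE),
    bulk_conc_g_per_L = bulk,
    peak_pos_left_um = peaks$left$pos_refined,
    peak_pos_right_um = peaks$right$pos_refined,
    thickness_left_um = th[["left"]],
    thickness_right_um = th[["right"]],
    thickness_flagged = thickness_flagged,
    clip_fraction = attr(profile, "clip_fraction", exact = TRUE) %||% 0
  )
  class(out) <- c("droplet_metrics", class(out))
  out
}

#' Analyze one droplet image end to end
#'
#' Convenience pipeline: [detect_center()], [extract_profiles()] (1°
#' increments), [average_profile()], [to_concentration()],
#' [measure_droplet()].
#'
#' @param image A [droplet_image()].
#' @param curve A `conc_calibration` from [calibrate()].
#' @inheritParams measure_droplet
#' @inheritParams extract_profiles
#' @inheritParams detect_center
#' @return A one-row `droplet_metrics` tibble (see [measure_droplet()]).
#' @examples
#' \donttest{
#' curve <- calibrate(gen_calibration_standards(gain = 1000))
#' gen_droplet_image(seed = 1) |> analyze_droplet_image(curve)
#' }
#' @export
analyze_droplet_image <- function(image, curve, n_angles = 360,
                                  ref_conc = 0.5, bulk_window_px = 10,
                                  refine = FALSE) {
  center <- detect_center(image, refine = refine)
  image |>
    extract_profiles(center = center, n_angles = n_angles) |>
    average_profile() |>
    to_concentration(curve) |>
    measure_droplet(ref_conc = ref_conc, bulk_window_px = bulk_window_px)
}

#' Summarize per-droplet metrics over an emulsion
#'
#' Mean and sample standard deviation of each droplet metric over the
#' analyzed droplets, the shape in which high-resolution image analyses of
#' emulsions are reported. Droplets with undefined (NA) core metrics are
#' excluded and logged.
#'
#' @param metrics A data frame of per-droplet rows, as returned by
#'   [measure_droplet()] / [analyze_droplet_image()] (rows may be bound
#'   together with `dplyr::bind_rows()`).
#' @return An `emulsion_summary` tibble: `metric`, `mean`, `sd`, `n`, with
#'   attribute `excluded` (row indices of excluded droplets). With a single
#'   droplet the SD is reported as 0 and flagged via the `n` column.
#' @export
summarize_emulsion <- function(metrics) {
  core <- c("diameter_um", "interface_conc_g_per_L",
            "interface_thickness_um", "bulk_conc_g_per_L")
  if (!all(core %in% names(metrics))) {
    stop_pickering(sprintf("`metrics` must contain columns %s.",
                           paste0("`", core, "`", collapse = ", ")),
                   "pickering_error_argument")
  }
  if (nrow(metrics) == 0) {
    stop_pickering("`metrics` is empty: no droplets to summarize.",
                   "pickering_error_argument")
  }
  keep <- stats::complete.cases(metrics[core])
  excluded <- which(!keep)
  kept <- metrics[keep, core]
  if (nrow(kept) == 0) {
    stop_pickering("All droplets were excluded (NA core metrics).",
                   "pickering_error_argument")
  }
  out <- kept |>
    tidyr::pivot_longer(dplyr::all_of(core), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, core))
  attr(out, "excluded") <- excluded
  class(out) <- c("emulsion_summary", class(out))
  out
}
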