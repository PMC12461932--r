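#' Tidy a harmonic oscillation fit
#'
#' @param x A `harmonic_fit` from [fit_harmonic()].
#' @param ... Unused.
#' @return A one-row tibble: `gamma_A_pct`, `tau_A_Pa_m`, `delta_deg`,
#'   `physical`, `omega_rad_per_s`.
#' @export
tidy.harmonic_fit <- function(x, ...) {
  tibble(gamma_A_pct = x$gamma_A_pct, tau_A_Pa_m = x$tau_A,
         delta_deg = x$delta_deg, physical = x$physical,
         omega_rad_per_s = x$omega)
}

#' Fit quality of a harmonic oscillation fit
#'
#' @inheritParams tidy.harmonic_fit
#' @return A one-row tibble: `harmonic_fraction`, `strain_offset`,
#'   `stress_offset`, `n`.
#' @export
glance.harmonic_fit <- function(x, ...) {
  tibble(harmonic_fraction = x$harmonic_fraction,
         strain_offset = x$strain_offset, stress_offset = x$stress_offset,
         n = x$n)
}

#' Tidy a calibration curve
#'
#' @param x A `conc_calibration` from [calibrate()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`offset`, `gain`).
#' @export
tidy.conc_calibration <- function(x, ...) {
  tibble(term = c("offset", "gain"),
         estimate = c(x$offset, x$gain),
         std.error = c(NA_real_, x$gain_se))
}

#' Fit quality of a calibration curve
#'
#' @inheritParams tidy.conc_calibration
#' @return A one-row tibble: `r.squared`, `n`.
#' @export
glance.conc_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n)
}
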