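#' Generate a synthetic interfacial-tension adsorption trace
#'
#' Produces a pendant-drop style interfacial tension (IFT) time series with a
#' bi-exponential decay from `ift0` to the plateau `ift_inf`: an initial rapid
#' drop (time constant `tau_fast`) followed by a slower decline (`tau_slow`),
#' the phenomenology of protein adsorption at an oil/water interface. The
#' kinetic form is phenomenological, not a thermodynamic adsorption model.
#'
#' @param ift0 Initial interfacial tension, mN/m.
#' @param ift_inf Plateau interfacial tension, mN/m. Must satisfy
#'   `ift0 >= ift_inf >= 0`.
#' @param tau_fast,tau_slow Fast and slow decay time constants, s
#'   (`tau_fast < tau_slow`).
#' @param weight_fast Fraction (0-1) of the total decay carried by the fast
#'   mode.
#' @param duration Trace length, s.
#' @param dt Sampling interval, s.
#' @param noise_sd Gaussian noise standard deviation, mN/m.
#' @param seed Integer seed; identical seeds reproduce the trace exactly.
#' @param ift_ref Reference clean-interface tension IFT_o/w, mN/m, stored as
#'   metadata for surface-pressure computation. Defaults to `ift0`.
#' @param pH,phase Metadata describing the condition.
#'
#' @return An `ift_trace` tibble with columns `time_s`, `ift_mN_per_m`,
#'   attributes `ift_ref`, `pH`, `phase`, and the [ground_truth()] record.
#' @examples
#' tr <- gen_ift_trace(ift0 = 8.1, ift_inf = 5.2, seed = 1)
#' head(tr)
#' ground_truth(tr)$ift_inf
#' @export
gen_ift_trace <- function(ift0 = 8.1, ift_inf = 5.0,
                          tau_fast = 60, tau_slow = 1200,
                          weight_fast = 0.6,
                          duration = 7000, dt = 10,
                          noise_sd = 0.02, seed = NULL,
                          ift_ref = ift0, pH = 7, phase = "octanol/buffer") {
  check_number(ift_inf, "ift_inf", lower = 0)
  check_number(ift0, "ift0", lower = ift_inf)
  check_number(tau_fast, "tau_fast", lower = 0, strict_lower = TRUE)
  check_number(tau_slow, "tau_slow", lower = tau_fast, strict_lower = TRUE)
  check_number(weight_fast, "weight_fast", lower = 0, upper = 1)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)

  time_s <- seq(0, duration, by = dt)
  decay <- weight_fast * exp(-time_s / tau_fast) +
    (1 - weight_fast) * exp(-time_s / tau_slow)
  ift <- ift_inf + (ift0 - ift_inf) * decay
  ift <- ift + with_seed_or_current(seed, rnorm(length(time_s), 0, noise_sd))

  gt <- list(ift0 = ift0, ift_inf = ift_inf, tau_fast = tau_fast,
             tau_slow = tau_slow, weight_fast = weight_fast,
             duration = duration, dt = dt, noise_sd = noise_sd,
             ift_ref = ift_ref, seed = seed)
  new_trace(tibble(time_s = time_s, ift_mN_per_m = ift),
            "ift_trace", ground_truth = gt,
            ift_ref = ift_ref, pH = pH, phase = phase)
}

#' Generate a synthetic oscillatory interfacial shear trace
#'
#' Simulates one block of an oscillatory interfacial shear test: a driven
#' strain \eqn{\gamma(t) = \gamma_A \sin(\omega t)} and the stress response
#' \eqn{\tau(t) = \tau_A \sin(\omega t + \delta)} with phase angle
#' \eqn{\delta}. The stress amplitude is `modulus_magnitude` times the strain
#' amplitude expressed as a dimensionless fraction, so the interfacial complex
#' modulus magnitude \eqn{|G_i^*|} of the synthetic interface is exactly
#' `modulus_magnitude`.
#'
#' Strain is user-facing in percent; internally it is converted to a fraction
#' before any modulus arithmetic.
#'
#' @param gamma_A Strain amplitude, percent.
#' @param omega Angular drive frequency, rad/s.
#' @param delta Phase angle between stress and strain, degrees, in [0, 90].
#' @param modulus_magnitude Complex interfacial modulus magnitude, Pa·m.
#' @param duration Trace length, s.
#' @param sample_rate Sampling rate, Hz. At least 4 samples per period are
#'   required.
#' @param noise_sd Gaussian noise on the stress, as a fraction of the stress
#'   amplitude.
#' @param seed Integer seed.
#' @param timestamp Optional experiment-time label, s (used by [time_test()]).
#'
#' @return An `oscillation_trace` tibble with columns `time_s`, `strain_pct`,
#'   `stress_Pa_m`, attribute `omega` and the [ground_truth()] record.
#' @examples
#' tr <- gen_oscillation_trace(delta = 30, noise_sd = 0, seed = 1)
#' fit_harmonic(tr)$delta_deg
#' @export
gen_oscillation_trace <- function(gamma_A = 0.1, omega = 1, delta = 0,
                                  modulus_magnitude = 0.01,
                                  duration = 10 * 2 * pi / omega,
                                  sample_rate = 100 * omega / (2 * pi),
                                  noise_sd = 0, seed = NULL,
                                  timestamp = NA_real_) {
  check_number(gamma_A, "gamma_A", lower = 0, strict_lower = TRUE)
  check_number(omega, "omega", lower = 0, strict_lower = TRUE)
  check_number(delta, "delta", lower = 0, upper = 90)
  check_number(modulus_magnitude, "modulus_magnitude", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  period <- 2 * pi / omega
  if (sample_rate * period < 4) {
    stop_pickering(
      sprintf("Undersampled trace: %.3g samples per period (need at least 4).",
              sample_rate * period),
      "pickering_error_undersampled"
    )
  }

  time_s <- seq(0, duration, by = 1 / sample_rate)
  strain_pct <- gamma_A * sin(omega * time_s)
  tau_A <- modulus_magnitude * gamma_A / 100
  stress <- tau_A * sin(omega * time_s + deg2rad(delta))
  stress <- stress +
    with_seed_or_current(seed, rnorm(length(time_s), 0, noise_sd * tau_A))

  gt <- list(gamma_A = gamma_A, omega = omega, delta = delta,
             modulus_magnitude = modulus_magnitude, tau_A = tau_A,
             duration = duration, sample_rate = sample_rate,
             noise_sd = noise_sd, seed = seed, timestamp = timestamp)
  new_trace(tibble(time_s = time_s, strain_pct = strain_pct,
                   stress_Pa_m = stress),
            "oscillation_trace", ground_truth = gt,
            omega = omega, timestamp = timestamp)
}

# Smooth log-logistic decay used for both moduli in the synthetic sweep:
# f(g) = 1 / (1 + (g / scale)^m), flat for g << scale.
.sweep_decay <- function(gamma, scale, m) 1 / (1 + (gamma / scale)^m)

#' Generate a synthetic interfacial amplitude sweep
#'
#' Builds a strain amplitude sweep (log-spaced strains, typically
#' 0.01-100 %) for a gel-like interfacial layer: the storage modulus
#' \eqn{G_i'} holds a linear-viscoelastic (LVE) plateau `gp_lve` up to the
#' yield strain `gamma_y` and then decays smoothly in log-strain; the loss
#' modulus \eqn{G_i''} decays more weakly, and its decay scale is solved so
#' that the \eqn{G_i' = G_i''} crossing (the flow point) falls exactly at
#' `gamma_f`.
#'
#' Both moduli follow log-logistic decays \eqn{1/(1+(\gamma/\gamma_c)^m)}.
#' The storage-modulus scale is fixed by requiring
#' \eqn{G_i'(\gamma_y) = 0.95\,G_{LVE}'} (the conventional 5 % departure
#' criterion for the yield point); the loss-modulus scale by the flow-point
#' constraint.
#'
#' @param gp_lve,gpp_lve LVE-plateau storage and loss moduli, Pa·m
#'   (`gp_lve > gpp_lve` for a gel-like interface).
#' @param gamma_y Yield strain, percent (5 % departure of G' from the plateau).
#' @param gamma_f Flow strain, percent, where G' = G''; must exceed `gamma_y`
#'   and lie inside the strain grid.
#' @param strain_grid Strain amplitudes, percent, strictly increasing
#'   (default 10 points/decade over 0.01-100 %).
#' @param m_gp,m_gpp Log-logistic decay exponents for G' and G''
#'   (`m_gpp < m_gp` gives the weaker G'' decay).
#' @param noise_sd Multiplicative Gaussian noise fraction applied to both
#'   moduli.
#' @param seed Integer seed.
#'
#' @return An `amplitude_sweep` tibble with columns `strain_pct`, `gp_Pa_m`,
#'   `gpp_Pa_m` and the [ground_truth()] record.
#' @examples
#' sw <- gen_amplitude_sweep(gamma_f = 13.9, seed = 1, noise_sd = 0)
#' flow_point(sw)$gamma_f
#' @export
gen_amplitude_sweep <- function(gp_lve = 0.02, gpp_lve = 0.004,
                                gamma_y = 1.65, gamma_f = 13.9,
                                strain_grid = 10^seq(-2, 2, by = 0.1),
                                m_gp = 4, m_gpp = 1.5,
                                noise_sd = 0, seed = NULL) {
  check_number(gpp_lve, "gpp_lve", lower = 0, strict_lower = TRUE)
  check_number(gp_lve, "gp_lve", lower = gpp_lve, strict_lower = TRUE)
  check_number(gamma_y, "gamma_y", lower = 0.01)
  check_number(gamma_f, "gamma_f", lower = gamma_y, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.numeric(strain_grid) || length(strain_grid) < 3 ||
      any(diff(strain_grid) <= 0)) {
    stop_pickering("`strain_grid` must be a strictly increasing numeric vector.",
                   "pickering_error_argument")
  }
  if (gamma_f < min(strain_grid) || gamma_f > max(strain_grid)) {
    stop_pickering("`gamma_f` lies outside the strain grid.",
                   "pickering_error_argument")
  }

  # G' scale from the 5% yield criterion: decay(gamma_y) = 0.95.
  scale_gp <- gamma_y * (1 / 0.95 - 1)^(-1 / m_gp)
  gp_at_f <- gp_lve * .sweep_decay(gamma_f, scale_gp, m_gp)
  if (gp_at_f >= gpp_lve) {
    stop_pickering(
      "No G'=G'' crossing is constructible: G' at `gamma_f` still exceeds `gpp_lve`; increase `gamma_f` or the gp/gpp contrast.",
      "pickering_error_argument"
    )
  }
  # G'' scale from the crossing constraint: gpp(gamma_f) = gp(gamma_f).
  scale_gpp <- gamma_f * (gpp_lve / gp_at_f - 1)^(-1 / m_gpp)

  gp <- gp_lve * .sweep_decay(strain_grid, scale_gp, m_gp)
  gpp <- gpp_lve * .sweep_decay(strain_grid, scale_gpp, m_gpp)
  if (noise_sd > 0) {
    fac <- with_seed_or_current(
      seed, rnorm(2 * length(strain_grid), 1, noise_sd))
    gp <- gp * fac[seq_along(strain_grid)]
    gpp <- gpp * fac[-seq_along(strain_grid)]
  }

  gt <- list(gp_lve = gp_lve, gpp_lve = gpp_lve, gamma_y = gamma_y,
             gamma_f = gamma_f, m_gp = m_gp, m_gpp = m_gpp,
             scale_gp = scale_gp, scale_gpp = scale_gpp,
             noise_sd = noise_sd, seed = seed)
  new_trace(tibble(strain_pct = strain_grid, gp_Pa_m = gp, gpp_Pa_m = gpp),
            "amplitude_sweep", ground_truth = gt, omega = 1)
}

#' Generate synthetic fluorescence calibration standards
#'
#' Simulates imaging of dye-labelled enzyme solutions of known concentration:
#' mean fluorescence intensity is linear in concentration,
#' `intensity = gain * conc + offset`, with additive Gaussian noise.
#'
#' @param concs Concentrations of the standards, g/L; at least 2 distinct
#'   values.
#' @param gain Intensity counts per g/L.
#' @param offset Intensity at zero concentration (detector background).
#' @param noise_sd Gaussian noise standard deviation, intensity counts.
#' @param seed Integer seed.
#'
#' @return A `calibration_standards` tibble with columns `conc_g_per_L`,
#'   `intensity`, and the [ground_truth()] record.
#' @examples
#' std <- gen_calibration_standards(concs = seq(0, 2, by = 0.25), seed = 1)
#' calibrate(std)
#' @export
gen_calibration_standards <- function(concs = seq(0, 2, by = 0.25),
                                      gain = 1000, offset = 0,
                                      noise_sd = 0, seed = NULL) {
  if (!is.numeric(concs) || length(unique(concs)) < 2 || any(concs < 0)) {
    stop_pickering("`concs` must contain at least 2 distinct nonnegative concentrations.",
                   "pickering_error_argument")
  }
  check_number(gain, "gain", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)

  intensity <- gain * concs + offset +
    with_seed_or_current(seed, rnorm(length(concs), 0, noise_sd))
  gt <- list(concs = concs, gain = gain, offset = offset,
             noise_sd = noise_sd, seed = seed)
  new_trace(tibble(conc_g_per_L = concs, intensity = intensity),
            "calibration_standards", ground_truth = gt)
}
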