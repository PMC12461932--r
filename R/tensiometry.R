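#' Surface pressure from interfacial tension
#'
#' The surface pressure is the reduction of the interfacial tension relative
#' to the clean (enzyme- and particle-free) oil/water interface,
#' \eqn{\Pi = IFT_{o/w} - IFT}. Negative values are reported as-is — weakly
#' or non-adsorbing stabilizers produce pressures that fluctuate around
#' zero — never clipped.
#'
#' @param ift Measured interfacial tension, mN/m (vectorized).
#' @param ift_ref Reference clean-interface tension IFT_o/w, mN/m.
#' @return Surface pressure, mN/m.
#' @examples
#' surface_pressure(5.1, 8.1)
#' @export
surface_pressure <- function(ift, ift_ref) {
  if (!is.numeric(ift) || !is.numeric(ift_ref) ||
      any(!is.finite(ift)) || any(!is.finite(ift_ref))) {
    stop_pickering("`ift` and `ift_ref` must be finite numbers.",
                   "pickering_error_argument")
  }
  ift_ref - ift
}

#' Detect steady state of an interfacial tension trace
#'
#' Applies the trailing-window steady-state criterion used in pendant-drop
#' adsorption experiments: the least-squares slope of the interfacial tension
#' over the final `window` seconds (by default the last 3 min) must be below
#' `slope_threshold` in magnitude (default 0.005 mN/m per minute) for the
#' plateau to count as reached. The plateau tension is the mean over that
#' window, and the surface pressure is computed against the trace's
#' reference tension.
#'
#' @param trace An `ift_trace` (see [gen_ift_trace()], [read_trace()]), or any
#'   data frame with columns `time_s` and `ift_mN_per_m`.
#' @param window Trailing window length, s.
#' @param slope_threshold Plateau slope threshold, mN/m per minute (strict
#'   `<` comparison on the absolute slope).
#' @param ift_ref Reference tension, mN/m; defaults to the trace's `ift_ref`
#'   attribute.
#' @return A one-row tibble: `plateau_ift` (mN/m), `plateau_slope`
#'   (mN/m per min), `plateau_reached`, `pi` (surface pressure, mN/m),
#'   `negative_pi` flag, `window_s`, `n_window`.
#' @examples
#' tr <- gen_ift_trace(noise_sd = 0, seed = 1)
#' steady_state(tr)
#' @export
steady_state <- function(trace, window = 180, slope_threshold = 0.005,
                         ift_ref = NULL) {
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  check_number(slope_threshold, "slope_threshold", lower = 0,
               strict_lower = TRUE)
  time <- trace$time_s
  ift <- trace$ift_mN_per_m
  if (is.null(time) || is.null(ift)) {
    stop_pickering("`trace` must have columns `time_s` and `ift_mN_per_m`.",
                   "pickering_error_argument")
  }
  if (any(diff(time) <= 0)) {
    stop_pickering("`time_s` must be strictly increasing.",
                   "pickering_error_argument")
  }
  span <- time[length(time)] - time[1]
  if (span < window) {
    stop_pickering(
      sprintf("Insufficient duration: trace spans %.4g s but the steady-state window is %.4g s.",
              span, window),
      "pickering_error_duration"
    )
  }
  ift_ref <- ift_ref %||% attr(trace, "ift_ref", exact = TRUE)
  if (is.null(ift_ref)) {
    stop_pickering("No reference tension: supply `ift_ref` or use a trace with an `ift_ref` attribute.",
                   "pickering_error_argument")
  }

  keep <- time >= time[length(time)] - window
  slope_per_min <- ls_slope(time[keep], ift[keep]) * 60
  plateau_ift <- mean(ift[keep])
  pi_val <- surface_pressure(plateau_ift, ift_ref)
  if (pi_val < 0) {
    warn("Negative surface pressure: plateau tension exceeds the reference; reporting it unclipped.",
         class = "pickering_warning_negative_pi")
  }
  tibble(
    plateau_ift = plateau_ift,
    plateau_slope = slope_per_min,
    plateau_reached = abs(slope_per_min) < slope_threshold,
    pi = pi_val,
    negative_pi = pi_val < 0,
    window_s = window,
    n_window = sum(keep)
  )
}

#' Adsorption cooperativity factor
#'
#' Quantifies how much the presence of particles at the interface influences
#' enzyme adsorption, by comparing individual and simultaneous adsorption
#' surface pressures:
#' \deqn{\alpha = (\Pi_{sim} - \Pi_{particle}) / \Pi_{enzyme}}
#' \eqn{\alpha = 1} indicates that enzyme and particles adsorb independently
#' (additive pressures); \eqn{\alpha < 1} indicates interaction — the
#' interface is partially blocked by the particles.
#'
#' @param pi_sim Surface pressure under simultaneous enzyme + particle
#'   adsorption, mN/m.
#' @param pi_particle Surface pressure of particle adsorption alone, mN/m.
#' @param pi_enzyme Surface pressure of enzyme adsorption alone, mN/m;
#'   must be positive for \eqn{\alpha} to be defined.
#' @return A one-row tibble: `alpha`, `pi_sim`, `pi_particle`, `pi_enzyme`.
#' @examples
#' cooperativity(pi_sim = 6, pi_particle = 2, pi_enzyme = 4) # independent
#' @export
cooperativity <- function(pi_sim, pi_particle, pi_enzyme) {
  check_number(pi_sim, "pi_sim")
  check_number(pi_particle, "pi_particle")
  if (!is.numeric(pi_enzyme) || length(pi_enzyme) != 1L ||
      !is.finite(pi_enzyme) || pi_enzyme <= 0) {
    stop_pickering(
      "Undefined cooperativity: `pi_enzyme` must be a positive surface pressure.",
      "pickering_error_undefined_cooperativity"
    )
  }
  tibble(
    alpha = (pi_sim - pi_particle) / pi_enzyme,
    pi_sim = pi_sim, pi_particle = pi_particle, pi_enzyme = pi_enzyme
  )
}

#' Particle desorption energy at a liquid/liquid interface
#'
#' Energy required to detach a spherical particle of radius `r` from an
#' oil/water interface of tension `ift_ow`:
#' \deqn{E = \pi r^2 \, IFT_{o/w} \, (1 - s\cos\theta)^2}
#' where \eqn{\theta} is the three-phase contact angle and
#' \eqn{s \in \{+1, -1\}} selects the phase into which the particle is
#' removed (the two conventional signs of the detachment-energy expression;
#' \eqn{s = +1} removes the particle into the phase it wets less). For
#' submicron particles at typical oil/water tensions this energy is many
#' thousands of \eqn{k_B T}, which is why adsorbed nanoparticles are regarded
#' as irreversibly attached.
#'
#' @param r Particle radius, metres.
#' @param ift_ow Interfacial tension, N/m (SI: 8.1 mN/m is `8.1e-3`).
#' @param theta Three-phase contact angle, degrees, in [0, 180].
#' @param sign Detachment direction, `+1` or `-1`.
#' @return Desorption energy, joules.
#' @examples
#' desorption_energy(r = 15e-9, ift_ow = 8.1e-3, theta = 107.5)
#' @export
desorption_energy <- function(r, ift_ow, theta, sign = +1) {
  check_number(r, "r", lower = 0)
  check_number(ift_ow, "ift_ow", lower = 0, strict_lower = TRUE)
  check_number(theta, "theta", lower = 0, upper = 180)
  if (!sign %in% c(-1, 1)) {
    stop_pickering("`sign` must be +1 or -1.", "pickering_error_argument")
  }
  pi * r^2 * ift_ow * (1 - sign * cos(deg2rad(theta)))^2
}
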