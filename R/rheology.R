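#' Extract amplitude and phase from an oscillatory shear trace
#'
#' Fits both channels of an oscillatory interfacial shear block — the driven
#' strain \eqn{\gamma(t) = \gamma_A \sin(\omega t)} and the stress response
#' \eqn{\tau(t) = \tau_A \sin(\omega t + \delta)} — by linear least squares
#' on the basis \eqn{\{\sin\omega t, \cos\omega t, 1\}} at the known drive
#' frequency. Amplitudes come from the quadrature components and the phase
#' angle \eqn{\delta} is the stress phase minus the strain phase, reported in
#' degrees and wrapped to [0, 180). A purely elastic interface gives
#' \eqn{\delta = 0}, a purely viscous one \eqn{\delta = 90}; values beyond
#' 90 are flagged unphysical. The fit is insensitive to constant offsets on
#' either channel.
#'
#' @param trace An `oscillation_trace` (see [gen_oscillation_trace()],
#'   [read_trace()]) or a data frame with columns `time_s`, `strain_pct`,
#'   `stress_Pa_m`.
#' @param omega Angular drive frequency, rad/s; defaults to the trace's
#'   `omega` attribute.
#' @param min_harmonic_fraction If the harmonic fit explains less than this
#'   fraction of the stress variance, a "not a harmonic response" warning is
#'   raised.
#' @return A `harmonic_fit` object: `gamma_A_pct` (strain amplitude, %),
#'   `tau_A` (stress amplitude, Pa·m), `delta_deg`, `physical`,
#'   `omega`, `harmonic_fraction`, `n`, plus channel offsets. Use [tidy()]
#'   for a one-row tibble.
#' @examples
#' tr <- gen_oscillation_trace(delta = 37, noise_sd = 0, seed = 1)
#' tidy(fit_harmonic(tr))
#' @export
fit_harmonic <- function(trace, omega = NULL,
                         min_harmonic_fraction = 0.5) {
  omega <- omega %||% attr(trace, "omega", exact = TRUE)
  if (is.null(omega)) {
    stop_pickering("Drive frequency unknown: supply `omega` or use a trace with an `omega` attribute.",
                   "pickering_error_argument")
  }
  t <- trace$time_s
  if (is.null(t) || is.null(trace$strain_pct) || is.null(trace$stress_Pa_m)) {
    stop_pickering("`trace` must have columns `time_s`, `strain_pct`, `stress_Pa_m`.",
                   "pickering_error_argument")
  }
  if (any(diff(t) <= 0)) {
    stop_pickering("`time_s` must be strictly increasing.",
                   "pickering_error_argument")
  }
  period <- 2 * pi / omega
  if (t[length(t)] - t[1] < 2 * period) {
    stop_pickering("Trace must span at least 2 full periods at the drive frequency.",
                   "pickering_error_duration")
  }

  basis <- cbind(sin(omega * t), cos(omega * t), 1)
  project <- function(y) {
    cf <- stats::lm.fit(basis, y)$coefficients
    list(amp = sqrt(cf[1]^2 + cf[2]^2),
         phase = atan2(cf[2], cf[1]),
         offset = cf[3])
  }
  fs <- project(trace$strain_pct)
  ft <- project(trace$stress_Pa_m)

  # fraction of (offset-removed) stress variance carried by the harmonic
  resid <- trace$stress_Pa_m - basis %*%
    c(ft$amp * cos(ft$phase), ft$amp * sin(ft$phase), ft$offset)
  tot <- sum((trace$stress_Pa_m - mean(trace$stress_Pa_m))^2)
  harmonic_fraction <- if (tot > 0) 1 - sum(resid^2) / tot else 1
  if (harmonic_fraction < min_harmonic_fraction) {
    warn(sprintf(
      "Not a harmonic response: the fit at omega = %g rad/s explains only %.1f%% of the stress variance.",
      omega, 100 * harmonic_fraction),
      class = "pickering_warning_not_harmonic")
  }

  delta_deg <- rad2deg(ft$phase - fs$phase) %% 360
  if (delta_deg >= 180) delta_deg <- delta_deg - 180
  structure(
    list(gamma_A_pct = unname(fs$amp), tau_A = unname(ft$amp),
         delta_deg = unname(delta_deg),
         physical = delta_deg <= 90 + 1e-9,
         omega = omega, harmonic_fraction = harmonic_fraction,
         strain_offset = unname(fs$offset), stress_offset = unname(ft$offset),
         n = length(t)),
    class = "harmonic_fit"
  )
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf(
    "<harmonic_fit> gamma_A = %.4g %%, tau_A = %.4g Pa·m, delta = %.4g deg (%s), omega = %g rad/s\n",
    x$gamma_A_pct, x$tau_A, x$delta_deg,
    if (x$physical) "physical" else "unphysical", x$omega))
  invisible(x)
}

#' Interfacial storage and loss moduli from amplitude ratio and phase
#'
#' Resolves the interfacial complex shear modulus into its elastic and
#' viscous parts,
#' \deqn{G_i' = (\tau_A / \gamma_A)\cos\delta, \qquad
#'       G_i'' = (\tau_A / \gamma_A)\sin\delta,}
#' with the strain amplitude converted from percent to a dimensionless
#' fraction. By construction \eqn{G_i'^2 + G_i''^2 = (\tau_A/\gamma_A)^2}.
#'
#' @param gamma_A Strain amplitude, percent (> 0), or a `harmonic_fit`
#'   object from [fit_harmonic()] (in which case the remaining arguments are
#'   taken from the fit).
#' @param tau_A Stress amplitude, Pa·m.
#' @param delta Phase angle, degrees.
#' @return A one-row tibble: `gp_Pa_m`, `gpp_Pa_m`, `delta_deg`,
#'   `gamma_A_pct`, `tau_A_Pa_m`.
#' @examples
#' moduli(gamma_A = 0.1, tau_A = 2e-5, delta = 45)
#' @export
moduli <- function(gamma_A, tau_A = NULL, delta = NULL) {
  if (inherits(gamma_A, "harmonic_fit")) {
    fit <- gamma_A
    gamma_A <- fit$gamma_A_pct
    tau_A <- fit$tau_A
    delta <- fit$delta_deg
  }
  check_number(gamma_A, "gamma_A", lower = 0, strict_lower = TRUE)
  check_number(tau_A, "tau_A", lower = 0)
  check_number(delta, "delta")
  ratio <- tau_A / (gamma_A / 100)
  tibble(
    gp_Pa_m = ratio * cos(deg2rad(delta)),
    gpp_Pa_m = ratio * sin(deg2rad(delta)),
    delta_deg = delta,
    gamma_A_pct = gamma_A,
    tau_A_Pa_m = tau_A
  )
}

#' Interfacial layer buildup from a sequence of oscillation blocks
#'
#' Monitors the formation of the interfacial layer over time (a "time test"):
#' each oscillation block, recorded at constant strain amplitude and drive
#' frequency, is reduced to one storage/loss modulus point via
#' [fit_harmonic()] and [moduli()], ordered by experiment time.
#'
#' @param traces A list of `oscillation_trace` objects sharing the drive
#'   frequency and strain amplitude, each carrying a `timestamp` attribute
#'   (s); or a list of such data frames plus `timestamps`.
#' @param timestamps Optional numeric vector of experiment times, s,
#'   overriding the traces' own timestamps.
#' @param amplitude_tol Maximum relative spread of fitted strain amplitudes
#'   before the blocks are declared inconsistent.
#' @return A `buildup_curve` tibble, one row per block: `timestamp_s`,
#'   `gp_Pa_m`, `gpp_Pa_m`, `delta_deg`, `gamma_A_pct`, `tau_A_Pa_m`.
#' @seealso [saturation_time()] for the trailing-slope saturation detector.
#' @export
time_test <- function(traces, timestamps = NULL, amplitude_tol = 0.02) {
  if (!is.list(traces) || length(traces) == 0) {
    stop_pickering("`traces` must be a nonempty list of oscillation traces.",
                   "pickering_error_argument")
  }
  timestamps <- timestamps %||% vapply(
    traces, function(tr) {
      ts <- attr(tr, "timestamp", exact = TRUE)
      if (is.null(ts)) NA_real_ else as.numeric(ts)
    }, numeric(1))
  if (anyNA(timestamps)) {
    stop_pickering("Every trace needs a timestamp (attribute or `timestamps`).",
                   "pickering_error_argument")
  }

  omegas <- vapply(traces, function(tr) {
    om <- attr(tr, "omega", exact = TRUE)
    if (is.null(om)) NA_real_ else om
  }, numeric(1))
  if (anyNA(omegas) || diff(range(omegas)) > 1e-12 * max(omegas)) {
    stop_pickering("All traces must share the same drive frequency `omega`.",
                   "pickering_error_inconsistent")
  }

  fits <- lapply(traces, fit_harmonic)
  amps <- vapply(fits, `[[`, numeric(1), "gamma_A_pct")
  rel_spread <- abs(amps - stats::median(amps)) / stats::median(amps)
  if (any(rel_spread > amplitude_tol)) {
    stop_pickering(
      sprintf("Inconsistent strain amplitudes across blocks: %s deviate by more than %.3g%% from the median.",
              paste(which(rel_spread > amplitude_tol), collapse = ", "),
              100 * amplitude_tol),
      "pickering_error_inconsistent"
    )
  }

  out <- purrr::map_dfr(fits, function(f) moduli(f))
  out <- dplyr::mutate(out, timestamp_s = timestamps, .before = 1)
  out <- dplyr::arrange(out, .data$timestamp_s)
  class(out) <- c("buildup_curve", class(out))
  out
}

#' Saturation time of a modulus buildup curve
#'
#' Applies the same trailing-window slope criterion as the tensiometric
#' steady-state test to the storage modulus of a buildup curve: the
#' saturation time is the earliest timestamp at which the least-squares
#' slope of \eqn{G_i'} over the preceding `window` seconds drops below
#' `slope_threshold` in magnitude.
#'
#' @param curve A `buildup_curve` from [time_test()] (columns `timestamp_s`,
#'   `gp_Pa_m`).
#' @param window Trailing window, s.
#' @param slope_threshold Slope threshold, Pa·m per minute.
#' @return A one-row tibble: `saturation_time_s` (NA if never saturated),
#'   `saturated`.
#' @export
saturation_time <- function(curve, window, slope_threshold) {
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  check_number(slope_threshold, "slope_threshold", lower = 0,
               strict_lower = TRUE)
  ts <- curve$timestamp_s
  gp <- curve$gp_Pa_m
  sat <- NA_real_
  for (i in seq_along(ts)) {
    keep <- ts >= ts[i] - window & ts <= ts[i]
    if (sum(keep) < 3 || ts[i] - ts[1] < window) next
    slope <- ls_slope(ts[keep], gp[keep]) * 60
    if (abs(slope) < slope_threshold) {
      sat <- ts[i]
      break
    }
  }
  tibble(saturation_time_s = sat, saturated = !is.na(sat))
}

#' Linear viscoelastic plateau of an amplitude sweep
#'
#' Mean storage modulus over the maximal leading run of sweep points whose
#' \eqn{G_i'} stays within `tolerance` (relative) of the first point — the
#' strain-independent linear viscoelastic (LVE) regime.
#'
#' @param sweep An `amplitude_sweep` (columns `strain_pct`, `gp_Pa_m`,
#'   `gpp_Pa_m`), strain strictly increasing.
#' @param tolerance Relative departure from the first point's `G'` that ends
#'   the plateau run.
#' @return A one-row tibble: `gp_lve` (Pa·m), `n_plateau` (points in the
#'   run), `single_point` flag (plateau collapsed to the first point).
#' @examples
#' sw <- gen_amplitude_sweep(gp_lve = 0.02, seed = 1)
#' lve_plateau(sw)
#' @export
lve_plateau <- function(sweep, tolerance = 0.05) {
  check_number(tolerance, "tolerance", lower = 0, strict_lower = TRUE)
  validate_sweep(sweep)
  gp <- sweep$gp_Pa_m
  if (!is.finite(gp[1]) || gp[1] <= 0) {
    stop_pickering("First sweep point has a non-positive storage modulus; no LVE plateau.",
                   "pickering_error_unphysical")
  }
  within_tol <- abs(gp - gp[1]) <= tolerance * gp[1]
  run <- which(!within_tol)
  n_run <- if (length(run) == 0) length(gp) else run[1] - 1L
  if (n_run == 1L) {
    warn("LVE plateau is a single point: the sweep decays immediately.",
         class = "pickering_warning_single_point_lve")
  }
  tibble(gp_lve = mean(gp[seq_len(n_run)]), n_plateau = n_run,
         single_point = n_run == 1L)
}

validate_sweep <- function(sweep) {
  need <- c("strain_pct", "gp_Pa_m", "gpp_Pa_m")
  if (!all(need %in% names(sweep))) {
    stop_pickering(sprintf("Sweep must have columns %s.",
                           paste0("`", need, "`", collapse = ", ")),
                   "pickering_error_argument")
  }
  if (nrow(sweep) < 3) {
    stop_pickering("Sweep needs at least 3 points.",
                   "pickering_error_argument")
  }
  if (any(diff(sweep$strain_pct) <= 0)) {
    stop_pickering("Sweep strain amplitudes must be strictly increasing.",
                   "pickering_error_argument")
  }
  invisible(sweep)
}

#' Yield point of an amplitude sweep
#'
#' Strain amplitude marking the onset of structural weakening of the
#' interfacial layer: the smallest strain at which \eqn{G_i'} has fallen by
#' `drop_fraction` (default 5 %, the common rheometric convention) below the
#' LVE plateau, refined by log-log linear interpolation between the
#' bracketing sweep points.
#'
#' @inheritParams lve_plateau
#' @param drop_fraction Relative drop of `G'` below the plateau defining
#'   yield.
#' @param tolerance Passed to [lve_plateau()].
#' @return A one-row tibble: `gamma_y` (%, NA if no yield), `yield_detected`,
#'   `gp_lve`.
#' @examples
#' sw <- gen_amplitude_sweep(gamma_y = 1.65, seed = 1)
#' yield_point(sw)
#' @export
yield_point <- function(sweep, drop_fraction = 0.05, tolerance = 0.05) {
  check_number(drop_fraction, "drop_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  validate_sweep(sweep)
  gp_lve <- lve_plateau(sweep, tolerance = tolerance)$gp_lve
  threshold <- (1 - drop_fraction) * gp_lve
  below <- which(sweep$gp_Pa_m < threshold)
  if (length(below) == 0) {
    return(tibble(gamma_y = NA_real_, yield_detected = FALSE,
                  gp_lve = gp_lve))
  }
  i <- below[1]
  gamma_y <- if (i == 1L) {
    sweep$strain_pct[1]
  } else {
    log_interp_x(sweep$strain_pct[i - 1], sweep$strain_pct[i],
                 sweep$gp_Pa_m[i - 1], sweep$gp_Pa_m[i], threshold)
  }
  tibble(gamma_y = gamma_y, yield_detected = TRUE, gp_lve = gp_lve)
}

# x where the log-log line through (x1,y1)-(x2,y2) reaches y = target
log_interp_x <- function(x1, x2, y1, y2, target) {
  lx <- log10(c(x1, x2))
  ly <- log10(c(y1, y2))
  f <- (log10(target) - ly[1]) / (ly[2] - ly[1])
  10^(lx[1] + f * (lx[2] - lx[1]))
}

#' Flow point of an amplitude sweep
#'
#' Strain amplitude of the \eqn{G_i' = G_i''} crossover — the transition of
#' the interfacial layer from gel-like to fluid behaviour. Determined as the
#' intersection of the storage and loss modulus curves by linear
#' approximation in log-log coordinates between the two bracketing sweep
#' points. If the curves cross more than once, the first crossing at which
#' \eqn{G_i'} is decreasing is taken.
#'
#' @inheritParams lve_plateau
#' @return A one-row tibble: `gamma_f` (%, NA if the curves never cross),
#'   `flow_detected`.
#' @examples
#' sw <- gen_amplitude_sweep(gamma_f = 13.9, seed = 1)
#' flow_point(sw)
#' @export
flow_point <- function(sweep) {
  validate_sweep(sweep)
  ok <- sweep$gp_Pa_m > 0 & sweep$gpp_Pa_m > 0
  d <- ifelse(ok, log10(sweep$gp_Pa_m) - log10(sweep$gpp_Pa_m), NA_real_)
  n <- length(d)
  for (i in seq_len(n - 1)) {
    if (is.na(d[i]) || is.na(d[i + 1])) next
    if (d[i] > 0 && d[i + 1] <= 0) {
      gp_decreasing <- sweep$gp_Pa_m[i + 1] < sweep$gp_Pa_m[i]
      if (!gp_decreasing) next
      lx <- log10(sweep$strain_pct[c(i, i + 1)])
      f <- d[i] / (d[i] - d[i + 1])
      return(tibble(gamma_f = 10^(lx[1] + f * (lx[2] - lx[1])),
                    flow_detected = TRUE))
    }
  }
  tibble(gamma_f = NA_real_, flow_detected = FALSE)
}

#' Full amplitude-sweep analysis
#'
#' Convenience wrapper combining [lve_plateau()], [yield_point()] and
#' [flow_point()] into one row per sweep.
#'
#' @inheritParams yield_point
#' @return A one-row `sweep_analysis` tibble: `gp_lve`, `gamma_y`, `gamma_f`
#'   and the associated flags.
#' @examples
#' gen_amplitude_sweep(seed = 1) |> analyze_sweep()
#' @export
analyze_sweep <- function(sweep, drop_fraction = 0.05, tolerance = 0.05) {
  lve <- lve_plateau(sweep, tolerance = tolerance)
  yld <- yield_point(sweep, drop_fraction = drop_fraction,
                     tolerance = tolerance)
  flw <- flow_point(sweep)
  out <- tibble(
    gp_lve = lve$gp_lve, n_plateau = lve$n_plateau,
    gamma_y = yld$gamma_y, yield_detected = yld$yield_detected,
    gamma_f = flw$gamma_f, flow_detected = flw$flow_detected
  )
  class(out) <- c("sweep_analysis", class(out))
  out
}
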