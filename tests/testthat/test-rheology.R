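test_that("harmonic fit recovers the elastic and viscous limits to machine precision", {
  el <- fit_harmonic(gen_oscillation_trace(delta = 0, noise_sd = 0))
  expect_equal(el$delta_deg, 0, tolerance = 1e-10)
  expect_true(el$physical)
  vis <- fit_harmonic(gen_oscillation_trace(delta = 90, noise_sd = 0))
  expect_equal(vis$delta_deg, 90, tolerance = 1e-10)
  expect_equal(el$gamma_A_pct, 0.1, tolerance = 1e-10)
  expect_equal(el$tau_A, 0.01 * 0.1 / 100, tolerance = 1e-10)
})

test_that("harmonic fit matches the single-bin Fourier oracle under noise", {
  tr <- gen_oscillation_trace(delta = 37, noise_sd = 0.01, seed = 5,
                              duration = 10 * 2 * pi - 2 * pi / 100)
  fit <- fit_harmonic(tr)
  strain <- dft_bin(tr$time_s, tr$strain_pct, 1)
  stress <- dft_bin(tr$time_s, tr$stress_Pa_m, 1)
  delta_oracle <- (stress$phase - strain$phase) * 180 / pi
  expect_lt(abs(fit$delta_deg - delta_oracle %% 360), 0.5)
  expect_lt(abs(fit$delta_deg - 37), 0.5)
})

test_that("harmonic fit is invariant to a constant stress offset", {
  tr <- gen_oscillation_trace(delta = 25, noise_sd = 0)
  shifted <- tr
  shifted$stress_Pa_m <- shifted$stress_Pa_m + 0.5
  f0 <- fit_harmonic(tr)
  f1 <- fit_harmonic(shifted, omega = 1)
  expect_equal(f1$delta_deg, f0$delta_deg, tolerance = 1e-9)
  expect_equal(f1$tau_A, f0$tau_A, tolerance = 1e-9)
})

test_that("harmonic fit rejects short traces and flags non-harmonic stress", {
  short <- gen_oscillation_trace(duration = 1.5 * 2 * pi, noise_sd = 0)
  expect_error(fit_harmonic(short), class = "pickering_error_duration")
  noise <- gen_oscillation_trace(delta = 0, noise_sd = 0)
  noise$stress_Pa_m <- withr::with_seed(1, rnorm(nrow(noise), 0, 1))
  expect_warning(fit_harmonic(noise),
                 class = "pickering_warning_not_harmonic")
})

test_that("moduli resolve the complex modulus with Pythagorean closure", {
  m0 <- moduli(gamma_A = 0.1, tau_A = 2e-5, delta = 0)
  expect_equal(m0$gpp_Pa_m, 0)
  expect_equal(m0$gp_Pa_m, 2e-5 / 0.001)
  m45 <- moduli(gamma_A = 0.1, tau_A = 2e-5, delta = 45)
  expect_equal(m45$gp_Pa_m, m45$gpp_Pa_m)
  m90 <- moduli(gamma_A = 0.1, tau_A = 2e-5, delta = 90)
  expect_lt(abs(m90$gp_Pa_m), 1e-12)
  for (d in c(0, 13, 45, 78, 90)) {
    m <- moduli(gamma_A = 0.25, tau_A = 3e-5, delta = d)
    expect_equal(m$gp_Pa_m^2 + m$gpp_Pa_m^2, (3e-5 / 0.0025)^2,
                 tolerance = 1e-12)
  }
  expect_error(moduli(gamma_A = 0, tau_A = 1, delta = 0),
               class = "pickering_error_argument")
})

test_that("round trip through generator, fit and moduli recovers the ground truth", {
  for (d in c(5, 37, 85)) {
    tr <- gen_oscillation_trace(delta = d, modulus_magnitude = 0.02,
                                noise_sd = 0)
    m <- moduli(fit_harmonic(tr))
    expect_equal(m$gp_Pa_m, 0.02 * cos(d * pi / 180), tolerance = 1e-7)
    expect_equal(m$gpp_Pa_m, 0.02 * sin(d * pi / 180), tolerance = 1e-7)
    expect_equal(m$gp_Pa_m^2 + m$gpp_Pa_m^2, 0.02^2, tolerance = 1e-6)
  }
})

test_that("time test reduces oscillation blocks to an ordered buildup curve", {
  mags <- c(0.005, 0.011, 0.016, 0.019, 0.02)
  traces <- lapply(seq_along(mags), function(i) {
    gen_oscillation_trace(modulus_magnitude = mags[i], delta = 20,
                          noise_sd = 0, timestamp = i * 600)
  })
  curve <- time_test(traces)
  expect_equal(curve$timestamp_s, seq_along(mags) * 600)
  expect_equal(curve$gp_Pa_m, mags * cos(20 * pi / 180), tolerance = 1e-7)
  expect_true(all(diff(curve$gp_Pa_m) > 0))
  # constant-modulus sequence gives a flat curve at ground truth
  flat <- time_test(lapply(1:3, function(i) {
    gen_oscillation_trace(modulus_magnitude = 0.01, delta = 0, noise_sd = 0,
                          timestamp = i)
  }))
  expect_equal(flat$gp_Pa_m, rep(0.01, 3), tolerance = 1e-8)
})

test_that("time test rejects blocks with inconsistent strain amplitudes", {
  traces <- list(
    gen_oscillation_trace(gamma_A = 0.1, noise_sd = 0, timestamp = 1),
    gen_oscillation_trace(gamma_A = 0.2, noise_sd = 0, timestamp = 2)
  )
  expect_error(time_test(traces), class = "pickering_error_inconsistent")
})

test_that("saturation time of an exponential buildup matches the analytic criterion", {
  g_inf <- 0.02
  tau <- 2000
  ts <- seq(300, 12000, by = 300)
  traces <- lapply(ts, function(t) {
    gen_oscillation_trace(modulus_magnitude = g_inf * (1 - exp(-t / tau)),
                          delta = 10, noise_sd = 0, timestamp = t)
  })
  curve <- time_test(traces)
  window <- 1800
  thr <- 1e-4  # Pa·m per min
  got <- saturation_time(curve, window = window, slope_threshold = thr)
  # oracle: same trailing-window criterion applied to the analytic curve
  g_true <- g_inf * (1 - exp(-ts / tau))
  sat_true <- NA_real_
  for (i in seq_along(ts)) {
    keep <- ts >= ts[i] - window & ts <= ts[i]
    if (sum(keep) < 3 || ts[i] - ts[1] < window) next
    xc <- ts[keep] - mean(ts[keep])
    slope <- sum(xc * g_true[keep]) / sum(xc^2) * 60
    if (abs(slope) < thr) { sat_true <- ts[i]; break }
  }
  expect_true(got$saturated)
  expect_lte(abs(got$saturation_time_s - sat_true), 300)
})

test_that("LVE plateau is the mean of the leading strain-independent run", {
  sweep <- tibble::tibble(
    strain_pct = 10^seq(-2, 1, by = 0.25),
    gp_Pa_m = c(rep(0.02, 6), 0.02 * 0.8^(1:7)),
    gpp_Pa_m = 0.004
  )
  lve <- lve_plateau(sweep)
  expect_equal(lve$gp_lve, 0.02)
  expect_equal(lve$n_plateau, 6)
  # generated sweep recovers its own plateau within tolerance
  sw <- gen_amplitude_sweep(gp_lve = 0.05, gpp_lve = 0.01, noise_sd = 0)
  expect_lt(abs(lve_plateau(sw)$gp_lve - 0.05) / 0.05, 0.05)
  # immediate decay collapses the plateau to a flagged single point
  drop_now <- tibble::tibble(
    strain_pct = c(0.01, 0.02, 0.04, 0.08),
    gp_Pa_m = c(0.02, 0.01, 0.005, 0.002),
    gpp_Pa_m = 0.001
  )
  expect_warning(one <- lve_plateau(drop_now),
                 class = "pickering_warning_single_point_lve")
  expect_equal(one$gp_lve, 0.02)
  expect_true(one$single_point)
})

test_that("yield point finds the 5% departure with log-log refinement", {
  sw <- gen_amplitude_sweep(gamma_y = 1.65, noise_sd = 0)
  got <- yield_point(sw)$gamma_y
  # within one log-grid step (10 points/decade) of the generating value
  expect_lt(abs(log10(got) - log10(1.65)), 0.1)
  # flat sweep: no yield flag
  flat <- tibble::tibble(strain_pct = 10^seq(-2, 0, by = 0.2),
                         gp_Pa_m = 0.02, gpp_Pa_m = 0.004)
  expect_false(yield_point(flat)$yield_detected)
  # step drop localizes at the step within grid resolution
  step <- tibble::tibble(
    strain_pct = 10^seq(-2, 1, by = 0.1),
    gp_Pa_m = ifelse(10^seq(-2, 1, by = 0.1) < 1, 0.02, 0.002),
    gpp_Pa_m = 0.001
  )
  got_step <- yield_point(step)$gamma_y
  below <- max(step$strain_pct[step$strain_pct < 1])
  expect_gte(got_step, below)
  expect_lte(got_step, 1)
})

test_that("flow point recovers constructed crossings and flags their absence", {
  for (gf in c(13.9, 10.78)) {
    sw <- gen_amplitude_sweep(gamma_f = gf, noise_sd = 0)
    got <- flow_point(sw)
    expect_true(got$flow_detected)
    expect_lt(abs(log10(got$gamma_f) - log10(gf)), 0.1)
  }
  # G' above G'' everywhere: flagged
  no_cross <- tibble::tibble(strain_pct = 10^seq(-2, 2, by = 0.2),
                             gp_Pa_m = 0.02, gpp_Pa_m = 0.004)
  expect_false(flow_point(no_cross)$flow_detected)
})

test_that("flow point is invariant to a common scaling of both moduli", {
  sw <- gen_amplitude_sweep(gamma_f = 13.9, noise_sd = 0.02, seed = 3)
  scaled <- sw
  scaled$gp_Pa_m <- scaled$gp_Pa_m * 137
  scaled$gpp_Pa_m <- scaled$gpp_Pa_m * 137
  expect_equal(flow_point(scaled)$gamma_f, flow_point(sw)$gamma_f,
               tolerance = 1e-12)
})

test_that("analyze_sweep combines the three landmarks consistently", {
  sw <- gen_amplitude_sweep(gp_lve = 0.02, gamma_y = 1.65, gamma_f = 13.9,
                            noise_sd = 0)
  res <- analyze_sweep(sw)
  expect_lte(res$gamma_y, res$gamma_f)
  expect_equal(res$gp_lve, lve_plateau(sw)$gp_lve)
  expect_equal(res$gamma_f, flow_point(sw)$gamma_f)
})
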