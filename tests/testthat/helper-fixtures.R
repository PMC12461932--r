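# Shared fixtures, all generated in code.

# Exact unit calibration: intensity = 1000 * conc, offset 0.
unit_curve <- function(gain = 1000) {
  calibrate(gen_calibration_standards(concs = c(0, 0.5, 1, 2), gain = gain,
                                      offset = 0, noise_sd = 0))
}

# Noise-free droplet image for a named preset condition.
preset_image <- function(preset = "NP+", seed = 1, ...) {
  p <- droplet_preset(preset)
  do.call(gen_droplet_image,
          c(p[c("diameter", "ring_width", "peak_conc", "bulk_conc")],
            list(seed = seed, condition = p$condition), list(...)))
}

# Single-bin discrete-Fourier phase/amplitude at the drive frequency:
# independent oracle for the least-squares harmonic fit. Assumes uniform
# sampling over an integer number of periods.
dft_bin <- function(t, y, omega) {
  z <- sum(y * exp(-1i * omega * t)) * 2 / length(y)
  list(amp = Mod(z), phase = Arg(z) + pi / 2)  # y = A sin(wt + phi)
}
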