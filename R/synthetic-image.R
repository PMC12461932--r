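#' Construct a droplet image object
#'
#' Container for a single-plane grayscale confocal image of one emulsion
#' droplet: an intensity matrix plus the physical pixel size. All imaging
#' functions in the package operate on this class.
#'
#' @param intensity Numeric matrix of nonnegative intensities (rows x cols).
#' @param pixel_size_um Physical pixel size, micrometres per pixel.
#' @param condition Optional condition label (e.g. `"NP+"`).
#' @param ground_truth Optional list of generating parameters (synthetic data).
#' @return A `droplet_image` object.
#' @export
droplet_image <- function(intensity, pixel_size_um, condition = NA_character_,
                          ground_truth = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity) || length(intensity) == 0) {
    stop_pickering("`intensity` must be a nonempty numeric matrix.",
                   "pickering_error_argument")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop_pickering("`intensity` must be finite and nonnegative.",
                   "pickering_error_argument")
  }
  check_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  structure(
    list(intensity = intensity, pixel_size_um = pixel_size_um,
         condition = condition),
    ground_truth = ground_truth,
    class = "droplet_image"
  )
}

#' @export
print.droplet_image <- function(x, ...) {
  cat(sprintf("<droplet_image> %d x %d px, %.3f um/px%s\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_um,
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  if (!is.null(ground_truth(x))) cat("  synthetic (ground truth attached)\n")
  invisible(x)
}

# Radial concentration profile of the synthetic ring: a two-sided Gaussian
# peak at radius R riding on an interior bulk plateau and exterior background.
# sigma_in / sigma_out are solved by .solve_ring_widths().
.ring_conc <- function(r, R, peak, bulk, background, sigma_in, sigma_out) {
  inner <- bulk + (peak - bulk) * exp(-((R - r) / sigma_in)^2)
  outer <- background + (peak - background) * exp(-((r - R) / sigma_out)^2)
  ifelse(r <= R, inner, outer)
}

# Solve the two Gaussian half-widths so that the full width of the peak at
# the `ref` concentration level equals `ring_width` exactly, with
# sigma_in = asymmetry * sigma_out.
.solve_ring_widths <- function(peak, bulk, background, ring_width, ref,
                               asymmetry) {
  if (peak <= ref) {
    stop_pickering(
      sprintf("Ring width at the %.3g g/L level is unreachable: peak_conc = %.3g does not exceed it.",
              ref, peak),
      "pickering_error_ring"
    )
  }
  if (bulk >= ref || background >= ref) {
    stop_pickering(
      sprintf("bulk_conc and background_conc must lie below the %.3g g/L width level.",
              ref),
      "pickering_error_ring"
    )
  }
  half_in <- sqrt(log((peak - bulk) / (ref - bulk)))
  half_out <- sqrt(log((peak - background) / (ref - background)))
  sigma_out <- ring_width / (asymmetry * half_in + half_out)
  list(sigma_in = asymmetry * sigma_out, sigma_out = sigma_out)
}

#' Generate a synthetic confocal droplet image
#'
#' Renders a single water-in-oil emulsion droplet as seen in a confocal
#' fluorescence section of dye-labelled enzyme: a bright, radially symmetric
#' but cross-sectionally asymmetric interfacial ring (the signal decays more
#' sharply on the oil-facing outer side than on the aqueous inner side), a
#' nonzero enzyme level in the droplet interior, and near-zero background in
#' the continuous oil phase. Pixel intensity is `gain` counts per g/L of the
#' underlying concentration field, with optional Gaussian or Poisson (photon
#' shot) noise.
#'
#' The ring cross-section is a two-sided Gaussian with distinct inner and
#' outer widths (`inner_outer_asymmetry` is their ratio). The widths are
#' solved in closed form so that the full width of the concentration peak at
#' the `ref_conc` level equals `ring_width` exactly and its maximum equals
#' `peak_conc`.
#'
#' @param diameter Droplet diameter (interfacial peak-to-peak), micrometres.
#' @param ring_width Full width of the interfacial peak at the `ref_conc`
#'   level, micrometres.
#' @param peak_conc Peak interfacial enzyme concentration, g/L; must exceed
#'   `ref_conc`.
#' @param bulk_conc Enzyme concentration in the droplet interior, g/L.
#' @param background_conc Apparent concentration in the oil phase, g/L.
#' @param ref_conc Concentration level at which `ring_width` is defined, g/L
#'   (the initial enzyme concentration of the emulsion preparation).
#' @param inner_outer_asymmetry Ratio of inner to outer Gaussian half-widths
#'   (> 1 means the outer decay is the sharper one).
#' @param pixel_size Pixel size, micrometres per pixel.
#' @param gain Intensity counts per g/L.
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise standard deviation, counts (ignored for the
#'   other noise models; Poisson noise is parameter-free given `gain`).
#' @param margin_um Oil-phase margin rendered beyond the ring, micrometres.
#' @param center_offset_px Numeric length-2 (row, col) subpixel offset of the
#'   droplet centre from the image midpoint.
#' @param condition Condition label stored on the image.
#' @param seed Integer seed.
#'
#' @return A [droplet_image()] whose [ground_truth()] records all generating
#'   parameters, the solved Gaussian widths and the true centre (0-based
#'   pixel coordinates).
#' @examples
#' img <- gen_droplet_image(seed = 1)
#' img
#' @export
gen_droplet_image <- function(diameter = 5.17, ring_width = 0.75,
                              peak_conc = 1.56, bulk_conc = 0.098,
                              background_conc = 0, ref_conc = 0.5,
                              inner_outer_asymmetry = 2,
                              pixel_size = 0.1, gain = 1000,
                              noise_model = c("none", "gaussian", "poisson"),
                              noise_sd = 0, margin_um = 1.5,
                              center_offset_px = c(0, 0),
                              condition = NA_character_, seed = NULL) {
  noise_model <- match.arg(noise_model)
  check_number(ring_width, "ring_width", lower = 0, strict_lower = TRUE)
  check_number(diameter, "diameter", lower = 2 * ring_width,
               strict_lower = TRUE)
  check_number(bulk_conc, "bulk_conc", lower = 0)
  check_number(peak_conc, "peak_conc", lower = bulk_conc, strict_lower = TRUE)
  check_number(background_conc, "background_conc", lower = 0)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(gain, "gain", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(inner_outer_asymmetry, "inner_outer_asymmetry",
               lower = 0, strict_lower = TRUE)

  R <- diameter / 2
  w <- .solve_ring_widths(peak_conc, bulk_conc, background_conc, ring_width,
                          ref_conc, inner_outer_asymmetry)

  half_extent_um <- R + max(margin_um, 4 * w$sigma_out)
  half_px <- ceiling(half_extent_um / pixel_size)
  n <- 2L * half_px + 1L
  center <- c(half_px, half_px) + center_offset_px  # 0-based pixel coords

  rows <- (seq_len(n) - 1) - center[1]
  cols <- (seq_len(n) - 1) - center[2]
  r_um <- sqrt(outer(rows^2, cols^2, `+`)) * pixel_size
  conc <- .ring_conc(r_um, R, peak_conc, bulk_conc, background_conc,
                     w$sigma_in, w$sigma_out)
  intensity <- gain * conc
  intensity <- with_seed_or_current(seed, switch(
    noise_model,
    none = intensity,
    gaussian = pmax(intensity + rnorm(length(intensity), 0, noise_sd), 0),
    poisson = matrix(as.numeric(rpois(length(intensity), intensity)),
                     nrow = n)
  ))
  if (!is.matrix(intensity)) intensity <- matrix(intensity, nrow = n)

  gt <- list(diameter = diameter, ring_width = ring_width,
             peak_conc = peak_conc, bulk_conc = bulk_conc,
             background_conc = background_conc, ref_conc = ref_conc,
             inner_outer_asymmetry = inner_outer_asymmetry,
             sigma_in = w$sigma_in, sigma_out = w$sigma_out,
             pixel_size = pixel_size, gain = gain,
             noise_model = noise_model, noise_sd = noise_sd,
             center_row = center[1], center_col = center[2], seed = seed)
  droplet_image(intensity, pixel_size, condition = condition,
                ground_truth = gt)
}

#' Droplet generator presets for the studied emulsion conditions
#'
#' Mean per-droplet parameters (and between-droplet standard deviations) for
#' emulsions stabilized by positively charged nanoparticles (`"NP+"`),
#' negatively charged nanoparticles (`"NP-"`), and enzyme without particles
#' (`"no-particles"`). Means follow the summary statistics of the
#' high-resolution image analysis of each condition; the droplet diameter and
#' bulk concentration of the particle-free condition are not tabulated there
#' and are set to plausible mid-range values.
#'
#' @param name Preset name: `"NP+"`, `"NP-"` or `"no-particles"`.
#' @return A list of mean generator arguments (`diameter`, `ring_width`,
#'   `peak_conc`, `bulk_conc`, `condition`) plus a `spread` list of
#'   between-droplet standard deviations.
#' @examples
#' do.call(gen_droplet_image, c(droplet_preset("NP+")[
#'   c("diameter", "ring_width", "peak_conc", "bulk_conc")], seed = 1))
#' @export
droplet_preset <- function(name = c("NP+", "NP-", "no-particles")) {
  name <- match.arg(name)
  switch(
    name,
    "NP+" = list(diameter = 5.17, ring_width = 0.75, peak_conc = 1.56,
                 bulk_conc = 0.098, condition = "NP+",
                 spread = list(diameter = 1.78, ring_width = 0.2,
                               peak_conc = 0.41, bulk_conc = 0.09)),
    "NP-" = list(diameter = 3.86, ring_width = 0.51, peak_conc = 1.2,
                 bulk_conc = 0.097, condition = "NP-",
                 spread = list(diameter = 1.23, ring_width = 0.19,
                               peak_conc = 0.35, bulk_conc = 0.09)),
    "no-particles" = list(diameter = 6, ring_width = 1.48, peak_conc = 1.27,
                          bulk_conc = 0.097, condition = "no-particles",
                          spread = list(diameter = 1.5, ring_width = 0.13,
                                        peak_conc = 0.43, bulk_conc = 0.09))
  )
}

#' Sample per-droplet generator parameters for an emulsion population
#'
#' Draws `n` droplets' generating parameters around a preset's means with its
#' between-droplet standard deviations (independent normals, truncated to the
#' generator's validity region: the diameter must exceed the ring plus a
#' bulk core, the peak must stay above the width reference level, and
#' concentrations stay nonnegative).
#'
#' @param n Number of droplets.
#' @param preset Preset name, see [droplet_preset()].
#' @param seed Integer seed.
#' @param ref_conc Width reference level passed through to the generator, g/L.
#' @return A tibble with one row per droplet: `diameter`, `ring_width`,
#'   `peak_conc`, `bulk_conc`, `condition`.
#' @export
sample_droplet_params <- function(n, preset = "NP+", seed = NULL,
                                  ref_conc = 0.5) {
  p <- droplet_preset(preset)
  s <- p$spread
  draw <- function(mean, sd, lower, upper) {
    x <- rnorm(n, mean, sd)
    pmin(pmax(x, lower), upper)
  }
  with_seed_or_current(seed, {
    ring_width <- draw(p$ring_width, s$ring_width, 0.25, 2.5)
    tibble(
      diameter = pmax(draw(p$diameter, s$diameter, 2, 12),
                      2 * ring_width + 1),
      ring_width = ring_width,
      peak_conc = draw(p$peak_conc, s$peak_conc, ref_conc + 0.2, 4),
      # floored above zero: the aqueous interior always retains some
      # labelled enzyme, and a vanishing bulk level is not measurable
      bulk_conc = draw(p$bulk_conc, s$bulk_conc, 0.02, 0.35),
      condition = p$condition
    )
  })
}
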