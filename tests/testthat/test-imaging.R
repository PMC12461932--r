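test_that("centre detection recovers the true centre and is translation-equivariant", {
  img <- gen_droplet_image(seed = 1)
  gt <- ground_truth(img)
  cen <- detect_center(img)
  expect_lt(abs(cen["row"] - gt$center_row), 0.5)
  expect_lt(abs(cen["col"] - gt$center_col), 0.5)
  # integer translation of the droplet shifts the centre by exactly as much
  off <- gen_droplet_image(seed = 1, center_offset_px = c(3, 5))
  cen_off <- detect_center(off)
  expect_equal(as.numeric(cen_off - cen), c(3, 5), tolerance = 1e-9)
  # refinement stays within half a pixel of truth
  cen_ref <- detect_center(img, refine = TRUE)
  expect_lt(abs(cen_ref["row"] - gt$center_row), 0.5)
  expect_lt(abs(cen_ref["col"] - gt$center_col), 0.5)
})

test_that("centre detection rejects uniform images", {
  flat <- droplet_image(matrix(5, 40, 40), 0.1)
  expect_error(detect_center(flat), class = "pickering_error_no_foreground")
})

test_that("rotated profiles of a symmetric droplet coincide across angles", {
  # ring well resolved by the pixel grid, so interpolation error is the
  # only source of angle-to-angle deviation
  img <- preset_image("no-particles")
  gt <- ground_truth(img)
  pr <- extract_profiles(img, center = c(gt$center_row, gt$center_col),
                         n_angles = 360)
  spread <- pr |>
    dplyr::group_by(position_um) |>
    dplyr::summarise(dev = diff(range(intensity)), .groups = "drop")
  expect_lt(max(spread$dev), 0.01 * max(img$intensity))
  # averaged profile from 4 angles matches the full 360-angle average
  pr4 <- extract_profiles(img, center = c(gt$center_row, gt$center_col),
                          n_angles = 4)
  avg360 <- average_profile(pr)
  avg4 <- average_profile(pr4)
  expect_lt(max(abs(avg4$value - avg360$value)), 0.01 * max(img$intensity))
})

test_that("profiles see an anisotropic pattern only along its direction", {
  mat <- matrix(1, 41, 41)
  mat[21, ] <- 100  # bright line through the centre along angle 0
  img <- droplet_image(mat, 0.1)
  pr <- extract_profiles(img, center = c(20, 20), n_angles = 4)
  along <- pr$intensity[pr$angle_deg == 0]
  perp <- pr$intensity[pr$angle_deg == 90]
  expect_true(all(along == 100))
  expect_true(all(perp[pr$position_um[pr$angle_deg == 90] != 0] == 1))
})

test_that("profile extraction validates the centre and flags truncation", {
  img <- gen_droplet_image(seed = 1)
  expect_error(extract_profiles(img, center = c(-5, 10)),
               class = "pickering_error_argument")
  expect_warning(
    pr <- extract_profiles(img, center = detect_center(img),
                           half_length = 100),
    class = "pickering_warning_truncated_profiles"
  )
  expect_true(anyNA(pr$intensity))
  expect_true(attr(pr, "truncated"))
})

test_that("average_profile is the pointwise mean with per-position counts", {
  pr <- tibble::tibble(
    angle_deg = rep(c(0, 180), each = 3),
    position_um = rep(c(-0.1, 0, 0.1), 2),
    intensity = c(1, 2, 3, 5, 6, 7)
  )
  avg <- average_profile(pr)
  expect_equal(avg$value, c(3, 4, 5))
  expect_equal(avg$n_samples, c(2, 2, 2))
  # identical profiles average to any one of them
  same <- tibble::tibble(angle_deg = rep(c(0, 90), each = 2),
                         position_um = rep(c(0, 0.1), 2),
                         intensity = rep(c(4, 9), 2))
  expect_equal(average_profile(same)$value, c(4, 9))
  # inconsistent grids are rejected
  bad <- same[-1, ]
  expect_error(average_profile(bad), class = "pickering_error_inconsistent")
})

test_that("averaged profile peak approaches gain times the peak concentration", {
  img <- gen_droplet_image(seed = 1)  # noise-free NP+ geometry
  gt <- ground_truth(img)
  avg <- average_profile(extract_profiles(
    img, center = c(gt$center_row, gt$center_col)))
  expect_lt(abs(max(avg$value) - gt$gain * gt$peak_conc),
            0.05 * gt$gain * gt$peak_conc)
})

test_that("calibration inverts intensities to concentrations with clipping", {
  curve <- calibrate(tibble::tibble(conc_g_per_L = c(0, 1),
                                    intensity = c(0, 100)))
  expect_equal(curve$gain, 100)
  expect_equal(curve$offset, 0)
  prof <- tibble::tibble(position_um = c(-0.1, 0, 0.1),
                         value = c(50, 10, -20))
  conc <- to_concentration(prof, curve)
  expect_equal(conc$value, c(0.5, 0.1, 0))
  expect_equal(attr(conc, "clip_fraction"), 1 / 3)
  # intensity equal to the offset maps to exactly zero
  curve2 <- calibrate(tibble::tibble(conc_g_per_L = c(0, 1),
                                     intensity = c(30, 130)))
  conc2 <- to_concentration(tibble::tibble(position_um = 0, value = 30),
                            curve2)
  expect_equal(conc2$value, 0)
  # degenerate standards are rejected
  expect_error(calibrate(tibble::tibble(conc_g_per_L = c(1, 1),
                                        intensity = c(5, 6))),
               class = "pickering_error_degenerate_calibration")
  expect_error(calibrate(tibble::tibble(conc_g_per_L = c(0, 1, 2),
                                        intensity = c(7, 7, 7))),
               class = "pickering_error_unusable_calibration")
})

test_that("droplet metrics recover the NP+ geometry from a noise-free image", {
  img <- preset_image("NP+")
  gt <- ground_truth(img)
  m <- analyze_droplet_image(img, unit_curve())
  expect_lt(abs(m$diameter_um - 5.17), gt$pixel_size)
  expect_lt(abs(m$interface_conc_g_per_L - 1.56) / 1.56, 0.02)
  expect_lt(abs(m$interface_thickness_um - 0.75), gt$pixel_size)
  expect_lt(abs(m$bulk_conc_g_per_L - 0.098) / 0.098, 0.05)
  # symmetric droplet: the two side thicknesses agree within a pixel
  expect_lt(abs(m$thickness_left_um - m$thickness_right_um), gt$pixel_size)
})

test_that("droplet metrics handle boundary peaks and unresolvable interfaces", {
  mk_profile <- function(vals) {
    p <- tibble::tibble(position_um = seq(-2, 2, by = 0.1), value = vals)
    attr(p, "value_unit") <- "g_per_L"
    class(p) <- c("diameter_profile", class(p))
    p
  }
  pos <- seq(-2, 2, by = 0.1)
  # triangular peaks topping out exactly at the reference level
  tri <- pmax(0.5 - abs(abs(pos) - 1.5), 0)
  m <- measure_droplet(mk_profile(tri), refine_peaks = FALSE)
  expect_equal(m$interface_thickness_um, 0)
  expect_true(m$thickness_flagged)
  # peaks below the reference level: no resolvable interface
  expect_error(measure_droplet(mk_profile(tri * 0.5)),
               class = "pickering_error_no_interface")
  # uncalibrated profiles are refused
  raw <- tibble::tibble(position_um = pos, value = tri * 1000)
  expect_error(measure_droplet(raw), class = "pickering_error_uncalibrated")
})

test_that("metrics are invariant under image rotation", {
  img <- preset_image("no-particles")
  curve <- unit_curve()
  m0 <- analyze_droplet_image(img, curve)
  for (ang in c(17, 90)) {
    rot_mat <- EBImage::imageData(EBImage::rotate(
      EBImage::Image(img$intensity), ang,
      output.dim = dim(img$intensity), bg.col = 0))
    rot <- droplet_image(pmax(rot_mat, 0), img$pixel_size_um)
    m1 <- analyze_droplet_image(rot, curve)
    expect_lt(abs(m1$diameter_um - m0$diameter_um), img$pixel_size_um)
    expect_lt(abs(m1$interface_conc_g_per_L - m0$interface_conc_g_per_L) /
                m0$interface_conc_g_per_L, 0.02)
    expect_lt(abs(m1$interface_thickness_um - m0$interface_thickness_um),
              img$pixel_size_um)
  }
})

test_that("360-angle and 180-angle averages agree for symmetric droplets", {
  img <- preset_image("NP+")
  gt <- ground_truth(img)
  cen <- c(gt$center_row, gt$center_col)
  a360 <- average_profile(extract_profiles(img, cen, n_angles = 360))
  a180 <- average_profile(extract_profiles(img, cen, n_angles = 180))
  expect_equal(a180$value, a360$value, tolerance = 1e-3)
})

test_that("end-to-end recovery over a parameter grid stays within pixel/percent budgets", {
  curve <- unit_curve()
  cases <- expand.grid(diameter = c(4, 8), ring_width = c(0.3, 1.2),
                       peak_conc = c(0.8, 2))
  errs <- purrr::pmap_dfr(cases, function(diameter, ring_width, peak_conc) {
    img <- gen_droplet_image(diameter = diameter, ring_width = ring_width,
                             peak_conc = peak_conc, bulk_conc = 0.1,
                             noise_model = "poisson", seed = 101)
    m <- analyze_droplet_image(img, curve)
    tibble::tibble(
      d_diam = abs(m$diameter_um - diameter),
      d_thick = abs(m$interface_thickness_um - ring_width),
      d_peak = abs(m$interface_conc_g_per_L - peak_conc) / peak_conc,
      d_bulk = abs(m$bulk_conc_g_per_L - 0.1) / 0.1
    )
  })
  expect_lte(median(errs$d_diam), 0.1)
  expect_lte(median(errs$d_thick), 0.1)
  expect_lte(median(errs$d_peak), 0.05)
  expect_lte(median(errs$d_bulk), 0.05)
})

test_that("emulsion summary aggregates droplet metrics as mean and SD", {
  one <- tibble::tibble(diameter_um = 5, interface_conc_g_per_L = 1.5,
                        interface_thickness_um = 0.7,
                        bulk_conc_g_per_L = 0.1)
  s1 <- summarize_emulsion(one)
  expect_equal(s1$mean[s1$metric == "diameter_um"], 5)
  expect_equal(s1$sd, rep(0, 4))
  expect_equal(s1$n, rep(1L, 4))

  # sampling oracle: mean of n normal diameters is within 3 SE of the truth
  n <- 100
  diams <- withr::with_seed(42, rnorm(n, 5.17, 1.78))
  many <- tibble::tibble(diameter_um = diams, interface_conc_g_per_L = 1.5,
                         interface_thickness_um = 0.7,
                         bulk_conc_g_per_L = 0.1)
  s <- summarize_emulsion(many)
  got <- s$mean[s$metric == "diameter_um"]
  expect_lt(abs(got - 5.17), 3 * 1.78 / sqrt(n))
  expect_equal(got, mean(diams))

  # duplicating the droplet list leaves the means unchanged
  s2 <- summarize_emulsion(rbind(many, many))
  expect_equal(s2$mean, s$mean)

  # NA droplets are excluded and logged
  with_na <- rbind(one, tibble::tibble(
    diameter_um = NA_real_, interface_conc_g_per_L = 1,
    interface_thickness_um = 1, bulk_conc_g_per_L = 0.1))
  s3 <- summarize_emulsion(with_na)
  expect_equal(attr(s3, "excluded"), 2L)
  expect_equal(s3$n, rep(1L, 4))
  expect_error(summarize_emulsion(one[0, ]), class = "pickering_error_argument")
})
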