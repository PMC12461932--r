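# Bilinear interpolation at (row, col) 0-based coordinates with pixel
# centres at integers; NA outside the image.
bilinear_sample <- function(mat, r, c) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  out <- rep(NA_real_, length(r))
  ok <- is.finite(r) & is.finite(c) &
    r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
  if (!any(ok)) return(out)
  r <- r[ok]
  c <- c[ok]
  r0 <- pmin(floor(r), nr - 2L)
  c0 <- pmin(floor(c), nc - 2L)
  fr <- r - r0
  fc <- c - c0
  v00 <- mat[cbind(r0 + 1L, c0 + 1L)]
  v01 <- mat[cbind(r0 + 1L, c0 + 2L)]
  v10 <- mat[cbind(r0 + 2L, c0 + 1L)]
  v11 <- mat[cbind(r0 + 2L, c0 + 2L)]
  out[ok] <- (1 - fr) * (1 - fc) * v00 + (1 - fr) * fc * v01 +
    fr * (1 - fc) * v10 + fr * fc * v11
  out
}

#' Detect the droplet centre in a confocal image
#'
#' Locates the centre of a single bright-ringed droplet: the image is
#' thresholded with Otsu's method and the centre estimated as the centroid
#' of the foreground (ring) pixel coordinates. Optionally the estimate is
#' refined by minimizing the angular variance of the per-angle peak radius —
#' for a circular ring the peak radius is the same in every direction only
#' when profiles are taken from the true centre.
#'
#' @param image A [droplet_image()].
#' @param refine Refine the centroid by Nelder-Mead minimization of the
#'   angular peak-radius variance.
#' @param n_refine_angles Number of angles used by the refinement objective.
#' @return Named numeric `c(row, col)`: subpixel centre in 0-based pixel
#'   coordinates, with attribute `border` flagging a ring that touches the
#'   image border.
#' @examples
#' img <- gen_droplet_image(seed = 1)
#' detect_center(img)
#' @export
detect_center <- function(image, refine = FALSE, n_refine_angles = 72) {
  mat <- image$intensity
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop_pickering("Image too small for centre detection.",
                   "pickering_error_argument")
  }
  mx <- max(mat)
  if (mx <= 0 || diff(range(mat)) == 0) {
    stop_pickering("No foreground: the image is uniform.",
                   "pickering_error_no_foreground")
  }
  th <- EBImage::otsu(EBImage::Image(mat / mx), range = c(0, 1)) * mx
  fg <- mat > th
  if (!any(fg)) {
    stop_pickering("No foreground pixels above the Otsu threshold.",
                   "pickering_error_no_foreground")
  }
  idx <- which(fg, arr.ind = TRUE)
  border <- any(idx[, 1] %in% c(1L, nrow(mat))) ||
    any(idx[, 2] %in% c(1L, ncol(mat)))
  if (border) {
    warn("Foreground ring touches the image border; centre estimate may be biased.",
         class = "pickering_warning_ring_at_border")
  }
  center <- c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)

  if (refine) {
    theta <- seq(0, 2 * pi, length.out = n_refine_angles + 1)[-(n_refine_angles + 1)]
    max_k <- floor(min(center["row"], nrow(mat) - 1 - center["row"],
                       center["col"], ncol(mat) - 1 - center["col"]))
    k <- seq_len(max_k)
    objective <- function(cen) {
      peak_r <- vapply(theta, function(a) {
        v <- bilinear_sample(mat, cen[1] + k * sin(a), cen[2] + k * cos(a))
        k[which.max(v)]
      }, numeric(1))
      stats::var(peak_r)
    }
    opt <- stats::optim(unname(center), objective, method = "Nelder-Mead",
                        control = list(maxit = 60, reltol = 1e-4))
    center <- c(row = opt$par[1], col = opt$par[2])
  }
  attr(center, "border") <- border
  center
}

#' Extract rotated diameter profiles around the droplet centre
#'
#' Reproduces the rotated-line-profile protocol of high-resolution droplet
#' analysis: a line profile along the droplet diameter is rotated in
#' `360 / n_angles` degree increments through a full turn around the centre
#' (1° increments by default). Each profile is sampled at pixel-size steps
#' by bilinear interpolation, at positions identical across angles, signed
#' with 0 at the centre.
#'
#' @param image A [droplet_image()].
#' @param center Subpixel centre `c(row, col)` (0-based) from
#'   [detect_center()]; detected automatically if omitted.
#' @param n_angles Number of rotation increments over 360°.
#' @param half_length Half-length of the diameter line, micrometres.
#'   Defaults to the largest half-length that fits inside the image from the
#'   centre; a longer request is truncated (out-of-image samples are NA) with
#'   a warning.
#' @return A `radial_profiles` tibble: `angle_deg`, `position_um`,
#'   `intensity`, with attributes `pixel_size_um`, `center`, `truncated`.
#' @examples
#' img <- gen_droplet_image(seed = 1)
#' pr <- extract_profiles(img, n_angles = 8)
#' @export
extract_profiles <- function(image, center = NULL, n_angles = 360,
                             half_length = NULL) {
  mat <- image$intensity
  px <- image$pixel_size_um
  center <- center %||% detect_center(image)
  if (center[1] < 0 || center[1] > nrow(mat) - 1 ||
      center[2] < 0 || center[2] > ncol(mat) - 1) {
    stop_pickering("`center` lies outside the image.",
                   "pickering_error_argument")
  }
  if (n_angles < 1) {
    stop_pickering("`n_angles` must be at least 1.", "pickering_error_argument")
  }
  max_half_px <- floor(min(center[1], nrow(mat) - 1 - center[1],
                           center[2], ncol(mat) - 1 - center[2]))
  half_px <- if (is.null(half_length)) {
    max_half_px
  } else {
    round(half_length / px)
  }
  truncated <- half_px > max_half_px
  if (truncated) {
    warn("Requested half-length extends beyond the image; profiles are truncated (NA outside).",
         class = "pickering_warning_truncated_profiles")
  }

  k <- seq(-half_px, half_px)
  angles <- seq(0, 360, length.out = n_angles + 1)[seq_len(n_angles)]
  grids <- purrr::map_dfr(angles, function(a) {
    rad <- deg2rad(a)
    tibble(
      angle_deg = a,
      position_um = k * px,
      intensity = bilinear_sample(mat, center[1] + k * sin(rad),
                                  center[2] + k * cos(rad))
    )
  })
  new_trace(grids, "radial_profiles",
            ground_truth = ground_truth(image),
            pixel_size_um = px, center = center, truncated = truncated)
}

#' Average rotated profiles into one representative diameter profile
#'
#' Pointwise mean over angles at each signed position, yielding the
#' representative concentration (or intensity) profile across the droplet.
#' Positions where some profiles were truncated keep a reduced sample count.
#'
#' @param profiles A `radial_profiles` tibble from [extract_profiles()], or
#'   any data frame with columns `position_um`, `intensity` (and optionally
#'   `angle_deg`).
#' @return A `diameter_profile` tibble: `position_um`, `value`, `n_samples`,
#'   with attribute `value_unit = "intensity"`.
#' @examples
#' gen_droplet_image(seed = 1) |>
#'   extract_profiles(n_angles = 30) |>
#'   average_profile()
#' @export
average_profile <- function(profiles) {
  if (!all(c("position_um", "intensity") %in% names(profiles))) {
    stop_pickering("`profiles` must have columns `position_um` and `intensity`.",
                   "pickering_error_argument")
  }
  if (nrow(profiles) == 0) {
    stop_pickering("`profiles` is empty.", "pickering_error_argument")
  }
  if ("angle_deg" %in% names(profiles)) {
    n_pos <- dplyr::n_distinct(profiles$position_um)
    per_angle <- table(profiles$angle_deg)
    if (any(per_angle != n_pos)) {
      stop_pickering("Inconsistent position grids across angles.",
                     "pickering_error_inconsistent")
    }
  }
  out <- profiles |>
    dplyr::group_by(.data$position_um) |>
    dplyr::summarise(
      value = mean(.data$intensity, na.rm = TRUE),
      n_samples = sum(!is.na(.data$intensity)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$position_um)
  new_trace(out, "diameter_profile",
            ground_truth = ground_truth(profiles),
            pixel_size_um = attr(profiles, "pixel_size_um", exact = TRUE),
            value_unit = "intensity")
}
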