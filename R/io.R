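# Required columns per trace kind; names carry machine-checkable unit
# suffixes and are mandatory.
.trace_columns <- list(
  ift = c("time_s", "ift_mN_per_m"),
  oscillation = c("time_s", "strain_pct", "stress_Pa_m"),
  sweep = c("strain_pct", "gp_Pa_m", "gpp_Pa_m")
)

#' Write a measurement trace as delimited text
#'
#' Tab-delimited UTF-8 text with a header row of unit-suffixed column names
#' (`_s`, `_mN_per_m`, `_pct`, `_Pa_m`) and `# key: value` metadata comment
#' lines (pH, reference tension, drive frequency, timestamp) above the
#' header. Deterministic for identical inputs.
#'
#' @param trace An `ift_trace`, `oscillation_trace` or `amplitude_sweep`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- list(
    pH = attr(trace, "pH", exact = TRUE),
    phase = attr(trace, "phase", exact = TRUE),
    ift_ref_mN_per_m = attr(trace, "ift_ref", exact = TRUE),
    omega_rad_per_s = attr(trace, "omega", exact = TRUE),
    timestamp_s = attr(trace, "timestamp", exact = TRUE)
  )
  meta <- meta[!vapply(meta, is.null, logical(1))]
  lines <- sprintf("# %s: %s", names(meta),
                   vapply(meta, function(v) format(v, digits = 15),
                          character(1)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  cols <- as.data.frame(trace)
  writeLines(paste(names(cols), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(cols, format, digits = 15, trim = TRUE,
                                  scientific = FALSE),
                           sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a measurement trace from delimited text
#'
#' Counterpart of [write_trace()]: expects a header row with the exact
#' unit-suffixed column names of the requested kind and optional
#' `# key: value` metadata lines. Readers reject rather than coerce: missing
#' or unexpectedly named columns and non-monotone time are errors.
#'
#' @param path Input file path.
#' @param kind `"ift"`, `"oscillation"` or `"sweep"`.
#' @return A typed trace tibble of the matching class with metadata
#'   attributes restored.
#' @export
read_trace <- function(path, kind = c("ift", "oscillation", "sweep")) {
  kind <- match.arg(kind)
  need <- .trace_columns[[kind]]
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  df <- readr::read_tsv(I(lines[!grepl("^#", lines)]),
                        col_types = readr::cols(.default = "d"),
                        progress = FALSE)
  unknown <- setdiff(names(df), need)
  if (length(unknown) > 0) {
    stop_pickering(
      sprintf("Unknown column(s) in %s trace: %s (expected %s).",
              kind, paste0("`", unknown, "`", collapse = ", "),
              paste0("`", need, "`", collapse = ", ")),
      "pickering_error_format"
    )
  }
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_pickering(
      sprintf("Missing required column(s): %s.",
              paste0("`", missing, "`", collapse = ", ")),
      "pickering_error_format"
    )
  }
  if ("time_s" %in% need && any(diff(df$time_s) <= 0)) {
    stop_pickering("`time_s` must be strictly increasing.",
                   "pickering_error_format")
  }
  if (kind == "sweep" && any(diff(df$strain_pct) <= 0)) {
    stop_pickering("`strain_pct` must be strictly increasing.",
                   "pickering_error_format")
  }

  subclass <- switch(kind, ift = "ift_trace",
                     oscillation = "oscillation_trace",
                     sweep = "amplitude_sweep")
  new_trace(as_tibble(df[need]), subclass,
            ift_ref = meta$ift_ref_mN_per_m,
            pH = meta$pH, phase = meta$phase,
            omega = meta$omega_rad_per_s,
            timestamp = meta$timestamp_s)
}

#' Write a droplet image as 16-bit grayscale TIFF with a sidecar
#'
#' Intensities are rounded to integer counts, clamped to the 16-bit range
#' and written as a single-plane grayscale TIFF. The physical pixel size
#' (and condition label) is recorded in a YAML sidecar `<path>.yaml`, since
#' image data alone does not carry physical scale.
#'
#' @param image A [droplet_image()].
#' @param path Output TIFF path.
#' @param sidecar Write the `<path>.yaml` sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path, sidecar = TRUE) {
  counts <- round(pmin(pmax(image$intensity, 0), 65535))
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16,
                  compression = "none")
  if (sidecar) {
    yaml::write_yaml(
      list(pixel_size_um = image$pixel_size_um,
           condition = if (is.na(image$condition)) NULL else image$condition),
      paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read a single-plane grayscale TIFF droplet image
#'
#' Reads integer counts from a grayscale TIFF. The pixel size must come from
#' the YAML sidecar `<path>.yaml` or the `pixel_size_um` argument; it is
#' never assumed. Multi-channel (e.g. RGB) images are rejected.
#'
#' @param path Input TIFF path.
#' @param pixel_size_um Pixel size override, micrometres per pixel.
#' @return A [droplet_image()].
#' @export
read_tiff <- function(path, pixel_size_um = NULL) {
  arr <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(arr)) != 2) {
    stop_pickering("Multi-channel TIFF: a single-plane grayscale image is required.",
                   "pickering_error_format")
  }
  condition <- NA_character_
  sidecar <- paste0(path, ".yaml")
  if (is.null(pixel_size_um) && file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    pixel_size_um <- meta$pixel_size_um
    condition <- meta$condition %||% NA_character_
  }
  if (is.null(pixel_size_um)) {
    stop_pickering(
      "Pixel size unknown: no sidecar `<path>.yaml` found and `pixel_size_um` not supplied.",
      "pickering_error_missing_pixel_size"
    )
  }
  droplet_image(matrix(as.numeric(arr), nrow = nrow(arr)), pixel_size_um,
                condition = condition)
}

#' Write the ground-truth record of a synthetic object
#'
#' Stores the generating parameters as a YAML record so that analyses of
#' written synthetic data can still be checked against truth.
#'
#' @param x A synthetic object carrying a [ground_truth()] record.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  gt <- ground_truth(x)
  if (is.null(gt)) {
    stop_pickering("`x` carries no ground-truth record.",
                   "pickering_error_argument")
  }
  yaml::write_yaml(gt[!vapply(gt, is.null, logical(1))], path)
  invisible(path)
}

#' Default analysis configuration
#'
#' Central record of the tunable analysis parameters with their defaults:
#' pixel size 0.1 um (the acquisition setting of the confocal protocol),
#' thickness reference level 0.5 g/L (the initial enzyme concentration),
#' steady-state window 180 s at 0.005 mN/m/min, 5 % yield drop fraction and
#' 5 % LVE tolerance, drive frequency 1 rad/s.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list (`pickering_config`).
#' @export
pickering_config <- function(...) {
  cfg <- list(
    pixel_size_um = 0.1,
    ref_conc_g_per_L = 0.5,
    bulk_window_px = 10,
    plateau_window_s = 180,
    plateau_slope_threshold = 0.005,
    drop_fraction = 0.05,
    lve_tolerance = 0.05,
    omega_rad_per_s = 1,
    n_angles = 360,
    seed = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop_pickering(sprintf("Unknown configuration field(s): %s.",
                           paste0("`", unknown, "`", collapse = ", ")),
                   "pickering_error_argument")
  }
  cfg[names(overrides)] <- overrides
  for (nm in setdiff(names(cfg), "seed")) {
    check_number(cfg[[nm]], nm, lower = 0, strict_lower = TRUE)
  }
  structure(cfg, class = "pickering_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pickering_config()]
#'   fields.
#' @return A validated `pickering_config`.
#' @export
read_config <- function(path) {
  do.call(pickering_config, yaml::read_yaml(path))
}
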