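#' Retrieve the ground truth attached to a synthetic object
#'
#' Every synthetic generator returns its data with the full set of generating
#' parameters (including the seed) attached, so downstream recovery can be
#' checked against known truth.
#'
#' @param x An object produced by one of the `gen_*()` generators.
#' @return A named list of generating parameters, or `NULL` for real data.
#' @export
ground_truth <- function(x) {
  attr(x, "ground_truth", exact = TRUE)
}

# Attach ground truth + extra attributes and a subclass to a tibble without
# disturbing tbl_df behaviour.
new_trace <- function(df, subclass, ground_truth = NULL, ...) {
  extra <- list(...)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  attr(df, "ground_truth") <- ground_truth
  class(df) <- c(subclass, class(df))
  df
}

stop_pickering <- function(msg, class, ...) {
  abort(msg, class = c(class, "pickering_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pickering(sprintf("`%s` must be a single finite number.", name),
                   "pickering_error_argument")
  }
  bad_low <- if (strict_lower) x <= lower else x < lower
  bad_high <- if (strict_upper) x >= upper else x > upper
  if (bad_low || bad_high) {
    stop_pickering(
      sprintf("`%s` = %g is outside the allowed range %s%g, %g%s.",
              name, x,
              if (strict_lower) "(" else "[", lower, upper,
              if (strict_upper) ")" else "]"),
      "pickering_error_argument"
    )
  }
  invisible(x)
}

# Run code under a fixed seed without touching the caller's RNG state.
# seed = NULL draws from the current stream (still reproducible via set.seed).
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Least-squares slope of y on x; returns slope in units of y per unit x.
ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}
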