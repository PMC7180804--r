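# Internal argument checking helpers. All user-facing errors are classed so
# the CLI can map them to exit codes: "foascope_parameter_error",
# "foascope_io_error", "foascope_placement_error".

stop_parameter <- function(msg) {
  abort(msg, class = "foascope_parameter_error")
}

stop_io <- function(msg) {
  abort(msg, class = "foascope_io_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_parameter(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_parameter(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < lower) {
    stop_parameter(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

check_shape <- function(shape) {
  if (!is.numeric(shape) || length(shape) != 2L || any(!is.finite(shape)) ||
      any(shape < 1) || any(shape != round(shape))) {
    stop_parameter("`shape` must be two positive integers (rows, cols).")
  }
  as.integer(shape)
}

check_gray_image <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_parameter(sprintf("`%s` must be a numeric matrix.", name))
  }
  rng <- range(img)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop_parameter(sprintf(
      "`%s` must hold intensities on the working scale [0, 1] (range %g..%g).",
      name, rng[1], rng[2]
    ))
  }
  invisible(img)
}

check_rgb_array <- function(x, name = "rgb") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop_parameter(sprintf(
      "`%s` must be a rows x cols x 3 array (got %s).", name,
      paste(dim(x), collapse = " x ")
    ))
  }
  invisible(x)
}

# Normalize an 8-bit style input (0..255) or working-scale input to [0, 1].
as_unit_scale <- function(x) {
  if (max(x) > 1 + 1e-9) x / 255 else x
}

quantize_8bit <- function(x) {
  storage.mode(x) <- "double"
  round(pmin(pmax(x, 0), 1) * 255)
}
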