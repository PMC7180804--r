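#' Read a PNG or TIFF image
#'
#' Returns intensities on the working scale \[0, 1\]; grayscale files give a
#' matrix, RGB files a `rows x cols x 3` array. The original bit depth is
#' recorded in the `"bit_depth"` attribute. Only 1- or 3-channel, 8- or
#' 16-bit images are supported.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return A numeric matrix or 3-channel array with attribute `bit_depth`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("Cannot read image: '%s' does not exist.", path))
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop_io(sprintf("Unsupported image format '.%s' for '%s' (use PNG or TIFF).", ext, path))
    )
  }, error = function(e) {
    if (inherits(e, "foascope_io_error")) stop(e)
    stop_io(sprintf("Failed to read '%s': %s", path, conditionMessage(e)))
  })
  if (is.array(img) && length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1]
    } else if (dim(img)[3] != 3L) {
      stop_io(sprintf("'%s' has %d channels; only 1 or 3 are supported.",
                      path, dim(img)[3]))
    }
  }
  # readers already scale to [0, 1]; infer the source depth from granularity
  bit_depth <- if (any(abs(img * 255 - round(img * 255)) > 1e-6)) 16L else 8L
  attr(img, "bit_depth") <- bit_depth
  img
}

#' Write an image as 8-bit PNG or TIFF
#'
#' @param img Numeric matrix or 3-channel array on \[0, 1\] (values are
#'   clipped and quantized to 8 bits) or an integer 0--255 matrix.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (max(img) > 1 + 1e-9) img <- img / 255
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop_io(sprintf("Unsupported image format '.%s' (use PNG or TIFF).", ext))
  )
  invisible(path)
}

#' Write / read ground-truth cell tables
#'
#' CSV with header `x,y,radius_px,label,cluster_member`.
#'
#' @param gt Ground-truth tibble (e.g. `scene$gt`).
#' @param path CSV path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the tibble.
#' @export
write_ground_truth <- function(gt, path) {
  readr::write_csv(gt[, c("x", "y", "radius_px", "label", "cluster_member")],
                   path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("Ground-truth file '%s' does not exist.", path))
  gt <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          x = readr::col_double(), y = readr::col_double(),
                          radius_px = readr::col_double(),
                          label = readr::col_character(),
                          cluster_member = readr::col_logical()))
  gt
}

#' Write / read detection tables
#'
#' CSV with header `x,y,score,label`.
#'
#' @param detections A `foa_detections` object or a tibble with those
#'   columns.
#' @param path CSV path.
#' @return `write_detections()` returns `path` invisibly;
#'   `read_detections()` returns the tibble.
#' @export
write_detections <- function(detections, path) {
  if (inherits(detections, "foa_detections")) {
    detections <- detections_table(detections)
  }
  readr::write_csv(detections[, c("x", "y", "score", "label")], path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("Detections file '%s' does not exist.", path))
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    x = readr::col_double(), y = readr::col_double(),
                    score = readr::col_double(),
                    label = readr::col_character()))
}

#' Pipeline configuration
#'
#' All tunables of the analysis chain in one validated, flat list. Defaults
#' follow the device protocol where one is printed (25 x 25 CLAHE tiles,
#' clip limit 0.1, minimum particle area 2 px) and the package's documented
#' choices elsewhere.
#'
#' @param ... Overrides of the defaults; unknown keys are rejected.
#' @return A `foa_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    num_tiles_rows = 25, num_tiles_cols = 25, clip_limit = 0.1, n_bins = 256,
    window_circumradius_px = 8, ring_thickness_px = 2,
    live_threshold = 0.17, dead_threshold = 0.43, nms_radius_px = 13,
    min_particle_area_px = 2, connectivity = 8,
    match_max_dist_px = 10, cluster_min_sep_px = 26,
    k = 5, seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop_parameter(sprintf("Unknown config key(s): %s.",
                           paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides)
  check_count(cfg$num_tiles_rows, "num_tiles_rows", lower = 1L)
  check_count(cfg$num_tiles_cols, "num_tiles_cols", lower = 1L)
  check_number(cfg$clip_limit, "clip_limit", lower = 0.01, upper = 1,
               strict_lower = TRUE)
  check_number(cfg$window_circumradius_px, "window_circumradius_px", lower = 2)
  check_number(cfg$nms_radius_px, "nms_radius_px", lower = 0, strict_lower = TRUE)
  check_count(cfg$min_particle_area_px, "min_particle_area_px", lower = 1L)
  if (!cfg$connectivity %in% c(4, 8)) stop_parameter("`connectivity` must be 4 or 8.")
  check_count(cfg$k, "k", lower = 2L)
  check_count(cfg$seed, "seed")
  structure(cfg, class = "foa_config")
}

#' @export
print.foa_config <- function(x, ...) {
  cat("<foa_config>\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write / read a pipeline configuration as a key=value text file
#'
#' @param config A [pipeline_config()].
#' @param path Text file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a validated `foa_config` (unknown keys are rejected).
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(nm) {
    sprintf("%s = %s", nm, format(config[[nm]], digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("Config file '%s' does not exist.", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop_parameter(sprintf("Malformed config line(s): %s",
                           paste(lines[bad], collapse = "; ")))
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, character(1), 2L)))
  if (any(is.na(vals))) {
    stop_parameter("All config values must be numeric.")
  }
  do.call(pipeline_config, as.list(setNames(vals, keys)))
}
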