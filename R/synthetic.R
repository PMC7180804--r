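#' Fiber lattice specification
#'
#' Describes the periodic core/gap transmission pattern that a tapered fiber
#' optic array imprints on a micrograph: bright circular fiber cores separated
#' by lighttight gaps, packed hexagonally (or on a square grid for
#' comparison).
#'
#' @param core_radius_px Core image radius in pixels. The default (3 px)
#'   corresponds to a ~9 um large-end core imaged at a 1.4 um pixel pitch.
#' @param pitch_px Center-to-center core distance in pixels; must be at least
#'   `2 * core_radius_px` so cores do not overlap.
#' @param arrangement `"hexagonal"` (rows offset by half a pitch, row spacing
#'   `pitch * sqrt(3) / 2`) or `"square"`.
#' @param core_gain Transmission inside a core, in (0, 1].
#' @param gap_gain Transmission in the gaps, in \[0, 1); must be below
#'   `core_gain`.
#'
#' @return A `foa_lattice_spec` list.
#' @seealso [render_fiber_lattice()]
#' @export
fiber_lattice_spec <- function(core_radius_px = 3, pitch_px = 7,
                               arrangement = c("hexagonal", "square"),
                               core_gain = 1, gap_gain = 0.45) {
  arrangement <- match.arg(arrangement)
  check_number(core_radius_px, "core_radius_px", lower = 0, strict_lower = TRUE)
  check_number(pitch_px, "pitch_px", lower = 0, strict_lower = TRUE)
  check_number(core_gain, "core_gain", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(gap_gain, "gap_gain", lower = 0, upper = 1)
  if (pitch_px < 2 * core_radius_px) {
    stop_parameter("`pitch_px` must be >= 2 * `core_radius_px` (cores must not overlap).")
  }
  if (gap_gain > core_gain) {
    # equal gains are allowed as the degenerate featureless lattice
    stop_parameter("`gap_gain` must not exceed `core_gain` (gaps are lighttight).")
  }
  structure(
    list(core_radius_px = core_radius_px, pitch_px = pitch_px,
         arrangement = arrangement, core_gain = core_gain,
         gap_gain = gap_gain),
    class = "foa_lattice_spec"
  )
}

#' Illumination specification
#'
#' Radial illumination profile of the FOA microscope: the field center is
#' darker than the rim (the cut large end of the fiber bundle admits extra
#' light at the borders).
#'
#' @param center_level Relative illumination at the image center, in (0, 1].
#' @param edge_level Relative illumination at the farthest corner, in (0, 1];
#'   must be at least `center_level`.
#' @param profile `"radial_quadratic"` (gain rises with the square of the
#'   normalized distance from center) or `"radial_quartic"`.
#'
#' @return A `foa_illumination_spec` list.
#' @seealso [render_illumination()]
#' @export
illumination_spec <- function(center_level = 0.7, edge_level = 1,
                              profile = c("radial_quadratic", "radial_quartic")) {
  profile <- match.arg(profile)
  check_number(center_level, "center_level", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(edge_level, "edge_level", lower = 0, upper = 1, strict_lower = TRUE)
  if (center_level > edge_level) {
    stop_parameter("`center_level` must not exceed `edge_level` (the field center is the dark region).")
  }
  structure(
    list(center_level = center_level, edge_level = edge_level, profile = profile),
    class = "foa_illumination_spec"
  )
}

#' Cell population specification
#'
#' Intensity and placement model for the synthetic yeast population.
#' Unstained live cells render as a bright interior disk with a dark rim;
#' methylene-blue stained dead cells render as a uniformly dark disk. All
#' levels are on the working intensity scale \[0, 1\] before lattice and
#' illumination gains are applied, with the ordering
#' `live_rim_level < background_level < live_interior_level` and
#' `dead_level < background_level`.
#'
#' The default 6.5--10.5 px radius range corresponds to 3--5 um yeast cells
#' at 6x magnification over a 1.4 um sensor pixel.
#'
#' @param n_live,n_dead Number of live / dead cells.
#' @param radius_px_range Length-2 numeric, min and max cell radius (pixels).
#' @param live_interior_level,live_rim_level,dead_level,background_level
#'   Intensity levels in \[0, 1\] obeying the ordering above.
#' @param min_separation_px Minimum center-to-center distance enforced
#'   between non-cluster cells.
#' @param cluster_fraction Fraction of cells deliberately placed closer than
#'   `min_separation_px` to a partner (emulating cell clusters, which the
#'   counting protocol excludes).
#'
#' @return A `foa_cells_spec` list.
#' @seealso [place_cells()], [render_scene()]
#' @export
cell_population_spec <- function(n_live = 15, n_dead = 15,
                                 radius_px_range = c(6.5, 10.5),
                                 live_interior_level = 0.85,
                                 live_rim_level = 0.25,
                                 dead_level = 0.3,
                                 background_level = 0.55,
                                 min_separation_px = 26,
                                 cluster_fraction = 0) {
  check_count(n_live, "n_live")
  check_count(n_dead, "n_dead")
  if (!is.numeric(radius_px_range) || length(radius_px_range) != 2L ||
      any(radius_px_range <= 0) || radius_px_range[1] > radius_px_range[2]) {
    stop_parameter("`radius_px_range` must be positive (min, max) with min <= max.")
  }
  for (nm in c("live_interior_level", "live_rim_level", "dead_level",
               "background_level")) {
    check_number(get(nm), nm, lower = 0, upper = 1)
  }
  check_number(min_separation_px, "min_separation_px", lower = 0)
  check_number(cluster_fraction, "cluster_fraction", lower = 0, upper = 1)
  if (!(live_rim_level < background_level &&
        background_level < live_interior_level)) {
    stop_parameter("Intensity ordering violated: need live_rim_level < background_level < live_interior_level.")
  }
  if (!(dead_level < background_level)) {
    stop_parameter("Intensity ordering violated: need dead_level < background_level.")
  }
  structure(
    list(n_live = as.integer(n_live), n_dead = as.integer(n_dead),
         radius_px_range = as.numeric(radius_px_range),
         live_interior_level = live_interior_level,
         live_rim_level = live_rim_level, dead_level = dead_level,
         background_level = background_level,
         min_separation_px = min_separation_px,
         cluster_fraction = cluster_fraction),
    class = "foa_cells_spec"
  )
}

# Nearest-lattice-center squared distance for every pixel, vectorized.
# Pixel centers sit at integer (row, col) coordinates, 1-based; a lattice
# center sits at (1, 1).
nearest_center_dist <- function(spec, shape) {
  rows <- shape[1]; cols <- shape[2]
  y <- matrix(seq_len(rows) - 1, rows, cols)          # 0-based offsets from origin
  x <- matrix(rep(seq_len(cols) - 1, each = rows), rows, cols)
  p <- spec$pitch_px
  if (spec$arrangement == "square") {
    dx <- x - round(x / p) * p
    dy <- y - round(y / p) * p
    return(sqrt(dx^2 + dy^2))
  }
  s <- p * sqrt(3) / 2                                 # hexagonal row spacing
  best <- matrix(Inf, rows, cols)
  k0 <- floor(y / s)
  for (dk in -1:2) {
    k <- k0 + dk
    cy <- k * s
    ox <- (abs(k) %% 2) * (p / 2)                      # odd rows offset half a pitch
    m <- round((x - ox) / p)
    cx <- ox + m * p
    d2 <- (x - cx)^2 + (y - cy)^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Render the fiber core/gap transmission raster
#'
#' Produces a per-pixel gain raster in \[0, 1\]: `core_gain` where the pixel
#' center lies strictly inside some core disk, `gap_gain` elsewhere.
#'
#' @param spec A [fiber_lattice_spec()].
#' @param shape Integer `(rows, cols)`.
#' @return A numeric `rows x cols` matrix of gains.
#' @export
render_fiber_lattice <- function(spec, shape) {
  if (!inherits(spec, "foa_lattice_spec")) {
    stop_parameter("`spec` must be a fiber_lattice_spec().")
  }
  shape <- check_shape(shape)
  d <- nearest_center_dist(spec, shape)
  ifelse(d < spec$core_radius_px, spec$core_gain, spec$gap_gain)
}

#' Render the radial illumination raster
#'
#' Gain equals `center_level` at the image center and `edge_level` at the
#' farthest corner, interpolated along the normalized radial distance `t` as
#' `center + (edge - center) * t^2` (quadratic) or `... * t^4` (quartic);
#' monotone non-decreasing along any ray from the center.
#'
#' @inheritParams render_fiber_lattice
#' @param spec An [illumination_spec()].
#' @return A numeric `rows x cols` gain matrix.
#' @export
render_illumination <- function(spec, shape) {
  if (!inherits(spec, "foa_illumination_spec")) {
    stop_parameter("`spec` must be an illumination_spec().")
  }
  shape <- check_shape(shape)
  rows <- shape[1]; cols <- shape[2]
  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  y <- matrix(seq_len(rows), rows, cols)
  x <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  r <- sqrt((y - cy)^2 + (x - cx)^2)
  rmax <- sqrt((rows - cy)^2 + (cols - cx)^2)
  t <- if (rmax > 0) r / rmax else r * 0
  pw <- if (spec$profile == "radial_quadratic") 2 else 4
  spec$center_level + (spec$edge_level - spec$center_level) * t^pw
}

#' Place cells with a minimum-separation constraint
#'
#' Rejection-samples cell centers so that every non-cluster pair is at least
#' `min_separation_px` apart; a `cluster_fraction` share of cells is then
#' deliberately placed closer than that to a random partner and flagged
#' `cluster_member`. Disks are kept fully inside the image. Deterministic for
#' a fixed seed.
#'
#' @param spec A [cell_population_spec()].
#' @param shape Integer `(rows, cols)`.
#' @param seed Integer RNG seed.
#' @param max_attempts Rejection-sampling cap per cell before failing loudly.
#' @return A tibble with columns `x`, `y` (pixel coordinates, 1-based),
#'   `radius_px`, `label` (`"live"`/`"dead"`), `cluster_member`.
#' @export
place_cells <- function(spec, shape, seed, max_attempts = 10000) {
  if (!inherits(spec, "foa_cells_spec")) {
    stop_parameter("`spec` must be a cell_population_spec().")
  }
  shape <- check_shape(shape)
  check_count(seed, "seed")
  n_total <- spec$n_live + spec$n_dead
  if (n_total == 0L) {
    return(tibble(x = numeric(), y = numeric(), radius_px = numeric(),
                  label = character(), cluster_member = logical()))
  }
  rmax <- spec$radius_px_range[2]
  lo <- rmax + 1
  hi_x <- shape[2] - rmax
  hi_y <- shape[1] - rmax
  if (hi_x <= lo || hi_y <= lo) {
    abort("Image too small to hold any cell disk.",
          class = "foa_placement_error")
  }
  n_cluster <- as.integer(round(spec$cluster_fraction * n_total))
  n_main <- n_total - n_cluster
  withr::with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(n_main)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        px <- runif(1, lo, hi_x); py <- runif(1, lo, hi_y)
        if (length(xs) == 0 ||
            all((xs - px)^2 + (ys - py)^2 >= spec$min_separation_px^2)) {
          xs <- c(xs, px); ys <- c(ys, py); placed <- TRUE; break
        }
      }
      if (!placed) {
        abort(sprintf(
          "Could not place cell %d of %d at min separation %g px after %d attempts.",
          i, n_main, spec$min_separation_px, max_attempts),
          class = "foa_placement_error")
      }
    }
    cl_x <- numeric(0); cl_y <- numeric(0)
    for (i in seq_len(n_cluster)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        j <- sample.int(n_main, 1)
        ang <- runif(1, 0, 2 * pi)
        dist <- runif(1, 0.4, 0.9) * spec$min_separation_px
        px <- xs[j] + dist * cos(ang); py <- ys[j] + dist * sin(ang)
        if (px >= lo && px <= hi_x && py >= lo && py <= hi_y) {
          cl_x <- c(cl_x, px); cl_y <- c(cl_y, py); placed <- TRUE; break
        }
      }
      if (!placed) {
        abort(sprintf("Could not place cluster cell %d of %d.", i, n_cluster),
              class = "foa_placement_error")
      }
    }
    radii <- runif(n_total, spec$radius_px_range[1], spec$radius_px_range[2])
    label <- sample(rep(c("live", "dead"), c(spec$n_live, spec$n_dead)))
    tibble(
      x = c(xs, cl_x), y = c(ys, cl_y), radius_px = radii, label = label,
      cluster_member = rep(c(FALSE, TRUE), c(n_main, n_cluster))
    )
  })
}

#' Render a synthetic FOA micrograph
#'
#' Paints cells on a uniform background (live: bright interior disk with a
#' dark rim of `rim_px` pixels; dead: uniformly dark disk), multiplies
#' elementwise by the fiber-lattice and illumination gain rasters, adds
#' Gaussian noise, clips to \[0, 1\] and quantizes to 8 bits.
#'
#' @param lattice A [fiber_lattice_spec()].
#' @param illumination An [illumination_spec()].
#' @param cells Either a [cell_population_spec()] (cells are placed with
#'   [place_cells()]) or a ground-truth tibble from a previous placement.
#' @param shape Integer `(rows, cols)`.
#' @param cells_spec Required when `cells` is a tibble: the
#'   [cell_population_spec()] supplying intensity levels.
#' @param noise_sigma Additive Gaussian noise sd on the \[0, 1\] scale.
#' @param seed Integer seed used for placement and noise.
#' @param rim_px Live-cell rim thickness in pixels (1--2 px is realistic).
#' @return A `foa_scene` object: list with `image` (integer matrix, 0--255),
#'   `gt` (ground-truth tibble), the three specs, `shape`, `noise_sigma`,
#'   `seed`.
#' @export
render_scene <- function(lattice = fiber_lattice_spec(),
                         illumination = illumination_spec(),
                         cells = cell_population_spec(),
                         shape = c(256, 256),
                         cells_spec = NULL,
                         noise_sigma = 0.02,
                         seed = 1,
                         rim_px = 2) {
  shape <- check_shape(shape)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(rim_px, "rim_px", lower = 0.5)
  if (inherits(cells, "foa_cells_spec")) {
    cells_spec <- cells
    gt <- place_cells(cells, shape, seed = seed)
  } else {
    if (is.null(cells_spec) || !inherits(cells_spec, "foa_cells_spec")) {
      stop_parameter("When `cells` is a ground-truth table, supply `cells_spec` for intensity levels.")
    }
    gt <- as_tibble(cells)
  }
  rows <- shape[1]; cols <- shape[2]
  base <- matrix(cells_spec$background_level, rows, cols)
  if (nrow(gt) > 0) {
    for (i in seq_len(nrow(gt))) {
      r <- gt$radius_px[i]
      ri <- ceiling(r)
      rr <- max(1, floor(gt$y[i] - ri)):min(rows, ceiling(gt$y[i] + ri))
      cc <- max(1, floor(gt$x[i] - ri)):min(cols, ceiling(gt$x[i] + ri))
      dy <- outer(rr - gt$y[i], rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - gt$x[i])
      d <- sqrt(dy^2 + dx^2)
      patch <- base[rr, cc, drop = FALSE]
      if (gt$label[i] == "dead") {
        patch[d <= r] <- cells_spec$dead_level
      } else {
        patch[d <= r] <- cells_spec$live_rim_level
        patch[d <= r - rim_px] <- cells_spec$live_interior_level
      }
      base[rr, cc] <- patch
    }
  }
  gain <- render_fiber_lattice(lattice, shape) *
    render_illumination(illumination, shape)
  img <- base * gain
  if (noise_sigma > 0) {
    img <- img + withr::with_seed(seed + 1L, {
      matrix(rnorm(rows * cols, 0, noise_sigma), rows, cols)
    })
  }
  structure(
    list(image = quantize_8bit(img), gt = gt, lattice = lattice,
         illumination = illumination, cells = cells_spec, shape = shape,
         noise_sigma = noise_sigma, seed = as.integer(seed), rim_px = rim_px),
    class = "foa_scene"
  )
}

#' @export
print.foa_scene <- function(x, ...) {
  cat(sprintf(
    "<foa_scene> %d x %d px, %d live + %d dead cells (seed %d, noise sd %.3g)\n",
    x$shape[1], x$shape[2], sum(x$gt$label == "live"),
    sum(x$gt$label == "dead"), x$seed, x$noise_sigma))
  invisible(x)
}

#' Working-scale image of a scene
#'
#' @param scene A `foa_scene`.
#' @return The scene's image as a numeric matrix on \[0, 1\].
#' @export
scene_image <- function(scene) {
  if (!inherits(scene, "foa_scene")) stop_parameter("`scene` must be a foa_scene.")
  scene$image / 255
}
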