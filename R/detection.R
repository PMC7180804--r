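# Unit outward normals of a flat-topped regular hexagon's six edges.
hex_normals <- function() {
  ang <- (c(30, 90, 150, 210, 270, 330)) * pi / 180
  cbind(cos(ang), sin(ang))     # (nx, ny)
}

#' Hexagonal scan-window mask
#'
#' Rasterizes a flat-topped regular hexagon of the given circumradius,
#' centered on a pixel, and splits it into an edge ring (pixels within
#' `ring_thickness` of the hexagon boundary) and an interior. The live-cell
#' detector contrasts interior against ring; the dead-cell detector averages
#' the whole hexagon.
#'
#' Offsets are `(dy, dx)` integer displacements from the window center
#' (pixel centers at integer coordinates). The mask is symmetric under 180
#' degree rotation.
#'
#' @param circumradius_px Hexagon circumradius in pixels (>= 2). Choose it
#'   close to the expected cell radius.
#' @param ring_thickness Ring thickness in pixels (>= 1).
#' @return A `foa_hex_window`: list with `ring` and `interior` (two-column
#'   `(dy, dx)` matrices), `offsets` (their union), `circumradius_px`,
#'   `ring_thickness`.
#' @export
make_hex_window <- function(circumradius_px, ring_thickness = 2) {
  check_number(circumradius_px, "circumradius_px", lower = 2)
  check_number(ring_thickness, "ring_thickness", lower = 1)
  R <- ceiling(circumradius_px)
  g <- expand.grid(dy = -R:R, dx = -R:R)
  nrm <- hex_normals()
  apothem <- circumradius_px * sqrt(3) / 2
  # signed slack to the boundary: >= 0 inside, equals distance to the
  # nearest edge for interior points of a regular hexagon
  proj <- outer(g$dx, nrm[, 1]) + outer(g$dy, nrm[, 2])
  slack <- apothem - apply(proj, 1, max)
  inside <- slack >= -1e-9
  ring <- inside & slack < ring_thickness
  interior <- inside & !ring
  if (!any(interior)) {
    stop_parameter("Window too small: interior is empty; increase circumradius or decrease ring thickness.")
  }
  structure(
    list(
      circumradius_px = circumradius_px,
      ring_thickness = ring_thickness,
      ring = as.matrix(g[ring, c("dy", "dx")]),
      interior = as.matrix(g[interior, c("dy", "dx")]),
      offsets = as.matrix(g[inside, c("dy", "dx")])
    ),
    class = "foa_hex_window"
  )
}

#' @export
print.foa_hex_window <- function(x, ...) {
  cat(sprintf("<foa_hex_window> circumradius %.3g px, ring %g px: %d interior + %d ring pixels\n",
              x$circumradius_px, x$ring_thickness,
              nrow(x$interior), nrow(x$ring)))
  invisible(x)
}

# Sum of img over a set of (dy, dx) offsets, evaluated on the region where
# every offset stays in bounds; returns list(sum matrix, margins).
offset_region_sum <- function(img, offsets, margin_y, margin_x) {
  rows <- nrow(img); cols <- ncol(img)
  vr <- (margin_y + 1):(rows - margin_y)
  vc <- (margin_x + 1):(cols - margin_x)
  s <- matrix(0, length(vr), length(vc))
  for (i in seq_len(nrow(offsets))) {
    s <- s + img[vr + offsets[i, 1], vc + offsets[i, 2]]
  }
  s
}

score_with <- function(img, window, mode) {
  check_gray_image(img)
  if (!inherits(window, "foa_hex_window")) {
    stop_parameter("`window` must come from make_hex_window().")
  }
  my <- max(abs(window$offsets[, 1]))
  mx <- max(abs(window$offsets[, 2]))
  rows <- nrow(img); cols <- ncol(img)
  if (rows < 2 * my + 1 || cols < 2 * mx + 1) {
    stop_parameter("Window larger than image: no valid positions.")
  }
  scores <- matrix(NA_real_, rows, cols)
  vr <- (my + 1):(rows - my); vc <- (mx + 1):(cols - mx)
  if (mode == "live") {
    s <- offset_region_sum(img, window$interior, my, mx) / nrow(window$interior) -
      offset_region_sum(img, window$ring, my, mx) / nrow(window$ring)
  } else {
    s <- offset_region_sum(img, window$offsets, my, mx) / nrow(window$offsets)
  }
  scores[vr, vc] <- s
  structure(list(scores = scores, mode = mode, window = window),
            class = "foa_score_map")
}

#' Live-cell score map
#'
#' At each valid position, mean intensity over the window interior minus
#' mean over the edge ring. Live cells (bright interior, dark rim after
#' enhancement) produce strong maxima; the score is invariant under a global
#' additive intensity shift. Border positions where the window does not fit
#' are `NA`.
#'
#' @param img Numeric matrix on \[0, 1\] (preprocessed grayscale).
#' @param window A [make_hex_window()] mask.
#' @return A `foa_score_map` (`scores` matrix, `mode = "live"`).
#' @export
score_live <- function(img, window) score_with(img, window, "live")

#' Dead-cell score map
#'
#' Mean intensity over the whole hexagon at each valid position; stained
#' dead cells (uniformly darker than background) produce minima. Border
#' positions are `NA`.
#'
#' @inheritParams score_live
#' @return A `foa_score_map` (`scores` matrix, `mode = "dead"`).
#' @export
score_dead <- function(img, window) score_with(img, window, "dead")

#' @export
print.foa_score_map <- function(x, ...) {
  v <- x$scores[!is.na(x$scores)]
  cat(sprintf("<foa_score_map> mode '%s', %d x %d, valid score range %.4g..%.4g\n",
              x$mode, nrow(x$scores), ncol(x$scores), min(v), max(v)))
  invisible(x)
}

# Local extrema (plateau-inclusive: >= / <= all 8 neighbors); NA-bordered.
local_extrema <- function(scores, polarity) {
  rows <- nrow(scores); cols <- ncol(scores)
  s <- scores
  if (polarity == "min") s <- -s
  pad <- matrix(-Inf, rows + 2, cols + 2)
  pad[2:(rows + 1), 2:(cols + 1)] <- ifelse(is.na(s), -Inf, s)
  best <- matrix(-Inf, rows, cols)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    best <- pmax(best, pad[2:(rows + 1) + dy, 2:(cols + 1) + dx])
  }
  which(!is.na(scores) & s >= best, arr.ind = TRUE)
}

#' Retain score peaks with greedy non-maximum suppression
#'
#' Finds local extrema of the requested polarity, keeps those strictly
#' beyond `threshold` (above for maxima, below for minima), and retains them
#' greedily from the most extreme, suppressing any candidate closer than
#' `nms_radius_px` (Euclidean) to an already retained one. Ties are broken
#' deterministically: lower row, then lower column wins.
#'
#' @param score_map A `foa_score_map` (or bare numeric matrix).
#' @param polarity `"max"` or `"min"`.
#' @param threshold Score cutoff.
#' @param nms_radius_px Suppression radius in pixels (> 0).
#' @return A tibble with `x`, `y`, `score`, ordered most extreme first. No
#'   two rows are closer than `nms_radius_px`.
#' @export
select_peaks <- function(score_map, polarity = c("max", "min"), threshold,
                         nms_radius_px) {
  polarity <- match.arg(polarity)
  check_number(threshold, "threshold")
  check_number(nms_radius_px, "nms_radius_px", lower = 0, strict_lower = TRUE)
  scores <- if (inherits(score_map, "foa_score_map")) score_map$scores else score_map
  if (!is.matrix(scores)) stop_parameter("`score_map` must be a foa_score_map or matrix.")
  idx <- local_extrema(scores, polarity)
  cands <- tibble(x = as.integer(idx[, 2]), y = as.integer(idx[, 1]),
                  score = scores[idx])
  nms_filter(cands, polarity, threshold, nms_radius_px)
}

# Threshold + greedy NMS on a candidate table (x, y, score); deterministic
# tie-break: lower row, then lower column.
nms_filter <- function(cands, polarity, threshold, nms_radius_px) {
  empty <- tibble(x = integer(), y = integer(), score = numeric())
  if (nrow(cands) == 0) return(empty)
  keep <- if (polarity == "max") cands$score > threshold else cands$score < threshold
  cands <- cands[keep, , drop = FALSE]
  if (nrow(cands) == 0) return(empty)
  ord <- order(if (polarity == "max") -cands$score else cands$score,
               cands$y, cands$x)
  cands <- cands[ord, , drop = FALSE]
  kept <- logical(nrow(cands))
  ky <- numeric(0); kx <- numeric(0)
  for (i in seq_len(nrow(cands))) {
    if (length(ky) == 0 ||
        all((ky - cands$y[i])^2 + (kx - cands$x[i])^2 >= nms_radius_px^2)) {
      kept[i] <- TRUE
      ky <- c(ky, cands$y[i]); kx <- c(kx, cands$x[i])
    }
  }
  cands[kept, , drop = FALSE]
}

# Cross-class conflict resolution: within nms_radius_px, keep the detection
# whose normalized margin over its threshold is larger.
resolve_cross_class <- function(live, dead, live_threshold, dead_threshold,
                                nms_radius_px, live_spread, dead_spread) {
  if (nrow(live) == 0 || nrow(dead) == 0) return(list(live = live, dead = dead))
  live_margin <- (live$score - live_threshold) / live_spread
  dead_margin <- (dead_threshold - dead$score) / dead_spread
  drop_live <- logical(nrow(live)); drop_dead <- logical(nrow(dead))
  for (i in seq_len(nrow(live))) {
    for (j in seq_len(nrow(dead))) {
      if (drop_live[i] || drop_dead[j]) next
      d2 <- (live$x[i] - dead$x[j])^2 + (live$y[i] - dead$y[j])^2
      if (d2 < nms_radius_px^2) {
        if (live_margin[i] >= dead_margin[j]) drop_dead[j] <- TRUE
        else drop_live[i] <- TRUE
      }
    }
  }
  list(live = live[!drop_live, , drop = FALSE],
       dead = dead[!drop_dead, , drop = FALSE])
}

#' Detect live and dead cells
#'
#' Runs [score_live()] and [score_dead()] with the same window, retains
#' peaks per class with [select_peaks()], then resolves cross-class
#' conflicts: when a live and a dead detection fall closer than
#' `nms_radius_px`, the one with the larger normalized score margin over its
#' threshold (margin divided by the spread of its valid score map) is kept.
#'
#' @param img Preprocessed grayscale matrix on \[0, 1\].
#' @param window A [make_hex_window()] mask.
#' @param live_threshold Minimum live score (interior minus ring mean). The
#'   live score is an intensity contrast, invariant to global shifts, so a
#'   fixed default works across exposure conditions.
#' @param dead_threshold Maximum dead score (window mean). The default
#'   (`NULL`) adapts to the image: the median of the valid dead-score map
#'   minus 0.095, i.e. just under the enhanced dead-cell/background
#'   contrast below the typical background window. Histogram equalization
#'   places the background at a data-dependent level, so an absolute default
#'   would not transfer between images.
#' @param nms_radius_px Suppression radius, typically about one cell
#'   diameter.
#' @return A list with tibbles `live` and `dead` (`x`, `y`, `score`,
#'   `label`), of class `foa_detections`.
#' @export
detect_cells <- function(img, window = make_hex_window(8),
                         live_threshold = 0.17, dead_threshold = NULL,
                         nms_radius_px = 13) {
  sl <- score_live(img, window)
  sd_ <- score_dead(img, window)
  if (is.null(dead_threshold)) {
    dead_threshold <- stats::median(sd_$scores, na.rm = TRUE) - 0.095
  }
  live <- select_peaks(sl, "max", live_threshold, nms_radius_px)
  dead <- select_peaks(sd_, "min", dead_threshold, nms_radius_px)
  spread <- function(m) {
    v <- m$scores[!is.na(m$scores)]
    d <- diff(range(v))
    if (d > 0) d else 1
  }
  res <- resolve_cross_class(live, dead, live_threshold, dead_threshold,
                             nms_radius_px, spread(sl), spread(sd_))
  live <- res$live; dead <- res$dead
  live$label <- rep("live", nrow(live))
  dead$label <- rep("dead", nrow(dead))
  structure(list(live = live, dead = dead), class = "foa_detections")
}

#' @export
print.foa_detections <- function(x, ...) {
  cat(sprintf("<foa_detections> %d live, %d dead\n", nrow(x$live), nrow(x$dead)))
  invisible(x)
}

#' Combine detections into one table
#'
#' @param det A `foa_detections` object.
#' @return One tibble with `x`, `y`, `score`, `label`.
#' @export
detections_table <- function(det) {
  if (!inherits(det, "foa_detections")) {
    stop_parameter("`det` must be a foa_detections object.")
  }
  dplyr::bind_rows(det$live, det$dead)
}

#' Binary candidate raster from detections
#'
#' Paints each detection as a small disk of foreground pixels, producing the
#' candidate mask consumed by the particle counter.
#'
#' @param detections Tibble with `x`, `y`.
#' @param shape Raster `(rows, cols)`.
#' @param dot_radius_px Painted disk radius (>= 1 guarantees each detection
#'   covers at least the minimum particle area).
#' @return A logical matrix.
#' @export
detections_mask <- function(detections, shape, dot_radius_px = 1.5) {
  shape <- check_shape(shape)
  mask <- matrix(FALSE, shape[1], shape[2])
  if (nrow(detections) == 0) return(mask)
  r <- ceiling(dot_radius_px)
  for (i in seq_len(nrow(detections))) {
    rr <- max(1, detections$y[i] - r):min(shape[1], detections$y[i] + r)
    cc <- max(1, detections$x[i] - r):min(shape[2], detections$x[i] + r)
    dy <- outer(rr - detections$y[i], rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - detections$x[i])
    mask[rr, cc] <- mask[rr, cc] | (dy^2 + dx^2 <= dot_radius_px^2)
  }
  mask
}
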