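#' Convert an RGB raster to grayscale
#'
#' Fixed BT.601 luma weights (0.299, 0.587, 0.114). Accepts values on
#' \[0, 1\] or 0--255 (8-bit inputs are rescaled); no intermediate
#' quantization is applied.
#'
#' @param rgb A `rows x cols x 3` numeric array.
#' @return A numeric matrix on \[0, 1\].
#' @export
to_grayscale <- function(rgb) {
  check_rgb_array(rgb)
  rgb <- as_unit_scale(rgb)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' sRGB to L*a*b* conversion
#'
#' Standard D65 sRGB -> CIE L*a*b* transform (via
#' [grDevices::convertColor()]). `L` is on 0--100, `a`/`b` roughly
#' -128..127.
#'
#' @param rgb A `rows x cols x 3` array on \[0, 1\] (or 0--255).
#' @return A list of matrices `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(rgb) {
  check_rgb_array(rgb)
  rgb <- as_unit_scale(rgb)
  if (min(rgb) < -1e-9 || max(rgb) > 1 + 1e-9) {
    stop_parameter("`rgb` values must lie in [0, 1] (or 0..255).")
  }
  d <- dim(rgb)
  m <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

#' L*a*b* to sRGB conversion
#'
#' Inverse of [rgb_to_lab()]; out-of-gamut values are clipped to \[0, 1\].
#'
#' @param L,a,b Matrices as returned by [rgb_to_lab()].
#' @return A `rows x cols x 3` array on \[0, 1\].
#' @export
lab_to_rgb <- function(L, a, b) {
  if (!is.matrix(L) || !all(dim(L) == dim(a)) || !all(dim(L) == dim(b))) {
    stop_parameter("`L`, `a`, `b` must be matrices of identical dimensions.")
  }
  if (min(L) < -1e-6 || max(L) > 100 + 1e-6) {
    stop_parameter("`L` must lie in [0, 100].")
  }
  m <- grDevices::convertColor(cbind(as.vector(L), as.vector(a), as.vector(b)),
                               from = "Lab", to = "sRGB")
  m <- pmin(pmax(m, 0), 1)
  array(m, dim = c(dim(L), 3L))
}

# Bin index on 0..n_bins-1 for working-scale values.
intensity_bin <- function(v, n_bins) {
  pmin(floor(v * n_bins), n_bins - 1L)
}

# Clipped, uniformly redistributed histogram -> CDF mapping (one pass).
# `counts` is a bins x tiles matrix; clip limit is a fraction of each tile's
# pixel count per bin.
clipped_cdf <- function(counts, clip_limit) {
  n_bins <- nrow(counts)
  totals <- colSums(counts)
  limit <- rep(clip_limit * totals, each = n_bins)
  clipped <- pmin(counts, limit)
  excess <- totals - colSums(clipped)
  clipped <- clipped + rep(excess / n_bins, each = n_bins)
  apply(clipped, 2, function(h) cumsum(h) / sum(h))
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a `num_tiles` grid; each tile's histogram is
#' clipped at `clip_limit` (a fraction of the tile's pixel count per bin,
#' so `clip_limit = 1` never clips), the excess mass is redistributed
#' uniformly over all bins in a single pass, and each tile's CDF becomes its
#' gray-level mapping. Every pixel is mapped by bilinear interpolation of
#' the four surrounding tile mappings; pixels in the border half-tiles use
#' the nearest available tiles. Output values lie in \[0, 1\] and the map is
#' monotone non-decreasing in the input for pixels sharing the same four
#' tiles.
#'
#' Defaults follow the device protocol: a 25 x 25 tile grid with clip limit
#' 0.1 suppresses the fiber-gap artifact and flattens uneven illumination
#' while keeping local cell contrast.
#'
#' @param img Numeric matrix on \[0, 1\].
#' @param num_tiles Integer `(rows, cols)` tile grid; the image must be at
#'   least this large.
#' @param clip_limit Contrast limit in (0.01, 1\].
#' @param n_bins Number of histogram bins.
#' @return A numeric matrix on \[0, 1\].
#' @export
clahe <- function(img, num_tiles = c(25, 25), clip_limit = 0.1, n_bins = 256) {
  check_gray_image(img)
  num_tiles <- check_shape(num_tiles)
  check_number(clip_limit, "clip_limit", lower = 0.01, upper = 1,
               strict_lower = TRUE)
  check_count(n_bins, "n_bins", lower = 1L)
  rows <- nrow(img); cols <- ncol(img)
  tr <- num_tiles[1]; tc <- num_tiles[2]
  if (rows < tr || cols < tc) {
    stop_parameter(sprintf(
      "Image (%d x %d) is smaller than the tile grid (%d x %d).",
      rows, cols, tr, tc))
  }
  img <- pmin(pmax(img, 0), 1)

  ti <- floor((seq_len(rows) - 1) * tr / rows)    # 0-based tile row per pixel row
  tj <- floor((seq_len(cols) - 1) * tc / cols)
  bin <- intensity_bin(img, n_bins)
  tile_id <- ti[row(img)] * tc + tj[col(img)]     # 0-based tile index
  counts <- matrix(
    tabulate(tile_id * n_bins + bin + 1L, nbins = tr * tc * n_bins),
    nrow = n_bins)
  maps <- clipped_cdf(counts, clip_limit)         # n_bins x (tr*tc)

  centers_r <- as.numeric(tapply(seq_len(rows), ti, mean))
  centers_c <- as.numeric(tapply(seq_len(cols), tj, mean))

  interp_index <- function(pos, centers) {
    i0 <- findInterval(pos, centers)
    i0 <- pmin(pmax(i0, 1L), length(centers))
    i1 <- pmin(i0 + 1L, length(centers))
    i0 <- ifelse(pos < centers[1], 1L, i0)
    w <- ifelse(i1 == i0, 0,
                (pos - centers[i0]) / (centers[i1] - centers[i0]))
    w <- pmin(pmax(w, 0), 1)
    list(i0 = i0, i1 = i1, w = w)
  }
  ri <- interp_index(seq_len(rows), centers_r)
  ci <- interp_index(seq_len(cols), centers_c)

  lookup <- function(tile_r, tile_c) {
    # value of each pixel under the mapping of tile (tile_r, tile_c)
    tid <- (tile_r[row(img)] - 1L) * tc + (tile_c[col(img)] - 1L)  # 0-based
    matrix(maps[bin + 1L + tid * n_bins], rows, cols)
  }
  wr <- matrix(ri$w, rows, cols)
  wc <- matrix(ci$w, rows, cols, byrow = TRUE)
  v00 <- lookup(ri$i0, ci$i0); v01 <- lookup(ri$i0, ci$i1)
  v10 <- lookup(ri$i1, ci$i0); v11 <- lookup(ri$i1, ci$i1)
  (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
}

#' Moving-template adaptive histogram equalization
#'
#' The reference per-pixel form of AHE: an odd `height x width` template
#' slides over the image line by line; at each position the histogram of the
#' covered window (with replicate padding at the borders) is equalized over
#' the full gray range and the transformed value replaces the center pixel.
#' Exact but O(N * window area); intended as the per-pixel oracle for
#' [clahe()] and for small images.
#'
#' @param img Numeric matrix on \[0, 1\].
#' @param height,width Odd window dimensions.
#' @param n_bins Number of histogram bins.
#' @return A numeric matrix on \[0, 1\].
#' @export
moving_window_equalize <- function(img, height = 15, width = 15, n_bins = 256) {
  check_gray_image(img)
  height <- check_count(height, "height", lower = 1L)
  width <- check_count(width, "width", lower = 1L)
  if (height %% 2L == 0L || width %% 2L == 0L) {
    stop_parameter("Window `height` and `width` must be odd so the center pixel is well defined.")
  }
  rows <- nrow(img); cols <- ncol(img)
  img <- pmin(pmax(img, 0), 1)
  bin <- intensity_bin(img, n_bins)
  hh <- (height - 1L) / 2L; hw <- (width - 1L) / 2L
  out <- matrix(0, rows, cols)
  for (r in seq_len(rows)) {
    rr <- pmin(pmax(r + (-hh:hh), 1L), rows)     # replicate padding via clamp
    for (c in seq_len(cols)) {
      cc <- pmin(pmax(c + (-hw:hw), 1L), cols)
      h <- tabulate(bin[rr, cc] + 1L, nbins = n_bins)
      cdf <- cumsum(h) / sum(h)
      out[r, c] <- cdf[bin[r, c] + 1L]
    }
  }
  out
}

#' Global histogram equalization
#'
#' Maps each pixel to the empirical CDF of its bin; the collapse case of
#' both [clahe()] (one tile, clip limit 1) and [moving_window_equalize()]
#' (window covering the image).
#'
#' @inheritParams moving_window_equalize
#' @return A numeric matrix on \[0, 1\].
#' @export
equalize_global <- function(img, n_bins = 256) {
  check_gray_image(img)
  img <- pmin(pmax(img, 0), 1)
  bin <- intensity_bin(img, n_bins)
  h <- tabulate(bin + 1L, nbins = n_bins)
  cdf <- cumsum(h) / sum(h)
  matrix(cdf[bin + 1L], nrow(img), ncol(img))
}

#' Full preprocessing pipeline
#'
#' Runs the device's enhancement chain: convert RGB to L*a*b*, scale the L
#' channel to \[0, 1\], apply [clahe()], rescale, convert back to sRGB, and
#' finally reduce to grayscale for detection. A grayscale matrix input is
#' replicated across channels first (so the chroma channels are neutral and
#' the chain reduces to CLAHE on the gray values up to quantization).
#'
#' @param img A `rows x cols x 3` RGB array or a grayscale matrix, values on
#'   \[0, 1\] or 0--255.
#' @param num_tiles,clip_limit,n_bins Passed to [clahe()].
#' @param keep_intermediates If `TRUE`, also return the enhanced L channel
#'   and the enhanced RGB array.
#' @return A grayscale matrix on \[0, 1\], or (with intermediates) a list
#'   with `gray`, `L_enhanced` (0--100) and `rgb_enhanced`.
#' @export
preprocess_pipeline <- function(img, num_tiles = c(25, 25), clip_limit = 0.1,
                                n_bins = 256, keep_intermediates = FALSE) {
  if (is.matrix(img)) {
    img <- as_unit_scale(img)
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  check_rgb_array(img)
  lab <- rgb_to_lab(img)
  L01 <- pmin(pmax(lab$L / 100, 0), 1)
  L_eq <- clahe(L01, num_tiles = num_tiles, clip_limit = clip_limit,
                n_bins = n_bins)
  rgb_enh <- lab_to_rgb(L_eq * 100, lab$a, lab$b)
  gray <- to_grayscale(rgb_enh)
  if (keep_intermediates) {
    list(gray = gray, L_enhanced = L_eq * 100, rgb_enhanced = rgb_enh)
  } else {
    gray
  }
}

#' Illumination flatness metric
#'
#' Ratio of the mean intensity in the central quarter (half the side length,
#' centered) to the mean over the border ring (everything outside the
#' central three-quarters). A value of 1 means flat illumination; the
#' preprocessing chain should move this ratio toward 1 on center-dark
#' scenes.
#'
#' @param img Numeric matrix.
#' @return A single number, center/border mean ratio.
#' @export
flatness_ratio <- function(img) {
  if (!is.matrix(img)) stop_parameter("`img` must be a matrix.")
  rows <- nrow(img); cols <- ncol(img)
  rc <- seq(floor(rows * 3 / 8) + 1, ceiling(rows * 5 / 8))
  cc <- seq(floor(cols * 3 / 8) + 1, ceiling(cols * 5 / 8))
  center <- mean(img[rc, cc])
  ring <- matrix(TRUE, rows, cols)
  ring[seq(floor(rows / 8) + 1, ceiling(rows * 7 / 8)),
       seq(floor(cols / 8) + 1, ceiling(cols * 7 / 8))] <- FALSE
  center / mean(img[ring])
}

#' Mean/median smoothing demonstration
#'
#' Plain box or median filtering, provided only to demonstrate why generic
#' smoothing fails on FOA micrographs (it blurs cell contours and fiber gaps
#' alike); not a pipeline stage.
#'
#' @param img Numeric matrix.
#' @param radius Half-width of the square neighborhood.
#' @param type `"mean"` or `"median"`.
#' @return The filtered matrix.
#' @export
smooth_demo <- function(img, radius = 2, type = c("mean", "median")) {
  type <- match.arg(type)
  if (!is.matrix(img)) stop_parameter("`img` must be a matrix.")
  radius <- check_count(radius, "radius", lower = 1L)
  rows <- nrow(img); cols <- ncol(img)
  out <- img
  f <- if (type == "mean") mean else stats::median
  for (r in seq_len(rows)) {
    rr <- max(1, r - radius):min(rows, r + radius)
    for (c in seq_len(cols)) {
      cc <- max(1, c - radius):min(cols, c + radius)
      out[r, c] <- f(img[rr, cc])
    }
  }
  out
}
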