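# Independent brute-force oracles. Each is written as a direct transcription
# of the mathematical definition (explicit loops, exhaustive enumeration),
# deliberately separate from the package's vectorized implementations.

# Nearest-lattice-center gain raster: enumerate every candidate center in an
# extended range and take the true minimum distance per pixel.
oracle_lattice <- function(spec, shape) {
  rows <- shape[1]; cols <- shape[2]
  p <- spec$pitch_px
  centers <- NULL
  if (spec$arrangement == "square") {
    ks <- seq(floor(-2), ceiling((rows + p) / p) + 2)
    ms <- seq(floor(-2), ceiling((cols + p) / p) + 2)
    for (k in ks) for (m in ms) centers <- rbind(centers, c(k * p, m * p))
  } else {
    s <- p * sqrt(3) / 2
    ks <- seq(-2, ceiling((rows + s) / s) + 2)
    for (k in ks) {
      ox <- (abs(k) %% 2) * p / 2
      ms <- seq(-3, ceiling((cols + p) / p) + 3)
      for (m in ms) centers <- rbind(centers, c(k * s, ox + m * p))
    }
  }
  out <- matrix(NA_real_, rows, cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      d <- sqrt((centers[, 1] - (r - 1))^2 + (centers[, 2] - (c - 1))^2)
      out[r, c] <- if (min(d) < spec$core_radius_px) spec$core_gain else spec$gap_gain
    }
  }
  out
}

# Global histogram equalization by definition.
oracle_global_he <- function(img, n_bins = 256) {
  bins <- pmin(floor(img * n_bins), n_bins - 1)
  out <- img
  n <- length(img)
  for (i in seq_along(img)) {
    out[i] <- sum(bins <= bins[i]) / n
  }
  out
}

# CLAHE by definition: per-tile clipped histogram CDFs, bilinear blend of
# the four surrounding tile mappings, nearest tile at the borders.
oracle_clahe <- function(img, num_tiles, clip_limit, n_bins = 256) {
  rows <- nrow(img); cols <- ncol(img)
  tr <- num_tiles[1]; tc <- num_tiles[2]
  tile_row <- function(r) floor((r - 1) * tr / rows) + 1
  tile_col <- function(c) floor((c - 1) * tc / cols) + 1
  bins <- pmin(floor(img * n_bins), n_bins - 1)

  cdfs <- vector("list", tr * tc)
  centers_r <- numeric(tr); centers_c <- numeric(tc)
  for (i in seq_len(tr)) centers_r[i] <- mean(which(tile_row(seq_len(rows)) == i))
  for (j in seq_len(tc)) centers_c[j] <- mean(which(tile_col(seq_len(cols)) == j))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      sel <- bins[tile_row(seq_len(rows)) == i,
                  tile_col(seq_len(cols)) == j, drop = FALSE]
      h <- numeric(n_bins)
      for (b in as.vector(sel)) h[b + 1] <- h[b + 1] + 1
      limit <- clip_limit * length(sel)
      excess <- sum(pmax(h - limit, 0))
      h <- pmin(h, limit) + excess / n_bins
      cdfs[[(i - 1) * tc + j]] <- cumsum(h) / sum(h)
    }
  }
  val <- function(i, j, b) cdfs[[(i - 1) * tc + j]][b + 1]
  out <- matrix(NA_real_, rows, cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      i1 <- max(which(centers_r <= r), 1); i2 <- min(i1 + 1, tr)
      if (r < centers_r[1]) { i1 <- i2 <- 1 }
      j1 <- max(which(centers_c <= c), 1); j2 <- min(j1 + 1, tc)
      if (c < centers_c[1]) { j1 <- j2 <- 1 }
      wy <- if (i2 == i1) 0 else (r - centers_r[i1]) / (centers_r[i2] - centers_r[i1])
      wx <- if (j2 == j1) 0 else (c - centers_c[j1]) / (centers_c[j2] - centers_c[j1])
      b <- bins[r, c]
      out[r, c] <- (1 - wy) * ((1 - wx) * val(i1, j1, b) + wx * val(i1, j2, b)) +
        wy * ((1 - wx) * val(i2, j1, b) + wx * val(i2, j2, b))
    }
  }
  out
}

# Per-pixel windowed equalization by definition (replicate padding).
oracle_ahe <- function(img, height, width, n_bins = 256) {
  rows <- nrow(img); cols <- ncol(img)
  bins <- pmin(floor(img * n_bins), n_bins - 1)
  hh <- (height - 1) / 2; hw <- (width - 1) / 2
  out <- matrix(NA_real_, rows, cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      vals <- c()
      for (dr in -hh:hh) {
        for (dc in -hw:hw) {
          rr <- min(max(r + dr, 1), rows)
          cc <- min(max(c + dc, 1), cols)
          vals <- c(vals, bins[rr, cc])
        }
      }
      out[r, c] <- sum(vals <= bins[r, c]) / length(vals)
    }
  }
  out
}

# Point-in-hexagon membership by the six explicit half-plane inequalities
# (flat-topped hexagon, circumradius R), plus the boundary-slack split.
oracle_hex_membership <- function(dx, dy, R, ring_t) {
  a <- R * sqrt(3) / 2
  slack <- min(
    a - dy, a + dy,
    a - (sqrt(3) * dx + dy) / 2, a + (sqrt(3) * dx + dy) / 2,
    a - (sqrt(3) * dx - dy) / 2, a + (sqrt(3) * dx - dy) / 2
  )
  if (slack < -1e-9) "outside" else if (slack < ring_t) "ring" else "interior"
}

# Exhaustive sliding-window score evaluation.
oracle_score <- function(img, window, mode) {
  rows <- nrow(img); cols <- ncol(img)
  my <- max(abs(window$offsets[, 1])); mx <- max(abs(window$offsets[, 2]))
  out <- matrix(NA_real_, rows, cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (r <= my || r > rows - my || c <= mx || c > cols - mx) next
      if (mode == "live") {
        vi <- mean(apply(window$interior, 1, function(o) img[r + o[1], c + o[2]]))
        ve <- mean(apply(window$ring, 1, function(o) img[r + o[1], c + o[2]]))
        out[r, c] <- vi - ve
      } else {
        out[r, c] <- mean(apply(window$offsets, 1,
                                function(o) img[r + o[1], c + o[2]]))
      }
    }
  }
  out
}

# Greedy NMS by direct enumeration over a score matrix: local extrema
# (plateau-inclusive 8-neighborhood), threshold, then repeated selection of
# the most extreme remaining candidate outside all kept radii.
oracle_nms <- function(scores, polarity, threshold, radius) {
  rows <- nrow(scores); cols <- ncol(scores)
  cands <- NULL
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (is.na(scores[r, c])) next
      is_ext <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > rows || cc < 1 || cc > cols) next
        if (is.na(scores[rr, cc])) next
        if (polarity == "max" && scores[rr, cc] > scores[r, c]) is_ext <- FALSE
        if (polarity == "min" && scores[rr, cc] < scores[r, c]) is_ext <- FALSE
      }
      ok <- if (polarity == "max") scores[r, c] > threshold else scores[r, c] < threshold
      if (is_ext && ok) cands <- rbind(cands, c(r, c, scores[r, c]))
    }
  }
  kept <- NULL
  while (!is.null(cands) && nrow(cands) > 0) {
    key <- if (polarity == "max") -cands[, 3] else cands[, 3]
    best <- order(key, cands[, 1], cands[, 2])[1]
    b <- cands[best, ]
    suppressed <- if (is.null(kept)) FALSE else {
      any((kept[, 1] - b[1])^2 + (kept[, 2] - b[2])^2 < radius^2)
    }
    if (!suppressed) kept <- rbind(kept, b)
    cands <- cands[-best, , drop = FALSE]
  }
  if (is.null(kept)) {
    data.frame(y = numeric(0), x = numeric(0), score = numeric(0))
  } else {
    data.frame(y = kept[, 1], x = kept[, 2], score = kept[, 3])
  }
}

# Connected components via igraph on the pixel-adjacency graph.
oracle_component_areas <- function(mask, connectivity) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(integer(0))
  id <- seq_len(n)
  edges <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dy <- abs(idx[i, 1] - idx[j, 1]); dx <- abs(idx[i, 2] - idx[j, 2])
      adj <- if (connectivity == 4) dy + dx == 1 else max(dy, dx) == 1
      if (adj) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  as.integer(sort(comp$csize))
}
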