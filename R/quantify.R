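# Connected-component labeling by iterative flood fill.
# connectivity: 4 or 8. Returns integer matrix of labels (0 = background).
label_components <- function(mask, connectivity = 8) {
  rows <- nrow(mask); cols <- ncol(mask)
  labels <- matrix(0L, rows, cols)
  if (connectivity == 4) {
    nb <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    nb <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
    nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), , drop = FALSE]
  }
  current <- 0L
  fg <- which(mask)
  for (start in fg) {
    if (labels[start] != 0L) next
    current <- current + 1L
    stack <- start
    labels[start] <- current
    while (length(stack) > 0) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pr <- ((p - 1L) %% rows) + 1L
      pc <- ((p - 1L) %/% rows) + 1L
      for (k in seq_len(nrow(nb))) {
        qr <- pr + nb[k, 1]; qc <- pc + nb[k, 2]
        if (qr >= 1 && qr <= rows && qc >= 1 && qc <= cols &&
            mask[qr, qc] && labels[qr, qc] == 0L) {
          labels[qr, qc] <- current
          stack <- c(stack, (qc - 1L) * rows + qr)
        }
      }
    }
  }
  labels
}

#' Count particles in a binary mask
#'
#' ImageJ-style "Analyze Particles": connected components of foreground
#' pixels with area at least `min_area_px` (no upper size limit) are counted
#' as cells; smaller specks are discarded. The default minimum of 2 pixels
#' follows the device counting protocol.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param min_area_px Minimum component area in pixels.
#' @param connectivity 4 or 8 (default 8, matching ImageJ's default).
#' @return A tibble with one row per retained particle: `particle`, `area`,
#'   `x`, `y` (area centroid). The particle count is `nrow()` of the result.
#' @export
count_particles <- function(mask, min_area_px = 2, connectivity = 8) {
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) {
      stop_parameter("`mask` must be binary (logical or 0/1).")
    }
    mask <- mask == 1
  }
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_parameter("`mask` must be a logical matrix.")
  }
  check_count(min_area_px, "min_area_px", lower = 1L)
  if (!connectivity %in% c(4, 8)) {
    stop_parameter("`connectivity` must be 4 or 8.")
  }
  labels <- label_components(mask, connectivity)
  n <- max(labels)
  if (n == 0L) {
    return(tibble(particle = integer(), area = integer(),
                  x = numeric(), y = numeric()))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  pr <- ((idx - 1L) %% nrow(mask)) + 1L
  pc <- ((idx - 1L) %/% nrow(mask)) + 1L
  out <- tibble(lab = lab, y = pr, x = pc) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(area = dplyr::n(), x = mean(.data$x), y = mean(.data$y),
                     .groups = "drop") |>
    dplyr::filter(.data$area >= min_area_px) |>
    dplyr::arrange(.data$lab)
  tibble(particle = seq_len(nrow(out)), area = as.integer(out$area),
         x = out$x, y = out$y)
}

#' Flag clustered ground-truth cells
#'
#' A cell is a cluster member if any other cell (of either label) lies
#' closer than `min_sep_px`; the relation is symmetric, so both partners are
#' flagged. Clustered cells are excluded from identification-rate
#' denominators, mirroring the manual protocol's "except for the cell
#' clusters".
#'
#' @param gt Ground-truth tibble with `x`, `y`.
#' @param min_sep_px Separation threshold (> 0). A practical default is
#'   1.5x the mean cell diameter.
#' @return A logical vector, `TRUE` for flagged (excluded) cells.
#' @export
flag_clusters <- function(gt, min_sep_px) {
  check_number(min_sep_px, "min_sep_px", lower = 0, strict_lower = TRUE)
  n <- nrow(gt)
  if (n < 2) return(rep(FALSE, n))
  d <- as.matrix(dist(cbind(gt$x, gt$y)))
  diag(d) <- Inf
  unname(apply(d < min_sep_px, 1, any))
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching by increasing distance among same-label
#' (detection, ground truth) pairs within `max_dist_px`. Cluster-member
#' ground-truth cells (per `flag_clusters()` when `cluster_min_sep_px` is
#' given, else the `cluster_member` column if present) are excluded from
#' matching and from the rate denominator. Detections landing within
#' `max_dist_px` of an excluded cluster cell are set aside as `cluster_hits`
#' rather than counted as false detections; all other unmatched detections
#' are false detections.
#'
#' Conservation holds per class: matched + missed + excluded = total ground
#' truth.
#'
#' @param detections Tibble with `x`, `y`, `label` (from [detect_cells()] /
#'   [detections_table()]).
#' @param gt Ground-truth tibble with `x`, `y`, `label` and optionally
#'   `cluster_member`.
#' @param max_dist_px Maximum match distance (> 0).
#' @param exclude_clusters Exclude clustered ground truth from the
#'   denominator.
#' @param cluster_min_sep_px Optional separation used to (re)flag clusters
#'   geometrically; if `NULL`, the `cluster_member` column is used.
#' @return A `foa_match` object: list of tibbles `pairs`, `misses`,
#'   `false_detections`, `cluster_hits`, `excluded`; see [glance.foa_match()].
#' @export
match_detections <- function(detections, gt, max_dist_px = 10,
                             exclude_clusters = TRUE,
                             cluster_min_sep_px = NULL) {
  check_number(max_dist_px, "max_dist_px", lower = 0, strict_lower = TRUE)
  if (inherits(detections, "foa_detections")) {
    detections <- detections_table(detections)
  }
  detections <- as_tibble(detections)
  gt <- as_tibble(gt)
  excluded_flag <- rep(FALSE, nrow(gt))
  if (exclude_clusters && nrow(gt) > 0) {
    if (!is.null(cluster_min_sep_px)) {
      excluded_flag <- flag_clusters(gt, cluster_min_sep_px)
    } else if ("cluster_member" %in% names(gt)) {
      excluded_flag <- gt$cluster_member
    }
  }
  gt$gt_id <- seq_len(nrow(gt))
  detections$det_id <- seq_len(nrow(detections))
  gt_open <- gt[!excluded_flag, , drop = FALSE]
  excluded <- gt[excluded_flag, , drop = FALSE]

  pairs <- tibble(det_id = integer(), gt_id = integer(),
                  label = character(), dist = numeric())
  if (nrow(detections) > 0 && nrow(gt_open) > 0) {
    cand <- tidyr::expand_grid(di = seq_len(nrow(detections)),
                               gi = seq_len(nrow(gt_open))) |>
      dplyr::filter(detections$label[.data$di] == gt_open$label[.data$gi])
    if (nrow(cand) > 0) {
      cand$dist <- sqrt(
        (detections$x[cand$di] - gt_open$x[cand$gi])^2 +
          (detections$y[cand$di] - gt_open$y[cand$gi])^2)
      cand <- cand |>
        dplyr::filter(.data$dist <= max_dist_px) |>
        dplyr::arrange(.data$dist, .data$di, .data$gi)
      used_d <- logical(nrow(detections)); used_g <- logical(nrow(gt_open))
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!used_d[cand$di[i]] && !used_g[cand$gi[i]]) {
          keep[i] <- TRUE
          used_d[cand$di[i]] <- TRUE
          used_g[cand$gi[i]] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- tibble(det_id = detections$det_id[cand$di],
                      gt_id = gt_open$gt_id[cand$gi],
                      label = detections$label[cand$di],
                      dist = cand$dist)
    }
  }
  un_det <- detections[!detections$det_id %in% pairs$det_id, , drop = FALSE]
  cluster_hit <- rep(FALSE, nrow(un_det))
  if (nrow(un_det) > 0 && nrow(excluded) > 0) {
    for (i in seq_len(nrow(un_det))) {
      same <- excluded[excluded$label == un_det$label[i], , drop = FALSE]
      if (nrow(same) > 0) {
        d <- sqrt((same$x - un_det$x[i])^2 + (same$y - un_det$y[i])^2)
        cluster_hit[i] <- any(d <= max_dist_px)
      }
    }
  }
  structure(
    list(
      pairs = pairs,
      misses = gt_open[!gt_open$gt_id %in% pairs$gt_id, , drop = FALSE],
      false_detections = un_det[!cluster_hit, , drop = FALSE],
      cluster_hits = un_det[cluster_hit, , drop = FALSE],
      excluded = excluded,
      n_gt = nrow(gt)
    ),
    class = "foa_match"
  )
}

#' @export
print.foa_match <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<foa_match> %d/%d live (%.1f%%), %d/%d dead (%.1f%%), %d false, %d excluded clusters\n",
    g$live_matched, g$live_gt, g$live_rate_pct,
    g$dead_matched, g$dead_gt, g$dead_rate_pct,
    g$false_detections, g$excluded))
  invisible(x)
}

#' Identification percentage
#'
#' The viability benchmark statistic: matched (correctly identified) cells
#' over ground-truth cells of that class, as a percentage reported to one
#' decimal place.
#'
#' @param n_detected_matched Number of detected-and-matched cells.
#' @param n_gt Ground-truth (or manually counted) cells; must be > 0.
#' @return A percentage in \[0, 100\], rounded to one decimal.
#' @export
identification_rate <- function(n_detected_matched, n_gt) {
  n_detected_matched <- check_count(n_detected_matched, "n_detected_matched")
  n_gt <- check_count(n_gt, "n_gt")
  if (n_gt == 0L) {
    stop_parameter("`n_gt` must be positive: the identification rate is undefined for zero cells.")
  }
  if (n_detected_matched > n_gt) {
    stop_parameter("`n_detected_matched` cannot exceed `n_gt`.")
  }
  round(100 * n_detected_matched / n_gt, 1)
}

match_class_counts <- function(m, lab) {
  open_gt <- m$n_gt - nrow(m$excluded)
  matched <- sum(m$pairs$label == lab)
  gt_open <- sum(m$misses$label == lab) + matched
  list(matched = matched, gt = gt_open,
       false_det = sum(m$false_detections$label == lab))
}

#' @describeIn match_detections One-row summary: per-class ground truth,
#'   matched counts, identification percentages, false detections.
#' @param x A `foa_match` object.
#' @param ... Unused.
#' @export
glance.foa_match <- function(x, ...) {
  lv <- match_class_counts(x, "live")
  dd <- match_class_counts(x, "dead")
  tibble(
    live_gt = lv$gt, live_matched = lv$matched,
    live_rate_pct = if (lv$gt > 0) identification_rate(lv$matched, lv$gt) else NA_real_,
    dead_gt = dd$gt, dead_matched = dd$matched,
    dead_rate_pct = if (dd$gt > 0) identification_rate(dd$matched, dd$gt) else NA_real_,
    false_detections = lv$false_det + dd$false_det,
    cluster_hits = nrow(x$cluster_hits),
    excluded = nrow(x$excluded)
  )
}

#' @describeIn match_detections Matched pairs as a tibble.
#' @export
tidy.foa_match <- function(x, ...) x$pairs
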