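# Per-scene detector state reused across threshold evaluations: preprocessed
# image, local-extrema candidate lists and score-map spreads.
scene_candidates <- function(scene, window, num_tiles, clip_limit,
                             preprocess = TRUE) {
  img <- scene_image(scene)
  if (preprocess) {
    img <- clahe(img, num_tiles = num_tiles, clip_limit = clip_limit)
  }
  sl <- score_live(img, window)
  sd_ <- score_dead(img, window)
  spread <- function(m) {
    v <- m$scores[!is.na(m$scores)]
    d <- diff(range(v))
    if (d > 0) d else 1
  }
  cand_of <- function(m, polarity) {
    idx <- local_extrema(m$scores, polarity)
    tibble(x = as.integer(idx[, 2]), y = as.integer(idx[, 1]),
           score = m$scores[idx])
  }
  list(
    gt = scene$gt,
    live = cand_of(sl, "max"),
    dead = cand_of(sd_, "min"),
    live_spread = spread(sl),
    dead_spread = spread(sd_)
  )
}

# Counts (matched, open gt, false detections per class) for one scene at one
# threshold pair.
evaluate_scene_at <- function(cand, live_threshold, dead_threshold,
                              nms_radius_px, max_dist_px) {
  live <- nms_filter(cand$live, "max", live_threshold, nms_radius_px)
  dead <- nms_filter(cand$dead, "min", dead_threshold, nms_radius_px)
  res <- resolve_cross_class(live, dead, live_threshold, dead_threshold,
                             nms_radius_px, cand$live_spread, cand$dead_spread)
  live <- res$live; dead <- res$dead
  live$label <- rep("live", nrow(live))
  dead$label <- rep("dead", nrow(dead))
  m <- match_detections(dplyr::bind_rows(live, dead), cand$gt,
                        max_dist_px = max_dist_px)
  lv <- match_class_counts(m, "live")
  dd <- match_class_counts(m, "dead")
  c(live_matched = lv$matched, live_gt = lv$gt, live_false = lv$false_det,
    dead_matched = dd$matched, dead_gt = dd$gt, dead_false = dd$false_det)
}

#' k-fold cross-validated threshold selection and identification rates
#'
#' Partitions the scenes into `k` folds by a seeded shuffle. For each fold,
#' the live and dead score thresholds are chosen on the other `k - 1` folds
#' by grid search, maximizing the mean identification rate minus the
#' false-detection rate (false detections as a fraction of ground truth,
#' both averaged over the two classes); the chosen pair is then evaluated on
#' the held-out fold. The thresholds are the pipeline's only free
#' parameters, so this is what the cross-validation selects.
#'
#' @param scenes A list of `foa_scene` objects (at least `k`).
#' @param k Number of folds.
#' @param live_grid,dead_grid Candidate thresholds for the live (interior
#'   minus ring) and dead (window mean) scores.
#' @param window A [make_hex_window()] mask.
#' @param nms_radius_px Suppression radius in pixels.
#' @param max_dist_px Match distance for [match_detections()].
#' @param num_tiles,clip_limit CLAHE parameters used when `preprocess` is
#'   `TRUE`.
#' @param preprocess Run [clahe()] on each scene before scoring.
#' @param seed Integer seed for the fold shuffle.
#' @return A `foa_cv` object; see [tidy.foa_cv()] and [glance.foa_cv()].
#'   Contains `folds` (per-fold rates and chosen thresholds) and `means`.
#' @export
kfold_evaluate <- function(scenes, k = 5,
                           live_grid = seq(0.14, 0.26, by = 0.02),
                           dead_grid = seq(0.39, 0.47, by = 0.01),
                           window = make_hex_window(8),
                           nms_radius_px = 13,
                           max_dist_px = 10,
                           num_tiles = c(25, 25),
                           clip_limit = 0.1,
                           preprocess = TRUE,
                           seed = 1) {
  k <- check_count(k, "k", lower = 2L)
  check_count(seed, "seed")
  if (!is.list(scenes) || length(scenes) < k) {
    stop_parameter(sprintf("Need at least k = %d scenes (got %d).",
                           k, length(scenes)))
  }
  n <- length(scenes)
  fold_of <- withr::with_seed(seed, {
    rep_len(seq_len(k), n)[sample.int(n)]
  })

  cands <- lapply(scenes, scene_candidates, window = window,
                  num_tiles = num_tiles, clip_limit = clip_limit,
                  preprocess = preprocess)
  grid <- tidyr::expand_grid(live_threshold = live_grid,
                             dead_threshold = dead_grid)
  # counts per scene x grid point, computed once and aggregated per fold
  counts <- array(0, dim = c(n, nrow(grid), 6L))
  for (s in seq_len(n)) {
    for (g in seq_len(nrow(grid))) {
      counts[s, g, ] <- evaluate_scene_at(
        cands[[s]], grid$live_threshold[g], grid$dead_threshold[g],
        nms_radius_px, max_dist_px)
    }
  }
  objective <- function(tot) {
    live_rate <- if (tot[2] > 0) tot[1] / tot[2] else 0
    dead_rate <- if (tot[5] > 0) tot[4] / tot[5] else 0
    false_rate <- (tot[3] + tot[6]) / max(tot[2] + tot[5], 1)
    (live_rate + dead_rate) / 2 - false_rate
  }
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    train <- which(fold_of != f); test <- which(fold_of == f)
    agg <- function(rows, g) apply(counts[rows, g, , drop = FALSE], 3, sum)
    obj <- vapply(seq_len(nrow(grid)), function(g) objective(agg(train, g)),
                  numeric(1))
    best <- which.max(obj)
    tot <- agg(test, best)
    tibble(
      fold = f,
      live_threshold = grid$live_threshold[best],
      dead_threshold = grid$dead_threshold[best],
      live_gt = tot[2], live_matched = tot[1],
      dead_gt = tot[5], dead_matched = tot[4],
      live_rate_pct = if (tot[2] > 0) identification_rate(tot[1], tot[2]) else NA_real_,
      dead_rate_pct = if (tot[5] > 0) identification_rate(tot[4], tot[5]) else NA_real_,
      false_detections = tot[3] + tot[6],
      false_rate_pct = round(100 * (tot[3] + tot[6]) / max(tot[2] + tot[5], 1), 1)
    )
  })
  structure(
    list(
      folds = folds,
      means = list(
        live_rate_pct = mean(folds$live_rate_pct, na.rm = TRUE),
        dead_rate_pct = mean(folds$dead_rate_pct, na.rm = TRUE),
        false_rate_pct = mean(folds$false_rate_pct)
      ),
      k = k, seed = as.integer(seed), fold_of = fold_of
    ),
    class = "foa_cv"
  )
}

#' @export
print.foa_cv <- function(x, ...) {
  cat(sprintf(
    "<foa_cv> %d folds: fold-mean identification %.1f%% live, %.1f%% dead; false detections %.1f%% of gt\n",
    x$k, x$means$live_rate_pct, x$means$dead_rate_pct, x$means$false_rate_pct))
  invisible(x)
}

#' Per-fold cross-validation results
#'
#' @param x A `foa_cv` object from [kfold_evaluate()].
#' @param ... Unused.
#' @return A tibble with one row per fold: chosen thresholds, per-class
#'   matched/ground-truth counts, identification percentages and the
#'   false-detection percentage.
#' @export
tidy.foa_cv <- function(x, ...) x$folds

#' Fold-mean cross-validation summary
#'
#' @inheritParams tidy.foa_cv
#' @return A one-row tibble: `k`, fold-mean live/dead identification
#'   percentages and fold-mean false-detection percentage.
#' @export
glance.foa_cv <- function(x, ...) {
  tibble(
    k = x$k,
    live_rate_pct = x$means$live_rate_pct,
    dead_rate_pct = x$means$dead_rate_pct,
    false_rate_pct = x$means$false_rate_pct
  )
}
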