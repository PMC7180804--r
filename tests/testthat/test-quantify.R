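test_that("particle counting applies the minimum-area rule", {
  m <- matrix(FALSE, 8, 8)
  expect_equal(nrow(count_particles(m)), 0)
  # one single-pixel speck and one 2-pixel component: only the latter counts
  m[2, 2] <- TRUE
  m[6, 6] <- TRUE; m[6, 7] <- TRUE
  parts <- count_particles(m, min_area_px = 2)
  expect_equal(nrow(parts), 1)
  expect_equal(parts$area, 2L)
  expect_equal(c(parts$x, parts$y), c(6.5, 6))
  # with min_area 1 both count
  expect_equal(nrow(count_particles(m, min_area_px = 1)), 2)
  expect_error(count_particles(matrix(0.5, 3, 3)),
               class = "foascope_parameter_error")
})

test_that("component areas equal the igraph flood-fill oracle", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (rep in 1:3) {
    mask <- matrix(runif(32 * 32) < 0.35, 32, 32)
    for (conn in c(4, 8)) {
      parts <- count_particles(mask, min_area_px = 1, connectivity = conn)
      expect_equal(sort(as.integer(parts$area)),
                   oracle_component_areas(mask, conn),
                   info = sprintf("rep %d conn %d", rep, conn))
    }
  }
})

test_that("diagonal adjacency separates 4- from 8-connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(nrow(count_particles(m, 1, connectivity = 8)), 1)
  expect_equal(nrow(count_particles(m, 1, connectivity = 4)), 2)
})

test_that("identification rate reproduces the worked-example percentages", {
  expect_equal(identification_rate(129, 139), 92.8)
  expect_equal(identification_rate(183, 214), 85.5)
  expect_equal(identification_rate(0, 57), 0)
  expect_equal(identification_rate(57, 57), 100)
  expect_error(identification_rate(1, 0), class = "foascope_parameter_error")
  expect_error(identification_rate(5, 3), class = "foascope_parameter_error")
})

test_that("cluster flagging equals the brute-force pairwise check", {
  set.seed(43)
  gt <- tibble::tibble(x = runif(25, 0, 100), y = runif(25, 0, 100),
                       label = sample(c("live", "dead"), 25, replace = TRUE))
  flags <- flag_clusters(gt, min_sep_px = 15)
  for (i in seq_len(25)) {
    near <- FALSE
    for (j in seq_len(25)) {
      if (i != j &&
          sqrt((gt$x[i] - gt$x[j])^2 + (gt$y[i] - gt$y[j])^2) < 15) near <- TRUE
    }
    expect_equal(flags[i], near, info = i)
  }
  # well-separated -> none flagged; coincident -> both flagged
  apart <- tibble::tibble(x = c(0, 100), y = c(0, 0))
  expect_equal(flag_clusters(apart, 15), c(FALSE, FALSE))
  co <- tibble::tibble(x = c(5, 5), y = c(5, 5))
  expect_equal(flag_clusters(co, 15), c(TRUE, TRUE))
})

test_that("matching is one-to-one, conservative, and handles edge cases", {
  gt <- tibble::tibble(x = c(10, 40, 70), y = c(10, 40, 70),
                       label = c("live", "live", "dead"),
                       cluster_member = FALSE)
  det <- tibble::tibble(x = c(10, 40, 70), y = c(10, 40, 70),
                        label = c("live", "live", "dead"), score = 1)
  m <- match_detections(det, gt, max_dist_px = 5)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(nrow(m$misses), 0)
  expect_equal(nrow(m$false_detections), 0)
  # empty detections: all gt missed
  m0 <- match_detections(det[0, ], gt, max_dist_px = 5)
  expect_equal(nrow(m0$pairs), 0)
  expect_equal(nrow(m0$misses), 3)
  # label mismatch is never matched
  swapped <- det; swapped$label <- c("dead", "dead", "live")
  ms <- match_detections(swapped, gt, max_dist_px = 5)
  expect_equal(nrow(ms$pairs), 0)
  expect_equal(nrow(ms$false_detections), 3)
  # conservation: matched + missed + excluded = total gt
  g <- glance(m)
  expect_equal(g$live_matched + nrow(m$misses[m$misses$label == "live", ]) +
                 sum(m$excluded$label == "live"), 2)
})

test_that("greedy matching agrees with exhaustive assignment when unambiguous", {
  set.seed(47)
  gt <- tibble::tibble(x = c(10, 30, 50, 70, 90), y = c(20, 60, 15, 80, 45),
                       label = "live", cluster_member = FALSE)
  det <- tibble::tibble(x = gt$x + runif(5, -2, 2), y = gt$y + runif(5, -2, 2),
                        label = "live", score = 1)
  m <- match_detections(det, gt, max_dist_px = 8)
  # exhaustive: all 5! assignments, minimize total distance
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in all_perms(1:5)) {
    cost <- sum(sqrt((det$x - gt$x[p])^2 + (det$y - gt$y[p])^2))
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  got <- m$pairs[order(m$pairs$det_id), ]
  expect_equal(got$gt_id, best)
})

test_that("cluster exclusion removes clustered gt from the denominator", {
  gt <- tibble::tibble(
    x = c(10, 50, 52, 90), y = c(10, 50, 50, 90),
    label = c("live", "live", "live", "live"),
    cluster_member = c(FALSE, TRUE, TRUE, FALSE))
  det <- tibble::tibble(x = c(10, 51, 90), y = c(10, 50, 90),
                        label = "live", score = 1)
  m <- match_detections(det, gt, max_dist_px = 5)
  expect_equal(nrow(m$excluded), 2)
  expect_equal(nrow(m$pairs), 2)          # the two isolated cells
  expect_equal(nrow(m$cluster_hits), 1)   # detection on the cluster
  expect_equal(nrow(m$false_detections), 0)
  g <- glance(m)
  expect_equal(g$live_gt, 2)
  expect_equal(g$live_rate_pct, 100)
  # geometric re-flagging finds the same clusters
  m2 <- match_detections(det, gt[, c("x", "y", "label")], max_dist_px = 5,
                         cluster_min_sep_px = 10)
  expect_equal(nrow(m2$excluded), 2)
})

test_that("k-fold evaluation is deterministic and structurally sound", {
  scenes <- lapply(c(2, 6, 9, 13), function(s) {
    tiny_scene(seed = s, noise_sigma = 0.01, n_live = 4, n_dead = 4,
               shape = c(160, 160))
  })
  cv <- kfold_evaluate(scenes, k = 4, live_grid = c(0.16, 0.2),
                       dead_grid = c(0.42, 0.44), seed = 11)
  folds <- tidy(cv)
  expect_equal(nrow(folds), 4)
  expect_equal(sort(unique(cv$fold_of)), 1:4)     # leave-one-out structure
  expect_true(all(table(cv$fold_of) == 1))
  expect_true(all(folds$live_rate_pct >= 0 & folds$live_rate_pct <= 100,
                  na.rm = TRUE))
  cv2 <- kfold_evaluate(scenes, k = 4, live_grid = c(0.16, 0.2),
                        dead_grid = c(0.42, 0.44), seed = 11)
  expect_identical(tidy(cv), tidy(cv2))
  expect_error(kfold_evaluate(scenes[1:2], k = 4),
               class = "foascope_parameter_error")
  g <- glance(cv)
  expect_named(g, c("k", "live_rate_pct", "dead_rate_pct", "false_rate_pct"))
})
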