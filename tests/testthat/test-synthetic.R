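test_that("degenerate gains give a constant lattice raster", {
  spec <- fiber_lattice_spec(core_radius_px = 1.5, pitch_px = 4,
                             core_gain = 1, gap_gain = 1)
  expect_equal(render_fiber_lattice(spec, c(10, 10)), matrix(1, 10, 10))
})

test_that("lattice rasters match the exhaustive nearest-center oracle", {
  for (arr in c("square", "hexagonal")) {
    spec <- fiber_lattice_spec(core_radius_px = 1.5, pitch_px = 4,
                               arrangement = arr, core_gain = 0.9,
                               gap_gain = 0.3)
    got <- render_fiber_lattice(spec, c(8, 8))
    expect_equal(got, oracle_lattice(spec, c(8, 8)), info = arr)
  }
  # non-trivial radius/pitch combination
  spec <- fiber_lattice_spec(core_radius_px = 2.6, pitch_px = 6.5,
                             arrangement = "hexagonal", gap_gain = 0.5)
  expect_equal(render_fiber_lattice(spec, c(13, 11)),
               oracle_lattice(spec, c(13, 11)))
})

test_that("hexagonal core pixel fraction approaches the packing formula", {
  spec <- fiber_lattice_spec(core_radius_px = 3, pitch_px = 7)
  g <- render_fiber_lattice(spec, c(400, 400))
  frac <- mean(g == spec$core_gain)
  expected <- pi / (2 * sqrt(3)) * (spec$core_radius_px / (spec$pitch_px / 2))^2
  expect_lt(abs(frac - expected), 0.02)
})

test_that("illumination raster obeys the closed form and is radially monotone", {
  spec <- illumination_spec(center_level = 0.5, edge_level = 1,
                            profile = "radial_quadratic")
  g <- render_illumination(spec, c(101, 101))
  # exact center pixel
  expect_equal(g[51, 51], 0.5)
  # closed form 0.5 + 0.5 t^2 at an arbitrary pixel, t computed from geometry
  rmax <- sqrt(50^2 + 50^2)
  t <- sqrt((80 - 51)^2 + (30 - 51)^2) / rmax
  expect_equal(g[80, 30], 0.5 + 0.5 * t^2)
  # t = 0.5 example: a synthetic evaluation point on the diagonal
  t_half <- 0.5
  expect_equal(spec$center_level +
                 (spec$edge_level - spec$center_level) * t_half^2, 0.625)
  # monotone along rays from the center (rows, cols, diagonal)
  expect_true(all(diff(g[51, 51:101]) >= 0))
  expect_true(all(diff(g[51:101, 51]) >= 0))
  expect_true(all(diff(diag(g[51:101, 51:101])) >= 0))
  # equal levels -> constant raster
  flat <- illumination_spec(center_level = 0.8, edge_level = 0.8)
  expect_equal(render_illumination(flat, c(21, 21)), matrix(0.8, 21, 21))
  # center brighter than edge is rejected
  expect_error(illumination_spec(center_level = 0.9, edge_level = 0.5),
               class = "foascope_parameter_error")
})

test_that("placement respects separation, counts, and determinism", {
  spec <- cell_population_spec(n_live = 10, n_dead = 10,
                               min_separation_px = 26, cluster_fraction = 0)
  gt <- place_cells(spec, c(256, 256), seed = 3)
  expect_equal(nrow(gt), 20)
  expect_equal(sum(gt$label == "live"), 10)
  expect_equal(sum(gt$label == "dead"), 10)
  # brute-force pairwise check
  d <- as.matrix(dist(cbind(gt$x, gt$y)))
  diag(d) <- Inf
  expect_true(all(d >= 26))
  # disks inside the image
  expect_true(all(gt$x - gt$radius_px >= 0 & gt$x + gt$radius_px <= 256))
  expect_true(all(gt$y - gt$radius_px >= 0 & gt$y + gt$radius_px <= 256))
  # determinism
  expect_identical(gt, place_cells(spec, c(256, 256), seed = 3))
  # empty request
  empty <- place_cells(cell_population_spec(n_live = 0, n_dead = 0),
                       c(64, 64), seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("cluster members are placed closer than the separation", {
  spec <- cell_population_spec(n_live = 6, n_dead = 6,
                               min_separation_px = 26,
                               cluster_fraction = 0.25)
  gt <- place_cells(spec, c(256, 256), seed = 9)
  cl <- gt[gt$cluster_member, ]
  expect_equal(nrow(cl), 3)
  main <- gt[!gt$cluster_member, ]
  for (i in seq_len(nrow(cl))) {
    d <- sqrt((main$x - cl$x[i])^2 + (main$y - cl$y[i])^2)
    expect_lt(min(d), 26)
  }
})

test_that("infeasible placement fails loudly with the failing count", {
  spec <- cell_population_spec(n_live = 40, n_dead = 40,
                               min_separation_px = 40)
  expect_error(place_cells(spec, c(128, 128), seed = 1, max_attempts = 50),
               class = "foa_placement_error")
})

test_that("noise-free render is the exact gain composition", {
  lat <- fiber_lattice_spec()
  ill <- illumination_spec()
  cells <- cell_population_spec(n_live = 0, n_dead = 0)
  sc <- render_scene(lat, ill, cells, shape = c(64, 64), noise_sigma = 0,
                     seed = 2)
  expected <- round(255 * cells$background_level *
                      render_fiber_lattice(lat, c(64, 64)) *
                      render_illumination(ill, c(64, 64)))
  expect_equal(sc$image, expected)
  expect_true(all(sc$image >= 0 & sc$image <= 255))
})

test_that("intensity orderings hold on noise-free renders", {
  # flat gains so local gain is equal everywhere
  lat <- fiber_lattice_spec(core_gain = 1, gap_gain = 1 - 1e-12)
  ill <- illumination_spec(center_level = 1, edge_level = 1)
  cells <- cell_population_spec(n_live = 4, n_dead = 4)
  sc <- render_scene(lat, ill, cells, shape = c(200, 200), noise_sigma = 0,
                     seed = 8)
  img <- scene_image(sc)
  gt <- sc$gt
  px <- expand.grid(y = 1:200, x = 1:200)
  ring_vals <- function(cx, cy, r_in, r_out) {
    d2 <- (px$x - cx)^2 + (px$y - cy)^2
    sel <- d2 > r_in^2 & d2 <= r_out^2
    img[cbind(px$y[sel], px$x[sel])]
  }
  bg <- mean(img[1:15, 1:15])   # corner patch, cell-free (cells keep a margin)
  for (i in seq_len(nrow(gt))) {
    interior <- ring_vals(gt$x[i], gt$y[i], -1, gt$radius_px[i] - sc$rim_px - 0.5)
    if (gt$label[i] == "dead") {
      expect_lt(mean(interior), bg)
    } else {
      expect_gt(mean(interior), bg)
      rim <- ring_vals(gt$x[i], gt$y[i], gt$radius_px[i] - sc$rim_px + 0.5,
                       gt$radius_px[i] - 0.5)
      expect_lt(mean(rim), bg)
    }
  }
})

test_that("renders are bit-identical for a fixed seed", {
  a <- tiny_scene(seed = 11, noise_sigma = 0.05)
  b <- tiny_scene(seed = 11, noise_sigma = 0.05)
  expect_identical(a$image, b$image)
  expect_identical(a$gt, b$gt)
  c <- tiny_scene(seed = 12, noise_sigma = 0.05)
  expect_false(identical(a$image, c$image))
})
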