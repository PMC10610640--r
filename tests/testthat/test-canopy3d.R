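test_that("classify_ground separates a plane from elevated points", {
  set.seed(31)
  n_g <- 200; n_c <- 50
  g <- cbind(runif(n_g, 0, 10), runif(n_g, 0, 10), 0)
  c_ <- cbind(runif(n_c, 2, 8), runif(n_c, 2, 8), 1.5)
  pc <- point_cloud(rbind(g, c_))
  # 2.5 m seed cells: with 200 ground points every cell then contains a
  # true ground point, so the seed TIN cannot be polluted by canopy
  out <- classify_ground(pc, ground_params(cell_size = 2.5))
  lab <- as.character(out$class_label)
  expect_identical(lab[seq_len(n_g)], rep("ground", n_g))
  expect_identical(lab[n_g + seq_len(n_c)], rep("canopy", n_c))
  # the partition covers every point
  expect_true(all(lab %in% c("ground", "canopy")))
})

test_that("classify_ground keeps high recall on tilted terrain", {
  set.seed(32)
  n <- 3000
  x <- runif(n, 0, 20); y <- runif(n, 0, 20)
  z <- tan(5 * pi / 180) * x          # 5 degree slope
  above <- sample(n, 300)
  z[above] <- z[above] + runif(300, 0.8, 2)
  pc <- point_cloud(cbind(x, y, z))
  out <- classify_ground(pc)
  truth_ground <- !(seq_len(n) %in% above)
  recall <- mean(out$class_label[truth_ground] == "ground")
  expect_gte(recall, 0.99)
})

test_that("classify_ground rejects degenerate geometry", {
  expect_error(classify_ground(point_cloud(matrix(c(0, 0, 0, 1, 1, 1), 2, 3,
                                                  byrow = TRUE))),
               "triangulate")
  collinear <- point_cloud(cbind(1:10 / 2, 1:10 / 2, 0))
  expect_error(classify_ground(collinear), "collinear|degenerate")
})

test_that("terrain_height interpolates the TIN linearly", {
  set.seed(33)
  x <- runif(300, 0, 10); y <- runif(300, 0, 10)
  pc <- point_cloud(cbind(x, y, 2 + 0.1 * x - 0.05 * y))
  out <- classify_ground(pc)
  tin <- attr(out, "terrain")
  qx <- runif(20, 1, 9); qy <- runif(20, 1, 9)
  expect_equal(terrain_height(tin, qx, qy), 2 + 0.1 * qx - 0.05 * qy,
               tolerance = 1e-9)
  expect_true(is.na(terrain_height(tin, 100, 100)))  # outside the hull
})

test_that("filter_noise removes gross outliers and nothing else", {
  grid10 <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  pc <- point_cloud(rbind(cbind(grid10, 0), c(5, 5, 100)))
  out <- filter_noise(pc)
  expect_equal(n_points(out), 100)
  expect_equal(max(out$coords[, 3]), 0)
  removed <- attr(out, "noise_points")
  expect_equal(n_points(removed), 1)
  expect_identical(as.character(removed$class_label), "noise")

  # permissive limit removes nothing and is idempotent
  loose <- noise_params(sigma_multiplier = 1e6)
  out2 <- filter_noise(pc, loose)
  expect_equal(n_points(out2), 101)
  expect_cloud_equal(filter_noise(out2, loose), out2)

  expect_error(filter_noise(point_cloud(matrix(rnorm(15), 5, 3)),
                            noise_params(k_neighbors = 8)), "more than")
})

test_that("filter_noise recovers implanted outliers in a Gaussian cluster", {
  set.seed(34)
  n <- 1000
  inliers <- matrix(rnorm(3 * n, sd = 1), ncol = 3)
  dirs <- matrix(rnorm(30), 10, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  outliers <- dirs * runif(10, 15, 30)
  pc <- point_cloud(rbind(inliers, outliers))
  out <- filter_noise(pc)
  removed <- attr(out, "noise_points")
  radius <- sqrt(rowSums(removed$coords^2))
  n_out_removed <- sum(radius > 10)              # implanted points sit at r >= 15
  n_in_removed <- n_points(removed) - n_out_removed
  expect_gte(n_out_removed, 9)
  expect_lte(n_in_removed / n, 0.02)
})

test_that("remove_understory drops trunks and out-of-hull points", {
  flat <- function(x, y) rep(0, length(x))
  trunk <- cbind(runif(20, 0, 5), runif(20, 0, 5), 0.2)
  crown <- cbind(runif(80, 0, 5), runif(80, 0, 5), runif(80, 0.8, 2))
  pc <- point_cloud(rbind(trunk, crown))
  out <- remove_understory(pc, flat, min_height = 0.5)
  expect_equal(n_points(out), 80)
  expect_true(all(out$coords[, 3] >= 0.8))
  # min_height 0 is the identity inside the terrain hull
  expect_equal(n_points(remove_understory(pc, flat, 0)), 100)
})

test_that("understory removal against scene truth keeps canopy pure", {
  cfg <- small_scene_config(seed = 13)
  sc <- generate_scene(cfg)
  classified <- classify_ground(sc$cloud)
  canopy <- subset_cloud(classified, classified$class_label == "canopy")
  truth <- subset_cloud(sc$cloud, classified$class_label == "canopy")
  clean_idx <- {
    h <- canopy$coords[, 3] -
      terrain_height(attr(classified, "terrain"), canopy$coords[, 1],
                     canopy$coords[, 2])
    !is.na(h) & h >= 0.5
  }
  purity <- mean(truth$class_label[clean_idx] == "canopy")
  expect_gte(purity, 0.98)
})

test_that("trim_bottom follows the uniform order-statistics oracle", {
  flat <- function(x, y) rep(0, length(x))
  set.seed(35)
  n <- 5000
  pc <- point_cloud(cbind(runif(n, 0, 10), runif(n, 0, 10),
                          runif(n, 0.5, 1.5)))
  expect_equal(n_points(trim_bottom(pc, flat, 0)), n)  # identity
  out <- trim_bottom(pc, flat, 0.2)
  expect_equal(n_points(out) / n, 0.8, tolerance = 0.03)
  expect_warning(trim_bottom(pc, flat, 5), "exceeds")
  expect_error(trim_bottom(pc, flat, -0.1), ">= 0")
})

test_that("segment_top keeps the per-cell top window", {
  pc <- point_cloud(cbind(c(0.1, 0.12, 0.15), c(0.1, 0.1, 0.12),
                          c(1.0, 1.5, 2.0)))
  out <- segment_top(pc, cell_size = 0.25, depth_m = 0.2)
  expect_equal(n_points(out), 1)
  expect_equal(out$coords[, 3], 2.0, ignore_attr = TRUE)
  # a window deeper than the canopy is the identity
  expect_equal(n_points(segment_top(pc, 0.25, 10)), 3)
  # subset property and monotonicity in depth
  set.seed(36)
  pc2 <- point_cloud(cbind(runif(500, 0, 5), runif(500, 0, 5),
                           runif(500, 0, 2)))
  n_prev <- 0
  for (d in c(0.1, 0.3, 0.8, 2.5)) {
    nd <- n_points(segment_top(pc2, 0.25, d))
    expect_gte(nd, n_prev)
    n_prev <- nd
  }
  expect_error(segment_top(pc2, 0, 0.2), "positive")
})

test_that("the top of the canopy is cooler than the whole canopy", {
  cfg <- small_scene_config(seed = 14)
  sc <- generate_scene(cfg)
  canopy <- subset_cloud(sc$cloud, sc$cloud$class_label == "canopy")
  top <- segment_top(canopy)
  expect_lt(mean(top$temperature), mean(canopy$temperature))
})

test_that("ground classification accuracy holds across seeds and slopes", {
  # scaled-down block (6 plants) so 10 seeds x 2 terrains stay fast; the
  # classifier runs at its default parameters
  accs <- c()
  for (seed in 1:5) {
    for (slope in c(0, tan(5 * pi / 180))) {
      cfg <- small_scene_config(seed = seed, terrain_slope_x = slope,
                                terrain_slope_y = 0)
      sc <- generate_scene(cfg)
      out <- classify_ground(sc$cloud)
      accs <- c(accs, mean(as.character(out$class_label) ==
                             as.character(sc$cloud$class_label)))
    }
  }
  expect_gte(min(accs), 0.95)
})
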