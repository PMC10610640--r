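# Shared fixtures. Module tests use a scaled-down vineyard block (2 rows x 3
# plants, thinner ground sampling) so the whole suite stays fast; the
# acceptance tests use the full default scene_config().

small_scene_config <- function(seed = 1L, ...) {
  scene_config(n_rows = 2L, plants_per_row = 3L, ground_point_density = 25,
               cell_size = 0.2, seed = seed, ...)
}

demo_raster <- function(values = matrix(as.numeric(1:6), 2, 3),
                        crs = "test metric") {
  raster_grid(values, xmin = 0, ymax = nrow(values), dx = 1, dy = 1,
              crs = crs)
}

# simple axis-aligned square ROI
square_roi <- function(side = 10) {
  roi_polygon(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
}

expect_cloud_equal <- function(a, b, tol = 0) {
  expect_equal(n_points(a), n_points(b))
  expect_equal(a$coords, b$coords, tolerance = tol, ignore_attr = TRUE)
  if (!is.null(a$temperature))
    expect_equal(a$temperature, b$temperature, tolerance = tol)
  if (!is.null(a$class_label))
    expect_equal(as.character(a$class_label), as.character(b$class_label))
  for (nm in names(a$scalars))
    expect_equal(a$scalars[[nm]], b$scalars[[nm]], tolerance = tol)
}
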