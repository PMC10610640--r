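test_that("GeoTIFF round-trips values, transform, CRS and nodata", {
  # float32-representable values so the default dtype round-trips exactly
  vals <- matrix(c(1.5, -2.25, 0.5, 1024), 2, 2)
  g <- raster_grid(vals, xmin = 500000, ymax = 4644000, dx = 0.25, dy = 0.5,
                   crs = "ETRS89 / UTM zone 29N")
  p <- file.path(tempdir(), "rt.tif")
  write_raster(g, p)
  r <- read_raster(p)
  expect_identical(r$values, vals)
  expect_equal(c(r$xmin, r$ymax, r$dx, r$dy),
               c(500000, 4644000, 0.25, 0.5))
  expect_identical(r$crs, "ETRS89 / UTM zone 29N")

  # float64 is lossless for arbitrary doubles
  g2 <- demo_raster(matrix(c(pi, exp(1), sqrt(2), 1 / 3), 2, 2))
  write_raster(g2, p, dtype = "float64")
  expect_identical(read_raster(p)$values, g2$values)
})

test_that("nodata cells round-trip as NA, including an all-nodata grid", {
  vals <- matrix(c(10, NA, 30, NA), 2, 2)
  g <- demo_raster(vals)
  p <- file.path(tempdir(), "nd.tif")
  write_raster(g, p)
  expect_identical(is.na(read_raster(p)$values), is.na(vals))

  g_all <- demo_raster(matrix(NA_real_, 2, 2))
  write_raster(g_all, p)
  expect_true(all(is.na(read_raster(p)$values)))

  # a custom sentinel (255 in a uint8 mask) flags exactly those cells
  g255 <- raster_grid(matrix(c(1, 255, 0, 255), 2, 2), 0, 2, 1, 1,
                      crs = "test metric", nodata = 255)
  write_raster(g255, p, dtype = "uint8")
  expect_identical(is.na(read_raster(p)$values),
                   matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
})

test_that("CWSI values outside [0, 1] are preserved on write", {
  g <- demo_raster(matrix(c(-0.25, 0.5, 1.5, 1.25), 2, 2))
  p <- file.path(tempdir(), "cwsi.tif")
  write_raster(g, p)
  expect_identical(read_raster(p)$values, g$values)
})

test_that("multi-band GeoTIFFs are band-selectable", {
  b1 <- demo_raster(matrix(c(1, 2, 3, 4), 2, 2))
  b2 <- demo_raster(matrix(c(10, 20, 30, 40), 2, 2))
  b3 <- demo_raster(matrix(c(0.5, 0.5, -1, 2), 2, 2))
  p <- file.path(tempdir(), "mb.tif")
  write_raster(list(b1, b2, b3), p)
  expect_identical(read_raster(p, band = 1)$values, b1$values)
  expect_identical(read_raster(p, band = 2)$values, b2$values)
  expect_identical(read_raster(p, band = 3)$values, b3$values)
  expect_error(read_raster(p, band = 4), "band")
})

test_that("raster contract errors are explicit", {
  expect_error(read_raster(file.path(tempdir(), "nope.tif")), "exist")
  # a plain TIFF without geotags must name the missing metadata
  g <- demo_raster()
  p <- file.path(tempdir(), "geo.tif")
  write_raster(g, p)
  raw <- readBin(p, "raw", file.info(p)$size)
  # retag ModelPixelScale (33550 = 0x830E) as a private tag to strip geotags
  pos <- which(raw[-length(raw)] == as.raw(0x0E) & raw[-1] == as.raw(0x83))
  raw[pos] <- as.raw(0x0E); raw[pos + 1] <- as.raw(0xFF)
  p2 <- file.path(tempdir(), "nogeo.tif")
  writeBin(raw, p2)
  expect_error(read_raster(p2), "georeferencing|CRS")
  expect_error(raster_grid(matrix(1, 1, 1), 0, 1, dx = 0, dy = 1, crs = "x"),
               "positive")
})

test_that("xyz text clouds parse minimal input and pass units through", {
  p <- file.path(tempdir(), "min.xyz")
  writeLines(c("# a comment", "0 0 0", "1 0 0", "0 1 0"), p)
  pc <- read_cloud(p, format = "xyz", column_map = c(x = 1, y = 2, z = 3))
  expect_equal(n_points(pc), 3)
  expect_null(pc$temperature)
  expect_equal(pc$coords[2, ], c(x = 1, y = 0, z = 0))

  writeLines(c("0,0,0,310.2", "1,0,0,305.0"), p)
  pc <- read_cloud(p, format = "xyz",
                   column_map = c(x = 1, y = 2, z = 3, temperature = 4),
                   temp_unit = "kelvin")
  expect_identical(pc$temp_unit, "kelvin")
  expect_equal(pc$temperature, c(310.2, 305.0))  # untouched values

  writeLines(c("0 0 0 1", "1 0"), p)
  expect_error(read_cloud(p, format = "xyz",
                          column_map = c(x = 1, y = 2, z = 3)), "ragged")
  writeLines(c("0 0 zero"), p)
  expect_error(read_cloud(p, format = "xyz",
                          column_map = c(x = 1, y = 2, z = 3)), "non-numeric")
})

test_that("text clouds with scalars round-trip losslessly", {
  pc <- point_cloud(matrix(c(pi, 0, 1, exp(1), 2, 0.1, -1, 3, 1e-7), 3, 3),
                    temperature = c(31.123456789, 35, 40.5),
                    temp_unit = "celsius",
                    class_label = c("ground", "canopy", "canopy"),
                    scalars = list(cwsi = c(-0.05, 0.31, 1.2)))
  p <- file.path(tempdir(), "sc.xyz")
  write_cloud(pc, p, format = "xyz")
  back <- read_cloud(p, format = "xyz")
  expect_cloud_equal(pc, back)
  expect_identical(back$temp_unit, "celsius")

  # empty cloud round-trips as N = 0
  empty <- point_cloud(matrix(numeric(0), 0, 3))
  write_cloud(empty, p, format = "xyz")
  expect_equal(n_points(read_cloud(p, format = "xyz")), 0)
})

test_that("LAS round-trips coordinates and class codes", {
  pc <- point_cloud(cbind(c(516989.02, 516990, 516991.5),
                          c(4644806.53, 4644807, 4644808),
                          c(100.001, 101.25, 99.5)),
                    class_label = c("ground", "canopy", "noise"))
  p <- file.path(tempdir(), "rt.las")
  write_cloud(pc, p, format = "las")
  back <- read_cloud(p, format = "las")
  expect_equal(back$coords, pc$coords, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(as.character(back$class_label),
                   c("ground", "canopy", "noise"))

  # LAS cannot carry temperature: explicit error
  pct <- point_cloud(pc$coords, temperature = c(30, 31, 32),
                     temp_unit = "celsius")
  expect_error(write_cloud(pct, p, format = "las"), "cannot carry")
  # but deselecting the unsupported attribute works
  expect_silent(write_cloud(pct, p, format = "las", attributes = character(0)))
})

test_that("PLY round-trips in ascii and binary within float32 tolerance", {
  set.seed(3)
  pc <- point_cloud(cbind(runif(50, 0, 30), runif(50, 0, 30), runif(50, 99, 103)),
                    temperature = runif(50, 30, 45), temp_unit = "celsius",
                    color = matrix(sample(0:255, 150, TRUE), 50, 3),
                    class_label = sample(c("ground", "canopy"), 50, TRUE),
                    scalars = list(cwsi = runif(50, -0.1, 1.2)))
  for (bin in c(FALSE, TRUE)) {
    p <- file.path(tempdir(), sprintf("rt_%d.ply", bin))
    write_cloud(pc, p, format = "ply", binary = bin)
    back <- read_cloud(p, format = "ply")
    expect_lt(max(abs(back$coords - pc$coords)), 1e-4)  # 30 m * float32 eps
    expect_equal(back$scalars$cwsi, pc$scalars$cwsi, tolerance = 1e-6)
    expect_identical(as.character(back$class_label),
                     as.character(pc$class_label))
    expect_identical(back$color, pc$color)
    expect_identical(back$temp_unit, "celsius")
  }
})

test_that("half-open cell convention maps each point to exactly one cell", {
  g <- demo_raster(matrix(0, 4, 4))  # 4 x 4 cells of 1 m
  # edge points: x on a shared vertical edge goes right, y on a shared
  # horizontal edge goes up
  loc <- locate_cells(g, x = c(1, 1, 0, 4), y = c(4, 3, 2, 1))
  expect_equal(loc$col, c(2L, 2L, 1L, NA))
  expect_equal(loc$row, c(1L, 1L, 2L, NA))
  # brute-force: every interior random point lands in exactly one cell
  set.seed(1)
  xs <- runif(200, 0, 4); ys <- runif(200, 0, 4)
  loc <- locate_cells(g, xs, ys)
  expect_false(anyNA(loc$row))
  expect_true(all(loc$row >= 1 & loc$row <= 4 & loc$col >= 1 & loc$col <= 4))
})
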