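test_that("ASCII grid round trip is bit-exact, including nodata", {
  set.seed(1)
  v <- matrix(runif(12) * 1000, 3, 4)
  v[2, 3] <- NA
  r <- raster_grid(v, cell_size = 250.5, xll = 1234.75, yll = -10,
                   nodata = -9999)
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(r, p)
  r2 <- read_ascii_grid(p)
  expect_identical(r2$values, r$values)
  expect_identical(r2$cell_size, r$cell_size)
  expect_identical(r2$xll, r$xll)
  expect_identical(r2$yll, r$yll)
  expect_identical(r2$nodata, r$nodata)
  # trivial 2x2 grid of ones
  p2 <- tempfile(fileext = ".asc")
  write_ascii_grid(raster_grid(matrix(1, 2, 2)), p2)
  expect_equal(read_ascii_grid(p2)$values, matrix(1, 2, 2))
})

test_that("malformed grids fail with the offending line", {
  p <- tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 2 3", "4 5"), p)
  expect_error(read_ascii_grid(p), "line 7")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 abc"), p)
  expect_error(read_ascii_grid(p), "non-numeric")
})

test_that("classified transform maps feature cells to R_max, rest to 1", {
  riv <- raster_grid(rbind(c(0, 1, 0), c(0, 1, 0)))
  out <- transform_raster(riv, transform_spec("rivers", "classified",
                                              r_max = 2))
  expect_equal(out$values, rbind(c(1, 2, 1), c(1, 2, 1)))
})

test_that("power-deviation transform honours optimum and extremes", {
  asp <- raster_grid(matrix(c(90, 270, 0, 180), 2, 2))
  sp <- transform_spec("aspect", "power_deviation", r_max = 2, x = 10,
                       optimum = 90)
  out <- transform_raster(asp, sp)
  expect_equal(out$values[1, 1], 1)        # at optimum
  expect_equal(out$values[2, 1], 2)        # opposite aspect, delta = 1
  # circular distance: 0 and 180 are both 90 degrees from the optimum
  expect_equal(out$values[1, 2], out$values[2, 2])
  # monotone in deviation for any x
  for (x in c(0.5, 1, 2, 5)) {
    spx <- transform_spec("slope", "power_deviation", r_max = 100, x = x,
                          optimum = 0)
    vals <- transform_raster(raster_grid(matrix(seq(0, 40, 10), 1)),
                             spx)$values
    expect_true(all(diff(as.numeric(vals)) >= 0))
  }
})

test_that("R_max = 1 gives the flat IBR surface for any shape parameter", {
  asp <- raster_grid(matrix(runif(20, 0, 359), 4, 5))
  for (x in c(0.5, 2, 10)) {
    out <- transform_raster(asp, transform_spec("aspect", "power_deviation",
                                                r_max = 1, x = x,
                                                optimum = 90))
    expect_equal(out$values, matrix(1, 4, 5))
  }
})

test_that("invalid transform inputs are rejected", {
  expect_error(transform_spec("rivers", "classified", r_max = 0.5),
               "r_max")
  asp <- raster_grid(matrix(c(10, 400), 1, 2))
  expect_error(transform_raster(asp,
                                transform_spec("aspect", "power_deviation",
                                               r_max = 2, optimum = 90)),
               "\\[0, 360\\)")
})

test_that("compose sums aligned surfaces and propagates nodata", {
  a <- raster_grid(matrix(1, 2, 2))
  b <- raster_grid(matrix(1, 2, 2))
  expect_equal(compose_surfaces(list(a, b))$values, matrix(2, 2, 2))
  # overlapping classified features add
  riv <- transform_raster(raster_grid(matrix(c(1, 0), 1, 2)),
                          transform_spec("rivers", "classified", r_max = 2))
  ro <- transform_raster(raster_grid(matrix(c(1, 0), 1, 2)),
                         transform_spec("roads", "classified", r_max = 2))
  expect_equal(compose_surfaces(list(riv, ro))$values[1, 1], 4)
  # identity on a single surface
  expect_identical(compose_surfaces(list(a)), a)
  # nodata propagates
  vn <- matrix(1, 2, 2); vn[1, 1] <- NA
  s <- compose_surfaces(list(a, raster_grid(vn)))
  expect_true(is.na(s$values[1, 1]))
  # misaligned grids error with both headers
  expect_error(compose_surfaces(list(a, raster_grid(matrix(1, 3, 3)))),
               "misaligned")
})

test_that("ibr_surface is uniform 1 and doubles under self-composition", {
  set.seed(2)
  t <- raster_grid(matrix(runif(225, 1, 50), 15, 15), cell_size = 1)
  ibr <- ibr_surface(t)
  expect_true(all(ibr$values == 1))
  xy <- data.frame(x = c(0.5, 7.5, 14.5), y = c(0.5, 7.5, 14.5))
  r1 <- resistance_matrix(build_graph(ibr, xy))
  r2 <- resistance_matrix(build_graph(compose_surfaces(list(ibr, ibr)), xy))
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
})

test_that("effective resistance on IBR grows monotonically with distance", {
  ibr <- ibr_surface(raster_grid(matrix(1, 15, 15), cell_size = 1))
  # focal points spread along the middle row, increasing separation
  xy <- data.frame(x = c(1.5, 3.5, 6.5, 10.5, 13.5), y = rep(7.5, 5))
  rm_ <- resistance_matrix(build_graph(ibr, xy))
  expect_true(all(diff(rm_[1, -1]) > 0))
})
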