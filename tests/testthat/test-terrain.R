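test_that("ESRI ASCII grids round-trip with nodata", {
  m <- matrix(c(1.5, NA, -3, 4e3, 0.25, 7), nrow = 2, byrow = TRUE)
  tmp <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(list(data = m, xll = 10, yll = 20, cellsize = 2.5), tmp)
  back <- read_ascii_grid(tmp)
  expect_equal(back$data, m)
  expect_equal(back$xll, 10)
  expect_equal(back$cellsize, 2.5)
})

test_that("raster aggregation takes means of contained pixel centres", {
  g <- grid_spec(2, 2, cell_size = 10, xll = 0, yll = 0)
  # constant raster -> every cell equals the constant
  r <- list(data = matrix(7, 8, 8), xll = 0, yll = 0, cellsize = 2.5)
  expect_equal(aggregate_raster(r, g)$values, rep(7, 4))
  # one cell covering exactly pixels 100 and 300
  g1 <- grid_spec(1, 1, cell_size = 10)
  r1 <- list(data = matrix(c(100, 300), 1, 2), xll = 0, yll = 0, cellsize = 5)
  expect_equal(aggregate_raster(r1, g1)$values, 200)
  # resolution coarser than the grid is refused
  expect_error(aggregate_raster(list(data = matrix(1, 2, 2), xll = 0,
                                     yll = 0, cellsize = 20), g),
               "coarser")
})

test_that("aggregation matches a per-pixel binning oracle and is mask-safe", {
  set.seed(7)
  g <- grid_spec(3, 4, cell_size = 1, xll = 0, yll = 0)
  npx <- 24; npy <- 18
  r <- list(data = matrix(rnorm(npx * npy), npy, npx), xll = 0, yll = 0,
            cellsize = 1 / 6)
  agg <- aggregate_raster(r, g)
  # oracle: loop over pixels, assign by centre containment
  sums <- matrix(0, 3, 4); cnts <- matrix(0, 3, 4)
  for (i in seq_len(npy)) for (j in seq_len(npx)) {
    x <- (j - 0.5) / 6; y <- (npy - i + 0.5) / 6
    col <- floor(x); row_top <- 3 - 1 - floor(y)
    sums[row_top + 1, col + 1] <- sums[row_top + 1, col + 1] + r$data[i, j]
    cnts[row_top + 1, col + 1] <- cnts[row_top + 1, col + 1] + 1
  }
  expect_equal(agg$values, as.vector(t(sums / cnts)), tolerance = 1e-9)
  # masking additional (sea) pixels never changes other cells' means
  r2 <- r
  r2$data[1:3, 1:2] <- NA   # part of the top-left cell
  agg2 <- aggregate_raster(r2, g)
  expect_equal(agg$values[-1], agg2$values[-1], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(agg$values[1], agg2$values[1])))
})

test_that("change layers difference present minus past", {
  g <- grid_spec(2, 2)
  now <- grid_layer(c(250, 10, NA, 5), g, "elev", "m")
  past <- grid_layer(c(106, 10, 3, NA), g, "elev", "m")
  ch <- change_layer(now, past)
  expect_equal(ch$values, c(144, 0, NA, NA))
  expect_error(change_layer(now, grid_layer(1:4, g, "t", "degC")),
               "unit mismatch", ignore.case = TRUE)
  set.seed(1)
  a <- grid_layer(rnorm(4), g, "elev", "m")
  b <- grid_layer(rnorm(4), g, "elev", "m")
  expect_equal(change_layer(a, b)$values, a$values - b$values)
})

test_that("submerged-past cells are discarded with the right fraction", {
  g <- grid_spec(2, 2)
  all_pos <- grid_layer(c(5, 10, 20, 1), g, "elev_past", "m")
  res <- discard_submerged(all_pos)
  expect_equal(res$fraction_discarded, 0)
  expect_equal(res$retained, 0:3)
  mixed <- grid_layer(c(-5, 10, 20, -1), g, "elev_past", "m")
  res2 <- discard_submerged(mixed)
  expect_equal(sort(res2$discarded), c(0L, 3L))
  expect_equal(res2$fraction_discarded, 0.5)
})

test_that("uplift/erosion classification follows the sign and is antisymmetric", {
  g <- grid_spec(1, 3, cell_size = 1)
  ch <- grid_layer(c(1, -1, 0), g, "d", "m")
  suppressMessages(cl <- classify_cells(ch))
  expect_equal(cl$uplift, 0L)
  expect_equal(cl$erosion, 1L)
  expect_equal(cl$excluded, 2L)

  set.seed(3)
  g2 <- grid_spec(5, 5, cell_size = 1)
  now <- grid_layer(rnorm(25, 100, 50), g2, "elev", "m")
  past <- grid_layer(rnorm(25, 100, 50), g2, "elev", "m")
  cl_fwd <- classify_cells(change_layer(now, past))
  cl_rev <- classify_cells(change_layer(past, now))
  expect_equal(cl_fwd$uplift, cl_rev$erosion)
  expect_equal(cl_fwd$erosion, cl_rev$uplift)
})

test_that("mean-zero change fields give roughly balanced classes", {
  land <- simulate_landscape(sim_config(seed = 21))
  ch <- change_layer(land$layers$elev_now, land$layers$elev_past)
  cl <- classify_cells(ch)
  n <- length(cl$uplift) + length(cl$erosion)
  expect_lt(abs(length(cl$uplift) - length(cl$erosion)) / n, 0.5)
})
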