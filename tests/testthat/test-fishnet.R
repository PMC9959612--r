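test_that("fishnet cell counts follow the positive-area intersection rule", {
  expect_equal(nrow(make_fishnet(c(0, 0, 3000, 2000))$cells), 6L)
  # edge cells are retained when they overlap the boundary at all
  expect_equal(nrow(make_fishnet(c(0, 0, 2500, 1000))$cells), 3L)
  # L-shaped boundary covering 5 of the 6 bounding-box cells
  L <- cbind(c(0, 3000, 3000, 2000, 2000, 0), c(0, 0, 1000, 1000, 2000, 2000))
  fn <- make_fishnet(L)
  expect_equal(nrow(fn$cells), 5L)
  expect_false(any(fn$cells$row == 2 & fn$cells$col == 3))
  # row-major, stable ordering
  expect_false(is.unsorted(fn$cells$cell_id))
  expect_error(make_fishnet(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
})

test_that("attach_raster aggregates raster centers per cell", {
  fn <- make_fishnet(c(0, 0, 2000, 1000))
  const <- density_surface(matrix(7, 10, 20), c(0, 0), 100)
  expect_equal(as.numeric(attach_raster(fn, const, "mean")), c(7, 7))
  # one fishnet cell holding the four raster centers {1,2,3,4}
  r <- density_surface(matrix(1:4, 2, 2), c(0, 0), 500)
  fn1 <- make_fishnet(c(0, 0, 1000, 1000))
  expect_equal(as.numeric(attach_raster(fn1, r, "mean")), 2.5)
  expect_equal(as.numeric(attach_raster(fn1, r, "sum")), 10)
  # nodata cells are excluded from the statistic
  rna <- density_surface(matrix(c(1, NA, 3, NA), 2, 2), c(0, 0), 500)
  expect_equal(as.numeric(attach_raster(fn1, rna, "mean")), 2)
  # coarser raster than the fishnet is refused
  coarse <- density_surface(matrix(1, 2, 2), c(0, 0), 2000)
  expect_error(attach_raster(fn, coarse), "coarser")
})

test_that("attach_raster(sum) conserves the raster total over the fishnet", {
  set.seed(601)
  fn <- make_fishnet(c(0, 0, 3000, 2000))
  r <- density_surface(matrix(runif(600), 20, 30), c(0, 0), 100)
  expect_equal(sum(attach_raster(fn, r, "sum")), sum(r$values))
})

test_that("attach_lines computes length-weighted means and flags empties", {
  fn <- make_fishnet(c(0, 0, 2000, 1000))
  # fully inside one cell
  v <- attach_lines(fn, list(rbind(c(100, 500), c(900, 500))), 5)
  expect_equal(as.numeric(v), c(5, 0))
  expect_equal(attr(v, "empty"), c(FALSE, TRUE))
  # pieces of 1 m (cell 1) + 3 m (cell 2) -> cell 2 mean is value of its piece;
  # one segment spanning the cell boundary gets length-weighted within each cell
  two <- attach_lines(fn,
                      list(rbind(c(999, 500), c(1000, 500)),   # 1 m, value 4
                           rbind(c(1000, 500), c(1003, 500))), # 3 m, value 8
                      c(4, 8))
  expect_equal(as.numeric(two), c(4, 8))
  # mixed pieces in one cell: (1*4 + 3*8)/4 = 7
  mix <- attach_lines(fn,
                      list(rbind(c(10, 500), c(11, 500)),
                           rbind(c(20, 500), c(23, 500))),
                      c(4, 8))
  expect_equal(as.numeric(mix)[1], 7)
})

test_that("attach_lines is invariant to splitting collinear segments", {
  fn <- make_fishnet(c(0, 0, 3000, 2000))
  whole <- attach_lines(fn, list(rbind(c(100, 700), c(2900, 700))), 6)
  halves <- attach_lines(fn, list(rbind(c(100, 700), c(1500, 700)),
                                  rbind(c(1500, 700), c(2900, 700))), c(6, 6))
  expect_equal(as.numeric(whole), as.numeric(halves))
})

test_that("attach_surface localizes a point-mass kernel to its cell", {
  fn <- make_fishnet(c(0, 0, 3000, 3000))
  # point centered in cell (row 2, col 2), bandwidth far below cell size
  s <- kde_surface(1500, 1500, bandwidth = 100,
                   origin = c(0, 0), cell_size = 50, dim = c(60, 60))
  v <- attach_surface(fn, s)
  best <- which.max(v)
  expect_equal(fn$cells$row[best], 2L)
  expect_equal(fn$cells$col[best], 2L)
  const <- density_surface(matrix(2, 30, 30), c(0, 0), 100)
  expect_equal(as.numeric(attach_surface(fn, const)), rep(2, 9))
})
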