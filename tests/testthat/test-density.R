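test_that("standard and median distance match closed forms", {
  expect_equal(standard_distance(c(0, 2), c(0, 0)), 1.0)
  expect_equal(standard_distance(5, 7), 0)
  expect_equal(standard_distance(c(0, 1, 1, 0), c(0, 0, 1, 1)), sqrt(0.5))
  expect_equal(median_distance(c(0, 2), c(0, 0)), 1.0)
  expect_equal(median_distance(rep(3, 5), rep(4, 5)), 0)
  # center (1,0); distances {1,1,2}; median 1
  expect_equal(median_distance(c(0, 0, 3), c(0, 0, 0)), 1.0)
})

test_that("rule-of-thumb radius matches the closed form and scales linearly", {
  expect_equal(rule_of_thumb_radius(c(0, 2), c(0, 0)), 0.9 * 2^(-0.2))
  expect_error(rule_of_thumb_radius(c(1, 1, 1), c(2, 2, 2)), "coincident")
  expect_error(rule_of_thumb_radius(1, 1), "at least 2")
  set.seed(501)
  x <- runif(40, 0, 10); y <- runif(40, 0, 10)
  expect_equal(rule_of_thumb_radius(x * 7, y * 7),
               7 * rule_of_thumb_radius(x, y), tolerance = 1e-12)
})

test_that("quartic kernel surface has the right peak, support and linearity", {
  s <- kde_surface(0, 0, bandwidth = 1,
                   origin = c(-1.05, -1.05), cell_size = 0.1, dim = c(21, 21))
  # value at the point itself is the kernel constant 3/(pi r^2)
  expect_equal(s$values[11, 11], 3 / pi)
  # compact support: zero at distances >= r
  pts <- surface_points(s)
  far <- sqrt(pts$x^2 + pts$y^2) >= 1
  expect_true(all(pts$value[far] == 0))
  # two coincident points double the surface everywhere
  s2 <- kde_surface(c(0, 0), c(0, 0), bandwidth = 1,
                    origin = c(-1.05, -1.05), cell_size = 0.1, dim = c(21, 21))
  expect_equal(s2$values, 2 * s$values)
  expect_error(kde_surface(0, 0, bandwidth = -1), "positive")
})

test_that("interior kernels conserve total point weight", {
  set.seed(502)
  x <- runif(50, 0, 30); y <- runif(50, 0, 30)
  w <- runif(50, 0.5, 2)
  s <- kde_surface(x, y, bandwidth = 4, weights = w, cell_size = 0.4)
  expect_lt(abs(surface_integral(s) - sum(w)) / sum(w), 0.01)
})

test_that("kde is equivariant under joint translation of points and grid", {
  set.seed(503)
  x <- runif(20, 0, 10); y <- runif(20, 0, 10)
  a <- kde_surface(x, y, bandwidth = 2, origin = c(-2, -2),
                   cell_size = 0.5, dim = c(28, 28))
  b <- kde_surface(x + 100, y - 50, bandwidth = 2, origin = c(98, -52),
                   cell_size = 0.5, dim = c(28, 28))
  expect_equal(a$values, b$values)
})

test_that("mixed density blends surfaces and enforces its contract", {
  grid <- list(origin = c(0, 0), cell_size = 1)
  mk <- function(v) density_surface(matrix(v, 4, 4), grid$origin, grid$cell_size)
  out <- mixed_density(list(a = mk(2), b = mk(4)), c(a = 0.5, b = 0.5))
  expect_equal(out$values, matrix(3, 4, 4))
  expect_equal(mixed_density(list(a = mk(7)), c(a = 1))$values, mk(7)$values)
  expect_error(mixed_density(list(a = mk(2), b = mk(4)), c(a = 0.6, b = 0.3)),
               "sum to 1")
  off <- density_surface(matrix(1, 4, 4), c(5, 0), 1)
  expect_error(mixed_density(list(a = mk(1), b = off), c(a = 0.5, b = 0.5)),
               "identical grid")
  # monotone: raising one input surface never lowers the blend
  up <- mixed_density(list(a = mk(2.5), b = mk(4)), c(a = 0.5, b = 0.5))
  expect_true(all(up$values >= out$values))
})
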