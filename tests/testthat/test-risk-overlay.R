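test_that("composite score is a bounded, monotone weighted sum", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(composite_score(matrix(1, 3, 4), w), rep(1, 3))
  expect_equal(composite_score(matrix(0, 3, 4), w), rep(0, 3))
  onehot <- diag(4)
  expect_equal(composite_score(onehot, w), w)
  expect_error(composite_score(matrix(1, 2, 3), w), "do not match")
  expect_error(composite_score(matrix(1, 2, 4), c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  # monotone in every indicator
  set.seed(801)
  x <- matrix(runif(40), 10, 4)
  s0 <- composite_score(x, w)
  x2 <- x; x2[3, 2] <- min(1, x2[3, 2] + 0.2)
  expect_true(all(composite_score(x2, w) >= s0 - 1e-12))
})

test_that("removing an indicator and renormalizing isolates its contribution", {
  set.seed(802)
  x <- matrix(runif(50), 10, 5)
  w <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  s <- composite_score(x, w)
  for (j in 1:5) {
    s_ab <- composite_score(x[, -j], w[-j] / (1 - w[j]))
    expect_equal(s_ab, (s - w[j] * x[, j]) / (1 - w[j]), tolerance = 1e-12)
  }
})

test_that("geometric interval breaks follow the closed form for fixed g", {
  v <- seq(0, 15, length.out = 200)
  b <- geometric_interval_breaks(v, k = 4, g = 2)
  expect_equal(b$breaks, c(1, 3, 7))   # widths 1, 2, 4 (and 8 to the max)
  b1 <- geometric_interval_breaks(v, k = 5, g = 1)
  expect_equal(b1$breaks, c(3, 6, 9, 12))
})

test_that("the count-variance search picks g near 1 for uniform values", {
  v <- seq(0, 15, length.out = 500)
  b <- geometric_interval_breaks(v, k = 5)
  expect_lt(abs(log(b$g)), 0.15)
  expect_equal(b$breaks, c(3, 6, 9, 12), tolerance = 0.2)
})

test_that("right-skewed values select widening classes (g > 1)", {
  set.seed(803)
  for (s in 1:5) {
    v <- rlnorm(400, sdlog = 1)
    expect_gt(geometric_interval_breaks(v, k = 5)$g, 1)
  }
})

test_that("classification is deterministic with boundaries going to the riskier class", {
  br <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(classify(1.0, br), 1L)
  expect_equal(classify(0.0, br), 5L)
  expect_equal(classify(0.6, br), 2L)     # exactly on a break -> higher-risk side
  expect_equal(classify(c(0.1, 0.35, 0.99), br), c(5L, 4L, 1L))
  expect_error(classify(0.5, c(0.4, 0.2)), "ascending")
  # fewer distinct values than classes falls back to quantiles with a warning
  expect_warning(geometric_interval_breaks(rep(c(1, 2), 10), k = 5), "quantile")
})

test_that("classify-then-break is invariant to affine rescaling of scores", {
  set.seed(804)
  v <- rlnorm(300)
  c1 <- classify(v, geometric_interval_breaks(v, k = 5))
  v2 <- 3.7 * v + 2
  c2 <- classify(v2, geometric_interval_breaks(v2, k = 5))
  expect_equal(c1, c2)
})

test_that("spatial structure labels main, secondary, belt and point components", {
  # one 10-cell blob -> a single main area
  blob <- as.matrix(expand.grid(row = 1:2, col = 1:5))
  s1 <- spatial_structure(fixture_risk_map(6, 8, blob))
  expect_equal(s1$components$label, "main")
  expect_equal(s1$components$n_cells, 10L)

  # 10-cell + 6-cell blobs + 1 isolated cell -> main, secondary, point
  cells <- rbind(as.matrix(expand.grid(row = 1:2, col = 1:5)),
                 as.matrix(expand.grid(row = 5:6, col = 1:3)),
                 cbind(row = 6, col = 8))
  s2 <- spatial_structure(fixture_risk_map(8, 10, cells))
  expect_equal(sort(s2$components$label), c("main", "point", "secondary"))
  expect_equal(s2$components$label[which.max(s2$components$n_cells)], "main")

  # a 1 x 12 chain that is not the largest component -> belt
  cells3 <- rbind(as.matrix(expand.grid(row = 1:4, col = 1:4)),   # 16-cell main
                  cbind(row = 10, col = 3:14))                    # 12-cell chain
  s3 <- spatial_structure(fixture_risk_map(12, 16, cells3))
  lab <- s3$components$label[s3$components$n_cells == 12]
  expect_equal(lab, "belt")
  expect_equal(sum(s3$components$label == "main"), 1L)

  # no class-1 cells -> empty structure
  fn <- make_fishnet(c(0, 0, 3000, 3000))
  rm0 <- risk_map(fn, seq(0, 0.5, length.out = 9), c(0.6, 0.7, 0.8, 0.9))
  expect_equal(nrow(spatial_structure(rm0)$components), 0L)
})

test_that("site validation counts classes and coverage correctly", {
  rm <- fixture_risk_map(4, 4, cbind(row = c(2, 2), col = c(2, 3)))
  v0 <- validate_sites(data.frame(x = numeric(0), y = numeric(0)), rm)
  expect_equal(sum(v0$counts), 0L)
  # sites centered in the two class-1 cells plus one outside the grid
  sites <- data.frame(x = c(1500, 2500, 9999), y = c(1500, 1500, 50))
  v <- validate_sites(sites, rm)
  expect_equal(v$n_in, 2L)
  expect_equal(v$n_outside, 1L)
  expect_equal(as.numeric(v$counts[1]), 2)
  expect_equal(v$coverage12, 1.0)
})
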