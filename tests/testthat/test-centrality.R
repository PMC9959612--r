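test_that("closeness matches hand enumeration on the unit path", {
  g <- unit_path3()
  expect_equal(road_closeness(g), c(1.5, 2.0, 1.5))
  # radius 1 excludes the far segment (distance 2)
  expect_equal(road_closeness(g, radius = 1), c(1.0, 2.0, 1.0))
  # a lone segment has an empty sum
  solo <- build_road_graph(list(rbind(c(0, 0), c(5, 0))))
  expect_equal(road_closeness(solo), 0)
  expect_equal(road_betweenness(solo), 0)
})

test_that("betweenness matches hand enumeration on the unit path", {
  g <- unit_path3()
  tp <- road_betweenness(g)
  expect_equal(tp, c(2 / 3, 4 / 3, 2 / 3))
})

test_that("centralities agree with the brute-force oracle on random graphs", {
  set.seed(402)
  for (rep in 1:10) {
    g <- random_road_graph(sample(4:8, 1), sample(0:3, 1))
    ds <- distance_spec(sample(c("metric", "angular", "hybrid"), 1),
                        angular_weight_m_per_deg = 0.5)
    Do <- oracle_distances(g, ds)
    radius <- if (rep %% 2) Inf else median(Do[is.finite(Do) & Do > 0])
    expect_lt(max(abs(road_closeness(g, radius, ds) -
                        oracle_closeness(g, radius, ds))), 1e-9)
    expect_lt(max(abs(road_betweenness(g, radius, ds) -
                        oracle_betweenness(g, radius, ds))), 1e-9)
  }
})

test_that("parallel duplicate segments are retained and handled", {
  # two identical links between the same junction pair, plus a spur
  g <- build_road_graph(list(rbind(c(0, 0), c(1, 0)),
                             rbind(c(0, 0), c(1, 0)),
                             rbind(c(1, 0), c(2, 0))))
  expect_equal(nrow(g$segments), 3L)
  ds <- distance_spec("metric")
  expect_lt(max(abs(road_betweenness(g, Inf, ds) -
                      oracle_betweenness(g, Inf, ds))), 1e-9)
})

test_that("closeness is non-decreasing in the search radius", {
  set.seed(403)
  g <- random_road_graph(8, 3)
  radii <- c(20, 50, 100, 200, Inf)
  vals <- sapply(radii, function(r) road_closeness(g, r))
  expect_true(all(diff(t(vals)) >= -1e-12))
})

test_that("metric closeness scales as 1/c and betweenness is scale-free", {
  set.seed(404)
  g <- random_road_graph(7, 2)
  scaled <- build_road_graph(lapply(g$geometry, function(m) m * 3), snap_tol_m = 1e-6)
  expect_equal(road_closeness(scaled), road_closeness(g) / 3, tolerance = 1e-10)
  expect_equal(road_betweenness(scaled), road_betweenness(g), tolerance = 1e-10)
})

test_that("relabeling segments permutes the centralities identically", {
  set.seed(405)
  g <- random_road_graph(7, 2)
  perm <- sample(length(g$geometry))
  gp <- build_road_graph(g$geometry[perm], snap_tol_m = 1e-6)
  expect_equal(road_closeness(gp), road_closeness(g)[perm], tolerance = 1e-10)
  expect_equal(road_betweenness(gp), road_betweenness(g)[perm], tolerance = 1e-10)
})

test_that("angular mode excludes coincident-midpoint pairs with a warning", {
  # two collinear segments continue without turning: angular distance 0
  g <- build_road_graph(list(rbind(c(0, 0), c(1, 0)), rbind(c(1, 0), c(2, 0))))
  expect_warning(v <- road_closeness(g, dist = distance_spec("angular")),
                 "zero network distance")
  expect_equal(v, c(0, 0))
})
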