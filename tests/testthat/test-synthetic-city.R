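test_that("identical config and seed reproduce the city exactly", {
  cfg <- small_city_config(seed = 21L)
  a <- generate_city(cfg)
  b <- generate_city(cfg)
  expect_identical(a$roads, b$roads)
  expect_identical(a$population$values, b$population$values)
  expect_identical(a$pois, b$pois)
  expect_identical(a$sites, b$sites)
  expect_identical(a$truth, b$truth)
  expect_identical(a$survey$mean, b$survey$mean)
  # and a different seed changes the random layers
  c2 <- generate_city(small_city_config(seed = 22L))
  expect_false(identical(a$pois, c2$pois))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_city_config(extent_m = c(-1, 100)), "positive")
  expect_error(synthetic_city_config(road_grid_pitch_m = 0), "positive")
  expect_error(synthetic_city_config(n_poi = 0), ">= 1")
  expect_error(synthetic_city_config(
    poi_category_props = c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(synthetic_city_config(
    survey_means = c(catering_service = 5.4)), "\\[1, 5\\]")
  expect_error(synthetic_city_config(n_respondents = 1), ">= 2")
})

test_that("without hotspots the population raster stays in the noise band", {
  cfg <- synthetic_city_config(extent_m = c(3000, 3000), n_hotspots = 0,
                               pop_hotspot_gain = 0, n_poi = 200,
                               n_sites = 10, seed = 23L)
  city <- generate_city(cfg)
  v <- city$population$values
  # lognormal(sdlog 0.3) multiplicative noise around the base level
  expect_true(all(v > cfg$pop_base * exp(-6 * 0.3)))
  expect_true(all(v < cfg$pop_base * exp(6 * 0.3)))
  expect_lt(abs(mean(v) / cfg$pop_base - 1), 0.05)
})

test_that("POI category shares track the configured proportions", {
  cfg <- synthetic_city_config(n_poi = 50000, seed = 24L)
  city <- generate_city(cfg)
  share <- mean(city$pois$category == "commercial")
  expect_lt(abs(share - 0.654), 0.01)
  # all POIs inside the extent
  expect_true(all(city$pois$x >= 0 & city$pois$x <= cfg$extent_m[1]))
  expect_true(all(city$pois$y >= 0 & city$pois$y <= cfg$extent_m[2]))
})

test_that("POI category counts pass a multinomial goodness-of-fit check", {
  props <- poi_taxonomy()
  expected <- tapply(props$prop, props$category, sum)
  for (s in 25:29) {
    city <- generate_city(synthetic_city_config(n_poi = 20000, seed = s))
    obs <- table(factor(city$pois$category, levels = names(expected)))
    p <- suppressWarnings(chisq.test(obs, p = as.numeric(expected))$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("planted hotspots raise population inside their footprints", {
  for (s in 30:34) {
    cfg <- small_city_config(seed = s)
    city <- generate_city(cfg)
    pts <- surface_points(city$population)
    d2min <- Reduce(pmin, lapply(seq_len(nrow(city$truth)), function(i) {
      (pts$x - city$truth[i, 1])^2 + (pts$y - city$truth[i, 2])^2
    }))
    inside <- d2min <= (2 * cfg$hotspot_sigma_m)^2
    expect_gt(mean(pts$value[inside]), mean(pts$value[!inside]))
  }
})

test_that("hotspot centers sit on arterial roads and keep their separation", {
  cfg <- synthetic_city_config(seed = 35L)
  city <- generate_city(cfg)
  expect_equal(nrow(city$truth), cfg$n_hotspots)
  arts <- city$roads[city$road_kind == "arterial"]
  for (i in seq_len(nrow(city$truth))) {
    dmin <- min(vapply(arts, function(seg) {
      # distance from the center to the (axis-aligned) arterial piece
      if (seg[1, 2] == seg[2, 2]) abs(city$truth[i, 2] - seg[1, 2])
      else abs(city$truth[i, 1] - seg[1, 1])
    }, 0))
    expect_lt(dmin, 1e-6)
  }
  expect_gt(min(dist(city$truth)), 2 * cfg$hotspot_sigma_m)
})

test_that("the survey simulator hits its targets", {
  cfg <- synthetic_city_config(seed = 36L)
  # boundary: a target mean of 5 forces every response to 5
  cfg5 <- cfg; cfg5$survey_means[] <- 5
  s5 <- generate_survey(cfg5)
  expect_true(all(attr(s5, "responses") == 5))
  expect_equal(s5$mean, rep(5, length(cfg$survey_means)))
  # CLT: target 3.0 at n = 10,000 lands within [2.95, 3.05]
  cfg3 <- synthetic_city_config(seed = 37L, n_respondents = 10000)
  cfg3$survey_means[] <- 3
  s3 <- generate_survey(cfg3)
  expect_true(all(s3$mean >= 2.95 & s3$mean <= 3.05))
  # default means at n = 204 stay within 0.15 of target
  sd_ <- generate_survey(cfg)
  expect_true(all(abs(sd_$mean - cfg$survey_means[sd_$subcategory]) <= 0.15))
  expect_true(all(attr(sd_, "responses") %in% 1:5))
  # noiseless mode returns the exact reference means
  sn <- generate_survey(cfg, noiseless = TRUE)
  ref <- reference_survey()
  expect_equal(sn$mean[match(ref$subcategory, sn$subcategory)], ref$mean)
})
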