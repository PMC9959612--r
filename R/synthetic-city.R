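# Seeded synthetic-city generator: a planar road grid with arterials,
# population and night-light rasters with planted Gaussian hotspots, spatially
# clustered POIs, a Likert survey and validation sites. The planted hotspot
# centers are kept as recoverable truth metadata and are never consumed by
# the analysis stages.

#' Reference POI taxonomy with observed counts
#'
#' The 6-category / 13-subcategory functional POI taxonomy with the observed
#' counts used as default sampling proportions by [generate_city()].
#'
#' @return data.frame with `category`, `subcategory`, `count` and derived
#'   `prop` (share of the grand total).
#' @export
poi_taxonomy <- function() {
  tab <- read.csv(system.file("extdata", "poi_taxonomy.csv", package = "epirisk"),
                  stringsAsFactors = FALSE)
  tab$prop <- tab$count / sum(tab$count)
  tab
}

#' Reference Likert survey of public dependence on POI subcategories
#'
#' Per-subcategory Likert-5 means and standard deviations from a 204
#' respondent survey, used as default target means by [generate_survey()].
#'
#' @return a [survey_table()].
#' @export
reference_survey <- function() {
  tab <- read.csv(system.file("extdata", "likert_survey.csv", package = "epirisk"),
                  stringsAsFactors = FALSE)
  survey_table(tab$category, tab$subcategory, tab$mean, tab$sd, tab$n)
}

#' Configuration of the synthetic city
#'
#' All quantities are in meters unless noted. Defaults describe a 6 x 6 km
#' city with a 500 m road grid, three arterials, and three planted hotspots
#' whose Gaussian footprints drive the population raster, the night-light
#' raster, the POI clusters and the validation sites.
#'
#' @param extent_m width/height of the rectangular study area.
#' @param road_grid_pitch_m spacing of the background road grid.
#' @param n_arterials number of long axis-aligned through-roads noded
#'   against the grid.
#' @param n_hotspots number of planted high-intensity centers.
#' @param hotspot_centers optional 2-column matrix of centers (overrides
#'   random placement on arterials).
#' @param hotspot_sigma_m Gaussian footprint of each hotspot.
#' @param n_poi total POI count.
#' @param poi_category_props named category proportions (default: the
#'   [poi_taxonomy()] count shares).
#' @param poi_cluster_frac fraction of POIs drawn from hotspot clusters (the
#'   rest are uniform background).
#' @param pop_base,pop_hotspot_gain population raster (100 m cells, persons
#'   per cell): base level and per-hotspot center amplitude.
#' @param light_base,light_hotspot_gain night-light raster (500 m cells,
#'   radiance-like units): base level and per-hotspot center amplitude.
#' @param noise_sdlog sdlog of the mean-one multiplicative lognormal noise on
#'   both rasters.
#' @param n_sites validation site count.
#' @param site_hotspot_frac fraction of sites drawn within `2 * hotspot_sigma_m`
#'   of a truth center (the rest are uniform).
#' @param survey_means named per-subcategory target Likert means in [1, 5]
#'   (default: the [reference_survey()] means).
#' @param n_respondents survey sample size (>= 2).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_city_config`.
#' @export
synthetic_city_config <- function(extent_m = c(6000, 6000),
                                  road_grid_pitch_m = 500,
                                  n_arterials = 3,
                                  n_hotspots = 3,
                                  hotspot_centers = NULL,
                                  hotspot_sigma_m = 400,
                                  n_poi = 2000,
                                  poi_category_props = NULL,
                                  poi_cluster_frac = 0.7,
                                  pop_base = 5, pop_hotspot_gain = 200,
                                  light_base = 2, light_hotspot_gain = 40,
                                  noise_sdlog = 0.3,
                                  n_sites = 100,
                                  site_hotspot_frac = 0.85,
                                  survey_means = NULL,
                                  n_respondents = 204,
                                  seed = 1L) {
  extent_m <- rep_len(as.numeric(extent_m), 2L)
  if (any(!is.finite(extent_m)) || any(extent_m <= 0)) {
    stop_ctx("`extent_m` must be strictly positive")
  }
  check_number(road_grid_pitch_m, "road_grid_pitch_m", positive = TRUE)
  check_number(hotspot_sigma_m, "hotspot_sigma_m", positive = TRUE)
  n_arterials <- check_count(n_arterials, "n_arterials")
  n_hotspots <- check_count(n_hotspots, "n_hotspots")
  n_poi <- check_count(n_poi, "n_poi", min = 1L)
  n_sites <- check_count(n_sites, "n_sites")
  n_respondents <- check_count(n_respondents, "n_respondents", min = 2L)
  for (nm in c("pop_base", "pop_hotspot_gain", "light_base",
               "light_hotspot_gain", "noise_sdlog")) {
    v <- get(nm)
    check_number(v, nm)
    if (v < 0) stop_ctx(sprintf("`%s` must be >= 0", nm))
  }
  if (poi_cluster_frac < 0 || poi_cluster_frac > 1) {
    stop_ctx("`poi_cluster_frac` must be in [0, 1]")
  }
  if (site_hotspot_frac < 0 || site_hotspot_frac > 1) {
    stop_ctx("`site_hotspot_frac` must be in [0, 1]")
  }
  tax <- poi_taxonomy()
  if (is.null(poi_category_props)) {
    poi_category_props <- tapply(tax$prop, tax$category, sum)
    poi_category_props <- setNames(as.numeric(poi_category_props),
                                   names(tapply(tax$prop, tax$category, sum)))
  }
  if (is.null(names(poi_category_props)) || any(poi_category_props < 0) ||
      abs(sum(poi_category_props) - 1) > 1e-9) {
    stop_ctx("`poi_category_props` must be named, >= 0 and sum to 1")
  }
  if (is.null(survey_means)) {
    ref <- reference_survey()
    survey_means <- setNames(ref$mean, ref$subcategory)
  }
  if (is.null(names(survey_means)) || any(survey_means < 1) || any(survey_means > 5)) {
    stop_ctx("`survey_means` must be named and lie in [1, 5]")
  }
  if (!is.null(hotspot_centers)) {
    hotspot_centers <- as.matrix(hotspot_centers)
    if (ncol(hotspot_centers) != 2L || nrow(hotspot_centers) != n_hotspots) {
      stop_ctx("`hotspot_centers` must be an n_hotspots x 2 matrix")
    }
  }
  structure(list(extent_m = extent_m, road_grid_pitch_m = road_grid_pitch_m,
                 n_arterials = n_arterials, n_hotspots = n_hotspots,
                 hotspot_centers = hotspot_centers,
                 hotspot_sigma_m = hotspot_sigma_m,
                 n_poi = n_poi, poi_category_props = poi_category_props,
                 poi_cluster_frac = poi_cluster_frac,
                 pop_base = pop_base, pop_hotspot_gain = pop_hotspot_gain,
                 light_base = light_base, light_hotspot_gain = light_hotspot_gain,
                 noise_sdlog = noise_sdlog,
                 n_sites = n_sites, site_hotspot_frac = site_hotspot_frac,
                 survey_means = survey_means, n_respondents = n_respondents,
                 seed = as.integer(seed)),
            class = "synthetic_city_config")
}

# grid + noded arterial road geometry; returns list(geometry, kind)
synth_roads <- function(config) {
  w <- config$extent_m[1]; h <- config$extent_m[2]
  p <- config$road_grid_pitch_m
  xs <- seq(0, w, by = p); if (max(xs) < w) xs <- c(xs, w)
  ys <- seq(0, h, by = p); if (max(ys) < h) ys <- c(ys, h)
  seg2 <- function(x0, y0, x1, y1) rbind(c(x0, y0), c(x1, y1))
  geom <- list(); kind <- character(0)
  # arterial offsets first (they re-node the grid)
  art_h <- numeric(0); art_v <- numeric(0)
  if (config$n_arterials > 0) {
    for (a in seq_len(config$n_arterials)) {
      horiz <- a %% 2L == 1L
      repeat {
        off <- runif(1, 0.2, 0.8) * (if (horiz) h else w)
        near <- if (horiz) ys else xs
        if (min(abs(near - off)) > 1) break
      }
      if (horiz) art_h <- c(art_h, off) else art_v <- c(art_v, off)
    }
  }
  # horizontal grid segments, split at vertical arterials
  xcuts <- sort(c(xs, art_v)); ycuts <- sort(c(ys, art_h))
  for (y in ys) {
    for (i in seq_len(length(xcuts) - 1L)) {
      geom[[length(geom) + 1L]] <- seg2(xcuts[i], y, xcuts[i + 1L], y)
      kind <- c(kind, "grid")
    }
  }
  for (x in xs) {
    for (i in seq_len(length(ycuts) - 1L)) {
      geom[[length(geom) + 1L]] <- seg2(x, ycuts[i], x, ycuts[i + 1L])
      kind <- c(kind, "grid")
    }
  }
  for (y in art_h) {
    for (i in seq_len(length(xcuts) - 1L)) {
      geom[[length(geom) + 1L]] <- seg2(xcuts[i], y, xcuts[i + 1L], y)
      kind <- c(kind, "arterial")
    }
  }
  for (x in art_v) {
    for (i in seq_len(length(ycuts) - 1L)) {
      geom[[length(geom) + 1L]] <- seg2(x, ycuts[i], x, ycuts[i + 1L])
      kind <- c(kind, "arterial")
    }
  }
  list(geometry = geom, kind = kind, arterials_h = art_h, arterials_v = art_v)
}

# hotspot centers on arterials (uniform in the central 20-80% span), with
# rejection sampling for >= 2 sigma pairwise separation
synth_hotspots <- function(config, roads) {
  n <- config$n_hotspots
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  if (!is.null(config$hotspot_centers)) return(config$hotspot_centers)
  w <- config$extent_m[1]; h <- config$extent_m[2]
  arts <- rbind(
    if (length(roads$arterials_h))
      cbind(NA, roads$arterials_h),           # horizontal: y fixed
    if (length(roads$arterials_v))
      cbind(roads$arterials_v, NA))           # vertical: x fixed
  centers <- matrix(NA_real_, n, 2)
  min_sep <- 2 * config$hotspot_sigma_m
  for (i in seq_len(n)) {
    for (try in 1:500) {
      if (!is.null(arts) && nrow(arts)) {
        a <- arts[sample.int(nrow(arts), 1L), ]
        pt <- if (is.na(a[1])) c(runif(1, 0.2, 0.8) * w, a[2])
              else c(a[1], runif(1, 0.2, 0.8) * h)
      } else {
        pt <- c(runif(1, 0.2, 0.8) * w, runif(1, 0.2, 0.8) * h)
      }
      if (i == 1L) break
      d <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                           matrix(pt, i - 1L, 2, byrow = TRUE))^2))
      if (all(d >= min_sep)) break
    }
    centers[i, ] <- pt
  }
  centers
}

# base + sum of hotspot Gaussians, times mean-one lognormal noise
synth_raster <- function(config, centers, base, gain, cell) {
  nx <- ceiling(config$extent_m[1] / cell)
  ny <- ceiling(config$extent_m[2] / cell)
  cx <- (seq_len(nx) - 0.5) * cell
  cy <- (seq_len(ny) - 0.5) * cell
  vals <- matrix(base, nrow = ny, ncol = nx)
  if (nrow(centers) && gain > 0) {
    s2 <- 2 * config$hotspot_sigma_m^2
    for (i in seq_len(nrow(centers))) {
      vals <- vals + gain *
        outer(exp(-(cy - centers[i, 2])^2 / s2),
              exp(-(cx - centers[i, 1])^2 / s2))
    }
  }
  if (config$noise_sdlog > 0) {
    noise <- matrix(rlnorm(nx * ny, meanlog = -config$noise_sdlog^2 / 2,
                           sdlog = config$noise_sdlog), ny, nx)
    vals <- vals * noise
  }
  density_surface(vals, c(0, 0), cell)
}

# points from a mixture of hotspot Gaussians and a uniform background,
# clamped to the extent; `trunc_mult` truncates the Gaussian at that many
# sigmas (Inf = no truncation)
synth_mixture_points <- function(n, config, centers, cluster_frac,
                                 trunc_mult = Inf) {
  w <- config$extent_m[1]; h <- config$extent_m[2]
  sig <- config$hotspot_sigma_m
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  clustered <- if (nrow(centers)) runif(n) < cluster_frac else rep(FALSE, n)
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    if (clustered[i]) {
      cc <- centers[sample.int(nrow(centers), 1L), ]
      for (try in 1:100) {
        pt <- cc + rnorm(2, sd = sig)
        r <- sqrt(sum((pt - cc)^2))
        if ((r <= trunc_mult * sig) && pt[1] >= 0 && pt[1] <= w &&
            pt[2] >= 0 && pt[2] <= h) break
      }
      pt[1] <- min(w, max(0, pt[1])); pt[2] <- min(h, max(0, pt[2]))
      x[i] <- pt[1]; y[i] <- pt[2]
    } else {
      x[i] <- runif(1, 0, w); y[i] <- runif(1, 0, h)
    }
  }
  cbind(x = x, y = y)
}

#' Generate a synthetic city
#'
#' Deterministically (given `config$seed`) generates every input the risk
#' pipeline needs: a connected road grid with noded arterials, population
#' (100 m) and night-light (500 m) rasters with planted Gaussian hotspots and
#' multiplicative lognormal noise, POIs drawn from a hotspot/background
#' mixture with configured category proportions, validation sites
#' concentrated in hotspot footprints, and a Likert survey. Draw order:
#' roads, hotspot centers, population raster, night-light raster, POIs,
#' sites, survey.
#'
#' @param config a [synthetic_city_config()].
#' @return object of class `synthetic_city` with elements `roads` (list of
#'   segment coordinate matrices), `road_kind`, `population`, `night_light`
#'   ([density_surface()]s), `pois` (data.frame `x`, `y`, `category`,
#'   `subcategory`), `survey` ([survey_table()]), `sites` (data.frame),
#'   `truth` (planted hotspot centers) and `boundary`.
#' @export
generate_city <- function(config) {
  if (!inherits(config, "synthetic_city_config")) {
    stop_ctx("`config` must be a synthetic_city_config")
  }
  set.seed(config$seed)
  roads <- synth_roads(config)
  centers <- synth_hotspots(config, roads)
  population <- synth_raster(config, centers, config$pop_base,
                             config$pop_hotspot_gain, 100)
  night_light <- synth_raster(config, centers, config$light_base,
                              config$light_hotspot_gain, 500)

  # POIs: locations, then categories, then subcategories within category
  xy <- synth_mixture_points(config$n_poi, config, centers,
                             config$poi_cluster_frac)
  props <- config$poi_category_props
  cat_draw <- sample(names(props), config$n_poi, replace = TRUE, prob = props)
  tax <- poi_taxonomy()
  sub_draw <- character(config$n_poi)
  for (cat in unique(cat_draw)) {
    rows <- tax[tax$category == cat, , drop = FALSE]
    sel <- cat_draw == cat
    sub_draw[sel] <- if (nrow(rows)) {
      sample(rows$subcategory, sum(sel), replace = TRUE, prob = rows$count)
    } else cat
  }
  pois <- data.frame(x = xy[, "x"], y = xy[, "y"],
                     category = cat_draw, subcategory = sub_draw)

  sxy <- synth_mixture_points(config$n_sites, config, centers,
                              config$site_hotspot_frac, trunc_mult = 2)
  sites <- data.frame(x = sxy[, "x"], y = sxy[, "y"])

  survey <- generate_survey(config)  # re-seeds from config$seed; drawn last

  w <- config$extent_m[1]; h <- config$extent_m[2]
  structure(list(config = config,
                 roads = roads$geometry, road_kind = roads$kind,
                 population = population, night_light = night_light,
                 pois = pois, survey = survey, sites = sites,
                 truth = centers,
                 boundary = cbind(c(0, w, w, 0), c(0, 0, h, h))),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf("<synthetic_city> %g x %g m, %d road segments, %d POIs, %d sites, %d hotspots\n",
              x$config$extent_m[1], x$config$extent_m[2],
              length(x$roads), nrow(x$pois), nrow(x$sites), nrow(x$truth)))
  invisible(x)
}

#' Simulate the public-dependence Likert survey
#'
#' Each respondent scores each subcategory on 1..5; a score is
#' `1 + Binomial(4, (target - 1)/4)`, which has exactly the target mean in
#' expectation, stays within the scale, and degenerates to all-5 responses at
#' a target of 5. In noiseless mode the table carries the exact target means
#' (with the binomial's theoretical standard deviations).
#'
#' @param config a [synthetic_city_config()] (supplies `survey_means`,
#'   `n_respondents` and `seed`).
#' @param noiseless return the exact target-mean table instead of sampling.
#' @return a [survey_table()]; for sampled surveys the respondent-by-item
#'   response matrix is attached as attribute `"responses"`, and the target
#'   means as attribute `"target_means"`.
#' @export
generate_survey <- function(config, noiseless = FALSE) {
  if (!inherits(config, "synthetic_city_config")) {
    stop_ctx("`config` must be a synthetic_city_config")
  }
  means <- config$survey_means
  tax <- poi_taxonomy()
  cat_of <- setNames(tax$category, tax$subcategory)
  cats <- ifelse(names(means) %in% names(cat_of), cat_of[names(means)], "other")
  p <- (means - 1) / 4
  sd_theory <- sqrt(4 * p * (1 - p))
  if (noiseless) {
    out <- survey_table(cats, names(means), as.numeric(means), sd_theory,
                        config$n_respondents)
    attr(out, "target_means") <- means
    return(out)
  }
  set.seed(config$seed)
  n <- config$n_respondents
  resp <- vapply(p, function(pp) 1 + rbinom(n, 4L, pp), numeric(n))
  colnames(resp) <- names(means)
  out <- survey_table(cats, names(means), colMeans(resp), apply(resp, 2, sd), n)
  attr(out, "responses") <- resp
  attr(out, "target_means") <- means
  out
}
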