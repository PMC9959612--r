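# End-to-end orchestration: synthetic city -> road centralities ->
# per-category KDE -> survey category weights -> mixed density -> fishnet
# aggregation -> min-max normalization -> entropy weights -> composite score
# -> geometric-interval classification -> spatial structure -> site
# validation.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_ctx(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full spatial risk assessment pipeline
#'
#' Executes every stage of the epidemic-disaster spatial risk assessment on a
#' synthetic city and returns all intermediate and final products. The run is
#' fully deterministic given the configuration seed.
#'
#' @param config a [synthetic_city_config()], or the path to a YAML file with
#'   `synthetic:` / `pipeline:` blocks (see [read_run_config()]).
#' @param cell_size_m fishnet cell size (default 1000 m).
#' @param radius network search radius for the centralities (default `Inf`,
#'   a global analysis).
#' @param dist a [distance_spec()]; the default hybrid metric combines
#'   meters and turn degrees 1:1.
#' @param snap_tol_m endpoint snapping tolerance for the road graph.
#' @param kde_cell_m cell size of the per-category KDE surfaces.
#' @param kde_bandwidth optional bandwidth override (m); by default each
#'   category uses its own rule-of-thumb radius.
#' @param raster_statistic per-cell aggregation for the population and
#'   night-light rasters, `"mean"` (density semantics, default) or `"sum"`.
#' @param k number of risk classes.
#' @param secondary_min_cells,belt_ratio,belt_min_cells,connectivity
#'   structure-extraction thresholds, see [spatial_structure()].
#' @param verbose print per-stage progress messages.
#' @return object of class `risk_assessment`: the generated `city`, the road
#'   `graph` and `centrality` table, `category_weights`, the `mixed` density
#'   surface, the `fishnet`, the per-cell `indicators` data.frame, the
#'   normalized matrix `normalized`, the `entropy` weights, the `riskmap`,
#'   the `structure`, the site `validation`, and `provenance`.
#' @export
run_pipeline <- function(config,
                         cell_size_m = 1000,
                         radius = Inf,
                         dist = distance_spec("hybrid", 1.0),
                         snap_tol_m = 0.1,
                         kde_cell_m = 100,
                         kde_bandwidth = NULL,
                         raster_statistic = c("mean", "sum"),
                         k = 5,
                         secondary_min_cells = 5,
                         belt_ratio = 4,
                         belt_min_cells = 8,
                         connectivity = 8,
                         verbose = FALSE) {
  if (is.character(config)) {
    rc <- read_run_config(config)
    args <- c(list(config = rc$config), rc$options)
    return(do.call(run_pipeline, args))
  }
  raster_statistic <- match.arg(raster_statistic)
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating synthetic city (seed %d)", config$seed)
  city <- with_stage("synthetic_city", generate_city(config))

  say("building road graph")
  graph <- with_stage("road_graph",
                      build_road_graph(city$roads, snap_tol_m = snap_tol_m))

  say("computing centralities (%s, radius %s) on %d segments",
      dist$mode, format(radius), nrow(graph$segments))
  centrality <- with_stage("centrality", road_centrality(graph, radius, dist))

  say("deriving POI category weights from the survey")
  catw <- with_stage("category_weights", category_weights(city$survey))

  say("kernel density per POI category")
  kde <- with_stage("kde", {
    ext <- config$extent_m
    dim_ <- c(ceiling(ext[2] / kde_cell_m), ceiling(ext[1] / kde_cell_m))
    zero <- density_surface(matrix(0, dim_[1], dim_[2]), c(0, 0), kde_cell_m)
    surfaces <- list()
    for (cat in names(catw)) {
      pts <- city$pois[city$pois$category == cat, , drop = FALSE]
      if (nrow(pts) < 2L) {
        surfaces[[cat]] <- zero
        next
      }
      bw <- kde_bandwidth %||% tryCatch(
        rule_of_thumb_radius(pts$x, pts$y),
        error = function(e) max(ext) / 10)
      surfaces[[cat]] <- kde_surface(pts$x, pts$y, bandwidth = bw,
                                     origin = c(0, 0), cell_size = kde_cell_m,
                                     dim = dim_)
    }
    surfaces
  })

  say("blending the functional mixed density surface")
  mixed <- with_stage("mixed_density", mixed_density(kde, catw))

  say("building %g m fishnet and attaching indicators", cell_size_m)
  fishnet <- with_stage("fishnet", make_fishnet(city$boundary, cell_size_m))
  indicators <- with_stage("attach", {
    data.frame(
      cell_id = fishnet$cells$cell_id,
      row = fishnet$cells$row, col = fishnet$cells$col,
      pop = as.numeric(attach_raster(fishnet, city$population, raster_statistic)),
      light = as.numeric(attach_raster(fishnet, city$night_light, raster_statistic)),
      nqpd = as.numeric(attach_lines(fishnet, graph, centrality$nqpd)),
      tpbt = as.numeric(attach_lines(fishnet, graph, centrality$tpbt)),
      mixdens = as.numeric(attach_surface(fishnet, mixed))
    )
  })

  say("entropy weighting and composite score")
  ind_cols <- c("pop", "light", "nqpd", "tpbt", "mixdens")
  normalized <- with_stage("normalize", {
    m <- sapply(ind_cols, function(cn) as.numeric(minmax_normalize(indicators[[cn]])))
    rownames(m) <- indicators$cell_id
    m
  })
  entropy <- with_stage("entropy_weights", entropy_weights(normalized))
  score <- with_stage("composite", composite_score(normalized, entropy))

  say("classifying into %d risk grades", k)
  breaks <- with_stage("breaks", geometric_interval_breaks(score, k = k))
  riskmap <- with_stage("risk_map", risk_map(fishnet, score, breaks))
  struct <- with_stage("structure",
                       spatial_structure(riskmap, secondary_min_cells,
                                         belt_ratio, belt_min_cells, connectivity))
  validation <- with_stage("validate_sites", validate_sites(city$sites, riskmap))

  structure(list(city = city, graph = graph, centrality = centrality,
                 category_weights = catw, kde = kde, mixed = mixed,
                 fishnet = fishnet, indicators = indicators,
                 normalized = normalized, entropy = entropy,
                 score = score, riskmap = riskmap, structure = struct,
                 validation = validation,
                 provenance = list(seed = config$seed,
                                   package_version = as.character(utils::packageVersion("epirisk")),
                                   cell_size_m = cell_size_m, radius = radius,
                                   dist = dist, k = k)),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("<risk_assessment>\n")
  cat(sprintf("  seed %d; %d fishnet cells; %d road segments; %d POIs\n",
              x$provenance$seed, nrow(x$indicators),
              nrow(x$graph$segments), nrow(x$city$pois)))
  cat("  entropy weights:\n")
  print(round(x$entropy$weights, 4))
  print(x$structure)
  cat(sprintf("  site coverage in classes 1-2: %.3f\n", x$validation$coverage12))
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits the standard plain-text artifact set of a run: roads with centrality
#' values (GeoJSON + CSV), POIs and sites (GeoJSON), rasters and the mixed
#' density surface (ASCII grid), survey and indicator/weight tables (CSV),
#' the risk map (GeoJSON + CSV), and a plain-text run report.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_assessment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_roads_geojson(result$graph, fp("roads.geojson"), result$centrality)
  write.csv(result$centrality, fp("centrality.csv"), row.names = FALSE)
  write_points_geojson(result$city$pois, fp("pois.geojson"))
  write_points_geojson(result$city$sites, fp("sites.geojson"))
  write_surface_asc(result$city$population, fp("population.asc"))
  write_surface_asc(result$city$night_light, fp("night_light.asc"))
  write_surface_asc(result$mixed, fp("mixed_density.asc"))
  write_survey_csv(result$city$survey, fp("survey.csv"))
  write.csv(result$indicators, fp("indicators.csv"), row.names = FALSE)
  write.csv(data.frame(indicator = names(result$entropy$weights),
                       entropy = as.numeric(result$entropy$entropy),
                       weight = as.numeric(result$entropy$weights)),
            fp("entropy_weights.csv"), row.names = FALSE)
  write.csv(data.frame(category = names(result$category_weights),
                       weight = as.numeric(result$category_weights)),
            fp("category_weights.csv"), row.names = FALSE)
  write_riskmap_geojson(result$riskmap, fp("riskmap.geojson"))
  write.csv(result$riskmap$cells, fp("riskmap.csv"), row.names = FALSE)
  write.csv(result$structure$components, fp("structure.csv"), row.names = FALSE)
  rep <- c(
    "epidemic-disaster spatial risk assessment run",
    sprintf("seed: %d", result$provenance$seed),
    sprintf("fishnet cells: %d (%g m)", nrow(result$indicators),
            result$provenance$cell_size_m),
    sprintf("entropy weights: %s",
            paste(sprintf("%s=%.4f", names(result$entropy$weights),
                          result$entropy$weights), collapse = ", ")),
    sprintf("risk class counts: %s",
            paste(sprintf("%d:%d", 1:5,
                          tabulate(result$riskmap$cells$risk_class, 5)),
                  collapse = ", ")),
    sprintf("structure: %s",
            paste(sprintf("%s=%d",
                          c("main", "secondary", "belt", "point"),
                          tabulate(factor(result$structure$components$label,
                                          c("main", "secondary", "belt", "point")),
                                   4)), collapse = ", ")),
    sprintf("site coverage classes 1-2: %.3f (%d of %d in grid, %d outside)",
            result$validation$coverage12, sum(result$validation$counts[1:2]),
            result$validation$n_in, result$validation$n_outside))
  writeLines(rep, fp("report.txt"))
  invisible(dir)
}
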