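# Plain-text interchange: GeoJSON for vector layers (roads, points, fishnet
# cells), ESRI ASCII grid for rasters, CSV for survey tables, YAML for run
# configuration.

#' Write road polylines to GeoJSON
#'
#' @param lines list of polyline coordinate matrices (or a `road_graph`).
#' @param path output file.
#' @param properties optional data.frame with one row per line (e.g. the
#'   `nqpd`/`tpbt` columns of [road_centrality()]).
#' @export
write_roads_geojson <- function(lines, path, properties = NULL) {
  if (inherits(lines, "road_graph")) lines <- lines$geometry
  feats <- lapply(seq_along(lines), function(i) {
    props <- if (!is.null(properties)) as.list(properties[i, , drop = FALSE])
             else list(id = i)
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString",
                         coordinates = unname(apply(as.matrix(lines[[i]]), 1,
                                                    as.numeric, simplify = FALSE))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read road polylines from GeoJSON
#'
#' @param path GeoJSON file of LineString features.
#' @return list with `geometry` (list of coordinate matrices) and
#'   `properties` (data.frame).
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  geom <- lapply(feats, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates, function(c2) as.numeric(unlist(c2))))
  })
  props <- do.call(rbind, lapply(feats, function(f) {
    as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v))
  }))
  list(geometry = geom, properties = props)
}

#' Write point records to GeoJSON
#'
#' @param points data.frame with `x`, `y` and any property columns (e.g.
#'   `category`, `subcategory`).
#' @param path output file.
#' @export
write_points_geojson <- function(points, path) {
  points <- as.data.frame(points)
  prop_cols <- setdiff(names(points), c("x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         properties = as.list(points[i, prop_cols, drop = FALSE]),
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read point records from GeoJSON
#'
#' @param path GeoJSON file of Point features.
#' @return data.frame with `x`, `y` and the feature properties.
#' @export
read_points_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(f) {
    cc <- as.numeric(unlist(f$geometry$coordinates))
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    c(list(x = cc[1], y = cc[2]), props)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write a surface as an ESRI ASCII grid
#'
#' @param surface a [density_surface()].
#' @param path output `.asc` file.
#' @param nodata value standing in for `NA` cells.
#' @export
write_surface_asc <- function(surface, path, nodata = -9999) {
  v <- surface$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", surface$origin[1]),
           sprintf("yllcorner %.10g", surface$origin[2]),
           sprintf("cellsize %.10g", surface$cell_size),
           sprintf("NODATA_value %g", nodata))
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(r) paste(format(r, digits = 10, trim = TRUE,
                                         scientific = FALSE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a surface
#'
#' @param path `.asc` file.
#' @return a [density_surface()] with `NA` for nodata cells.
#' @export
read_surface_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  density_surface(vals, c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize)
}

#' Write / read a survey table as CSV
#'
#' Columns `category`, `subcategory`, `mean`, `sd`, `n` (the `dependence`
#' column is recomputed on read).
#'
#' @param survey a [survey_table()].
#' @param path CSV file.
#' @export
write_survey_csv <- function(survey, path) {
  write.csv(survey[, c("category", "subcategory", "mean", "sd", "n")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  survey_table(tab$category, tab$subcategory, tab$mean,
               tab$sd %||% NA_real_, tab$n %||% NA_integer_)
}

#' Write a risk map's cells as GeoJSON polygons
#'
#' @param riskmap a [risk_map()].
#' @param path output file.
#' @export
write_riskmap_geojson <- function(riskmap, path) {
  cs <- riskmap$fishnet$cell_size
  cells <- riskmap$cells
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    x0 <- cells$x0[i]; y0 <- cells$y0[i]
    ring <- list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
                 c(x0, y0 + cs), c(x0, y0))
    list(type = "Feature",
         properties = list(cell_id = cells$cell_id[i], row = cells$row[i],
                           col = cells$col[i], score = cells$score[i],
                           risk_class = cells$risk_class[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' The file may contain a `synthetic:` block (arguments of
#' [synthetic_city_config()]) and a `pipeline:` block (arguments of
#' [run_pipeline()] other than the config).
#'
#' @param path YAML file.
#' @return list with `config` (a [synthetic_city_config()]) and `options`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$synthetic)) stop_ctx("YAML config needs a `synthetic:` block")
  syn <- y$synthetic
  for (nm in c("poi_category_props", "survey_means")) {
    if (!is.null(syn[[nm]])) syn[[nm]] <- unlist(syn[[nm]])
  }
  if (!is.null(syn$extent_m)) syn$extent_m <- as.numeric(unlist(syn$extent_m))
  list(config = do.call(synthetic_city_config, syn),
       options = y$pipeline %||% list())
}
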