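# Regular square analysis grid ("fishnet") and spatial-join helpers that
# attach raster, line and surface values to its cells.

# Sutherland-Hodgman clip of a polygon (matrix, open ring) to an axis-aligned
# rectangle; returns the clipped ring (possibly 0 rows)
clip_poly_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1L) n else i - 1L, ]
      ci <- inside(cur); pi <- inside(prev)
      if (ci) {
        if (!pi) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pi) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  p <- poly
  p <- clip_half(p, function(v) v[1] >= xmin, function(a, b) ix(a, b, xmin, 1))
  p <- clip_half(p, function(v) v[1] <= xmax, function(a, b) ix(a, b, xmax, 1))
  p <- clip_half(p, function(v) v[2] >= ymin, function(a, b) ix(a, b, ymin, 2))
  p <- clip_half(p, function(v) v[2] <= ymax, function(a, b) ix(a, b, ymax, 2))
  p
}

poly_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Build a regular fishnet over a study boundary
#'
#' Tiles the boundary's bounding box with axis-aligned square cells anchored
#' at the lower-left corner and keeps the cells that intersect the boundary
#' polygon with positive area. Cells are ordered row-major from the
#' south-west corner (row 1 = southernmost), and keep stable integer ids
#' derived from their (row, col) position.
#'
#' @param boundary polygon as a 2-column matrix of vertices (open ring), or a
#'   numeric `c(xmin, ymin, xmax, ymax)` rectangle.
#' @param cell_size_m cell side length in meters (default 1000).
#' @return An object of class `fishnet`: list with `cells` (data.frame
#'   `cell_id`, `row`, `col`, `x0`, `y0`), `origin`, `cell_size`, `nrow`,
#'   `ncol` and the `boundary` ring.
#' @export
make_fishnet <- function(boundary, cell_size_m = 1000) {
  check_number(cell_size_m, "cell_size_m", positive = TRUE)
  if (is.numeric(boundary) && length(boundary) == 4L) {
    boundary <- cbind(c(boundary[1], boundary[3], boundary[3], boundary[1]),
                      c(boundary[2], boundary[2], boundary[4], boundary[4]))
  }
  boundary <- as.matrix(boundary)
  if (nrow(boundary) < 3L || any(!is.finite(boundary))) {
    stop_ctx("`boundary` must be a polygon with >= 3 finite vertices")
  }
  if (poly_area(boundary) <= 0) stop_ctx("`boundary` polygon is degenerate")
  xmin <- min(boundary[, 1]); xmax <- max(boundary[, 1])
  ymin <- min(boundary[, 2]); ymax <- max(boundary[, 2])
  ncol_ <- ceiling((xmax - xmin) / cell_size_m)
  nrow_ <- ceiling((ymax - ymin) / cell_size_m)
  keep_row <- integer(0); keep_col <- integer(0)
  tol <- 1e-9 * cell_size_m^2
  for (r in seq_len(nrow_)) {
    y0 <- ymin + (r - 1) * cell_size_m
    for (cc in seq_len(ncol_)) {
      x0 <- xmin + (cc - 1) * cell_size_m
      clp <- clip_poly_rect(boundary, x0, x0 + cell_size_m, y0, y0 + cell_size_m)
      if (poly_area(clp) > tol) {
        keep_row <- c(keep_row, r); keep_col <- c(keep_col, cc)
      }
    }
  }
  if (!length(keep_row)) stop_ctx("no fishnet cell intersects the boundary")
  cells <- data.frame(
    cell_id = (keep_row - 1L) * ncol_ + keep_col,
    row = keep_row, col = keep_col,
    x0 = xmin + (keep_col - 1) * cell_size_m,
    y0 = ymin + (keep_row - 1) * cell_size_m
  )
  structure(list(cells = cells, origin = c(xmin, ymin),
                 cell_size = cell_size_m, nrow = nrow_, ncol = ncol_,
                 boundary = boundary),
            class = "fishnet")
}

#' @export
print.fishnet <- function(x, ...) {
  cat(sprintf("<fishnet> %d cells of %g m (grid %d x %d)\n",
              nrow(x$cells), x$cell_size, x$nrow, x$ncol))
  invisible(x)
}

# map point coordinates to the retained-cell index (NA when outside)
fishnet_cell_index <- function(fishnet, x, y) {
  col <- floor((x - fishnet$origin[1]) / fishnet$cell_size) + 1L
  row <- floor((y - fishnet$origin[2]) / fishnet$cell_size) + 1L
  ok <- col >= 1L & col <= fishnet$ncol & row >= 1L & row <= fishnet$nrow
  id <- ifelse(ok, (row - 1L) * fishnet$ncol + col, NA_integer_)
  match(id, fishnet$cells$cell_id)
}

#' Attach raster values to fishnet cells
#'
#' Aggregates a raster over the fishnet: every raster cell is assigned to the
#' fishnet cell containing its center, nodata (`NA`) cells are excluded, and
#' the chosen statistic is taken per fishnet cell. Fishnet cells receiving no
#' raster centers get 0 and are flagged in the `"empty"` attribute.
#'
#' @param fishnet a [make_fishnet()] result.
#' @param raster a [density_surface()] whose cell size does not exceed the
#'   fishnet cell size.
#' @param statistic `"mean"` or `"sum"`.
#' @return numeric vector aligned with `fishnet$cells`, with a logical
#'   `"empty"` attribute.
#' @export
attach_raster <- function(fishnet, raster, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  if (!inherits(raster, "density_surface")) stop_ctx("`raster` must be a density_surface")
  if (raster$cell_size > fishnet$cell_size + 1e-9) {
    stop_ctx("raster resolution is coarser than the fishnet cell size")
  }
  pts <- surface_points(raster)
  pts <- pts[!is.na(pts$value), , drop = FALSE]
  idx <- fishnet_cell_index(fishnet, pts$x, pts$y)
  sel <- !is.na(idx)
  if (!any(sel)) stop_ctx("raster does not overlap the fishnet")
  f <- factor(idx[sel], levels = seq_len(nrow(fishnet$cells)))
  out <- if (statistic == "mean") {
    v <- tapply(pts$value[sel], f, mean)
    as.numeric(ifelse(is.na(v), 0, v))
  } else {
    as.numeric(tapply(pts$value[sel], f, sum, default = 0))
  }
  attr(out, "empty") <- tabulate(f, nbins = nrow(fishnet$cells)) == 0L
  out
}

#' Attach per-segment values to fishnet cells
#'
#' Clips every road segment to the fishnet cells and computes, per cell, the
#' length-weighted mean of the segment values over the clipped pieces inside
#' the cell. Cells crossed by no road get 0 and are flagged in the `"empty"`
#' attribute.
#'
#' @param fishnet a [make_fishnet()] result.
#' @param lines list of polyline coordinate matrices (or a `road_graph`,
#'   whose segment geometries are used).
#' @param values one numeric value per line.
#' @return numeric vector aligned with `fishnet$cells`, with a logical
#'   `"empty"` attribute.
#' @export
attach_lines <- function(fishnet, lines, values) {
  if (inherits(lines, "road_graph")) lines <- lines$geometry
  if (length(values) != length(lines)) {
    stop_ctx("`values` must have one entry per line")
  }
  if (any(!is.finite(values))) stop_ctx("segment values must be finite")
  ncell <- nrow(fishnet$cells)
  wsum <- numeric(ncell)
  vsum <- numeric(ncell)
  cs <- fishnet$cell_size
  ox <- fishnet$origin[1]; oy <- fishnet$origin[2]
  for (i in seq_along(lines)) {
    g <- as.matrix(lines[[i]])
    for (k in seq_len(nrow(g) - 1L)) {
      p0 <- g[k, 1:2]; p1 <- g[k + 1L, 1:2]
      len <- sqrt(sum((p1 - p0)^2))
      if (len == 0) next
      # split the straight piece at every grid line it crosses
      ts <- c(0, 1)
      for (coord in 1:2) {
        o <- if (coord == 1) ox else oy
        lo <- min(p0[coord], p1[coord]); hi <- max(p0[coord], p1[coord])
        ks <- seq(ceiling((lo - o) / cs), floor((hi - o) / cs))
        ks <- ks[o + ks * cs > lo & o + ks * cs < hi]
        if (length(ks) && p1[coord] != p0[coord]) {
          ts <- c(ts, (o + ks * cs - p0[coord]) / (p1[coord] - p0[coord]))
        }
      }
      ts <- sort(unique(pmin(1, pmax(0, ts))))
      for (s in seq_len(length(ts) - 1L)) {
        tm <- (ts[s] + ts[s + 1L]) / 2
        mid <- p0 + tm * (p1 - p0)
        idx <- fishnet_cell_index(fishnet, mid[1], mid[2])
        if (is.na(idx)) next
        piece <- len * (ts[s + 1L] - ts[s])
        wsum[idx] <- wsum[idx] + piece
        vsum[idx] <- vsum[idx] + piece * values[i]
      }
    }
  }
  out <- ifelse(wsum > 0, vsum / pmax(wsum, .Machine$double.xmin), 0)
  attr(out, "empty") <- wsum == 0
  out
}

#' Attach a density surface to fishnet cells
#'
#' Mean of the surface cells whose centers fall inside each fishnet cell
#' (same center-point rule as [attach_raster()] with `statistic = "mean"`).
#'
#' @param fishnet a [make_fishnet()] result.
#' @param surface a [density_surface()].
#' @return numeric vector aligned with `fishnet$cells`.
#' @export
attach_surface <- function(fishnet, surface) {
  attach_raster(fishnet, surface, statistic = "mean")
}
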