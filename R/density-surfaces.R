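#' Gridded scalar surface
#'
#' Light-weight raster container used for population grids, night-light grids
#' and kernel density surfaces. Values are stored in a matrix whose rows run
#' south to north and whose columns run west to east; `values[iy, ix]` is the
#' cell whose lower-left corner is at
#' `(origin[1] + (ix-1)*cell_size, origin[2] + (iy-1)*cell_size)`.
#'
#' @param values numeric matrix of cell values (may contain `NA` for nodata);
#'   finite values must be non-negative.
#' @param origin numeric length-2, coordinates (m) of the grid's lower-left
#'   corner.
#' @param cell_size cell side length in meters.
#' @param bandwidth kernel bandwidth (m) used to build the surface, if any.
#' @return An object of class `density_surface`.
#' @export
density_surface <- function(values, origin, cell_size, bandwidth = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_ctx("`values` must be a numeric matrix")
  }
  if (any(values < 0, na.rm = TRUE)) stop_ctx("surface values must be >= 0")
  check_number(cell_size, "cell_size", positive = TRUE)
  if (length(origin) != 2L || !is.numeric(origin) || any(!is.finite(origin))) {
    stop_ctx("`origin` must be two finite coordinates")
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), bandwidth = bandwidth),
    class = "density_surface"
  )
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("<density_surface> %d x %d cells of %g m\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  origin (%g, %g); value range [%g, %g]%s\n",
              x$origin[1], x$origin[2],
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              if (is.finite(x$bandwidth)) sprintf("; bandwidth %g m", x$bandwidth) else ""))
  invisible(x)
}

# cell-center coordinates of a surface, as vectors along each axis
surface_axes <- function(s) {
  list(x = s$origin[1] + (seq_len(ncol(s$values)) - 0.5) * s$cell_size,
       y = s$origin[2] + (seq_len(nrow(s$values)) - 0.5) * s$cell_size)
}

#' Cell centers and values of a surface
#'
#' @param surface a [density_surface()].
#' @return data.frame with columns `x`, `y`, `value`, one row per cell.
#' @export
surface_points <- function(surface) {
  ax <- surface_axes(surface)
  data.frame(x = rep(ax$x, each = nrow(surface$values)),
             y = rep(ax$y, times = ncol(surface$values)),
             value = as.vector(surface$values))
}

#' Total integral of a surface
#'
#' Sum of cell values times cell area; for a kernel density surface whose
#' kernels lie inside the grid this approximates the total point weight.
#'
#' @param surface a [density_surface()].
#' @return scalar integral.
#' @export
surface_integral <- function(surface) {
  sum(surface$values, na.rm = TRUE) * surface$cell_size^2
}

#' Standard distance of a point set
#'
#' Root mean squared distance of the points from their (weighted) mean
#' center: `SD = sqrt(sum(w_i * ((x_i - xbar)^2 + (y_i - ybar)^2)) / sum(w_i))`.
#'
#' @param x,y point coordinates in meters.
#' @param weights optional non-negative point weights (default 1).
#' @return scalar standard distance in meters.
#' @export
standard_distance <- function(x, y, weights = NULL) {
  pts <- check_points(x, y, weights)
  w <- pts$w / sum(pts$w)
  cx <- sum(w * pts$x); cy <- sum(w * pts$y)
  sqrt(sum(w * ((pts$x - cx)^2 + (pts$y - cy)^2)))
}

#' Median distance of a point set
#'
#' Median of the Euclidean distances from each point to the (weighted) mean
#' center. With an even number of points the mean of the two central order
#' statistics is returned.
#'
#' @inheritParams standard_distance
#' @return scalar median distance in meters.
#' @export
median_distance <- function(x, y, weights = NULL) {
  pts <- check_points(x, y, weights)
  w <- pts$w / sum(pts$w)
  cx <- sum(w * pts$x); cy <- sum(w * pts$y)
  median(sqrt((pts$x - cx)^2 + (pts$y - cy)^2))
}

#' Rule-of-thumb kernel search radius
#'
#' The bandwidth rule `H = 0.9 * min(sqrt(1/ln 2) * Dm, SD) * n^(-0.2)`,
#' where `Dm` is the median distance and `SD` the standard distance of the
#' points about their mean center. Scales linearly with the coordinates.
#'
#' @inheritParams standard_distance
#' @return bandwidth in meters.
#' @export
rule_of_thumb_radius <- function(x, y, weights = NULL) {
  pts <- check_points(x, y, weights)
  n <- length(pts$x)
  if (n < 2L) stop_ctx("need at least 2 points; supply an explicit bandwidth instead")
  sd_ <- standard_distance(pts$x, pts$y, pts$w)
  dm <- median_distance(pts$x, pts$y, pts$w)
  h <- 0.9 * min(sqrt(1 / log(2)) * dm, sd_) * n^(-0.2)
  if (h <= 0) {
    stop_ctx("points are (nearly) coincident; rule-of-thumb radius degenerates to 0 -- ",
             "supply an explicit bandwidth")
  }
  h
}

check_points <- function(x, y, weights = NULL) {
  if (length(x) != length(y) || length(x) < 1L) {
    stop_ctx("`x` and `y` must be equal-length, non-empty coordinate vectors")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_ctx("coordinates must be finite")
  w <- weights %||% rep(1, length(x))
  if (length(w) != length(x) || any(!is.finite(w)) || any(w < 0)) {
    stop_ctx("`weights` must be non-negative and match the points")
  }
  if (sum(w) == 0) stop_ctx("total point weight is zero")
  list(x = as.numeric(x), y = as.numeric(y), w = as.numeric(w))
}

#' Kernel density surface from weighted points
#'
#' Evaluates, at every cell center `s` of a regular grid, the quartic
#' (biweight) kernel density
#' `f(s) = sum_i w_i * 3/(pi r^2) * (1 - d_i^2 / r^2)^2` over the points
#' within distance `r = bandwidth` of `s`. The kernel has compact support, so
#' the surface integrates to the total point weight whenever all kernels lie
#' inside the grid (to about 1% at `cell_size <= bandwidth/10`).
#'
#' @inheritParams standard_distance
#' @param bandwidth kernel search radius `r` in meters (> 0).
#' @param origin lower-left corner of the output grid.
#' @param cell_size output cell side in meters; defaults to `bandwidth/10`.
#' @param dim integer `c(nrow, ncol)` of the output grid. If omitted the grid
#'   spans the points plus one bandwidth of padding.
#' @return A [density_surface()] in weight-per-square-meter units.
#' @export
kde_surface <- function(x, y, bandwidth, weights = NULL,
                        origin = NULL, cell_size = NULL, dim = NULL) {
  pts <- check_points(x, y, weights)
  check_number(bandwidth, "bandwidth", positive = TRUE)
  cell_size <- cell_size %||% (bandwidth / 10)
  check_number(cell_size, "cell_size", positive = TRUE)
  if (is.null(origin) || is.null(dim)) {
    pad <- bandwidth
    origin <- c(min(pts$x) - pad, min(pts$y) - pad)
    dim <- c(ceiling((max(pts$y) + pad - origin[2]) / cell_size),
             ceiling((max(pts$x) + pad - origin[1]) / cell_size))
  }
  dim <- as.integer(dim)
  if (length(dim) != 2L || any(dim < 1L)) stop_ctx("`dim` must be c(nrow, ncol) >= 1")

  vals <- matrix(0, nrow = dim[1], ncol = dim[2])
  cx <- origin[1] + (seq_len(dim[2]) - 0.5) * cell_size
  cy <- origin[2] + (seq_len(dim[1]) - 0.5) * cell_size
  r2 <- bandwidth^2
  const <- 3 / (pi * r2)
  for (i in seq_along(pts$x)) {
    jx <- which(abs(cx - pts$x[i]) < bandwidth)
    jy <- which(abs(cy - pts$y[i]) < bandwidth)
    if (!length(jx) || !length(jy)) next
    d2 <- outer(cy[jy] - pts$y[i], cx[jx] - pts$x[i],
                function(dy, dx) dy^2 + dx^2)
    k <- (1 - d2 / r2)^2
    k[d2 >= r2] <- 0
    vals[jy, jx] <- vals[jy, jx] + pts$w[i] * const * k
  }
  density_surface(vals, origin, cell_size, bandwidth = bandwidth)
}

#' Functional mixed density surface
#'
#' Cell-wise weighted sum of per-category density surfaces. All surfaces must
#' share the same grid and the weights must be non-negative and sum to one;
#' no silent renormalization is performed.
#'
#' @param surfaces named list of [density_surface()] objects on identical
#'   grids, one per POI category.
#' @param weights named numeric vector of category weights (same names as
#'   `surfaces`), summing to 1 within `1e-6`.
#' @return A [density_surface()] with the blended values.
#' @export
mixed_density <- function(surfaces, weights) {
  if (!length(surfaces)) stop_ctx("`surfaces` must be a non-empty list")
  if (is.null(names(surfaces)) || is.null(names(weights))) {
    stop_ctx("`surfaces` and `weights` must be named by category")
  }
  if (!setequal(names(surfaces), names(weights))) {
    stop_ctx("`surfaces` and `weights` must cover the same categories")
  }
  weights <- weights[names(surfaces)]
  if (any(weights < 0)) stop_ctx("category weights must be >= 0")
  if (abs(sum(weights) - 1) > 1e-6) {
    stop_ctx(sprintf("category weights must sum to 1 (got %.8f); not renormalizing",
                     sum(weights)))
  }
  ref <- surfaces[[1]]
  for (s in surfaces) {
    if (!identical(base::dim(s$values), base::dim(ref$values)) ||
        any(s$origin != ref$origin) || s$cell_size != ref$cell_size) {
      stop_ctx("all surfaces must share an identical grid")
    }
  }
  vals <- matrix(0, nrow = nrow(ref$values), ncol = ncol(ref$values))
  for (nm in names(surfaces)) vals <- vals + weights[[nm]] * surfaces[[nm]]$values
  density_surface(vals, ref$origin, ref$cell_size)
}
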