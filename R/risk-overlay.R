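# Composite risk score, geometric-interval classification, spatial structure
# of the top risk class, and validation against point sites.

#' Composite risk score
#'
#' Weighted sum `score_i = sum_j D_j * x_ij` of normalized indicators; with
#' weights summing to 1 and indicators in [0, 1] the score is bounded in
#' [0, 1] and monotone in every indicator.
#'
#' @param x normalized indicator matrix (cells x indicators).
#' @param weights indicator weights (an [entropy_weights()] object or a
#'   numeric vector summing to 1).
#' @return numeric score per cell.
#' @export
composite_score <- function(x, weights) {
  if (inherits(weights, "entropy_weights")) weights <- weights$weights
  x <- as.matrix(x)
  if (ncol(x) != length(weights)) stop_ctx("weights do not match indicator columns")
  if (abs(sum(weights) - 1) > 1e-9) stop_ctx("weights must sum to 1")
  if (!is.null(colnames(x)) && !is.null(names(weights))) {
    weights <- weights[colnames(x)]
    if (any(is.na(weights))) stop_ctx("weight names do not match indicator columns")
  }
  as.numeric(x %*% weights)
}

#' Geometric-interval class breaks
#'
#' Class widths forming a geometric series `w_m = w_1 * g^(m-1)` that spans
#' `[min, max]`, with `w_1 = (max - min) (g - 1) / (g^k - 1)`. The common
#' ratio `g` is chosen by a one-dimensional search over a log-spaced grid in
#' `g_range` minimizing the variance of the per-class counts (ties broken
#' toward the smallest `g`); `g = 1` recovers equal intervals. Suited to the
#' right-skewed value distributions typical of risk scores.
#'
#' @param values numeric values to classify.
#' @param k number of classes (default 5).
#' @param g fixed common ratio; `NULL` (default) searches.
#' @param g_range search interval for `g`.
#' @param n_g number of grid points in the search.
#' @return list of class `geom_breaks` with `breaks` (the `k - 1` interior
#'   break values, ascending), `g`, `min` and `max`. With fewer than `k`
#'   distinct values, falls back to quantile breaks with a warning
#'   (`g = NA`).
#' @export
geometric_interval_breaks <- function(values, k = 5, g = NULL,
                                      g_range = c(1 / 8, 8), n_g = 400) {
  k <- check_count(k, "k", min = 2L)
  if (any(!is.finite(values))) stop_ctx("`values` must be finite")
  rng <- range(values)
  if (length(unique(values)) < k) {
    warning(sprintf("fewer than %d distinct values; falling back to quantile breaks", k),
            call. = FALSE)
    br <- unname(quantile(values, probs = seq_len(k - 1L) / k, type = 7))
    return(structure(list(breaks = br, g = NA_real_, min = rng[1], max = rng[2]),
                     class = "geom_breaks"))
  }
  breaks_for <- function(gv) {
    if (abs(gv - 1) < 1e-12) {
      rng[1] + diff(rng) * seq_len(k - 1L) / k
    } else {
      w1 <- diff(rng) * (gv - 1) / (gv^k - 1)
      rng[1] + w1 * (gv^seq_len(k - 1L) - 1) / (gv - 1)
    }
  }
  if (!is.null(g)) {
    check_number(g, "g", positive = TRUE)
    return(structure(list(breaks = breaks_for(g), g = g, min = rng[1], max = rng[2]),
                     class = "geom_breaks"))
  }
  grid <- sort(unique(c(1, exp(seq(log(g_range[1]), log(g_range[2]),
                                   length.out = n_g)))))
  best_g <- NA_real_; best_v <- Inf
  for (gv in grid) {
    cls <- classify(values, breaks_for(gv))
    v <- var(tabulate(cls, nbins = k))
    if (v < best_v - 1e-12) { best_v <- v; best_g <- gv }
  }
  structure(list(breaks = breaks_for(best_g), g = best_g,
                 min = rng[1], max = rng[2]),
            class = "geom_breaks")
}

#' @export
print.geom_breaks <- function(x, ...) {
  cat(sprintf("<geom_breaks> g = %.4g over [%.4g, %.4g]\n  breaks: %s\n",
              x$g, x$min, x$max, paste(signif(x$breaks, 5), collapse = ", ")))
  invisible(x)
}

#' Classify scores into risk grades
#'
#' Class 1 is the highest-risk (top) interval and class `k` the lowest.
#' A value falling exactly on a break is assigned to the riskier (higher
#' score) class.
#'
#' @param scores numeric values.
#' @param breaks ascending interior break values (a [geometric_interval_breaks()]
#'   result is also accepted).
#' @return integer classes in `1..(length(breaks) + 1)`.
#' @export
classify <- function(scores, breaks) {
  if (inherits(breaks, "geom_breaks")) breaks <- breaks$breaks
  if (is.unsorted(breaks)) stop_ctx("`breaks` must be ascending")
  k <- length(breaks) + 1L
  as.integer(k - findInterval(scores, breaks))
}

#' Risk map over a fishnet
#'
#' Bundles per-cell composite scores, risk classes and the class breaks.
#'
#' @param fishnet a [make_fishnet()] result.
#' @param score per-cell composite score.
#' @param breaks a [geometric_interval_breaks()] result (or numeric breaks).
#' @return object of class `risk_map` with a `cells` data.frame carrying
#'   `score` and `risk_class`.
#' @export
risk_map <- function(fishnet, score, breaks) {
  if (length(score) != nrow(fishnet$cells)) stop_ctx("one score per fishnet cell required")
  cls <- classify(score, breaks)
  cells <- cbind(fishnet$cells, score = score, risk_class = cls)
  structure(list(fishnet = fishnet, cells = cells, breaks = breaks),
            class = "risk_map")
}

#' @export
print.risk_map <- function(x, ...) {
  k <- max(x$cells$risk_class)
  cat(sprintf("<risk_map> %d cells in %d classes (1 = highest risk)\n",
              nrow(x$cells), k))
  print(table(risk_class = x$cells$risk_class))
  invisible(x)
}

# connected components of a set of (row, col) cells under 4- or 8-connectivity
grid_components <- function(row, col, connectivity = 8) {
  n <- length(row)
  comp <- integer(n)
  key <- paste(row, col)
  lookup <- setNames(seq_len(n), key)
  offs <- if (connectivity == 8) {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nc <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    nc <- nc + 1L
    queue <- i
    comp[i] <- nc
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- paste(row[cur] + offs[, 1], col[cur] + offs[, 2])
      hit <- lookup[nb]
      hit <- hit[!is.na(hit)]
      new <- hit[comp[hit] == 0L]
      comp[new] <- nc
      queue <- c(queue, new)
    }
  }
  comp
}

#' Spatial structure of the first-level risk area
#'
#' Labels the connected components (8-connected by default) of class-1 cells:
#' the largest component is the `main` risk concentration area; elongated
#' chains (major/minor principal-axis extent ratio at least `belt_ratio` and
#' major extent at least `belt_min_cells` cells) are `belt`s; remaining
#' components with at least `secondary_min_cells` cells are `secondary`
#' centers; the rest are isolated `point`s.
#'
#' @param riskmap a [risk_map()].
#' @param secondary_min_cells minimum component size for a secondary center.
#' @param belt_ratio minimum elongation for a belt.
#' @param belt_min_cells minimum major-axis extent (cells) for a belt.
#' @param connectivity 8 (default) or 4.
#' @return object of class `spatial_structure`: data.frame `components`
#'   (`component`, `label`, `n_cells`, `elongation`) plus a `membership`
#'   vector giving each class-1 cell's component.
#' @export
spatial_structure <- function(riskmap, secondary_min_cells = 5,
                              belt_ratio = 4, belt_min_cells = 8,
                              connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop_ctx("`connectivity` must be 4 or 8")
  top <- riskmap$cells[riskmap$cells$risk_class == 1L, , drop = FALSE]
  if (!nrow(top)) {
    return(structure(list(components = data.frame(component = integer(0),
                                                  label = character(0),
                                                  n_cells = integer(0),
                                                  elongation = numeric(0)),
                          membership = integer(0), cells = top),
                     class = "spatial_structure"))
  }
  comp <- grid_components(top$row, top$col, connectivity)
  ncomp <- max(comp)
  sizes <- tabulate(comp, nbins = ncomp)
  elong <- major <- numeric(ncomp)
  for (cidx in seq_len(ncomp)) {
    m <- cbind(top$col[comp == cidx], top$row[comp == cidx])
    if (nrow(m) == 1L) { elong[cidx] <- 1; major[cidx] <- 1; next }
    cm <- sweep(m, 2, colMeans(m))
    ev <- eigen(crossprod(cm) / nrow(m), symmetric = TRUE)$vectors
    pr <- cm %*% ev
    ext <- apply(pr, 2, function(v) diff(range(v))) + 1
    major[cidx] <- max(ext)
    elong[cidx] <- max(ext) / min(ext)
  }
  label <- character(ncomp)
  main_id <- which(sizes == max(sizes))[1]
  for (cidx in seq_len(ncomp)) {
    label[cidx] <-
      if (cidx == main_id) "main"
      else if (elong[cidx] >= belt_ratio && major[cidx] >= belt_min_cells) "belt"
      else if (sizes[cidx] >= secondary_min_cells) "secondary"
      else "point"
  }
  structure(list(components = data.frame(component = seq_len(ncomp),
                                         label = label, n_cells = sizes,
                                         elongation = elong),
                 membership = comp, cells = top),
            class = "spatial_structure")
}

#' @export
print.spatial_structure <- function(x, ...) {
  tab <- table(factor(x$components$label,
                      levels = c("main", "secondary", "belt", "point")))
  cat(sprintf("<spatial_structure> %s\n",
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Validate a risk map against point sites
#'
#' Assigns each site the risk class of its containing fishnet cell and
#' reports per-class counts, the number of sites outside the fishnet, and
#' the coverage fraction of the two highest-risk classes.
#'
#' @param sites data.frame (or matrix) with `x`, `y` site coordinates.
#' @param riskmap a [risk_map()].
#' @return object of class `site_validation` with `counts` (per class),
#'   `n_outside`, `n_in` and `coverage12`.
#' @export
validate_sites <- function(sites, riskmap) {
  sites <- as.data.frame(sites)
  k <- length(if (inherits(riskmap$breaks, "geom_breaks")) riskmap$breaks$breaks
              else riskmap$breaks) + 1L
  if (!nrow(sites)) {
    return(structure(list(counts = setNames(integer(k), seq_len(k)),
                          n_outside = 0L, n_in = 0L, coverage12 = NA_real_),
                     class = "site_validation"))
  }
  idx <- fishnet_cell_index(riskmap$fishnet, sites$x, sites$y)
  inside <- !is.na(idx)
  cls <- riskmap$cells$risk_class[idx[inside]]
  counts <- tabulate(cls, nbins = k)
  names(counts) <- seq_len(k)
  n_in <- sum(inside)
  structure(list(counts = counts, n_outside = sum(!inside), n_in = n_in,
                 coverage12 = if (n_in) sum(counts[1:2]) / n_in else NA_real_),
            class = "site_validation")
}

#' @export
print.site_validation <- function(x, ...) {
  cat(sprintf("<site_validation> %d sites in grid (%d outside)\n", x$n_in, x$n_outside))
  print(x$counts)
  cat(sprintf("  coverage of classes 1-2: %.3f\n", x$coverage12))
  invisible(x)
}
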