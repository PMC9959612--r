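#' Build a segment-based road graph
#'
#' Turns a collection of polylines into the segment graph used by the
#' closeness/betweenness analysis. Polyline endpoints closer than
#' `snap_tol_m` are merged into a single junction; two segments are adjacent
#' when they share a junction. Segments are deliberately *not* split where
#' their geometries cross without a shared endpoint (no planarization), and
#' parallel duplicate segments are retained as distinct segments.
#'
#' @param polylines list of numeric matrices with columns x, y (>= 2 rows
#'   each), one per road segment; or a single such matrix.
#' @param snap_tol_m endpoint snapping tolerance in meters.
#' @param weights per-segment weight W (recycled; default 1).
#' @return An object of class `road_graph` with elements `segments`
#'   (data.frame: `segment`, `length_m`, `turn_deg`, `weight`, `j1`, `j2`),
#'   `geometry` (list of coordinate matrices), `junctions` (data.frame with
#'   junction coordinates) and `dual` (data.frame of inter-segment
#'   transitions with their junction and turn angle in degrees).
#' @export
build_road_graph <- function(polylines, snap_tol_m = 0.5, weights = 1) {
  if (is.matrix(polylines)) polylines <- list(polylines)
  if (!is.list(polylines) || !length(polylines)) {
    stop_ctx("`polylines` must be a non-empty list of coordinate matrices")
  }
  check_number(snap_tol_m, "snap_tol_m")
  if (snap_tol_m < 0) stop_ctx("`snap_tol_m` must be >= 0")
  geom <- lapply(polylines, function(p) {
    p <- as.matrix(p)
    if (ncol(p) < 2L || nrow(p) < 2L || any(!is.finite(p[, 1:2]))) {
      stop_ctx("each polyline needs >= 2 finite x,y vertices")
    }
    unname(p[, 1:2, drop = FALSE])
  })
  lens <- vapply(geom, polyline_length, 0)
  bad <- which(lens <= 0)
  if (length(bad)) {
    warning(sprintf("rejected %d zero-length polyline(s): %s",
                    length(bad), paste(head(bad, 10L), collapse = ", ")),
            call. = FALSE)
    geom <- geom[-bad]
    lens <- lens[-bad]
  }
  n <- length(geom)
  if (!n) stop_ctx("no usable polylines (all zero-length)")
  w <- rep_len(as.numeric(weights), n)
  if (any(!is.finite(w)) || any(w < 0)) stop_ctx("segment weights must be >= 0")

  # snap endpoints into junctions (greedy, order-deterministic)
  ends <- do.call(rbind, lapply(geom, function(p) rbind(p[1, ], p[nrow(p), ])))
  jx <- numeric(0); jy <- numeric(0)
  jid <- integer(nrow(ends))
  for (i in seq_len(nrow(ends))) {
    if (length(jx)) {
      d2 <- (jx - ends[i, 1])^2 + (jy - ends[i, 2])^2
      hit <- which(d2 <= snap_tol_m^2)
    } else hit <- integer(0)
    if (length(hit)) {
      jid[i] <- hit[1]
    } else {
      jx <- c(jx, ends[i, 1]); jy <- c(jy, ends[i, 2])
      jid[i] <- length(jx)
    }
  }
  j1 <- jid[seq(1L, by = 2L, length.out = n)]
  j2 <- jid[seq(2L, by = 2L, length.out = n)]

  segments <- data.frame(
    segment = seq_len(n),
    length_m = lens,
    turn_deg = vapply(geom, polyline_turn_deg, 0),
    weight = w,
    j1 = j1, j2 = j2
  )
  junctions <- data.frame(junction = seq_along(jx), x = jx, y = jy)

  # dual transitions: one per unordered pair of distinct segment ends
  # meeting at a junction
  inc <- data.frame(junction = c(j1, j2),
                    segment = rep(seq_len(n), 2L),
                    end = rep(c(1L, 2L), each = n))
  dual <- list()
  for (j in seq_along(jx)) {
    at <- inc[inc$junction == j, , drop = FALSE]
    m <- nrow(at)
    if (m < 2L) next
    for (a in 1:(m - 1L)) {
      for (b in (a + 1L):m) {
        if (at$segment[a] == at$segment[b]) next  # no u-turn onto self
        turn <- transition_angle(geom[[at$segment[a]]], at$end[a],
                                 geom[[at$segment[b]]], at$end[b])
        dual[[length(dual) + 1L]] <- data.frame(
          from = at$segment[a], to = at$segment[b], junction = j, turn_deg = turn)
      }
    }
  }
  dual <- if (length(dual)) do.call(rbind, dual) else
    data.frame(from = integer(0), to = integer(0),
               junction = integer(0), turn_deg = numeric(0))

  structure(list(segments = segments, geometry = geom,
                 junctions = junctions, dual = dual,
                 snap_tol_m = snap_tol_m),
            class = "road_graph")
}

# turn angle (deg) when travelling along segment a into the shared junction
# (at end `ea`) and out along segment b (from its end `eb`); symmetric in the
# direction of travel
transition_angle <- function(ga, ea, gb, eb) {
  v_in <- if (ea == 1L) ga[1, ] - ga[2, ] else ga[nrow(ga), ] - ga[nrow(ga) - 1L, ]
  v_out <- if (eb == 1L) gb[2, ] - gb[1, ] else gb[nrow(gb) - 1L, ] - gb[nrow(gb), ]
  vec_angle_deg(v_in, v_out)
}

#' @export
print.road_graph <- function(x, ...) {
  cat(sprintf("<road_graph> %d segments, %d junctions, %d transitions\n",
              nrow(x$segments), nrow(x$junctions), nrow(x$dual)))
  cat(sprintf("  total length %.1f m; snap tolerance %g m\n",
              sum(x$segments$length_m), x$snap_tol_m))
  invisible(x)
}

#' Distance metric specification for network analysis
#'
#' @param mode `"metric"` (network meters), `"angular"` (cumulative turn
#'   degrees) or `"hybrid"` (meters plus `angular_weight_m_per_deg` meters of
#'   equivalent cost per degree of turn).
#' @param angular_weight_m_per_deg hybrid conversion factor, meters per
#'   degree (>= 0); ignored by the pure modes.
#' @return An object of class `distance_spec`.
#' @export
distance_spec <- function(mode = c("metric", "angular", "hybrid"),
                          angular_weight_m_per_deg = 1.0) {
  mode <- match.arg(mode)
  check_number(angular_weight_m_per_deg, "angular_weight_m_per_deg")
  if (angular_weight_m_per_deg < 0) stop_ctx("`angular_weight_m_per_deg` must be >= 0")
  structure(list(mode = mode, angular_weight = angular_weight_m_per_deg),
            class = "distance_spec")
}

# cost of each dual transition under a distance spec; segment-to-segment
# distance is midpoint-to-midpoint, so each transition carries half of both
# segments' internal cost plus the junction turn
dual_costs <- function(graph, dist) {
  d <- graph$dual
  seg <- graph$segments
  met <- (seg$length_m[d$from] + seg$length_m[d$to]) / 2
  ang <- d$turn_deg + (seg$turn_deg[d$from] + seg$turn_deg[d$to]) / 2
  switch(dist$mode,
         metric = met,
         angular = ang,
         hybrid = met + dist$angular_weight * ang)
}

# full matrix of segment-to-segment shortest-path costs
seg_dist_matrix <- function(graph, dist = distance_spec("metric")) {
  n <- nrow(graph$segments)
  if (nrow(graph$dual) == 0L) {
    m <- matrix(Inf, n, n); diag(m) <- 0
    return(m)
  }
  g <- igraph::graph_from_data_frame(
    graph$dual[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  m <- igraph::distances(g, weights = dual_costs(graph, dist))
  ord <- match(as.character(seq_len(n)), igraph::V(g)$name)
  m <- m[ord, ord, drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Network distance between road segments
#'
#' Least-cost distance from the midpoint of one segment to the midpoint of
#' another along the network. Under the metric mode each terminal segment
#' contributes half its length; the angular mode accumulates turn degrees at
#' junctions (plus half of each terminal segment's internal curvature); the
#' hybrid mode is their linear combination. `d(x, x) = 0`; unreachable pairs
#' are `Inf`.
#'
#' @param graph a [build_road_graph()] result.
#' @param x,y segment ids; `NULL` means all segments.
#' @param dist a [distance_spec()].
#' @return numeric matrix of distances (rows `x`, columns `y`), dropped to a
#'   vector/scalar when a single id is given on either side.
#' @export
segment_distance <- function(graph, x = NULL, y = NULL,
                             dist = distance_spec("metric")) {
  n <- nrow(graph$segments)
  ids <- function(v, nm) {
    if (is.null(v)) return(seq_len(n))
    v <- as.integer(v)
    if (any(is.na(v)) || any(v < 1L) || any(v > n)) {
      stop_ctx(sprintf("unknown segment id in `%s`", nm))
    }
    v
  }
  xi <- ids(x, "x"); yi <- ids(y, "y")
  m <- seg_dist_matrix(graph, dist)[xi, yi, drop = TRUE]
  m
}
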