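# Radius-limited segment centralities (sDNA-style closeness and betweenness).
#
# Both measures work on midpoint-to-midpoint network distances between
# segments (see segment_distance) and restrict attention to segments within a
# search radius R of the origin segment. Discrete space is assumed: a segment
# is either inside the radius (P = 1) or outside (P = 0).

# number of equal-cost geodesics between every pair of segments, consistent
# with the distances in D; parallel transitions through different junctions
# count as distinct routes. Zero-cost transitions (possible in pure angular
# mode along collinear continuations) are handled by fixpoint iteration over
# equal-distance groups, which is exact because zero-cost cycles cannot occur
# in plane geometry.
geodesic_counts <- function(graph, D, costs, tol) {
  n <- nrow(graph$segments)
  d <- graph$dual
  ed_from <- c(d$from, d$to)
  ed_to <- c(d$to, d$from)
  ed_w <- rep(costs, 2L)
  inc <- split(seq_along(ed_to), factor(ed_to, levels = seq_len(n)))
  S <- matrix(0, n, n)
  for (y in seq_len(n)) {
    dy <- D[y, ]
    sig <- numeric(n)
    sig[y] <- 1
    reach <- which(is.finite(dy))
    ord <- reach[order(dy[reach])]
    # partition into tie groups by distance
    if (length(ord) > 1L) {
      brk <- cumsum(c(0, diff(dy[ord]) > tol))
      for (g in split(ord, brk)) {
        g2 <- setdiff(g, y)
        if (!length(g2)) next
        for (pass in seq_len(length(g2))) {
          changed <- FALSE
          for (v in g2) {
            idx <- inc[[v]]
            pre <- ed_from[idx]
            ok <- is.finite(dy[pre]) & abs(dy[pre] + ed_w[idx] - dy[v]) <= tol
            s_new <- sum(sig[pre[ok]])
            if (s_new != sig[v]) { sig[v] <- s_new; changed <- TRUE }
          }
          if (!changed) break
        }
      }
    }
    S[y, ] <- sig
  }
  S
}

dist_tol <- function(D) {
  fin <- D[is.finite(D)]
  1e-7 * (1 + if (length(fin)) max(fin) else 0)
}

check_radius <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) || radius <= 0) {
    stop_ctx("`radius` must be a positive number or Inf")
  }
  radius
}

#' Radius-limited closeness of road segments (NQPD)
#'
#' For each segment `x`, sums `W(y) / d(x, y)` over all other segments `y`
#' whose network distance from `x` is at most the search radius. High values
#' mark central, easily reached segments. Under the metric mode the units are
#' 1/m. Segments whose midpoints coincide with `x` (distance 0, only possible
#' under the pure angular mode) are excluded with a warning.
#'
#' @param graph a [build_road_graph()] result.
#' @param radius search radius in cost units (`Inf` for a global analysis).
#' @param dist a [distance_spec()].
#' @return numeric vector of NQPD values, one per segment.
#' @export
road_closeness <- function(graph, radius = Inf, dist = distance_spec("metric")) {
  check_radius(radius)
  D <- seg_dist_matrix(graph, dist)
  n <- nrow(D)
  W <- graph$segments$weight
  diag(D) <- NA
  zero <- which(D == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    warning("segment pairs at zero network distance excluded from closeness",
            call. = FALSE)
    D[zero] <- NA
  }
  out <- numeric(n)
  for (x in seq_len(n)) {
    dy <- D[x, ]
    sel <- which(!is.na(dy) & is.finite(dy) & dy <= radius)
    out[x] <- sum(W[sel] / dy[sel])
  }
  out
}

#' Radius-limited betweenness of road segments (TPBt)
#'
#' Weighted count of shortest inter-segment routes passing through each
#' segment. For every origin `y` and every destination `z` within radius of
#' `y`, the pair contributes `OD(y,z,x) * W(z) / TotalWeight(y)` to segment
#' `x`, where `OD` is 1 when `x` lies strictly inside the geodesic, 0.5 when
#' `x` is `y` or `z`, and 0 otherwise; equal-cost geodesics split `OD`
#' equally. `TotalWeight(y)` is the summed weight of all segments within
#' radius of `y` (including `y` itself by default).
#'
#' @inheritParams road_closeness
#' @param include_self_in_total whether `TotalWeight(y)` includes `y` itself.
#' @return numeric vector of TPBt values, one per segment.
#' @export
road_betweenness <- function(graph, radius = Inf, dist = distance_spec("metric"),
                             include_self_in_total = TRUE) {
  check_radius(radius)
  costs <- dual_costs(graph, dist)
  D <- seg_dist_matrix(graph, dist)
  tol <- dist_tol(D)
  S <- geodesic_counts(graph, D, costs, tol)
  n <- nrow(D)
  W <- graph$segments$weight
  tp <- numeric(n)
  for (y in seq_len(n)) {
    dy <- D[y, ]
    ry <- which(is.finite(dy) & dy <= radius)
    tw <- sum(W[ry]) - if (include_self_in_total) 0 else W[y]
    zs <- setdiff(ry, y)
    if (!length(zs) || tw <= 0) next
    wz <- W[zs] / tw
    # OD = 0.5 at the route endpoints y and z
    tp[y] <- tp[y] + 0.5 * sum(wz)
    tp[zs] <- tp[zs] + 0.5 * wz
    # OD split across equal-cost geodesics for strictly interior x
    m <- length(zs)
    A <- matrix(dy, n, m) + D[, zs, drop = FALSE]
    tgt <- matrix(dy[zs], n, m, byrow = TRUE)
    Fm <- (matrix(S[y, ], n, m) * S[, zs, drop = FALSE]) /
      matrix(S[y, zs], n, m, byrow = TRUE)
    Fm[!(is.finite(A) & abs(A - tgt) <= tol)] <- 0
    Fm[y, ] <- 0
    Fm[cbind(zs, seq_len(m))] <- 0
    tp <- tp + as.vector(Fm %*% wz)
  }
  tp
}

#' Closeness and betweenness in one table
#'
#' @inheritParams road_betweenness
#' @return data.frame with columns `segment`, `length_m`, `nqpd`, `tpbt`.
#' @export
road_centrality <- function(graph, radius = Inf, dist = distance_spec("metric"),
                            include_self_in_total = TRUE) {
  data.frame(segment = graph$segments$segment,
             length_m = graph$segments$length_m,
             nqpd = road_closeness(graph, radius, dist),
             tpbt = road_betweenness(graph, radius, dist, include_self_in_total))
}
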