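# Independent brute-force reference for the segment centralities:
# Floyd-Warshall distances over the segment transition graph and explicit
# depth-first enumeration of every equal-cost geodesic. Shares only the
# road_graph data structure with the implementation under test.

oracle_edge_costs <- function(graph, dist) {
  d <- graph$dual
  seg <- graph$segments
  met <- (seg$length_m[d$from] + seg$length_m[d$to]) / 2
  ang <- d$turn_deg + (seg$turn_deg[d$from] + seg$turn_deg[d$to]) / 2
  switch(dist$mode,
         metric = met,
         angular = ang,
         hybrid = met + dist$angular_weight * ang)
}

oracle_distances <- function(graph, dist) {
  n <- nrow(graph$segments)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  w <- oracle_edge_costs(graph, dist)
  d <- graph$dual
  for (e in seq_along(w)) {
    D[d$from[e], d$to[e]] <- min(D[d$from[e], d$to[e]], w[e])
    D[d$to[e], d$from[e]] <- D[d$from[e], d$to[e]]
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (is.finite(D[i, k])) {
        alt <- D[i, k] + D[k, ]
        upd <- alt < D[i, ]
        D[i, upd] <- alt[upd]
      }
    }
  }
  D
}

# all simple equal-cost geodesics y -> z as segment-id vectors
oracle_geodesics <- function(graph, dist, D, y, z, tol) {
  d <- graph$dual
  w <- oracle_edge_costs(graph, dist)
  ef <- c(d$from, d$to); et <- c(d$to, d$from); ew <- c(w, w)
  target <- D[y, z]
  if (!is.finite(target)) return(list())
  paths <- list()
  rec <- function(node, cost, path) {
    if (cost > target + tol) return()
    if (node == z) {
      if (abs(cost - target) <= tol) paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (e in which(ef == node)) {
      nx <- et[e]
      if (nx %in% path) next
      rec(nx, cost + ew[e], c(path, nx))
    }
  }
  rec(y, 0, y)
  paths
}

oracle_closeness <- function(graph, radius, dist) {
  D <- oracle_distances(graph, dist)
  n <- nrow(D)
  W <- graph$segments$weight
  vapply(seq_len(n), function(x) {
    sel <- setdiff(which(is.finite(D[x, ]) & D[x, ] <= radius & D[x, ] > 0), x)
    sum(W[sel] / D[x, sel])
  }, 0)
}

oracle_betweenness <- function(graph, radius, dist) {
  D <- oracle_distances(graph, dist)
  n <- nrow(D)
  W <- graph$segments$weight
  tol <- 1e-7 * (1 + max(D[is.finite(D)]))
  tp <- numeric(n)
  for (y in seq_len(n)) {
    ry <- which(is.finite(D[y, ]) & D[y, ] <= radius)
    tw <- sum(W[ry])
    for (z in setdiff(ry, y)) {
      paths <- oracle_geodesics(graph, dist, D, y, z, tol)
      np <- length(paths)
      if (!np) next
      share <- W[z] / tw
      tp[y] <- tp[y] + 0.5 * share
      tp[z] <- tp[z] + 0.5 * share
      for (p in paths) {
        interior <- setdiff(p, c(y, z))
        if (length(interior)) tp[interior] <- tp[interior] + share / np
      }
    }
  }
  tp
}

# random connected road graph: a spanning tree over random junctions plus
# extra non-duplicate links; straight segments, generic coordinates (no
# accidental equal-cost ties)
random_road_graph <- function(n_junctions, n_extra = 2L) {
  pts <- cbind(runif(n_junctions, 0, 100), runif(n_junctions, 0, 100))
  edges <- cbind(2:n_junctions,
                 vapply(2:n_junctions, function(i) sample.int(i - 1L, 1L), 0L))
  tries <- 0L
  while (n_extra > 0L && tries < 50L) {
    cand <- sort(sample.int(n_junctions, 2L))
    dup <- any(pmin(edges[, 1], edges[, 2]) == cand[1] &
                 pmax(edges[, 1], edges[, 2]) == cand[2])
    if (!dup) {
      edges <- rbind(edges, cand)
      n_extra <- n_extra - 1L
    }
    tries <- tries + 1L
  }
  build_road_graph(lapply(seq_len(nrow(edges)), function(i) {
    rbind(pts[edges[i, 1], ], pts[edges[i, 2], ])
  }), snap_tol_m = 1e-6)
}
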