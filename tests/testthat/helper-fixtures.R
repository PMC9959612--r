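# shared deterministic fixtures

# three collinear unit segments A-B-C sharing endpoints
unit_path3 <- function() {
  build_road_graph(list(rbind(c(0, 0), c(1, 0)),
                        rbind(c(1, 0), c(2, 0)),
                        rbind(c(2, 0), c(3, 0))))
}

# a risk map over an nrow x ncol rectangle where the cells listed in
# `top_cells` (matrix of row, col) score 1 and all others 0
fixture_risk_map <- function(nrow_, ncol_, top_cells) {
  fn <- make_fishnet(c(0, 0, ncol_ * 1000, nrow_ * 1000), 1000)
  score <- rep(0, nrow(fn$cells))
  for (i in seq_len(nrow(top_cells))) {
    hit <- fn$cells$row == top_cells[i, 1] & fn$cells$col == top_cells[i, 2]
    score[hit] <- 1
  }
  risk_map(fn, score, c(0.2, 0.4, 0.6, 0.8))
}

small_city_config <- function(seed = 11L, ...) {
  synthetic_city_config(extent_m = c(3000, 3000), road_grid_pitch_m = 500,
                        n_arterials = 2, n_hotspots = 2, hotspot_sigma_m = 300,
                        n_poi = 400, n_sites = 40, seed = seed, ...)
}
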