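# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_ctx(sprintf("`%s` must be a single number", name))
  }
  if (finite && !is.finite(x)) stop_ctx(sprintf("`%s` must be finite", name))
  if (positive && x <= 0) stop_ctx(sprintf("`%s` must be strictly positive", name))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name)
  if (x %% 1 != 0 || x < min) {
    stop_ctx(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

# angle in degrees [0, 180] between two 2-d vectors
vec_angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

polyline_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

# cumulative interior turn (degrees) along a polyline's internal vertices
polyline_turn_deg <- function(coords) {
  n <- nrow(coords)
  if (n < 3L) return(0)
  total <- 0
  for (i in 2:(n - 1L)) {
    total <- total + vec_angle_deg(coords[i, ] - coords[i - 1L, ],
                                   coords[i + 1L, ] - coords[i, ])
  }
  total
}
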