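# Indicator weighting: survey-derived POI category weights and
# entropy-method indicator weights.

#' Public dependence index from a Likert mean
#'
#' Linear rescale of a 5-point Likert item mean onto [0, 1], anchored so that
#' a mean of 3 ("generally important") maps to 0 and a mean of 5 ("very
#' important") maps to 1, clipped below at 0. Vectorized.
#'
#' @param mean Likert item mean(s) in [1, 5].
#' @return dependence index value(s) in [0, 1].
#' @export
dependence_index <- function(mean) {
  if (any(!is.finite(mean)) || any(mean < 1) || any(mean > 5)) {
    stop_ctx("Likert means must lie in [1, 5]")
  }
  pmin(1, pmax(0, (mean - 3) / 2))
}

#' Build a survey table of POI subcategory Likert means
#'
#' @param category functional category of each subcategory.
#' @param subcategory subcategory names (unique).
#' @param mean Likert means in [1, 5].
#' @param sd per-item standard deviations (optional).
#' @param n respondents behind each mean (optional).
#' @return data.frame of class `survey_table` with a computed `dependence`
#'   column.
#' @export
survey_table <- function(category, subcategory, mean, sd = NA_real_, n = NA_integer_) {
  if (anyDuplicated(subcategory)) stop_ctx("subcategory names must be unique")
  dep <- dependence_index(mean)
  out <- data.frame(category = as.character(category),
                    subcategory = as.character(subcategory),
                    mean = as.numeric(mean), sd = as.numeric(sd),
                    dependence = dep, n = as.integer(n))
  class(out) <- c("survey_table", "data.frame")
  out
}

#' POI category weights from a survey table
#'
#' Averages the subcategory Likert means within each functional category and
#' normalizes the category averages to sum to one.
#'
#' @param survey a [survey_table()] (or data.frame with `category` and
#'   `mean` columns).
#' @return named numeric vector of category weights summing to 1.
#' @export
category_weights <- function(survey) {
  if (!all(c("category", "mean") %in% names(survey))) {
    stop_ctx("`survey` needs `category` and `mean` columns")
  }
  if (!nrow(survey)) stop_ctx("`survey` is empty")
  if (any(!is.finite(survey$mean))) stop_ctx("survey means must be finite")
  avg <- tapply(survey$mean, survey$category, mean)
  if (any(is.na(avg))) stop_ctx("every category needs at least one subcategory mean")
  w <- as.numeric(avg) / sum(avg)
  names(w) <- names(avg)
  w
}

#' Min-max normalization of an indicator column
#'
#' Positive orientation maps `[min, max]` to `[0, 1]`; negative orientation
#' reverses it. A constant column returns all zeros and is flagged degenerate
#' in the `"degenerate"` attribute.
#'
#' @param x numeric values.
#' @param orientation `"positive"` (larger is riskier) or `"negative"`.
#' @return values in [0, 1] with a logical `"degenerate"` attribute.
#' @export
minmax_normalize <- function(x, orientation = c("positive", "negative")) {
  orientation <- match.arg(orientation)
  if (!length(x) || any(!is.finite(x))) stop_ctx("`x` must be non-empty and finite")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- if (orientation == "positive") (x - rng[1]) / diff(rng)
         else (rng[2] - x) / diff(rng)
  attr(out, "degenerate") <- FALSE
  out
}

#' Entropy-method indicator weights
#'
#' Shannon-entropy weighting of a normalized indicator matrix. Column shares
#' `p_ij = x_ij / sum_i(x_ij)` give the column entropy
#' `E_j = -(1/ln n) * sum_i p_ij ln p_ij` (with `0 ln 0 := 0`), and the
#' weights are `D_j = (1 - E_j) / (k - sum_j E_j)`. More dispersed columns
#' carry more information (lower entropy) and receive larger weights. An
#' all-zero column is fully uninformative: its entropy is set to 1 and its
#' weight to 0.
#'
#' @param x numeric matrix with cells in rows and normalized indicators
#'   (values in [0, 1]) in columns; needs >= 2 rows.
#' @param epsilon optional shift added to every entry before computing the
#'   column shares (default 0, i.e. zeros contribute nothing).
#' @return list of class `entropy_weights` with `weights` (summing to 1) and
#'   `entropy` per column.
#' @export
entropy_weights <- function(x, epsilon = 0) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) stop_ctx("need at least 2 rows (cells)")
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_ctx("`x` must be normalized to [0, 1]; see minmax_normalize()")
  }
  if (epsilon < 0) stop_ctx("`epsilon` must be >= 0")
  x <- x + epsilon
  cs <- colSums(x)
  ent <- numeric(k)
  for (j in seq_len(k)) {
    if (cs[j] == 0) { ent[j] <- 1; next }  # degenerate column
    p <- x[, j] / cs[j]
    plogp <- ifelse(p > 0, p * log(p), 0)
    ent[j] <- -sum(plogp) / log(n)
  }
  if (all(cs == 0)) stop_ctx("all indicator columns are zero; cannot weight")
  denom <- k - sum(ent)
  d <- if (denom > 0) {
    (1 - ent) / denom
  } else {
    # every column at maximal entropy: no column is more informative than
    # another, so weight the non-degenerate columns equally
    live <- cs > 0
    ifelse(live, 1 / sum(live), 0)
  }
  names(d) <- names(ent) <- colnames(x)
  structure(list(weights = d, entropy = ent), class = "entropy_weights")
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat("<entropy_weights>\n")
  print(round(rbind(entropy = x$entropy, weight = x$weights), 4))
  invisible(x)
}
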