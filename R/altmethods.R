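#' Weighted-sum scores
#'
#' Scores each alternative by the weighted sum of its defuzzified ratings.
#' Cost criteria are first converted to a benefit scale; the default
#' convention complements the rating on the \[0, 1\] linguistic scale
#' (`v -> 1 - v`), with the alternative conventions available behind the
#' `cost_handling` flag so a replication search can enumerate them:
#'
#' * `"complement"`: `1 - v` (default; ratings live on a common \[0, 1\]
#'   defuzzified scale);
#' * `"ratio"`: `min(column) / v` (classical linear ratio transform);
#' * `"shift"`: `max(column) - v`;
#' * `"reciprocal"`: `1 / v`.
#'
#' Raw scores are divided by their grand total so the published column
#' convention (scores summing to 1 across alternatives) is reproduced;
#' the normalization does not change the ranking.
#'
#' @param c A [crispify()]-ed matrix.
#' @param cost_handling Benefit conversion for `min` criteria (see above).
#' @param digits Tie-detection precision for ranking (default 4).
#' @return A `score_table` data.frame: `alternative`, `score`, `rank`,
#'   with attribute `method = "weighted_sum"`.
#' @export
weighted_sum_scores <- function(c, cost_handling = c("complement", "ratio",
                                                     "shift", "reciprocal"),
                                digits = 4) {
  stopifnot(inherits(c, "crisp_matrix"))
  cost_handling <- match.arg(cost_handling)
  B <- c$values
  for (j in which(c$directions < 0)) {
    v <- B[, j]
    B[, j] <- switch(cost_handling,
      complement = 1 - v,
      ratio = min(v) / v,
      shift = max(v) - v,
      reciprocal = 1 / v)
  }
  raw <- drop(B %*% c$weights)
  if (sum(raw) <= 0)
    stop("degenerate weighted-sum scores: grand total is zero", call. = FALSE)
  score_table(c$alternatives, raw / sum(raw), "weighted_sum", digits)
}

#' TOPSIS closeness coefficients
#'
#' Ranks by relative closeness to the ideal solution: the weighted matrix
#' `u(t, k) = w_k v(t, k)` is compared against the per-criterion ideal
#' (best value: max for benefit, min for cost) and anti-ideal (worst
#' value); with Euclidean distances `D+` and `D-` to the two, the
#' closeness is `C = D- / (D+ + D-)`, in \[0, 1\]. An alternative equal to
#' the ideal on every criterion scores exactly 1, one equal to the
#' anti-ideal exactly 0. If all alternatives are identical (`D+ + D- = 0`)
#' the closeness is defined as 0.5.
#'
#' Because the defuzzified ratings already share the \[0, 1\] linguistic
#' scale, no column normalization is applied by default; the classical
#' vector normalization (`v / sqrt(sum v^2)` per column) is available via
#' `normalization = "vector"`. Cost criteria are handled by `"min_ideal"`
#' (the ideal takes the column minimum) or by complementing the column
#' first (`"complement"`).
#'
#' @param c A [crispify()]-ed matrix.
#' @param normalization `"none"` (default) or `"vector"`.
#' @param cost_handling `"min_ideal"` (default) or `"complement"`.
#' @param digits Tie-detection precision for ranking (default 4).
#' @return A `score_table` data.frame with attribute `method = "topsis"`.
#' @export
topsis_scores <- function(c, normalization = c("none", "vector"),
                          cost_handling = c("min_ideal", "complement"),
                          digits = 4) {
  stopifnot(inherits(c, "crisp_matrix"))
  normalization <- match.arg(normalization)
  cost_handling <- match.arg(cost_handling)
  V <- c$values
  dirs <- c$directions
  if (cost_handling == "complement") {
    for (j in which(dirs < 0)) V[, j] <- 1 - V[, j]
    dirs <- rep(1, length(dirs))
  }
  if (normalization == "vector") {
    nrm <- sqrt(colSums(V^2))
    nrm[nrm == 0] <- 1
    V <- sweep(V, 2, nrm, "/")
  }
  U <- sweep(V, 2, c$weights, "*")
  ideal <- vapply(seq_along(dirs), function(j)
    if (dirs[j] > 0) max(U[, j]) else min(U[, j]), numeric(1))
  anti <- vapply(seq_along(dirs), function(j)
    if (dirs[j] > 0) min(U[, j]) else max(U[, j]), numeric(1))
  dplus <- sqrt(rowSums(sweep(U, 2, ideal)^2))
  dminus <- sqrt(rowSums(sweep(U, 2, anti)^2))
  tot <- dplus + dminus
  cc <- ifelse(tot == 0, 0.5, dminus / ifelse(tot == 0, 1, tot))
  score_table(c$alternatives, cc, "topsis", digits)
}

score_table <- function(alternatives, score, method, digits = 4) {
  st <- data.frame(alternative = alternatives, score = score,
                   row.names = NULL, stringsAsFactors = FALSE)
  st$rank <- competition_rank(-round(st$score, digits))
  st <- st[order(st$rank, st$alternative), , drop = FALSE]
  rownames(st) <- NULL
  attr(st, "method") <- method
  class(st) <- c("score_table", "data.frame")
  st
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("%s scores:\n", attr(x, "method")))
  out <- as.data.frame(x)
  out$score <- round(out$score, 4)
  print(out[c("rank", "alternative", "score")], row.names = FALSE)
  invisible(x)
}
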