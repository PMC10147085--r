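#' Pairwise preference index matrix
#'
#' The aggregated preference of each alternative over each other:
#' `pi[t, u] = sum_k w_k * P_k(d_tu_k)` with normalized weights `w_k`,
#' preference function `P_k` and direction-adjusted difference `d_tu_k`.
#' With normalized weights every entry lies in \[0, 1\]; the diagonal is 0
#' (self-comparison is excluded from all flow sums).
#'
#' @param c A [crispify()]-ed matrix.
#' @param specs Optional list of [pref_fn()] per criterion; defaults to the
#'   specifications carried by the criteria.
#' @return An `n x n` numeric matrix with alternative labels as dimnames.
#' @export
preference_index <- function(c, specs = NULL) {
  stopifnot(inherits(c, "crisp_matrix"))
  n <- nrow(c$values)
  if (n < 2)
    stop("outranking needs at least two alternatives", call. = FALSE)
  specs <- resolve_specs(c, specs)
  D <- difference_array(c)
  pi <- matrix(0, n, n, dimnames = list(c$alternatives, c$alternatives))
  for (j in seq_along(specs)) {
    P <- matrix(preference_value(as.vector(D[, , j]), specs[[j]]), n, n)
    pi <- pi + c$weights[j] * P
  }
  diag(pi) <- 0
  pi
}

resolve_specs <- function(cm, specs) {
  if (is.null(specs)) specs <- cm$pref_fns
  if (inherits(specs, "pref_fn")) specs <- rep(list(specs), ncol(cm$values))
  if (length(specs) != ncol(cm$values))
    stop("need one preference function per criterion", call. = FALSE)
  lapply(specs, function(s) {
    if (!inherits(s, "pref_fn")) stop("invalid preference function spec",
                                      call. = FALSE)
    s
  })
}

#' Positive, negative and net outranking flows
#'
#' `phi_plus(t)` is the average preference of `t` over the other `n - 1`
#' alternatives (its strength), `phi_minus(t)` the average preference of the
#' others over `t` (its weakness), and `phi_net = phi_plus - phi_minus`.
#' Net flows always sum to zero across alternatives.
#'
#' @param pi A preference index matrix from [preference_index()].
#' @return A `flow_table`: data.frame with columns `alternative`,
#'   `phi_plus`, `phi_minus`, `phi_net`.
#' @export
outranking_flows <- function(pi) {
  n <- nrow(pi)
  if (is.null(n) || n < 2 || n != ncol(pi))
    stop("`pi` must be a square matrix with n >= 2", call. = FALSE)
  ft <- data.frame(
    alternative = rownames(pi) %||% paste0("a", seq_len(n)),
    phi_plus = rowSums(pi) / (n - 1),
    phi_minus = colSums(pi) / (n - 1),
    row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
  ft$phi_net <- ft$phi_plus - ft$phi_minus
  class(ft) <- c("flow_table", "data.frame")
  ft
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PROMETHEE I partial order
#'
#' Classifies every ordered pair from the two unicriterion-free flows:
#' `P` (preferred) when one alternative is at least as strong and strictly
#' less weak (or strictly stronger and equally weak); `I` (indifferent)
#' when both flows tie; `R` (incomparable) when the flows disagree — one
#' alternative is stronger but also weaker. Equality of flows is tested
#' with an absolute tolerance of 1e-12.
#'
#' @param f A [outranking_flows()] table.
#' @param tol Absolute tolerance for flow equality.
#' @return A character matrix with entries `"P"`, `"I"`, `"R"` and
#'   `"self"` on the diagonal; `rel[t, u] == "P"` means t is preferred
#'   to u.
#' @export
promethee1_relations <- function(f, tol = 1e-12) {
  stopifnot(inherits(f, "flow_table"))
  n <- nrow(f)
  rel <- matrix("R", n, n, dimnames = list(f$alternative, f$alternative))
  for (t in seq_len(n)) {
    for (u in seq_len(n)) {
      if (t == u) { rel[t, u] <- "self"; next }
      dplus <- f$phi_plus[t] - f$phi_plus[u]
      dminus <- f$phi_minus[t] - f$phi_minus[u]
      eq_p <- abs(dplus) <= tol; eq_m <- abs(dminus) <= tol
      rel[t, u] <-
        if (eq_p && eq_m) "I"
        else if ((dplus > 0 || eq_p) && dminus < 0 && !eq_m) "P"
        else if (dplus > 0 && !eq_p && eq_m) "P"
        else if ((dplus < 0 || eq_p) && dminus > 0 && !eq_m) "R0" # u preferred
        else if (dplus < 0 && !eq_p && eq_m) "R0"
        else "R"
    }
  }
  # mark the mirrored preference: rel[u,t] of a P pair is not itself P
  rel[rel == "R0"] <- "-"
  rel
}

#' PROMETHEE II complete ranking
#'
#' Orders alternatives by decreasing net flow. Ties are detected on values
#' rounded to `digits` decimals (reporting precision) and ranked by
#' competition ranking: tied alternatives share a rank and the next rank is
#' offset by the tie count (1, 2, 2, 4, ...).
#'
#' @param f A [outranking_flows()] table.
#' @param digits Rounding precision used for tie detection (default 4).
#' @return The flow table with an added integer `rank` column, sorted by
#'   decreasing net flow.
#' @export
promethee2_rank <- function(f, digits = 4) {
  stopifnot(inherits(f, "flow_table"))
  r <- round(f$phi_net, digits)
  f$rank <- competition_rank(-r)
  f <- f[order(f$rank, f$alternative), , drop = FALSE]
  rownames(f) <- NULL
  class(f) <- c("flow_table", "data.frame")
  f
}

# competition ranking of a vector where smaller is better
competition_rank <- function(x) {
  vapply(x, function(v) 1L + sum(x < v), integer(1))
}

#' Run the full PROMETHEE pipeline
#'
#' Convenience wrapper: defuzzify, build the preference index, compute
#' flows, the PROMETHEE I relation matrix and the PROMETHEE II ranking.
#'
#' @param m A [decision_matrix()] or [crispify()]-ed matrix.
#' @param scale Linguistic scale for defuzzification.
#' @param specs Optional per-criterion [pref_fn()] override (a single
#'   spec is recycled to all criteria).
#' @param digits Tie-detection precision for the ranking.
#' @return A list of class `"promethee_result"`: `flows` (ranked flow
#'   table), `relations` (PROMETHEE I matrix), `pi` (preference index
#'   matrix), `crisp` (the crisp matrix used).
#' @examples
#' fx <- tau_pet_fixture()
#' res <- promethee(fx$matrix, fx$scale, specs = replication_config()$pref_fn)
#' head(res$flows)
#' @export
promethee <- function(m, scale = default_scale(), specs = NULL, digits = 4) {
  cm <- crispify(m, scale)
  pi <- preference_index(cm, specs)
  f <- outranking_flows(pi)
  structure(list(flows = promethee2_rank(f, digits),
                 relations = promethee1_relations(f),
                 pi = pi, crisp = cm),
            class = "promethee_result")
}

#' @export
print.promethee_result <- function(x, ...) {
  cat("PROMETHEE II ranking (phi_net = phi_plus - phi_minus):\n")
  out <- x$flows
  out[c("phi_plus", "phi_minus", "phi_net")] <-
    lapply(out[c("phi_plus", "phi_minus", "phi_net")], round, 4)
  print(as.data.frame(out[c("rank", "alternative", "phi_net",
                            "phi_plus", "phi_minus")]), row.names = FALSE)
  invisible(x)
}

#' Unicriterion net flow decomposition
#'
#' Splits each alternative's net flow into per-criterion contributions:
#' `phi_k(t) = (1/(n-1)) * sum_u [P_k(d_tu) - P_k(d_ut)]`. The weighted sum
#' of the columns reconstructs the net flow exactly:
#' `phi_net(t) = sum_k w_k phi_k(t)`. Positive entries are the strengths of
#' an alternative, negative entries its weaknesses — the usual stacked-bar
#' diagnostic of a PROMETHEE analysis.
#'
#' @param c A [crispify()]-ed matrix.
#' @param specs Optional per-criterion [pref_fn()] list (defaults to the
#'   criteria's own).
#' @return An alternatives x criteria numeric matrix of unicriterion net
#'   flows (unweighted).
#' @export
unicriterion_net_flows <- function(c, specs = NULL) {
  stopifnot(inherits(c, "crisp_matrix"))
  n <- nrow(c$values)
  if (n < 2) stop("outranking needs at least two alternatives", call. = FALSE)
  specs <- resolve_specs(c, specs)
  D <- difference_array(c)
  phi <- matrix(0, n, length(specs),
                dimnames = list(c$alternatives, c$criteria))
  for (j in seq_along(specs)) {
    P <- matrix(preference_value(as.vector(D[, , j]), specs[[j]]), n, n)
    diag(P) <- 0
    phi[, j] <- (rowSums(P) - colSums(P)) / (n - 1)
  }
  phi
}

#' Plot per-criterion strengths and weaknesses
#'
#' Stacked bars of weighted unicriterion net flows, one bar per
#' alternative: segments above zero are criteria on which the alternative
#' outranks the field, segments below are its weaknesses.
#'
#' @param c A [crispify()]-ed matrix.
#' @param specs Optional per-criterion [pref_fn()] list.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the weighted contribution matrix (criteria x
#'   alternatives).
#' @export
plot_criterion_contributions <- function(c, specs = NULL, ...) {
  phi <- unicriterion_net_flows(c, specs)
  contrib <- t(phi * rep(c$weights, each = nrow(phi)))
  pos <- pmax(contrib, 0); neg <- pmin(contrib, 0)
  ylim <- range(colSums(pos), colSums(neg))
  graphics::barplot(pos, las = 2, ylim = ylim * 1.1,
                    legend.text = rownames(contrib),
                    main = "Per-criterion contribution to net flow", ...)
  graphics::barplot(neg, add = TRUE, las = 2, axes = FALSE, ...)
  graphics::abline(h = 0)
  invisible(contrib)
}
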