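#' Define a decision criterion
#'
#' A criterion carries its optimization direction, an importance weight
#' (a linguistic term or a crisp nonnegative number) and the preference
#' function used by PROMETHEE on that criterion.
#'
#' @param name Criterion label.
#' @param direction `"max"` (benefit) or `"min"` (cost).
#' @param weight Linguistic term (e.g. `"VH"`) or nonnegative number.
#' @param pref_fn A [pref_fn()] specification; default is the usual
#'   (strict) preference function.
#' @return An object of class `"criterion"`.
#' @export
criterion <- function(name, direction = c("max", "min"), weight = 1,
                      pref_fn = fuzzyMCDA::pref_fn("usual")) {
  direction <- match.arg(direction)
  stopifnot(inherits(pref_fn, "pref_fn"))
  structure(list(name = as.character(name), direction = direction,
                 weight = weight, pref_fn = pref_fn),
            class = "criterion")
}

#' Assemble a decision matrix
#'
#' The decision matrix holds one row per alternative and one column per
#' criterion; cells are linguistic terms or crisp numbers (as characters or
#' numerics). Duplicate alternative labels are rejected; duplicate rating
#' rows are allowed (distinct alternatives may genuinely tie).
#'
#' @param cells Matrix or data.frame of evaluations (character or numeric),
#'   one row per alternative.
#' @param criteria List of [criterion()] objects, one per column.
#' @param alternatives Character vector of alternative labels; defaults to
#'   the rownames of `cells`.
#' @return An object of class `"decision_matrix"`.
#' @export
decision_matrix <- function(cells, criteria, alternatives = rownames(cells)) {
  cells <- as.matrix(cells)
  if (is.null(alternatives))
    stop("alternative labels are required (rownames or `alternatives`)",
         call. = FALSE)
  alternatives <- as.character(alternatives)
  if (nrow(cells) != length(alternatives))
    stop("one row of cells per alternative is required", call. = FALSE)
  if (anyDuplicated(alternatives))
    stop("duplicate alternative labels: ",
         paste(unique(alternatives[duplicated(alternatives)]), collapse = ", "),
         call. = FALSE)
  if (!all(vapply(criteria, inherits, logical(1), "criterion")))
    stop("`criteria` must be a list of criterion() objects", call. = FALSE)
  if (ncol(cells) != length(criteria))
    stop(sprintf("matrix has %d columns but %d criteria were declared",
                 ncol(cells), length(criteria)), call. = FALSE)
  storage.mode(cells) <- "character"
  dimnames(cells) <- list(alternatives,
                          vapply(criteria, `[[`, character(1), "name"))
  structure(list(alternatives = alternatives, criteria = criteria,
                 cells = cells),
            class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("Decision matrix: %d alternatives x %d criteria\n",
              length(x$alternatives), length(x$criteria)))
  aim <- vapply(x$criteria, `[[`, character(1), "direction")
  w <- vapply(x$criteria, function(cr) as.character(cr$weight), character(1))
  hdr <- rbind(aim = aim, weight = w)
  colnames(hdr) <- colnames(x$cells)
  print(rbind(hdr, x$cells), quote = FALSE)
  invisible(x)
}

#' Defuzzify a decision problem
#'
#' Turns a [decision_matrix()] into its crisp form: every cell and every
#' criterion weight is defuzzified with the Yager index, and the weights are
#' divided by their sum so they add to one. With normalized weights the
#' PROMETHEE preference index is guaranteed to live in \[0, 1\].
#' `crispify()` is idempotent: applying it to a crisp matrix returns the
#' matrix unchanged.
#'
#' @param m A [decision_matrix()] (or an already-crisp matrix, returned
#'   as is).
#' @param scale A [linguistic_scale()] used to resolve linguistic cells.
#' @return An object of class `"crisp_matrix"` with elements `values`
#'   (numeric alternatives x criteria matrix), `weights` (normalized),
#'   `directions` (`+1` maximize / `-1` minimize) and `pref_fns`.
#' @export
crispify <- function(m, scale = default_scale()) {
  if (inherits(m, "crisp_matrix")) return(m)
  stopifnot(inherits(m, "decision_matrix"))
  vals <- m$cells
  num <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (i in seq_len(nrow(vals))) {
    for (j in seq_len(ncol(vals))) {
      num[i, j] <- yager_defuzzify(
        resolve_cell(scale, vals[i, j],
                     where = sprintf("cell (%s, %s)", rownames(vals)[i],
                                     colnames(vals)[j])))
    }
  }
  w <- vapply(seq_along(m$criteria), function(j) {
    cr <- m$criteria[[j]]
    yager_defuzzify(resolve_cell(scale, cr$weight,
                                 where = sprintf("weight of '%s'", cr$name)))
  }, numeric(1))
  if (any(w < 0)) stop("criterion weights must be nonnegative", call. = FALSE)
  if (sum(w) <= 0) stop("degenerate weights: all criterion weights are zero",
                        call. = FALSE)
  structure(list(
    values = num,
    weights = w / sum(w),
    directions = ifelse(vapply(m$criteria, `[[`, character(1),
                               "direction") == "max", 1, -1),
    pref_fns = lapply(m$criteria, `[[`, "pref_fn"),
    alternatives = m$alternatives,
    criteria = colnames(vals)
  ), class = "crisp_matrix")
}

#' @export
print.crisp_matrix <- function(x, ...) {
  cat(sprintf("Crisp matrix: %d alternatives x %d criteria\n",
              nrow(x$values), ncol(x$values)))
  cat("weights:", paste(sprintf("%.5f", x$weights), collapse = " "), "\n")
  cat("aims:   ", paste(ifelse(x$directions > 0, "max", "min"),
                        collapse = "  "), "\n")
  print(round(x$values, 5))
  invisible(x)
}

#' Direction-adjusted pairwise difference
#'
#' The deviation `d` fed to a preference function: for a benefit criterion
#' `value(t) - value(u)`, for a cost criterion the sign is flipped, so a
#' positive `d` always means "t is better than u on criterion j".
#'
#' @param c A [crispify()]-ed matrix.
#' @param t,u Alternative labels or indices.
#' @param j Criterion label or index.
#' @return A single signed numeric difference.
#' @export
signed_difference <- function(c, t, u, j) {
  stopifnot(inherits(c, "crisp_matrix"))
  ti <- idx_of(t, c$alternatives, "alternative")
  ui <- idx_of(u, c$alternatives, "alternative")
  ji <- idx_of(j, c$criteria, "criterion")
  c$directions[ji] * (c$values[ti, ji] - c$values[ui, ji])
}

idx_of <- function(x, labels, what) {
  if (is.numeric(x)) {
    if (x < 1 || x > length(labels))
      stop(sprintf("%s index %s out of range", what, x), call. = FALSE)
    return(as.integer(x))
  }
  i <- match(x, labels)
  if (is.na(i)) stop(sprintf("unknown %s '%s'", what, x), call. = FALSE)
  i
}

# n x n x k array of direction-adjusted differences, D[t, u, j]
difference_array <- function(cm) {
  v <- cm$values
  n <- nrow(v); k <- ncol(v)
  D <- array(0, c(n, n, k))
  for (j in seq_len(k))
    D[, , j] <- cm$directions[j] * outer(v[, j], v[, j], `-`)
  D
}

#' Read or write a decision matrix as CSV
#'
#' Layout mirrors the bundled fixture: first column `alternative`, header
#' row of criterion names, then two metadata rows labelled `.aim`
#' (max/min) and `.weight` (term or number) before the alternative rows.
#' A unicode minus sign in numeric cells is normalized to ASCII `-` on
#' ingest.
#'
#' @param path CSV file path.
#' @param pref_fn Preference function attached to every criterion on read
#'   (the CSV itself carries no preference configuration).
#' @return `read_matrix_csv()` returns a [decision_matrix()];
#'   `write_matrix_csv()` returns `path` invisibly.
#' @export
read_matrix_csv <- function(path, pref_fn = fuzzyMCDA::pref_fn("usual")) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "alternative")
    stop("matrix CSV must have 'alternative' as its first column",
         call. = FALSE)
  lab <- df[[1]]
  aim_row <- which(lab == ".aim"); w_row <- which(lab == ".weight")
  if (length(aim_row) != 1 || length(w_row) != 1)
    stop("matrix CSV needs exactly one '.aim' and one '.weight' row",
         call. = FALSE)
  aims <- tolower(unlist(df[aim_row, -1]))
  aims <- ifelse(grepl("^max", aims), "max",
                 ifelse(grepl("^min", aims), "min", NA))
  if (anyNA(aims)) stop("'.aim' entries must be max or min", call. = FALSE)
  weights <- unlist(df[w_row, -1])
  crits <- lapply(seq_along(aims), function(j) {
    criterion(names(df)[j + 1], direction = aims[j], weight = weights[[j]],
              pref_fn = pref_fn)
  })
  body <- df[-c(aim_row, w_row), , drop = FALSE]
  decision_matrix(as.matrix(body[, -1, drop = FALSE]), crits,
                  alternatives = body[[1]])
}

#' @rdname read_matrix_csv
#' @param m A [decision_matrix()] to serialize.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "decision_matrix"))
  hdr <- data.frame(
    alternative = c(".aim", ".weight"),
    rbind(vapply(m$criteria, `[[`, character(1), "direction"),
          vapply(m$criteria, function(cr) as.character(cr$weight),
                 character(1))),
    check.names = FALSE)
  names(hdr)[-1] <- colnames(m$cells)
  body <- data.frame(alternative = m$alternatives, m$cells,
                     check.names = FALSE, row.names = NULL)
  utils::write.csv(rbind(hdr, body), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
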