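#' Triangular fuzzy number
#'
#' A triangular fuzzy number (TFN) is the fuzzy quantity whose membership
#' function rises linearly from `left` to 1 at `mode` and falls back to 0 at
#' `right`. Linguistic ratings such as "Very High" are modelled as TFNs; a
#' crisp number `v` is the degenerate triangle `(v, v, v)`.
#'
#' @param left Lower bound of the support.
#' @param mode Center of the set (membership 1).
#' @param right Upper bound of the support.
#' @return An object of class `"tfn"`: a named numeric vector
#'   `c(left, mode, right)`.
#' @examples
#' tfn(0.25, 0.5, 0.75)
#' tfn(1)            # crisp value as degenerate triangle
#' @export
tfn <- function(left, mode = left, right = mode) {
  x <- c(left = as.numeric(left), mode = as.numeric(mode),
         right = as.numeric(right))
  if (anyNA(x) || length(x) != 3L)
    stop("a triangular fuzzy number needs three finite vertices", call. = FALSE)
  if (x[["left"]] > x[["mode"]] || x[["mode"]] > x[["right"]])
    stop(sprintf("malformed fuzzy number (%g, %g, %g): need left <= mode <= right",
                 x[["left"]], x[["mode"]], x[["right"]]), call. = FALSE)
  structure(x, class = "tfn")
}

#' @export
print.tfn <- function(x, ...) {
  cat(sprintf("TFN (%g, %g, %g)\n", x[["left"]], x[["mode"]], x[["right"]]))
  invisible(x)
}

is_tfn <- function(x) inherits(x, "tfn")

#' Yager-index defuzzification
#'
#' Converts a triangular fuzzy number to a crisp value with the Yager index
#' `(3N - a + b) / 3`, where `N` is the center of the set, `a = N - left` is
#' the distance from the center to the left bound and `b = right - N` the
#' distance to the right bound. The index uses all three vertices: symmetric
#' triangles defuzzify to their mode, right-skewed ones slightly above it.
#'
#' @param x A [tfn()], or a numeric vector of length 3 `(left, mode, right)`.
#' @return A single crisp numeric value.
#' @examples
#' yager_defuzzify(tfn(0.25, 0.50, 0.75))  # symmetric -> 0.5
#' yager_defuzzify(tfn(0.75, 1, 1))        # 0.91667
#' @export
yager_defuzzify <- function(x) {
  if (!is_tfn(x)) x <- tfn(x[1], x[2], x[3])
  n <- x[["mode"]]
  a <- n - x[["left"]]
  b <- x[["right"]] - n
  (3 * n - a + b) / 3
}

# vectorized form used internally: l, m, r numeric vectors
yager3 <- function(l, m, r) (3 * m - (m - l) + (r - m)) / 3

#' Linguistic rating scale
#'
#' An ordered mapping from linguistic terms to triangular fuzzy numbers,
#' declared from the strongest term down (e.g. VH > H > M > L > VL). The
#' modes must strictly decrease along the declared order so the scale is
#' ordinally consistent.
#'
#' @param terms Named list; each element a [tfn()] or a numeric vector of
#'   length 3 `(left, mode, right)`. Order of the list is the strength order.
#' @return An object of class `"linguistic_scale"`.
#' @seealso [default_scale()] for the five-term scale shipped with the
#'   tau PET fixture.
#' @export
linguistic_scale <- function(terms) {
  if (is.null(names(terms)) || any(!nzchar(names(terms))))
    stop("all scale terms must be named", call. = FALSE)
  if (anyDuplicated(toupper(names(terms))))
    stop("scale term labels must be unique (case-insensitively)", call. = FALSE)
  terms <- lapply(terms, function(t) if (is_tfn(t)) t else tfn(t[1], t[2], t[3]))
  modes <- vapply(terms, function(t) t[["mode"]], numeric(1))
  if (length(modes) > 1 && any(diff(modes) >= 0))
    stop("scale modes must strictly decrease along the declared term order",
         call. = FALSE)
  structure(list(terms = terms), class = "linguistic_scale")
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat("Linguistic scale (", length(x$terms), " terms):\n", sep = "")
  for (nm in names(x$terms)) {
    t <- x$terms[[nm]]
    cat(sprintf("  %-4s (%g, %g, %g)  ->  %.5f\n", nm,
                t[["left"]], t[["mode"]], t[["right"]], yager_defuzzify(t)))
  }
  invisible(x)
}

#' Five-term linguistic scale used by the tau PET fixture
#'
#' Very High (0.75, 1, 1), High (0.5, 0.75, 1), Medium (0.25, 0.5, 0.75),
#' Low (0, 0.25, 0.5), Very Low (0, 0, 0.25). This is the shipped default,
#' not hard-coded into any of the ranking mathematics: every function takes
#' a scale argument.
#'
#' @return A [linguistic_scale()].
#' @export
default_scale <- function() {
  linguistic_scale(list(
    VH = c(0.75, 1.00, 1.00),
    H  = c(0.50, 0.75, 1.00),
    M  = c(0.25, 0.50, 0.75),
    L  = c(0.00, 0.25, 0.50),
    VL = c(0.00, 0.00, 0.25)
  ))
}

#' Resolve a linguistic term to its fuzzy number
#'
#' Lookup is case-insensitive. Unknown labels raise an error naming the
#' offending label so that a bad matrix cell can be located.
#'
#' @param scale A [linguistic_scale()].
#' @param label A term label such as `"VH"` or `"vh"`.
#' @return The mapped [tfn()].
#' @export
resolve_term <- function(scale, label) {
  stopifnot(inherits(scale, "linguistic_scale"))
  i <- match(toupper(trimws(label)), toupper(names(scale$terms)))
  if (is.na(i))
    stop(sprintf("unknown linguistic term '%s' (scale has: %s)", label,
                 paste(names(scale$terms), collapse = ", ")), call. = FALSE)
  scale$terms[[i]]
}

# Resolve a cell that may be a linguistic term or a crisp number.
# Crisp numbers become degenerate triangles so a single code path serves both.
resolve_cell <- function(scale, cell, where = "cell") {
  if (is.numeric(cell)) return(tfn(cell))
  chr <- gsub("−", "-", trimws(as.character(cell)))  # unicode minus
  i <- match(toupper(chr), toupper(names(scale$terms)))
  if (!is.na(i)) return(scale$terms[[i]])
  num <- suppressWarnings(as.numeric(chr))
  if (!is.na(num)) return(tfn(num))
  stop(sprintf("cannot resolve %s '%s': not a scale term or a number",
               where, cell), call. = FALSE)
}

#' Read or write a linguistic scale as JSON or YAML
#'
#' The file maps each term label to a `[left, mode, right]` triple; the
#' order of keys is the strength order of the scale.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_scale()` returns a [linguistic_scale()];
#'   `write_scale()` returns `path` invisibly.
#' @export
read_scale <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  linguistic_scale(lapply(raw, as.numeric))
}

#' @rdname read_scale
#' @param scale A [linguistic_scale()] to serialize.
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "linguistic_scale"))
  lst <- lapply(scale$terms, function(t) as.numeric(t))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}
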