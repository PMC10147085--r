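#' Preference function specification
#'
#' The six classical PROMETHEE preference functions translate a pairwise
#' advantage `d` on one criterion into a preference degree in \[0, 1\]:
#'
#' * `usual`: 0 for `d <= 0`, else 1 (any strict advantage counts fully);
#' * `u_shape`: 0 up to the indifference threshold `q`, else 1;
#' * `v_shape`: `min(d / p, 1)` for `d > 0` (linear up to `p`);
#' * `level`: 0 on `(-Inf, q]`, 1/2 on `(q, p]`, 1 beyond `p`;
#' * `linear`: 0 up to `q`, then `(d - q) / (p - q)`, 1 beyond `p`;
#' * `gaussian`: `1 - exp(-d^2 / (2 s^2))` for `d > 0`.
#'
#' Every form is 0 for `d <= 0` and nondecreasing in `d`.
#'
#' @param type One of `"usual"`, `"u_shape"`, `"v_shape"`, `"level"`,
#'   `"linear"`, `"gaussian"`.
#' @param q Indifference threshold (>= 0); used by `u_shape`, `level`,
#'   `linear`.
#' @param p Preference threshold (> `q`); used by `v_shape`, `level`,
#'   `linear`.
#' @param s Gaussian spread (> 0); inflection point of the `gaussian` form.
#' @return An object of class `"pref_fn"`.
#' @examples
#' pref_fn("gaussian", s = 2.85)
#' pref_fn("linear", q = 0.1, p = 0.5)
#' @export
pref_fn <- function(type = c("usual", "u_shape", "v_shape", "level",
                             "linear", "gaussian"),
                    q = NULL, p = NULL, s = NULL) {
  type <- match.arg(type)
  need <- function(x, nm, cond, msg) {
    if (is.null(x)) stop(sprintf("preference function '%s' needs `%s`",
                                 type, nm), call. = FALSE)
    if (!cond(x)) stop(sprintf("invalid `%s` for '%s': %s", nm, type, msg),
                       call. = FALSE)
    as.numeric(x)
  }
  spec <- switch(type,
    usual = list(),
    u_shape = list(q = need(q, "q", function(x) x >= 0, "must be >= 0")),
    v_shape = list(p = need(p, "p", function(x) x > 0, "must be > 0")),
    level = ,
    linear = {
      qq <- need(q, "q", function(x) x >= 0, "must be >= 0")
      pp <- need(p, "p", function(x) x > qq, "must exceed q")
      list(q = qq, p = pp)
    },
    gaussian = list(s = need(s, "s", function(x) x > 0, "must be > 0"))
  )
  structure(c(list(type = type), spec), class = "pref_fn")
}

#' @export
print.pref_fn <- function(x, ...) {
  par <- x[setdiff(names(x), "type")]
  cat(sprintf("Preference function: %s%s\n", x$type,
              if (length(par)) paste0(" (", paste(names(par), unlist(par),
                                                  sep = " = ",
                                                  collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Evaluate a preference function
#'
#' Vectorized over `d`. Returns values in \[0, 1\], equal to 0 whenever
#' `d <= 0`.
#'
#' @param d Numeric vector of direction-adjusted pairwise differences.
#' @param spec A [pref_fn()].
#' @return Numeric vector of preference degrees, same length as `d`.
#' @examples
#' preference_value(c(-0.3, 0, 0.25), pref_fn("v_shape", p = 0.5))
#' @export
preference_value <- function(d, spec) {
  if (!inherits(spec, "pref_fn"))
    stop("`spec` must be a pref_fn() object", call. = FALSE)
  pos <- d > 0
  out <- numeric(length(d))
  dp <- d[pos]
  out[pos] <- switch(spec$type,
    usual = 1,
    u_shape = as.numeric(dp > spec$q),
    v_shape = pmin(dp / spec$p, 1),
    level = ifelse(dp <= spec$q, 0, ifelse(dp <= spec$p, 0.5, 1)),
    linear = ifelse(dp <= spec$q, 0,
                    ifelse(dp <= spec$p, (dp - spec$q) / (spec$p - spec$q), 1)),
    gaussian = 1 - exp(-dp^2 / (2 * spec$s^2))
  )
  out
}
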