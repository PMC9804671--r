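#' Ordered quality scale
#'
#' Defines the common ordered scale on which provider quality profiles live:
#' either a genuinely ordinal scale (named categories such as
#' "very poor" < ... < "very good") or an ordinal scale obtained by
#' discretizing a cardinal indicator, whose levels are ascending numeric
#' support points.
#'
#' @param levels For `kind = "ordinal"`, a character vector of category
#'   labels in increasing quality order; for `kind = "cardinal-discretized"`,
#'   a strictly increasing numeric vector of support points.
#' @param kind Either `"ordinal"` or `"cardinal-discretized"`.
#'
#' @return An object of class `quality_scale` with elements `kind`, `levels`
#'   and `Q` (the number of levels).
#' @examples
#' quality_scale(c("poor", "OK", "good"))
#' quality_scale(c(95.1, 96.9, 100), kind = "cardinal-discretized")
#' @export
quality_scale <- function(levels, kind = c("ordinal", "cardinal-discretized")) {
  kind <- match.arg(kind)
  if (kind == "cardinal-discretized") {
    levels <- as.numeric(levels)
    if (any(!is.finite(levels))) {
      stop("cardinal-discretized scale levels must be finite numbers", call. = FALSE)
    }
    if (length(levels) >= 2 && any(diff(levels) <= 0)) {
      stop("cardinal-discretized scale levels must be strictly increasing", call. = FALSE)
    }
  } else {
    levels <- as.character(levels)
  }
  if (anyDuplicated(levels)) {
    stop("scale levels must not contain duplicates", call. = FALSE)
  }
  if (length(levels) < 2) {
    stop("a quality scale needs at least 2 levels", call. = FALSE)
  }
  structure(
    list(kind = kind, levels = levels, Q = length(levels)),
    class = "quality_scale"
  )
}

#' @export
print.quality_scale <- function(x, ...) {
  cat(sprintf("<quality_scale: %s, Q = %d>\n", x$kind, x$Q))
  cat("  ", paste(x$levels, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' @export
format.quality_scale <- function(x, ...) {
  sprintf("%s scale with %d levels", x$kind, x$Q)
}

scales_identical <- function(a, b) {
  identical(a$kind, b$kind) && identical(as.character(a$levels), as.character(b$levels))
}
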