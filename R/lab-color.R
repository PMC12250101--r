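#' Construct and validate CIELAB colour coordinates
#'
#' A CIELAB colour is a triplet (L*, a*, b*): L* is lightness on the closed
#' interval \[0, 100\] (0 = black, 100 = white), a* is the green(-)/red(+)
#' opponent coordinate and b* the blue(-)/yellow(+) opponent coordinate.
#' `lab()` builds a validated tibble of colours; most package functions accept
#' anything coercible by [as_lab()] (a length-3 numeric, a 3-column matrix, or
#' a data frame with columns `L`, `a`, `b`).
#'
#' @param L,a,b Numeric vectors of equal length (length-1 vectors are
#'   recycled). `L` must lie in \[0, 100\]; `a` and `b` must be finite.
#' @return A tibble with columns `L`, `a`, `b`.
#' @examples
#' lab(50, 25, 15)
#' lab(L = c(46.3, 48.2), a = c(27.2, 26.5), b = c(15.2, 15.5))
#' @export
lab <- function(L, a, b) {
  n <- max(length(L), length(a), length(b))
  L <- rep_len(as.numeric(L), n)
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  validate_lab(L, a, b)
  tibble::tibble(L = L, a = a, b = b)
}

validate_lab <- function(L, a, b) {
  if (any(!is.finite(L)) || any(L < 0) || any(L > 100)) {
    stop("L* must be finite and within [0, 100]", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("a* and b* must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Coerce to a CIELAB coordinate matrix
#'
#' @param x A length-3 numeric `(L, a, b)`, a 3-column matrix, or a data
#'   frame with columns `L`, `a`, `b`.
#' @return A numeric matrix with columns `L`, `a`, `b`; coordinates are
#'   validated (see [lab()]).
#' @keywords internal
#' @export
as_lab <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("L", "a", "b") %in% names(x))) {
      stop("data-frame colour input needs columns L, a, b", call. = FALSE)
    }
    m <- cbind(L = as.numeric(x$L), a = as.numeric(x$a), b = as.numeric(x$b))
  } else if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("colour matrix must have 3 columns", call. = FALSE)
    m <- x
    colnames(m) <- c("L", "a", "b")
  } else if (is.numeric(x) && length(x) == 3L) {
    m <- matrix(as.numeric(x), nrow = 1L, dimnames = list(NULL, c("L", "a", "b")))
  } else {
    stop("cannot interpret input as CIELAB coordinates", call. = FALSE)
  }
  validate_lab(m[, "L"], m[, "a"], m[, "b"])
  m
}
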