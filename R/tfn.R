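#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) is an ordered triple \eqn{(l, m, u)} with
#' \eqn{l \le m \le u}: the support is \eqn{[l, u]} and the membership peaks
#' at the modal value \eqn{m}.  `tfn()` builds a (vectorised) TFN object; all
#' ratings, reliabilities, weights, matrix cells and scores in this package
#' are carried as TFNs.  A degenerate TFN with \eqn{l = m = u} behaves
#' exactly like the crisp real \eqn{m} under every operation.
#'
#' @param l,m,u numeric vectors (recycled to a common length): lower support
#'   bound, modal value and upper support bound.
#' @return An object of class `"tfn"`: a list of numeric vectors `l`, `m`,
#'   `u` of equal length.
#' @examples
#' a <- tfn(1, 2, 3)
#' b <- tfn(4, 5, 6)
#' a + b
#' defuzzify(a + b)
#' @seealso [defuzzify()], [tfn_membership()], [linguistic_scale()]
#' @export
tfn <- function(l, m, u) {
  n <- max(length(l), length(m), length(u))
  l <- rep_len(as.numeric(l), n)
  m <- rep_len(as.numeric(m), n)
  u <- rep_len(as.numeric(u), n)
  if (anyNA(l) || anyNA(m) || anyNA(u))
    stop("TFN components must be non-missing numerics", call. = FALSE)
  bad <- l > m + 1e-12 | m > u + 1e-12
  if (any(bad))
    stop(sprintf("invalid TFN: l <= m <= u violated at position %d (%g, %g, %g)",
                 which(bad)[1], l[which(bad)[1]], m[which(bad)[1]],
                 u[which(bad)[1]]), call. = FALSE)
  structure(list(l = l, m = m, u = u), class = "tfn")
}

#' @export
is.tfn <- function(x) inherits(x, "tfn")

#' Coerce to a triangular fuzzy number
#'
#' Numerics become degenerate (crisp) TFNs; length-3 unnamed numerics are
#' interpreted elementwise as `c(l, m, u)` only via [tfn()], not here, to
#' avoid ambiguity with crisp vectors.
#'
#' @param x a `tfn` or numeric vector.
#' @return a `tfn`.
#' @export
as.tfn <- function(x) {
  if (is.tfn(x)) return(x)
  if (is.numeric(x)) return(tfn(x, x, x))
  stop("cannot coerce to tfn", call. = FALSE)
}

#' @export
length.tfn <- function(x) length(x$l)

#' @export
`[.tfn` <- function(x, i) tfn(x$l[i], x$m[i], x$u[i])

#' @export
c.tfn <- function(...) {
  xs <- lapply(list(...), as.tfn)
  tfn(unlist(lapply(xs, `[[`, "l")),
      unlist(lapply(xs, `[[`, "m")),
      unlist(lapply(xs, `[[`, "u")))
}

#' @export
format.tfn <- function(x, digits = 4L, ...) {
  sprintf("(%s, %s, %s)", signif(x$l, digits), signif(x$m, digits),
          signif(x$u, digits))
}

#' @export
print.tfn <- function(x, ...) {
  cat("<tfn[", length(x), "]>\n", sep = "")
  print(format(x, ...), quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.tfn <- function(x, ...) {
  data.frame(l = x$l, m = x$m, u = x$u)
}

#' Arithmetic on triangular fuzzy numbers
#'
#' Extension-principle arithmetic restricted to the operations used by the
#' risk pipeline:
#' \describe{
#'   \item{`a + b`}{componentwise sum \eqn{(l_1+l_2, m_1+m_2, u_1+u_2)}.}
#'   \item{`a - b`}{the interval-widening rule
#'     \eqn{(l_1-u_2,\; m_1-m_2,\; u_1-l_2)}; always yields a valid TFN.}
#'   \item{`a * b`}{componentwise product, defined for nonnegative operands
#'     only (ordering is not guaranteed otherwise); a plain nonnegative
#'     numeric operand acts as scalar scaling \eqn{\lambda a}.}
#'   \item{`a / b`}{\eqn{(l_1/u_2,\; m_1/m_2,\; u_1/l_2)}; the denominator
#'     must be strictly positive componentwise.}
#' }
#' Comparison operators `==`/`!=` test componentwise equality.
#'
#' @param e1,e2 `tfn` objects or numerics (numerics are treated as crisp
#'   scalars for `*` and `/`, and as degenerate TFNs otherwise).
#' @return a `tfn` (or logical for comparisons).
#' @name tfn-arith
#' @export
Ops.tfn <- function(e1, e2) {
  op <- .Generic
  if (missing(e2))
    stop("unary '", op, "' is not defined for TFNs", call. = FALSE)
  if (op %in% c("==", "!=")) {
    a <- as.tfn(e1); b <- as.tfn(e2)
    eq <- a$l == b$l & a$m == b$m & a$u == b$u
    return(if (op == "==") eq else !eq)
  }
  if (!op %in% c("+", "-", "*", "/"))
    stop(sprintf("operation '%s' is not defined for TFNs", op), call. = FALSE)
  # scalar scaling keeps plain-numeric semantics for * and /
  if (op == "*" && xor(is.tfn(e1), is.tfn(e2))) {
    lam <- if (is.tfn(e1)) e2 else e1
    a <- if (is.tfn(e1)) e1 else e2
    if (any(lam < 0))
      stop("scalar multiplier must be nonnegative (ordering would reverse)",
           call. = FALSE)
    return(tfn(lam * a$l, lam * a$m, lam * a$u))
  }
  if (op == "/" && is.tfn(e1) && is.numeric(e2)) {
    if (any(e2 <= 0)) stop("scalar divisor must be positive", call. = FALSE)
    return(tfn(e1$l / e2, e1$m / e2, e1$u / e2))
  }
  a <- as.tfn(e1); b <- as.tfn(e2)
  switch(op,
    "+" = tfn(a$l + b$l, a$m + b$m, a$u + b$u),
    "-" = tfn(a$l - b$u, a$m - b$m, a$u - b$l),
    "*" = {
      if (any(a$l < 0) || any(b$l < 0))
        stop("fuzzy product is defined for nonnegative operands only",
             call. = FALSE)
      tfn(a$l * b$l, a$m * b$m, a$u * b$u)
    },
    "/" = {
      if (any(b$l <= 0))
        stop("fuzzy division requires a strictly positive denominator",
             call. = FALSE)
      tfn(a$l / b$u, a$m / b$m, a$u / b$l)
    })
}

#' @export
sum.tfn <- function(..., na.rm = FALSE) {
  x <- c.tfn(...)
  tfn(sum(x$l), sum(x$m), sum(x$u))
}

#' @export
mean.tfn <- function(x, ...) tfn(mean(x$l), mean(x$m), mean(x$u))

#' Triangular membership function
#'
#' Degree of membership of a crisp value `x` in the fuzzy set described by
#' `a`: 0 outside the support, linear up to 1 at the modal value and back
#' down.  Degenerate legs (`m == l` or `u == m`) return 1 at the shared
#' point.
#'
#' @param a a single `tfn` (length 1).
#' @param x numeric vector of evaluation points.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' tfn_membership(tfn(0, 1, 2), c(0.5, 1, 3))
#' @export
tfn_membership <- function(a, x) {
  stopifnot(is.tfn(a), length(a) == 1L)
  mu <- numeric(length(x))
  left <- x >= a$l & x <= a$m
  mu[left] <- if (a$m > a$l) (x[left] - a$l) / (a$m - a$l) else 1
  right <- x > a$m & x <= a$u
  mu[right] <- if (a$u > a$m) (a$u - x[right]) / (a$u - a$m) else 1
  mu[x == a$m] <- 1
  mu
}

#' Defuzzification
#'
#' Converts a TFN to a crisp representative value.  Two operators are used
#' in the pipeline:
#' \describe{
#'   \item{`"centroid"`}{the support-vertex mean \eqn{(l + m + u)/3}; the
#'     default, and the operator applied to final MABAC scores.}
#'   \item{`"gmir"`}{the graded mean integration representation
#'     \eqn{(l + 4m + u)/6}; used for crisp reliability values and for
#'     weight normalisation.}
#' }
#' The two coincide for symmetric TFNs (\eqn{m - l = u - m}).
#'
#' @param x a `tfn`.
#' @param method `"centroid"` or `"gmir"`.
#' @return numeric vector of crisp values.
#' @examples
#' defuzzify(tfn(0.09, 0.23, 0.27))           # 0.1967
#' defuzzify(tfn(0.7, 1, 1), method = "gmir") # 0.95
#' @export
defuzzify <- function(x, method = c("centroid", "gmir")) {
  stopifnot(is.tfn(x))
  method <- match.arg(method)
  switch(method,
         centroid = (x$l + x$m + x$u) / 3,
         gmir     = (x$l + 4 * x$m + x$u) / 6)
}

#' Graded mean integration representation
#'
#' Convenience wrapper for `defuzzify(x, method = "gmir")`, i.e.
#' \eqn{(l + 4m + u)/6}.
#'
#' @param x a `tfn`.
#' @return numeric vector.
#' @export
gmir <- function(x) defuzzify(x, method = "gmir")
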