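#' Crisp reliability of a fuzzy confidence term
#'
#' Collapses the fuzzy reliability component \eqn{B} of a Z-number to a
#' crisp weight \eqn{b \in [0,1]} by graded mean integration,
#' \eqn{b = (l + 4m + u)/6}.
#'
#' @param reliability_tfn a `tfn` with support inside `[0, 1]`.
#' @return numeric vector of crisp reliabilities in `[0, 1]`.
#' @examples
#' crisp_reliability(tfn(0.7, 1, 1))  # 0.95
#' @export
crisp_reliability <- function(reliability_tfn) {
  stopifnot(is.tfn(reliability_tfn))
  if (any(reliability_tfn$l < -1e-12) || any(reliability_tfn$u > 1 + 1e-12))
    stop("reliability TFN support must lie within [0, 1]", call. = FALSE)
  gmir(reliability_tfn)
}

#' Group consensus ratio
#'
#' Signed agreement level of an expert panel vote,
#' \eqn{R = (Y - N) / (n - \theta)}, where \eqn{Y}, \eqn{N} and
#' \eqn{\theta} count agreeing, disagreeing and neutral panelists out of
#' \eqn{n}.  Since \eqn{Y + N = n - \theta}, \eqn{R \in [-1, 1]}.
#'
#' @param Y,N,theta nonnegative integer vote counts with
#'   `Y + N + theta == n`.
#' @param n panel size (default 12).
#' @return numeric vector in `[-1, 1]`.
#' @examples
#' consensus_ratio(8, 2, 2)   #  0.6
#' consensus_ratio(1, 8, 3)   # -0.7778
#' @export
consensus_ratio <- function(Y, N, theta, n = 12) {
  k <- max(length(Y), length(N), length(theta), length(n))
  Y <- rep_len(Y, k); N <- rep_len(N, k)
  theta <- rep_len(theta, k); n <- rep_len(n, k)
  if (any(Y < 0) || any(N < 0) || any(theta < 0) || any(n <= 0))
    stop("vote counts must be nonnegative and panel size positive",
         call. = FALSE)
  if (any(Y + N + theta != n))
    stop("vote counts must satisfy Y + N + theta = n", call. = FALSE)
  if (any(theta >= n))
    stop("consensus is undefined when every panelist is neutral (theta = n)",
         call. = FALSE)
  (Y - N) / (n - theta)
}

#' Consensus-adjusted reliability
#'
#' Refines a crisp reliability \eqn{b} by the panel consensus \eqn{R}:
#' \deqn{b^* = \begin{cases} b(1+R) & R < 0 \\ b & R = 0 \\
#'   1 - (1-b)(1-R) & R > 0.\end{cases}}
#' Agreement pulls the reliability toward 1, disagreement shrinks it toward
#' 0; the map is continuous at \eqn{R = 0} and nondecreasing in \eqn{R}.
#'
#' @param b crisp reliability in `[0, 1]`.
#' @param R consensus ratio in `[-1, 1]`.
#' @return adjusted reliability in `[0, 1]`.
#' @examples
#' adjust_reliability(0.5, 0.6)    # 0.8
#' adjust_reliability(0.9, -0.5)   # 0.45
#' @export
adjust_reliability <- function(b, R) {
  k <- max(length(b), length(R))
  b <- rep_len(b, k); R <- rep_len(R, k)
  if (any(b < -1e-12 | b > 1 + 1e-12))
    stop("reliability b must lie in [0, 1]", call. = FALSE)
  if (any(R < -1 - 1e-12 | R > 1 + 1e-12))
    stop("consensus ratio R must lie in [-1, 1]", call. = FALSE)
  out <- b
  out[R < 0] <- (b * (1 + R))[R < 0]
  out[R > 0] <- (1 - (1 - b) * (1 - R))[R > 0]
  pmin(pmax(out, 0), 1)
}

#' Fold a reliability weight into a fuzzy rating
#'
#' Converts a Z-number \eqn{(A, \alpha)} with fuzzy restriction \eqn{A} and
#' crisp reliability \eqn{\alpha} into a plain TFN by the standard
#' square-root discount, \eqn{\sqrt{\alpha}\, A}.
#'
#' @param rating_tfn the fuzzy restriction (a `tfn`).
#' @param alpha crisp reliability in `[0, 1]`.
#' @return a `tfn`.
#' @examples
#' z_to_fuzzy(tfn(4, 5, 6), 0.8)  # (3.578, 4.472, 5.367)
#' @export
z_to_fuzzy <- function(rating_tfn, alpha) {
  stopifnot(is.tfn(rating_tfn))
  if (any(alpha < 0 | alpha > 1))
    stop("reliability weight alpha must lie in [0, 1]", call. = FALSE)
  sqrt(alpha) * rating_tfn
}

#' Convert a ZE judgment to a triangular fuzzy number
#'
#' A ZE judgment is an expert's `(rating term, reliability term)` pair plus
#' the panel vote `(Y, N, theta)` that moderates it.  The conversion chain
#' is: crisp reliability by [crisp_reliability()], consensus ratio by
#' [consensus_ratio()], adjusted reliability by [adjust_reliability()], and
#' finally the square-root discount [z_to_fuzzy()] applied to the rating
#' TFN.  For Z-numbers without a group vote set `Y = N = 0` is not valid;
#' use `consensus = FALSE` instead, which keeps \eqn{b^* = b}.
#'
#' @param rating_term,reliability_term linguistic labels, resolved on
#'   `scales$rating` and `scales$reliability`.
#' @param Y,N,theta,n panel vote; ignored when `consensus = FALSE`.
#' @param scales named list with `rating` and `reliability`
#'   [linguistic_scale()]s (default [builtin_scales()]).
#' @param consensus if `FALSE`, skip the vote adjustment (plain Z-number
#'   conversion, the "Z" pipeline variant).
#' @return a `tfn` (vectorised over the inputs).
#' @examples
#' # unanimous agreement with full reliability leaves the rating unchanged
#' ze_convert("VH", "VH", Y = 12, N = 0, theta = 0)
#' @export
ze_convert <- function(rating_term, reliability_term, Y = NULL, N = NULL,
                       theta = NULL, n = 12, scales = builtin_scales(),
                       consensus = TRUE) {
  a <- term_tfn(scales$rating, rating_term)
  b <- crisp_reliability(term_tfn(scales$reliability, reliability_term))
  if (consensus) {
    if (is.null(Y) || is.null(N) || is.null(theta))
      stop("ZE conversion needs the panel vote (Y, N, theta); ",
           "use consensus = FALSE for plain Z-numbers", call. = FALSE)
    R <- consensus_ratio(Y, N, theta, n)
    b <- adjust_reliability(b, R)
  }
  z_to_fuzzy(a, b)
}
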