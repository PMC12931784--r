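#' Fuzzy decision matrix
#'
#' An alternatives-by-criteria grid of triangular fuzzy cells, the object
#' flowing through every MABAC stage.  Internally three numeric matrices
#' (`l`, `m`, `u`) share dimnames `alternatives` x `criteria`; the `stage`
#' marker (`"initial"`, `"normalized"`, `"weighted"`, `"distance"`) guards
#' against running stages out of order.
#'
#' @param l,m,u numeric matrices of identical dimension.
#' @param alternatives,criteria dimension labels (defaults taken from the
#'   dimnames of `l`).
#' @param stage pipeline stage marker.
#' @return an object of class `"fuzzy_matrix"`.
#' @export
fuzzy_matrix <- function(l, m, u, alternatives = rownames(l),
                         criteria = colnames(l), stage = "initial") {
  stopifnot(is.matrix(l), identical(dim(l), dim(m)),
            identical(dim(l), dim(u)))
  if (is.null(alternatives)) alternatives <- paste0("A", seq_len(nrow(l)))
  if (is.null(criteria)) criteria <- paste0("C", seq_len(ncol(l)))
  stage <- match.arg(stage, c("initial", "normalized", "weighted",
                              "distance"))
  if (anyNA(l) || anyNA(m) || anyNA(u))
    stop("decision matrix has missing cells", call. = FALSE)
  if (any(l > m + 1e-12) || any(m > u + 1e-12))
    stop("decision matrix cell violates l <= m <= u", call. = FALSE)
  dn <- list(alternatives, criteria)
  dimnames(l) <- dimnames(m) <- dimnames(u) <- dn
  structure(list(l = l, m = m, u = u, alternatives = alternatives,
                 criteria = criteria, stage = stage),
            class = "fuzzy_matrix")
}

#' Build a fuzzy matrix from a long data frame
#'
#' @param df data frame with columns `alternative`, `criterion`, `l`, `m`,
#'   `u` (optionally `expert`, which must then be filtered beforehand).
#' @param alternatives,criteria orderings; default order of appearance.
#' @param stage stage marker passed to [fuzzy_matrix()].
#' @return a `"fuzzy_matrix"`.
#' @export
fuzzy_matrix_from_df <- function(df, alternatives = unique(df$alternative),
                                 criteria = unique(df$criterion),
                                 stage = "initial") {
  need <- c("alternative", "criterion", "l", "m", "u")
  if (!all(need %in% names(df)))
    stop("need columns alternative, criterion, l, m, u", call. = FALSE)
  key <- paste(df$alternative, df$criterion)
  if (anyDuplicated(key))
    stop("duplicate (alternative, criterion) cell: ",
         key[anyDuplicated(key)], call. = FALSE)
  shape <- function(v) {
    x <- matrix(NA_real_, length(alternatives), length(criteria),
                dimnames = list(alternatives, criteria))
    x[cbind(match(df$alternative, alternatives),
            match(df$criterion, criteria))] <- v
    x
  }
  fuzzy_matrix(shape(df$l), shape(df$m), shape(df$u),
               alternatives, criteria, stage)
}

#' @export
print.fuzzy_matrix <- function(x, digits = 3L, ...) {
  cat(sprintf("<fuzzy_matrix %d x %d, stage '%s'>\n",
              length(x$alternatives), length(x$criteria), x$stage))
  body <- matrix(sprintf("(%.*f, %.*f, %.*f)", digits, x$l, digits, x$m,
                         digits, x$u),
                 nrow = length(x$alternatives),
                 dimnames = list(x$alternatives, x$criteria))
  print(body, quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fuzzy_matrix <- function(x, ...) {
  data.frame(alternative = rep(x$alternatives, times = length(x$criteria)),
             criterion = rep(x$criteria, each = length(x$alternatives)),
             l = as.vector(x$l), m = as.vector(x$m), u = as.vector(x$u))
}

#' Average per-expert matrices into one initial matrix
#'
#' Componentwise arithmetic mean across experts' fuzzy decision matrices
#' (fuzzy addition followed by scaling with \eqn{1/k}).
#'
#' @param per_expert_matrices list of `"fuzzy_matrix"` objects of identical
#'   shape and stage `"initial"`.
#' @return a `"fuzzy_matrix"` at stage `"initial"`.
#' @export
assemble_matrix <- function(per_expert_matrices) {
  ms <- per_expert_matrices
  if (!length(ms)) stop("no matrices to assemble", call. = FALSE)
  ref <- ms[[1]]
  for (m2 in ms[-1])
    if (!identical(dim(m2$l), dim(ref$l)) ||
        !identical(m2$criteria, ref$criteria) ||
        !identical(m2$alternatives, ref$alternatives))
      stop("expert matrices differ in shape or labels", call. = FALSE)
  k <- length(ms)
  fuzzy_matrix(Reduce(`+`, lapply(ms, `[[`, "l")) / k,
               Reduce(`+`, lapply(ms, `[[`, "m")) / k,
               Reduce(`+`, lapply(ms, `[[`, "u")) / k,
               ref$alternatives, ref$criteria, stage = "initial")
}

#' Column-wise min--max normalization
#'
#' Maps every column into `[0, 1]` by the column range: with
#' \eqn{x^- = \min_i l_{ij}} and \eqn{x^+ = \max_i u_{ij}}, benefit
#' criteria transform each component as \eqn{(x - x^-)/(x^+ - x^-)} and
#' cost criteria as \eqn{(x - x^+)/(x^- - x^+)} (components are mapped in
#' order, so cells remain valid TFNs for benefit criteria; cost criteria
#' additionally swap l and u to preserve ordering).
#'
#' The alternative `method = "max"` divides all components by the column
#' maximum of upper bounds; it is retained for fidelity experiments only
#' and does not reproduce the reference normalization tables.
#'
#' @param dm a `"fuzzy_matrix"` at stage `"initial"`.
#' @param directions named character vector mapping each criterion to
#'   `"benefit"` or `"cost"`; defaults to all-benefit (higher severity /
#'   occurrence / detection score means higher risk).
#' @param method `"minmax"` (default) or `"max"`.
#' @return a `"fuzzy_matrix"` at stage `"normalized"`.
#' @export
normalize_matrix <- function(dm, directions = NULL,
                             method = c("minmax", "max")) {
  stopifnot(inherits(dm, "fuzzy_matrix"))
  method <- match.arg(method)
  if (dm$stage != "initial")
    stop("normalization expects an initial-stage matrix", call. = FALSE)
  if (is.null(directions))
    directions <- stats::setNames(rep("benefit", length(dm$criteria)),
                                  dm$criteria)
  if (!all(dm$criteria %in% names(directions)))
    stop("missing direction for some criteria", call. = FALSE)
  l <- dm$l; m <- dm$m; u <- dm$u
  for (j in seq_along(dm$criteria)) {
    dir <- match.arg(directions[[dm$criteria[j]]], c("benefit", "cost"))
    if (method == "max") {
      top <- max(u[, j])
      if (top <= 0) stop("max-divide normalization needs positive columns",
                         call. = FALSE)
      l[, j] <- dm$l[, j] / top; m[, j] <- dm$m[, j] / top
      u[, j] <- dm$u[, j] / top
      next
    }
    lo <- min(dm$l[, j]); hi <- max(dm$u[, j])
    if (hi == lo) {
      warning("constant column '", dm$criteria[j],
              "': normalized to 0", call. = FALSE)
      l[, j] <- m[, j] <- u[, j] <- 0
      next
    }
    if (dir == "benefit") {
      l[, j] <- (dm$l[, j] - lo) / (hi - lo)
      m[, j] <- (dm$m[, j] - lo) / (hi - lo)
      u[, j] <- (dm$u[, j] - lo) / (hi - lo)
    } else {
      # cost: reflect, then swap bounds to keep l <= u
      l[, j] <- (hi - dm$u[, j]) / (hi - lo)
      m[, j] <- (hi - dm$m[, j]) / (hi - lo)
      u[, j] <- (hi - dm$l[, j]) / (hi - lo)
    }
  }
  fuzzy_matrix(l, m, u, dm$alternatives, dm$criteria, stage = "normalized")
}

#' Apply fuzzy criterion weights
#'
#' Each normalized cell \eqn{\tilde n_{ij}} becomes
#' \eqn{\tilde w_j \otimes (\tilde C \oplus \tilde n_{ij})} with the MABAC
#' constant \eqn{\tilde C = (1,1,1)}, keeping every weighted cell strictly
#' positive.
#'
#' @param dm a `"fuzzy_matrix"` at stage `"normalized"`.
#' @param weights a named `tfn` (names = criteria) or list of length-1
#'   `tfn`s; all components must be strictly positive.
#' @return a `"fuzzy_matrix"` at stage `"weighted"`.
#' @export
weight_matrix <- function(dm, weights) {
  stopifnot(inherits(dm, "fuzzy_matrix"))
  if (dm$stage != "normalized")
    stop("weighting expects a normalized-stage matrix", call. = FALSE)
  w <- .resolve_weights(weights, dm$criteria)
  if (any(w$l <= 0))
    stop("criterion weights must be strictly positive", call. = FALSE)
  l <- sweep(1 + dm$l, 2, w$l, `*`)
  m <- sweep(1 + dm$m, 2, w$m, `*`)
  u <- sweep(1 + dm$u, 2, w$u, `*`)
  fuzzy_matrix(l, m, u, dm$alternatives, dm$criteria, stage = "weighted")
}

.resolve_weights <- function(weights, criteria) {
  if (is.list(weights) && !is.tfn(weights))
    weights <- do.call(c, lapply(weights, as.tfn))
  w <- as.tfn(weights)
  nm <- attr(weights, "criteria")
  if (is.null(nm)) nm <- names(weights$l)
  if (!is.null(nm)) {
    i <- match(criteria, nm)
    if (anyNA(i)) stop("weights missing for criterion '",
                       criteria[which(is.na(i))[1]], "'", call. = FALSE)
    w <- w[i]
  } else if (length(w) != length(criteria))
    stop("need one weight per criterion", call. = FALSE)
  w
}

#' Border approximation area
#'
#' The per-criterion border \eqn{\tilde g_j} is the componentwise geometric
#' mean of the weighted column,
#' \eqn{\tilde g_j = (\prod_i \tilde r_{ij})^{1/m}}.
#'
#' @param dm a `"fuzzy_matrix"` at stage `"weighted"` with strictly
#'   positive cells.
#' @return a named `tfn`, one element per criterion.
#' @export
compute_baa <- function(dm) {
  stopifnot(inherits(dm, "fuzzy_matrix"))
  if (dm$stage != "weighted")
    stop("the border approximation area is computed from the weighted matrix",
         call. = FALSE)
  if (any(dm$l <= 0))
    stop("geometric mean needs strictly positive cells", call. = FALSE)
  g <- tfn(exp(colMeans(log(dm$l))), exp(colMeans(log(dm$m))),
           exp(colMeans(log(dm$u))))
  attr(g, "criteria") <- dm$criteria
  g
}

#' Distances from the border approximation area
#'
#' \eqn{\tilde q_{ij} = \tilde r_{ij} \ominus \tilde g_j} with the
#' interval-widening fuzzy subtraction \eqn{(l_r - u_g,\; m_r - m_g,\;
#' u_r - l_g)}.  Cells above the border carry positive centroids, cells
#' below negative ones.
#'
#' @param dm a `"fuzzy_matrix"` at stage `"weighted"`.
#' @param baa border from [compute_baa()] (recomputed when omitted).
#' @return a `"fuzzy_matrix"` at stage `"distance"`.
#' @export
compute_distances <- function(dm, baa = compute_baa(dm)) {
  stopifnot(inherits(dm, "fuzzy_matrix"))
  if (dm$stage != "weighted")
    stop("distances are computed from the weighted matrix", call. = FALSE)
  g <- .resolve_weights(baa, dm$criteria)
  l <- sweep(dm$l, 2, g$u, `-`)
  m <- sweep(dm$m, 2, g$m, `-`)
  u <- sweep(dm$u, 2, g$l, `-`)
  fuzzy_matrix(l, m, u, dm$alternatives, dm$criteria, stage = "distance")
}

#' Score and rank alternatives
#'
#' Sums the distance cells over criteria into a fuzzy total score
#' \eqn{\tilde S_i}, defuzzifies it (centroid by default), and ranks in
#' descending order of the crisp score; rank 1 is the most critical
#' alternative.  Ties in the crisp score are broken by the larger modal
#' value of \eqn{\tilde S_i}, then by input order.
#'
#' @param dm a `"fuzzy_matrix"` at stage `"distance"`.
#' @param defuzzifier `"centroid"` (default) or `"gmir"`.
#' @return an object of class `"ranking_result"`: a data frame with columns
#'   `alternative`, `S_l`, `S_m`, `S_u`, `score`, `rank`.
#' @export
score_and_rank <- function(dm, defuzzifier = c("centroid", "gmir")) {
  stopifnot(inherits(dm, "fuzzy_matrix"))
  defuzzifier <- match.arg(defuzzifier)
  if (dm$stage != "distance")
    stop("scoring expects the distance-stage matrix", call. = FALSE)
  S <- tfn(rowSums(dm$l), rowSums(dm$m), rowSums(dm$u))
  score <- defuzzify(S, method = defuzzifier)
  ord <- order(-score, -S$m, seq_along(score))
  rank <- integer(length(score)); rank[ord] <- seq_along(ord)
  res <- data.frame(alternative = dm$alternatives, S_l = S$l, S_m = S$m,
                    S_u = S$u, score = score, rank = rank,
                    stringsAsFactors = FALSE)
  class(res) <- c("ranking_result", "data.frame")
  attr(res, "defuzzifier") <- defuzzifier
  res
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("MABAC ranking (", attr(x, "defuzzifier"), " defuzzification)\n",
      sep = "")
  df <- as.data.frame(x)[order(x$rank), ]
  print(format(df, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Run the MABAC stages on an initial matrix
#'
#' Convenience wrapper chaining [normalize_matrix()], [weight_matrix()],
#' [compute_baa()], [compute_distances()] and [score_and_rank()].
#'
#' @param dm initial-stage `"fuzzy_matrix"`.
#' @param weights fuzzy criterion weights (see [weight_matrix()]).
#' @param directions criterion directions (see [normalize_matrix()]).
#' @param defuzzifier final defuzzification operator.
#' @param normalization normalization variant.
#' @return a `"ranking_result"` whose `"stages"` attribute holds all
#'   intermediate matrices for audit.
#' @export
mabac <- function(dm, weights, directions = NULL,
                  defuzzifier = c("centroid", "gmir"),
                  normalization = c("minmax", "max")) {
  nz <- normalize_matrix(dm, directions, method = match.arg(normalization))
  wt <- weight_matrix(nz, weights)
  g  <- compute_baa(wt)
  q  <- compute_distances(wt, g)
  res <- score_and_rank(q, defuzzifier = match.arg(defuzzifier))
  attr(res, "stages") <- list(normalized = nz, weighted = wt, baa = g,
                              distance = q)
  res
}
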