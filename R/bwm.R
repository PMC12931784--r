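#' Best--Worst comparison vector
#'
#' One expert's input to the Best--Worst Method: the identity of the best
#' (most important) and worst (least important) criterion, a Best-to-Others
#' (BO) vector of importance terms comparing the best criterion against
#' every criterion, and an Others-to-Worst (OW) vector comparing every
#' criterion against the worst.  The self-comparisons must be "EI".
#' Internally inconsistent panels (e.g. a best-to-worst term weaker than
#' some other entry) are deliberately not rejected: consistency is judged
#' afterwards through the consistency ratio, not by construction.
#'
#' @param criteria ordered character vector of criterion labels.
#' @param best,worst criterion labels, `best != worst`.
#' @param best_to_others,others_to_worst named character vectors of
#'   importance terms covering all criteria.
#' @param expert optional expert label.
#' @param importance_scale scale the terms must resolve on.
#' @return an object of class `"comparison_vector"`.
#' @export
comparison_vector <- function(criteria, best, worst, best_to_others,
                              others_to_worst, expert = NA_character_,
                              importance_scale = builtin_scales()$importance) {
  stopifnot(is.character(criteria), length(criteria) >= 2)
  if (anyDuplicated(criteria)) stop("duplicate criteria", call. = FALSE)
  if (!best %in% criteria || !worst %in% criteria)
    stop("best and worst must be among the criteria", call. = FALSE)
  if (best == worst)
    stop("best and worst criterion must differ", call. = FALSE)
  for (v in list(BO = best_to_others, OW = others_to_worst)) {
    miss <- setdiff(criteria, names(v))
    if (length(miss))
      stop("comparison vector missing entry for criterion '", miss[1], "'",
           call. = FALSE)
  }
  term_tfn(importance_scale, unname(best_to_others[criteria]))  # resolve check
  term_tfn(importance_scale, unname(others_to_worst[criteria]))
  if (best_to_others[[best]] != "EI" || others_to_worst[[worst]] != "EI")
    stop("self-comparisons (best vs best, worst vs worst) must be 'EI'",
         call. = FALSE)
  structure(list(criteria = criteria, best = best, worst = worst,
                 best_to_others = best_to_others[criteria],
                 others_to_worst = others_to_worst[criteria],
                 expert = expert),
            class = "comparison_vector")
}

#' @export
print.comparison_vector <- function(x, ...) {
  cat(sprintf("BWM comparisons%s: best=%s worst=%s\n",
              if (is.na(x$expert)) "" else paste0(" [", x$expert, "]"),
              x$best, x$worst))
  cat("  BO:", paste(x$criteria, x$best_to_others, sep = "=",
                     collapse = "  "), "\n")
  cat("  OW:", paste(x$criteria, x$others_to_worst, sep = "=",
                     collapse = "  "), "\n")
  invisible(x)
}

# decode an unconstrained parameter vector into valid fuzzy weights whose
# GMIRs sum to one: per criterion (l, m, u) = (exp(a), l + b^2, m + c^2),
# rescaled by the total GMIR (GMIR is linear, so the sum is exactly 1)
.bwm_decode <- function(theta, k) {
  l <- exp(theta[seq_len(k)])
  m <- l + theta[k + seq_len(k)]^2
  u <- m + theta[2 * k + seq_len(k)]^2
  tot <- sum(l + 4 * m + u) / 6
  list(l = l / tot, m = m / tot, u = u / tot)
}

# worst constraint violation of a candidate weight set: componentwise
# |w_B / w_j - a_Bj| and |w_j / w_W - a_jW| with fuzzy division
# (l/u', m/m', u/l')
.bwm_violation <- function(w, iB, iW, bo, ow) {
  rB <- c(w$l[iB] / w$u, w$m[iB] / w$m, w$u[iB] / w$l)
  rW <- c(w$l / w$u[iW], w$m / w$m[iW], w$u / w$l[iW])
  max(abs(rB - c(bo$l, bo$m, bo$u)), abs(rW - c(ow$l, ow$m, ow$u)))
}

#' Fuzzy criterion weights by the Best--Worst Method
#'
#' Solves the fuzzy BWM program: find fuzzy weights
#' \eqn{\tilde w_j = (l_j, m_j, u_j)} minimising the scalar \eqn{\xi}
#' bounding, componentwise, every deviation
#' \eqn{|\tilde w_B \oslash \tilde w_j - \tilde a_{Bj}|} and
#' \eqn{|\tilde w_j \oslash \tilde w_W - \tilde a_{jW}|}, subject to
#' \eqn{\sum_j (l_j + 4 m_j + u_j)/6 = 1}, \eqn{0 < l_j \le m_j \le u_j}.
#' Fuzzy division follows the extension rule \eqn{(l_1/u_2, m_1/m_2,
#' u_1/l_2)}.
#'
#' The minimax program is solved by seeded multi-start Nelder--Mead over an
#' unconstrained parametrisation that enforces ordering and the
#' sum-to-one constraint exactly.  One start is the crisp seed derived from
#' the GMIR ratios of the BO vector (exact for perfectly consistent crisp
#' inputs, where \eqn{\xi^* = 0}); the rest are seeded random perturbations.
#' The best incumbent is polished by repeated restarts until stagnation, so
#' results are deterministic for a fixed `seed`.
#'
#' @param cv a [comparison_vector()].
#' @param importance_scale the importance [linguistic_scale()] (with CIs).
#' @param n_starts number of multi-start points (default 32).
#' @param seed RNG seed for the random starts (restored on exit).
#' @param maxit Nelder--Mead iteration budget per start.
#' @return an object of class `"bwm_solution"`: list with `weights` (a
#'   named `tfn`), `xi_star` (the optimal consistency objective), `cr`
#'   (consistency ratio \eqn{\xi^*/CI}), `cr_acceptable` (`cr < 0.1`),
#'   `criteria` and `expert`.
#' @examples
#' \donttest{
#' cv <- comparison_vector(c("S", "O", "D"), best = "D", worst = "O",
#'   best_to_others = c(S = "I", O = "WI", D = "EI"),
#'   others_to_worst = c(S = "I", O = "EI", D = "FI"))
#' solve_fuzzy_bwm(cv, seed = 1)
#' }
#' @export
solve_fuzzy_bwm <- function(cv, importance_scale = builtin_scales()$importance,
                            n_starts = 32, seed = 1, maxit = 2000) {
  stopifnot(inherits(cv, "comparison_vector"))
  if (n_starts < 1) stop("solver budget must allow at least one start",
                         call. = FALSE)
  k <- length(cv$criteria)
  iB <- match(cv$best, cv$criteria)
  iW <- match(cv$worst, cv$criteria)
  bo <- term_tfn(importance_scale, unname(cv$best_to_others))
  ow <- term_tfn(importance_scale, unname(cv$others_to_worst))

  obj <- function(theta)
    .bwm_violation(.bwm_decode(theta, k), iB, iW, bo, ow)

  # crisp seed from the GMIR of the BO ratios: w_j proportional to 1/a_Bj
  w0 <- (1 / gmir(bo)); w0 <- w0 / sum(w0)
  starts <- list(c(log(w0), rep(0, 2 * k)))

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  for (s in seq_len(max(0, n_starts - 1))) {
    w <- w0 * stats::rgamma(k, shape = 2)   # Dirichlet-type perturbation
    w <- w / sum(w)
    starts[[s + 1]] <- c(log(w), stats::rnorm(2 * k, 0, 0.15))
  }

  best <- NULL
  for (th0 in starts) {
    fit <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value - 1e-15) best <- fit
  }
  # polish the incumbent with restarted Nelder-Mead until stagnation
  repeat {
    fit <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-14))
    if (fit$value >= best$value - 1e-12) break
    best <- fit
  }
  w <- .bwm_decode(best$par, k)
  weights <- tfn(w$l, w$m, w$u)
  xi <- best$value
  ci <- term_ci(importance_scale, cv$best_to_others[[cv$worst]])
  structure(list(weights = weights, criteria = cv$criteria,
                 xi_star = xi, cr = xi / ci, cr_acceptable = xi / ci < 0.1,
                 expert = cv$expert),
            class = "bwm_solution")
}

#' @export
print.bwm_solution <- function(x, ...) {
  cat(sprintf("Fuzzy BWM solution%s  (xi* = %.4g, CR = %.4g%s)\n",
              if (is.na(x$expert)) "" else paste0(" [", x$expert, "]"),
              x$xi_star, x$cr,
              if (x$cr_acceptable) ", acceptable" else ""))
  df <- as.data.frame(x$weights)
  df$criterion <- x$criteria
  df$gmir <- gmir(x$weights)
  print(df[, c("criterion", "l", "m", "u", "gmir")], row.names = FALSE,
        digits = 4)
  invisible(x)
}

#' Consistency ratio of a BWM solution
#'
#' \eqn{CR = \xi^* / CI}, where the consistency index CI is the one bound to
#' the best-to-worst comparison term on the importance scale.  Judgments are
#' conventionally acceptable when `CR < 0.1`.
#'
#' @param sol a `"bwm_solution"`.
#' @param cv the [comparison_vector()] it was solved from.
#' @param importance_scale scale carrying the CIs.
#' @return numeric consistency ratio, with attribute `acceptable`.
#' @export
consistency_ratio <- function(sol, cv,
                              importance_scale = builtin_scales()$importance) {
  stopifnot(inherits(sol, "bwm_solution"), inherits(cv, "comparison_vector"))
  ci <- term_ci(importance_scale, cv$best_to_others[[cv$worst]])
  cr <- sol$xi_star / ci
  attr(cr, "acceptable") <- cr < 0.1
  cr
}

#' Aggregate per-expert fuzzy weights
#'
#' Componentwise arithmetic mean of the experts' fuzzy weight vectors,
#' rescaled so the GMIRs sum to one.
#'
#' @param solutions list of `"bwm_solution"` objects, or a list of named
#'   `tfn` weight vectors with identical criteria.
#' @param criteria criterion labels (taken from the first solution when
#'   omitted).
#' @return named `tfn` of aggregated weights (names are the criteria).
#' @export
aggregate_expert_weights <- function(solutions, criteria = NULL) {
  if (!length(solutions)) stop("no weight solutions to aggregate",
                               call. = FALSE)
  ws <- lapply(solutions, function(s) {
    if (inherits(s, "bwm_solution")) {
      if (is.null(criteria)) criteria <<- s$criteria
      if (!identical(s$criteria, criteria))
        stop("criteria mismatch across expert weight solutions",
             call. = FALSE)
      s$weights
    } else {
      if (is.null(criteria) && !is.null(attr(s, "criteria")))
        criteria <<- attr(s, "criteria")
      as.tfn(s)
    }
  })
  if (is.null(criteria)) criteria <- paste0("C", seq_len(length(ws[[1]])))
  if (any(vapply(ws, length, 1L) != length(criteria)))
    stop("criteria mismatch across expert weight solutions", call. = FALSE)
  l <- rowMeans(vapply(ws, `[[`, numeric(length(criteria)), "l"))
  m <- rowMeans(vapply(ws, `[[`, numeric(length(criteria)), "m"))
  u <- rowMeans(vapply(ws, `[[`, numeric(length(criteria)), "u"))
  w <- tfn(l, m, u)
  w <- w / sum(gmir(w))   # rescale so the defuzzified weights sum to one
  attr(w, "criteria") <- criteria
  w
}
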