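# shared helpers: random generators and independent oracles

# random valid TFN with nonnegative support
rand_tfn <- function(n = 1, lo = 0, hi = 10) {
  a <- matrix(runif(3 * n, lo, hi), ncol = 3)
  a <- t(apply(a, 1, sort))
  tfn(a[, 1], a[, 2], a[, 3])
}

# independent classical (crisp) MABAC on a plain numeric matrix:
# column min-max normalization, v = w (1 + n), geometric-mean border,
# q = v - g, scores = row sums
crisp_mabac_oracle <- function(X, w) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  N <- sweep(sweep(X, 2, lo, `-`), 2, hi - lo, `/`)
  V <- sweep(1 + N, 2, w, `*`)
  g <- exp(colMeans(log(V)))
  Q <- sweep(V, 2, g, `-`)
  rowSums(Q)
}

# brute-force grid search for the crisp 3-criteria BWM minimax objective
# at a given simplex resolution; returns the smallest objective found
crisp_bwm_grid_oracle <- function(aB, aW, iB, iW, step = 1e-3) {
  w1 <- seq(step, 1 - 2 * step, by = step)
  grid <- expand.grid(w1 = w1, w2 = w1)
  grid <- grid[grid$w1 + grid$w2 < 1 - step / 2, ]
  W <- cbind(grid$w1, grid$w2, 1 - grid$w1 - grid$w2)
  viol <- rep(0, nrow(W))
  for (j in 1:3) {
    viol <- pmax(viol, abs(W[, iB] / W[, j] - aB[j]),
                 abs(W[, j] / W[, iW] - aW[j]))
  }
  list(value = min(viol), weights = W[which.min(viol), ])
}

# scale fuzzy weights so their GMIRs follow a Dirichlet-perturbed profile
perturb_weights <- function(w, concentration = 40) {
  g <- stats::rgamma(length(w), shape = concentration * gmir(w))
  g <- g / sum(g)
  wp <- tfn(w$l * g / gmir(w), w$m * g / gmir(w), w$u * g / gmir(w))
  attr(wp, "criteria") <- attr(w, "criteria")
  wp
}

ze_reference_cells <- function(cs) {
  v <- cs$votes
  i <- match(paste(cs$judgments$alternative, cs$judgments$expert),
             paste(v$alternative, v$expert))
  rec <- ze_convert(cs$judgments$rating_term, cs$judgments$reliability_term,
                    v$Y[i], v$N[i], v$theta[i], v$n[i])
  k <- match(paste(cs$judgments$alternative, cs$judgments$expert,
                   cs$judgments$criterion),
             paste(cs$ze_matrix$alternative, cs$ze_matrix$expert,
                   cs$ze_matrix$criterion))
  list(recomputed = rec, printed = cs$ze_matrix[k, ],
       judgments = cs$judgments)
}
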