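make_fm <- function(cells, alts = NULL, crit = NULL, stage = "initial") {
  # cells: list of rows, each row a list of c(l, m, u)
  m <- length(cells); n <- length(cells[[1]])
  L <- M <- U <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    tr <- cells[[i]][[j]]
    L[i, j] <- tr[1]; M[i, j] <- tr[2]; U[i, j] <- tr[3]
  }
  fuzzy_matrix(L, M, U,
               alternatives = alts %||% paste0("A", 1:m),
               criteria = crit %||% paste0("C", 1:n), stage = stage)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("matrix construction validates shape and cells", {
  expect_error(fuzzy_matrix(matrix(2, 2, 2), matrix(1, 2, 2),
                            matrix(3, 2, 2)), "l <= m <= u")
  df <- data.frame(alternative = c("A1", "A1"), criterion = c("S", "S"),
                   l = 1, m = 2, u = 3)
  expect_error(fuzzy_matrix_from_df(df), "duplicate")
  df <- data.frame(alternative = "A1", criterion = "S", l = 1, m = 2, u = 3)
  expect_error(fuzzy_matrix_from_df(df, criteria = c("S", "O")), "missing")
})

test_that("expert matrices average componentwise", {
  a <- make_fm(list(list(c(1, 2, 3))))
  b <- make_fm(list(list(c(3, 4, 5))))
  expect_equal(assemble_matrix(list(a))$m, a$m)
  ab <- assemble_matrix(list(a, b))
  expect_equal(unname(c(ab$l, ab$m, ab$u)), c(2, 3, 4))
  expect_equal(assemble_matrix(list(a, a, a))$l, a$l)
  expect_error(assemble_matrix(list(a, make_fm(list(list(c(1, 2, 3)),
                                                    list(c(1, 2, 3)))))),
               "shape")
})

test_that("min-max normalization reproduces the reference anchors", {
  cs <- case_study()
  nz <- normalize_matrix(cs$initial_matrix)
  expect_equal(unname(nz$m["A1", "S"]), (3.67 - 0.33) / 9, tolerance = 1e-12)
  expect_equal(unname(nz$m["A1", "S"]), 0.37, tolerance = 0.005)
  expect_equal(unname(nz$m["A3", "D"]), 0.16, tolerance = 0.005)
  # every column touches 0 and 1
  expect_equal(unname(apply(nz$l, 2, min)), c(0, 0, 0))
  expect_equal(unname(apply(nz$u, 2, max)), c(1, 1, 1))
  expect_true(all(nz$l >= 0 & nz$u <= 1))
})

test_that("cost criteria reflect and constant columns warn", {
  dm <- make_fm(list(list(c(1, 2, 3), c(5, 5, 5)),
                     list(c(2, 4, 9), c(5, 5, 5))), crit = c("B", "C"))
  expect_warning(nz <- normalize_matrix(dm, c(B = "benefit", C = "cost")),
                 "constant column")
  expect_equal(unname(nz$l[, "C"]), c(0, 0))
  nz2 <- normalize_matrix(make_fm(list(list(c(1, 2, 3)), list(c(2, 4, 9)))),
                          c(C1 = "cost"))
  # cost direction: best (lowest) cell maps to the top of [0, 1]
  expect_equal(unname(nz2$u[1, 1]), 1)
  expect_equal(unname(nz2$l[2, 1]), 0)
  expect_true(all(nz2$l <= nz2$m & nz2$m <= nz2$u))
})

test_that("the max-divide normalization variant is available", {
  dm <- make_fm(list(list(c(1, 2, 3)), list(c(2, 4, 8))))
  nz <- normalize_matrix(dm, method = "max")
  expect_equal(unname(nz$u), matrix(c(3 / 8, 1), 2))
})

test_that("weighting applies w (C + n) with the unit constant", {
  nz <- make_fm(list(list(c(0, 0, 0)), list(c(0.59, 0.81, 1))),
                stage = "normalized")
  w <- tfn(0.3277, 0.3367, 0.3890)
  wt <- weight_matrix(nz, w)
  expect_equal(unname(c(wt$l[1], wt$m[1], wt$u[1])),
               c(0.3277, 0.3367, 0.3890))
  expect_equal(unname(c(wt$l[2], wt$m[2], wt$u[2])),
               c(0.521043, 0.609427, 0.778), tolerance = 1e-9)
  expect_error(weight_matrix(nz, tfn(0, 0.3, 0.4)), "strictly positive")
  expect_error(weight_matrix(make_fm(list(list(c(1, 2, 3)))), w),
               "normalized-stage")
})

test_that("the border approximation area is the geometric column mean", {
  wt <- make_fm(list(list(c(0.2, 0.3, 0.4)), list(c(0.8, 0.9, 1.0))),
                stage = "weighted")
  g <- compute_baa(wt)
  expect_equal(as.data.frame(g),
               data.frame(l = 0.4, m = sqrt(0.27), u = sqrt(0.4)),
               tolerance = 1e-12)
  # all-equal column returns the shared cell; single row returns itself
  same <- make_fm(list(list(c(0.5, 0.6, 0.7)), list(c(0.5, 0.6, 0.7))),
                  stage = "weighted")
  expect_equal(as.data.frame(compute_baa(same)),
               data.frame(l = 0.5, m = 0.6, u = 0.7), tolerance = 1e-12)
  one <- make_fm(list(list(c(0.3, 0.4, 0.5))), stage = "weighted")
  expect_equal(as.data.frame(compute_baa(one)),
               data.frame(l = 0.3, m = 0.4, u = 0.5))
  # the border lies within the componentwise column range
  set.seed(8)
  wt <- make_fm(lapply(1:6, function(i) list(sort(runif(3, 0.1, 1)),
                                             sort(runif(3, 0.1, 1)))),
                stage = "weighted")
  g <- compute_baa(wt)
  for (j in 1:2) {
    expect_gte(g$l[j], min(wt$l[, j])); expect_lte(g$l[j], max(wt$l[, j]))
    expect_gte(g$u[j], min(wt$u[, j])); expect_lte(g$u[j], max(wt$u[, j]))
  }
})

test_that("distances widen around the border and preserve dominance", {
  wt <- make_fm(list(list(c(0.52, 0.61, 0.78)), list(c(0.40, 0.52, 0.63))),
                stage = "weighted")
  q <- compute_distances(wt, tfn(0.40, 0.52, 0.63))
  expect_equal(unname(c(q$l[1], q$m[1], q$u[1])), c(-0.11, 0.09, 0.38),
               tolerance = 1e-12)
  # a cell equal to the border has centroid zero
  expect_equal(defuzzify(tfn(q$l[2], q$m[2], q$u[2])), 0, tolerance = 1e-12)
  # linearity: column sums of centroids
  set.seed(9)
  wt <- make_fm(lapply(1:5, function(i) list(sort(runif(3, 0.1, 1)))),
                stage = "weighted")
  g <- compute_baa(wt)
  q <- compute_distances(wt, g)
  cq <- (q$l + q$m + q$u) / 3
  cr <- (wt$l + wt$m + wt$u) / 3
  expect_equal(sum(cq), sum(cr) - 5 * defuzzify(g), tolerance = 1e-12)
})

test_that("scoring ranks by descending crisp score with documented ties", {
  q <- make_fm(list(list(c(-0.1, 0.0, 0.1), c(0.1, 0.2, 0.3)),
                    list(c(-0.2, -0.1, 0.0), c(0.0, 0.1, 0.2)),
                    list(c(-0.15, 0.05, 0.1), c(0.1, 0.2, 0.3))),
               stage = "distance")
  r <- score_and_rank(q)
  expect_equal(sort(r$rank), 1:3)
  expect_equal(r$score, (r$S_l + r$S_m + r$S_u) / 3)
  expect_true(r$rank[2] == 3)   # strictly dominated row ranks last
  one <- score_and_rank(make_fm(list(list(c(-1, 0, 1))), stage = "distance"))
  expect_equal(one$rank, 1L)
  # tie on score broken by larger modal value
  tie <- make_fm(list(list(c(-0.3, 0.0, 0.3)), list(c(-0.2, 0.0, 0.2))),
                 stage = "distance")
  tie$m[1, 1] <- 0.05; tie$l[1, 1] <- -0.35
  r <- score_and_rank(tie)
  expect_equal(r$rank, c(1L, 2L))
})

test_that("the fuzzy pipeline matches classical MABAC on crisp inputs", {
  set.seed(123)
  for (rep in 1:100) {
    X <- matrix(runif(15, 1, 10), 5, 3)
    w <- runif(3, 0.1, 1); w <- w / sum(w)
    dm <- fuzzy_matrix(X, X, X)
    res <- mabac(dm, tfn(w, w, w))
    expect_equal(res$score, crisp_mabac_oracle(X, w), tolerance = 1e-10)
  }
})

test_that("ranks are invariant to positive affine rescaling of columns", {
  set.seed(21)
  base <- make_fm(lapply(1:6, function(i)
    lapply(1:3, function(j) sort(runif(3, 1, 9)))))
  w <- tfn(c(0.3, 0.3, 0.4), c(0.3, 0.3, 0.4), c(0.3, 0.3, 0.4))
  r1 <- mabac(base, w)
  scaled <- fuzzy_matrix(sweep(base$l, 2, c(2, 5, 0.5), `*`) + 3,
                         sweep(base$m, 2, c(2, 5, 0.5), `*`) + 3,
                         sweep(base$u, 2, c(2, 5, 0.5), `*`) + 3)
  r2 <- mabac(scaled, w)
  expect_equal(r1$rank, r2$rank)
})

test_that("componentwise dominance is never rank-reversed", {
  set.seed(31)
  for (rep in 1:20) {
    cells <- lapply(1:5, function(i)
      lapply(1:3, function(j) sort(runif(3, 1, 8))))
    # plant a dominating copy of row 1
    cells[[2]] <- lapply(cells[[1]], function(x) x + runif(1, 0.2, 1))
    dm <- make_fm(cells)
    w <- runif(3, 0.2, 1)
    r <- mabac(dm, tfn(w, w, w))
    expect_lt(r$rank[2], r$rank[1])
  }
})

test_that("stages cannot be run out of order", {
  dm <- make_fm(list(list(c(1, 2, 3)), list(c(2, 3, 4))))
  expect_error(compute_baa(dm), "weighted")
  expect_error(score_and_rank(dm), "distance")
  expect_error(normalize_matrix(normalize_matrix(dm)), "initial-stage")
})
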