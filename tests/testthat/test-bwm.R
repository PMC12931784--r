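test_that("comparison vectors are validated structurally", {
  cs <- case_study()
  tm1 <- cs$comparisons$TM1
  expect_s3_class(tm1, "comparison_vector")
  expect_equal(tm1$best, "D"); expect_equal(tm1$worst, "O")
  expect_error(
    comparison_vector(c("S", "O", "D"), best = "S", worst = "S",
                      best_to_others = c(S = "EI", O = "I", D = "I"),
                      others_to_worst = c(S = "EI", O = "I", D = "I")),
    "must differ")
  expect_error(
    comparison_vector(c("S", "O", "D"), best = "S", worst = "O",
                      best_to_others = c(S = "EI", O = "I"),
                      others_to_worst = c(S = "I", O = "EI", D = "I")),
    "missing entry for criterion 'D'")
  expect_error(
    comparison_vector(c("S", "O", "D"), best = "S", worst = "O",
                      best_to_others = c(S = "I", O = "I", D = "I"),
                      others_to_worst = c(S = "I", O = "EI", D = "I")),
    "must be 'EI'")
})

test_that("a perfectly symmetric two-criterion panel splits evenly", {
  cv <- comparison_vector(c("C1", "C2"), best = "C1", worst = "C2",
                          best_to_others = c(C1 = "EI", C2 = "EI"),
                          others_to_worst = c(C1 = "EI", C2 = "EI"))
  s <- solve_fuzzy_bwm(cv, seed = 1, n_starts = 8)
  expect_lt(s$xi_star, 1e-9)
  expect_equal(s$weights$m, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(s$weights$l, s$weights$u, tolerance = 1e-6)
  expect_equal(s$cr, 0, tolerance = 1e-9)
  expect_true(s$cr_acceptable)
})

test_that("crisp consistent comparisons recover the closed-form weights", {
  # w_B/w_2 = 2, w_B/w_W = 4, w_2/w_W = 2  =>  w = (4/7, 2/7, 1/7), xi* = 0
  sc <- linguistic_scale("crisp", data.frame(
    term = c("EI", "X2", "X4"), l = c(1, 2, 4), m = c(1, 2, 4),
    u = c(1, 2, 4), ci = c(3, 5, 9)))
  cv <- comparison_vector(c("C1", "C2", "C3"), best = "C1", worst = "C3",
                          best_to_others = c(C1 = "EI", C2 = "X2", C3 = "X4"),
                          others_to_worst = c(C1 = "X4", C2 = "X2", C3 = "EI"),
                          importance_scale = sc)
  s <- solve_fuzzy_bwm(cv, importance_scale = sc, seed = 3)
  expect_lt(s$xi_star, 1e-8)
  expect_equal(s$weights$m, c(4, 2, 1) / 7, tolerance = 1e-4)
  expect_equal(s$weights$l, s$weights$u, tolerance = 1e-4)
  # independent grid-search oracle agrees on optimum and objective
  or <- crisp_bwm_grid_oracle(aB = c(1, 2, 4), aW = c(4, 2, 1),
                              iB = 1, iW = 3, step = 1e-3)
  expect_lt(or$value, 1e-2)           # grid can do no better than its step
  expect_equal(or$weights, c(4, 2, 1) / 7, tolerance = 2e-3)
  expect_lte(s$xi_star, or$value + 1e-8)
})

test_that("defuzzified weights sum to one and are deterministic per seed", {
  cs <- case_study()
  s1 <- solve_fuzzy_bwm(cs$comparisons$TM1, seed = 7)
  s2 <- solve_fuzzy_bwm(cs$comparisons$TM1, seed = 7)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$xi_star, s2$xi_star)
  expect_equal(sum(gmir(s1$weights)), 1, tolerance = 1e-9)
  expect_true(all(s1$weights$l > 0))
})

test_that("consistency ratio scales the objective by the scale CI", {
  cs <- case_study()
  s <- solve_fuzzy_bwm(cs$comparisons$TM2, seed = 7)
  cr <- consistency_ratio(s, cs$comparisons$TM2)
  # TM2's best-to-worst term is VI (CI 8.04)
  expect_equal(as.numeric(cr), s$xi_star / 8.04, tolerance = 1e-12)
  expect_identical(attr(cr, "acceptable"), as.numeric(cr) < 0.1)
  fake <- s; fake$xi_star <- 0.8
  expect_equal(fake$xi_star / 9.35, 0.0856, tolerance = 1e-3)
})

test_that("expert weight aggregation averages componentwise and rescales", {
  cs <- case_study()
  # componentwise mean of the reported severity weights
  sw <- do.call(c, lapply(cs$expert_weights, `[`, 1))
  expect_equal(as.data.frame(mean(sw)),
               data.frame(l = 0.3276667, m = 0.3366667, u = 0.389),
               tolerance = 1e-6)
  agg <- aggregate_expert_weights(cs$expert_weights)
  expect_equal(attr(agg, "criteria"), c("S", "O", "D"))
  expect_equal(sum(gmir(agg)), 1, tolerance = 1e-12)
  # rescaling preserves the proportions of the raw means
  expect_equal(agg$m[1] / agg$m[3], 0.3366667 / 0.3463333, tolerance = 1e-6)
  # single expert: own weights, renormalized only
  one <- aggregate_expert_weights(cs$expert_weights["TM1"])
  expect_equal(gmir(one) / gmir(cs$expert_weights$TM1),
               rep(1 / sum(gmir(cs$expert_weights$TM1)), 3),
               tolerance = 1e-12)
  # identical experts return that vector
  same <- aggregate_expert_weights(list(one, one, one))
  expect_equal(as.data.frame(same), as.data.frame(one), tolerance = 1e-12)
  expect_error(aggregate_expert_weights(list()), "no weight")
})

test_that("zero objective only occurs when comparisons are reproduced", {
  # a deliberately inconsistent panel cannot reach xi* = 0
  cv <- comparison_vector(c("C1", "C2", "C3"), best = "C1", worst = "C3",
                          best_to_others = c(C1 = "EI", C2 = "AI", C3 = "WI"),
                          others_to_worst = c(C1 = "WI", C2 = "AI", C3 = "EI"))
  s <- solve_fuzzy_bwm(cv, seed = 2, n_starts = 16)
  expect_gt(s$xi_star, 0.1)
})
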