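test_that("limit pairs classify into the documented kinds", {
  expect_equal(classify_limit(0, 1.0), "max_only")
  expect_equal(classify_limit(0, 0), "exact_zero")
  expect_equal(classify_limit(2, 2), "point")
  expect_equal(classify_limit(1, 3), "band")
  expect_equal(classify_limit(1, Inf), "min_only")
  expect_equal(classify_limit(NA, 1), "missing")
  expect_equal(classify_limit(0, Inf), "missing")
  expect_equal(classify_limit(c(0, 2, 0), c(1, 2, 0)),
               c("max_only", "point", "exact_zero"))
  expect_error(classify_limit(2, 1), "invalid limit")
  expect_error(classify_limit(-1, 1), "invalid limit")
})

test_that("branch examples score as documented", {
  # maximum-only: linear descent, 0 at and beyond the limit
  expect_equal(simple_qualification_degree(1.2, 0, 1.0), 0)
  expect_equal(simple_qualification_degree(1.0, 0, 1.0), 0)
  expect_equal(simple_qualification_degree(0.5, 0, 1.0), 0.5)
  expect_equal(simple_qualification_degree(0, 0, 1.0), 1)
  # must-be-absent analytes
  expect_equal(simple_qualification_degree(0, 0, 0), 1)
  expect_equal(simple_qualification_degree(1e-6, 0, 0), 0)
  # point target: 1 at the target, clamped linear descent above it
  expect_equal(simple_qualification_degree(2, 2, 2), 1)
  expect_equal(simple_qualification_degree(3, 2, 2), 0.5)
  expect_equal(simple_qualification_degree(4, 2, 2), 0)
  expect_equal(simple_qualification_degree(1.9, 2, 2), 0)   # below the minimum
  # band: midpoint is safest, edges score 0.5, outside scores 0
  expect_equal(simple_qualification_degree(2, 1, 3), 1)
  expect_equal(simple_qualification_degree(1, 1, 3), 0.5)
  expect_equal(simple_qualification_degree(2.5, 1, 3), 0.75)
  expect_equal(simple_qualification_degree(3, 1, 3), 0)
  expect_equal(simple_qualification_degree(0.5, 1, 3), 0)
  # pure lower bound: pass/fail (no graded branch exists for it)
  expect_equal(simple_qualification_degree(c(0.5, 2), 1, Inf), c(0, 1))
})

test_that("the alternative point-limit parse is reciprocal", {
  expect_equal(simple_qualification_degree(4, 2, 2, point_parse = "reciprocal"),
               0.5)
  expect_equal(simple_qualification_degree(2, 2, 2, point_parse = "reciprocal"),
               1)
})

test_that("Q stays in [0,1] and is 0 exactly on out-of-bound results", {
  set.seed(101)
  n <- 20000
  kd <- sample(c("max_only", "band", "point", "exact_zero"), n,
               replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1))
  mn <- ifelse(kd %in% c("band", "point"), runif(n, 0.1, 5), 0)
  mx <- ifelse(kd == "max_only", runif(n, 0.1, 5),
        ifelse(kd == "band", mn + rexp(n),
        ifelse(kd == "point", mn, 0)))
  t_res <- runif(n, 0, 2.5) * pmax(mx, mn, 0.5)
  t_res[kd == "exact_zero" & runif(n) < 0.5] <- 0
  q <- simple_qualification_degree(t_res, mn, mx)
  expect_true(all(q >= 0 & q <= 1))
  kind <- classify_limit(mn, mx)
  violated <- (kind == "max_only" & t_res >= mx) |
    (kind == "band" & (t_res < mn | t_res >= mx)) |
    (kind == "exact_zero" & t_res > 0) |
    (kind == "point" & (t_res < mn | t_res >= 2 * mn))
  expect_identical(q == 0, violated)
})

test_that("Q is strictly decreasing in T under a maximum-only limit", {
  t_grid <- seq(0, 0.999, length.out = 200)
  q <- simple_qualification_degree(t_grid, 0, 1)
  expect_true(all(diff(q) < 0))
  expect_true(all(simple_qualification_degree(seq(1, 3, by = 0.5), 0, 1) == 0))
})

test_that("invalid measurements and missing limits are rejected", {
  expect_error(simple_qualification_degree(-0.1, 0, 1), "non-negative")
  expect_error(simple_qualification_degree(NA, 0, 1), "non-negative")
  expect_error(simple_qualification_degree(1, NA, NA), "no usable permissible limit")
  expect_equal(simple_qualification_degree(1, NA, NA, na_action = "na"),
               NA_real_)
})

test_that("score_records appends Q and excludes unlimited records with a log", {
  rec <- data.frame(sample_id = c("a", "b", "c", "d"),
                    test_result = c(0.5, 2, 0.2, 1),
                    min_limit = c(0, 1, NA, NA),
                    max_limit = c(1, 3, 0.5, NA))
  out <- score_records(rec)
  expect_equal(nrow(out$records), 3)
  expect_equal(out$records$Q, c(0.5, 1, 0.6))   # NA min reads as 0
  expect_equal(out$excluded$sample_id, "d")
  expect_match(out$log, "excluded 1")
  expect_error(score_records(rec[, -2]), "lacks column")
})
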