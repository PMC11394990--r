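test_that("encode_mixed builds standardized and indicator blocks", {
  set.seed(11)
  d <- data.frame(x = rnorm(10), y = runif(10),
                  f = rep(c("a", "b", "c"), length.out = 10),
                  g = rep(c("u", "v"), 5),
                  const = 1)
  spec <- data.frame(
    variable = c("x", "y", "const", "f", "g"),
    type = c("quantitative", "quantitative", "quantitative",
             "qualitative", "qualitative"))
  enc <- encode_mixed(d, spec)
  # 2 qualitative variables with 3 and 2 levels -> m = 5 indicator columns
  expect_equal(ncol(enc$qual), 5)
  # one-hot rows sum to the number of qualitative variables before centering
  expect_equal(unname(rowSums(enc$qual_raw)), rep(2, 10))
  # standardized: zero mean, unit population variance
  expect_equal(unname(colMeans(enc$quant)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(colMeans(enc$quant^2)), c(1, 1), tolerance = 1e-12)
  # centered indicators
  expect_equal(max(abs(colMeans(enc$qual))), 0, tolerance = 1e-12)
  # constant column dropped and logged
  expect_true("const" %in% enc$dropped)
  expect_match(enc$log, "dropped 1")
})

test_that("encode_mixed rejects degenerate designs", {
  d <- data.frame(x = 1:2, f = c("a", "b"))
  spec <- data.frame(variable = c("x", "f"),
                     type = c("quantitative", "qualitative"))
  expect_error(encode_mixed(d, spec), "at least 3")
  d3 <- data.frame(x = c(1, 1, 1), f = c("a", "a", "a"))
  expect_error(encode_mixed(d3, spec), "degenerate")
  # single observed level is dropped, the rest survives
  d4 <- data.frame(x = rnorm(5), f = "only")
  enc <- encode_mixed(d4, spec)
  expect_true("f" %in% enc$dropped)
  expect_null(enc$qual)
})

test_that("first_eigenvalue matches a brute-force eigendecomposition", {
  # single standardized column -> exactly 1
  set.seed(3)
  x <- standardize_pop(matrix(rnorm(12), ncol = 1))
  expect_equal(first_eigenvalue(x), 1, tolerance = 1e-12)
  # orthogonal equal-norm columns: lambda1 equals either column's variance
  m <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1)) * 2
  expect_equal(first_eigenvalue(m), sum(m[, 1]^2) / 4, tolerance = 1e-12)
  # general case vs eigen() oracle, and permutation invariance
  for (i in 1:5) {
    m <- matrix(rnorm(24), nrow = 6)
    oracle <- max(eigen(crossprod(m) / 6, symmetric = TRUE)$values)
    expect_equal(first_eigenvalue(m), oracle, tolerance = 1e-10)
    expect_equal(first_eigenvalue(m[, c(3, 1, 2, 4)]), oracle,
                 tolerance = 1e-10)
  }
  expect_error(first_eigenvalue(matrix(0, 4, 2)), "degenerate")
})

test_that("quantitative-only factor scores match the brute-force SVD oracle", {
  set.seed(21)
  for (i in 1:10) {
    raw <- matrix(rnorm(48), nrow = 8)
    design <- encode_mixed(
      as.data.frame(raw),
      data.frame(variable = paste0("V", 1:6),
                 type = "quantitative"))
    model <- famd_decompose(design, fadm_params())
    oracle <- oracle_factor_scores(design$quant)
    r <- length(oracle$d)
    got <- align_signs(oracle$scores,
                       model$factor_scores[, seq_len(r), drop = FALSE])
    expect_equal(got, oracle$scores, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(model$d[seq_len(r)], oracle$d, tolerance = 1e-8)
  }
})

test_that("the SVD reconstructs the global matrix and contributions sum to 1", {
  camp <- small_campaign(n = 60, seed = 5)
  design <- encode_mixed(camp$records, campaign_variable_spec(camp$records))
  model <- famd_decompose(design)
  recon <- model$u %*% diag(model$d) %*% t(model$v)
  expect_lt(max(abs(recon - model$global)), 1e-8)
  expect_equal(sum(model$variance_contributions), 1, tolerance = 1e-10)
  expect_true(all(model$variance_contributions >= 0))
  expect_true(all(diff(model$d) <= 1e-12))           # non-increasing
  expect_lt(max(abs(crossprod(model$u) - diag(ncol(model$u)))), 1e-8)
  expect_lt(max(abs(crossprod(model$v) - diag(ncol(model$v)))), 1e-8)
})

test_that("retention rules pick the documented number of factors", {
  fake <- list(quant = standardize_pop(matrix(rnorm(200), nrow = 20)),
               qual = NULL, n = 20)
  m_cum <- famd_decompose(fake, fadm_params(retention = "cumulative",
                                            threshold = 0.8))
  omega <- m_cum$variance_contributions
  expect_equal(m_cum$n_retained, which(cumsum(omega) >= 0.8)[1])
  m_fix <- famd_decompose(fake, fadm_params(retention = "fixed", r = 3))
  expect_equal(m_fix$n_retained, 3L)
  m_kai <- famd_decompose(fake, fadm_params(retention = "kaiser"))
  lam <- m_kai$d^2 / m_kai$n
  expect_equal(m_kai$n_retained, sum(lam > mean(lam)))
  expect_error(fadm_params(retention = "fixed"), "r >= 1")
  expect_error(fadm_params(threshold = 0), "threshold")
})

test_that("transform_score is a continuous increasing map into (1, k)", {
  expect_equal(transform_score(0, k = 100), 50.5)
  for (k in c(10, 100, 1000)) {
    grid <- seq(-8, 8, length.out = 2001)
    f <- transform_score(grid, k = k)
    expect_true(all(diff(f) > 0))
    expect_true(all(f > 1 & f < k))
    expect_equal(transform_score(0, k = k), (k + 1) / 2)
    # asymptotes
    expect_equal(transform_score(50, k = k), k, tolerance = 1e-6)
    expect_equal(transform_score(-50, k = k), 1, tolerance = 1e-6)
    # the two branch orientations mirror each other around (k+1)/2
    expect_equal(transform_score(grid, k = k, direction = "decreasing"),
                 k + 1 - f)
  }
  expect_error(transform_score(0, k = 1), "exceed 1")
})

test_that("fadm_weight is the contribution-weighted mean of transformed scores", {
  # invert the transform so f(F) is exactly (60, 40), then check the mean
  k <- 100
  f1 <- log((k - 1) / 2 / (k - 60))            # f(F1) = 60, F1 > 0
  f2 <- log((40 - 1) / ((k - 1) / 2))          # f(F2) = 40, F2 < 0
  model <- list(factor_scores = matrix(c(f1, f2), nrow = 1),
                variance_contributions = c(0.6, 0.2, 0.2),
                n_retained = 2L)
  expect_equal(fadm_weight(model, fadm_params(k = 100)), 55,
               tolerance = 1e-10)
  # r = 1 reduces to the transformed first score
  model$n_retained <- 1L
  expect_equal(fadm_weight(model, fadm_params(k = 100)), 60, tolerance = 1e-10)
  # a constant transformed score is returned unchanged by any contributions
  model2 <- list(factor_scores = matrix(0, nrow = 3, ncol = 4),
                 variance_contributions = c(0.4, 0.3, 0.2, 0.1),
                 n_retained = 4L)
  expect_equal(fadm_weight(model2, fadm_params(k = 100)), rep(50.5, 3))
})

test_that("fadm weights stay in (1, k) and are sample-permutation equivariant", {
  camp <- small_campaign(n = 80, seed = 9)
  design <- encode_mixed(camp$records, campaign_variable_spec(camp$records))
  params <- fadm_params(k = 100)
  model <- famd_decompose(design, params)
  w <- fadm_weight(model, params)
  expect_true(all(w > 1 & w < 100))
  set.seed(42)
  perm <- sample(nrow(camp$records))
  design_p <- encode_mixed(camp$records[perm, ],
                           campaign_variable_spec(camp$records))
  w_p <- fadm_weight(famd_decompose(design_p, params), params)
  expect_equal(w_p, w[perm], tolerance = 1e-8)
})
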