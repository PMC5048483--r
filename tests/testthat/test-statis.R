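test_that("cross-products are symmetric PSD and match explicit inner products", {
  eye <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(cross_product(eye), diag(2), ignore_attr = TRUE)

  set.seed(3)
  f <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("i", 1:5), NULL))
  w <- cross_product(f)
  expect_equal(w, t(w))
  expect_true(all(eigen(w, symmetric = TRUE)$values >= -1e-10))
  manual <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) manual[i, j] <- sum(f[i, ] * f[j, ])
  expect_equal(w, manual, ignore_attr = TRUE)
})

test_that("RV coefficient: self-cosine, scale invariance, trace formula", {
  set.seed(4)
  a <- crossprod(matrix(rnorm(9), 3, 3))
  b <- crossprod(matrix(rnorm(9), 3, 3))
  expect_equal(rv_coefficient(a, a), 1)
  expect_equal(rv_coefficient(a, 3.7 * a), 1)
  expect_equal(rv_coefficient(a, b), rv_coefficient(b, a))

  # term-by-term independent evaluation of the trace formula
  tr <- function(m) sum(diag(m))
  expect_equal(rv_coefficient(a, b),
               tr(t(a) %*% b) / sqrt(tr(t(a) %*% a) * tr(t(b) %*% b)))
  expect_true(rv_coefficient(a, b) >= 0 && rv_coefficient(a, b) <= 1)
  expect_error(rv_coefficient(matrix(0, 3, 3), a), "all-zero")
})

test_that("identical configurations get equal weights and reproduce themselves", {
  ds <- tiny_set(S = 2, n = 4, p = c(3, 2), seed = 6)
  cfg <- mfa(ds, d = 2)
  for (M in c(1L, 4L)) {
    res <- statis_compromise(rep(list(cfg), M), d = 2)
    expect_equal(res$alpha, rep(1 / M, M))
    expect_equal(sum(res$alpha), 1, tolerance = 1e-10)
    expect_equal(rv_between_configurations(res$compromise, cfg), 1,
                 tolerance = 1e-10)
    # up-to-sign recovery of the common configuration
    expect_equal(abs(res$compromise$scores), abs(cfg$scores),
                 tolerance = 1e-8 * max(abs(cfg$scores)))
  }
})

test_that("alpha comes from the leading eigenvector of R and downweights outliers", {
  ds <- tiny_set(S = 2, n = 5, p = c(4, 3), seed = 8)
  inc <- drop_rows(ds, "table1", ds$individual_ids[1])
  imp <- multiple_imputation(inc, M = 2, seed = 2)
  cfgs <- lapply(imp$completions, mfa, d = 3)
  set.seed(99)
  outlier <- new_config(matrix(rnorm(30), 10, 3,
                               dimnames = list(ds$individual_ids, NULL)))
  res <- statis_compromise(c(cfgs, list(outlier)), d = 2)
  expect_equal(which.min(res$alpha), 3L)
  expect_true(all(res$alpha >= -1e-12))

  # direct eigendecomposition oracle for alpha
  w <- lapply(c(cfgs, list(outlier)), cross_product)
  r <- diag(1, 3)
  for (j in 1:2) for (k in (j + 1):3)
    r[j, k] <- r[k, j] <- sum(w[[j]] * w[[k]]) /
      sqrt(sum(w[[j]]^2) * sum(w[[k]]^2))
  expect_equal(res$rv_matrix, r)
  v1 <- eigen(r, symmetric = TRUE)$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  expect_equal(res$alpha, v1 / sum(v1), tolerance = 1e-10)
})

test_that("permuting configurations permutes alpha and keeps the compromise", {
  ds <- tiny_set(S = 2, n = 5, p = c(4, 3), seed = 10)
  inc <- drop_rows(ds, "table1", ds$individual_ids[1:2])
  imp <- multiple_imputation(inc, M = 3, seed = 7)
  cfgs <- lapply(imp$completions, mfa, d = 3)
  res <- statis_compromise(cfgs, d = 2)
  perm <- c(3L, 1L, 2L)
  res_p <- statis_compromise(cfgs[perm], d = 2)
  expect_equal(res_p$alpha, res$alpha[perm], tolerance = 1e-10)
  expect_equal(abs(res_p$compromise$scores), abs(res$compromise$scores),
               tolerance = 1e-8)
})

test_that("the compromise agrees with the configurations at least as well as
           any single one", {
  for (seed in c(1, 5, 9)) {
    ds <- generate_multitable(S = 3, n_per_stratum = 4, p = c(6, 4),
                              seed = seed)
    inc <- insert_missingness(ds, missingness_scenario(c(1, 0)),
                              seed = seed)$dataset
    imp <- multiple_imputation(inc, M = 5, seed = seed)
    cfgs <- lapply(imp$completions, mfa, d = 4)
    res <- statis_compromise(cfgs, d = 4)
    w <- lapply(cfgs, cross_product)
    wc <- cross_product(res$compromise)
    avg_comp <- mean(vapply(w, function(x) rv_coefficient(wc, x), 0))
    avg_single <- vapply(seq_along(w), function(m)
      mean(vapply(w, function(x) rv_coefficient(w[[m]], x), 0)), 0)
    expect_gte(avg_comp, max(avg_single) - 1e-6)
  }
})

test_that("trajectories project each configuration onto the compromise axes", {
  ds <- tiny_set(S = 2, n = 4, p = c(3, 2), seed = 15)
  inc <- drop_rows(ds, "table1", ds$individual_ids[1])
  imp <- multiple_imputation(inc, M = 3, seed = 1)
  cfgs <- lapply(imp$completions, mfa, d = 3)
  res <- statis_compromise(cfgs, d = 2)
  # mean of trajectories weighted by alpha reproduces the compromise scores
  avg <- Reduce(`+`, Map(`*`, res$trajectories, res$alpha))
  expect_equal(avg, res$compromise$scores, tolerance = 1e-8)
  expect_error(statis_compromise(list(), d = 2), "at least one")
})
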