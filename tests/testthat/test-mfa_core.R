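test_that("first table eigenvalue matches analytic cases and a dense oracle", {
  ids <- paste0("i", 1:6)
  one <- omics_table(matrix(rnorm(6), 6, 1, dimnames = list(ids, "v1")), "t")
  expect_equal(table_first_eigenvalue(one), 1)

  x <- rnorm(6)
  m2 <- cbind(v1 = x, v2 = 2 * x + 3)
  rownames(m2) <- ids
  expect_equal(table_first_eigenvalue(omics_table(m2, "t")), 2)

  set.seed(11)
  m <- matrix(rnorm(18), 6, 3, dimnames = list(ids, paste0("v", 1:3)))
  tb <- omics_table(m, "t")
  xc <- sweep(m, 2, colMeans(m), "-")
  xs <- sweep(xc, 2, sqrt(colMeans(xc^2)), "/")
  expect_equal(table_first_eigenvalue(tb),
               max(eigen(crossprod(xs) / 6, symmetric = TRUE)$values))
})

test_that("first eigenvalue errors on incomplete or degenerate tables", {
  ids <- paste0("i", 1:4)
  m <- matrix(rnorm(8), 4, 2, dimnames = list(ids, c("v1", "v2")))
  m[2, ] <- NA_real_
  expect_error(table_first_eigenvalue(omics_table(m, "t")), "missing rows")

  m2 <- matrix(c(rnorm(4), rep(1, 4)), 4, 2,
               dimnames = list(ids, c("ok", "flat")))
  expect_error(table_first_eigenvalue(omics_table(m2, "t")), "flat")
})

test_that("mfa matches a brute-force weighted-merged-covariance oracle", {
  for (seed in c(3, 17)) {
    ds <- generate_multitable(S = 2, n_per_stratum = 5, p = c(3, 4),
                              seed = seed)
    cfg <- mfa(ds, d = 3)
    orc <- oracle_mfa_scores(ds, d = 3)
    expect_equal(abs(cfg$scores), abs(orc$scores), ignore_attr = TRUE,
                 tolerance = 1e-8)
    expect_equal(rv_between_configurations(cfg$scores, orc$scores), 1,
                 tolerance = 1e-8)
    # trace conservation: spectrum sums to total variance of weighted table
    expect_equal(sum(cfg$eigenvalues), sum(orc$z^2) / nrow(orc$z),
                 tolerance = 1e-8)
  }
})

test_that("single-table mfa is the table's own PCA shrunk by sqrt(lambda1)", {
  set.seed(5)
  m <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("i", 1:8), paste0("v", 1:5)))
  tb <- omics_table(m, "only")
  ds <- multiomics_set(list(tb), setNames(rep(c("a", "b"), each = 4),
                                          rownames(m)))
  cfg <- mfa(ds, d = 2)
  x <- sweep(m, 2, colMeans(m), "-")
  x <- sweep(x, 2, sqrt(colMeans(x^2)), "/")
  sv <- svd(x)
  pc <- (sv$u %*% diag(sv$d))[, 1:2]
  l1 <- sv$d[1]^2 / 8
  expect_equal(abs(cfg$scores), abs(pc / sqrt(l1)), ignore_attr = TRUE)
})

test_that("after weighting no table can dominate: weighted lambda1 is 1", {
  ds <- tiny_set(S = 2, n = 5, p = c(4, 2), seed = 8)
  cfg <- mfa(ds, d = 2)
  for (j in seq_along(ds$tables)) {
    tb <- ds$tables[[j]]
    x <- sweep(tb$values, 2, colMeans(tb$values), "-")
    x <- sweep(x, 2, sqrt(colMeans(x^2)), "/")
    wtb <- omics_table(x * cfg$table_weights$weight[j], "w")
    expect_equal(table_first_eigenvalue(
      wtb, preprocess_spec(scale_unit_variance = FALSE)), 1)
  }
})

test_that("mfa output is invariant to positive rescaling of a table", {
  ds <- tiny_set(S = 2, n = 5, p = c(4, 3), seed = 13)
  for (scale_flag in c(TRUE, FALSE)) {
    spec <- preprocess_spec(scale_unit_variance = scale_flag)
    base <- mfa(ds, d = 2, spec = spec)
    tables <- ds$tables
    tables$table1 <- omics_table(tables$table1$values * 7.5, "table1")
    scaled <- mfa(multiomics_set(tables, ds$strata), d = 2, spec = spec)
    expect_equal(rv_between_configurations(base, scaled), 1,
                 tolerance = 1e-10)
  }
})

test_that("duplicating a table splits its weight evenly and leaves the
           configuration unchanged (RV = 1)", {
  ds <- tiny_set(S = 2, n = 5, p = c(4, 3), seed = 21)
  t1 <- ds$tables$table1
  single <- multiomics_set(list(t1), ds$strata)
  dup <- multiomics_set(list(t1, omics_table(t1$values, "copy")), ds$strata)
  cfg1 <- mfa(single, d = 2)
  cfg2 <- mfa(dup, d = 2)
  expect_equal(cfg2$table_weights$weight[1], cfg2$table_weights$weight[2])
  expect_equal(rv_between_configurations(cfg1, cfg2), 1, tolerance = 1e-10)
})

test_that("mfa validates inputs and pads past the numerical rank", {
  ds <- tiny_set(S = 2, n = 3, p = c(2, 2), seed = 2)
  inc <- drop_rows(ds, "table1", ds$individual_ids[1])
  expect_error(mfa(inc, d = 2), "impute")
  expect_error(mfa(ds, d = 10), "between 1 and")

  # rank-deficient: two proportional columns collapse to rank 1 after scaling
  set.seed(1)
  x <- rnorm(6)
  m <- cbind(v1 = x, v2 = 2 * x)
  rownames(m) <- paste0("i", 1:6)
  ds2 <- multiomics_set(list(omics_table(m, "t")),
                        setNames(rep(c("a", "b"), each = 3), rownames(m)))
  expect_warning(cfg <- mfa(ds2, d = 2), "rank")
  expect_equal(cfg$scores[, 2], setNames(rep(0, 6), rownames(m)))
})

test_that("scores columns are orthogonal and eigenvalues nonincreasing", {
  ds <- tiny_set(S = 3, n = 4, p = c(5, 3), seed = 31)
  cfg <- mfa(ds, d = 4)
  g <- crossprod(cfg$scores)
  expect_equal(g - diag(diag(g)), matrix(0, 4, 4), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(diff(cfg$eigenvalues) <= 1e-12))
  expect_true(all(cfg$eigenvalues >= 0))
})
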