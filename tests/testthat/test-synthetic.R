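test_that("per-stratum incomplete-case counts match the standard two-table
           design values", {
  # stratum size 8, disjoint removal across (transcriptome, clinical)
  expect_equal(count_incomplete_cases(8, c(1, 1)), 56)
  expect_equal(count_incomplete_cases(8, c(2, 1)), 168)
  expect_equal(count_incomplete_cases(8, c(1, 2)), 168)
  expect_equal(count_incomplete_cases(8, c(3, 1)), 280)
  expect_equal(count_incomplete_cases(8, c(2, 2)), 420)
  expect_equal(count_incomplete_cases(8, c(3, 2)), 560)
  expect_equal(count_incomplete_cases(8, c(4, 1)), 280)
  expect_equal(count_incomplete_cases(8, c(0, 0)), 1)
  expect_error(count_incomplete_cases(4, c(3, 2)), "infeasible")
})

test_that("case counts equal exhaustive enumeration of removal patterns", {
  enumerate_patterns <- function(n, t, disjoint) {
    # count ordered pairs of removal sets by brute force
    members <- seq_len(n)
    sets1 <- if (t[1] == 0) list(integer(0)) else
      combn(members, t[1], simplify = FALSE)
    total <- 0
    for (a in sets1) {
      pool2 <- if (disjoint) setdiff(members, a) else members
      # combn over an index count avoids the scalar-vector gotcha
      total <- total + if (t[2] == 0) 1 else
        ncol(combn(length(pool2), t[2]))
    }
    total
  }
  for (n in 3:6) {
    for (t1 in 0:2) {
      for (t2 in 0:2) {
        if (t1 + t2 > n) next
        expect_equal(count_incomplete_cases(n, c(t1, t2), disjoint = TRUE),
                     enumerate_patterns(n, c(t1, t2), TRUE))
        if (max(t1, t2) <= n)
          expect_equal(count_incomplete_cases(n, c(t1, t2), disjoint = FALSE),
                       enumerate_patterns(n, c(t1, t2), FALSE))
      }
    }
  }
})

test_that("inserted missingness matches the scenario bookkeeping", {
  ds <- liver_synthetic(p = c(20, 6), seed = 1)
  sc <- liver_scenarios()
  expect_equal(nrow(insert_missingness(ds, sc$low, seed = 2)$ledger), 8L)
  expect_equal(nrow(insert_missingness(ds, sc$medium, seed = 2)$ledger), 16L)
  out <- insert_missingness(ds, sc$high, seed = 2)
  expect_equal(nrow(out$ledger), 24L)
  expect_true(all(out$ledger$table == "transcriptome"))
  expect_equal(sum(!out$dataset$tables$transcriptome$observed), 24L)

  # same seed reproduces the ledger; all-zero scenario is a no-op
  out2 <- insert_missingness(ds, sc$high, seed = 2)
  expect_identical(out$ledger, out2$ledger)
  none <- insert_missingness(ds, missingness_scenario(c(0, 0)), seed = 2)
  expect_equal(nrow(none$ledger), 0L)
  expect_identical(none$dataset$tables$transcriptome$values,
                   ds$tables$transcriptome$values)
})

test_that("disjoint scenarios never remove an individual from two tables", {
  ds <- liver_synthetic(p = c(15, 5), seed = 3)
  out <- insert_missingness(ds, missingness_scenario(c(1, 1)), seed = 9)
  expect_equal(nrow(out$ledger), 16L)
  dup <- duplicated(out$ledger[c("stratum", "individual_id")])
  expect_false(any(dup))

  # infeasible request names the stratum
  expect_error(insert_missingness(ds, missingness_scenario(c(6, 3)), seed = 1),
               "infeasible for stratum")
})

test_that("generator presets have the documented shapes", {
  liv <- liver_synthetic(p = c(30, 10), seed = 5)
  expect_length(liv$individual_ids, 64L)
  expect_equal(unname(table(liv$strata)[unique(liv$strata)]),
               rep(8L, 8L), ignore_attr = TRUE)
  expect_true(is_complete(liv))

  nci <- nci60_synthetic(p = c(25, 8), seed = 5)
  expect_length(nci$individual_ids, 60L)
  expect_equal(sort(as.integer(table(nci$strata))),
               sort(c(8L, 6L, 7L, 6L, 9L, 8L, 6L, 2L, 8L)))
})

test_that("with no effect the leading eigenvalue share sits in the pure-noise
           band", {
  share1 <- function(ds) {
    ev <- mfa(ds, d = 2)$eigenvalues
    ev[1] / sum(ev)
  }
  set.seed(42)
  null_shares <- vapply(1:20, function(s) {
    # independent pure-noise oracle assembled by hand
    ids <- sprintf("i%02d", 1:12)
    m1 <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(ids, paste0("a", 1:6)))
    m2 <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(ids, paste0("b", 1:4)))
    ds <- multiomics_set(list(omics_table(m1, "t1"), omics_table(m2, "t2")),
                         setNames(rep(c("x", "y"), each = 6), ids))
    share1(ds)
  }, 0)
  set.seed(99)
  got <- vapply(1:5, function(s)
    share1(generate_multitable(S = 2, n_per_stratum = 6, p = c(6, 4),
                               effect_size = 0, seed = s)), 0)
  lo <- mean(null_shares) - 4 * sd(null_shares)
  hi <- mean(null_shares) + 4 * sd(null_shares)
  expect_true(all(got >= lo & got <= hi))
})

test_that("a strong effect makes strata recoverable (silhouette > 0.5)", {
  ds <- generate_multitable(S = 4, n_per_stratum = 8, p = c(40, 10),
                            effect_size = 6, noise_sd = 1, seed = 11)
  sc <- mfa(ds, d = 2)$scores
  sil <- cluster::silhouette(as.integer(factor(ds$strata)), dist(sc))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})
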