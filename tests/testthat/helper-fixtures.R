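# Shared fixtures and independent oracles, built in code at test time.

# tiny two-table set: S strata of size n, optionally with missing rows
tiny_set <- function(S = 2L, n = 4L, p = c(3L, 2L), seed = 42L,
                     effect_size = 1.5) {
  generate_multitable(S = S, n_per_stratum = n, p = p,
                      effect_size = effect_size, seed = seed)
}

# drop the rows of `ids` from table `table` of a complete set
drop_rows <- function(dataset, table, ids) {
  tables <- dataset$tables
  v <- tables[[table]]$values
  v[ids, ] <- NA_real_
  tables[[table]] <- omics_table(v, tables[[table]]$name)
  multiomics_set(tables, dataset$strata)
}

# brute-force MFA oracle: explicitly build the centered/scaled/weighted
# merged matrix and eigendecompose its (population) covariance
oracle_mfa_scores <- function(dataset, d, scale = TRUE) {
  I <- length(dataset$individual_ids)
  blocks <- lapply(dataset$tables, function(tb) {
    x <- sweep(tb$values, 2L, colMeans(tb$values), "-")
    if (scale) x <- sweep(x, 2L, sqrt(colMeans(x^2)), "/")
    lambda1 <- max(eigen(crossprod(x) / I, symmetric = TRUE)$values)
    x / sqrt(lambda1)
  })
  z <- do.call(cbind, blocks)
  ev <- eigen(crossprod(z) / I, symmetric = TRUE)
  scores <- z %*% ev$vectors[, seq_len(d), drop = FALSE]
  list(scores = scores, eigenvalues = ev$values, z = z)
}

# exhaustive enumeration of all distinct hot-deck assignment maps
enumerate_assignments <- function(dataset) {
  pools <- build_donor_pools(dataset)
  slots <- list()
  for (p in pools) {
    for (r in p$recipient_ids) {
      slots[[length(slots) + 1L]] <- list(table = p$table, recipient = r,
                                          donors = p$donor_ids)
    }
  }
  if (!length(slots)) return(list(data.frame(table = character(0),
                                             recipient = character(0),
                                             donor = character(0))))
  grid <- expand.grid(lapply(slots, function(s) s$donors),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    data.frame(table = vapply(slots, `[[`, "", "table"),
               recipient = vapply(slots, `[[`, "", "recipient"),
               donor = unlist(grid[i, ]), stringsAsFactors = FALSE)
  })
}

# canonical string form of an assignment map, order-independent
canon_assignment <- function(a) {
  a <- a[order(a$table, a$recipient), ]
  paste(a$table, a$recipient, a$donor, sep = ":", collapse = "|")
}

# O(n^3) convex hull oracle: (i, j) is a hull edge iff all other points lie
# on one side of the line through them
oracle_hull_vertices <- function(points) {
  n <- nrow(points)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- points[j, ] - points[i, ]
      cr <- (points[, 1L] - points[i, 1L]) * d[2L] -
            (points[, 2L] - points[i, 2L]) * d[1L]
      if (all(cr <= 1e-12) || all(cr >= -1e-12))
        on_hull[c(i, j)] <- TRUE
    }
  }
  which(on_hull)
}

# grid-search Procrustes oracle: dense sweep over rotation angle and
# reflection, with closed-form optimal scale and translation per candidate
oracle_procrustes_residual <- function(mobile, target, step = 1e-3) {
  mc <- sweep(mobile, 2L, colMeans(mobile), "-")
  tc <- sweep(target, 2L, colMeans(target), "-")
  best <- Inf
  for (refl in c(1, -1)) {
    m <- mc
    m[, 2L] <- refl * m[, 2L]
    for (th in seq(0, 2 * pi, by = step)) {
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
      mr <- m %*% rot
      s <- sum(mr * tc) / sum(mr^2)
      best <- min(best, sum((s * mr - tc)^2))
    }
  }
  best
}
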