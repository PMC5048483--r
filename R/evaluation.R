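#' Mean-variable imputation MFA (MVI-MFA)
#'
#' Baseline: every missing row's entries are replaced by the per-variable
#' mean over the observed rows of the same table, after which a plain MFA is
#' run. On a complete dataset this is identical to [mfa()].
#'
#' @param dataset A [multiomics_set].
#' @param d Reported dimensionality.
#' @param spec A [preprocess_spec()].
#' @return An [mfa_config].
#' @export
mvi_mfa <- function(dataset, d = 2L, spec = preprocess_spec()) {
  tables <- lapply(dataset$tables, function(tb) {
    if (all(tb$observed)) return(tb)
    obs <- tb$values[tb$observed, , drop = FALSE]
    if (!nrow(obs))
      stop("table '", tb$name, "' has no observed rows to average")
    mu <- colMeans(obs)
    v <- tb$values
    v[!tb$observed, ] <- rep(mu, each = sum(!tb$observed))
    omics_table(v, tb$name)
  })
  mfa(multiomics_set(tables, dataset$strata), d = d, spec = spec)
}

# Complete a dataset by regularized iterative low-rank imputation and return
# the completed multiomics_set (internal; see iterative_mfa_impute).
iterative_impute_dataset <- function(dataset, ncp, tol = 1e-6,
                                     max_iter = 200L, spec = preprocess_spec()) {
  ncp <- as.integer(ncp)
  if (ncp < 0L) stop("`ncp` must be >= 0")
  # initialize missing rows with observed column means (raw space)
  filled <- lapply(dataset$tables, function(tb) {
    v <- tb$values
    if (!all(tb$observed)) {
      obs <- v[tb$observed, , drop = FALSE]
      if (!nrow(obs)) stop("table '", tb$name, "' has no observed rows")
      v[!tb$observed, ] <- rep(colMeans(obs), each = sum(!tb$observed))
    }
    v
  })
  miss_rows <- lapply(dataset$tables, function(tb) !tb$observed)
  if (!any(unlist(miss_rows))) {
    return(list(dataset = dataset, iterations = 0L, converged = TRUE,
                rss = numeric(0)))
  }

  # preprocessing statistics and table weights fixed at the initial fill
  centers <- scales <- weights <- vector("list", length(filled))
  z_blocks <- vector("list", length(filled))
  I <- nrow(filled[[1L]])
  for (j in seq_along(filled)) {
    x <- preprocess_values(filled[[j]], spec, dataset$tables[[j]]$name)
    centers[[j]] <- attr(x, "centers")
    scales[[j]] <- attr(x, "scales")
    l1 <- svd(x, nu = 0L, nv = 0L)$d[1L]^2 / I
    weights[[j]] <- 1 / sqrt(l1)
    z_blocks[[j]] <- x * weights[[j]]
  }
  z <- do.call(cbind, z_blocks)
  p_off <- cumsum(c(0L, vapply(z_blocks, ncol, integer(1))))
  mask <- matrix(FALSE, nrow(z), ncol(z))
  for (j in seq_along(filled))
    mask[miss_rows[[j]], (p_off[j] + 1L):p_off[j + 1L]] <- TRUE

  rss <- numeric(0)
  converged <- FALSE
  iter <- 0L
  ncp_eff <- min(ncp, nrow(z) - 1L, ncol(z))
  while (iter < max_iter) {
    iter <- iter + 1L
    if (ncp_eff == 0L) {
      fitted <- matrix(0, nrow(z), ncol(z))
    } else {
      sv <- svd(z)
      dd <- sv$d
      keep <- seq_len(ncp_eff)
      # regularization: shrink each retained singular value by the mean
      # squared magnitude of the discarded ones
      sigma2 <- if (length(dd) > ncp_eff) mean(dd[-keep]^2) else 0
      d_shrunk <- pmax((dd[keep]^2 - sigma2) / dd[keep], 0)
      fitted <- sv$u[, keep, drop = FALSE] %*%
        (d_shrunk * t(sv$v[, keep, drop = FALSE]))
    }
    rss <- c(rss, sum((z[!mask] - fitted[!mask])^2))
    old <- z[mask]
    z[mask] <- fitted[mask]
    delta <- sum((z[mask] - old)^2) / max(sum(old^2), .Machine$double.eps)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("iterative imputation did not converge in ", max_iter,
            " iterations; returning last iterate")

  tables <- dataset$tables
  for (j in seq_along(tables)) {
    cols <- (p_off[j] + 1L):p_off[j + 1L]
    raw <- sweep(sweep(z[, cols, drop = FALSE] / weights[[j]], 2L,
                       scales[[j]], "*"), 2L, centers[[j]], "+")
    v <- tables[[j]]$values
    v[miss_rows[[j]], ] <- raw[miss_rows[[j]], , drop = FALSE]
    tables[[j]] <- omics_table(v, tables[[j]]$name)
  }
  list(dataset = multiomics_set(tables, dataset$strata),
       iterations = iter, converged = converged, rss = rss)
}

#' Regularized iterative imputation MFA (RI-MFA)
#'
#' EM-style comparator: missing cells are initialized with observed column
#' means; then the weighted merged table is repeatedly fit by a rank-`ncp`
#' SVD with regularized (shrunken) singular values and the missing cells are
#' replaced by their low-rank reconstruction, until the relative change of
#' the imputed cells falls below `tol`. The completed dataset is then
#' analyzed by a plain MFA. With `ncp = 0` the reconstruction is the column
#' mean and the result equals [mvi_mfa()]; on a complete dataset the loop is
#' a no-op and the result equals [mfa()].
#'
#' @param dataset A [multiomics_set].
#' @param ncp Number of components of the low-rank reconstruction (>= 0).
#' @param d Reported dimensionality of the final MFA.
#' @param tol Relative-change convergence threshold (default 1e-6).
#' @param max_iter Iteration cap (default 200); non-convergence returns the
#'   last iterate with a warning.
#' @param spec A [preprocess_spec()].
#' @return An [mfa_config], with attributes `iterations`, `converged` and
#'   `rss` (per-iteration sum of squared residuals on observed cells).
#' @export
iterative_mfa_impute <- function(dataset, ncp = 2L, d = 2L, tol = 1e-6,
                                 max_iter = 200L, spec = preprocess_spec()) {
  fit <- iterative_impute_dataset(dataset, ncp, tol, max_iter, spec)
  config <- mfa(fit$dataset, d = d, spec = spec)
  attr(config, "iterations") <- fit$iterations
  attr(config, "converged") <- fit$converged
  attr(config, "rss") <- fit$rss
  config
}

#' Ordinary Procrustes alignment of two configurations
#'
#' Least-squares superposition of `mobile` onto `target` by translation,
#' orthogonal transformation (rotation, reflection permitted) and isotropic
#' scaling, via [vegan::procrustes()]. Used to remove arbitrary component
#' order/sign/rotation differences before configurations are compared
#' coordinate-wise.
#'
#' @param mobile,target [mfa_config]s (or score matrices) with the same
#'   individuals and dimensionality.
#' @return A list with `aligned` (an [mfa_config] holding the transformed
#'   mobile scores), `residual` (sum of squared coordinate differences after
#'   alignment), `rotation`, `scale` and `translation`.
#' @export
procrustes_align <- function(mobile, target) {
  ms <- if (is.matrix(mobile)) mobile else mobile$scores
  ts <- if (is.matrix(target)) target else target$scores
  if (!all(dim(ms) == dim(ts)))
    stop("configurations must have identical dimensions")
  pr <- vegan::procrustes(X = ts, Y = ms, scale = TRUE, symmetric = FALSE)
  # vegan returns the rotated scores in the centered frame; shift back to
  # the target's frame before residuals are taken
  aligned <- sweep(pr$Yrot, 2L, pr$xmean, "+")
  dimnames(aligned) <- dimnames(ts)
  list(aligned = new_config(aligned),
       residual = sum((aligned - ts)^2),
       rotation = pr$rotation, scale = pr$scale,
       translation = pr$translation)
}

#' RV coefficient between two configurations
#'
#' The RV coefficient of the two score matrices' cross-products; columns are
#' centered first, making the value invariant to translation, rotation,
#' reflection and positive scaling of either configuration.
#'
#' @param a,b [mfa_config]s (or score matrices) over the same individuals.
#' @return The RV coefficient in \[0, 1\].
#' @export
rv_between_configurations <- function(a, b) {
  sa <- if (is.matrix(a)) a else a$scores
  sb <- if (is.matrix(b)) b else b$scores
  if (nrow(sa) != nrow(sb))
    stop("configurations must describe the same individuals")
  sa <- sweep(sa, 2L, colMeans(sa), "-")
  sb <- sweep(sb, 2L, colMeans(sb), "-")
  rv_coefficient(tcrossprod(sa), tcrossprod(sb))
}

# pick ncp for the RI comparator given a known reference configuration
select_ncp <- function(dataset, truth, d, ncp_rule, ncp_grid, spec) {
  if (ncp_rule == "fixed" || is.null(truth)) return(max(d, 1L))
  rvs <- vapply(ncp_grid, function(ncp) {
    cf <- suppressWarnings(iterative_mfa_impute(dataset, ncp = ncp, d = d,
                                                spec = spec))
    rv_between_configurations(cf, truth)
  }, numeric(1))
  if (ncp_rule == "best") ncp_grid[which.max(rvs)] else ncp_grid[which.min(rvs)]
}

#' Benchmark MI-MFA against RI-MFA and MVI-MFA on known-truth data
#'
#' Takes a complete dataset as ground truth, repeatedly inserts missing rows
#' according to each scenario, reconstructs a configuration with each of the
#' three methods, Procrustes-aligns it to the true MFA configuration and
#' scores it with the RV coefficient (plus per-individual divergences, the
#' Euclidean distances between aligned and true coordinates, for arrow
#' plots).
#'
#' @param dataset A complete [multiomics_set] (the truth).
#' @param scenarios Named list of [missingness_scenario()]s.
#' @param replicates Random removals per scenario (default 20).
#' @param M Imputations for MI-MFA (default 30).
#' @param d Configuration dimensionality compared (default 2).
#' @param seed Master RNG seed.
#' @param methods Subset of `c("MI", "RI", "MVI")`.
#' @param ncp_rule How to pick `ncp` for RI-MFA: `"best"` (maximize RV to
#'   the known truth, over `ncp_grid`), `"worst"` (minimize it) or
#'   `"fixed"` (`ncp = d`).
#' @param ncp_grid Candidate `ncp` values for the best/worst rules.
#' @param spec A [preprocess_spec()].
#' @return An object of class `mimfa_benchmark`: `results` (data frame with
#'   one row per scenario x replicate x method and its RV), `summary`
#'   (mean/sd RV per scenario x method) and `reports` (list of per-run
#'   comparison reports with aligned scores and divergences).
#' @export
benchmark <- function(dataset, scenarios, replicates = 20L, M = 30L, d = 2L,
                      seed = 1L, methods = c("MI", "RI", "MVI"),
                      ncp_rule = c("best", "worst", "fixed"),
                      ncp_grid = 0:5, spec = preprocess_spec()) {
  if (!is_complete(dataset))
    stop("`dataset` must be complete: it serves as the ground truth")
  ncp_rule <- match.arg(ncp_rule)
  methods <- match.arg(methods, c("MI", "RI", "MVI"), several.ok = TRUE)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  truth <- mfa(dataset, d = d, spec = spec)

  results <- list()
  reports <- list()
  run <- 0L
  for (sc in seq_along(scenarios)) {
    for (rep_i in seq_len(as.integer(replicates))) {
      run <- run + 1L
      seed_r <- derive_seed(seed, 1000L * sc + rep_i)
      incomplete <- insert_missingness(dataset, scenarios[[sc]],
                                       seed = seed_r)$dataset
      for (method in methods) {
        config <- switch(
          method,
          MI = {
            res <- suppressMessages(
              run_mi_mfa(incomplete, M = M, d = d,
                         seed = derive_seed(seed_r, 1L), spec = spec))
            res$compromise$compromise
          },
          RI = {
            ncp <- select_ncp(incomplete, truth, d, ncp_rule, ncp_grid, spec)
            suppressWarnings(iterative_mfa_impute(incomplete, ncp = ncp,
                                                  d = d, spec = spec))
          },
          MVI = mvi_mfa(incomplete, d = d, spec = spec)
        )
        al <- procrustes_align(config, truth)
        rv <- rv_between_configurations(config, truth)
        div <- sqrt(rowSums((al$aligned$scores - truth$scores)^2))
        results[[length(results) + 1L]] <- data.frame(
          scenario = names(scenarios)[sc], replicate = rep_i,
          method = method, rv = rv)
        reports[[length(reports) + 1L]] <- list(
          scenario = names(scenarios)[sc], replicate = rep_i,
          method = method, rv_to_true = rv,
          aligned_scores = al$aligned$scores,
          true_scores = truth$scores, divergences = div)
      }
    }
  }
  results <- do.call(rbind, results)
  summary <- do.call(rbind, lapply(split(results, results[c("scenario", "method")],
                                         drop = TRUE),
    function(g) data.frame(scenario = g$scenario[1L], method = g$method[1L],
                           mean_rv = mean(g$rv), sd_rv = stats::sd(g$rv),
                           n = nrow(g))))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, reports = reports,
                 truth = truth),
            class = "mimfa_benchmark")
}

#' @export
print.mimfa_benchmark <- function(x, ...) {
  cat("mimfa_benchmark summary (mean RV to true configuration):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
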