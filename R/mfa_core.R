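#' Preprocessing specification for MFA
#'
#' Variables are always centered (a PCA requirement); by default they are also
#' scaled to unit variance within each table, matching the behaviour of
#' standard MFA implementations for quantitative variable groups. Variances
#' use the population convention (divisor I), consistent with uniform row
#' weights 1/I in the PCA.
#'
#' @param center Must be `TRUE`.
#' @param scale_unit_variance Scale every variable to unit variance
#'   (default `TRUE`).
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(center = TRUE, scale_unit_variance = TRUE) {
  if (!isTRUE(center)) stop("centering is required for MFA")
  structure(list(center = TRUE, scale_unit_variance = isTRUE(scale_unit_variance)),
            class = "preprocess_spec")
}

# Center (and optionally unit-variance scale, population divisor) the columns
# of a fully observed numeric matrix. Errors name any zero-variance column
# when scaling is requested.
preprocess_values <- function(values, spec, table_name = "table") {
  ctr <- colMeans(values)
  x <- sweep(values, 2L, ctr, "-")
  if (spec$scale_unit_variance) {
    sds <- sqrt(colMeans(x^2))
    bad <- colnames(values)[sds <= .Machine$double.eps * 1e3]
    if (length(bad))
      stop("zero-variance variable(s) in table '", table_name,
           "' cannot be scaled: ", paste(bad, collapse = ", "))
    x <- sweep(x, 2L, sds, "/")
  } else {
    sds <- rep(1, ncol(values))
  }
  attr(x, "centers") <- ctr
  attr(x, "scales") <- sds
  x
}

#' First eigenvalue of one table's PCA
#'
#' Returns the largest eigenvalue of the (population) variance-covariance
#' matrix of the preprocessed table. In MFA each variable of table j is
#' subsequently weighted by the inverse square root of this value, so that no
#' single table can dominate the first global dimension.
#'
#' @param table An [omics_table] with no missing rows.
#' @param spec A [preprocess_spec()].
#' @return The largest eigenvalue (positive scalar).
#' @export
table_first_eigenvalue <- function(table, spec = preprocess_spec()) {
  if (!inherits(table, "omics_table")) stop("`table` must be an omics_table")
  if (!all(table$observed))
    stop("table '", table$name, "' has missing rows; MFA requires complete data")
  if (nrow(table$values) < 2L) stop("need at least 2 individuals")
  x <- preprocess_values(table$values, spec, table$name)
  d1 <- svd(x, nu = 0L, nv = 0L)$d[1L]
  d1^2 / nrow(x)
}

# Deterministic sign convention: flip each component so the loading with the
# largest absolute value is positive; ties broken by earliest column index.
fix_signs <- function(u, v) {
  for (k in seq_len(ncol(v))) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  list(u = u, v = v)
}

#' Multiple factor analysis of a complete multi-table dataset
#'
#' Each table is centered (and scaled, per `spec`), its variables are weighted
#' by the inverse square root of the table's first PCA eigenvalue, and a
#' global PCA (SVD with uniform row weights 1/I) is run on the column-wise
#' concatenation. Scores are the principal components of that weighted merged
#' table; eigenvalues are reported on the covariance scale (singular value
#' squared over I).
#'
#' @param dataset A complete [multiomics_set].
#' @param d Number of dimensions to report; must not exceed
#'   `min(I - 1, total number of variables)`. If `d` exceeds the numerical
#'   rank, zero-eigenvalue components pad the result with a warning.
#' @param spec A [preprocess_spec()].
#' @return An object of class `mfa_config` with fields `scores`
#'   (I x d matrix), `eigenvalues` (full spectrum, nonincreasing),
#'   `table_weights` (per-table first eigenvalue and weight) and
#'   `individual_ids`.
#' @export
mfa <- function(dataset, d = 2L, spec = preprocess_spec()) {
  if (!inherits(dataset, "multiomics_set"))
    stop("`dataset` must be a multiomics_set")
  if (!is_complete(dataset))
    stop("dataset contains missing rows; impute first ",
         "(e.g. multiple_imputation() / run_mi_mfa())")
  ids <- dataset$individual_ids
  I <- length(ids)
  p_total <- sum(vapply(dataset$tables, function(tb) length(tb$variable_ids),
                        integer(1)))
  d <- as.integer(d)
  if (d < 1L || d > min(I - 1L, p_total))
    stop("`d` must be between 1 and min(I - 1, total variables) = ",
         min(I - 1L, p_total))

  blocks <- vector("list", length(dataset$tables))
  tw <- data.frame(table = names(dataset$tables), lambda1 = NA_real_,
                   weight = NA_real_)
  for (j in seq_along(dataset$tables)) {
    tb <- dataset$tables[[j]]
    x <- preprocess_values(tb$values, spec, tb$name)
    l1 <- svd(x, nu = 0L, nv = 0L)$d[1L]^2 / I
    tw$lambda1[j] <- l1
    tw$weight[j] <- 1 / sqrt(l1)
    blocks[[j]] <- x / sqrt(l1)
  }
  z <- do.call(cbind, blocks)

  sv <- svd(z)
  eig <- sv$d^2 / I
  tol <- max(dim(z)) * .Machine$double.eps * sv$d[1L]
  r <- sum(sv$d > tol)
  fixed <- fix_signs(sv$u, sv$v)
  scores <- fixed$u %*% diag(sv$d, nrow = length(sv$d))

  k <- min(d, r)
  out <- matrix(0, I, d,
                dimnames = list(ids, paste0("dim", seq_len(d))))
  out[, seq_len(k)] <- scores[, seq_len(k)]
  if (d > r)
    warning("requested d = ", d, " exceeds numerical rank ", r,
            "; padding with zero-eigenvalue components")
  eig[eig < 0 | seq_along(eig) > r] <- 0

  structure(
    list(scores = out, eigenvalues = eig, table_weights = tw,
         individual_ids = ids),
    class = "mfa_config"
  )
}

# Internal: wrap an existing score matrix as a configuration object so that
# compromise coordinates can flow through the same comparison machinery.
new_config <- function(scores, eigenvalues = NULL, table_weights = NULL) {
  structure(
    list(scores = scores,
         eigenvalues = eigenvalues %||% (colSums(scores^2) / nrow(scores)),
         table_weights = table_weights,
         individual_ids = rownames(scores)),
    class = "mfa_config"
  )
}

#' @export
print.mfa_config <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("mfa_config: %d individuals x %d dimensions\n",
              nrow(x$scores), ncol(x$scores)))
  shown <- utils::head(ev, ncol(x$scores))
  cat("  eigenvalues:", paste(sprintf("%.4g", shown), collapse = ", "),
      if (length(ev) > length(shown)) "..." else "", "\n")
  invisible(x)
}
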