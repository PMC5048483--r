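#' Cross-product matrix of a configuration
#'
#' The I x I matrix \eqn{W = F F^T} of inner products between individuals'
#' score vectors. Working with cross-products rather than the scores
#' themselves makes the comparison of configurations invariant to rotation
#' and reflection.
#'
#' @param config An [mfa_config] (or any object with a numeric `scores`
#'   matrix), or a plain numeric matrix of scores.
#' @return A symmetric positive semidefinite matrix.
#' @export
cross_product <- function(config) {
  scores <- if (is.matrix(config)) config else config$scores
  if (!is.numeric(scores)) stop("configuration scores must be numeric")
  tcrossprod(scores)
}

#' RV coefficient between two cross-product matrices
#'
#' The cosine between two configurations represented by their cross-product
#' matrices:
#' \deqn{RV = trace(W_j^T W_k) / \sqrt{trace(W_j^T W_j) trace(W_k^T W_k)}}
#' For positive semidefinite inputs the value lies in \[0, 1\]; it is
#' symmetric in its arguments and invariant to positive scaling of either.
#'
#' @param w_j,w_k Square matrices of identical size; neither may be all zero.
#' @return The RV coefficient.
#' @export
rv_coefficient <- function(w_j, w_k) {
  if (!all(dim(w_j) == dim(w_k)))
    stop("cross-product matrices must have identical dimensions")
  njj <- sum(w_j * w_j)
  nkk <- sum(w_k * w_k)
  if (njj == 0 || nkk == 0)
    stop("RV coefficient undefined for an all-zero matrix")
  sum(w_j * w_k) / sqrt(njj * nkk)
}

#' STATIS compromise of several configurations
#'
#' Combines M configurations of the same individuals into one consensus.
#' The inter-configuration RV matrix R is built from the cross-products
#' \eqn{W_n = F_n F_n^T}; the weights \eqn{\alpha_n} are the leading
#' eigenvector of R (sign-flipped so its sum is positive, then normalized to
#' sum to 1); the compromise is the eigendecomposition of
#' \eqn{W_c = \sum_n \alpha_n W_n}, with scores in principal coordinates
#' (eigenvector times square-root eigenvalue). Each input configuration is
#' also projected onto the compromise axes (`trajectories`,
#' \eqn{W_n U_c \Lambda_c^{-1/2}}), giving M points per individual.
#'
#' @param configs List of M [mfa_config] objects sharing individual ids and
#'   dimensionality.
#' @param d Number of compromise dimensions to report.
#' @return An object of class `statis_result` with fields `rv_matrix` (M x M),
#'   `alpha` (length M, sums to 1), `compromise` (an [mfa_config] whose scores
#'   are the compromise coordinates), `compromise_eigenvalues` (full
#'   spectrum) and `trajectories` (list of M I x d matrices).
#' @export
statis_compromise <- function(configs, d = 2L) {
  M <- length(configs)
  if (M < 1L) stop("need at least one configuration")
  ids <- configs[[1L]]$individual_ids %||% rownames(configs[[1L]]$scores)
  dims <- vapply(configs, function(cf) ncol(cf$scores), integer(1))
  if (length(unique(dims)) != 1L)
    stop("all configurations must have the same number of dimensions")
  same_ids <- vapply(configs, function(cf)
    identical(cf$individual_ids %||% rownames(cf$scores), ids), logical(1))
  if (!all(same_ids))
    stop("all configurations must share the same ordered individual ids")
  I <- nrow(configs[[1L]]$scores)
  d <- as.integer(d)
  if (d < 1L || d > I) stop("`d` must be between 1 and I")

  w <- lapply(configs, cross_product)
  r <- diag(1, M)
  if (M > 1L) {
    for (j in seq_len(M - 1L)) {
      for (k in (j + 1L):M) {
        r[j, k] <- r[k, j] <- rv_coefficient(w[[j]], w[[k]])
      }
    }
  }
  alpha <- eigen(r, symmetric = TRUE)$vectors[, 1L]
  if (sum(alpha) < 0) alpha <- -alpha
  alpha <- alpha / sum(alpha)

  w_c <- Reduce(`+`, Map(`*`, w, alpha))
  ec <- eigen(w_c, symmetric = TRUE)
  ev <- pmax(ec$values, 0)
  u <- ec$vectors
  for (k in seq_len(ncol(u))) {
    j <- which.max(abs(u[, k]))
    if (u[j, k] < 0) u[, k] <- -u[, k]
  }
  tol <- I * .Machine$double.eps * max(ev, 0)
  r_c <- sum(ev > tol)
  k_use <- min(d, r_c)
  if (d > r_c)
    warning("requested d = ", d, " exceeds compromise rank ", r_c,
            "; padding with zero-eigenvalue components")

  scores <- matrix(0, I, d, dimnames = list(ids, paste0("dim", seq_len(d))))
  scores[, seq_len(k_use)] <- u[, seq_len(k_use), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k_use)]), nrow = k_use)

  proj <- matrix(0, I, d)
  proj_basis <- u[, seq_len(k_use), drop = FALSE] %*%
    diag(1 / sqrt(ev[seq_len(k_use)]), nrow = k_use)
  trajectories <- lapply(w, function(wn) {
    tr <- matrix(0, I, d, dimnames = list(ids, paste0("dim", seq_len(d))))
    tr[, seq_len(k_use)] <- wn %*% proj_basis
    tr
  })

  structure(
    list(rv_matrix = r, alpha = alpha,
         compromise = new_config(scores, eigenvalues = ev),
         compromise_eigenvalues = ev,
         trajectories = trajectories),
    class = "statis_result"
  )
}

#' @export
print.statis_result <- function(x, ...) {
  cat(sprintf("statis_result: compromise of %d configurations (%d individuals x %d dims)\n",
              length(x$trajectories), nrow(x$compromise$scores),
              ncol(x$compromise$scores)))
  cat("  alpha:", paste(sprintf("%.3f", utils::head(x$alpha, 8)),
                        collapse = ", "),
      if (length(x$alpha) > 8) "..." else "", "\n")
  invisible(x)
}

#' Export a STATIS result to delimited files
#'
#' Writes the compromise configuration, the weights and the RV matrix.
#'
#' @param result A [statis_compromise()] result.
#' @param dir Output directory.
#' @return Invisibly, the vector of paths written.
#' @export
write_statis <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "compromise.csv")
  write_configuration(result$compromise, p1)
  p2 <- file.path(dir, "alpha.csv")
  utils::write.table(
    data.frame(configuration = seq_along(result$alpha), alpha = result$alpha),
    p2, sep = ",", row.names = FALSE, quote = FALSE)
  p3 <- file.path(dir, "rv_matrix.csv")
  utils::write.table(result$rv_matrix, p3, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(p1, p2, p3))
}
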