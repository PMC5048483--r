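#' Run the full multiple-imputation MFA pipeline
#'
#' Steps: (1) stratified multiple hot-deck imputation giving M pairwise
#' distinct completions; (2) MFA on each completion; (3) STATIS combination
#' of the M configurations into a compromise. Per-imputation MFA
#' configurations are computed at full rank and STATIS consumes their full
#' cross-products (equivalently, the weighted-data Gram matrices), so the
#' compromise does not depend on `d`: `d` only selects how many compromise
#' dimensions are reported, and solutions are nested across `d`.
#'
#' On a complete dataset only one completion exists, so `M` is forced to 1
#' and the compromise coincides with the plain MFA configuration.
#'
#' @param dataset A [multiomics_set], possibly with missing rows.
#' @param M Number of imputations (default 30).
#' @param d Reported compromise dimensionality (default 2; all standard
#'   comparisons are two-dimensional).
#' @param seed Master RNG seed.
#' @param spec A [preprocess_spec()].
#' @return An object of class `mi_mfa` with fields `compromise` (a
#'   [statis_compromise()] result), `per_imputation_configs` (M full-rank
#'   [mfa_config]s), `imputations` (the [multiple_imputation()] result), `d`
#'   and `parameters`.
#' @export
run_mi_mfa <- function(dataset, M = 30L, d = 2L, seed = 1L,
                       spec = preprocess_spec()) {
  if (!inherits(dataset, "multiomics_set"))
    stop("`dataset` must be a multiomics_set")
  I <- length(dataset$individual_ids)
  p_total <- sum(vapply(dataset$tables, function(tb) length(tb$variable_ids),
                        integer(1)))
  d <- as.integer(d)
  if (d < 1L || d > min(I - 1L, p_total))
    stop("`d` must be between 1 and min(I - 1, total variables) = ",
         min(I - 1L, p_total))
  M <- as.integer(M)
  if (is_complete(dataset) && M > 1L) {
    message("dataset is complete: only one completion exists, forcing M = 1")
    M <- 1L
  }
  imputations <- multiple_imputation(dataset, M, seed)
  d_full <- min(I - 1L, p_total)
  configs <- muffle_rank_warnings(
    lapply(imputations$completions, mfa, d = d_full, spec = spec))
  compromise <- statis_compromise(configs, d = d)
  structure(
    list(compromise = compromise, per_imputation_configs = configs,
         imputations = imputations, d = d,
         parameters = list(M = M, d = d, seed = seed, spec = spec)),
    class = "mi_mfa"
  )
}

#' @export
print.mi_mfa <- function(x, ...) {
  cat(sprintf("mi_mfa: M = %d imputations, compromise %d individuals x %d dims\n",
              x$parameters$M, nrow(x$compromise$compromise$scores), x$d))
  invisible(x)
}

# ids of individuals that were hot-deck recipients anywhere
imputed_individuals <- function(result) {
  unique(unlist(lapply(result$imputations$assignments,
                       function(a) a$recipient)))
}

#' Stability curve for choosing the number of imputations
#'
#' For each of `N` replicates, nested imputation collections are grown across
#' the requested `M_levels` (the collection at one level is a subset of the
#' next), a compromise configuration is computed at every level, and the RV
#' coefficient between compromises at consecutive levels measures stability.
#' The curve of per-level means (and standard deviations) across replicates
#' indicates how many imputations are needed; convergence is declared at the
#' first level where the difference between two successive mean RVs drops
#' below `tol`.
#'
#' When the total number of possible completions is small
#' (`M_total <= 50`) the procedure short-circuits and recommends using all
#' of them.
#'
#' @param dataset A [multiomics_set] with missing rows.
#' @param M_levels Strictly increasing imputation counts; the largest must
#'   not exceed `M_total`.
#' @param N Number of replicate collections per level (>= 2).
#' @param seed Master RNG seed.
#' @param tol Convergence threshold on successive mean RV differences
#'   (default 0.01, i.e. two-decimal stability).
#' @param d Compromise dimensionality used for the comparisons.
#' @param spec A [preprocess_spec()].
#' @return An object of class `stability_curve` with fields `M_levels`,
#'   `mean_r`/`sd_r` (per level, `NA` for the first level, which has no
#'   predecessor), `N`, `converged_at` (M level, or `NA`), `recommended_M`
#'   and `short_circuit`.
#' @export
choose_num_imputations <- function(dataset, M_levels = c(10L, 20L, 30L),
                                   N = 5L, seed = 1L, tol = 0.01, d = 2L,
                                   spec = preprocess_spec()) {
  M_levels <- as.integer(M_levels)
  if (any(diff(M_levels) <= 0L)) stop("`M_levels` must be strictly increasing")
  m_total <- count_total_imputations(dataset)

  if (is_complete(dataset)) {
    # every completion equals the data, every compromise is the plain MFA:
    # the curve is identically 1 and converged from the start
    return(structure(
      list(M_levels = M_levels,
           mean_r = c(NA_real_, rep(1, length(M_levels) - 1L)),
           sd_r = c(NA_real_, rep(0, length(M_levels) - 1L)),
           N = N, converged_at = M_levels[1L], recommended_M = 1L,
           short_circuit = TRUE),
      class = "stability_curve"))
  }
  if (m_total <= 50) {
    message("M_total = ", m_total, " <= 50: use all possible imputations")
    return(structure(
      list(M_levels = M_levels, mean_r = rep(NA_real_, length(M_levels)),
           sd_r = rep(NA_real_, length(M_levels)), N = N,
           converged_at = NA_integer_, recommended_M = as.integer(m_total),
           short_circuit = TRUE),
      class = "stability_curve"))
  }
  if (max(M_levels) > m_total)
    stop("max(M_levels) = ", max(M_levels), " exceeds M_total = ",
         format(m_total, big.mark = ","))
  N <- as.integer(N)
  if (N < 2L) stop("`N` must be at least 2")

  L <- length(M_levels)
  r_mat <- matrix(NA_real_, N, L)
  for (n in seq_len(N)) {
    # one nested draw per replicate: level l uses the first M_l completions
    imp <- multiple_imputation(dataset, max(M_levels), derive_seed(seed, n))
    I <- length(dataset$individual_ids)
    p_total <- sum(vapply(dataset$tables,
                          function(tb) length(tb$variable_ids), integer(1)))
    configs <- muffle_rank_warnings(
      lapply(imp$completions, mfa, d = min(I - 1L, p_total), spec = spec))
    prev <- NULL
    for (l in seq_len(L)) {
      comp <- statis_compromise(configs[seq_len(M_levels[l])], d = d)
      cur <- comp$compromise$scores
      if (!is.null(prev))
        r_mat[n, l] <- rv_coefficient(cross_product(cur), cross_product(prev))
      prev <- cur
    }
  }
  mean_r <- colMeans(r_mat)
  sd_r <- apply(r_mat, 2L, stats::sd)
  converged_at <- NA_integer_
  if (L >= 3L) {
    diffs <- abs(diff(mean_r[-1L]))
    hit <- which(diffs < tol)
    if (length(hit)) converged_at <- M_levels[hit[1L] + 2L]
  }
  structure(
    list(M_levels = M_levels, mean_r = mean_r, sd_r = sd_r, N = N,
         converged_at = converged_at,
         recommended_M = if (is.na(converged_at)) max(M_levels) else converged_at,
         short_circuit = FALSE),
    class = "stability_curve"
  )
}

#' @export
print.stability_curve <- function(x, ...) {
  cat("stability_curve (N =", x$N, "replicates)\n")
  print(data.frame(M = x$M_levels, mean_r = x$mean_r, sd_r = x$sd_r),
        row.names = FALSE)
  cat("recommended M:", x$recommended_M,
      if (x$short_circuit) "(short-circuit)" else "", "\n")
  invisible(x)
}
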