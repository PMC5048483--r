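#' Build stratified donor pools for missing rows
#'
#' For every (table, stratum) pair containing at least one recipient (an
#' individual whose row is missing in that table), the donor pool is the set
#' of individuals of the same stratum whose row is observed in the same
#' table. Recipients within one stratum share the same pool. A recipient
#' whose pool is empty (stratum fully missing in a table) is an error.
#'
#' @param dataset A [multiomics_set].
#' @return A list of `donor_pool` objects with fields `table`, `stratum`,
#'   `donor_ids` and `recipient_ids`; empty list when the dataset is complete.
#' @export
build_donor_pools <- function(dataset) {
  if (!inherits(dataset, "multiomics_set"))
    stop("`dataset` must be a multiomics_set")
  pools <- list()
  for (tb in dataset$tables) {
    miss_ids <- tb$individual_ids[!tb$observed]
    if (!length(miss_ids)) next
    for (s in unique(dataset$strata[miss_ids])) {
      members <- names(dataset$strata)[dataset$strata == s]
      recips <- intersect(members, miss_ids)
      donors <- members[tb$observed[members]]
      if (!length(donors))
        stop("empty donor pool: table '", tb$name, "', stratum '", s,
             "' has recipients but no observed donors")
      pools[[length(pools) + 1L]] <- structure(
        list(table = tb$name, stratum = s, donor_ids = donors,
             recipient_ids = recips),
        class = "donor_pool")
    }
  }
  pools
}

#' Total number of distinct hot-deck completions
#'
#' Each recipient independently receives one donor drawn from its
#' (table, stratum) pool, so the number of distinct single-completion
#' assignment maps is the product over all recipients of their pool sizes.
#' A complete dataset yields 1 (the empty product). Counts beyond 2^53 are
#' subject to double-precision rounding.
#'
#' @param dataset A [multiomics_set].
#' @return The count `M_total` as a double.
#' @export
count_total_imputations <- function(dataset) {
  pools <- build_donor_pools(dataset)
  if (!length(pools)) return(1)
  prod(vapply(pools, function(p)
    length(p$donor_ids)^length(p$recipient_ids), numeric(1)))
}

# Draw one assignment map under the current RNG state: for each recipient, a
# donor sampled with replacement from its pool. Deterministic iteration order
# (tables, then canonical individual order) keeps seeded runs reproducible.
draw_assignment <- function(pools) {
  if (!length(pools))
    return(data.frame(table = character(0), recipient = character(0),
                      donor = character(0)))
  rows <- lapply(pools, function(p) {
    data.frame(table = p$table,
               recipient = p$recipient_ids,
               donor = p$donor_ids[sample.int(length(p$donor_ids),
                                              length(p$recipient_ids),
                                              replace = TRUE)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Apply an assignment map: copy each donor row verbatim into the recipient
# row of the same table.
apply_assignment <- function(dataset, assignment) {
  tables <- dataset$tables
  if (nrow(assignment)) {
    for (i in seq_len(nrow(assignment))) {
      tb <- tables[[assignment$table[i]]]
      tb$values[assignment$recipient[i], ] <- tb$values[assignment$donor[i], ]
      tb$observed[assignment$recipient[i]] <- TRUE
      tables[[assignment$table[i]]] <- tb
    }
  }
  multiomics_set(tables, dataset$strata)
}

#' Single hot-deck completion
#'
#' Replaces every missing row by a verbatim copy of a randomly drawn donor
#' row from the same (table, stratum) pool, using the current RNG state.
#' Observed entries are untouched. A complete dataset is returned unchanged
#' with an empty assignment.
#'
#' @param dataset A [multiomics_set].
#' @param pools Donor pools, defaulting to [build_donor_pools()].
#' @return A list with `dataset` (complete [multiomics_set]) and `assignment`
#'   (data frame with columns `table`, `recipient`, `donor`).
#' @export
impute_once <- function(dataset, pools = build_donor_pools(dataset)) {
  assignment <- if (length(pools)) draw_assignment(pools) else
    data.frame(table = character(0), recipient = character(0),
               donor = character(0))
  list(dataset = apply_assignment(dataset, assignment),
       assignment = assignment)
}

assignment_key <- function(a) paste(a$table, a$recipient, a$donor,
                                    sep = "\r", collapse = "\n")

#' Multiple hot-deck imputation
#'
#' Draws `M` pairwise-distinct assignment maps (duplicates are redrawn, with
#' a retry cap of `100 * M`) and materializes the corresponding completions.
#' All completions agree exactly on the originally observed entries and
#' differ only in the imputed rows. Sub-seeds are derived deterministically
#' from `seed` per draw attempt, so for a fixed dataset and seed the first
#' m completions do not depend on `M` (collections grown by increasing `M`
#' are nested).
#'
#' @param dataset A [multiomics_set] (may be complete, in which case only
#'   `M = 1` is possible).
#' @param M Number of imputed datasets; must not exceed
#'   [count_total_imputations()].
#' @param seed Master RNG seed.
#' @return An object of class `imputation_set` with fields `completions`
#'   (list of M complete [multiomics_set]s), `assignments` (list of M data
#'   frames), `M` and `seed`.
#' @export
multiple_imputation <- function(dataset, M, seed = 1L) {
  M <- as.integer(M)
  if (M < 1L) stop("`M` must be at least 1")
  m_total <- count_total_imputations(dataset)
  if (M > m_total)
    stop("M = ", M, " exceeds the number of distinct completions M_total = ",
         format(m_total, big.mark = ","))
  pools <- build_donor_pools(dataset)

  assignments <- list()
  keys <- character(0)
  attempt <- 0L
  while (length(assignments) < M) {
    attempt <- attempt + 1L
    if (attempt > 100L * M)
      stop("could not find ", M, " distinct assignment maps after ",
           attempt - 1L, " draws; choose a smaller M (M_total = ",
           format(m_total, big.mark = ","), ")")
    a <- with_preserved_seed(derive_seed(seed, attempt),
                             if (length(pools)) draw_assignment(pools) else
                               draw_assignment(list()))
    k <- assignment_key(a)
    if (k %in% keys) next
    keys <- c(keys, k)
    assignments[[length(assignments) + 1L]] <- a
  }
  completions <- lapply(assignments, function(a) apply_assignment(dataset, a))
  structure(list(completions = completions, assignments = assignments,
                 M = M, seed = seed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("imputation_set: M = %d completions (seed %s), %d imputed rows each\n",
              x$M, format(x$seed), nrow(x$assignments[[1]])))
  invisible(x)
}

#' Serialize assignment maps to JSON
#'
#' Writes one record per imputed row per completion
#' (`completion`, `table`, `recipient`, `donor`) for audit.
#'
#' @param imputations An [multiple_imputation()] result.
#' @param path Output JSON path.
#' @export
write_assignments <- function(imputations, path) {
  recs <- do.call(rbind, lapply(seq_along(imputations$assignments), function(m) {
    a <- imputations$assignments[[m]]
    if (!nrow(a)) return(NULL)
    cbind(completion = m, a)
  }))
  jsonlite::write_json(recs %||% list(), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
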