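#' Generate a stratified multi-table dataset with known structure
#'
#' Each table is stratum-mean signal plus Gaussian noise: every stratum
#' carries its own latent factor, shared across tables, with sparse random
#' loadings on a subset of each table's variables. A measurement is
#' `effect_size` times the stratum's loading on that variable plus
#' independent Gaussian noise. With `effect_size` well above `noise_sd` the
#' strata are recoverable from the leading MFA dimensions; with
#' `effect_size = 0` the data are pure noise.
#'
#' @param S Number of strata (>= 2).
#' @param n_per_stratum Individuals per stratum: scalar or length-S vector
#'   (all >= 2).
#' @param p Per-table variable counts (length J, all >= 1).
#' @param effect_size Magnitude of the stratum-separation signal (default 2).
#' @param noise_sd Residual standard deviation (default 1).
#' @param prop_informative Fraction of each table's variables loading on the
#'   stratum factors (default 0.5, at least one variable).
#' @param table_names Optional table labels.
#' @param stratum_names Optional stratum labels.
#' @param seed RNG seed.
#' @return A complete [multiomics_set].
#' @export
generate_multitable <- function(S, n_per_stratum, p, effect_size = 2,
                                noise_sd = 1, prop_informative = 0.5,
                                table_names = NULL,
                                stratum_names = NULL, seed = 1L) {
  S <- as.integer(S)
  if (S < 2L) stop("need at least 2 strata")
  n_per_stratum <- rep_len(as.integer(n_per_stratum), S)
  if (any(n_per_stratum < 2L)) stop("every stratum needs at least 2 individuals")
  p <- as.integer(p)
  if (any(p < 1L)) stop("every table needs at least 1 variable")
  if (is.null(stratum_names)) stratum_names <- paste0("s", seq_len(S))
  if (is.null(table_names)) table_names <- paste0("table", seq_along(p))

  I <- sum(n_per_stratum)
  ids <- sprintf("ind%03d", seq_len(I))
  strata <- stats::setNames(rep(stratum_names, times = n_per_stratum), ids)

  with_preserved_seed(seed, {
    tables <- vector("list", length(p))
    for (j in seq_along(p)) {
      n_inf <- max(1L, round(prop_informative * p[j]))
      # per-stratum loading signatures, sparse over the variables
      a <- matrix(0, S, p[j], dimnames = list(stratum_names, NULL))
      a[, seq_len(n_inf)] <- stats::rnorm(S * n_inf)
      signal <- effect_size * a[strata, , drop = FALSE]
      x <- signal + matrix(stats::rnorm(I * p[j], sd = noise_sd), I, p[j])
      dimnames(x) <- list(ids, sprintf("%s_v%04d", table_names[j], seq_len(p[j])))
      tables[[j]] <- omics_table(x, table_names[j])
    }
    multiomics_set(tables, strata)
  })
}

#' Liver-toxicity-shaped synthetic dataset
#'
#' 64 individuals in 8 balanced strata of 8 (mirroring a 4 time x 2 dose
#' design), with one wide expression-like table and one narrow clinical-like
#' table (300 and 10 variables by default, the wide table scaled down from
#' thousands of transcripts for desk-scale computation).
#'
#' @param p Per-table variable counts, default `c(300, 10)`.
#' @param seed RNG seed.
#' @param ... Passed to [generate_multitable()].
#' @return A complete [multiomics_set].
#' @export
liver_synthetic <- function(p = c(300L, 10L), seed = 1L, ...) {
  generate_multitable(S = 8L, n_per_stratum = 8L, p = p,
                      table_names = c("transcriptome", "clinical"),
                      stratum_names = c("low6h", "low18h", "low24h", "low48h",
                                        "high6h", "high18h", "high24h", "high48h"),
                      seed = seed, ...)
}

#' NCI-60-shaped synthetic dataset
#'
#' 60 individuals in 9 unequal strata matching the cancer-cell-line panel
#' sizes (breast 8, CNS 6, colon 7, leukemia 6, lung 9, melanoma 8,
#' ovarian 6, prostate 2, renal 8), with transcriptome-like and
#' proteome-like tables (150 and 40 variables by default, scaled down).
#'
#' @param p Per-table variable counts, default `c(150, 40)`.
#' @param seed RNG seed.
#' @param ... Passed to [generate_multitable()].
#' @return A complete [multiomics_set].
#' @export
nci60_synthetic <- function(p = c(150L, 40L), seed = 1L, ...) {
  sizes <- c(breast = 8L, cns = 6L, colon = 7L, leukemia = 6L, lung = 9L,
             melanoma = 8L, ovarian = 6L, prostate = 2L, renal = 8L)
  generate_multitable(S = length(sizes), n_per_stratum = sizes,
                      p = p, table_names = c("transcriptome", "proteome"),
                      stratum_names = names(sizes), seed = seed, ...)
}

#' Define a missing-row scenario
#'
#' Specifies how many rows to remove per (stratum, table). When `disjoint`
#' is `TRUE` (the default) an individual is removed from at most one table
#' within its stratum, which is the reading under which the standard
#' per-stratum case counts (see [count_incomplete_cases()]) hold.
#'
#' @param rows_removed Either a numeric vector of length J (rows removed per
#'   targeted stratum in each table) or an S x J matrix with stratum row
#'   names for per-stratum counts.
#' @param strata `"all"` or a character vector naming the targeted strata
#'   (ignored when `rows_removed` is a matrix, whose row names govern).
#' @param disjoint Logical, see above.
#' @return An object of class `missingness_scenario`.
#' @export
missingness_scenario <- function(rows_removed, strata = "all",
                                 disjoint = TRUE) {
  if (is.matrix(rows_removed)) {
    if (is.null(rownames(rows_removed)))
      stop("matrix `rows_removed` needs stratum row names")
  } else {
    rows_removed <- as.numeric(rows_removed)
  }
  if (any(rows_removed < 0)) stop("removal counts must be >= 0")
  structure(list(rows_removed = rows_removed, strata = strata,
                 disjoint = isTRUE(disjoint)),
            class = "missingness_scenario")
}

# expand a scenario to an S x J count matrix for a given dataset
scenario_matrix <- function(scenario, dataset) {
  strata_names <- unique(dataset$strata)
  J <- length(dataset$tables)
  if (is.matrix(scenario$rows_removed)) {
    m <- matrix(0, length(strata_names), J,
                dimnames = list(strata_names, names(dataset$tables)))
    src <- scenario$rows_removed
    unknown <- setdiff(rownames(src), strata_names)
    if (length(unknown))
      stop("scenario names unknown strata: ", paste(unknown, collapse = ", "))
    if (ncol(src) != J)
      stop("scenario has ", ncol(src), " table columns; dataset has ", J)
    m[rownames(src), ] <- src
    return(m)
  }
  if (length(scenario$rows_removed) != J)
    stop("scenario has ", length(scenario$rows_removed),
         " per-table counts; dataset has ", J, " tables")
  targeted <- if (identical(scenario$strata, "all")) strata_names
              else scenario$strata
  unknown <- setdiff(targeted, strata_names)
  if (length(unknown))
    stop("scenario targets unknown strata: ", paste(unknown, collapse = ", "))
  m <- matrix(0, length(strata_names), J,
              dimnames = list(strata_names, names(dataset$tables)))
  m[targeted, ] <- matrix(scenario$rows_removed, length(targeted), J,
                          byrow = TRUE)
  m
}

#' Insert missing rows into a complete dataset
#'
#' Randomly flags rows as missing per the scenario, honoring the disjoint
#' constraint when set (an individual removed from at most one table within
#' its stratum) and never leaving an individual unobserved in every table.
#' Rerunning with the same seed reproduces the ledger exactly.
#'
#' @param dataset A [multiomics_set].
#' @param scenario A [missingness_scenario()].
#' @param seed RNG seed.
#' @return A list with `dataset` (the incomplete [multiomics_set]) and
#'   `ledger` (data frame of removed `(table, stratum, individual_id)`).
#' @export
insert_missingness <- function(dataset, scenario, seed = 1L) {
  counts <- scenario_matrix(scenario, dataset)
  J <- length(dataset$tables)
  for (s in rownames(counts)) {
    size <- sum(dataset$strata == s)
    if (scenario$disjoint && sum(counts[s, ]) > size)
      stop("scenario infeasible for stratum '", s, "': ",
           sum(counts[s, ]), " disjoint removals from ", size, " members")
    if (any(counts[s, ] > size))
      stop("scenario infeasible for stratum '", s, "': more removals than members")
  }

  ledger <- with_preserved_seed(seed, {
    rows <- list()
    for (s in rownames(counts)) {
      members <- names(dataset$strata)[dataset$strata == s]
      for (attempt in seq_len(1000L)) {
        taken <- character(0)          # used when disjoint
        removed <- matrix(FALSE, length(members), J,
                          dimnames = list(members, names(dataset$tables)))
        ok <- TRUE
        for (j in seq_len(J)) {
          t_j <- counts[s, j]
          if (t_j == 0) next
          avail <- if (scenario$disjoint) setdiff(members, taken) else members
          if (length(avail) < t_j) { ok <- FALSE; break }
          pick <- sample(avail, t_j)
          taken <- c(taken, pick)
          removed[pick, j] <- TRUE
        }
        # an individual must stay observed somewhere
        if (ok) ok <- all(rowSums(removed) < J)
        if (ok) break
      }
      if (!ok)
        stop("could not draw a valid removal pattern for stratum '", s,
             "' (would leave an individual unobserved in every table)")
      for (j in seq_len(J)) {
        picked <- members[removed[, j]]
        if (length(picked))
          rows[[length(rows) + 1L]] <- data.frame(
            table = names(dataset$tables)[j], stratum = s,
            individual_id = picked)
      }
    }
    do.call(rbind, rows) %||% data.frame(table = character(0),
                                         stratum = character(0),
                                         individual_id = character(0))
  })

  tables <- dataset$tables
  for (j in seq_along(tables)) {
    drop_ids <- ledger$individual_id[ledger$table == names(tables)[j]]
    if (length(drop_ids)) {
      v <- tables[[j]]$values
      v[drop_ids, ] <- NA_real_
      tables[[j]] <- omics_table(v, tables[[j]]$name)
    }
  }
  list(dataset = multiomics_set(tables, dataset$strata), ledger = ledger)
}

#' Number of distinct incomplete cases per stratum
#'
#' How many ways rows can be removed from one stratum of size `n` given
#' per-table removal counts. Under the disjoint constraint the count is the
#' sequential product of binomial coefficients
#' \eqn{C(n, t_1) C(n - t_1, t_2) \cdots}; without it, the product of
#' independent binomials \eqn{\prod_j C(n, t_j)}.
#'
#' @param stratum_size Stratum size n.
#' @param removals Per-table removal counts.
#' @param disjoint Logical (default `TRUE`).
#' @return The count (double).
#' @export
count_incomplete_cases <- function(stratum_size, removals, disjoint = TRUE) {
  n <- as.integer(stratum_size)
  removals <- as.integer(removals)
  if (any(removals < 0)) stop("removal counts must be >= 0")
  if (disjoint) {
    if (sum(removals) > n)
      stop("infeasible: ", sum(removals), " disjoint removals from ", n)
    remaining <- n
    total <- 1
    for (t in removals) {
      total <- total * choose(remaining, t)
      remaining <- remaining - t
    }
    total
  } else {
    if (any(removals > n)) stop("infeasible: more removals than members")
    prod(choose(n, removals))
  }
}

#' Standard liver-design missingness scenarios
#'
#' The low/medium/high scenarios remove 1, 2 and 3 rows per stratum from the
#' first (transcriptome) table only, totalling 8, 16 and 24 missing rows
#' over 8 strata.
#'
#' @return Named list of three [missingness_scenario()]s.
#' @export
liver_scenarios <- function() {
  list(low = missingness_scenario(c(1, 0)),
       medium = missingness_scenario(c(2, 0)),
       high = missingness_scenario(c(3, 0)))
}

#' Two-table liver-design scenario grid
#'
#' The seven per-stratum (transcriptome, clinical) removal-count pairs of
#' the standard two-table design: (1,1), (2,1), (1,2), (3,1), (2,2), (3,2),
#' (4,1), removed disjointly within each stratum.
#'
#' @return Named list of seven [missingness_scenario()]s.
#' @export
liver_table_scenarios <- function() {
  pairs <- list(c(1, 1), c(2, 1), c(1, 2), c(3, 1), c(2, 2), c(3, 2), c(4, 1))
  out <- lapply(pairs, missingness_scenario)
  names(out) <- vapply(pairs, function(p) paste0("t", p[1], "_c", p[2]), "")
  out
}

#' NCI-60-design missingness scenario
#'
#' Per-cell-line removal counts for the (transcriptome, proteome) tables:
#' breast (1,0), CNS (1,1), colon (2,0), lung (2,2), leukemia (1,1),
#' melanoma (2,2), ovarian (1,1), prostate (0,0), renal (2,1).
#'
#' @return A [missingness_scenario()] with per-stratum counts.
#' @export
nci60_scenario <- function() {
  m <- rbind(breast = c(1, 0), cns = c(1, 1), colon = c(2, 0),
             lung = c(2, 2), leukemia = c(1, 1), melanoma = c(2, 2),
             ovarian = c(1, 1), prostate = c(0, 0), renal = c(2, 1))
  missingness_scenario(m)
}

#' NCI-60-design uncertainty scenarios (10% and 30% missing rows)
#'
#' The 10% pattern removes 6 transcriptome rows (4 melanoma, 2 leukemia);
#' the 30% pattern adds 2 transcriptome rows in each of six further strata
#' (colon, renal, ovarian, breast, lung, CNS) for 18 of 60 rows.
#'
#' @param pct Either 10 or 30.
#' @return A [missingness_scenario()].
#' @export
nci60_uncertainty_scenario <- function(pct = 10) {
  base <- rbind(melanoma = c(4, 0), leukemia = c(2, 0))
  if (pct == 10) return(missingness_scenario(base))
  if (pct == 30) {
    extra <- c("colon", "renal", "ovarian", "breast", "lung", "cns")
    m <- rbind(base, matrix(rep(c(2, 0), each = length(extra)),
                            ncol = 2, dimnames = list(extra, NULL)))
    return(missingness_scenario(m))
  }
  stop("`pct` must be 10 or 30")
}
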