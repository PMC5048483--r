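#' Construct a single omics data table
#'
#' An `omics_table` holds one table of quantitative variables (individuals in
#' rows, variables in columns) together with a per-individual observation
#' flag. An individual may be missing its entire row in a given table; such
#' rows are stored as `NA` throughout. Cell-level (partial-row) missingness is
#' not supported: either a row is fully observed or fully missing.
#'
#' @param values Numeric matrix, individuals x variables, with row names
#'   (individual identifiers) and column names (variable identifiers).
#' @param name Label for the table (e.g. `"transcriptome"`).
#' @param observed Optional logical vector, one entry per row, `TRUE` when the
#'   row is observed. Defaults to flagging rows that are entirely `NA` as
#'   missing.
#' @return An object of class `omics_table` with fields `name`, `values`,
#'   `individual_ids`, `variable_ids` and `observed`.
#' @export
omics_table <- function(values, name = "table", observed = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  ids <- rownames(values)
  vars <- colnames(values)
  if (is.null(ids) || is.null(vars))
    stop("`values` must have row names (individuals) and column names (variables)")
  if (anyDuplicated(ids))
    stop("duplicate individual ids in table '", name, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(vars))
    stop("duplicate variable ids in table '", name, "'")

  all_na <- apply(values, 1L, function(r) all(is.na(r)))
  any_na <- apply(values, 1L, function(r) anyNA(r))
  if (is.null(observed)) {
    observed <- !all_na
  } else {
    observed <- as.logical(observed)
    if (length(observed) != nrow(values))
      stop("`observed` must have one entry per row")
  }
  if (any(any_na & !all_na & observed))
    stop("table '", name, "' has partially missing rows; ",
         "only whole-row missingness is supported")
  values[!observed, ] <- NA_real_
  structure(
    list(name = name, values = values, individual_ids = ids,
         variable_ids = vars, observed = stats::setNames(observed, ids)),
    class = "omics_table"
  )
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("omics_table '%s': %d individuals x %d variables (%d missing rows)\n",
              x$name, nrow(x$values), ncol(x$values), sum(!x$observed)))
  invisible(x)
}

#' Construct a multi-table omics dataset
#'
#' Bundles J [omics_table]s sharing one ordered set of individuals with a
#' stratum assignment. The canonical individual order is taken from `strata`
#' and enforced on every table. Every individual must be observed in at least
#' one table (an individual absent everywhere could never act as a hot-deck
#' recipient and is rejected).
#'
#' @param tables List of [omics_table] objects (length J >= 1).
#' @param strata Named character vector mapping individual id to stratum
#'   label, or a data frame with columns `individual_id` and `stratum`. Its
#'   order defines the canonical individual order.
#' @return An object of class `multiomics_set` with fields `tables`, `strata`
#'   (named character vector) and `individual_ids`.
#' @export
multiomics_set <- function(tables, strata) {
  if (is.data.frame(strata)) {
    if (!all(c("individual_id", "stratum") %in% names(strata)))
      stop("strata data frame needs columns `individual_id` and `stratum`")
    strata <- stats::setNames(as.character(strata$stratum),
                              as.character(strata$individual_id))
  }
  if (is.null(names(strata)))
    stop("`strata` must be named by individual id")
  if (anyDuplicated(names(strata)))
    stop("duplicate individual ids in strata: ",
         paste(unique(names(strata)[duplicated(names(strata))]), collapse = ", "))
  if (!length(tables)) stop("need at least one table")
  if (!all(vapply(tables, inherits, logical(1), "omics_table")))
    stop("`tables` must be a list of omics_table objects")

  ids <- names(strata)
  nm <- vapply(tables, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("table names must be unique")
  tables <- lapply(tables, function(tb) {
    extra <- setdiff(tb$individual_ids, ids)
    if (length(extra))
      stop("table '", tb$name, "' contains individuals absent from the strata file: ",
           paste(extra, collapse = ", "))
    miss <- setdiff(ids, tb$individual_ids)
    if (length(miss)) {
      pad <- matrix(NA_real_, length(miss), length(tb$variable_ids),
                    dimnames = list(miss, tb$variable_ids))
      tb <- omics_table(rbind(tb$values, pad)[ids, , drop = FALSE], tb$name)
    } else if (!identical(tb$individual_ids, ids)) {
      tb <- omics_table(tb$values[ids, , drop = FALSE], tb$name)
    }
    tb
  })
  names(tables) <- vapply(tables, `[[`, character(1), "name")

  obs <- vapply(tables, function(tb) tb$observed[ids], logical(length(ids)))
  obs <- matrix(obs, nrow = length(ids))
  never <- ids[rowSums(obs) == 0L]
  if (length(never))
    stop("individual(s) missing from every table: ",
         paste(never, collapse = ", "))

  structure(list(tables = tables, strata = strata, individual_ids = ids),
            class = "multiomics_set")
}

#' @export
print.multiomics_set <- function(x, ...) {
  cat(sprintf("multiomics_set: %d individuals, %d strata, %d tables\n",
              length(x$individual_ids), length(unique(x$strata)),
              length(x$tables)))
  for (tb in x$tables)
    cat(sprintf("  %-15s %4d variables, %2d missing rows\n",
                tb$name, length(tb$variable_ids), sum(!tb$observed)))
  invisible(x)
}

#' Is the dataset fully observed?
#' @param dataset A [multiomics_set].
#' @return `TRUE` when no table has a missing row.
#' @export
is_complete <- function(dataset) {
  all(vapply(dataset$tables, function(tb) all(tb$observed), logical(1)))
}

# field separator from file extension (.csv comma, anything else tab)
infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a multi-table dataset from delimited files
#'
#' Each table file is a delimited matrix with a header row of variable ids and
#' a first column of individual ids; the strata file has columns
#' `individual_id,stratum` and defines the canonical individual order. A
#' missing row may be encoded either as an absent line or as a row whose every
#' entry equals `missing_marker`; both normalize to the observation mask.
#' Comma vs tab separation is inferred from the file extension
#' (`.csv` = comma, otherwise tab).
#'
#' @param table_paths Character vector of table file paths.
#' @param strata_path Path of the strata file.
#' @param missing_marker Token marking missing entries (default `"NA"`).
#' @param table_names Optional labels for the tables; defaults to file base
#'   names without extension.
#' @return A validated [multiomics_set].
#' @export
read_multiomics <- function(table_paths, strata_path, missing_marker = "NA",
                            table_names = NULL) {
  sdf <- utils::read.table(strata_path, header = TRUE, sep = infer_sep(strata_path),
                           colClasses = "character", check.names = FALSE)
  if (!all(c("individual_id", "stratum") %in% names(sdf)))
    stop("strata file must have columns `individual_id` and `stratum`")
  if (is.null(table_names))
    table_names <- sub("\\.[^.]*$", "", basename(table_paths))
  tables <- vector("list", length(table_paths))
  for (j in seq_along(table_paths)) {
    df <- utils::read.table(table_paths[j], header = TRUE,
                            sep = infer_sep(table_paths[j]),
                            na.strings = missing_marker, check.names = FALSE,
                            colClasses = NA)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    tables[[j]] <- omics_table(m, table_names[j])
  }
  multiomics_set(tables, sdf)
}

#' Write an MFA configuration to a delimited file
#'
#' One row per individual, columns `dim1..dimd`, written at full double
#' precision so that [read_configuration()] reproduces the scores exactly.
#'
#' @param config An [mfa_config] (or the compromise block of a STATIS result).
#' @param path Output file path; comma vs tab separation inferred from the
#'   extension.
#' @export
write_configuration <- function(config, path) {
  scores <- config$scores
  if (is.null(scores) || ncol(scores) < 1L)
    stop("configuration must have at least one dimension")
  sep <- infer_sep(path)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  header <- c("individual_id", paste0("dim", seq_len(ncol(scores))))
  writeLines(paste(header, collapse = sep), con)
  for (i in seq_len(nrow(scores))) {
    cells <- c(rownames(scores)[i], sprintf("%.17g", scores[i, ]))
    writeLines(paste(cells, collapse = sep), con)
  }
  invisible(path)
}

#' Read back a configuration written by [write_configuration()]
#' @param path File path.
#' @return Numeric matrix of scores with individual ids as row names.
#' @export
read_configuration <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a JSON run manifest
#'
#' Records paths, parameters and the RNG seed of a run for provenance.
#' @param path Output JSON path.
#' @param ... Named fields to record.
#' @export
write_manifest <- function(path, ...) {
  jsonlite::write_json(list(...), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a multi-table dataset to delimited files
#'
#' One file per table plus a strata file, in the layout accepted by
#' [read_multiomics()]. Missing rows are written as rows of `NA`.
#'
#' @param dataset A [multiomics_set].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"tsv"`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_multiomics <- function(dataset, dir, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tb in dataset$tables) {
    p <- file.path(dir, paste0(tb$name, ".", format))
    df <- data.frame(individual_id = tb$individual_ids, tb$values,
                     check.names = FALSE)
    utils::write.table(df, p, sep = sep, row.names = FALSE, quote = FALSE)
    paths[tb$name] <- p
  }
  sp <- file.path(dir, paste0("strata.", format))
  utils::write.table(
    data.frame(individual_id = names(dataset$strata),
               stratum = unname(dataset$strata)),
    sp, sep = sep, row.names = FALSE, quote = FALSE)
  paths["strata"] <- sp
  invisible(paths)
}
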