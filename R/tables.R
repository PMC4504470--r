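#' Read a locality x unit community table
#'
#' The table holds presence/absence (0/1) or counts of OTUs or haplotypes per
#' locality, one locality per row.
#'
#' @param path CSV or TSV file with a header row.
#' @param locality_col Name of the column holding locality labels
#'   (default `"locality"`).
#' @return Numeric matrix with localities as row names.
#' @export
read_community_table <- function(path, locality_col = "locality") {
  df <- read_table_file(path)
  if (!locality_col %in% names(df)) {
    stopf("no '%s' column in %s", locality_col, path)
  }
  loc <- as.character(df[[locality_col]])
  df[[locality_col]] <- NULL
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(loc, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(as.character(df[[j]])))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stopf("non-numeric value '%s' at row %d, column '%s'",
            as.character(df[[j]])[i], i, names(df)[j])
    }
    m[, j] <- v
  }
  if (any(m < 0)) stopf("community table has negative entries")
  m
}

#' Read a locality x variable environmental table
#'
#' Numeric columns are kept as numbers; a categorical substrate column (rock
#' chemistry class) is preserved as labels and only expanded to indicators by
#' [normalize_env()].
#'
#' @param path CSV or TSV file with a header row.
#' @param locality_col Name of the locality column (default `"locality"`).
#' @param substrate_col Name of the categorical column, or `NULL` if absent
#'   (default `"substrate"`, ignored when missing).
#' @return Data frame with localities as row names and a `normalized`
#'   attribute set to `FALSE`.
#' @export
read_env_table <- function(path, locality_col = "locality",
                           substrate_col = "substrate") {
  df <- read_table_file(path)
  if (!locality_col %in% names(df)) {
    stopf("no '%s' column in %s", locality_col, path)
  }
  rownames(df) <- as.character(df[[locality_col]])
  df[[locality_col]] <- NULL
  for (j in names(df)) {
    if (!is.null(substrate_col) && j == substrate_col) {
      df[[j]] <- as.character(df[[j]])
      next
    }
    v <- suppressWarnings(as.numeric(as.character(df[[j]])))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stopf("non-numeric value '%s' at row %d, column '%s'",
            as.character(df[[j]])[i], i, j)
    }
    df[[j]] <- v
  }
  attr(df, "normalized") <- FALSE
  df
}

read_table_file <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("no data rows in %s", path)
  df
}

#' Check that a community matrix and an environmental table are paired
#'
#' @param comm Community matrix (localities in rows).
#' @param env Environmental table (localities in rows).
#' @return Invisibly `TRUE`; errors if the locality sets differ.
#' @export
check_pairing <- function(comm, env) {
  a <- rownames(comm); b <- rownames(env)
  if (is.null(a) || is.null(b)) stopf("both tables need locality row names")
  miss <- c(setdiff(a, b), setdiff(b, a))
  if (length(miss)) {
    stopf("locality mismatch between paired tables: %s",
          paste(unique(miss), collapse = ", "))
  }
  invisible(TRUE)
}

#' Normalize an environmental table
#'
#' Categorical substrate columns are expanded to 0/1 indicator columns first;
#' every column is then centred and scaled to unit standard deviation, the
#' normalization applied to the study's WorldClim/Bio-ORACLE variables.
#'
#' @param env Data frame as returned by [read_env_table()].
#' @return Numeric data frame with mean-0, sd-1 columns and attribute
#'   `normalized = TRUE`. Constant columns are an error.
#' @export
normalize_env <- function(env) {
  stopifnot(is.data.frame(env))
  out <- list()
  for (j in names(env)) {
    v <- env[[j]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      for (lv in sort(unique(v))) {
        out[[paste0(j, "_", lv)]] <- as.numeric(v == lv)
      }
    } else {
      out[[j]] <- v
    }
  }
  out <- as.data.frame(out, row.names = rownames(env), check.names = FALSE)
  for (j in names(out)) {
    s <- sd(out[[j]])
    if (!is.finite(s) || s == 0) stopf("constant column '%s' cannot be normalized", j)
    out[[j]] <- (out[[j]] - mean(out[[j]])) / s
  }
  attr(out, "normalized") <- TRUE
  out
}
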