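#' Expression matrices as tibbles
#'
#' The whole workflow operates on a genes-by-timepoints expression table
#' held as a tibble: a `gene_id` character column followed by one numeric
#' column per time point, the column names being the (strictly increasing)
#' numeric time stamps. `as_expression_matrix()` validates an existing data
#' frame and stamps it with the `expr_mat` class; `expression_matrix()`
#' builds one from a numeric matrix.
#'
#' Invariants enforced: unique gene identifiers, strictly increasing numeric
#' times, all expression values finite.
#'
#' @param x A data frame whose first column is `gene_id` and whose remaining
#'   columns are numeric time points (names parseable as numbers).
#' @param values Numeric matrix, genes in rows, time points in columns.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param times Strictly increasing numeric vector, one entry per column.
#' @return A tibble of class `expr_mat`.
#' @examples
#' em <- expression_matrix(matrix(1:6, 2, 3), c("g1", "g2"), times = c(0, 4, 8))
#' em
#' @export
expression_matrix <- function(values, gene_ids, times) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    abort("time points must be strictly increasing")
  }
  df <- tibble::as_tibble(values, .name_repair = "minimal")
  names(df) <- format_times(times)
  df <- dplyr::bind_cols(tibble::tibble(gene_id = as.character(gene_ids)), df)
  as_expression_matrix(df)
}

#' @rdname expression_matrix
#' @export
as_expression_matrix <- function(x) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L || names(x)[1L] != "gene_id") {
    abort("an expression matrix needs a leading `gene_id` column plus one column per time point")
  }
  x$gene_id <- as.character(x$gene_id)
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate gene id(s): ", paste(unique(dup), collapse = ", ")))
  }
  times <- suppressWarnings(as.numeric(names(x)[-1L]))
  if (anyNA(times)) {
    bad <- names(x)[-1L][is.na(times)]
    abort(paste0("time-point column name(s) not numeric: ", paste(bad, collapse = ", ")))
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    abort("time points must be strictly increasing")
  }
  vals <- as.matrix(x[-1L])
  if (nrow(x) > 0L && !is.numeric(vals)) abort("expression values must be numeric")
  if (nrow(x) > 0L && any(!is.finite(vals))) {
    idx <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite expression value at gene '%s', time column %d",
                  x$gene_id[idx[1L]], idx[2L]))
  }
  class(x) <- c("expr_mat", class(tibble::tibble()))
  x
}

format_times <- function(times) {
  times <- as.numeric(times)
  format(times, digits = 15L, trim = TRUE, scientific = FALSE)
}

# matrix view: genes x times, rownames = gene ids
em_values <- function(x) {
  m <- as.matrix(x[-1L])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

em_times <- function(x) as.numeric(names(x)[-1L])

em_gene_ids <- function(x) x$gene_id

#' Read or write an expression matrix
#'
#' The on-disk format is a delimited table whose cell (1,1) is the literal
#' `gene_id`, whose header row holds the numeric time points, and which has
#' one row per gene. The delimiter is taken from the file extension
#' (`.csv` comma, `.tsv`/anything else tab) unless given explicitly.
#'
#' @param path File path.
#' @param delimiter Single delimiter character, or `NULL` to infer from the
#'   extension.
#' @param x An `expr_mat` (any data frame in that layout is accepted for
#'   writing).
#' @return `read_expression_matrix()` returns an `expr_mat` tibble with rows
#'   in file order; `write_expression_matrix()` invisibly returns `x`.
#' @export
read_expression_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delimiter <- delimiter %||% infer_delimiter(path)
  df <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (names(df)[1L] != "gene_id") {
    abort(paste0("first header cell must be 'gene_id', got '", names(df)[1L], "'"))
  }
  body <- df[-1L]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
      abort(sprintf("non-numeric cell at row %d, column %d of %s",
                    bad, j + 1L, path))
    }
  }
  as_expression_matrix(df)
}

#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(x, path, delimiter = NULL) {
  delimiter <- delimiter %||% infer_delimiter(path)
  readr::write_delim(tibble::as_tibble(x), path, delim = delimiter)
  invisible(x)
}

infer_delimiter <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop genes with zero variance
#'
#' Genes whose expression is exactly constant across the time course carry
#' no temporal signal and break standardization, so they are removed before
#' any analysis. Constancy is tested as exact equality of all entries (the
#' sample standard deviation, n-1 denominator, is exactly zero), not with a
#' tolerance.
#'
#' @param x An `expr_mat`.
#' @return A list with `matrix` (the retained `expr_mat`, original order)
#'   and `removed` (character vector of dropped gene ids, original order).
#' @export
filter_zero_variance <- function(x) {
  x <- as_expression_matrix(x)
  vals <- em_values(x)
  constant <- apply(vals, 1L, function(r) all(r == r[1L]))
  list(
    matrix = as_expression_matrix(x[!constant, , drop = FALSE]),
    removed = x$gene_id[constant]
  )
}

#' Standardize each gene to mean 0, sd 1
#'
#' Row-wise z-scoring (sample sd, n-1 denominator). All downstream stages —
#' clustering, target smoothing, distances and the VAR fit — operate on the
#' standardized matrix so every stage sees one consistent scale.
#'
#' @param x An `expr_mat` with no constant rows.
#' @return A standardized `expr_mat`.
#' @export
standardize_genes <- function(x) {
  x <- as_expression_matrix(x)
  vals <- em_values(x)
  sds <- apply(vals, 1L, sd)
  if (any(sds == 0)) {
    abort(paste0("constant gene row(s): ",
                 paste(x$gene_id[sds == 0], collapse = ", "),
                 "; run filter_zero_variance() first"))
  }
  z <- (vals - rowMeans(vals)) / sds
  expression_matrix(z, x$gene_id, em_times(x))
}
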