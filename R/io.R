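#' Read an expression matrix from TSV/CSV
#'
#' Expects one header row and one id column. Public expression files come in
#' both orientations, so the caller states it explicitly rather than having
#' the reader guess; internally the matrix is always samples x genes.
#'
#' @param path File path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @param orientation `"samples_by_genes"` (rows are samples) or
#'   `"genes_by_samples"` (rows are genes; the matrix is transposed on
#'   load).
#' @return Numeric samples-by-genes matrix with sample ids as row names and
#'   gene ids as column names.
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes",
                                            "genes_by_samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L)
    stop("expected an id column plus at least one data column in ", path,
         call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(df)[-1L]))
    stop("duplicate column ids in ", path, call. = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))[1L]
    cell <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1L]]))))[1L]
    stop("non-numeric value in ", path, " at row ",
         if (is.na(cell)) "?" else cell + 1L,
         " (id '", if (is.na(cell)) "?" else ids[cell],
         "'), column '", names(df)[bad + 1L], "'", call. = FALSE)
  }
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)[1L, ]
    stop("missing value in ", path, " at row id '", ids[idx[1L]],
         "', column '", colnames(M)[idx[2L]],
         "'; impute upstream (e.g. KNN imputation) before running kpls",
         call. = FALSE)
  }
  if (any(!is.finite(M)))
    stop("non-finite value in ", path, call. = FALSE)
  rownames(M) <- ids
  if (orientation == "genes_by_samples") M <- t(M)
  M
}

#' Read a sample-to-label table
#'
#' Two-column TSV/CSV (`sample_id`, `label`), with or without a header. The
#' file must cover every requested sample exactly once.
#'
#' @param path File path.
#' @param sample_ids Sample ids to align the labels to (typically
#'   `rownames()` of the expression matrix).
#' @return Character vector of labels in `sample_ids` order.
#' @export
read_labels <- function(path, sample_ids) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = FALSE, sep = sep, quote = "",
                          stringsAsFactors = FALSE)
  if (identical(tolower(as.character(df[1L, 1L])), "sample_id"))
    df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 2L)
    stop("label file needs two columns: sample_id, label", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in label file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  missing <- setdiff(sample_ids, ids)
  if (length(missing))
    stop("no label for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  as.character(df[[2L]])[match(sample_ids, ids)]
}

#' Write a gene ranking to TSV
#'
#' Columns `rank`, `gene_id`, `importance`, preceded by `#`-comment header
#' lines recording the kernel, the number of retained components and the
#' per-component diagnostics so a selection run can be audited later.
#'
#' @param ranking A `kpls_ranking` from [importance_scores()].
#' @param path Output file.
#' @param fit Optional [kpls()] fit used to populate the header comments
#'   (taken from `attr(ranking, "fit")` when present).
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, fit = attr(ranking, "fit"),
                          seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(fit)) {
    writeLines(sprintf("# kernel=%s gamma=%s", fit$kernel$name,
                       format(fit$kernel$gamma %||% NA)), con)
    writeLines(sprintf("# kappa=%d stopping=%s lambda_rel=%g",
                       fit$kappa, fit$stopping_reason, fit$lambda_rel), con)
    writeLines(sprintf("# component=%d Rd=%.6g J=%.6g",
                       seq_len(fit$kappa), fit$rd, fit$fisher_j), con)
  }
  if (!is.null(seed)) writeLines(sprintf("# seed=%s", format(seed)), con)
  out <- data.frame(rank = ranking$rank, gene_id = ranking$gene_id,
                    importance = sprintf("%.12g", ranking$importance))
  writeLines(paste(names(out), collapse = "\t"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
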