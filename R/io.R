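# Delimited feature-matrix input/output and sample harmonization across
# data types.

#' Read a delimited feature matrix
#'
#' Expects a rectangular table with a header row of feature names and a
#' first column of sample identifiers (or the transpose with
#' `orientation = "samples_in_columns"`). Missing or non-numeric cells are
#' errors that name the offending entry; imputation is out of scope.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter (default tab).
#' @param orientation `"samples_in_rows"` (default) or
#'   `"samples_in_columns"`.
#' @return Numeric matrix, samples in rows, sample identifiers as rownames.
#' @export
read_feature_matrix <- function(path, delimiter = "\t",
                                orientation = c("samples_in_rows",
                                                "samples_in_columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          row.names = NULL, quote = "", comment.char = "")
  if (ncol(df) < 2L || nrow(df) < 1L) stop("table in ", path, " is too small", call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[-1])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | vals == "" | is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("missing or non-numeric cell in ", path, " at row '", ids[bad[1, 1]],
         "', column '", colnames(vals)[bad[1, 2]], "'", call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (orientation == "samples_in_columns") num <- t(num)
  num
}

#' Write a feature matrix as a delimited table
#'
#' Header row of feature names, first column `sample_id`; the round-trip
#' through [read_feature_matrix()] is value- and identifier-exact.
#'
#' @param X Numeric matrix with sample identifiers as rownames.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path, delimiter = "\t") {
  X <- as_feature_matrix(X)
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Restrict data types to their shared samples
#'
#' Intersects sample identifiers across feature matrices and reorders every
#' matrix to the shared set, in the order the identifiers appear in the
#' first matrix. Dropped samples are reported per data type.
#'
#' @param matrices Named list of feature matrices (samples in rows).
#' @param quiet Suppress the per-data-type drop report (default FALSE).
#' @return Named list of matrices over the identical, identically ordered
#'   shared samples.
#' @export
harmonize_samples <- function(matrices, quiet = FALSE) {
  stopifnot(length(matrices) >= 1L)
  matrices <- purrr::imap(matrices, ~ as_feature_matrix(.x, .y %||% "matrix"))
  shared <- Reduce(intersect, purrr::map(matrices, rownames))
  if (length(shared) == 0L) stop("no samples shared across data types", call. = FALSE)
  purrr::imap(matrices, function(X, nm) {
    dropped <- setdiff(rownames(X), shared)
    if (length(dropped) && !quiet) {
      message("harmonize_samples: dropping ", length(dropped),
              " sample(s) from '", nm, "'")
    }
    X[shared, , drop = FALSE]
  })
}

#' Canonicalize cluster labels
#'
#' Relabels clusters 1..C by descending cluster size, ties broken by the
#' smallest member index, so outputs are stable and diffable across runs.
#'
#' @param labels Integer-like cluster labels.
#' @return Integer labels in 1..C with no gaps.
#' @export
canonicalize_labels <- function(labels) {
  f <- as.integer(factor(labels))
  sizes <- tabulate(f)
  first_member <- vapply(seq_along(sizes), function(c) min(which(f == c)), integer(1))
  ord <- order(-sizes, first_member)
  out <- integer(length(f))
  for (new in seq_along(ord)) out[f == ord[new]] <- new
  out
}
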