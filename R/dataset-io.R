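#' Read a delimited expression table
#'
#' Loads a samples-by-genes (or genes-by-samples) expression table with a
#' header row, a leading identifier column, and one class-label column (or
#' row, when genes are in rows).  The delimiter is auto-detected from the
#' file extension (`.csv` comma, anything else tab) and can be overridden.
#'
#' Orientation `features_in_rows` covers the common microarray layout with
#' one gene per row and one sample per column; there the labels are the row
#' whose identifier equals `labelColumn`.  The table is transposed on load —
#' samples always index rows of [exprsMatrix()] internally.
#'
#' Cells that do not parse as finite numbers are rejected with an error
#' naming the offending feature and sample; missing values are not imputed.
#'
#' @param path path to a delimited text file with a header
#' @param orientation `samples_in_rows` (default) or `features_in_rows`
#' @param labelColumn name of the label column (or label row), default
#'   `"class"`
#' @param sep field delimiter; `NULL` (default) auto-detects from extension
#' @return an [ExpressionDataset-class]
#' @seealso [writeExpressionTable()]
#' @export
readExpressionTable <- function(path,
                                orientation = c("samples_in_rows",
                                                "features_in_rows"),
                                labelColumn = "class", sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", row.names = 1L)
  if (orientation == "features_in_rows") {
    if (!labelColumn %in% rownames(raw))
      stop(sprintf("label row '%s' not found", labelColumn))
    labels <- as.character(raw[labelColumn, ])
    vals <- raw[setdiff(rownames(raw), labelColumn), , drop = FALSE]
    ids <- list(features = rownames(vals), samples = colnames(vals))
    cells <- t(as.matrix(vals))            # samples x features
  } else {
    if (!labelColumn %in% colnames(raw))
      stop(sprintf("label column '%s' not found", labelColumn))
    labels <- as.character(raw[[labelColumn]])
    vals <- raw[, setdiff(colnames(raw), labelColumn), drop = FALSE]
    ids <- list(features = colnames(vals), samples = rownames(vals))
    cells <- as.matrix(vals)
  }
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric expression value '%s' at sample '%s', feature '%s'",
      cells[bad[1, 1], bad[1, 2]], ids$samples[bad[1, 1]],
      ids$features[bad[1, 2]]))
  }
  if (length(unique(labels)) < 2L)
    stop("fewer than 2 classes in label column")
  ExpressionDataset(num, labels, featureIds = ids$features,
                    sampleIds = ids$samples)
}

#' Write an expression table
#'
#' Inverse of [readExpressionTable()]: writes the dataset as delimited text
#' with an identifier column/row and the class labels, so that reading the
#' file back reproduces the dataset.
#'
#' @param dataset an [ExpressionDataset-class]
#' @param path output path; `.csv` writes comma-separated, otherwise tabs
#' @param orientation layout to write (see [readExpressionTable()])
#' @param labelColumn name used for the label column/row
#' @param sep delimiter override
#' @return `path`, invisibly
#' @export
writeExpressionTable <- function(dataset, path,
                                 orientation = c("samples_in_rows",
                                                 "features_in_rows"),
                                 labelColumn = "class", sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- exprsMatrix(dataset)
  if (orientation == "samples_in_rows") {
    df <- data.frame(id = sampleIds(dataset),
                     as.data.frame(x, check.names = FALSE),
                     check.names = FALSE)
    df[[labelColumn]] <- as.character(classLabels(dataset))
  } else {
    tx <- t(x)
    df <- data.frame(id = c(featureIds(dataset), labelColumn),
                     rbind(as.data.frame(tx, check.names = FALSE),
                           as.list(as.character(classLabels(dataset)))),
                     check.names = FALSE)
    colnames(df) <- c("id", sampleIds(dataset))
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep the features flagged in a binary mask
#'
#' @param dataset an [ExpressionDataset-class] with m features
#' @param mask length-m 0/1 vector; kept features are those with 1, in their
#'   original order
#' @return the subset [ExpressionDataset-class]
#' @examples
#' d <- ExpressionDataset(matrix(rnorm(12), 4), c("a", "a", "b", "b"))
#' subsetFeatures(d, c(1, 0, 1))
#' @export
subsetFeatures <- function(dataset, mask) {
  mask <- .checkMask(mask, nFeatures(dataset))
  if (sum(mask) == 0L) stop("mask selects no features")
  dataset[mask == 1L, ]
}

#' Integer-encode class labels
#'
#' Assigns codes `0..c-1` in first-appearance order, the encoding used by
#' the correlation scorer and by the classifiers.
#'
#' @param labels categorical vector with at least two distinct values
#' @return list with `codes` (integer vector) and `classNames` (ordered
#'   unique values)
#' @examples
#' encodeLabels(c("B", "A", "B", "A"))
#' @export
encodeLabels <- function(labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) < 2L) stop("at least two distinct classes are required")
  list(codes = match(labels, cls) - 1L, classNames = cls)
}
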