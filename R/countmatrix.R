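#' Construct a UMI count matrix
#'
#' The central container of the package: a sparse genes x barcodes matrix of
#' non-negative integer UMI counts, tagged with the modality it came from
#' (dissociated cells or isolated nuclei).
#'
#' @param counts matrix or sparse Matrix of non-negative integer counts,
#'   genes in rows, barcodes in columns.
#' @param genes character vector of unique gene symbols, one per row.
#' @param barcodes character vector of unique barcode strings, one per column.
#' @param modality `"cells"` or `"nuclei"`.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix` carrying dimnames), `genes`, `barcodes` and `modality`.
#' @export
CountMatrix <- function(counts, genes, barcodes, modality) {
  modality <- match.arg(modality, c("cells", "nuclei"))
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(genes))
    stop("number of rows (", nrow(counts), ") does not match number of genes (",
         length(genes), ")")
  if (ncol(counts) != length(barcodes))
    stop("number of columns (", ncol(counts),
         ") does not match number of barcodes (", length(barcodes), ")")
  x <- counts@x
  if (length(x) && any(x < 0))
    stop("counts must be non-negative")
  if (length(x) && any(x != round(x)))
    stop("counts must be integral")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbol(s): ", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(barcodes[duplicated(barcodes)])
  if (length(dup))
    stop("duplicate barcode(s): ", paste(utils::head(dup, 5), collapse = ", "))
  dimnames(counts) <- list(genes, barcodes)
  structure(list(counts = counts, genes = as.character(genes),
                 barcodes = as.character(barcodes), modality = modality),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix [%s]: %d genes x %d barcodes, %d non-zero entries\n",
              x$modality, length(x$genes), length(x$barcodes),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by barcodes and/or genes
#'
#' Order-preserving subsetting used by the QC filters.
#'
#' @param cm a `CountMatrix`.
#' @param barcodes,genes character vectors (subset of `cm$barcodes` /
#'   `cm$genes`) or logical/integer indices. `NULL` keeps everything.
#' @return A `CountMatrix` restricted to the requested rows/columns.
#' @export
subset_matrix <- function(cm, barcodes = NULL, genes = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  bi <- if (is.null(barcodes)) seq_along(cm$barcodes) else {
    if (is.character(barcodes)) {
      miss <- setdiff(barcodes, cm$barcodes)
      if (length(miss))
        stop("unknown barcode(s): ", paste(utils::head(miss, 5), collapse = ", "))
      match(barcodes, cm$barcodes)
    } else seq_along(cm$barcodes)[barcodes]
  }
  gi <- if (is.null(genes)) seq_along(cm$genes) else {
    if (is.character(genes)) {
      miss <- setdiff(genes, cm$genes)
      if (length(miss))
        stop("unknown gene(s): ", paste(utils::head(miss, 5), collapse = ", "))
      match(genes, cm$genes)
    } else seq_along(cm$genes)[genes]
  }
  CountMatrix(cm$counts[gi, bi, drop = FALSE], cm$genes[gi], cm$barcodes[bi],
              cm$modality)
}
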