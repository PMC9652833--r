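# 10x triplet IO: matrix.mtx(.gz) + features.tsv(.gz) + barcodes.tsv(.gz).
# Gene symbols come from column 2 of features.tsv (10x convention); a
# single-column file is accepted too.

.find_10x_file <- function(dir_path, stem) {
  for (nm in c(paste0(stem, ".gz"), stem)) {
    p <- file.path(dir_path, nm)
    if (file.exists(p)) return(p)
  }
  # legacy name for features
  if (stem == "features.tsv")
    return(.find_10x_file(dir_path, "genes.tsv"))
  stop("file '", stem, "' not found in ", dir_path)
}

.read_tsv_nohdr <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read a 10x-style count matrix triplet
#'
#' Reads `matrix.mtx(.gz)`, `features.tsv(.gz)` (or `genes.tsv`) and
#' `barcodes.tsv(.gz)` from a directory into a [CountMatrix]. Duplicate gene
#' symbols are disambiguated by suffixing `.1`, `.2`, ... in file order;
#' duplicate barcodes are an error (they would break barcode tracking).
#'
#' @param dir_path directory containing the three files.
#' @param modality `"cells"` or `"nuclei"` tag for the resulting matrix.
#' @return A [CountMatrix].
#' @export
read_10x <- function(dir_path, modality = c("cells", "nuclei")) {
  modality <- match.arg(modality)
  mtx <- .find_10x_file(dir_path, "matrix.mtx")
  feats <- .read_tsv_nohdr(.find_10x_file(dir_path, "features.tsv"))
  bcs <- .read_tsv_nohdr(.find_10x_file(dir_path, "barcodes.tsv"))[[1]]
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MTX file ", mtx, ": ",
                                         conditionMessage(e)))
  if (nrow(m) != nrow(feats))
    stop("dimension mismatch: MTX declares ", nrow(m), " rows but ",
         "features file has ", nrow(feats), " entries")
  if (ncol(m) != length(bcs))
    stop("dimension mismatch: MTX declares ", ncol(m), " columns but ",
         "barcodes file has ", length(bcs), " entries")
  dup <- unique(bcs[duplicated(bcs)])
  if (length(dup))
    stop("duplicate barcode(s) in barcodes file: ",
         paste(utils::head(dup, 5), collapse = ", "))
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  symbols <- make.unique(symbols, sep = ".")
  CountMatrix(m, symbols, bcs, modality)
}

#' Write a CountMatrix as a 10x-style triplet
#'
#' Emits a 1-based coordinate Matrix Market file with header
#' `%%MatrixMarket matrix coordinate integer general`, plus `features.tsv`
#' (gene symbol in both columns, type `Gene Expression` in the third) and
#' `barcodes.tsv`.
#'
#' @param cm a [CountMatrix].
#' @param dir_path output directory (created if missing).
#' @return Invisibly, the paths of the three files written.
#' @export
write_10x <- function(cm, dir_path) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (length(cm$counts@x) && any(cm$counts@x < 0))
    stop("refusing to write negative counts")
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  tm <- methods::as(cm$counts, "TsparseMatrix")
  o <- order(tm@j, tm@i)  # column-major, the conventional MTX order
  mtx <- file.path(dir_path, "matrix.mtx")
  con <- file(mtx, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x))), con)
  if (length(tm@x))
    writeLines(sprintf("%d %d %d", tm@i[o] + 1L, tm@j[o] + 1L,
                       as.integer(tm@x[o])), con)
  fp <- file.path(dir_path, "features.tsv")
  utils::write.table(data.frame(cm$genes, cm$genes, "Gene Expression"),
                     fp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  bp <- file.path(dir_path, "barcodes.tsv")
  writeLines(cm$barcodes, bp)
  invisible(c(matrix = mtx, features = fp, barcodes = bp))
}

#' Read a marker matrix (identity x gene reference)
#'
#' Parses a tab-delimited file with header columns `identity`, `gene` and an
#' optional positive `weight` (default 1) into the reference used for cluster
#' annotation. Duplicated (identity, gene) rows are collapsed keeping the
#' maximum weight.
#'
#' @param path TSV file path.
#' @return A `MarkerMatrix`: list with `identities` (ordered labels) and
#'   `markers` (named list identity -> named numeric vector of weights).
#' @export
read_marker_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("identity", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("marker matrix file missing column(s): ", paste(miss, collapse = ", "))
  if (!"weight" %in% names(df)) df$weight <- 1
  df$weight <- as.numeric(df$weight)
  marker_matrix(df$identity, df$gene, df$weight)
}

#' Construct a MarkerMatrix from vectors
#'
#' @param identity,gene,weight parallel vectors of identity labels, marker
#'   gene symbols and positive weights.
#' @return A `MarkerMatrix` (see [read_marker_matrix]).
#' @export
marker_matrix <- function(identity, gene, weight = rep(1, length(identity))) {
  identity <- as.character(identity)
  gene <- as.character(gene)
  if (any(!nzchar(identity)) || anyNA(identity))
    stop("empty identity label")
  if (any(!nzchar(gene)) || anyNA(gene))
    stop("empty marker gene symbol")
  if (anyNA(weight) || any(weight <= 0))
    stop("marker weights must be > 0")
  ids <- unique(identity)
  markers <- lapply(ids, function(id) {
    g <- gene[identity == id]
    w <- weight[identity == id]
    # collapse duplicates keeping max weight, preserve first-seen gene order
    tapply(w, factor(g, levels = unique(g)), max)
  })
  names(markers) <- ids
  structure(list(identities = ids, markers = markers), class = "MarkerMatrix")
}

#' @export
print.MarkerMatrix <- function(x, ...) {
  cat(sprintf("MarkerMatrix: %d identities, %d marker entries\n",
              length(x$identities), sum(lengths(x$markers))))
  invisible(x)
}

#' Read a cluster-merge map
#'
#' Parses a tab-delimited file with header columns `fine_label` and
#' `combined_label` mapping fine cluster labels (including dual labels such
#' as `"MFurrow|SMW"`) to combined cell-type labels.
#'
#' @param path TSV file path.
#' @return A `MergeMap`: named character vector fine label -> combined label.
#' @export
read_merge_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(c("fine_label", "combined_label"), names(df))
  if (length(miss))
    stop("merge map file missing column(s): ", paste(miss, collapse = ", "))
  merge_map(df$fine_label, df$combined_label)
}

#' Construct a MergeMap from vectors
#'
#' @param fine_label,combined_label parallel character vectors.
#' @return A `MergeMap` (named character vector).
#' @export
merge_map <- function(fine_label, combined_label) {
  fine_label <- as.character(fine_label)
  combined_label <- as.character(combined_label)
  for (f in unique(fine_label)) {
    tg <- unique(combined_label[fine_label == f])
    if (length(tg) > 1)
      stop("conflicting merge targets for fine label '", f, "': ",
           paste(tg, collapse = ", "))
  }
  keep <- !duplicated(fine_label)
  structure(stats::setNames(combined_label[keep], fine_label[keep]),
            class = "MergeMap")
}
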