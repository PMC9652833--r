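# Per-barcode QC metrics and the modality-specific barcode/gene filters.
#
# Boundary semantics follow the "more than / less than" wording strictly:
# barcodes at exactly 300 or 3000 detected genes, or exactly 10% mito, are
# kept. The nuclei upper filter is a top-1% rule: the 99th percentile of
# detected genes (linear interpolation, computed before any drop) is frozen
# into the QC table, and barcodes strictly above it are dropped.

.drop_levels <- c("none", "too_few_genes", "too_many_genes",
                  "top1pct_genes", "high_mito")

#' Gene-class prefix rules
#'
#' Gene symbol prefixes that define the mitochondrial, ribosomal and
#' heat-shock gene classes (Drosophila conventions: `mt:`, `RpS`/`RpL`,
#' `Hsp`).
#'
#' @param mito_prefixes,ribo_prefixes,hsp_prefixes non-empty character
#'   vectors of symbol prefixes.
#' @return A `GeneClassRules` list.
#' @export
gene_class_rules <- function(mito_prefixes = "mt:",
                             ribo_prefixes = c("RpS", "RpL"),
                             hsp_prefixes = "Hsp") {
  r <- list(mito_prefixes = mito_prefixes, ribo_prefixes = ribo_prefixes,
            hsp_prefixes = hsp_prefixes)
  if (any(!nzchar(unlist(r))) || !all(lengths(r) >= 1))
    stop("prefixes must be non-empty strings")
  class(r) <- "GeneClassRules"
  r
}

.match_prefix <- function(genes, prefixes) {
  m <- rep(FALSE, length(genes))
  for (p in prefixes) m <- m | startsWith(genes, p)
  m
}

#' Compute per-barcode QC metrics
#'
#' For every barcode: the number of detected genes (count > 0) and the
#' percentage of total counts falling on mitochondrial, ribosomal and
#' heat-shock genes. Barcodes with zero total counts get 0 for all
#' percentages.
#'
#' @param cm a [CountMatrix].
#' @param rules a [gene_class_rules] object.
#' @return A `QCTable` data frame (one row per barcode, input order) with
#'   columns `barcode`, `n_genes_detected`, `pct_mito`, `pct_ribo`,
#'   `pct_hsp`, `keep`, `drop_reason`; the matrix modality is carried as an
#'   attribute.
#' @export
compute_qc <- function(cm, rules = gene_class_rules()) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (length(cm$barcodes) == 0) stop("empty matrix")
  tot <- Matrix::colSums(cm$counts)
  n_genes <- Matrix::colSums(cm$counts > 0)
  pct <- function(cls) {
    s <- Matrix::colSums(cm$counts[.match_prefix(cm$genes, cls), ,
                                   drop = FALSE])
    ifelse(tot > 0, 100 * s / tot, 0)
  }
  qct <- data.frame(barcode = cm$barcodes,
                    n_genes_detected = as.integer(n_genes),
                    pct_mito = pct(rules$mito_prefixes),
                    pct_ribo = pct(rules$ribo_prefixes),
                    pct_hsp = pct(rules$hsp_prefixes),
                    keep = NA, drop_reason = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(qct, "modality") <- cm$modality
  class(qct) <- c("QCTable", "data.frame")
  qct
}

#' Flag poor-quality barcodes
#'
#' Cells are dropped if they detect more than `max_genes` (default 3000) or
#' fewer than `min_genes` (default 300) genes; nuclei if they detect fewer
#' than `min_genes` genes or strictly more than the 99th percentile of
#' detected genes (the "top 1%" rule). Both modalities additionally drop
#' barcodes with strictly more than `max_pct_mito` percent mitochondrial
#' reads. Reasons are assigned in the order too-few, too-many/top-1%,
#' high-mito; the first matching reason is recorded. The nuclei percentile
#' threshold is computed on the full pre-filter table and stored as an
#' attribute, making re-filtering idempotent.
#'
#' @param qct a `QCTable` from [compute_qc].
#' @param modality `"cells"` or `"nuclei"`; defaults to the table's own tag.
#' @param min_genes,max_genes detected-gene bounds (strict inequalities).
#' @param top_quantile upper quantile for the nuclei rule (0.99 = top 1%).
#' @param max_pct_mito mitochondrial percentage bound (strict).
#' @return The `QCTable` with `keep` and `drop_reason` filled in.
#' @export
filter_barcodes <- function(qct, modality = attr(qct, "modality"),
                            min_genes = 300, max_genes = 3000,
                            top_quantile = 0.99, max_pct_mito = 10) {
  stopifnot(inherits(qct, "QCTable"))
  if (!modality %in% c("cells", "nuclei"))
    stop("modality must be 'cells' or 'nuclei'")
  n <- qct$n_genes_detected
  reason <- rep("none", nrow(qct))
  too_few <- n < min_genes
  if (modality == "cells") {
    too_many <- n > max_genes
    upper_reason <- "too_many_genes"
  } else {
    thr <- attr(qct, "top1pct_threshold")
    if (is.null(thr))
      thr <- unname(stats::quantile(n, top_quantile, type = 7))
    too_many <- n > thr
    upper_reason <- "top1pct_genes"
    attr(qct, "top1pct_threshold") <- thr
  }
  high_mito <- qct$pct_mito > max_pct_mito
  reason[high_mito] <- "high_mito"
  reason[too_many] <- upper_reason
  reason[too_few] <- "too_few_genes"
  qct$keep <- reason == "none"
  qct$drop_reason <- factor(reason, levels = .drop_levels)
  qct
}

#' Drop flagged barcodes from a CountMatrix
#'
#' @param cm a [CountMatrix].
#' @param qct the filtered `QCTable` for the same matrix.
#' @return The [CountMatrix] restricted to kept barcodes.
#' @export
keep_barcodes <- function(cm, qct) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(qct, "QCTable"))
  if (!identical(qct$barcode, cm$barcodes))
    stop("QC table does not match the matrix barcodes")
  if (anyNA(qct$keep)) stop("run filter_barcodes() first")
  subset_matrix(cm, barcodes = qct$keep)
}

#' Filter genes by barcode support
#'
#' Keeps a gene iff it is detected (count > 0) in at least `min_support`
#' barcodes: 5 for cells, 3 for nuclei by default. Must run after barcode
#' filtering so support is counted on kept barcodes only.
#'
#' @param cm a barcode-filtered [CountMatrix].
#' @param min_support minimum number of supporting barcodes; defaults by
#'   modality.
#' @return The [CountMatrix] restricted to supported genes (order kept).
#' @export
filter_genes <- function(cm, min_support = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(min_support))
    min_support <- if (cm$modality == "cells") 5L else 3L
  support <- Matrix::rowSums(cm$counts > 0)
  keep <- support >= min_support
  if (!any(keep))
    stop("no gene passes the support filter (>= ", min_support, " barcodes)")
  subset_matrix(cm, genes = keep)
}
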