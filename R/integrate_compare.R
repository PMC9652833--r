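# Joint analysis of the cells and nuclei datasets and the cross-modality
# comparison statistics: corrected contribution proportions, variable-gene
# overlap counts, per-identity DE overlap, and barcode-tracked transitions.
#
# Integration is deliberately simple: restrict to the union of both
# datasets' top variable genes (within the shared universe), standardize
# each gene within each dataset, concatenate, then embed and cluster as for
# a single dataset. The comparison statistics only require a joint
# labelling, not any particular batch-correction algorithm.

.scale_rows_per_dataset <- function(M) {
  mu <- rowMeans(M)
  sd <- sqrt(pmax(0, rowMeans(M ^ 2) - mu ^ 2))
  Z <- (M - mu) / ifelse(sd == 0, 1, sd)
  Z[sd == 0, ] <- 0
  Z
}

#' Jointly embed and cluster two normalized datasets
#'
#' @param nm_cells,nm_nuclei `NormMatrix` objects for the two modalities.
#' @param n_features per-dataset number of variable genes feeding the
#'   shared feature set (default 3000).
#' @param k,knn,prune,resolution,seed embedding/clustering parameters as in
#'   [cluster_cells].
#' @return A `JointAssignment`: list with `cluster` (named integer vector
#'   over all barcodes of both datasets), `dataset` (named modality tag per
#'   barcode), `features` (the joint feature set) and the `embedding`.
#' @export
integrate_pair <- function(nm_cells, nm_nuclei, n_features = 3000, k = 30,
                           knn = 20, prune = 1 / 15, resolution = 1,
                           seed = 1L) {
  stopifnot(inherits(nm_cells, "NormMatrix"), inherits(nm_nuclei, "NormMatrix"))
  shared <- intersect(nm_cells$genes, nm_nuclei$genes)
  if (!length(shared)) stop("the two datasets share no genes")
  if (any(nm_nuclei$barcodes %in% nm_cells$barcodes))
    stop("barcode strings collide across datasets")
  feats <- intersect(union(select_hvg(nm_cells, n_features)$gene,
                           select_hvg(nm_nuclei, n_features)$gene), shared)
  if (!length(feats)) stop("no shared variable features")
  MA <- .scale_rows_per_dataset(
    as.matrix(nm_cells$values[match(feats, nm_cells$genes), , drop = FALSE]))
  MB <- .scale_rows_per_dataset(
    as.matrix(nm_nuclei$values[match(feats, nm_nuclei$genes), , drop = FALSE]))
  X <- t(cbind(MA, MB))
  barcodes <- c(nm_cells$barcodes, nm_nuclei$barcodes)
  rownames(X) <- barcodes
  emb <- .pca_embed(X, k, barcodes)
  ca <- cluster_snn(snn_graph(emb, knn, prune), resolution, seed)
  structure(list(cluster = ca$cluster,
                 dataset = stats::setNames(
                   rep(c("cells", "nuclei"),
                       c(length(nm_cells$barcodes),
                         length(nm_nuclei$barcodes))), barcodes),
                 features = feats, embedding = emb,
                 resolution = resolution, seed = as.integer(seed)),
            class = "JointAssignment")
}

#' Joint normalized matrix on the shared gene universe
#'
#' Concatenates both datasets' normalized values over their shared genes,
#' for marker detection on joint clusters.
#'
#' @param nm_cells,nm_nuclei `NormMatrix` objects.
#' @return A `NormMatrix` tagged with the cells modality covering all
#'   barcodes of both datasets.
#' @export
joint_norm_matrix <- function(nm_cells, nm_nuclei) {
  shared <- intersect(nm_cells$genes, nm_nuclei$genes)
  if (!length(shared)) stop("the two datasets share no genes")
  v <- cbind(nm_cells$values[match(shared, nm_cells$genes), , drop = FALSE],
             nm_nuclei$values[match(shared, nm_nuclei$genes), , drop = FALSE])
  structure(list(values = v,
                 size_factors = c(nm_cells$size_factors,
                                  nm_nuclei$size_factors),
                 genes = shared,
                 barcodes = c(nm_cells$barcodes, nm_nuclei$barcodes),
                 modality = "cells"),
            class = "NormMatrix")
}

#' Corrected per-cluster contribution proportions
#'
#' The cells percentage of each joint cluster is corrected for unequal
#' dataset sizes with the factor r = filtered nuclei / filtered cells:
#' corrected cells share = 100 * n_cells * r / (n_cells * r + n_nuclei).
#'
#' @param ja a `JointAssignment`.
#' @param n_filtered_cells,n_filtered_nuclei post-QC barcode counts of the
#'   two datasets (defaults: counted from `ja`).
#' @param labels optional named vector barcode -> label; clusters are then
#'   reported per label instead of per joint cluster id.
#' @return A data frame with columns `label`, `n_cells`, `n_nuclei`,
#'   `pct_cells_corrected`, `pct_nuclei_corrected`; the correction factor is
#'   attached as attribute `correction_factor`.
#' @export
contribution <- function(ja, n_filtered_cells = sum(ja$dataset == "cells"),
                         n_filtered_nuclei = sum(ja$dataset == "nuclei"),
                         labels = NULL) {
  stopifnot(inherits(ja, "JointAssignment"))
  if (n_filtered_cells <= 0 || n_filtered_nuclei <= 0)
    stop("filtered counts must be positive")
  grp <- if (is.null(labels)) as.character(ja$cluster) else {
    l <- labels[names(ja$cluster)]
    if (anyNA(l)) stop("labels do not cover all barcodes")
    unname(l)
  }
  r <- n_filtered_nuclei / n_filtered_cells
  tab <- table(grp, factor(ja$dataset, levels = c("cells", "nuclei")))
  nA <- as.vector(tab[, "cells"]); nB <- as.vector(tab[, "nuclei"])
  keep <- nA + nB > 0
  pctA <- 100 * nA * r / (nA * r + nB)
  out <- data.frame(label = rownames(tab), n_cells = nA, n_nuclei = nB,
                    pct_cells_corrected = pctA,
                    pct_nuclei_corrected = 100 - pctA,
                    stringsAsFactors = FALSE, row.names = NULL)[keep, ]
  attr(out, "correction_factor") <- r
  out
}

#' Venn partition counts of two gene sets
#'
#' @param listA,listB character vectors (duplicates ignored).
#' @return Named integer vector `c(unique_A, shared, unique_B)`.
#' @export
venn_counts <- function(listA, listB) {
  a <- unique(as.character(listA)); b <- unique(as.character(listB))
  shared <- length(intersect(a, b))
  c(unique_A = length(a) - shared, shared = shared,
    unique_B = length(b) - shared)
}

#' Differential-expression overlap between datasets for one cell type
#'
#' Percentages are taken over the union of both datasets' significant gene
#' sets for the cell type, so the three percentages sum to exactly 100.
#'
#' @param sigA,sigB character vectors: significant genes for the cell type
#'   in each dataset.
#' @return Named vector `pct_unique_A`, `pct_unique_B`, `pct_shared`,
#'   `total`; all-`NA` percentages if the union is empty.
#' @export
de_overlap <- function(sigA, sigB) {
  a <- unique(as.character(sigA)); b <- unique(as.character(sigB))
  u <- union(a, b)
  if (!length(u))
    return(c(pct_unique_A = NA_real_, pct_unique_B = NA_real_,
             pct_shared = NA_real_, total = 0))
  sh <- length(intersect(a, b))
  c(pct_unique_A = 100 * (length(a) - sh) / length(u),
    pct_unique_B = 100 * (length(b) - sh) / length(u),
    pct_shared = 100 * sh / length(u), total = length(u))
}

#' Per-label DE overlap across two marker tables
#'
#' Pools each dataset's significant genes over the clusters carrying the
#' same (merged) label and applies [de_overlap] to every label present in
#' both datasets.
#'
#' @param mtA,mtB `MarkerTable`s of the two datasets.
#' @param arA,arB matching (merged) `AnnotationResult`s.
#' @return Data frame with one row per shared label: `label`,
#'   `pct_unique_cells`, `pct_unique_nuclei`, `pct_shared`, `total_genes`.
#' @export
de_overlap_by_label <- function(mtA, arA, mtB, arB) {
  pool <- function(mt, ar) {
    sig <- significant_genes(mt)
    labs <- ar$labels[names(sig)]
    lapply(split(sig, labs), function(x) unique(unlist(x)))
  }
  pa <- pool(mtA, arA); pb <- pool(mtB, arB)
  shared_labels <- intersect(names(pa), names(pb))
  rows <- lapply(shared_labels, function(l) {
    ov <- de_overlap(pa[[l]], pb[[l]])
    data.frame(label = l, pct_unique_cells = ov[["pct_unique_A"]],
               pct_unique_nuclei = ov[["pct_unique_B"]],
               pct_shared = ov[["pct_shared"]],
               total_genes = ov[["total"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Barcode-tracked label transitions
#'
#' Contingency of each barcode's label in an individually analyzed dataset
#' against its label in the joint analysis, in long form for alluvial
#' plotting. Every individually labelled barcode must be present in the
#' joint labelling.
#'
#' @param individual named vector barcode -> source label.
#' @param joint named vector barcode -> joint label.
#' @return Data frame `source_label`, `joint_label`, `count` (rows with
#'   count 0 omitted).
#' @export
transitions <- function(individual, joint) {
  miss <- setdiff(names(individual), names(joint))
  if (length(miss))
    stop("barcode(s) missing from the joint assignment: ",
         paste(utils::head(miss, 5), collapse = ", "))
  tab <- table(source_label = unname(individual),
               joint_label = unname(joint[names(individual)]))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3] <- "count"
  df <- df[df$count > 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}
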