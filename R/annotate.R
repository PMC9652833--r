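# Marker-matrix cluster annotation.
#
# A cluster's score for an identity is the (weighted) count of that
# identity's reference markers among the cluster's significantly
# overexpressed genes. Tie rules at the maximum score: one winner -> that
# identity; exactly two -> dual label "A|B" (alphabetical); three or more,
# or no marker evidence at all -> "Other".

#' Score clusters against a marker matrix
#'
#' @param mt a `MarkerTable` (see [find_markers]).
#' @param mm a `MarkerMatrix` (see [read_marker_matrix]).
#' @param gene_universe optional character vector of genes present in the
#'   dataset; reference markers outside it are ignored with a message.
#'   Defaults to the genes appearing in `mt`.
#' @param clusters optional vector of cluster ids to score; ids without any
#'   tested gene (e.g. clusters too small for marker detection) get an
#'   all-zero column, which the tie rules turn into `"Other"`. Defaults to
#'   the clusters present in `mt`.
#' @param normalize divide each identity's scores by its marker-set size
#'   (weight total), making identities with different marker counts
#'   comparable. Off by default: the tie rule is phrased on marker counts.
#' @return A `ScoreHeatmap`: numeric matrix identities x clusters.
#' @export
score_clusters <- function(mt, mm, gene_universe = NULL, clusters = NULL,
                           normalize = FALSE) {
  stopifnot(inherits(mt, "MarkerTable"), inherits(mm, "MarkerMatrix"))
  if (is.null(gene_universe)) gene_universe <- unique(mt$gene)
  sig <- significant_genes(mt)
  if (!is.null(clusters)) {
    clusters <- as.character(sort(unique(clusters)))
    empty <- setdiff(clusters, names(sig))
    sig <- c(sig, stats::setNames(rep(list(character(0)), length(empty)),
                                  empty))[clusters]
  }
  sh <- matrix(0, nrow = length(mm$identities), ncol = length(sig),
               dimnames = list(mm$identities, names(sig)))
  dropped <- character(0)
  for (id in mm$identities) {
    w <- mm$markers[[id]]
    absent <- setdiff(names(w), gene_universe)
    if (length(absent)) {
      dropped <- c(dropped, absent)
      w <- w[setdiff(names(w), absent)]
    }
    denom <- if (normalize && sum(w) > 0) sum(w) else 1
    for (k in names(sig))
      sh[id, k] <- sum(w[intersect(names(w), sig[[k]])]) / denom
  }
  if (length(dropped))
    message("ignoring ", length(unique(dropped)),
            " reference marker(s) absent from the gene universe: ",
            paste(utils::head(unique(dropped), 5), collapse = ", "))
  class(sh) <- c("ScoreHeatmap", "matrix")
  sh
}

#' Assign identities from a score heatmap
#'
#' Applies the tie rules per cluster: the unique top-scoring identity wins;
#' a two-way tie yields the dual label `"A|B"` with the identities in
#' alphabetical order; a tie of three or more, or an all-zero column,
#' yields `"Other"`.
#'
#' @param sh a `ScoreHeatmap`.
#' @param tol equality tolerance for real-weighted scores (default 1e-9).
#' @return An `AnnotationResult`: list with `labels` (named character vector
#'   cluster -> label), `scores` (the heatmap) and `runners_up` (per cluster,
#'   identities ordered by decreasing score).
#' @export
assign_identities <- function(sh, tol = 1e-9) {
  stopifnot(inherits(sh, "ScoreHeatmap"))
  labels <- character(ncol(sh))
  runners <- vector("list", ncol(sh))
  for (k in seq_len(ncol(sh))) {
    s <- sh[, k]
    S <- max(s)
    top <- sort(rownames(sh)[s >= S - tol])
    labels[k] <- if (S <= tol) "Other"
      else if (length(top) == 1) top
      else if (length(top) == 2) paste(top, collapse = "|")
      else "Other"
    runners[[k]] <- rownames(sh)[order(-s, rownames(sh))]
  }
  names(labels) <- colnames(sh)
  names(runners) <- colnames(sh)
  structure(list(labels = labels, scores = sh, runners_up = runners),
            class = "AnnotationResult")
}

#' @export
print.AnnotationResult <- function(x, ...) {
  cat("AnnotationResult:", length(x$labels), "clusters\n")
  print(x$labels)
  invisible(x)
}

#' Merge fine labels into combined cell types
#'
#' Replaces each cluster's label by its combined label from the merge map;
#' clusters sharing a combined label form one merged cluster for downstream
#' composition statistics. Every label must be mapped.
#'
#' @param ar an `AnnotationResult`.
#' @param mm a `MergeMap` (see [read_merge_map]).
#' @return The `AnnotationResult` with `labels` replaced and the original
#'   labels kept as `fine_labels`.
#' @export
merge_labels <- function(ar, mm) {
  stopifnot(inherits(ar, "AnnotationResult"), inherits(mm, "MergeMap"))
  unmapped <- setdiff(unique(ar$labels), names(mm))
  if (length(unmapped))
    stop("label(s) missing from the merge map: ",
         paste(unmapped, collapse = ", "))
  out <- ar
  out$fine_labels <- ar$labels
  out$labels <- stats::setNames(unname(mm[ar$labels]), names(ar$labels))
  out
}

#' Per-barcode labels from a cluster assignment and annotation
#'
#' @param ca a `ClusterAssignment`.
#' @param ar an `AnnotationResult` labelling the same clusters.
#' @return Named character vector barcode -> label.
#' @export
barcode_labels <- function(ca, ar) {
  stopifnot(inherits(ca, "ClusterAssignment"),
            inherits(ar, "AnnotationResult"))
  lab <- ar$labels[as.character(ca$cluster)]
  if (anyNA(lab))
    stop("annotation does not cover cluster(s): ",
         paste(setdiff(unique(ca$cluster), names(ar$labels)), collapse = ", "))
  stats::setNames(unname(lab), names(ca$cluster))
}

#' Identity merge map
#'
#' Convenience map sending every given label to itself.
#'
#' @param labels character vector of labels.
#' @return A `MergeMap`.
#' @export
identity_merge_map <- function(labels) {
  labels <- unique(as.character(labels))
  merge_map(labels, labels)
}
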