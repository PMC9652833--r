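# One-vs-rest marker detection: Wilcoxon rank-sum (normal approximation
# with tie and continuity corrections, plus an exact enumeration path for
# tiny groups), fold changes on de-logged means, and Benjamini-Hochberg
# adjustment. Significance cutoffs: log2 fold change > 0.25 and adjusted
# p < 0.05, both strict.

# Rank-sum machinery shared by the scalar and the vectorized path.
.u_moments <- function(n1, n2, tie_term) {
  N <- n1 + n2
  mu <- n1 * n2 / 2
  s2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  list(mu = mu, sd = sqrt(pmax(0, s2)))
}

.tie_term <- function(v) {
  t <- table(v)
  sum(t ^ 3 - t)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Normal approximation with tie correction and continuity correction. For
#' pooled sizes of at most 10 the approximation is poor (it can deviate by
#' more than 0.3 from the exact tail probability under heavy ties), so by
#' default those calls take the exact path: enumeration of all group
#' assignments of the pooled values, giving the exact permutation p-value
#' of the U statistic.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact force the exact enumeration path (|x| + |y| <= 10 only) or,
#'   with `FALSE`, force the normal approximation. Default `NULL`:
#'   exact iff |x| + |y| <= 10.
#' @return Two-sided p-value in [0, 1].
#' @export
rank_sum_p <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stop("empty group")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (is.null(exact)) exact <- N <= 10
  v <- c(x, y)
  r <- rank(v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mo <- .u_moments(n1, n2, .tie_term(v))
  if (exact) {
    if (N > 10) stop("exact path supports |x| + |y| <= 10")
    dev_obs <- abs(U - mo$mu)
    combs <- utils::combn(N, n1)
    devs <- apply(combs, 2, function(idx)
      abs(sum(r[idx]) - n1 * (n1 + 1) / 2 - mo$mu))
    return(mean(devs >= dev_obs - 1e-9))
  }
  if (mo$sd == 0) return(1)
  z <- max(0, abs(U - mo$mu) - 0.5) / mo$sd
  min(1, 2 * stats::pnorm(-z))
}

#' Log2 fold change on de-logged means
#'
#' Inputs are natural-log normalized values; the fold change is computed on
#' de-logged means with a pseudocount of 1:
#' `log2((mean(exp(v) - 1 in cluster) + 1) / (mean(exp(v) - 1 in rest) + 1))`.
#'
#' @param cluster_vals,rest_vals numeric vectors of normalized values.
#' @return The log2 fold change.
#' @export
log2fc <- function(cluster_vals, rest_vals) {
  log2((mean(expm1(cluster_vals)) + 1) / (mean(expm1(rest_vals)) + 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up procedure: sort ascending, multiply by m/i, take the cumulative
#' minimum from the largest rank, cap at 1, restore input order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals)
  adj <- pvals[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(1, adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One-vs-rest marker detection for every cluster
#'
#' For each cluster of size >= `min_cluster`, every gene detected in at
#' least `min_pct` of the cluster's barcodes is tested against all other
#' barcodes with the rank-sum test; p-values are BH-adjusted per cluster
#' across its tested genes. A gene is significant iff log2FC > `logfc_cut`
#' and adjusted p < `alpha`.
#'
#' @param nm a `NormMatrix`.
#' @param ca a `ClusterAssignment` on the same barcodes.
#' @param min_pct detection-fraction gate within the cluster (default 0.1).
#' @param logfc_cut,alpha significance cutoffs (defaults 0.25 and 0.05).
#' @param min_cluster clusters smaller than this are skipped with a warning.
#' @return A `MarkerTable` data frame with columns `cluster`, `gene`,
#'   `log2fc`, `p`, `p_adj`, `significant`.
#' @export
find_markers <- function(nm, ca, min_pct = 0.1, logfc_cut = 0.25,
                         alpha = 0.05, min_cluster = 3) {
  stopifnot(inherits(nm, "NormMatrix"), inherits(ca, "ClusterAssignment"))
  cl <- ca$cluster[nm$barcodes]
  if (anyNA(cl)) stop("cluster assignment does not cover all barcodes")
  ids <- sort(unique(cl))
  if (length(ids) < 2) stop("need at least 2 clusters")
  X <- as.matrix(nm$values)
  n <- ncol(X)
  G <- nrow(X)
  # ranks and tie terms are cluster-independent: compute once per gene
  R <- matrix(0, G, n)
  tie <- numeric(G)
  for (g in seq_len(G)) {
    R[g, ] <- rank(X[g, ])
    tie[g] <- .tie_term(X[g, ])
  }
  E <- expm1(X)
  tot_e <- rowSums(E)
  det <- X > 0
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    in_cl <- cl == ids[k]
    n1 <- sum(in_cl)
    if (n1 < min_cluster) {
      warning("cluster ", ids[k], " has fewer than ", min_cluster,
              " barcodes; skipped")
      next
    }
    n2 <- n - n1
    pct_in <- rowMeans(det[, in_cl, drop = FALSE])
    test <- which(pct_in >= min_pct)
    if (!length(test)) next
    U <- rowSums(R[test, in_cl, drop = FALSE]) - n1 * (n1 + 1) / 2
    mo <- .u_moments(n1, n2, tie[test])
    z <- pmax(0, abs(U - mo$mu) - 0.5) / ifelse(mo$sd == 0, Inf, mo$sd)
    p <- pmin(1, 2 * stats::pnorm(-z))
    mean_in <- rowSums(E[test, in_cl, drop = FALSE]) / n1
    mean_out <- (tot_e[test] - mean_in * n1) / n2
    lfc <- log2((mean_in + 1) / (mean_out + 1))
    p_adj <- bh_adjust(p)
    out[[k]] <- data.frame(cluster = ids[k], gene = nm$genes[test],
                           log2fc = lfc, p = p, p_adj = p_adj,
                           significant = lfc > logfc_cut & p_adj < alpha,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  mt <- do.call(rbind, out)
  if (is.null(mt)) stop("no cluster was large enough to test")
  class(mt) <- c("MarkerTable", "data.frame")
  mt
}

#' Top marker genes per cluster
#'
#' Significant genes ordered by (adjusted p ascending, log2FC descending,
#' symbol ascending); the first `n` per cluster are returned (fewer if the
#' cluster has fewer significant genes).
#'
#' @param mt a `MarkerTable`.
#' @param n genes per cluster (default 4).
#' @return Named list cluster -> character vector of gene symbols.
#' @export
top_markers <- function(mt, n = 4) {
  stopifnot(inherits(mt, "MarkerTable"))
  sig <- mt[mt$significant, , drop = FALSE]
  lapply(split(sig, sig$cluster), function(d) {
    d <- d[order(d$p_adj, -d$log2fc, d$gene), , drop = FALSE]
    utils::head(d$gene, n)
  })
}

#' Significant gene sets per cluster
#'
#' @param mt a `MarkerTable`.
#' @return Named list cluster -> character vector of significant genes.
#' @export
significant_genes <- function(mt) {
  stopifnot(inherits(mt, "MarkerTable"))
  sig <- mt[mt$significant, , drop = FALSE]
  cl <- sort(unique(mt$cluster))
  out <- lapply(cl, function(k) sig$gene[sig$cluster == k])
  names(out) <- as.character(cl)
  out
}
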