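# Median-depth log normalization and binned-dispersion HVG ranking.
#
# value(g, b) = ln(1 + count(g, b) * M / depth(b)), M = median depth.
# Zeros map to zeros, so the normalized matrix stays sparse.

#' Depth-normalize a count matrix
#'
#' Scales each barcode to the median depth and applies ln(1 + x).
#'
#' @param cm a filtered [CountMatrix].
#' @return A `NormMatrix`: list with `values` (sparse genes x barcodes matrix
#'   on the natural-log scale), `size_factors` (depth / median depth),
#'   `genes`, `barcodes` and `modality`.
#' @export
normalize_counts <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  depth <- Matrix::colSums(cm$counts)
  if (any(depth == 0))
    stop("barcode(s) with zero total counts: ",
         paste(utils::head(cm$barcodes[depth == 0], 5), collapse = ", "))
  M <- stats::median(depth)
  sf <- depth / M
  v <- cm$counts %*% Matrix::Diagonal(x = 1 / sf)
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- list(cm$genes, cm$barcodes)
  structure(list(values = v, size_factors = sf, genes = cm$genes,
                 barcodes = cm$barcodes, modality = cm$modality),
            class = "NormMatrix")
}

#' @export
print.NormMatrix <- function(x, ...) {
  cat(sprintf("NormMatrix [%s]: %d genes x %d barcodes (ln scale)\n",
              x$modality, length(x$genes), length(x$barcodes)))
  invisible(x)
}

# Dispersion score of each gene: variance of z-scored values, where the
# z-scoring sd is a mean-dependent expectation estimated by pooling genes
# into equal-occupancy mean bins, and values are clipped at |z| <= sqrt(n).
.hvg_scores <- function(values, nbins = 20) {
  n <- ncol(values)
  mu <- Matrix::rowMeans(values)
  ex2 <- Matrix::rowMeans(values ^ 2)
  v <- (ex2 - mu ^ 2) * n / max(1, n - 1)
  v[v < 0] <- 0
  G <- nrow(values)
  nb <- if (G < nbins) 1L else nbins
  bin <- if (nb == 1L) rep(1L, G) else
    as.integer(cut(rank(mu, ties.method = "first"),
                   breaks = nb, labels = FALSE))
  exp_var <- stats::ave(v, bin, FUN = mean)
  esd <- sqrt(exp_var)
  clip <- sqrt(n)
  score <- numeric(G)
  dense <- as.matrix(values)
  blocks <- split(seq_len(G), ceiling(seq_len(G) / 500))
  for (idx in blocks) {
    z <- (dense[idx, , drop = FALSE] - mu[idx]) / esd[idx]
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    m <- rowMeans(z)
    score[idx] <- (rowMeans(z ^ 2) - m ^ 2) * n / max(1, n - 1)
  }
  score[esd == 0] <- 0
  score[!is.finite(score)] <- 0
  score
}

#' Select highly variable genes
#'
#' Ranks genes by a binned-dispersion score (variance of mean-standardized,
#' clipped values; 20 equal-occupancy mean bins) and returns the top `n`.
#' Ties are broken lexicographically by gene symbol; if `n` exceeds the gene
#' count the full ranked list is returned. Deterministic and invariant to
#' barcode order.
#'
#' @param nm a `NormMatrix`.
#' @param n number of genes to return (default 3000).
#' @param nbins number of mean bins for the expected-variance fit.
#' @return An `HVGList` data frame with columns `gene` and `score`,
#'   descending score.
#' @export
select_hvg <- function(nm, n = 3000, nbins = 20) {
  stopifnot(inherits(nm, "NormMatrix"))
  if (n < 1) stop("n must be >= 1")
  score <- .hvg_scores(nm$values, nbins = nbins)
  o <- order(-score, nm$genes)
  k <- min(n, length(nm$genes))
  out <- data.frame(gene = nm$genes[o][seq_len(k)],
                    score = score[o][seq_len(k)],
                    stringsAsFactors = FALSE)
  class(out) <- c("HVGList", "data.frame")
  out
}
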