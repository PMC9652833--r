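# PCA embedding, shared-nearest-neighbor graph, and greedy modularity
# clustering (Louvain-style local moving with one aggregation pass).

#' PCA embedding of normalized data
#'
#' Principal components of the HVG-restricted, gene-centered matrix
#' (barcodes as observations). Components follow a deterministic sign
#' convention: the loading with the largest magnitude is positive.
#'
#' @param nm a `NormMatrix`.
#' @param hvg an `HVGList` (or character vector of genes) restricting the
#'   gene set; `NULL` uses all genes.
#' @param k number of components (>= 2); truncated with a warning if it
#'   exceeds the matrix rank.
#' @return An `Embedding`: list with `coords` (barcodes x k matrix) and
#'   `var` (component variances, non-increasing).
#' @export
embed_pca <- function(nm, hvg = NULL, k = 30) {
  stopifnot(inherits(nm, "NormMatrix"))
  if (k < 2) stop("k must be >= 2")
  genes <- if (is.null(hvg)) nm$genes else {
    g <- if (is.data.frame(hvg)) hvg$gene else as.character(hvg)
    miss <- setdiff(g, nm$genes)
    if (length(miss))
      stop("HVG gene(s) absent from the matrix: ",
           paste(utils::head(miss, 5), collapse = ", "))
    g
  }
  X <- t(as.matrix(nm$values[match(genes, nm$genes), , drop = FALSE]))
  .pca_embed(X, k, nm$barcodes)
}

# Shared PCA core (also used by the joint integration).
.pca_embed <- function(X, k, barcodes) {
  X <- scale(X, center = TRUE, scale = FALSE)
  maxk <- min(dim(X)) - 1L
  if (k > maxk) {
    warning("k = ", k, " exceeds the matrix rank; truncated to ", maxk)
    k <- maxk
  }
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  rownames(coords) <- barcodes
  structure(list(coords = coords, var = pc$sdev[seq_len(k)] ^ 2),
            class = "Embedding")
}

#' Shared-nearest-neighbor graph
#'
#' Builds the kNN graph (Euclidean distance in the embedding, neighbor
#' lists include the barcode itself) and weights each edge by the Jaccard
#' overlap of the two neighbor lists, pruning weights below `prune`.
#'
#' @param emb an `Embedding`.
#' @param knn neighborhood size (including self); must be < n barcodes.
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @return A symmetric sparse weight matrix (zero diagonal) with barcode
#'   dimnames.
#' @export
snn_graph <- function(emb, knn = 20, prune = 1 / 15) {
  stopifnot(inherits(emb, "Embedding"))
  n <- nrow(emb$coords)
  if (knn >= n) stop("knn must be smaller than the number of barcodes")
  d <- as.matrix(stats::dist(emb$coords))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(knn)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = knn),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)              # shared-neighbor counts
  S <- methods::as(S, "TsparseMatrix")
  w <- S@x / (2 * knn - S@x)              # Jaccard from shared counts
  keep <- w >= prune & S@i != S@j
  W <- Matrix::sparseMatrix(i = S@i[keep] + 1L, j = S@j[keep] + 1L,
                            x = w[keep], dims = c(n, n),
                            dimnames = list(rownames(emb$coords),
                                            rownames(emb$coords)))
  methods::as(W, "CsparseMatrix")
}

# Greedy modularity local moving at a given resolution. W: symmetric sparse
# weights, comm: integer membership. Returns improved membership. The
# community strengths are recomputed at every sweep and the acceptance
# threshold is well above arithmetic noise, so rounding drift cannot
# manufacture phantom gains (which would cycle forever); a sweep cap
# bounds the worst case.
.local_move <- function(W, comm, resolution, order_nodes, eps = 1e-9,
                        max_sweeps = 100L) {
  n <- nrow(W)
  m2 <- sum(W)                       # 2m
  if (m2 == 0) return(comm)
  strength <- Matrix::colSums(W)
  Wp <- methods::as(W, "CsparseMatrix")
  for (sweep in seq_len(max_sweeps)) {
    sig_tot <- numeric(max(comm))
    agg <- tapply(strength, comm, sum)
    sig_tot[as.integer(names(agg))] <- as.vector(agg)
    moved <- FALSE
    for (i in order_nodes) {
      lo <- Wp@p[i] + 1L; hi <- Wp@p[i + 1L]
      if (hi < lo) next
      nbr <- Wp@i[lo:hi] + 1L
      wts <- Wp@x[lo:hi]
      self <- nbr == i                 # self-loops move with the node
      if (any(self)) {
        nbr <- nbr[!self]; wts <- wts[!self]
        if (!length(nbr)) next
      }
      ci <- comm[i]
      ki <- strength[i]
      # links from i to each neighboring community
      k_in <- tapply(wts, comm[nbr], sum)
      cand <- as.integer(names(k_in))
      sig_tot[ci] <- sig_tot[ci] - ki
      base <- k_in - resolution * ki * sig_tot[cand] / m2
      stay <- if (ci %in% cand) base[match(ci, cand)] else
        -resolution * ki * sig_tot[ci] / m2
      best <- which(base > stay + eps)
      if (length(best)) {
        gains <- base[best]
        pick <- best[order(-gains, cand[best])[1]]
        comm[i] <- cand[pick]
        sig_tot[cand[pick]] <- sig_tot[cand[pick]] + ki
        moved <- TRUE
      } else {
        sig_tot[ci] <- sig_tot[ci] + ki
      }
    }
    if (!moved) break
  }
  comm
}

.relabel_by_size <- function(comm) {
  sz <- table(comm)
  o <- names(sz)[order(-as.vector(sz), as.integer(names(sz)))]
  as.integer(match(as.character(comm), o)) - 1L
}

#' Cluster an SNN graph by greedy modularity
#'
#' Louvain-style clustering: seeded-order local moving to a local modularity
#' optimum at the given resolution, one aggregation pass over the community
#' graph, and a final local moving round. Barcodes without any surviving
#' edge become singleton clusters. Labels are relabelled by decreasing
#' cluster size, contiguous from 0.
#'
#' @param W a sparse SNN weight matrix from [snn_graph].
#' @param resolution modularity resolution (default 1).
#' @param seed integer seed for the node visiting order.
#' @return A `ClusterAssignment`: list with `cluster` (named integer vector,
#'   one entry per barcode), `resolution` and `seed`.
#' @export
cluster_snn <- function(W, resolution = 1, seed = 1L) {
  n <- nrow(W)
  set.seed(seed)
  ord <- sample.int(n)
  comm <- seq_len(n)
  comm <- .local_move(W, comm, resolution, ord)
  # one aggregation pass: collapse communities and move again
  ids <- sort(unique(comm))
  cmap <- match(comm, ids)
  nc <- length(ids)
  Tm <- methods::as(W, "TsparseMatrix")
  Wc <- Matrix::sparseMatrix(i = cmap[Tm@i + 1L], j = cmap[Tm@j + 1L],
                             x = Tm@x, dims = c(nc, nc))
  ordc <- sample.int(nc)
  comm2 <- .local_move(Wc, seq_len(nc), resolution, ordc)
  comm <- comm2[cmap]
  labels <- .relabel_by_size(comm)
  structure(list(cluster = stats::setNames(labels, rownames(W)),
                 resolution = resolution, seed = as.integer(seed)),
            class = "ClusterAssignment")
}

#' Embed and cluster in one step
#'
#' @param nm a `NormMatrix`.
#' @param hvg an `HVGList` or gene vector (see [embed_pca]).
#' @param k number of principal components.
#' @param knn,prune SNN graph parameters (see [snn_graph]).
#' @param resolution,seed clustering parameters (see [cluster_snn]).
#' @return A `ClusterAssignment`.
#' @export
cluster_cells <- function(nm, hvg = NULL, k = 30, knn = 20, prune = 1 / 15,
                          resolution = 1, seed = 1L) {
  emb <- embed_pca(nm, hvg, k)
  cluster_snn(snn_graph(emb, knn, prune), resolution, seed)
}

#' Sweep clustering resolutions
#'
#' Reports the number of clusters at each resolution, for choosing a
#' resolution by inspection.
#'
#' @param W an SNN weight matrix.
#' @param resolutions numeric vector of resolutions.
#' @param seed seed passed to [cluster_snn].
#' @return Data frame with columns `resolution` and `n_clusters`.
#' @export
sweep_resolution <- function(W, resolutions = c(0.2, 0.5, 1, 1.5, 2),
                             seed = 1L) {
  data.frame(resolution = resolutions,
             n_clusters = vapply(resolutions, function(r)
               length(unique(cluster_snn(W, r, seed)$cluster)), integer(1)))
}
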