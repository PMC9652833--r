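norm_from_values <- function(vals, genes, barcodes) {
  structure(list(values = Matrix::Matrix(vals, sparse = TRUE),
                 size_factors = rep(1, length(barcodes)), genes = genes,
                 barcodes = barcodes, modality = "cells"),
            class = "NormMatrix")
}

test_that("rank-1 data loads entirely on the first component", {
  set.seed(4)
  t_ <- runif(20)
  vals <- outer(c(1, 2, 3), t_)              # 3 genes on a line
  nm <- norm_from_values(vals, paste0("g", 1:3), paste0("b", 1:20))
  emb <- suppressWarnings(embed_pca(nm, k = 2))
  expect_gt(emb$var[1] / sum(emb$var), 1 - 1e-10)
})

test_that("duplicated barcodes map to identical coordinates and variances
           are non-increasing", {
  set.seed(5)
  vals <- matrix(rnorm(30 * 40), 30, 40)
  vals[, 2] <- vals[, 1]
  nm <- norm_from_values(abs(vals), paste0("g", 1:30), paste0("b", 1:40))
  emb <- embed_pca(nm, k = 10)
  expect_equal(emb$coords[1, ], emb$coords[2, ], ignore_attr = TRUE)
  expect_true(all(diff(emb$var) <= 1e-10))
})

test_that("excessive k is truncated with a warning", {
  nm <- norm_from_values(matrix(rexp(5 * 8), 5, 8), paste0("g", 1:5),
                         paste0("b", 1:8))
  expect_warning(emb <- embed_pca(nm, k = 20), "truncated")
  expect_lte(ncol(emb$coords), 5)
})

blob_embedding <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  rownames(coords) <- sprintf("b%03d", seq_len(nrow(coords)))
  structure(list(coords = coords, var = c(1, 1)), class = "Embedding")
}

test_that("two well-separated blobs give exactly their two clusters", {
  emb <- blob_embedding(40, rbind(c(0, 0), c(10, 10)))
  ca <- cluster_snn(snn_graph(emb, knn = 15), seed = 3)
  expect_equal(length(unique(ca$cluster)), 2)
  expect_equal(length(unique(ca$cluster[1:40])), 1)
  expect_equal(length(unique(ca$cluster[41:80])), 1)
})

test_that("clustering is deterministic under a fixed seed", {
  emb <- blob_embedding(30, rbind(c(0, 0), c(4, 0), c(0, 4)), sd = 0.8)
  W <- snn_graph(emb, knn = 12)
  expect_identical(cluster_snn(W, 1, 7)$cluster, cluster_snn(W, 1, 7)$cluster)
})

test_that("clusters never span disconnected graph components", {
  # two 4-cliques with no edges between them
  W <- Matrix::bdiag(matrix(1, 4, 4) - diag(4), matrix(1, 4, 4) - diag(4))
  rownames(W) <- colnames(W) <- paste0("n", 1:8)
  ca <- cluster_snn(methods::as(W, "CsparseMatrix"), 1, 2)
  expect_equal(length(unique(ca$cluster[1:4])), 1)
  expect_equal(length(unique(ca$cluster[5:8])), 1)
  expect_false(ca$cluster[1] == ca$cluster[5])
})

test_that("higher resolution does not give fewer clusters (loose trend)", {
  emb <- blob_embedding(25, rbind(c(0, 0), c(3, 0), c(0, 3), c(3, 3)),
                        sd = 0.7)
  W <- snn_graph(emb, knn = 10)
  sw <- sweep_resolution(W, c(0.2, 2), seed = 1)
  expect_gte(sw$n_clusters[sw$resolution == 2],
             sw$n_clusters[sw$resolution == 0.2])
})

test_that("planted identities are recovered and match an independent
           community-detection implementation", {
  pair <- small_pair()
  cm <- filter_genes(keep_barcodes(pair$cells,
                                   filter_barcodes(compute_qc(pair$cells))))
  nm <- normalize_counts(cm)
  emb <- embed_pca(nm, select_hvg(nm, 400), k = 15)
  W <- snn_graph(emb, knn = 15)
  ca <- cluster_snn(W, 1, 5)
  lab <- truth_labels(pair$truth, "cells")[nm$barcodes]
  keep <- !startsWith(lab, "doublet") & lab != "lowq"
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(ca$cluster[keep], lab[keep]), 0.8)
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "max", weighted = TRUE)
  ref <- igraph::cluster_louvain(g)
  expect_gte(mclust::adjustedRandIndex(ca$cluster,
                                       igraph::membership(ref)), 0.8)
})
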