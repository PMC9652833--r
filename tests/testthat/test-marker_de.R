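test_that("the exact rank-sum path reproduces enumerated p-values", {
  expect_equal(rank_sum_p(1:3, 4:6, exact = TRUE), 0.1)
  expect_equal(rank_sum_p(4:6, 1:3, exact = TRUE), 0.1)   # symmetry
  expect_equal(rank_sum_p(c(1, 2), c(1, 2), exact = TRUE), 1)
  expect_error(rank_sum_p(1:6, 1:6, exact = TRUE), "<= 10")
  expect_error(rank_sum_p(numeric(0), 1:3), "empty group")
})

test_that("the normal approximation is calibrated against wilcox.test", {
  set.seed(19)
  for (i in 1:25) {
    x <- rnorm(sample(5:30, 1))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(rank_sum_p(x, y, exact = FALSE), ref, tolerance = 1e-10)
  }
  # identical multisets: p = 1 under the continuity correction
  expect_equal(rank_sum_p(rep(1:4, 3), rep(1:4, 3)), 1)
  # symmetry under group exchange
  x <- rpois(12, 3); y <- rpois(9, 4)
  expect_equal(rank_sum_p(x, y), rank_sum_p(y, x))
})

test_that("log2 fold change uses de-logged means with pseudocount 1", {
  cl <- rep(log(1 + 3), 5)                     # de-logged mean 3
  rest <- rep(log(1 + 1), 7)                   # de-logged mean 1
  expect_equal(log2fc(cl, rest), 1)            # log2(4 / 2)
  expect_equal(log2fc(rest, rest), 0)
  # increasing cluster expression strictly increases the fold change
  lf <- sapply(c(1, 2, 4, 8), function(s) log2fc(log(1 + s * 2), rest))
  expect_true(all(diff(lf) > 0))
})

test_that("BH adjustment matches the hand example and brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  brute_bh <- function(p) {
    m <- length(p)
    sapply(seq_len(m), function(i)
      min(1, min(sapply(which(p >= p[i] - 1e-15), function(j)
        p[j] * m / sum(p <= p[j] + 1e-15)))))
  }
  set.seed(23)
  for (i in 1:40) {
    p <- round(runif(sample(1:25, 1)), 3)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("the fold-change cutoff is strict around 0.25", {
  # one gene just below and one just above the threshold, both with tiny p
  n1 <- 40; n2 <- 40
  below <- c(rep(log(1.18), n1), rep(0, n2))   # lfc = log2(2.18/2) < 0.25
  above <- c(rep(log(1.40), n1), rep(0, n2))   # lfc = log2(2.40/2) > 0.25
  vals <- rbind(below, above, rep(0.5, n1 + n2))
  nm <- structure(list(values = Matrix::Matrix(vals, sparse = TRUE),
                       size_factors = rep(1, n1 + n2),
                       genes = c("below", "above", "flat"),
                       barcodes = sprintf("b%02d", seq_len(n1 + n2)),
                       modality = "cells"), class = "NormMatrix")
  ca <- structure(list(cluster = setNames(rep(0:1, c(n1, n2)),
                                          nm$barcodes),
                       resolution = 1, seed = 1),
                  class = "ClusterAssignment")
  mt <- find_markers(nm, ca)
  r <- mt[mt$cluster == 0 & mt$gene %in% c("below", "above"), ]
  expect_lt(r$p_adj[r$gene == "above"], 0.05)
  expect_false(r$significant[r$gene == "below"])
  expect_true(r$significant[r$gene == "above"])
})

test_that("planted markers are significant only in their own cluster", {
  pair <- small_pair()
  cm <- filter_genes(keep_barcodes(pair$cells,
                                   filter_barcodes(compute_qc(pair$cells))))
  nm <- normalize_counts(cm)
  lab <- truth_labels(pair$truth, "cells")[nm$barcodes]
  keep <- !startsWith(lab, "doublet") & lab != "lowq"
  nm$values <- nm$values[, keep]
  nm$barcodes <- nm$barcodes[keep]
  nm$size_factors <- nm$size_factors[keep]
  ids <- sort(unique(lab[keep]))
  ca <- structure(list(cluster = setNames(match(lab[keep], ids) - 1L,
                                          nm$barcodes),
                       resolution = 1, seed = 1),
                  class = "ClusterAssignment")
  mt <- find_markers(nm, ca)
  gcls <- pair$truth$genes
  for (k in seq_along(ids)) {
    mk <- intersect(gcls$gene[gcls$class == paste0("marker-of-", ids[k])],
                    nm$genes)
    own <- mt[mt$cluster == k - 1 & mt$gene %in% mk, ]
    expect_true(all(own$significant))
    foreign <- mt[mt$cluster != k - 1 & mt$gene %in% mk, ]
    expect_true(all(!foreign$significant))
  }
})

test_that("shuffled labels yield almost no significant calls", {
  pair <- small_pair()
  cm <- filter_genes(keep_barcodes(pair$nuclei,
                                   filter_barcodes(compute_qc(pair$nuclei))))
  nm <- normalize_counts(cm)
  set.seed(55)
  fake <- structure(list(cluster = setNames(
    sample(rep(0:2, length.out = length(nm$barcodes))), nm$barcodes),
    resolution = 1, seed = 1), class = "ClusterAssignment")
  mt <- find_markers(nm, fake)
  expect_lte(mean(mt$significant), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(mt)))
})

test_that("top markers follow the stated ordering and tie-breaks", {
  mt <- data.frame(
    cluster = 0L,
    gene = c("weak", "strong", "late", "insig"),
    log2fc = c(1.0, 2.0, 1.5, 3.0),
    p = c(1e-12, 1e-12, 1e-6, 0.5),
    p_adj = c(1e-10, 1e-10, 1e-5, 0.9),
    significant = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  class(mt) <- c("MarkerTable", "data.frame")
  top <- top_markers(mt, n = 4)[["0"]]
  expect_identical(top, c("strong", "weak", "late"))  # lfc breaks the tie
  expect_identical(top_markers(mt, n = 2)[["0"]], c("strong", "weak"))
  expect_true(all(top %in% mt$gene[mt$significant]))
})
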