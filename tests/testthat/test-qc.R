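test_that("per-barcode percentages are exact on a hand-built barcode", {
  m <- matrix(c(10, 20, 5, 65), 4, 1)
  cm <- CountMatrix(m, c("mt:CoI", "RpL3", "Hsp23", "dpp"), "bc1", "cells")
  qc <- compute_qc(cm)
  expect_equal(qc$n_genes_detected, 4L)
  expect_equal(qc$pct_mito, 10)
  expect_equal(qc$pct_ribo, 20)
  expect_equal(qc$pct_hsp, 5)
})

test_that("all-zero barcodes get zero metrics and are dropped as too few", {
  m <- cbind(c(500, 500), c(0, 0))
  cm <- CountMatrix(m, c("gA", "gB"), c("full", "void"), "cells")
  qc <- filter_barcodes(compute_qc(cm))
  expect_equal(qc$n_genes_detected[2], 0L)
  expect_equal(qc$pct_mito[2], 0)
  expect_identical(as.character(qc$drop_reason[2]), "too_few_genes")
})

test_that("cells gene-count bounds are strict: 300 and 3000 are kept", {
  qc <- filter_barcodes(fake_qc(c(200, 300, 1500, 3000, 3500)), "cells")
  expect_identical(qc$keep, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(as.character(qc$drop_reason[c(1, 5)]),
                   c("too_few_genes", "too_many_genes"))
})

test_that("the mitochondrial bound is strict: exactly 10% is kept", {
  qc <- filter_barcodes(fake_qc(c(1000, 1000, 1000),
                                pct_mito = c(10, 10.0001, 9.99)), "cells")
  expect_identical(qc$keep, c(TRUE, FALSE, TRUE))
  expect_identical(as.character(qc$drop_reason[2]), "high_mito")
})

test_that("nuclei top-1% rule uses the interpolated 99th percentile", {
  qc <- filter_barcodes(fake_qc(301:500, modality = "nuclei"), "nuclei")
  expect_equal(attr(qc, "top1pct_threshold"), 498.01)
  dropped <- qc$barcode[!qc$keep]
  expect_identical(qc$n_genes_detected[!qc$keep], c(499L, 500L))
  expect_true(all(qc$drop_reason[!qc$keep] == "top1pct_genes"))
  # the threshold is frozen: re-filtering the kept subset drops nothing
  kept <- qc[qc$keep, ]
  attr(kept, "modality") <- "nuclei"
  attr(kept, "top1pct_threshold") <- attr(qc, "top1pct_threshold")
  class(kept) <- c("QCTable", "data.frame")
  again <- filter_barcodes(kept, "nuclei")
  expect_true(all(again$keep))
})

test_that("drop reasons are assigned in order and partition the drops", {
  qc <- filter_barcodes(fake_qc(c(100, 100, 5000, 1000),
                                pct_mito = c(50, 0, 50, 50)), "cells")
  # too-few wins over high-mito; too-many wins over high-mito
  expect_identical(as.character(qc$drop_reason),
                   c("too_few_genes", "too_few_genes", "too_many_genes",
                     "high_mito"))
  expect_equal(sum(qc$keep) + sum(!qc$keep), nrow(qc))
  expect_true(all(qc$keep == (qc$drop_reason == "none")))
})

test_that("gene support thresholds are exact: 5 cells / 3 nuclei", {
  m <- rbind(c(1, 1, 1, 1, 0, 0), # 4 barcodes
             c(1, 1, 1, 1, 1, 0), # 5 barcodes
             c(1, 1, 1, 0, 0, 0), # 3 barcodes
             rep(1, 6))           # ubiquitous
  genes <- c("four", "five", "three", "all")
  cells <- CountMatrix(m, genes, paste0("b", 1:6), "cells")
  expect_identical(filter_genes(cells)$genes, c("five", "all"))
  nuclei <- CountMatrix(m, genes, paste0("b", 1:6), "nuclei")
  expect_identical(filter_genes(nuclei)$genes,
                   c("four", "five", "three", "all"))
  ubi <- CountMatrix(matrix(1, 2, 6), c("x", "y"), paste0("b", 1:6), "cells")
  expect_identical(filter_genes(ubi)$genes, c("x", "y"))
  expect_error(filter_genes(CountMatrix(matrix(c(1, rep(0, 5)), 1, 6),
                                        "solo", paste0("b", 1:6), "cells")),
               "no gene passes")
})

test_that("filtering is idempotent on already-filtered data", {
  pair <- small_pair()
  qc <- filter_barcodes(compute_qc(pair$cells))
  cm <- filter_genes(keep_barcodes(pair$cells, qc))
  qc2 <- filter_barcodes(compute_qc(cm))
  expect_true(all(qc2$keep))
  expect_identical(filter_genes(cm)$genes, cm$genes)
})

test_that("planted low-quality barcodes are dropped as too few genes", {
  p <- sim_params(n_types = 3, cells_per_type = 60, lowq_rate = 0.15,
                  doublet_rate = 0, n_background_genes = 400, seed = 13)
  pair <- generate_pair(p)
  lab <- truth_labels(pair$truth, "cells")
  qc <- filter_barcodes(compute_qc(pair$cells))
  lowq <- names(lab)[lab == "lowq"]
  idx <- match(lowq, qc$barcode)
  expect_true(all(!qc$keep[idx]))
  expect_true(all(qc$drop_reason[idx] == "too_few_genes"))
})
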