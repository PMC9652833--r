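test_that("a coordinate triplet is transcribed verbatim into counts", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 2", "1 1 3", "2 2 1"), file.path(d, "matrix.mtx"))
  writeLines(c("FBgn01\tgeneA\tGene Expression",
               "FBgn02\tgeneB\tGene Expression"), file.path(d, "features.tsv"))
  writeLines(c("AAAC-1", "AAAG-1"), file.path(d, "barcodes.tsv"))
  cm <- read_10x(d, "cells")
  expect_equal(as.matrix(cm$counts),
               matrix(c(3, 0, 0, 1), 2, 2,
                      dimnames = list(c("geneA", "geneB"),
                                      c("AAAC-1", "AAAG-1"))))
  expect_identical(cm$modality, "cells")
})

test_that("write_10x / read_10x round-trips, including the empty matrix", {
  set.seed(3)
  m <- matrix(rpois(35, 0.8), 7, 5)
  cm <- CountMatrix(m, paste0("g", 1:7), paste0("bc", 1:5), "nuclei")
  d <- withr::local_tempdir()
  write_10x(cm, d)
  hdr <- readLines(file.path(d, "matrix.mtx"), n = 1)
  expect_identical(hdr, "%%MatrixMarket matrix coordinate integer general")
  back <- read_10x(d, "nuclei")
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
  expect_identical(back$genes, cm$genes)
  expect_identical(back$barcodes, cm$barcodes)

  empty <- CountMatrix(matrix(0L, 3, 2), paste0("g", 1:3), c("a", "b"),
                       "cells")
  d2 <- withr::local_tempdir()
  write_10x(empty, d2)
  expect_identical(readLines(file.path(d2, "matrix.mtx"))[2], "3 2 0")
  back2 <- read_10x(d2, "cells")
  expect_equal(as.matrix(back2$counts), as.matrix(empty$counts))
})

test_that("malformed triplets are rejected with informative errors", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 1", "1 1 3"), file.path(d, "matrix.mtx"))
  writeLines(c("a\tgA", "b\tgB", "c\tgC"), file.path(d, "features.tsv"))
  writeLines(c("bc1", "bc2"), file.path(d, "barcodes.tsv"))
  expect_error(read_10x(d), "dimension mismatch.*features")

  writeLines(c("a\tgA", "b\tgB"), file.path(d, "features.tsv"))
  writeLines(c("bc1", "bc1"), file.path(d, "barcodes.tsv"))
  expect_error(read_10x(d), "duplicate barcode.*bc1")
})

test_that("count invariants are enforced, duplicate symbols disambiguated", {
  expect_error(CountMatrix(matrix(-1, 1, 1), "g", "b", "cells"),
               "non-negative")
  expect_error(CountMatrix(matrix(1.5, 1, 1), "g", "b", "cells"),
               "integral")
  expect_error(CountMatrix(matrix(1, 1, 1), "g", c("b", "b"), "cells"),
               "barcodes")
  bad <- structure(list(counts = Matrix::Matrix(-2, 1, 1, sparse = TRUE),
                        genes = "g", barcodes = "b", modality = "cells"),
                   class = "CountMatrix")
  expect_error(write_10x(bad, withr::local_tempdir()), "negative")

  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 1 0"), file.path(d, "matrix.mtx"))
  writeLines(c("x\tdup", "y\tdup"), file.path(d, "features.tsv"))
  writeLines("bc1", file.path(d, "barcodes.tsv"))
  expect_identical(read_10x(d)$genes, c("dup", "dup.1"))
})

test_that("marker matrix parsing collapses duplicates and checks weights", {
  d <- withr::local_tempdir()
  p <- file.path(d, "mm.tsv")
  writeLines(c("identity\tgene", "PhR\tgl", "PhR\tscrt", "Antenna\tDll"), p)
  mm <- read_marker_matrix(p)
  expect_identical(mm$identities, c("PhR", "Antenna"))
  expect_identical(names(mm$markers$PhR), c("gl", "scrt"))

  writeLines(c("identity\tgene\tweight", "PhR\tgl\t1", "PhR\tgl\t3"), p)
  mm2 <- read_marker_matrix(p)
  expect_equal(unname(mm2$markers$PhR["gl"]), 3)
  expect_length(mm2$markers$PhR, 1)

  writeLines(c("identity\tgene\tweight", "PhR\tgl\t0"), p)
  expect_error(read_marker_matrix(p), "weights must be > 0")
  writeLines(c("identity\tsymbol", "PhR\tgl"), p)
  expect_error(read_marker_matrix(p), "missing column")
})

test_that("merge maps keep pipes verbatim and reject conflicts", {
  d <- withr::local_tempdir()
  p <- file.path(d, "map.tsv")
  writeLines(c("fine_label\tcombined_label", "MFurrow|SMW\tMFurrow"), p)
  mp <- read_merge_map(p)
  expect_identical(unname(mp["MFurrow|SMW"]), "MFurrow")

  writeLines(c("fine_label\tcombined_label", "Dorsal|Ocelli\tDorsal",
               "Dorsal|Ocelli\tOcelli"), p)
  expect_error(read_merge_map(p), "conflicting.*Dorsal\\|Ocelli")

  writeLines("fine_label\tcombined_label", p)
  empty <- read_merge_map(p)
  expect_length(empty, 0)
  ar <- assign_identities(
    structure(matrix(1, 1, 1, dimnames = list("A", "0")),
              class = c("ScoreHeatmap", "matrix")))
  expect_error(merge_labels(ar, empty), "missing from the merge map")
})
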