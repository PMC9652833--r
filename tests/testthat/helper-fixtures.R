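# Shared fixtures. Heavy objects are memoized so expensive simulations and
# pipeline runs are computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small hand-built count matrix: 4 genes x 3 barcodes.
tiny_cm <- function(modality = "cells") {
  m <- rbind(c(3L, 0L, 1L),
             c(0L, 1L, 0L),
             c(2L, 2L, 0L),
             c(0L, 0L, 5L))
  CountMatrix(m, c("gA", "gB", "mt:CoI", "RpS5"),
              c("b1", "b2", "b3"), modality)
}

# Small simulated pair: 5 identities x 60 barcodes per modality.
small_pair <- function() {
  memo("small_pair", generate_pair(sim_params(
    n_types = 5, cells_per_type = 60, n_background_genes = 400, seed = 42)))
}

# QC table with prescribed metrics, for boundary-rule tests.
fake_qc <- function(n_genes, pct_mito = rep(0, length(n_genes)),
                    modality = "cells") {
  qct <- data.frame(barcode = sprintf("b%03d", seq_along(n_genes)),
                    n_genes_detected = as.integer(n_genes),
                    pct_mito = pct_mito, pct_ribo = 0, pct_hsp = 0,
                    keep = NA, drop_reason = NA_character_,
                    stringsAsFactors = FALSE)
  attr(qct, "modality") <- modality
  class(qct) <- c("QCTable", "data.frame")
  qct
}

# Marker table with prescribed significant sets, for annotation tests.
fake_marker_table <- function(sig_sets) {
  rows <- do.call(rbind, lapply(names(sig_sets), function(k) {
    g <- sig_sets[[k]]
    if (!length(g)) g <- "placeholder.gene"
    data.frame(cluster = as.integer(k), gene = g, log2fc = 1, p = 1e-6,
               p_adj = 1e-5,
               significant = !identical(sig_sets[[k]], character(0)),
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("MarkerTable", "data.frame")
  rows
}

# Full pipeline run at the generator's default study conditions
# (11 identities x 200 barcodes per modality).
default_run <- function() {
  memo("default_run",
       suppressWarnings(run_pipeline(list(seed = 101))))
}

# Reduced-size pipeline config for determinism checks.
reduced_config <- function(out_dir, seed = 7) {
  list(seed = seed, out_dir = out_dir,
       sim = list(n_types = 5, cells_per_type = 60,
                  n_background_genes = 400))
}

# Fraction of clusters (of at least `minsz` barcodes) whose assigned label
# equals the dominant planted identity of their members.
recovery_fraction <- function(ca, ar, truth_lab, minsz = 3) {
  ok <- vapply(names(ar$labels), function(k) {
    b <- names(ca$cluster)[ca$cluster == as.integer(k)]
    if (length(b) < minsz) return(NA)
    tt <- truth_lab[b]
    tt <- tt[!startsWith(tt, "doublet") & tt != "lowq"]
    if (!length(tt)) return(NA)
    ar$labels[[k]] == names(sort(table(tt), decreasing = TRUE))[1]
  }, logical(1))
  mean(ok, na.rm = TRUE)
}
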