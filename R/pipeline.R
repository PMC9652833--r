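# End-to-end orchestration: simulate (or read) -> QC -> normalize -> HVG ->
# embed/cluster -> markers -> annotate/merge -> integrate -> compare.
# One root seed; each stage draws from a deterministic offset of it.

.default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    input = list(cells_dir = NULL, nuclei_dir = NULL,
                 marker_matrix = NULL, merge_map = NULL),
    sim = list(n_types = 11L, cells_per_type = 200L,
               n_marker_genes_per_type = 8L, n_background_genes = 1000L,
               marker_fold = 8, base_depth = 2000,
               mito_fail_fraction_cells = 0.14,
               mito_fail_fraction_nuclei = 2e-4,
               ribo_fraction_cells = 0.20, ribo_reduction_nuclei = 0.28,
               hsp_fraction_cells = 0.06, hsp_fraction_nuclei = 0.002,
               doublet_rate = 0.03, lowq_rate = 0.03),
    qc = list(min_genes = 300L, max_genes_cells = 3000L,
              nuclei_top_quantile = 0.99, max_pct_mito = 10,
              min_support_cells = 5L, min_support_nuclei = 3L),
    hvg = list(n = 3000L, nbins = 20L),
    cluster = list(pcs = 30L, knn = 20L, prune = 1 / 15, resolution = 1.0),
    markers = list(min_pct = 0.1, logfc_cut = 0.25, alpha = 0.05,
                   top_n = 4L),
    integrate = list(n_features = 3000L)
  )
}

.merge_config <- function(defaults, cfg, path = "") {
  for (key in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(cfg[[key]])) {
      if (!is.list(cfg[[key]]))
        stop("config key ", full, " must be a section")
      defaults[[key]] <- .merge_config(defaults[[key]], cfg[[key]], full)
    } else {
      defaults[key] <- cfg[key]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every missing parameter with its default (the QC thresholds,
#' marker cutoffs, HVG count and top-n defaults of the workflow) and
#' rejects unknown keys by name.
#'
#' @param cfg nested list (possibly empty) of overrides.
#' @return A fully populated `PipelineConfig` list.
#' @export
validate_config <- function(cfg = list()) {
  out <- .merge_config(.default_config(), cfg)
  if (is.null(out$seed) || is.na(suppressWarnings(as.integer(out$seed))))
    stop("seed must be an integer")
  out$seed <- as.integer(out$seed)
  if (out$hvg$n < 1) stop("hvg.n must be >= 1")
  if (out$markers$top_n < 1) stop("markers.top_n must be >= 1")
  if (out$qc$min_genes < 0 || out$qc$max_genes_cells <= out$qc$min_genes)
    stop("qc gene bounds are inconsistent")
  if (out$qc$nuclei_top_quantile <= 0 || out$qc$nuclei_top_quantile >= 1)
    stop("qc.nuclei_top_quantile must lie in (0, 1)")
  for (f in c("mito_fail_fraction_cells", "mito_fail_fraction_nuclei",
              "ribo_fraction_cells", "ribo_reduction_nuclei",
              "hsp_fraction_cells", "hsp_fraction_nuclei",
              "doublet_rate", "lowq_rate"))
    if (out$sim[[f]] < 0 || out$sim[[f]] > 1)
      stop("sim.", f, " must lie in [0, 1]")
  class(out) <- "PipelineConfig"
  out
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the config structure; `seed` required.
#' @return A validated `PipelineConfig`.
#' @export
config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config file must set a seed")
  validate_config(cfg)
}

# Analysis of one modality: QC -> filters -> normalize -> HVG -> cluster ->
# markers -> annotation.
.run_modality <- function(cm, cfg, mm, map, seed) {
  qct <- compute_qc(cm)
  qct <- filter_barcodes(qct, cm$modality,
                         min_genes = cfg$qc$min_genes,
                         max_genes = cfg$qc$max_genes_cells,
                         top_quantile = cfg$qc$nuclei_top_quantile,
                         max_pct_mito = cfg$qc$max_pct_mito)
  filtered <- keep_barcodes(cm, qct)
  support <- if (cm$modality == "cells") cfg$qc$min_support_cells else
    cfg$qc$min_support_nuclei
  filtered <- filter_genes(filtered, min_support = support)
  nm <- normalize_counts(filtered)
  hvg <- select_hvg(nm, n = cfg$hvg$n, nbins = cfg$hvg$nbins)
  ca <- cluster_cells(nm, hvg, k = cfg$cluster$pcs, knn = cfg$cluster$knn,
                      prune = cfg$cluster$prune,
                      resolution = cfg$cluster$resolution, seed = seed)
  mt <- find_markers(nm, ca, min_pct = cfg$markers$min_pct,
                     logfc_cut = cfg$markers$logfc_cut,
                     alpha = cfg$markers$alpha)
  sh <- score_clusters(mt, mm, gene_universe = nm$genes,
                       clusters = ca$cluster)
  ar <- merge_labels(assign_identities(sh), map)
  list(qc = qct, filtered = filtered, norm = nm, hvg = hvg, clusters = ca,
       markers = mt, scores = sh, annotation = ar,
       top_markers = top_markers(mt, cfg$markers$top_n))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full paired-comparison pipeline
#'
#' Obtains a paired dataset (from the synthetic generator, or from 10x
#' triplets named in `cfg$input`), runs the per-modality analysis for cells
#' and nuclei, integrates both, and computes the comparison report. If
#' `cfg$out_dir` is set, stage outputs are written as TSV files and their
#' checksums recorded in the manifest.
#'
#' @param cfg a [validate_config] configuration (a plain list is validated
#'   first).
#' @return A list with `cells`, `nuclei` (per-modality stage outputs),
#'   `joint` (the `JointAssignment` plus joint annotation), `report` (the
#'   `ComparisonReport`), `truth` (synthetic runs only) and `manifest`.
#' @export
run_pipeline <- function(cfg = list()) {
  if (!inherits(cfg, "PipelineConfig")) cfg <- validate_config(cfg)
  seeds <- cfg$seed + c(sim = 0L, cells = 1L, nuclei = 2L, joint = 3L)
  truth <- NULL
  if (!is.null(cfg$input$cells_dir)) {
    if (is.null(cfg$input$nuclei_dir) || is.null(cfg$input$marker_matrix))
      stop("input mode needs cells_dir, nuclei_dir and marker_matrix")
    cells <- read_10x(cfg$input$cells_dir, "cells")
    nuclei <- read_10x(cfg$input$nuclei_dir, "nuclei")
    mm <- read_marker_matrix(cfg$input$marker_matrix)
    map <- if (is.null(cfg$input$merge_map))
      identity_merge_map(c(.all_labels(mm))) else
      read_merge_map(cfg$input$merge_map)
  } else {
    sp <- do.call(sim_params, c(cfg$sim, list(seed = seeds[["sim"]])))
    pair <- generate_pair(sp)
    cells <- pair$cells; nuclei <- pair$nuclei; truth <- pair$truth
    mm <- truth_marker_matrix(truth)
    map <- identity_merge_map(.all_labels(mm))
  }

  res_c <- .run_modality(cells, cfg, mm, map, seeds[["cells"]])
  res_n <- .run_modality(nuclei, cfg, mm, map, seeds[["nuclei"]])

  ja <- integrate_pair(res_c$norm, res_n$norm,
                       n_features = cfg$integrate$n_features,
                       k = cfg$cluster$pcs, knn = cfg$cluster$knn,
                       prune = cfg$cluster$prune,
                       resolution = cfg$cluster$resolution,
                       seed = seeds[["joint"]])
  jnm <- joint_norm_matrix(res_c$norm, res_n$norm)
  jca <- structure(list(cluster = ja$cluster, resolution = ja$resolution,
                        seed = ja$seed), class = "ClusterAssignment")
  jmt <- find_markers(jnm, jca, min_pct = cfg$markers$min_pct,
                      logfc_cut = cfg$markers$logfc_cut,
                      alpha = cfg$markers$alpha)
  jsh <- score_clusters(jmt, mm, gene_universe = jnm$genes,
                        clusters = jca$cluster)
  jar <- merge_labels(assign_identities(jsh), map)
  joint_labels <- barcode_labels(jca, jar)

  contrib <- contribution(ja, labels = joint_labels)
  venn <- venn_counts(res_c$hvg$gene, res_n$hvg$gene)
  deov <- de_overlap_by_label(res_c$markers, res_c$annotation,
                              res_n$markers, res_n$annotation)
  trans <- list(
    cells = transitions(barcode_labels(res_c$clusters, res_c$annotation),
                        joint_labels),
    nuclei = transitions(barcode_labels(res_n$clusters, res_n$annotation),
                         joint_labels))
  report <- structure(
    list(venn = venn, contribution = contrib, de_overlap = deov,
         transitions = trans,
         correction_factor = attr(contrib, "correction_factor")),
    class = "ComparisonReport")

  manifest <- list(
    config = unclass(cfg),
    version = as.character(utils::packageVersion("discpair")),
    timestamp = format(Sys.time(), tz = "UTC"),
    counts = list(
      cells = c(barcodes_in = length(cells$barcodes),
                barcodes_kept = length(res_c$filtered$barcodes),
                genes_in = length(cells$genes),
                genes_kept = length(res_c$filtered$genes),
                clusters = length(unique(res_c$clusters$cluster))),
      nuclei = c(barcodes_in = length(nuclei$barcodes),
                 barcodes_kept = length(res_n$filtered$barcodes),
                 genes_in = length(nuclei$genes),
                 genes_kept = length(res_n$filtered$genes),
                 clusters = length(unique(res_n$clusters$cluster))),
      joint = c(barcodes = length(ja$cluster),
                clusters = length(unique(ja$cluster)))))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      .write_tsv(res_c$qc, file.path(cfg$out_dir, "qc_cells.tsv")),
      .write_tsv(res_n$qc, file.path(cfg$out_dir, "qc_nuclei.tsv")),
      .write_tsv(res_c$markers, file.path(cfg$out_dir, "markers_cells.tsv")),
      .write_tsv(res_n$markers, file.path(cfg$out_dir, "markers_nuclei.tsv")),
      .write_tsv(data.frame(cluster = names(res_c$annotation$labels),
                            label = unname(res_c$annotation$labels)),
                 file.path(cfg$out_dir, "annotation_cells.tsv")),
      .write_tsv(data.frame(cluster = names(res_n$annotation$labels),
                            label = unname(res_n$annotation$labels)),
                 file.path(cfg$out_dir, "annotation_nuclei.tsv")),
      .write_tsv(contrib, file.path(cfg$out_dir, "contribution.tsv")),
      .write_tsv(deov, file.path(cfg$out_dir, "de_overlap.tsv")),
      .write_tsv(trans$cells, file.path(cfg$out_dir, "transitions_cells.tsv")),
      .write_tsv(trans$nuclei,
                 file.path(cfg$out_dir, "transitions_nuclei.tsv")),
      .write_tsv(data.frame(set = names(venn), count = as.integer(venn)),
                 file.path(cfg$out_dir, "venn.tsv")))
    manifest$checksums <- tools::md5sum(files)
  }

  list(cells = res_c, nuclei = res_n,
       joint = list(assignment = ja, markers = jmt, scores = jsh,
                    annotation = jar, labels = joint_labels),
       report = report, truth = truth, manifest = manifest)
}

.all_labels <- function(mm) {
  ids <- mm$identities
  duals <- if (length(ids) >= 2) {
    cmb <- utils::combn(sort(ids), 2)
    paste(cmb[1, ], cmb[2, ], sep = "|")
  } else character(0)
  c(ids, duals, "Other")
}

#' Per-disc sequencing-run arithmetic
#'
#' Summary arithmetic for a droplet run on pooled imaginal discs: barcodes
#' recovered per disc, the percentage of the expected cells per disc that
#' this represents, and mean reads per barcode. Counts are reported rounded
#' to the nearest integer; the percentage and the mean reads are reported
#' truncated at the printed precision (one decimal / integer), matching the
#' usual run-summary convention.
#'
#' @param n_barcodes estimated number of cells or nuclei recovered.
#' @param n_discs number of pooled discs.
#' @param total_reads total sequenced reads.
#' @param expected_cells_per_disc expected cells in one disc (default
#'   44000, a late third-instar eye-antennal disc).
#' @return List with `per_disc`, `pct_of_expected`, `mean_reads_per_barcode`
#'   and the exact unrounded values under `exact`.
#' @export
per_disc_summary <- function(n_barcodes, n_discs, total_reads,
                             expected_cells_per_disc = 44000) {
  per_disc <- n_barcodes / n_discs
  pct <- 100 * per_disc / expected_cells_per_disc
  mean_reads <- total_reads / n_barcodes
  list(per_disc = round(per_disc),
       pct_of_expected = floor(pct * 10) / 10,
       mean_reads_per_barcode = floor(mean_reads),
       exact = c(per_disc = per_disc, pct_of_expected = pct,
                 mean_reads_per_barcode = mean_reads))
}
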