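# Synthetic paired cells/nuclei generator with planted ground truth.
#
# Each barcode's counts are a multinomial draw over the gene universe with a
# negative-binomial depth. Identity structure comes from exclusive marker
# genes whose expected proportion within their own type is marker_fold times
# the background level; modality contrasts (mitochondrial failure rate,
# ribosomal load, heat-shock load, flatter expression in nuclei) are imposed
# as expected read-fraction blocks of the per-barcode probability vector.

.default_identities <- c(
  "Antenna", "EAB", "PhR", "MFurrow", "SMW", "PPN", "Interom",
  "Ventral PE", "Dorsal|Ocelli", "Hemocytes", "Other-background")

.mito_genes <- c("mt:CoI", "mt:CoII", "mt:CoIII", "mt:ND1", "mt:ND2",
                 "mt:ND4", "mt:ND5", "mt:Cyt-b", "mt:ATPase6", "mt:srRNA")
.ribo_genes <- c(paste0("RpS", c(2:9, 11:13, 15, 17:19)),
                 paste0("RpL", c(3:15)))
.hsp_genes  <- c("Hsp23", "Hsp26", "Hsp27", "Hsp60A", "Hsp67Ba", "Hsp68",
                 "Hsp70Aa", "Hsp70Ab", "Hsp70Ba", "Hsp83")

#' Parameters of the synthetic paired-disc generator
#'
#' Defaults encode the modality contrasts the generator emulates: about 14%
#' of cell barcodes (and almost no nuclei) exceed 10% mitochondrial reads,
#' nuclei carry 28% fewer ribosomal reads than cells, heat-shock load is
#' essentially cell-specific, and nuclei detect more genes per barcode
#' (flatter expression profile).
#'
#' @param n_types number of planted cell identities (>= 2).
#' @param identities identity labels; defaults to the eye-antennal disc set.
#' @param cells_per_type singlet barcodes per identity, per modality.
#' @param n_marker_genes_per_type exclusive marker genes planted per identity.
#' @param n_background_genes shared background genes.
#' @param marker_fold expected within-type enrichment of a marker over its
#'   background level (> 1).
#' @param base_depth mean UMI depth per barcode (negative-binomial mean).
#' @param depth_size negative-binomial size (dispersion) of depths.
#' @param mito_fail_fraction_cells,mito_fail_fraction_nuclei fraction of
#'   barcodes planted as mitochondrial failures (mito fraction drawn
#'   U(0.15, 0.35), i.e. always above the 10% QC threshold).
#' @param mito_base_cells,mito_base_nuclei baseline expected mitochondrial
#'   read fraction of healthy barcodes.
#' @param ribo_fraction_cells expected ribosomal read fraction in cells.
#' @param ribo_reduction_nuclei relative reduction of the ribosomal fraction
#'   in nuclei (0.28 = 28% fewer ribosomal reads).
#' @param hsp_fraction_cells,hsp_fraction_nuclei expected heat-shock read
#'   fractions per modality.
#' @param doublet_rate expected doublets per singlet barcode.
#' @param lowq_rate expected low-quality (shallow) barcodes per singlet.
#' @param flatten_nuclei exponent (< 1) applied to nuclei expression weights;
#'   flattens the profile so nuclei detect more genes per barcode.
#' @param dirichlet_conc concentration of the per-barcode multiplicative
#'   gamma noise on expression weights (larger = less noise).
#' @param seed integer seed; the whole pair is reproducible from it.
#' @return A validated `SimParams` list.
#' @export
sim_params <- function(n_types = 11,
                       identities = .default_identities[seq_len(n_types)],
                       cells_per_type = 200,
                       n_marker_genes_per_type = 8,
                       n_background_genes = 1000,
                       marker_fold = 8,
                       base_depth = 2000,
                       depth_size = 10,
                       mito_fail_fraction_cells = 0.14,
                       mito_fail_fraction_nuclei = 2e-4,
                       mito_base_cells = 0.02,
                       mito_base_nuclei = 0.004,
                       ribo_fraction_cells = 0.20,
                       ribo_reduction_nuclei = 0.28,
                       hsp_fraction_cells = 0.06,
                       hsp_fraction_nuclei = 0.002,
                       doublet_rate = 0.03,
                       lowq_rate = 0.03,
                       flatten_nuclei = 0.75,
                       dirichlet_conc = 50,
                       seed = 1L) {
  p <- list(n_types = as.integer(n_types), identities = as.character(identities),
            cells_per_type = as.integer(cells_per_type),
            n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
            n_background_genes = as.integer(n_background_genes),
            marker_fold = marker_fold, base_depth = base_depth,
            depth_size = depth_size,
            mito_fail_fraction_cells = mito_fail_fraction_cells,
            mito_fail_fraction_nuclei = mito_fail_fraction_nuclei,
            mito_base_cells = mito_base_cells,
            mito_base_nuclei = mito_base_nuclei,
            ribo_fraction_cells = ribo_fraction_cells,
            ribo_reduction_nuclei = ribo_reduction_nuclei,
            hsp_fraction_cells = hsp_fraction_cells,
            hsp_fraction_nuclei = hsp_fraction_nuclei,
            doublet_rate = doublet_rate, lowq_rate = lowq_rate,
            flatten_nuclei = flatten_nuclei,
            dirichlet_conc = dirichlet_conc, seed = as.integer(seed))
  if (p$n_types < 2) stop("n_types must be >= 2")
  if (length(p$identities) != p$n_types)
    stop("identities must have length n_types")
  if (anyDuplicated(p$identities)) stop("identities must be unique")
  if (p$marker_fold <= 1) stop("marker_fold must be > 1")
  fr <- c(p$mito_fail_fraction_cells, p$mito_fail_fraction_nuclei,
          p$mito_base_cells, p$mito_base_nuclei, p$ribo_fraction_cells,
          p$ribo_reduction_nuclei, p$hsp_fraction_cells,
          p$hsp_fraction_nuclei, p$doublet_rate, p$lowq_rate)
  if (any(fr < 0) || any(fr > 1))
    stop("all fractions must lie in [0, 1]")
  if (p$cells_per_type < 1 || p$n_marker_genes_per_type < 1 ||
      p$n_background_genes < 1)
    stop("counts must be positive")
  if (is.na(p$seed)) stop("seed is required")
  class(p) <- "SimParams"
  p
}

.sanitize_label <- function(x) gsub("[^A-Za-z0-9]+", ".", x)

# Gene universe and per-class weights, shared by both modalities.
.sim_gene_universe <- function(p) {
  marker_genes <- unlist(lapply(p$identities, function(id)
    paste0(.sanitize_label(id), ".mk", seq_len(p$n_marker_genes_per_type))))
  bg_genes <- sprintf("bg%04d", seq_len(p$n_background_genes))
  genes <- c(marker_genes, bg_genes, .mito_genes, .ribo_genes, .hsp_genes)
  cls <- c(rep(paste0("marker-of-", rep(p$identities,
                                        each = p$n_marker_genes_per_type)), 1),
           rep("background", p$n_background_genes),
           rep("mito", length(.mito_genes)),
           rep("ribo", length(.ribo_genes)),
           rep("hsp", length(.hsp_genes)))
  list(genes = genes, class = cls,
       idx_expr = seq_len(length(marker_genes) + p$n_background_genes),
       idx_mito = length(marker_genes) + p$n_background_genes +
         seq_along(.mito_genes),
       idx_ribo = length(marker_genes) + p$n_background_genes +
         length(.mito_genes) + seq_along(.ribo_genes),
       idx_hsp = length(marker_genes) + p$n_background_genes +
         length(.mito_genes) + length(.ribo_genes) + seq_along(.hsp_genes),
       marker_index = lapply(seq_along(p$identities), function(i)
         (i - 1L) * p$n_marker_genes_per_type +
           seq_len(p$n_marker_genes_per_type)))
}

# Expression-block weights per type: background weights are shared across
# types; a type's own markers sit at marker_fold x the median background
# weight, foreign markers at the median background weight.
.sim_type_weights <- function(p, uni) {
  n_mk <- p$n_types * p$n_marker_genes_per_type
  bg_w <- stats::rlnorm(p$n_background_genes, meanlog = 0, sdlog = 1)
  base_mk <- stats::median(bg_w)
  w <- matrix(rep(c(rep(base_mk, n_mk), bg_w), p$n_types),
              ncol = p$n_types)
  for (i in seq_len(p$n_types))
    w[uni$marker_index[[i]], i] <- base_mk * p$marker_fold
  w
}

.sim_class_weights <- function(uni) {
  list(mito = stats::rlnorm(length(uni$idx_mito), 0, 0.5),
       ribo = stats::rlnorm(length(uni$idx_ribo), 0, 0.5),
       hsp = stats::rlnorm(length(uni$idx_hsp), 0, 0.5))
}

# Assemble one barcode's gene probability vector from its expression-block
# weights and the target class fractions.
.sim_prob <- function(uni, expr_w, class_w, f_mito, f_ribo, f_hsp) {
  f_expr <- 1 - f_mito - f_ribo - f_hsp
  pr <- numeric(length(uni$genes))
  pr[uni$idx_expr] <- expr_w / sum(expr_w) * f_expr
  pr[uni$idx_mito] <- class_w$mito / sum(class_w$mito) * f_mito
  pr[uni$idx_ribo] <- class_w$ribo / sum(class_w$ribo) * f_ribo
  pr[uni$idx_hsp] <- class_w$hsp / sum(class_w$hsp) * f_hsp
  pr
}

.sim_modality <- function(p, uni, type_w, class_w, modality) {
  is_cells <- modality == "cells"
  f_ribo <- if (is_cells) p$ribo_fraction_cells else
    p$ribo_fraction_cells * (1 - p$ribo_reduction_nuclei)
  f_hsp <- if (is_cells) p$hsp_fraction_cells else p$hsp_fraction_nuclei
  mito_base <- if (is_cells) p$mito_base_cells else p$mito_base_nuclei
  mito_fail_frac <- if (is_cells) p$mito_fail_fraction_cells else
    p$mito_fail_fraction_nuclei
  flatten <- if (is_cells) 1 else p$flatten_nuclei

  n_singlet <- p$n_types * p$cells_per_type
  n_doublet <- stats::rbinom(1, n_singlet, p$doublet_rate)
  n_lowq <- stats::rbinom(1, n_singlet, p$lowq_rate)
  n_total <- n_singlet + n_doublet + n_lowq

  type_of <- rep(seq_len(p$n_types), each = p$cells_per_type)
  # per-barcode expression weights: type block x flattening x gamma noise
  expr_w_of <- function(ti) {
    w <- type_w[, ti] ^ flatten
    w * stats::rgamma(length(w), shape = p$dirichlet_conc,
                      rate = p$dirichlet_conc)
  }
  depth_of <- function(n)
    pmax(100L, stats::rnbinom(n, mu = p$base_depth, size = p$depth_size))

  counts <- matrix(0L, nrow = length(uni$genes), ncol = n_total)
  labels <- character(n_total)
  mito_fail <- logical(n_total)

  depths <- depth_of(n_singlet)
  fails <- stats::runif(n_singlet) < mito_fail_frac
  singlet_expr <- vector("list", n_singlet)
  for (b in seq_len(n_singlet)) {
    ew <- expr_w_of(type_of[b])
    singlet_expr[[b]] <- ew
    f_m <- if (fails[b]) stats::runif(1, 0.15, 0.35) else mito_base
    pr <- .sim_prob(uni, ew, class_w, f_m, f_ribo, f_hsp)
    counts[, b] <- stats::rmultinom(1, depths[b], pr)
    labels[b] <- p$identities[type_of[b]]
  }
  mito_fail[seq_len(n_singlet)] <- fails

  if (n_doublet > 0) {
    for (d in seq_len(n_doublet)) {
      b <- n_singlet + d
      pair <- sample.int(n_singlet, 2)
      ew <- (singlet_expr[[pair[1]]] + singlet_expr[[pair[2]]]) / 2
      pr <- .sim_prob(uni, ew, class_w, mito_base, f_ribo, f_hsp)
      counts[, b] <- stats::rmultinom(1, sum(depth_of(2)), pr)
      tys <- sort(p$identities[type_of[pair]])
      labels[b] <- paste0("doublet:", tys[1], "+", tys[2])
    }
  }
  if (n_lowq > 0) {
    for (l in seq_len(n_lowq)) {
      b <- n_singlet + n_doublet + l
      ti <- sample.int(p$n_types, 1)
      pr <- .sim_prob(uni, expr_w_of(ti), class_w, mito_base, f_ribo, f_hsp)
      # shallow depth: detected genes necessarily < 300
      counts[, b] <- stats::rmultinom(1, sample(40:150, 1), pr)
      labels[b] <- "lowq"
    }
  }

  prefix <- if (is_cells) "C" else "N"
  bcs <- sprintf("%s-%06d", prefix, seq_len(n_total))
  cm <- CountMatrix(counts, uni$genes, bcs, modality)
  truth <- data.frame(barcode = bcs, modality = modality, label = labels,
                      mito_fail = mito_fail, stringsAsFactors = FALSE)
  list(cm = cm, truth = truth)
}

#' Generate a paired cells/nuclei synthetic dataset
#'
#' Draws two [CountMatrix] objects over a common gene universe and identity
#' set, with planted singlet identities, doublets (sum of two singlet
#' profiles at ~2x depth), low-quality barcodes (depth so shallow that
#' detected genes < 300), planted mitochondrial failures, and the modality
#' contrasts described in [sim_params]. Fully reproducible from the seed.
#'
#' @param params a [sim_params] object.
#' @return A list with elements `cells`, `nuclei` (CountMatrix) and `truth`
#'   (a `SyntheticTruth`: `barcodes` data frame with per-barcode labels,
#'   `genes` data frame with per-gene classes, and the `params` used).
#' @export
generate_pair <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(params$seed)
  uni <- .sim_gene_universe(params)
  type_w <- .sim_type_weights(params, uni)
  class_w <- .sim_class_weights(uni)
  cells <- .sim_modality(params, uni, type_w, class_w, "cells")
  nuclei <- .sim_modality(params, uni, type_w, class_w, "nuclei")
  truth <- structure(
    list(barcodes = rbind(cells$truth, nuclei$truth),
         genes = data.frame(gene = uni$genes, class = uni$class,
                            stringsAsFactors = FALSE),
         params = params),
    class = "SyntheticTruth")
  list(cells = cells$cm, nuclei = nuclei$cm, truth = truth)
}

#' Summarize planted ground truth
#'
#' @param truth a `SyntheticTruth` from [generate_pair].
#' @return A list with `barcode_counts` (modality x label-category table of
#'   barcode counts; doublets and low-quality barcodes pooled under
#'   `"doublet"` / `"lowq"`) and `gene_counts` (gene-class table).
#' @export
summarize_truth <- function(truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  lab <- truth$barcodes$label
  lab[startsWith(lab, "doublet:")] <- "doublet"
  list(barcode_counts = table(modality = truth$barcodes$modality, label = lab),
       gene_counts = table(class = truth$genes$class))
}

#' Marker matrix of the planted identities
#'
#' Builds the identity x gene reference from the generator's planted marker
#' genes, for use as the annotation reference in recovery experiments.
#'
#' @param truth a `SyntheticTruth` from [generate_pair].
#' @return A `MarkerMatrix`.
#' @export
truth_marker_matrix <- function(truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  g <- truth$genes
  is_mk <- startsWith(g$class, "marker-of-")
  marker_matrix(sub("^marker-of-", "", g$class[is_mk]), g$gene[is_mk])
}

#' Per-barcode true identity labels
#'
#' @param truth a `SyntheticTruth`.
#' @param modality `"cells"` or `"nuclei"`.
#' @return Named character vector barcode -> planted label.
#' @export
truth_labels <- function(truth, modality = c("cells", "nuclei")) {
  modality <- match.arg(modality)
  b <- truth$barcodes[truth$barcodes$modality == modality, ]
  stats::setNames(b$label, b$barcode)
}
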