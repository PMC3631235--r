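#' Tiling-array PMi pipeline
#'
#' End-to-end driver: read annotation and probe table, assign probes to
#' intron/exon features, summarize by median, compute per-gene PMi, and
#' (optionally) write the result TSV, histogram TSV and a JSON run
#' manifest with the discarded-probe/gene accounting.
#'
#' @param annotation_path GFF3/BED12 annotation
#' @param probe_path probe intensity TSV
#' @param out_dir output directory, or NULL to skip writing
#' @param rp_genes curated RP gene-id list (GFF3 \code{rp} attribute
#'   also honoured)
#' @param min_probes minimum probes per feature
#' @param samples expected sample labels, or NULL to accept the header
#' @return list: \code{pmi} (PMi table), \code{distribution},
#'   \code{groups}, \code{manifest}
#' @export
run_tiling_pmi <- function(annotation_path, probe_path, out_dir = NULL,
                           rp_genes = NULL, min_probes = 3L,
                           samples = NULL) {
  genes <- read_gene_models(annotation_path, rp_genes = rp_genes)
  probes <- read_probe_table(probe_path, samples = samples)
  assignment <- map_probes_to_features(probes, genes)
  signals <- summarize_feature_signal(assignment, probes,
                                      min_probes = min_probes)
  pmi <- compute_pmi(signals, genes = genes)
  dist <- classify_pmi_distribution(pmi)
  groups <- group_summary(pmi)
  manifest <- list(
    n_genes_annotated = length(genes),
    n_genes_dropped_no_intron = attr(genes, "n_dropped") %||% 0L,
    n_probes = nrow(probes),
    n_probes_unassigned = attr(assignment, "n_unassigned"),
    n_probes_ambiguous = attr(assignment, "n_ambiguous"),
    n_probes_flagged_missing = attr(probes, "n_flagged"),
    n_genes_pmi = sum(pmi$status == "OK"),
    n_genes_na = sum(pmi$status == "NA"),
    na_reasons = as.list(table(pmi$reason[pmi$status == "NA"])))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(pmi, file.path(out_dir, "pmi.tsv"), sep = "\t")
    data.table::fwrite(dist$histogram,
                       file.path(out_dir, "pmi_histogram.tsv"), sep = "\t")
    data.table::fwrite(groups, file.path(out_dir, "pmi_groups.tsv"),
                       sep = "\t")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(pmi = pmi, distribution = dist, groups = groups,
       manifest = manifest)
}

#' TR analysis pipeline
#'
#' Normalizes a TR matrix, clusters the selected (complete) profiles,
#' computes dTR at 15 min and, when a PMi table is given, the
#' PMi-vs-dTR regression.
#'
#' @param tr_path TR TSV (genes x timepoints)
#' @param pmi optional PMi table (from \code{\link{run_tiling_pmi}} or
#'   \code{\link{compute_pmi}})
#' @param k clusters
#' @param seed clustering seed
#' @param out_dir output directory, or NULL
#' @return list: \code{profiles}, \code{clusters}, \code{dtr},
#'   \code{regression} (NULL without pmi)
#' @export
run_tr_analysis <- function(tr_path, pmi = NULL, k = 3L, seed = 1L,
                            out_dir = NULL) {
  tr <- read_tr_table(tr_path)
  profiles <- normalize_tr(tr)
  clusters <- kmeans_cluster(profiles, k = k, seed = seed)
  dtr <- delta_tr(profiles, t = 15)
  regression <- NULL
  if (!is.null(pmi)) {
    pv <- setNames(pmi$pmi, pmi$gene_id)
    regression <- regress_pmi_vs_dtr(dtr, pv)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(
      data.table(gene_id = names(clusters$assignments),
                 cluster = unname(clusters$assignments)),
      file.path(out_dir, "clusters.tsv"), sep = "\t")
    cent <- data.table::as.data.table(clusters$centroids)
    cent[, cluster := seq_len(nrow(clusters$centroids))]
    data.table::fwrite(cent, file.path(out_dir, "centroids.tsv"),
                       sep = "\t")
    if (!is.null(regression))
      jsonlite::write_json(
        regression[c("slope", "intercept", "r2", "t_stat", "p_value",
                     "df", "n")],
        file.path(out_dir, "regression.json"),
        auto_unbox = TRUE, digits = NA)
  }
  list(profiles = profiles, clusters = clusters, dtr = dtr,
       regression = regression)
}
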