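#' Assign tiling probes to gene features
#'
#' A probe is assigned to a gene's intron or exon only when its interval
#' is fully contained in that feature (strict containment rule: probes
#' straddling an exon/intron boundary carry mixed signal and are
#' discarded). Probes contained in features of more than one gene are
#' ambiguous and also discarded. Both counts are reported.
#'
#' @param probes probe table (\code{\link{read_probe_table}})
#' @param genes list of \code{gene_model}
#' @return data.table \code{probe_id, gene_id, feature} with attributes
#'   \code{n_unassigned} and \code{n_ambiguous}
#' @export
map_probes_to_features <- function(probes, genes) {
  feats <- data.table::rbindlist(lapply(genes, function(m) {
    rbind(
      data.table(gene_id = m$gene_id, chrom = m$chrom, feature = "exon",
                 start = m$exons[, 1L], end = m$exons[, 2L]),
      data.table(gene_id = m$gene_id, chrom = m$chrom, feature = "intron",
                 start = m$introns[, 1L], end = m$introns[, 2L])
    )
  }))
  if (nrow(probes) == 0L || nrow(feats) == 0L) {
    out <- data.table(probe_id = character(), gene_id = character(),
                      feature = character())
    data.table::setattr(out, "n_unassigned", nrow(probes))
    data.table::setattr(out, "n_ambiguous", 0L)
    return(out)
  }
  # half-open [start, end) -> closed [start, end-1] for IRanges
  pr <- GenomicRanges::GRanges(probes$chrom,
          IRanges::IRanges(probes$start + 1L, probes$end))
  fr <- GenomicRanges::GRanges(feats$chrom,
          IRanges::IRanges(feats$start + 1L, feats$end))
  hits <- GenomicRanges::findOverlaps(pr, fr, type = "within")
  hdt <- data.table(pi = S4Vectors::queryHits(hits),
                    fi = S4Vectors::subjectHits(hits))
  hdt[, gene_id := feats$gene_id[fi]]
  hdt[, feature := feats$feature[fi]]
  # a probe inside two exons of the same gene is still one assignment
  hdt <- unique(hdt[, .(pi, gene_id, feature)])
  ngene <- hdt[, .(ng = data.table::uniqueN(gene_id)), by = pi]
  ambiguous <- ngene$pi[ngene$ng > 1L]
  keep <- hdt[!pi %in% ambiguous]
  # containment in both intron and exon is impossible (disjoint), but a
  # probe exactly filling an exon plus intron gap cannot occur either;
  # defensively drop any residual duplicates
  keep <- keep[!duplicated(pi)]
  out <- data.table(probe_id = probes$probe_id[keep$pi],
                    gene_id = keep$gene_id, feature = keep$feature)
  data.table::setattr(out, "n_unassigned",
                      nrow(probes) - length(unique(hdt$pi)))
  data.table::setattr(out, "n_ambiguous", length(ambiguous))
  out
}

#' Summarize probe intensities into per-feature signals
#'
#' For each gene x feature (intron/exon, all introns pooled) x condition
#' x replicate, the summarized intensity is the median over assigned
#' probes with a non-missing value. Features supported by fewer than
#' \code{min_probes} probes yield no signal (the gene will be reported NA
#' downstream).
#'
#' @param assignment from \code{\link{map_probes_to_features}}
#' @param probes probe table
#' @param min_probes minimum probes per feature (default 3)
#' @return data.table \code{gene_id, feature, condition, replicate,
#'   intensity, n_probes}
#' @export
summarize_feature_signal <- function(assignment, probes, min_probes = 3L) {
  smap <- attr(probes, "samples")
  if (is.null(smap)) {
    labels <- setdiff(names(probes), c("probe_id", "chrom", "start", "end"))
    smap <- parse_sample_labels(labels)
  }
  if (nrow(assignment) == 0L)
    return(data.table(gene_id = character(), feature = character(),
                      condition = character(), replicate = integer(),
                      intensity = numeric(), n_probes = integer()))
  long <- data.table::melt(
    merge(assignment,
          probes[, c("probe_id", smap$sample_label), with = FALSE],
          by = "probe_id"),
    id.vars = c("probe_id", "gene_id", "feature"),
    variable.name = "sample_label", value.name = "intensity",
    variable.factor = FALSE)
  long <- merge(long, smap, by = "sample_label")
  long <- long[!is.na(intensity)]
  sig <- long[, .(intensity = median(intensity), n_probes = .N),
              by = .(gene_id, feature, condition, replicate)]
  sig <- sig[n_probes >= min_probes]
  data.table::setorder(sig, gene_id, feature, condition, replicate)
  sig[]
}

#' Compute the PM index from summarized feature signals
#'
#' Per gene, replicate intensities are first averaged in linear space
#' within each feature x condition, then
#' \deqn{PMi = \log_2\frac{it_{15}/it_{0}}{et_{15}/et_{0}}}
#' is computed from the four averages. Per-replicate PMi values (over
#' replicates with all four signals) provide the spread \code{pmi_sd}.
#' Genes missing any of the four signals are reported with status NA and
#' reason \code{"missing_feature"}; genes whose averaged intensity falls
#' at or below the signal floor get reason \code{"signal_floor"} (the
#' floor avoids log of zero and is \code{floor_frac} times the median of
#' all summarized intensities).
#'
#' @param signals from \code{\link{summarize_feature_signal}}
#' @param genes optional list of \code{gene_model} (provides is_rp and
#'   reports annotated genes absent from the signal)
#' @param conditions the two condition labels, reference first
#' @param floor_frac signal floor as a fraction of the median intensity
#' @return data.table \code{gene_id, pmi, intron_ratio, exon_ratio,
#'   pmi_sd, is_rp, status, reason}
#' @export
compute_pmi <- function(signals, genes = NULL,
                        conditions = c("t0", "t15"), floor_frac = 1e-6) {
  stopifnot(length(conditions) == 2L)
  eps <- if (nrow(signals)) floor_frac * median(signals$intensity) else 0
  avg <- signals[condition %in% conditions,
                 .(intensity = mean(intensity)),
                 by = .(gene_id, feature, condition)]
  gene_ids <- unique(avg$gene_id)
  if (!is.null(genes))
    gene_ids <- union(gene_ids, vapply(genes, `[[`, "", "gene_id"))
  recs <- lapply(gene_ids, function(g) {
    a <- avg[gene_id == g]
    val <- function(f, cn) {
      v <- a[feature == f & condition == cn, intensity]
      if (length(v) == 1L) v else NA_real_
    }
    it0 <- val("intron", conditions[1L]); it15 <- val("intron", conditions[2L])
    et0 <- val("exon",   conditions[1L]); et15 <- val("exon",   conditions[2L])
    four <- c(it0, it15, et0, et15)
    if (anyNA(four))
      return(data.table(gene_id = g, pmi = NA_real_,
                        intron_ratio = NA_real_, exon_ratio = NA_real_,
                        pmi_sd = NA_real_, status = "NA",
                        reason = "missing_feature"))
    if (any(four <= eps))
      return(data.table(gene_id = g, pmi = NA_real_,
                        intron_ratio = NA_real_, exon_ratio = NA_real_,
                        pmi_sd = NA_real_, status = "NA",
                        reason = "signal_floor"))
    ir <- it15 / it0; er <- et15 / et0
    # per-replicate PMis, for spread only
    rep_pmi <- {
      s <- signals[gene_id == g & condition %in% conditions]
      wide <- data.table::dcast(s, replicate ~ feature + condition,
                                value.var = "intensity")
      cols <- c(paste0("intron_", conditions), paste0("exon_", conditions))
      if (all(cols %in% names(wide))) {
        ok <- stats::complete.cases(wide[, cols, with = FALSE])
        w <- wide[ok]
        if (nrow(w) >= 2L)
          log2((w[[cols[2L]]] / w[[cols[1L]]]) /
               (w[[cols[4L]]] / w[[cols[3L]]]))
        else numeric()
      } else numeric()
    }
    data.table(gene_id = g, pmi = log2(ir / er), intron_ratio = ir,
               exon_ratio = er,
               pmi_sd = if (length(rep_pmi) >= 2L) sd(rep_pmi) else NA_real_,
               status = "OK", reason = NA_character_)
  })
  out <- data.table::rbindlist(recs)
  rp <- if (is.null(genes)) rep(NA, nrow(out)) else {
    flags <- vapply(genes, `[[`, TRUE, "is_rp")
    names(flags) <- vapply(genes, `[[`, "", "gene_id")
    unname(flags[out$gene_id])
  }
  out[, is_rp := rp]
  data.table::setorder(out, gene_id)
  data.table::setcolorder(out, c("gene_id", "pmi", "intron_ratio",
                                 "exon_ratio", "pmi_sd", "is_rp",
                                 "status", "reason"))
  out[]
}

#' Classify a PMi distribution into below/within/above bands
#'
#' Counts genes with PMi below \code{low}, within \code{[low, high]}
#' (closed interval: boundary values count as within), and above
#' \code{high}, plus a fixed-width histogram for plotting. NA records
#' are excluded and counted.
#'
#' @param records PMi table (\code{\link{compute_pmi}}) or numeric vector
#' @param low,high band limits (defaults -0.5, +0.5)
#' @param binwidth histogram bin width
#' @return list with \code{counts} (below/within/above), \code{percent}
#'   (one decimal), \code{n}, \code{n_na}, and \code{histogram}
#' @export
classify_pmi_distribution <- function(records, low = -0.5, high = 0.5,
                                      binwidth = 0.25) {
  x <- if (is.numeric(records)) records else records$pmi
  n_na <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no non-missing PMi values")
  counts <- c(below = sum(x < low),
              within = sum(x >= low & x <= high),
              above = sum(x > high))
  lo <- floor(min(x) / binwidth) * binwidth
  hi <- ceiling(max(x) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  h <- hist(x, breaks = breaks, plot = FALSE)
  list(counts = counts,
       percent = round(100 * counts / length(x), 1),
       n = length(x), n_na = n_na,
       histogram = data.table(bin_start = head(breaks, -1L),
                              bin_end = tail(breaks, -1L),
                              count = h$counts))
}

#' Per-group PMi summary for RP and non-RP genes
#'
#' @param records PMi table with an \code{is_rp} flag on every record
#' @return data.table, one row per group (RP, non_RP):
#'   \code{group, n, mean, sd, n_negative, n_na}
#' @export
group_summary <- function(records) {
  if (anyNA(records$is_rp))
    stop("is_rp flag must be set on all records")
  out <- lapply(c(TRUE, FALSE), function(flag) {
    r <- records[records$is_rp == flag, ]
    x <- r$pmi[!is.na(r$pmi)]
    if (length(x) == 0L) {
      warning("empty group: ", if (flag) "RP" else "non_RP")
      return(data.table(group = if (flag) "RP" else "non_RP",
                        n = 0L, mean = NA_real_, sd = NA_real_,
                        n_negative = 0L, n_na = sum(is.na(r$pmi))))
    }
    data.table(group = if (flag) "RP" else "non_RP",
               n = length(x), mean = mean(x),
               sd = if (length(x) >= 2L) sd(x) else NA_real_,
               n_negative = sum(x < 0), n_na = sum(is.na(r$pmi)))
  })
  data.table::rbindlist(out)
}
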