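#' Read a tiling-array probe intensity table
#'
#' Expects a TSV with columns \code{probe_id chrom start end} followed by
#' one intensity column per sample, labelled \code{t<min>_r<rep>}
#' (e.g. \code{t0_r1}, \code{t15_r3}). Coordinates are 0-based half-open.
#' Negative intensities are an error; missing cells are tolerated and the
#' affected probe is excluded from summarization for that sample.
#'
#' @param path TSV file
#' @param samples optional character vector of expected sample labels
#'   (from the run config); a header mismatch is an error
#' @return data.table with the input columns; attributes
#'   \code{samples} (label/condition/replicate map) and
#'   \code{n_flagged} (probes with at least one missing cell)
#' @export
read_probe_table <- function(path, samples = NULL) {
  assert_file_exists(path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(dt)))
    stop("probe table must have columns: ", paste(need, collapse = ", "))
  labels <- setdiff(names(dt), need)
  if (length(labels) == 0L) stop("probe table has no sample columns")
  smap <- parse_sample_labels(labels)
  if (!is.null(samples) && !setequal(labels, samples))
    stop("probe table samples (", paste(labels, collapse = ","),
         ") do not match configured samples (",
         paste(samples, collapse = ","), ")")
  if (nrow(dt) == 0L) {
    warning("probe table ", path, " is empty (header only)")
    data.table::setattr(dt, "samples", smap)
    data.table::setattr(dt, "n_flagged", 0L)
    return(dt[])
  }
  if (any(dt$end <= dt$start))
    stop("probe(s) with end <= start: ",
         paste(dt$probe_id[dt$end <= dt$start], collapse = ", "))
  for (lab in labels) {
    v <- dt[[lab]]
    if (!is.numeric(v)) stop("non-numeric intensity column: ", lab)
    if (any(v < 0, na.rm = TRUE))
      stop("negative intensity in ", lab, " for probe(s): ",
           paste(dt$probe_id[which(v < 0)], collapse = ", "))
    if (any(is.infinite(v)))
      stop("non-finite intensity in ", lab)
  }
  flagged <- rowSums(is.na(as.matrix(dt[, ..labels]))) > 0L
  data.table::setattr(dt, "samples", smap)
  data.table::setattr(dt, "n_flagged", sum(flagged))
  dt[]
}

#' Write a probe intensity table
#' @param dt probe table (as from \code{read_probe_table} or the simulator)
#' @param path output TSV
#' @return path, invisibly
#' @export
write_probe_table <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' CSV with columns \code{primer_pair, sample, timepoint, replicate, ct}
#' and an optional \code{dilution} column. Rows with a non-missing
#' dilution factor form the standard-curve block used for efficiency
#' estimation (their timepoint may be missing). All Ct values must be
#' positive; a timepoint outside the declared design is an error.
#'
#' @param path CSV file
#' @param timepoints allowed timepoints in minutes (experimental design)
#' @return data.table of Ct observations (standard-curve rows included,
#'   distinguishable by non-NA \code{dilution})
#' @export
read_ct_table <- function(path, timepoints = c(0, 5, 10, 15)) {
  assert_file_exists(path)
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  need <- c("primer_pair", "sample", "timepoint", "replicate", "ct")
  if (!all(need %in% names(dt)))
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  if (!"dilution" %in% names(dt)) dt[, dilution := NA_real_]
  if (any(!is.finite(dt$ct)) || any(dt$ct <= 0))
    stop("ct values must be finite and > 0")
  is_std <- !is.na(dt$dilution)
  bad_tp <- !is_std & !(dt$timepoint %in% timepoints)
  if (any(bad_tp))
    stop("unknown timepoint(s): ",
         paste(unique(dt$timepoint[bad_tp]), collapse = ", "),
         " (design: ", paste(timepoints, collapse = ","), ")")
  if (any(is_std & dt$dilution <= 0))
    stop("dilution factors must be > 0")
  dt[]
}

#' Write a qPCR Ct table
#' @param dt Ct table
#' @param path output CSV
#' @return path, invisibly
#' @export
write_ct_table <- function(dt, path) {
  data.table::fwrite(dt, path, sep = ",")
  invisible(path)
}

#' Read a transcription-rate time-course matrix
#'
#' TSV with a \code{gene_id} column followed by one column per timepoint
#' (minutes; default design 0,2,4,6,8,10,15). Values are transcription
#' rates in arbitrary units; missing cells are allowed and flag the
#' profile as incomplete downstream.
#'
#' @param path TSV file
#' @param timepoints expected timepoints (minutes)
#' @return numeric matrix genes x timepoints, rownames = gene ids,
#'   colnames = timepoints as character
#' @export
read_tr_table <- function(path, timepoints = c(0, 2, 4, 6, 8, 10, 15)) {
  assert_file_exists(path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!"gene_id" %in% names(dt))
    stop("TR table must have a gene_id column")
  tp_cols <- setdiff(names(dt), "gene_id")
  if (!setequal(tp_cols, as.character(timepoints)))
    stop("TR table timepoints (", paste(tp_cols, collapse = ","),
         ") do not match design (", paste(timepoints, collapse = ","), ")")
  m <- as.matrix(dt[, as.character(timepoints), with = FALSE])
  rownames(m) <- dt$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write a transcription-rate matrix
#' @param m matrix genes x timepoints (rownames = gene ids)
#' @param path output TSV
#' @return path, invisibly
#' @export
write_tr_table <- function(m, path) {
  dt <- data.table::data.table(gene_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
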