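#' Construct a gene model
#'
#' A gene model holds the exon/intron partition of one intron-containing
#' gene. All intervals are 0-based half-open (BED convention); GFF3 input
#' is converted on read. Introns are derived as the gaps between
#' consecutive exons when not supplied.
#'
#' @param gene_id gene identifier (unique within an annotation)
#' @param chrom chromosome name
#' @param strand "+" or "-"
#' @param exons two-column matrix (start, end) of exon intervals,
#'   0-based half-open
#' @param introns optional two-column matrix of intron intervals; derived
#'   from exon gaps when NULL
#' @param is_rp logical; ribosomal-protein gene membership. Taken from
#'   annotation, never inferred from the gene name.
#' @return object of class \code{gene_model}
#' @export
gene_model <- function(gene_id, chrom, strand = "+", exons,
                       introns = NULL, is_rp = FALSE) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("gene ", gene_id, ": exon with end <= start")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene ", gene_id, ": overlapping exons")
  if (is.null(introns)) {
    if (nrow(exons) < 2L)
      stop("gene ", gene_id, ": no introns (single exon)")
    introns <- cbind(start = exons[-nrow(exons), 2L],
                     end   = exons[-1L, 1L])
  } else {
    introns <- matrix(as.numeric(introns), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
    introns <- introns[order(introns[, 1L]), , drop = FALSE]
  }
  if (nrow(introns) < 1L)
    stop("gene ", gene_id, ": intron-containing gene required")
  if (any(introns[, 2L] <= introns[, 1L]))
    stop("gene ", gene_id, ": intron with end <= start")
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, introns = introns, is_rp = isTRUE(is_rp)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %d exon(s), %d intron(s)%s\n",
              x$gene_id, x$chrom, min(x$exons), max(x$exons), x$strand,
              nrow(x$exons), nrow(x$introns),
              if (x$is_rp) " [RP]" else ""))
  invisible(x)
}

#' Read gene models from GFF3 or BED12 annotation
#'
#' Reads an exon-level annotation and returns one \code{gene_model} per
#' gene that has at least one intron. Single-exon genes are dropped (the
#' PM index is only defined for intron-containing genes); the number
#' dropped is reported via \code{message()} and the \code{"n_dropped"}
#' attribute. GFF3 coordinates (1-based closed) are converted to the
#' internal 0-based half-open convention; BED12 block coordinates are
#' used as-is.
#'
#' @param path annotation file (GFF3 with gene/exon features, or BED12)
#' @param rp_genes character vector of ribosomal-protein gene ids
#'   (curated list; membership is never inferred from names). GFF3 gene
#'   records may alternatively carry an \code{rp=true} attribute.
#' @param format "auto" (by extension), "gff3" or "bed12"
#' @return named list of \code{gene_model}, attribute \code{n_dropped}
#' @export
read_gene_models <- function(path, rp_genes = NULL,
                             format = c("auto", "gff3", "bed12")) {
  assert_file_exists(path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12"
              else "gff3"
  }
  models <- if (format == "gff3") .read_gff3_models(path, rp_genes)
            else .read_bed12_models(path, rp_genes)
  ids <- vapply(models, `[[`, "", "gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(models) <- ids
  models
}

#' @noRd
.read_gff3_models <- function(path, rp_genes) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gid <- genes$ID
  if (is.null(gid) || anyNA(gid)) stop("gene features must carry ID")
  parent <- as.character(BiocGenerics::unlist(exons$Parent))
  rp_attr <- genes$rp
  out <- list(); dropped <- 0L
  for (i in seq_along(genes)) {
    ex <- exons[parent == gid[i]]
    if (length(ex) < 2L) { dropped <- dropped + 1L; next }
    # GFF3 1-based closed -> 0-based half-open
    exm <- cbind(start = GenomicRanges::start(ex) - 1L,
                 end   = GenomicRanges::end(ex))
    is_rp <- (!is.null(rp_attr) && isTRUE(tolower(
                as.character(rp_attr[i])) %in% c("true", "1", "yes"))) ||
             gid[i] %in% rp_genes
    out[[length(out) + 1L]] <- gene_model(
      gene_id = gid[i],
      chrom = as.character(GenomicRanges::seqnames(genes)[i]),
      strand = .strand_chr(genes[i]),
      exons = exm, is_rp = is_rp)
  }
  if (dropped > 0L)
    message("read_gene_models: dropped ", dropped,
            " gene(s) without introns")
  structure(out, n_dropped = dropped)
}

#' @noRd
.read_bed12_models <- function(path, rp_genes) {
  # manual BED12 parse: keeps full control over the half-open arithmetic
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  out <- list(); dropped <- 0L
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      stop("BED12 line ", ln, ": expected 12 fields, got ", length(f))
    chromStart <- as.numeric(f[2L]); chromEnd <- as.numeric(f[3L])
    if (is.na(chromStart) || is.na(chromEnd) || chromEnd <= chromStart)
      stop("BED12 line ", ln, ": end <= start")
    nblocks <- as.integer(f[10L])
    sizes  <- as.numeric(strsplit(f[11L], ",")[[1L]])[seq_len(nblocks)]
    starts <- as.numeric(strsplit(f[12L], ",")[[1L]])[seq_len(nblocks)]
    if (nblocks < 2L) { dropped <- dropped + 1L; next }
    exm <- cbind(start = chromStart + starts,
                 end   = chromStart + starts + sizes)
    out[[length(out) + 1L]] <- gene_model(
      gene_id = f[4L], chrom = f[1L],
      strand = if (f[6L] %in% c("+", "-")) f[6L] else "+",
      exons = exm, is_rp = f[4L] %in% rp_genes)
  }
  if (dropped > 0L)
    message("read_gene_models: dropped ", dropped,
            " gene(s) without introns")
  structure(out, n_dropped = dropped)
}

#' @noRd
.strand_chr <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  if (s %in% c("+", "-")) s else "+"
}

#' Write gene models to GFF3
#'
#' Inverse of \code{\link{read_gene_models}} for the GFF3 route; internal
#' 0-based half-open intervals are converted back to 1-based closed.
#'
#' @param models list of \code{gene_model}
#' @param path output file
#' @return path, invisibly
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    span <- c(min(m$exons), max(m$exons))
    lines <- c(lines, sprintf(
      "%s\tpmindex\tgene\t%d\t%d\t.\t%s\t.\tID=%s;rp=%s",
      m$chrom, span[1L] + 1L, span[2L], m$strand, m$gene_id,
      if (m$is_rp) "true" else "false"))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, sprintf(
        "%s\tpmindex\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        m$chrom, m$exons[i, 1L] + 1L, m$exons[i, 2L], m$strand,
        m$gene_id, i, m$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
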