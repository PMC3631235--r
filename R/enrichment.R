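#' Hypergeometric over-representation test
#'
#' For each annotation category, tests whether the study set (e.g. the
#' genes with PMi < -0.5) contains more category members than expected
#' by drawing \code{n} genes from the universe without replacement. The
#' p-value is the upper tail P(X >= k) of the hypergeometric
#' distribution with category size K in a universe of size N. The
#' natural universe for this analysis is all intron-containing genes
#' with a computed PMi; pass it explicitly.
#'
#' Categories not hit by the study set (k = 0, p = 1) are omitted.
#' A Bonferroni-adjusted column is reported for reference but results
#' are never filtered by it.
#'
#' @param gene_set character vector, the study set (must be contained in
#'   the universe)
#' @param annotation named list category -> gene ids, or a 2-column
#'   data.frame \code{category, gene} (flattened GAF-like table)
#' @param universe character vector, the background gene population
#' @return data.table \code{category, k, n, K, N, p, p_bonferroni},
#'   sorted by ascending p
#' @export
hypergeometric_enrichment <- function(gene_set, annotation, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  gene_set <- unique(gene_set)
  extra <- setdiff(gene_set, universe)
  if (length(extra))
    stop("gene_set members not in universe: ",
         paste(head(extra, 5L), collapse = ", "))
  if (is.data.frame(annotation)) {
    stopifnot(ncol(annotation) >= 2L)
    annotation <- split(as.character(annotation[[2L]]),
                        as.character(annotation[[1L]]))
  }
  N <- length(universe); n <- length(gene_set)
  res <- lapply(names(annotation), function(cat) {
    members <- intersect(unique(annotation[[cat]]), universe)
    K <- length(members)
    k <- length(intersect(gene_set, members))
    if (k < 1L) return(NULL)
    data.table(category = cat, k = k, n = n, K = K, N = N,
               p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
  })
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L)
    return(data.table(category = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p = numeric(), p_bonferroni = numeric()))
  out[, p_bonferroni := pmin(1, p * .N)]
  data.table::setorder(out, p)
  out[]
}

#' Read a flattened category-gene annotation table
#'
#' Two tab-separated columns, \code{category} then \code{gene}; no
#' header required (one is detected and skipped when the first line
#' reads "category\\tgene").
#'
#' @param path TSV file
#' @return named list category -> character vector of genes
#' @export
read_annotation_table <- function(path) {
  assert_file_exists(path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("category", "gene"))
  if (nrow(dt) && dt$category[1L] == "category") dt <- dt[-1L]
  split(dt$gene, dt$category)
}
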