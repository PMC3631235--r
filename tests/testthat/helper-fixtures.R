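# Fixture builders: every fixture is generated in code at test time.

# two-gene GFF3: one intron-containing gene, one intronless
write_gff3_fixture <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chrI\ttest\tgene\t101\t600\t.\t+\t.\tID=GENE1;rp=true",
    "chrI\ttest\texon\t101\t200\t.\t+\t.\tID=GENE1.e1;Parent=GENE1",
    "chrI\ttest\texon\t401\t600\t.\t+\t.\tID=GENE1.e2;Parent=GENE1",
    "chrI\ttest\tgene\t1001\t1400\t.\t-\t.\tID=GENE2;rp=false",
    "chrI\ttest\texon\t1001\t1400\t.\t-\t.\tID=GENE2.e1;Parent=GENE2"
  ), path)
  path
}

# one BED12 line: 2 blocks -> 1 intron in the inter-block gap
write_bed12_fixture <- function(path = tempfile(fileext = ".bed")) {
  writeLines(paste(
    "chrII", 1000, 2000, "BGENE1", 0, "+", 1000, 2000, "0",
    2, "150,300,", "0,700,", sep = "\t"), path)
  path
}

# small probe table with t0/t15 x n_reps samples
write_probe_fixture <- function(path = tempfile(fileext = ".tsv"),
                                n_reps = 3L) {
  labels <- as.vector(outer(c("t0", "t15"), seq_len(n_reps),
                            function(t, r) paste0(t, "_r", r)))
  dt <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chrI",
                   start = c(110, 150, 420), end = c(135, 175, 445))
  for (lab in labels) dt[[lab]] <- c(10, 20, 90) + runif(3)
  write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# FeatureSignal table from explicit it/et values, one replicate
make_signals <- function(gene_id, it0, it15, et0, et15, replicate = 1L) {
  data.table::data.table(
    gene_id = rep(gene_id, each = 4L),
    feature = rep(c("intron", "intron", "exon", "exon"),
                  length(gene_id)),
    condition = rep(c("t0", "t15", "t0", "t15"), length(gene_id)),
    replicate = replicate,
    intensity = as.vector(rbind(it0, it15, et0, et15)),
    n_probes = 5L)
}

# random gene models on one chromosome, non-overlapping
random_gene_models <- function(n) {
  # caller is responsible for set.seed()
  models <- list()
  pos <- 100
  for (i in seq_len(n)) {
    e1 <- round(runif(1, 80, 200)); intr <- round(runif(1, 100, 300))
    e2 <- round(runif(1, 150, 400))
    models[[i]] <- pmindex::gene_model(
      sprintf("G%03d", i), "chrT",
      exons = rbind(c(pos, pos + e1),
                    c(pos + e1 + intr, pos + e1 + intr + e2)))
    pos <- pos + e1 + intr + e2 + round(runif(1, 50, 150))
  }
  names(models) <- vapply(models, `[[`, "", "gene_id")
  models
}
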