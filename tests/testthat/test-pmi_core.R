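make_probe_dt <- function(probe_id, chrom, start, end, ...) {
  dt <- data.table::data.table(probe_id = probe_id, chrom = chrom,
                               start = start, end = end, ...)
  labs <- setdiff(names(dt), c("probe_id", "chrom", "start", "end"))
  data.table::setattr(dt, "samples",
                      pmindex:::parse_sample_labels(labs))
  dt
}

test_that("probe assignment follows strict containment", {
  g <- gene_model("G1", "chrI",
                  exons = rbind(c(0, 100), c(200, 320)))
  probes <- make_probe_dt(c("in", "boundary", "outside"),
                          "chrI", c(110, 95, 500), c(135, 115, 525),
                          t0_r1 = c(1, 1, 1), t15_r1 = c(1, 1, 1))
  asn <- map_probes_to_features(probes, list(G1 = g))
  expect_equal(asn$probe_id, "in")
  expect_equal(asn$feature, "intron")
  expect_equal(attr(asn, "n_unassigned"), 2L)
})

test_that("assignment matches brute-force containment on random probes", {
  set.seed(101)
  genes <- random_gene_models(5)
  span <- range(unlist(lapply(genes, function(g) g$exons)))
  starts <- round(runif(200, span[1L] - 100, span[2L] + 100))
  probes <- make_probe_dt(sprintf("p%03d", 1:200), "chrT",
                          starts, starts + 25L,
                          t0_r1 = runif(200, 1, 100),
                          t15_r1 = runif(200, 1, 100))
  got <- map_probes_to_features(probes, genes)
  want <- oracle_containment(probes, genes)
  got_df <- as.data.frame(got)[order(got$probe_id), ]
  want_df <- want[order(want$probe_id), ]
  rownames(got_df) <- rownames(want_df) <- NULL
  expect_equal(got_df, want_df, ignore_attr = TRUE)
})

test_that("median summarization and min_probes threshold", {
  g <- gene_model("G1", "chrI", exons = rbind(c(0, 100), c(200, 320)))
  probes <- make_probe_dt(c("a", "b", "c", "x", "y"), "chrI",
                          c(110, 130, 150, 10, 40),
                          c(125, 145, 165, 25, 55),
                          t0_r1 = c(10, 20, 90, 5, 7),
                          t15_r1 = c(1, 2, 3, 4, 6))
  asn <- map_probes_to_features(probes, list(G1 = g))
  sig <- summarize_feature_signal(asn, probes, min_probes = 3L)
  # intron has 3 probes -> median 20 at t0; exon has 2 -> filtered out
  expect_equal(sig[sig$feature == "intron" & sig$condition == "t0",
                   ]$intensity, 20)
  expect_false("exon" %in% sig$feature)

  sig2 <- summarize_feature_signal(asn, probes, min_probes = 2L)
  expect_equal(sig2[sig2$feature == "exon" & sig2$condition == "t0",
                    ]$intensity, 6)
})

test_that("summarization equals brute-force medians on a random fixture", {
  set.seed(102)
  panel <- simulate_gene_panel(6, 4, seed = 55)
  probes <- simulate_probe_intensities(panel, sigma = 0.2, seed = 56)
  asn <- map_probes_to_features(probes, panel$models)
  sig <- summarize_feature_signal(asn, probes, min_probes = 1L)
  smap <- attr(probes, "samples")
  for (i in sample(nrow(sig), 25L)) {
    row <- sig[i]
    lab <- smap$sample_label[smap$condition == row$condition &
                            smap$replicate == row$replicate]
    pids <- asn$probe_id[asn$gene_id == row$gene_id &
                         asn$feature == row$feature]
    vals <- probes[[lab]][match(pids, probes$probe_id)]
    expect_equal(row$intensity, median(vals, na.rm = TRUE))
    expect_equal(row$n_probes, sum(!is.na(vals)))
  }
})

test_that("compute_pmi reproduces direct formula evaluation", {
  sig <- make_signals("G1", 100, 100, 100, 100)
  expect_equal(compute_pmi(sig)$pmi, 0)
  sig <- make_signals("G1", 100, 50, 100, 100)
  expect_equal(compute_pmi(sig)$pmi, -1)
  sig <- make_signals("G1", 80, 30, 120, 100)
  expect_equal(compute_pmi(sig)$pmi, log2((30 / 80) / (100 / 120)))

  # randomized oracle check, replicate-averaged values
  set.seed(103)
  for (rep in 1:100) {
    vals <- matrix(runif(12, 1, 1000), nrow = 3L)  # 3 replicates x 4
    sig <- data.table::rbindlist(lapply(1:3, function(r)
      make_signals("G", vals[r, 1L], vals[r, 2L], vals[r, 3L],
                   vals[r, 4L], replicate = r)))
    got <- compute_pmi(sig)
    means <- colMeans(vals)
    expect_equal(got$pmi, oracle_pmi(means[1L], means[2L], means[3L],
                                     means[4L]), tolerance = 1e-12)
    expect_equal(got$intron_ratio, means[2L] / means[1L])
    expect_equal(got$exon_ratio, means[4L] / means[3L])
  }
})

test_that("PMi record invariant: pmi == log2(intron_ratio/exon_ratio)", {
  set.seed(104)
  sig <- data.table::rbindlist(lapply(1:3, function(r)
    make_signals(sprintf("G%02d", 1:10), runif(10, 10, 100),
                 runif(10, 10, 100), runif(10, 10, 100),
                 runif(10, 10, 100), replicate = r)))
  got <- compute_pmi(sig)
  expect_equal(got$pmi, log2(got$intron_ratio / got$exon_ratio),
               tolerance = 1e-12)
  expect_true(all(!is.na(got$pmi_sd)))
})

test_that("missing features and floored signals are reported NA", {
  sig <- make_signals("G1", 80, 30, 120, 100)
  sig <- sig[!(sig$feature == "exon" & sig$condition == "t15"), ]
  got <- compute_pmi(sig)
  expect_equal(got$status, "NA")
  expect_equal(got$reason, "missing_feature")

  sig2 <- rbind(make_signals("G1", 80, 30, 120, 100),
                make_signals("G2", 0, 30, 120, 100))
  got2 <- compute_pmi(sig2)
  expect_equal(got2[got2$gene_id == "G2", ]$reason, "signal_floor")
  expect_equal(got2[got2$gene_id == "G1", ]$status, "OK")

  # annotated gene absent from the signal -> NA with reason
  g3 <- gene_model("G3", "chrI", exons = rbind(c(0, 50), c(100, 150)))
  got3 <- compute_pmi(make_signals("G1", 80, 30, 120, 100),
                      genes = list(G3 = g3))
  expect_equal(got3[got3$gene_id == "G3", ]$reason, "missing_feature")
})

test_that("PMi is invariant to global condition scaling and antisymmetric", {
  set.seed(105)
  base <- data.table::rbindlist(lapply(1:3, function(r)
    make_signals(sprintf("G%02d", 1:8), runif(8, 10, 100),
                 runif(8, 10, 100), runif(8, 10, 100),
                 runif(8, 10, 100), replicate = r)))
  ref <- compute_pmi(base)

  scaled <- data.table::copy(base)
  scaled$intensity[scaled$condition == "t15"] <-
    scaled$intensity[scaled$condition == "t15"] * 37.5
  got <- compute_pmi(scaled)
  expect_equal(got$pmi, ref$pmi, tolerance = 1e-12)

  swapped <- data.table::copy(base)
  swapped$condition <- ifelse(swapped$condition == "t0", "t15", "t0")
  expect_equal(compute_pmi(swapped)$pmi, -ref$pmi, tolerance = 1e-12)
})

test_that("distribution classification uses closed [low, high]", {
  d <- classify_pmi_distribution(rep(0, 10))
  expect_equal(unname(d$counts), c(0L, 10L, 0L))
  expect_equal(unname(d$percent["within"]), 100)

  d2 <- classify_pmi_distribution(c(-1, -0.5, 0, 0.6))
  expect_equal(unname(d2$counts), c(1L, 2L, 1L))
  expect_equal(sum(d2$counts), d2$n)
  expect_equal(sum(d2$histogram$count), d2$n)

  d3 <- classify_pmi_distribution(c(-1, NA, 0.2))
  expect_equal(d3$n_na, 1L)
})

test_that("group summary matches brute-force means", {
  r1 <- data.table::data.table(gene_id = "R1", pmi = -0.3, is_rp = TRUE)
  expect_equal(group_summary(r1)[group == "RP", mean], -0.3)

  set.seed(106)
  recs <- data.table::data.table(
    gene_id = sprintf("G%02d", 1:40),
    pmi = c(rnorm(38, -0.2, 0.4), NA, NA),
    is_rp = rep(c(TRUE, FALSE), 20))
  got <- group_summary(recs)
  for (flag in c(TRUE, FALSE)) {
    x <- recs$pmi[recs$is_rp == flag]
    row <- got[got$group == (if (flag) "RP" else "non_RP"), ]
    expect_equal(row$mean, mean(x, na.rm = TRUE))
    expect_equal(row$sd, sd(x[!is.na(x)]))
    expect_equal(row$n_negative, sum(x < 0, na.rm = TRUE))
    expect_equal(row$n_na, sum(is.na(x)))
  }
  expect_warning(group_summary(recs[recs$is_rp == TRUE, ]), "empty group")
})

test_that("RP PMi decreases monotonically in the decay factor f", {
  means <- vapply(c(1, 2, 3, 5), function(f) {
    cfg <- panel_config(rp_mult = c(tr = 0.5, ks = 1, d_pre = f,
                                    d_m = 1.3))
    panel <- simulate_gene_panel(40, 0, seed = 77, config = cfg)
    mean(true_pmi(panel$params)[panel$params$is_rp])
  }, numeric(1L))
  expect_true(all(diff(means) < 0))
  expect_true(all(means[-1L] < 0))
})

test_that("NMD genotype abolishes the RP PMi drop (sigma = 0.1, n = 80)", {
  cfg <- panel_config(genotype = "upf1")
  panel <- simulate_gene_panel(80, 0, seed = 78, config = cfg)
  probes <- simulate_probe_intensities(panel, sigma = 0.1, seed = 79)
  res <- compute_pmi(summarize_feature_signal(
    map_probes_to_features(probes, panel$models), probes),
    genes = panel$models)
  expect_lt(abs(mean(res$pmi[res$is_rp], na.rm = TRUE)), 0.1)
})
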