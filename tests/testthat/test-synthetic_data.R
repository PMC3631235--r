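test_that("generators are bit-reproducible under a fixed seed", {
  p1 <- simulate_gene_panel(10, 5, seed = 42)
  p2 <- simulate_gene_panel(10, 5, seed = 42)
  expect_identical(p1, p2)
  expect_identical(simulate_probe_intensities(p1, seed = 5),
                   simulate_probe_intensities(p2, seed = 5))
  expect_identical(simulate_ct_values(p1, seed = 6),
                   simulate_ct_values(p2, seed = 6))
  expect_identical(simulate_tr_profiles(p1, seed = 7),
                   simulate_tr_profiles(p2, seed = 7))
})

test_that("panel construction honours group structure", {
  panel <- simulate_gene_panel(0, 20, seed = 43)
  expect_true(all(!panel$params$is_rp))
  mult <- as.matrix(panel$params[, c("m_tr", "m_ks", "m_dpre", "m_dm")])
  expect_true(all(abs(log(mult[panel$params$gene_id != "CTLPOS001", ]))
                  < 0.2))
  expect_lt(panel$params[gene_id == "CTLPOS001", m_dpre], 1)

  nc <- simulate_gene_panel(5, 5, seed = 44,
                            config = panel_config(control_gene = FALSE))
  expect_false("CTLPOS001" %in% nc$params$gene_id)
  expect_error(simulate_gene_panel(0, 0), ">= 1")
  expect_error(simulate_gene_panel(2, 2,
    config = panel_config(genotype = "nonsense")), "unknown genotype")
})

test_that("steady state follows tr/(ks + d_pre) and ks P*/d_m", {
  p <- data.table::data.table(gene_id = "g", is_rp = FALSE,
    genotype = "WT", tr = 100, ks = 9, d_pre = 1, d_m = 0.9,
    m_tr = 1, m_ks = 1, m_dpre = 1, m_dm = 1)
  ss <- steady_state(p)
  expect_equal(ss$P0, 10)
  expect_equal(ss$M0, 100)
  # all multipliers 1 -> trajectory constant at steady state
  ab <- simulate_abundances(p, c(0, 5, 15))
  expect_equal(ab$P, rep(10, 3))
  expect_equal(ab$M, rep(100, 3))
})

test_that("closed-form trajectories match an RK4 integrator to 1e-9", {
  set.seed(45)
  times <- c(0, 1, 2, 5, 10, 15)
  for (rep in 1:5) {
    p <- data.table::data.table(
      gene_id = "g", is_rp = TRUE, genotype = "WT",
      tr = runif(1, 5, 50), ks = runif(1, 0.1, 2),
      d_pre = runif(1, 0.1, 1), d_m = runif(1, 0.02, 0.3),
      m_tr = runif(1, 0.3, 1.2), m_ks = runif(1, 0.7, 1.3),
      m_dpre = runif(1, 1, 4), m_dm = runif(1, 0.8, 1.6))
    got <- simulate_abundances(p, times)
    want <- oracle_rk4_abundance(p, times)
    expect_equal(got$P, unname(want[, "P"]), tolerance = 1e-9)
    expect_equal(got$M, unname(want[, "M"]), tolerance = 1e-9)
  }
  # degenerate branch: d_m' == ks' + d_pre'
  p <- data.table::data.table(gene_id = "g", is_rp = TRUE,
    genotype = "WT", tr = 10, ks = 0.2, d_pre = 0.3, d_m = 0.5,
    m_tr = 0.5, m_ks = 1, m_dpre = 1, m_dm = 1)
  got <- simulate_abundances(p, times)
  want <- oracle_rk4_abundance(p, times)
  expect_equal(got$M, unname(want[, "M"]), tolerance = 1e-9)
  expect_error(simulate_abundances(
    data.table::data.table(gene_id = "g", is_rp = FALSE, genotype = "WT",
      tr = -1, ks = 1, d_pre = 1, d_m = 1, m_tr = 1, m_ks = 1,
      m_dpre = 1, m_dm = 1), 0:2), "> 0")
})

test_that("noise-free probe intensities equal abundances exactly", {
  panel <- simulate_gene_panel(3, 2, seed = 46)
  probes <- simulate_probe_intensities(panel, sigma = 0,
                                       affinity_sdlog = 0, scale = 1,
                                       n_reps = 1L, seed = 47)
  ab <- simulate_abundances(panel$params, c(0, 15))
  asn <- map_probes_to_features(probes, panel$models)
  long <- merge(asn, probes, by = "probe_id")
  for (g in panel$params$gene_id) {
    abg <- ab[ab$gene_id == g & ab$time == 0, ]
    iv <- long$t0_r1[long$gene_id == g & long$feature == "intron"]
    ev <- long$t0_r1[long$gene_id == g & long$feature == "exon"]
    expect_equal(iv, rep(abg$P, length(iv)), tolerance = 1e-12)
    expect_equal(ev, rep(abg$P + abg$M, length(ev)), tolerance = 1e-12)
  }
})

test_that("zero-noise pipeline PMi equals the closed-form truth to 1e-9", {
  panel <- simulate_gene_panel(10, 5, seed = 48)
  probes <- simulate_probe_intensities(panel, sigma = 0, seed = 49)
  res <- compute_pmi(summarize_feature_signal(
    map_probes_to_features(probes, panel$models), probes),
    genes = panel$models)
  truth <- true_pmi(panel$params)
  expect_equal(setNames(res$pmi, res$gene_id)[names(truth)], truth,
               tolerance = 1e-9)
})

test_that("probe affinities cancel in zero-noise PMi", {
  panel <- simulate_gene_panel(5, 0, seed = 50)
  probes <- simulate_probe_intensities(panel, sigma = 0,
                                       affinity_sdlog = 1.2, seed = 51)
  res <- compute_pmi(summarize_feature_signal(
    map_probes_to_features(probes, panel$models), probes),
    genes = panel$models)
  truth <- true_pmi(panel$params)
  expect_equal(setNames(res$pmi, res$gene_id)[names(truth)], truth,
               tolerance = 1e-9)
})

test_that("genotype contract: NMD mutants flatten RP PMi, WT does not", {
  for (gt in c("upf1", "upf2", "upf3", "xrn1")) {
    panel <- simulate_gene_panel(30, 0, seed = 52,
                                 config = panel_config(genotype = gt))
    expect_lt(abs(mean(true_pmi(panel$params)[panel$params$is_rp])), 0.1)
  }
  wt <- simulate_gene_panel(30, 0, seed = 52)
  expect_lt(mean(true_pmi(wt$params)[wt$params$is_rp]), -0.3)
})

test_that("Ct generation: doubling chemistry and reference coverage", {
  p <- data.table::data.table(gene_id = c("g1", "g2"), is_rp = FALSE,
    genotype = "WT", tr = c(10, 10), ks = 0.2, d_pre = 0.3, d_m = 0.08,
    m_tr = 1, m_ks = 1, m_dpre = 1, m_dm = 1)
  panel <- list(params = p)
  ct <- as.data.frame(simulate_ct_values(panel, sigma_ct = 0, seed = 53))
  # halving the abundance costs exactly one cycle at E = 2
  g1 <- ct[ct$primer_pair == "g1_exon" & is.na(ct$dilution) &
           ct$timepoint %in% 0, ]
  std <- ct[ct$primer_pair == "g1_exon" & !is.na(ct$dilution), ]
  expect_equal(std$ct[std$dilution == 1e-1] - g1$ct[1L],
               log2(10), tolerance = 1e-12)
  expect_equal(std$ct[std$dilution == 2e-1] - std$ct[std$dilution == 1e-1],
               -1, tolerance = 1e-12)
  # reference rows at every observed timepoint
  ref <- ct[ct$primer_pair == "ACT1_exon2" & is.na(ct$dilution), ]
  expect_setequal(unique(ref$timepoint), c(0, 5, 10, 15))
  # standard-curve block present at the six dilution factors
  expect_setequal(unique(std$dilution),
                  c(2e-1, 1e-1, 2e-2, 1e-2, 2e-3, 1e-3))
})

test_that("TR profiles: flat without repression, planted drop at t15", {
  p <- data.table::data.table(gene_id = "g1", is_rp = FALSE,
    genotype = "WT", tr = 10, ks = 0.2, d_pre = 0.3, d_m = 0.08,
    m_tr = 1, m_ks = 1, m_dpre = 1, m_dm = 1)
  flat <- simulate_tr_profiles(list(params = p), sigma = 0, seed = 54)
  expect_equal(unname(flat$tr[1L, ]), rep(10, 7))

  prp <- data.table::copy(p)
  prp$is_rp <- TRUE; prp$m_tr <- 0.25
  fast <- simulate_tr_profiles(list(params = prp), sigma = 0,
                               plant_classes = FALSE, tau = 1,
                               seed = 55)
  np <- normalize_tr(fast$tr)
  expect_equal(unname(np$log2_ratio["g1", "15"]), -2, tolerance = 1e-4)
})

test_that("simulate_dataset writes a self-consistent file set", {
  out <- file.path(tempdir(), "simds")
  paths <- simulate_dataset(out, n_rp = 6, n_other = 4, seed = 56,
                            sigma = 0.05, sigma_ct = 0.05)
  expect_true(all(file.exists(paths)))
  res <- run_tiling_pmi(paths[["annotation"]], paths[["probes"]])
  truth <- jsonlite::read_json(paths[["truth"]])
  tv <- unlist(truth$true_pmi)
  m <- merge(data.frame(gene_id = names(tv), truth = tv),
             as.data.frame(res$pmi))
  expect_gt(nrow(m), 9L)
  expect_lt(max(abs(m$pmi - m$truth), na.rm = TRUE), 0.25)
  # RP flags survive the GFF3 round trip into the pipeline
  expect_equal(sum(res$pmi$is_rp), 6L)
  unlink(out, recursive = TRUE)
})
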