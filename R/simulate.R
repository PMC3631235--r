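#' Default configuration of the synthetic gene panel
#'
#' Base rates describe a fast-turnover yeast transcript: pre-mRNA
#' half-life ~1.5 min (splicing 0.15/min plus pre-mRNA decay 0.3/min)
#' and mature half-life ~9 min. Wild-type stress multipliers are the
#' generator's convention for osmotic shock: transcription halved,
#' pre-mRNA decay tripled and mature decay mildly increased for RP
#' genes, which plants an RP PMi around -0.5 at 15 min while leaving
#' non-RP genes near 0. NMD-deficient genotypes (upf1/2/3, xrn1) force
#' the pre-mRNA decay multiplier back to 1 for RP genes, abolishing the
#' planted drop. An optional control gene with a pre-mRNA decay
#' multiplier < 1 mimics the positive-PMi behaviour of genes whose
#' pre-mRNA accumulates under stress.
#'
#' @param ... named overrides of the defaults
#' @return list of generator settings
#' @export
panel_config <- function(...) {
  cfg <- list(
    tr = 10, ks = 0.15, d_pre = 0.3, d_m = 0.08,
    tr_sdlog = 0.3, rate_sdlog = 0.1,
    rp_mult = c(tr = 0.5, ks = 1, d_pre = 3, d_m = 1.3),
    rp_mult_sdlog = 0.05,
    other_mult_sdlog = 0.03,
    control_gene = TRUE, control_d_pre_mult = 0.35,
    genotype = "WT"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown panel_config field(s): ",
                        paste(bad, collapse = ", "))
  modifyList(cfg, over)
}

#' Genotypes in which NMD-dependent pre-mRNA decay is lost
#' @noRd
.NMD_GENOTYPES <- c("upf1", "upf2", "upf3", "xrn1")

#' @noRd
.KNOWN_GENOTYPES <- c("WT", "hog1", "cbc1", "rrp6", .NMD_GENOTYPES)

#' Simulate a gene panel with kinetic ground truth
#'
#' Builds \code{n_rp} ribosomal-protein-like and \code{n_other}
#' non-ribosomal intron-containing genes (two exons, one intron, laid
#' out on one synthetic chromosome) together with per-gene kinetic
#' rates and stress multipliers. Rates are jittered log-normally around
#' the configured base values; multipliers around the configured group
#' means. For genotypes upf1/upf2/upf3/xrn1 the pre-mRNA decay
#' multiplier of RP genes is forced to exactly 1 (no stress-induced
#' decay increase); hog1, cbc1 and rrp6 leave the wild-type behaviour
#' unchanged. Reproducible for a given seed.
#'
#' @param n_rp,n_other group sizes (sum >= 1)
#' @param seed integer seed
#' @param config list from \code{\link{panel_config}}
#' @return list: \code{models} (named list of \code{gene_model}),
#'   \code{params} (kinetic parameter data.table)
#' @export
simulate_gene_panel <- function(n_rp, n_other, seed = 1L,
                                config = panel_config()) {
  if (n_rp + n_other < 1L) stop("n_rp + n_other must be >= 1")
  if (!config$genotype %in% .KNOWN_GENOTYPES)
    stop("unknown genotype: ", config$genotype)
  if (any(config$rp_mult <= 0) || config$control_d_pre_mult <= 0)
    stop("multipliers must be > 0")
  with_seed(seed, {
    n_ctl <- if (isTRUE(config$control_gene)) 1L else 0L
    ids <- c(if (n_rp) sprintf("RPSYN%03d", seq_len(n_rp)),
             if (n_other) sprintf("ICGSYN%03d", seq_len(n_other)),
             if (n_ctl) "CTLPOS001")
    is_rp <- c(rep(TRUE, n_rp), rep(FALSE, n_other + n_ctl))
    n <- length(ids)
    # gene structure: exon1 - intron - exon2 along one synthetic chromosome
    e1 <- round(runif(n, 120, 300))
    in1 <- round(runif(n, 250, 450))
    e2 <- round(runif(n, 400, 800))
    gap <- 200L
    starts <- cumsum(c(1000, head(e1 + in1 + e2 + gap, -1L)))
    models <- lapply(seq_len(n), function(i) {
      s <- starts[i]
      gene_model(ids[i], "chrS",
                 strand = if (i %% 2L) "+" else "-",
                 exons = rbind(c(s, s + e1[i]),
                               c(s + e1[i] + in1[i],
                                 s + e1[i] + in1[i] + e2[i])),
                 is_rp = is_rp[i])
    })
    names(models) <- ids
    jitter <- function(base, sdlog, n) base * rlnorm(n, 0, sdlog)
    params <- data.table(
      gene_id = ids, is_rp = is_rp, genotype = config$genotype,
      tr = jitter(config$tr, config$tr_sdlog, n),
      ks = jitter(config$ks, config$rate_sdlog, n),
      d_pre = jitter(config$d_pre, config$rate_sdlog, n),
      d_m = jitter(config$d_m, config$rate_sdlog, n)
    )
    mj <- function(center, sdlog, n) center * rlnorm(n, 0, sdlog)
    m <- matrix(1, n, 4L, dimnames = list(NULL,
                c("m_tr", "m_ks", "m_dpre", "m_dm")))
    if (n_rp) {
      idx <- which(is_rp)
      m[idx, "m_tr"]   <- mj(config$rp_mult[["tr"]], config$rp_mult_sdlog, n_rp)
      m[idx, "m_ks"]   <- mj(config$rp_mult[["ks"]], config$rp_mult_sdlog, n_rp)
      m[idx, "m_dpre"] <- mj(config$rp_mult[["d_pre"]], config$rp_mult_sdlog, n_rp)
      m[idx, "m_dm"]   <- mj(config$rp_mult[["d_m"]], config$rp_mult_sdlog, n_rp)
    }
    if (n_other) {
      idx <- which(!is_rp & ids != "CTLPOS001")
      for (cn in colnames(m))
        m[idx, cn] <- mj(1, config$other_mult_sdlog, length(idx))
    }
    if (n_ctl) {
      # pre-mRNA stabilized under stress -> positive PMi control
      m[n, "m_dpre"] <- config$control_d_pre_mult
    }
    if (config$genotype %in% .NMD_GENOTYPES && n_rp)
      m[is_rp, "m_dpre"] <- 1
    params <- cbind(params, data.table::as.data.table(m))
    list(models = models, params = params)
  })
}

#' Simulate a tiling-array probe intensity table
#'
#' Places \code{probes_per_feature} probes fully inside each exon and
#' (pooled) intron, assigns each a fixed log-normal affinity, and
#' reports, per condition (t0, t15 minutes of stress) and replicate,
#' intensity = affinity x abundance x multiplicative log-normal noise.
#' Intron probes see pre-mRNA P only; exon probes see total mRNA P + M
#' (the exon sequence is present in both species).
#'
#' @param panel list from \code{\link{simulate_gene_panel}}
#' @param probes_per_feature probes per exon/intron
#' @param n_reps replicates per condition
#' @param sigma sdlog of the multiplicative intensity noise
#' @param affinity_sdlog sdlog of the per-probe affinity (fixed across
#'   conditions and replicates)
#' @param probe_len probe length in bp
#' @param scale overall intensity scale (arbitrary units)
#' @param times the two sampled stress times (minutes)
#' @param seed integer seed
#' @return probe table (data.table) in the \code{read_probe_table}
#'   layout, with the \code{samples} attribute set
#' @export
simulate_probe_intensities <- function(panel, probes_per_feature = 5L,
                                       n_reps = 3L, sigma = 0.1,
                                       affinity_sdlog = 0.25,
                                       probe_len = 25L, scale = 100,
                                       times = c(0, 15), seed = 1L) {
  stopifnot(sigma >= 0, length(times) == 2L)
  models <- panel$models; params <- panel$params
  ab <- simulate_abundances(params, times)
  labels <- as.vector(outer(paste0("t", times), seq_len(n_reps),
                            function(t, r) paste0(t, "_r", r)))
  with_seed(seed, {
    rows <- list()
    for (g in names(models)) {
      m <- models[[g]]
      abg <- ab[gene_id == g]
      sig <- list(
        intron = setNames(abg$P, paste0("t", abg$time)),
        exon   = setNames(abg$P + abg$M, paste0("t", abg$time)))
      feats <- rbind(
        data.table(feature = "exon", start = m$exons[, 1L],
                   end = m$exons[, 2L]),
        data.table(feature = "intron", start = m$introns[, 1L],
                   end = m$introns[, 2L]))
      # distribute the per-feature probe budget over the feature's
      # intervals proportionally to length (introns pooled downstream)
      for (ftype in c("exon", "intron")) {
        fr <- feats[feature == ftype]
        lens <- fr$end - fr$start
        alloc <- diff(round(probes_per_feature *
                            cumsum(c(0, lens)) / sum(lens)))
        pid <- 0L
        for (j in seq_len(nrow(fr))) {
          nj <- alloc[j]
          if (nj == 0L) next
          avail <- (fr$end[j] - probe_len) - fr$start[j]
          if (avail < 0) stop("feature shorter than probe length")
          ps <- fr$start[j] + sort(round(runif(nj, 0, avail)))
          aff <- rlnorm(nj, 0, affinity_sdlog)
          ints <- sapply(labels, function(lab) {
            cond <- sub("_r[0-9]+$", "", lab)
            aff * scale * sig[[ftype]][[cond]] *
              rlnorm(nj, 0, sigma)
          })
          if (is.null(dim(ints))) ints <- matrix(ints, nrow = 1L,
                                                 dimnames = list(NULL, labels))
          row <- data.table(
            probe_id = sprintf("%s_%s%d_p%d", g, ftype, j,
                               pid + seq_len(nj)),
            chrom = m$chrom, start = ps, end = ps + probe_len)
          rows[[length(rows) + 1L]] <- cbind(row,
                                             data.table::as.data.table(ints))
          pid <- pid + nj
        }
      }
    }
    out <- data.table::rbindlist(rows)
    data.table::setattr(out, "samples", parse_sample_labels(labels))
    out[]
  })
}

#' Simulate a qPCR Ct table
#'
#' For every gene, intron (\code{<gene>_intron}, reads P) and exon
#' (\code{<gene>_exon}, reads P + M) primer pairs are observed at the
#' requested timepoints, alongside a constant-abundance reference pair.
#' Ct values follow \eqn{Ct = C_0 - \log_E(\text{abundance})} plus
#' additive normal noise. A standard-curve block (serial dilutions of
#' the unstressed sample, 2e-1 down to 1e-3) is included per primer
#' pair so efficiencies can be re-estimated downstream.
#'
#' @param panel list from \code{\link{simulate_gene_panel}}
#' @param timepoints sampled stress times (minutes)
#' @param n_reps biological replicates
#' @param sigma_ct sd of the additive Ct noise (cycles)
#' @param efficiency amplification efficiency used to generate Ct
#'   (single value or named per primer pair)
#' @param reference reference pair name (constant abundance)
#' @param ref_abundance abundance of the reference amplicon
#' @param c0 baseline cycle offset
#' @param dilutions standard-curve dilution factors
#' @param std_reps replicates per dilution point
#' @param seed integer seed
#' @return Ct table (data.table) in the \code{read_ct_table} layout
#' @export
simulate_ct_values <- function(panel, timepoints = c(0, 5, 10, 15),
                               n_reps = 3L, sigma_ct = 0.1,
                               efficiency = 2, reference = "ACT1_exon2",
                               ref_abundance = 50, c0 = 25,
                               dilutions = c(2e-1, 1e-1, 2e-2,
                                             1e-2, 2e-3, 1e-3),
                               std_reps = 1L, seed = 1L) {
  stopifnot(sigma_ct >= 0)
  params <- panel$params
  ab <- simulate_abundances(params, sort(timepoints))
  pair_abund <- list()
  for (g in params$gene_id) {
    abg <- ab[gene_id == g]
    pair_abund[[paste0(g, "_intron")]] <- setNames(abg$P, abg$time)
    pair_abund[[paste0(g, "_exon")]] <- setNames(abg$P + abg$M, abg$time)
  }
  pair_abund[[reference]] <- setNames(rep(ref_abundance,
                                          length(timepoints)),
                                      sort(timepoints))
  eff_of <- function(pp) {
    if (length(efficiency) == 1L && is.null(names(efficiency)))
      return(efficiency)
    if (!pp %in% names(efficiency))
      stop("no efficiency given for ", pp)
    efficiency[[pp]]
  }
  with_seed(seed, {
    rows <- list()
    for (pp in names(pair_abund)) {
      E <- eff_of(pp)
      for (tp in sort(timepoints)) {
        a <- pair_abund[[pp]][[as.character(tp)]]
        ct <- c0 - log(a, base = E) + rnorm(n_reps, 0, sigma_ct)
        rows[[length(rows) + 1L]] <- data.table(
          primer_pair = pp, sample = paste0("t", tp), timepoint = tp,
          replicate = seq_len(n_reps), ct = ct, dilution = NA_real_)
      }
      a0 <- pair_abund[[pp]][["0"]]
      for (d in dilutions) {
        ct <- c0 - log(a0 * d, base = E) + rnorm(std_reps, 0, sigma_ct)
        rows[[length(rows) + 1L]] <- data.table(
          primer_pair = pp, sample = "standard", timepoint = NA_real_,
          replicate = seq_len(std_reps), ct = ct, dilution = d)
      }
    }
    data.table::rbindlist(rows)[]
  })
}

#' Simulate transcription-rate time courses
#'
#' Transcription rates relax exponentially from the pre-stress value
#' toward tr x multiplier: \eqn{tr(t) = tr_0 (m + (1-m)e^{-t/\tau})},
#' with multiplicative log-normal noise. When \code{plant_classes} is
#' TRUE, RP genes are split evenly into three repression-kinetic
#' classes (strong/fast, intermediate, mild/slow) that a k = 3
#' clustering should recover; non-RP genes stay flat at m = 1.
#'
#' @param panel list from \code{\link{simulate_gene_panel}}
#' @param times sampled times (minutes)
#' @param sigma sdlog of the multiplicative noise
#' @param plant_classes plant the 3-class structure among RP genes
#' @param class_params data.frame of per-class final level m and time
#'   constant tau (minutes)
#' @param tau relaxation time constant (minutes) for genes outside the
#'   planted classes
#' @param seed integer seed
#' @return list: \code{tr} matrix genes x timepoints,
#'   \code{classes} named integer vector (0 = non-RP)
#' @export
simulate_tr_profiles <- function(panel, times = c(0, 2, 4, 6, 8, 10, 15),
                                 sigma = 0.1, plant_classes = TRUE,
                                 class_params = data.frame(
                                   m = c(0.15, 0.35, 0.6),
                                   tau = c(2, 4, 8)),
                                 tau = 4, seed = 1L) {
  stopifnot(sigma >= 0)
  params <- panel$params
  n <- nrow(params)
  classes <- integer(n)
  if (plant_classes && any(params$is_rp)) {
    idx <- which(params$is_rp)
    classes[idx] <- rep_len(seq_len(nrow(class_params)), length(idx))
  }
  with_seed(seed, {
    tr <- matrix(NA_real_, n, length(times),
                 dimnames = list(params$gene_id, as.character(times)))
    for (i in seq_len(n)) {
      if (classes[i] > 0L) {
        m <- class_params$m[classes[i]]
        tau_i <- class_params$tau[classes[i]]
      } else if (params$is_rp[i]) {
        m <- params$m_tr[i]; tau_i <- tau
      } else {
        m <- 1; tau_i <- tau
      }
      mean_tr <- params$tr[i] * (m + (1 - m) * exp(-times / tau_i))
      tr[i, ] <- mean_tr * rlnorm(length(times), 0, sigma)
    }
    list(tr = tr, classes = setNames(classes, params$gene_id))
  })
}

#' Write a complete, self-consistent synthetic dataset
#'
#' Emits everything the analysis readers consume -- annotation (GFF3),
#' probe intensities (TSV), Ct values (CSV), TR time courses (TSV) --
#' plus a ground-truth JSON (kinetic parameters, planted PMi, planted
#' TR classes).
#'
#' @param out_dir output directory (created if needed)
#' @param n_rp,n_other panel sizes
#' @param seed integer master seed
#' @param config \code{\link{panel_config}} list
#' @param sigma probe-intensity noise sdlog
#' @param sigma_ct Ct noise sd
#' @param n_reps replicates
#' @param probes_per_feature probes per feature
#' @return named character vector of written file paths, invisibly
#' @export
simulate_dataset <- function(out_dir, n_rp = 80L, n_other = 60L,
                             seed = 1L, config = panel_config(),
                             sigma = 0.1, sigma_ct = 0.1, n_reps = 3L,
                             probes_per_feature = 5L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_gene_panel(n_rp, n_other, seed = seed, config = config)
  probes <- simulate_probe_intensities(panel,
    probes_per_feature = probes_per_feature, n_reps = n_reps,
    sigma = sigma, seed = seed + 1L)
  cts <- simulate_ct_values(panel, n_reps = n_reps, sigma_ct = sigma_ct,
                            seed = seed + 2L)
  trp <- simulate_tr_profiles(panel, sigma = sigma, seed = seed + 3L)
  paths <- c(
    annotation = file.path(out_dir, "annotation.gff3"),
    probes = file.path(out_dir, "probes.tsv"),
    ct = file.path(out_dir, "ct.csv"),
    tr = file.path(out_dir, "tr.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_gene_models_gff3(panel$models, paths[["annotation"]])
  write_probe_table(probes, paths[["probes"]])
  write_ct_table(cts, paths[["ct"]])
  write_tr_table(trp$tr, paths[["tr"]])
  truth <- list(
    seed = seed, genotype = config$genotype,
    params = panel$params,
    true_pmi = as.list(true_pmi(panel$params, t = 15)),
    tr_classes = as.list(trp$classes))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}
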