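# Independent oracles: deliberately naive re-implementations used to
# cross-check the package's computation paths. They must stay free of
# pmindex internals.

oracle_pmi <- function(it0, it15, et0, et15) {
  log2((it15 / it0) / (et15 / et0))
}

# OLS by the normal equations, with r2 and a two-sided slope t-test
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  df <- n - 2L
  se <- sqrt(ss_res / df / sxx)
  t_stat <- if (se == 0) if (slope == 0) 0 else Inf else slope / se
  p <- if (se == 0) { if (slope == 0) 1 else 0 } else
    2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r2 = r2,
       t_stat = t_stat, p_value = p, df = df)
}

oracle_efficiency <- function(dilution, ct) {
  f <- oracle_ols(log10(dilution), ct)
  10^(-1 / f$slope)
}

# upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) draws (small N only)
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the category members
  mean(hits >= k)
}

# hypergeometric pmf from first principles (binomial coefficients)
oracle_hyper_pmf <- function(N, K, n, k) {
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}

# brute-force probe-to-feature containment over all pairs
oracle_containment <- function(probes, genes) {
  res <- list()
  for (i in seq_len(nrow(probes))) {
    hits <- list()
    for (g in genes) {
      if (g$chrom != probes$chrom[i]) next
      feats <- rbind(
        cbind(feature = "exon", as.data.frame(g$exons)),
        cbind(feature = "intron", as.data.frame(g$introns)))
      for (j in seq_len(nrow(feats))) {
        if (probes$start[i] >= feats$start[j] &&
            probes$end[i] <= feats$end[j]) {
          hits[[length(hits) + 1L]] <-
            data.frame(gene_id = g$gene_id, feature = feats$feature[j])
        }
      }
    }
    if (length(hits) == 0L) next
    h <- unique(do.call(rbind, hits))
    if (length(unique(h$gene_id)) > 1L) next  # ambiguous -> discarded
    res[[length(res) + 1L]] <- data.frame(probe_id = probes$probe_id[i],
                                          h[1L, , drop = FALSE])
  }
  if (length(res) == 0L)
    return(data.frame(probe_id = character(), gene_id = character(),
                      feature = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# fixed-step RK4 integrator for the two-compartment decay kinetics;
# oracle for the closed-form trajectory
oracle_rk4_abundance <- function(p, times, dt = 0.001) {
  a0 <- p$ks + p$d_pre
  P <- p$tr / a0
  M <- p$ks * P / p$d_m
  tr2 <- p$tr * p$m_tr; ks2 <- p$ks * p$m_ks
  dpre2 <- p$d_pre * p$m_dpre; dm2 <- p$d_m * p$m_dm
  deriv <- function(s) c(tr2 - (ks2 + dpre2) * s[1L],
                         ks2 * s[1L] - dm2 * s[2L])
  out <- matrix(NA_real_, length(times), 2L,
                dimnames = list(NULL, c("P", "M")))
  s <- c(P, M); t <- 0
  for (i in seq_along(times)) {
    while (t < times[i] - 1e-12) {
      h <- min(dt, times[i] - t)
      k1 <- deriv(s)
      k2 <- deriv(s + h / 2 * k1)
      k3 <- deriv(s + h / 2 * k2)
      k4 <- deriv(s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- s
  }
  out
}

# run code under a local seed without disturbing the global RNG stream
with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
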