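# pmindex

Quantifying stress-induced changes in pre-mRNA levels of yeast
intron-containing genes (ICGs).

## The problem

In *Saccharomyces cerevisiae*, only ~5% of genes contain introns, but
most ribosomal-protein (RP) genes do. Under osmotic stress (0.4 M NaCl),
RP gene expression is repressed at several levels; one open question is
what happens to the *unspliced* (pre-mRNA) pool relative to total mRNA —
a drop can reflect either more efficient splicing or faster pre-mRNA
degradation (e.g. by the nonsense-mediated decay pathway, NMD).

`pmindex` implements the analysis around the **PM index**:

```
PMi = log2[ (it15 / it0) / (et15 / et0) ]
```

where `it`/`et` are intron and exon signal intensities before (`t0`) and
after 15 min (`t15`) of stress. PMi < 0 means the pre-mRNA pool dropped
relative to total mRNA. For qPCR data the same index is computed from
efficiency-corrected relative levels,
`PMi = log2[ (E^-ddCt)_intron / (E^-ddCt)_exon ]`, with
`ddCt = (Ct_t,sample - Ct_t,reference) - (Ct_0,sample - Ct_0,reference)`
and `E = 10^(-1/slope)` estimated from a serial-dilution standard curve.

The package covers, per module:

* **I/O** — GFF3/BED12 gene models (0-based half-open internally),
  tiling probe tables (TSV), qPCR Ct tables (CSV), transcription-rate
  (TR) matrices (TSV); YAML-driven CLI (`exec/pmi`).
* **Tiling PMi** — strict-containment probe-to-feature assignment,
  median summarization, PMi with NA reasons, distribution bands and
  RP/non-RP group summaries.
* **qPCR PMi** — standard-curve efficiency fits, delta-delta-Ct
  relative levels, per-gene qPCR PMi.
* **TR analysis** — log2-to-t0 normalization, deterministic k-means
  (k-means++ seeding, best of 100 restarts), dTR at 15 min, and the
  PMi-vs-dTR ordinary-least-squares regression with r² and a two-sided
  slope t-test.
* **Enrichment** — upper-tail hypergeometric over-representation test.
* **Synthetic data** — a two-compartment kinetic generator
  (transcription → pre-mRNA → splicing → mature mRNA, with separate
  pre-mRNA and mature decay) with stress-triggered rate changes and
  genotype contracts (NMD-deficient genotypes lose the stress-induced
  pre-mRNA decay increase); used as ground truth by the entire test
  suite.

## Worked example

```r
library(pmindex)

panel  <- simulate_gene_panel(80, 60, seed = 1)       # RP + non-RP genes
probes <- simulate_probe_intensities(panel, sigma = 0.05, seed = 2)

asn <- map_probes_to_features(probes, panel$models)
sig <- summarize_feature_signal(asn, probes)
pmi <- compute_pmi(sig, genes = panel$models)

group_summary(pmi)
#>     group     n       mean         sd n_negative  n_na
#>    <char> <int>      <num>      <num>      <int> <int>
#> 1:     RP    80 -0.5169761 0.13573369         80     0
#> 2: non_RP    61 -0.0184649 0.08823974         36     0

classify_pmi_distribution(pmi)$percent
#>  below within  above
#>   33.3   66.7    0.0
```

The RP group mean near −0.5 is the planted stress effect (tripled
pre-mRNA decay, halved transcription, mildly faster mature decay), and
every RP gene comes out negative; non-RP genes sit at 0 (the built-in
positive control has PMi ≈ +0.2, inside the central band). Two thirds
of genes fall in the [−0.5, +0.5] band — the "below" group is exactly
the strongly affected RP tail. Under an NMD-deficient genotype the RP
effect disappears:

```r
upf1 <- simulate_gene_panel(80, 60, seed = 1,
                            config = panel_config(genotype = "upf1"))
mean(true_pmi(upf1$params)[upf1$params$is_rp])
#> [1] -0.07650619
```

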