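# quadclip

Downstream analysis of PAR-CLIP experiments on RNA G-quadruplex (rG4)
binding proteins — written for people who have transcript-space CLIP
alignments with T-to-C conversion marks plus matched RNA-seq/Ribo-seq count
matrices, and want to go from reads to occupancy-stratified conclusions
about mRNA abundance and translation.

PAR-CLIP reads out protein–RNA contacts through 4-thiouridine: crosslinked
positions appear as T-to-C substitutions, so genuine binding sites are
clusters of overlapping reads with conversion support. quadclip implements
the full downstream arc on tidy tibbles:

* **Cluster calling** — merge transitively overlapping reads per transcript;
  keep clusters with `n_reads ≥ 5`, `n_crosslinked ≥ 2`, conversion
  fraction ≥ 0.2; annotate to 5′UTR/CDS/3′UTR by maximal overlap.
* **Occupancy (NXPM)** — normalized crosslinked reads per million:
  NXPM(g) = 10⁶ · xl(g)/Σxl / TPM(g), overall and per region, with
  replicate R² on log₁₀(NXPM + ε).
* **k-mer enrichment** — Z = (X − μ)/σ per 5-mer, where X is the target
  proportion and μ, σ come from composition-preserving scrambles of the
  cluster sequences; 5-mers labeled G-rich (≥3 G) or AU-rich (≥4 A/U).
* **rG4 scanning** — canonical motifs of ≥4 G-tracts (≥3 G) with 1–7 nt
  loops, leftmost-greedy with maximal extension, plus recovery fractions of
  motif catalogs by binding clusters.
* **Metagene profiles** — binned cluster density 200 nt after the start
  codon / 500 nt after the stop codon against a null of 1000
  length-preserving uniform repositionings.
* **Integration** — median-of-ratios or CPM normalization, per-gene log₂
  fold changes, translational efficiency TE = RPF/RNA with
  ΔTE = log₂(TE_KO/TE_WT), NXPM-binned CDF comparisons with two-sided
  Kolmogorov–Smirnov tests, exponential mRNA half-life fits
  (t½ = ln2/k from ln(level) ~ time), and CTCF imaging correction.
* **Synthetic data** — a seeded generator planting rG4 sites, conversion
  reads, and WT/KO count matrices with known ground truth, so every stage
  is testable end to end.

Fitted objects have broom-style `tidy()`/`glance()` methods and
`autoplot()`/`plot_binned_cdf()` ggplot2 graphics. A thin CLI lives at
`inst/cli/quadclip.R` (`simulate`, `clusters`, `nxpm`, `kmer-enrich`,
`g4scan`, `metagene`).

## Worked example

```r
library(quadclip)
library(dplyr)

cfg <- sim_config(n_genes = 200, seed = 1)
sim <- simulate_transcriptome(cfg)
reads <- simulate_parclip_reads(sim$transcripts, sim$truth, cfg)
clusters <- call_clusters(reads, sim$transcripts)
counts <- simulate_counts(sim$transcripts, sim$truth, cfg)
head(clusters, 3)
#> # A tibble: 3 × 9
#>   transcript_id gene_id  start   end n_reads n_crosslinked conversion_fraction
#> 1 tx0006        gene0006   220   326      10             2               0.2
#> 2 tx0007        gene0007   393   445       5             2               0.4
#> 3 tx0008        gene0008    68   159     124           111               0.895
```

Occupancy tracks the planted site strength (Spearman rank correlation of
NXPM against ground-truth occupancy over target genes):

```r
profiles <- compute_nxpm(clusters, compute_tpm(counts, sim$transcripts))
profiles |>
  inner_join(sim$truth, by = "gene_id") |>
  filter(is_target, !is.na(nxpm)) |>
  summarise(rank_cor = cor(nxpm, occupancy, method = "spearman"))
#>   rank_cor
#> 1    0.917
```

The motif scanner recovers every planted rG4 (71 of 71 on this seed, and
none elsewhere — background G-runs are capped below 3 by construction):

```r
g4 <- scan_g4(sim$transcripts)
overlap_with_sites(
  sim$truth |> filter(is_target) |>
    transmute(transcript_id, start = site_start, end = site_end),
  g4
)
#>   region n_sites n_recovered fraction
#> 1 all         71          71        1
```

A decay series halving every ~4 h fits accordingly:

```r
fit_halflife(c(0, 2, 4, 8), c(1, 0.71, 0.5, 0.25))
#> <decay_fit> k = 0.1735 per h, half-life = 3.996 h, R^2 = 1
```

See `vignettes/occupancy-analysis.Rmd` for the full methods account.

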