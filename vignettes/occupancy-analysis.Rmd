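---
title: "Conversion-aware PAR-CLIP occupancy analysis with quadclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conversion-aware PAR-CLIP occupancy analysis with quadclip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadclip)
library(dplyr)
```

## The analysis problem

PAR-CLIP maps where an RNA-binding protein touches the transcriptome. Cells
are fed 4-thiouridine, crosslinked with UV light, and the protein-bound RNA
fragments are sequenced; reverse transcription through a crosslinked 4SU
reads out as a T-to-C substitution, so true contact sites carry a diagnostic
conversion signature that co-purifying background does not. For a
G-quadruplex (rG4) resolving helicase, the downstream questions are: where
are the binding sites along transcripts, do they look like rG4s, how much of
each mRNA is occupied, and what happens to mRNA abundance and translation
when the protein is knocked out.

quadclip implements that downstream arc as composable, pipe-friendly steps
on tibbles: cluster calling from conversion-marked reads, per-gene occupancy
(NXPM), k-mer and rG4 motif analysis of cluster sequences, metagene
positional profiles with a randomization null, and occupancy-binned
integration of RNA-seq and Ribo-seq count matrices. A seeded synthetic-data
generator produces datasets with known ground truth so every stage can be
validated end to end at desk scale.

## Cluster calling

Reads live in transcript coordinates (0-based, half-open) and carry the
read-relative offsets of their T-to-C conversions. `call_clusters()` merges
transitively overlapping reads on each transcript into one interval (the
union of read extents) and keeps a cluster only if

* `n_reads >= min_reads` (default 5),
* `n_crosslinked >= min_crosslinked` (default 2), where a crosslinked read
  has at least one conversion, and
* `conversion_fraction >= min_conversion_fraction` (default 0.2).

This is deliberately a transparent merge-based caller: it captures the
conversion-supported-cluster concept without the kernel-density boundary
refinement that dedicated PAR-CLIP pipelines add. The defaults were chosen
once as a conservative desk-scale setting: five overlapping reads with two
independent crosslink events and a 20% conversion fraction is far above what
uniform background reads produce at the simulated depths, while planted
sites pass easily. The caller is verified against a brute-force O(n^2)
interval-merge oracle on random instances.

Clusters are annotated to the region of maximal overlap, with ties broken
UTR over CDS and 5'UTR first (precedence 5'UTR > 3'UTR > CDS) and a
`spanning` flag recording boundary-crossing clusters, so per-region read
sums partition deterministically.

## NXPM occupancy

Crosslinked reads per gene are normalized two ways: within the library
(XPM, crosslinked reads per million crosslinked reads) and by mRNA
abundance,

$$\mathrm{NXPM}(g) = \frac{10^6 \cdot \mathrm{xl}(g) / \sum_{g'} \mathrm{xl}(g')}{\mathrm{TPM}(g)}.$$

Abundance is TPM computed from the wild-type RNA-seq counts
(`compute_tpm()`); the absolute NXPM scale therefore depends on this unit
choice and is not comparable across implementations that normalize
differently — only orderings and bin contrasts are. Genes below `min_tpm`
(default 1) are flagged `low_abundance` and excluded from scoring rather
than dropped. Replicate agreement is summarized as the squared Pearson
correlation of `log10(NXPM + eps)` with `eps = 1e-3`, the conventional
scatterplot R^2.

## k-mer enrichment and the scrambled null

The recognition-element analysis counts all 4^5 overlapping 5-mers in the
cluster sequences and scores each against a background built by scrambling
every cluster sequence (a uniformly random permutation of its characters,
which preserves the entire base composition and hence GC content — strictly
stronger than preserving GC alone, and unambiguous). With X the target
proportion of a 5-mer and mu, sigma the mean and standard deviation of its
proportion over `n_background` scramble draws,

$$Z = \frac{X - \mu}{\sigma}.$$

The draw count is not a quantity with a canonical value; 50 draws (the
default) already gives mu and sigma estimates stable enough that the Z
ranking of strongly enriched k-mers does not move, and the null calibration
test checks that composition-matched random targets give Z centered within
±0.2 of zero. Degenerate k-mers (sigma = 0) are reported but excluded from
ranking; the homopolymer case X = mu gets Z = 0. 5-mers are labeled G-rich
(at least three Gs), else AU-rich (at least four of five bases A or U — the
threshold is not canonical either and is exposed as the documented rule),
else other; G-rich takes precedence.

## rG4 motif scanning

`scan_g4()` finds canonical quadruplex-competent motifs: at least
`min_tracts = 4` maximal G-runs of length `>= min_tract = 3`, separated by
loops of 1 to `max_loop = 7` nt. The scan is leftmost-greedy with maximal
extension (consecutive qualifying tracts within loop distance are absorbed
into one motif) and reports non-overlapping motifs with their tract and loop
structure. Because recent biophysics argues rG4s can form with fewer Gs and
longer loops, all three parameters are exposed. The scanner is checked
against an exhaustive enumerating scanner across a parameter grid on random
sequences.

`overlap_with_sites()` quantifies recovery of a motif catalog by binding
clusters: a site is recovered if any same-transcript cluster overlaps it by
at least 1 nt, reported overall and per region.

## Metagene profiles and the randomization null

`metagene_profile()` accumulates per-nt cluster coverage in windows
downstream of the start codon (default 200 nt) or stop codon (default 500
nt), in `bin_width = 10` nt bins. Transcripts whose region is shorter than
the window contribute their truncated part, and each bin is divided by the
number of transcript-nt actually available to it, so 3'-short transcripts do
not deflate distal bins. The profile is normalized to sum to 1; an all-zero
profile is returned unnormalized and flagged.

The null ("mismatched randomized controls" in the figure-legend idiom of
the field, but never formally defined there) is implemented as
length-preserving uniform repositioning of every cluster within its own
transcript, recomputed `n = 1000` times by default. This is the minimal
null for positional enrichment: it preserves per-transcript cluster load and
the cluster length distribution and randomizes only position. Shuffling
clusters across transcripts was considered and rejected because it
confounds positional enrichment with transcript-composition effects. The
per-bin mean and SD of the draws give the envelope, and
`(observed - null_mean) / null_sd` the enrichment in SD units.

## Count integration: fold changes, TE, binned CDFs

Count matrices are normalized with `normalize_counts()`: CPM, or
median-of-ratios (per-sample size factor = median over all-nonzero genes of
count / geometric row mean) — the same estimator as the standard
differential-expression tools, cross-checked against one of them in the
test suite. Per-gene responses are transparent normalized-mean log2 fold
changes with pseudocount 1 (`log2fc()`); a dispersion-moderated test is
deliberately out of scope because the binned CDF comparisons consume
per-gene fold changes, not significance calls, and no multiple-testing
correction is applied across bins (one KS p-value per panel is reported, as
is conventional for CDF displays).

One caveat matters when a third of the genes move in one direction: any
median-anchored size factor absorbs part of the composition shift, biasing
every per-gene fold change slightly against the shift. The recovery
analyses therefore report the target fold change relative to the non-target
median — exactly the contrast a binned CDF display makes — rather than the
raw normalized value.

Translational efficiency is TE = RPF abundance / RNA abundance per
condition, and `delta_te = log2(TE_KO / TE_WT)`. Genes with mean normalized
abundance below 1 in any (assay, condition) group are flagged and excluded,
not dropped. `bin_targets()` partitions the gene universe into a non-target
reference (no clusters), right-open occupancy bins, and — when binning on an
NXPM metric — an "unscored" bin for clustered genes removed by the abundance
filter, so the bins always partition the universe. `cdf_ks_compare()` runs
two-sided two-sample KS tests of each bin against the reference
(exact p-values in the small-sample no-ties regime, asymptotic otherwise,
as implemented by `stats::ks.test`), reporting D, p, and medians for
direction.

## Decay fits and imaging

`fit_halflife()` fits ln(level) ~ time by least squares — the log-linear
form of first-order decay behind actinomycin-D chase qPCR series sampled at
0/2/4/8 h — returning k = -slope, half-life ln(2)/k for k > 0, and flagging
non-decaying series instead of reporting a negative half-life. Input is a
generic long table of relative levels (normalized to t = 0 by convention),
so real ddCt tables drop in. `ctcf()` applies the standard imaging
background correction, integrated density - area x background mean, with a
flag for negative values.

## What the synthetic generator emulates — and what it does not

`sim_config()` fixes the study conditions. Defaults: 500 genes; 5'UTR
100-300 nt, CDS 300-1500 nt (in frame), 3'UTR 200-800 nt; 30% target genes;
site placement weights 0.2/0.4/0.4 over 5'UTR/CDS/3'UTR (UTR-heavy, as
G4-helicase binding analyses emphasize UTR sites); log-normal occupancy
with sdlog 1 (heavy-tailed, like real NXPM distributions) clipped at its
95th percentile and rescaled so planted effects stay bounded; planted KO
effects beta_mrna = 0.3 and beta_rpf = 0 per unit scaled occupancy (mRNA up,
ribosome footprints flat, hence TE down — the phenotype of interest);
negative-binomial dispersion 0.05; 30,000 PAR-CLIP reads of 30 nt with 80%
from sites; conversion probabilities 0.25 per T for site reads versus 0.01
for background; RNA/RPF depths 2M/1M over 3 replicates per condition. The
degenerate setting `occupancy_scale = 0` gives every target unit scaled
occupancy, which makes every planted mRNA LFC exactly beta_mrna; the
parameter-recovery analyses use it so that the recovered median has a sharp
planted value to match.

Background sequence is uniform over A/C/T with G-runs capped below 3 nt,
and each planted motif (four G-tracts of 3-4 Gs, loops 1-7 nt over A/C/T,
non-G buffer at both flanks) is drawn from the scanner's own grammar, so
planted motifs are by construction the only canonical G4s and
scanner recovery on synthetic data is exact. That is the point — it
separates scanner correctness from grammar debates — but it also means
passing tests say nothing about how real transcriptomes blur the
planted/background boundary with near-miss G-rich sequence. Likewise the
generator has no splicing, no isoforms, no sequencing error, no adapter or
UMI artifacts, no positional coverage bias, and one site per target gene;
conclusions about those aspects of real data are out of reach of this test
bed by design.

Every generator call takes one seed (recorded in the output attributes) and
is byte-reproducible; the three stages derive defaults seed, seed+1, seed+2
from the config so a single integer pins the whole dataset.

## Problem sizes and numerical choices

The validation suite runs the full arc — simulate, call clusters, NXPM,
k-mer Z, G4 scan, normalize, TE, bin, KS — at 500 genes with 3+3
replicates, and the oracle comparisons at up to 200 reads, 500-nt
sequences, and KS sample sizes up to 6 (where full enumeration is exact).
These sizes were chosen so the whole suite completes in about a minute
while every statistic is still well inside its asymptotic regime of
interest. Metagene nulls in tests use 300-500 draws; the default for
analysis remains 1000. Numerical edge cases are handled explicitly rather
than by convention: zero-signal metagene profiles are flagged instead of
normalized, sigma = 0 k-mers are flagged instead of dividing by zero,
non-decaying series are flagged instead of returning negative half-lives,
and negative CTCF values are flagged rather than clipped.

## Worked example

```{r example}
cfg <- sim_config(n_genes = 200, seed = 1)
sim <- simulate_transcriptome(cfg)
reads <- simulate_parclip_reads(sim$transcripts, sim$truth, cfg)
clusters <- call_clusters(reads, sim$transcripts)
counts <- simulate_counts(sim$transcripts, sim$truth, cfg)

profiles <- compute_nxpm(clusters, compute_tpm(counts, sim$transcripts))
profiles |>
  inner_join(sim$truth, by = "gene_id") |>
  filter(is_target, !is.na(nxpm)) |>
  summarise(rank_cor = cor(nxpm, occupancy, method = "spearman"))
```

```{r g4}
g4 <- scan_g4(sim$transcripts)
overlap_with_sites(
  sim$truth |>
    filter(is_target) |>
    transmute(transcript_id, start = site_start, end = site_end),
  g4
)
```

## Known limitations

* Transcript-space only, one principal transcript per gene; genome-space
  lifting, splicing, and multi-isoform assignment are out of scope.
* The merge-based caller does not model within-cluster conversion
  positions; cluster boundaries are read-extent unions.
* Absolute NXPM values depend on the TPM normalization choice; bin bounds
  expressed in NXPM units do not transfer across pipelines.
* KS p-values are per comparison; no correction across bins.
* The synthetic generator validates algorithmic correctness, not robustness
  to real-data artifacts (see above).
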