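---
title: "Methods: Pol II occupancy profiling on a synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pol II occupancy profiling on a synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`polprof` implements a ChIP-seq-style analysis of RNA polymerase II
occupancy — anchored metagene profiles, fold enrichment over input, a
window comparison test, promoter-proximal pausing indices — together with
regulated-gene-set statistics, core-promoter motif enrichment, and a
phosphoproteomic triage pipeline. Because the statistics are meant to be
auditable, the package also ships the synthetic data generator used to
validate every claim: all planted effects are recorded in truth tables, so
recovery can be scored exactly.

This vignette documents the model, the parameter choices, the numerical
conventions, and the known limitations. It makes no empirical claim that
is not recomputed by the test suite or by `scripts/acceptance.R`.

## Coordinates and anchors

All intervals are 0-based half-open `[start, end)`. The TSS of a
plus-strand gene is `start`; for a minus-strand gene it is `end - 1`, and
"downstream" always means the direction of transcription. A relative
interval `[lo, hi)` around an anchor maps to genomic
`[anchor - hi + 1, anchor - lo + 1)` on the minus strand. On-disk formats
keep their native conventions (BED 0-based, GFF3/SAM 1-based) and are
converted on read.

## The synthetic occupancy model

`sim_config()` + `simulate_genome()` build a toy genome: by default one
1-Mb chromosome carrying 200 non-overlapping genes (minimum 2 kb,
shifted-exponential lengths, at least 1 kb apart, random strands). Genes
belong to classes; the default study has 50 "coact" genes (co-activated
targets whose upstream recruitment component is halved in the `smk1`
condition) and 150 background genes.

`simulate_reads()` draws one library of `depth` fragments whose 5' starts
follow a per-gene mixture, in transcription-direction coordinates:

* a Gaussian **upstream recruitment** component at −150 bp from the TSS,
* a Gaussian **promoter-proximal pause** component at +50 bp,
* **uniform gene-body** coverage over `[TSS + 500, TES]`,
* a Gaussian **termination** component at the TES (shifted downstream by
  `tes_shift` per condition),

all Gaussians with sd 80 bp truncated at ±4 sd, plus genome-wide uniform
**background**. Component weights are `amplitudes × class multipliers`
(background: `background_rate` per kb), normalised jointly so each
library totals `depth` fragments (one multinomial draw). Input libraries
draw from the background alone. Reads are 200 bp, 5'-anchored,
strand-aware, clipped at chromosome bounds.

Default parameters and rationale:

| parameter | default | rationale |
|---|---|---|
| `amplitudes` | up 30, pause 100, body 60, tes 30 | dominant promoter-proximal peak, as in typical Pol II ChIP; recruitment and termination are shoulders |
| `pause_center` | +50 bp | canonical pause position |
| `upstream_center` | −150 bp | pre-initiation/recruitment shoulder upstream of the TSS |
| `peak_sd` | 80 bp | peak widths comparable to fragment size |
| `background_rate` | 20 fragments/kb (relative) | visible but non-dominant input-like floor |
| `depth` | 2 × 10⁵ per library | desk-scale depth at which the planted recruitment defect is near the detection boundary |
| `fragment_length` | 200 bp | standard sonication/extension scale |

Because the library size is fixed, the model is **compositional**:
reducing one component (e.g. halving recruitment at 50 genes) slightly
raises expected coverage everywhere else (~1% here). This is a real
property of fixed-depth sequencing, not a bug; it matters for the
"unaffected set" analyses below.

Determinism: every stochastic operation draws from a stream derived from
`(seed, operation label)`, so any single artefact (genome, one library,
one table) is reproducible in isolation.

`simulate_genome()` also plants a literal `TATAAAAG` instance at −30 ± 5
on the sense strand for class genes selected with `tata_prob`, and
records planted log2 fold-changes per DE contrast; `simulate_de_table()`
and `simulate_phospho_table()` turn the truth into screen-like tables
(null genes get uniform q-values, so a nominal FDR-fraction of them are
false positives, as in a real screen).

## Coverage, enrichment, and the window test

`bin_density()` counts extended fragments overlapping 60-bp bins in a
±600 bp window around the TSS/TES/summit (or 1% gene-body bins) and
scales to `count × 10⁹ / (bin bp × total mapped)` (RPKM-like). A fragment
increments every bin it overlaps. Out-of-bounds bins are kept but `NA`.

`fold_enrichment()` divides IP by input densities per bin. The default
aggregation averages densities across the gene set first and then takes
the ratio (`set_mean`), which is the convention for plotted average
profiles; per-gene ratios are available via `aggregate = "per_gene"`. A
pseudocount of 1 density unit guards empty input bins; empty-vs-empty
bins are exactly 1.

`compare_window()` tests the 20 bins in −600..+600 with a paired t-test
across bins (pairs = the same bin under two conditions; Welch unpaired is
available). Degenerate cases follow fixed conventions: all differences
zero → p = 1; constant non-zero differences → t = ±∞, p = 0.

**Known limitation (measured, not hidden):** adjacent 60-bp bins share
200-bp fragments, so the 20 "paired observations" are positively
correlated and the across-bin t-test is anticonservative. The acceptance
suite and `scripts/acceptance.R` measure the null rejection rate of this
test at α = 0.05 by comparing independent library pairs drawn from
identical settings; it comes out near 0.33 rather than 0.05. Treat the
window p-value as a descriptive ranking statistic, as is common for
average-profile comparisons, not as a calibrated error rate. The
moderated per-peptide test in the phospho module, by contrast, is
calibrated (null rate ≈ 0.05, also measured there).

## Pausing indices

`ratio_track()` tiles the genome with 60-bp bins and forms
`(RPKM_ip + 1) / (RPKM_input + 1)` after 200-bp fragment extension.
`pausing_indices()` averages the track over three per-gene regions in
transcription direction — relaxed `[-500, +500)`, stringent `[0, +500)`,
body `[+500, TES)` — with overlap weighting at region edges, and forms
index = region mean / body mean. Genes whose body is shorter than one
complete bin are excluded with a recorded reason. The set-level index is
the arithmetic mean of per-gene indices over usable genes.

On the default study the stringent set-mean index changes by well under
10% between conditions (the recruitment defect does not masquerade as a
pausing change), while doubling only the pause amplitude raises the index
— both are asserted in the acceptance suite, the latter on noise-free
expected densities computed in closed form.

## Gene sets, suppression, overlap, motifs

`classify_regulated()` thresholds screen q-values at FDR 0.05:
`up_in_mutant`/`down_in_mutant` from the `mutant_vs_wt` contrast, and
`activated_by_X`/`repressed_by_X` from each within-mutant RNAi contrast.
`suppression_fraction()` reports the fraction of mutant-regulated genes
that the RNAi significantly reverses (default) or attenuates below 50% of
the mutant fold-change. `overlap_test()` is the exact one-sided
hypergeometric upper tail, computed in log space and verified against
full enumeration for every universe up to 12.

`motif_enrichment()` extracts sense-strand promoter windows (default
TATA: `TATAWAWR` in `[-100, 0)`), scans the IUPAC consensus with
`Biostrings`, and applies the same hypergeometric test to set vs
set∪background hit counts.

## Phosphoproteomic triage

`normalize_intensities()` divides each sample by its total (relative
intensities; idempotent). `differential_phospho()` tests log2 relative
intensities per peptide; zeros are floored at half the smallest non-zero
value. The default test is limma's moderated t — at 3 vs 3 replicates the
per-peptide Welch test has almost no power after BH correction (measured
recall below 1% on the planted benchmark, versus ≈ 90% moderated), which
is why moderated is the default and Welch an option. BH-adjusted p < 0.05
with a positive fold-change flags a peptide `increased`.
`rank_candidates()` collapses to proteins (best adjusted p among
increased peptides), keeps reporter-screen hits, ranks by best p, and
annotates co-purification without filtering on it.

## Problem sizes used in validation

Module tests run on 120-kb/20-gene configurations; oracle-equality tests
use ≤10-kb toys where brute-force per-base pileups are exact; the
acceptance suite runs the full default study over 20 seeds, 200-replicate
null calibrations on a 600-kb/100-gene null genome (shared genome,
independent libraries), and 20 phospho tables of 2000 peptides.

## Limitations

* The generator is a stylised single-factor model: no replicate
  variability between libraries, no mappability/GC structure, no
  antibody-efficiency differences, and background shared between IP and
  input. Fold-enrichment magnitudes are therefore cleaner than real data.
* The window test's bin correlation (above) makes its p-values
  anticonservative; rates are measured and reported rather than
  corrected, matching common practice for profile comparisons.
* The compositional renormalisation of fixed-depth libraries gives
  "unaffected" genes a small real shift when other genes change; with
  strong planted effects this bounds how specific any between-condition
  test at unaffected genes can be.
* DE and phospho tables are simulated at the summary-statistic level
  (planted fold-changes and calling power), not from count models.
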