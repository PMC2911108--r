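---
title: "Bar-seq fitness profiling: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bar-seq fitness profiling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqfit)
```

## The measurement

A barcoded deletion library tags every strain with one or two unique 20-nt
DNA sequences (the *uptag* and *dntag*) flanking the deletion cassette. When
thousands of strains grow together in one culture, the number of sequencing
reads carrying a strain's barcode is proportional to that strain's cell
number, so deep sequencing of barcode PCR amplicons turns pooled competitive
growth into a per-strain fitness readout.

Each sequencing read is 42 nt laid out as

```
cycles  1-4    5-22                    23-42
        index  universal primer        strain barcode
        (4 nt) (18 nt, up- or dn-tag)  (20 nt)
```

The 4-nt multiplex index identifies the sample (several samples share a
sequencing lane), the 18-nt universal primer identifies the amplicon class
(uptag vs dntag), and the final 20-mer identifies the strain.

## Read-to-count rules

`count_reads()` applies three matching steps, in order:

1. **Index, exact.** The first four cycles must equal a known index exactly.
   Index sets from `design_indexes()` have pairwise Hamming distance at
   least 2 (a parity code over `{A,C,G,T}^4`; 64 codewords, which is the
   maximum), so one sequencing error can never reassign a read to a
   different sample — it simply fails to match. No mismatch rescue is
   attempted.
2. **Primer, at most 2 mismatches.** Cycles 5–22 are compared to both
   universal primers; the closer primer wins if it is within
   `max_primer_mismatch` (default 2) substitutions. The two primers differ
   at far more than four positions, so the tie branch is defensive only.
3. **Barcode, exact.** Cycles 23–42 are looked up verbatim in the catalog.
   Barcodes used by more than one (strain, tag-class) association are
   *ambiguous*: reads matching them are counted under a discard reason, not
   assigned. The catalog lookup supplies the gene and the tag class; the
   primer step only gates the amplicon. Data in which primer class and
   barcode class disagree cannot arise from a consistent catalog, so the two
   readings are operationally identical.

Every read is either assigned or lands in exactly one discard counter
(`malformed`, `unknown_index`, `primer_fail`, `barcode_unmatched`,
`ambiguous_barcode`), so assigned + discarded = processed always holds.

A barcode serving as uptag for one gene and dntag for another is excluded as
ambiguous even though the primer could in principle disambiguate it; the
catalog-level contract stays conservative. A barcode occurring as both tags
of a *single* strain is excluded for the same reason.

## The growth-inhibition score

With raw barcode reads \(c\) (control) and \(t\) (treatment) and per-sample,
per-tag-class matched totals \(N_c, N_t\), the normalized fold change at
pool generation \(g\) is

\[
FC_g \;=\; \frac{(c_g + 1)\, \cdot 10^6/N_{c,g}}{(t_g + 1)\, \cdot 10^6/N_{t,g}},
\]

and the growth-inhibition score is the weighted mean of per-generation
log-depletion rates,

\[
GI \;=\; \sum_g a_g \,\frac{\log_2 FC_g}{g}, \qquad \sum_g a_g = 1,\; a_g \ge 0 .
\]

An unaffected strain has \(FC_g = 1\) throughout and \(GI = 0\); a strain
whose cell number stays constant while the pool doubles \(g\) times has
\(FC_g = 2^g\) and \(GI = 1\); enrichment under treatment gives negative
scores. For the one-timepoint drug designs (\(a_5 = 1\)) the score inverts
exactly: \(FC = 2^{5\,GI}\), so \(GI = -0.78\) corresponds to a
\(2^{3.9} \approx 15\)-fold abundance gain over five doublings.

Parameter choices, all exposed in `scoring_params()`:

* **pseudocount = 1 read** — added to both counts before the ratio, purely
  to avoid division by zero. Scale factors use the raw totals, which real
  reads dominate.
* **min_control_reads = 12** — a tag is not scored when its *raw* control
  reads fall below 12 at any positively weighted generation. Whether this
  threshold should apply to raw or per-million counts is ambiguous in the
  source conventions (the replicate-agreement filter appears to use
  normalized values); raw is the conservative choice here because it never
  admits a barcode the normalized rule would admit at typical depths, and
  the threshold is a plain parameter for anyone who wants otherwise.
* **normalization_total = 10^6** — counts per million, per sample and per
  tag class, so uptag and dntag libraries of different depth are comparable.

Per strain, uptag and dntag scores are averaged when both exist; a single
defined score is used as-is; neither leaves the strain unscored
(`status` column: `ok`, `insufficient_control_reads`, `no_barcode`).

## Hit calling

Screens run as three independent experiments (A, B at one dose, C at double
dose). Per experiment the combined-GI distribution of all scored strains
supplies robust location and spread: median and
\(NIQR = 0.7413 \times IQR\), the interquartile range rescaled to estimate
a normal standard deviation. Cutoffs are median + k·NIQR with

* k = 3 for strains scored by a single tag;
* k = 2.5 for the averaged score of dual-tag strains, **and** k = 2 for each
  individual tag.

Low-coverage barcodes can reach high GI by chance, so a second filter
requires at least one tag per gene to reject equal-proportions by the
likelihood-ratio G-test, \(G = 2\sum O \ln(O/E)\) on the 2×2 table (barcode
reads vs all other reads, control vs treatment), \(\chi^2_1\) tail,
p < 0.005. The test needs no replicates, which suits per-barcode count
data. Design choices: the table uses the *final* weighted generation's raw
counts (the time point carrying the accumulated fitness signal; the source
does not state which time points entered the test, and the choice is
config-exposed); the statistic is uncorrected (a Williams-correction toggle
exists); p-values are not multiplicity-adjusted because the scheme relies on
a fixed cutoff *plus* replication, not an FDR target.

A gene is a **sensitive hit** when it passes both filters in at least 2 of
the 3 experiments. All boundary comparisons are inclusive.

**Resistant mutants** are not called by a formal test: strains are ranked by
ascending GI (`rank_resistant()`, ties broken by gene id for determinism)
and flagged descriptively at GI ≤ −0.5, inclusive. The rationale is that
dose–response, not a distribution cutoff, is what distinguishes true
resistance in this assay, and ranking preserves that judgement for the
analyst.

## Quality control

* `replicate_correlation()` — Pearson r of log10 normalized counts over
  barcodes positive in both samples. Log scale is used because barcode
  abundances span orders of magnitude; a raw-scale option exists.
* `tag_agreement()` — correlation of uptag- vs dntag-derived log2
  control/treatment ratios over strains with both tags scored, control
  reads ≥ 12 for both tags and treatment reads > 0.
* `spikein_fit()` — slope/R² of log10 normalized reads vs log10 spike-in
  cell ratio (study design used ratios 1/200 down to 1/20,000); slope 1 on
  noise-free proportional data.
* `cluster_profiles()` — agglomerative average-linkage clustering of the
  gene × condition GI matrix under the uncentered-correlation distance
  \(1 - \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}\) (similarity about
  zero, because GI = 0 is the biologically neutral point, unlike centred
  Pearson similarity). Missing cells are imputed as 0 — the neutral value —
  with a message per run; zero-norm profiles get similarity 0 to everything.
  Average linkage admits height inversions in principle, so monotone heights
  are not asserted anywhere; heights are nonnegative by construction.
  Dendrograms export to Newick with merge heights as branch lengths.

## The simulator

`simulate_pool_experiment()` generates the data the pipeline is tested
against:

* **Growth.** Competitive exponential growth under repeated dilution:
  strain fractions \(p_i(g) \propto p_i(0)\, 2^{f_i g}\), where \(f_i\) is
  relative fitness in doublings per pool doubling (1 = wild type, 0 =
  arrested, >1 = advantage) and \(g\) counts doublings of the *total* pool,
  as monitored by optical density in the wet protocol.
* **Initial pool.** Log-normal abundances, sigma 1 by default. The true
  dispersion of a pooled library is not documented; sigma 1 (roughly
  1.5 orders of magnitude between 2.5th and 97.5th percentile) reproduces
  the wide abundance scatter seen in replicate scatter plots and is
  configurable.
* **Sequencing.** One multinomial draw per tag class of `depth` reads
  (10^6 by default, the per-sample scale of the study), probabilities
  proportional to abundance × per-barcode amplification bias. Bias weights
  are log-normal, drawn once per barcode and reused across samples — they
  emulate PCR/tag efficiency differences, which cancel in control-vs-
  treatment ratios exactly because they are sample-invariant.
* **Spike-ins.** Binomial reads at expectation \(L \cdot r/(1-\sum r)\) for
  library reads \(L\) and cell ratio \(r\), appended without altering
  library counts.
* **Reads.** `emit_fastq()` writes one 42-nt read per count with
  substitution-only errors (uniform over the three alternative bases),
  constant quality `I`, deterministic shuffling. No indels are modelled:
  fixed-cycle short-read substitutions dominate, and indels would only
  shift reads out of frame and lower the matched fraction without changing
  any contract. Under a 1% per-base error the fully error-free fraction is
  \(0.99^{42} \approx 0.66\); the default 2-mismatch primer tolerance
  raises survival to \(0.99^{24}\,P[\mathrm{Bin}(18, 0.01) \le 2]
  \approx 0.79\). Both closed forms are asserted in the tests (the strict
  figure under `read_layout(max_primer_mismatch = 0)`).

What the simulator deliberately does **not** model: lag and recovery phases,
drug pharmacodynamics, cross-well contamination, strain interactions, or
indel/chimera artefacts. Passing tests therefore demonstrate that the
*analysis* is correct and well-calibrated under the stated sampling model,
not that real libraries are free of these additional noise sources.

## Numerical conventions

* Quartiles by linear interpolation of order statistics (type-7), so
  `robust_stats(1:5)` gives IQR 2 and NIQR 2 × 0.7413 = 1.4826.
* G-test zero cells contribute 0 to the sum; equal proportions give G = 0,
  p = 1 exactly.
* All randomness flows through explicit integer seeds; every simulation
  function accepts one, and `run_barseq()` seeds once per run, so reruns are
  byte-identical.
* Resistant ranking and index design break ties deterministically (gene id,
  lexicographic order).
* All pipeline steps are single-threaded vectorized R; results are
  independent of any thread setting by construction.

## Problem sizes used in the test suite

Unit tests run on toy catalogs (3–30 strains) and closed-form cases. The
simulation-based checks use the study-scale conditions where the claim
depends on them: 2,500 strains at 10^6 reads per tag class for replicate
correlation, auxotroph recovery (7 planted arrested strains among 2,500,
rich vs minimal, generations 1–5 weighted 0, 0, 1/3, 1/3, 1/3) and
sensitive-hit recovery (5 planted f = 0.5 strains, 3 replicate experiments,
single generation g = 5); 10^5 reads for the error-attrition checks. The
full suite completes in well under a minute.

## Known limitations

* Exact barcode matching discards reads with any barcode error rather than
  attempting rescue; this trades ~1-2% sensitivity per percent error for
  zero risk of cross-strain misassignment.
* The G-test's chi-square approximation is rough for very low counts; the
  min-control-reads filter removes the worst cases, but p-values for
  barcodes with a handful of reads should not be over-interpreted.
* GI compresses a growth trajectory into one number; strains with
  time-varying effects (e.g. delayed death) are summarized, not resolved.
* The resistant flag at GI ≤ −0.5 is descriptive; confirming resistance
  requires a dose series, as the dose-dependence of known resistant mutants
  shows.
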