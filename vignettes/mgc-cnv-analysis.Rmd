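---
title: "Copy-number variation analysis of metabolic gene clusters: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number variation analysis of metabolic gene clusters: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgcnv)
library(dplyr)
```

## The problem

Metabolic gene clusters (MGCs) — groups of three or more adjacent,
functionally related but nonhomologous genes encoding one specialized
metabolic pathway — tend to sit in dynamic chromosomal regions. Within a
species, that dynamism shows up as copy-number variation (CNV): individual
member genes, or runs of them, deleted or duplicated in some accessions.
Measuring this variation at population scale requires combining noisy
copy-number assays, classifying the resulting per-cluster genotype patterns,
and recognising two failure modes of mapping-based genotyping that carry real
signal: divergent duplicates that are invisible to read depth but betray
themselves as heterozygous SNP calls in an otherwise homozygous genome, and
redundant, jittered structural-variant calls that must be collapsed before
haplotype frequencies can be counted.

`mgcnv` implements this chain for cohorts of naturally inbred accessions
(the Arabidopsis setting: effectively homozygous lines), together with a
synthetic-cohort generator that plants known truth so every stage can be
validated quantitatively.

## Copy-number genotyping model

Each platform yields an accession × gene table of non-negative measurements
on the copy-number scale, where the reference diploid level is 2 (the RD
convention is adopted for all platforms; thresholds are only meaningful
under it).

* **RD** estimates are used as-is.
* **MLPA** intensities are relative; for each probe separately, values are
  divided by the probe's median over all assayed samples and multiplied
  by 2, forcing every normalized probe median to exactly 2. A probe with a
  non-positive median cannot be normalized and is set missing with a
  warning. This per-probe normalization is required because probe
  efficiencies vary over an order of magnitude; the generator draws a fixed
  log-normal efficiency per probe precisely so that skipping this step
  breaks recovery. A caveat inherent to median normalization: it assumes
  fewer than half the samples deviate from two copies at that probe; a gene
  deleted in about half the cohort can push the probe median to zero in a
  small assay batch, and the probe is then flagged rather than silently
  misnormalized.
* **ddPCR** concentrations are background-corrected by the no-template
  control and normalized against a verified two-copy control gene (DCL1):
  CN = 2(target − background)/(control − background), floored at 0.
  Accessions whose control does not exceed background are flagged missing.

Calls use `<=` / `>` boundary semantics exactly: RD ≤ 1 → LOSS, > 3.4 →
GAIN, with both thresholds lowered by 0.2 for *BARS1* (its mapped depth runs
low because most accessions lack its largest, transposon-bearing intron);
MLPA ≤ 1 / > 3. The shifted thresholds are rounded to nine decimals so that
3.4 − 0.2 behaves as exactly 3.2 at the boundary. The ddPCR rule in the
source survey is stated only as CN = 0 → LOSS, CN = 2 → REF; we adopt
MLPA-consistent cutoffs (< 1.5 LOSS, > 3.0 GAIN) and expose them in the
threshold set. Values within ε = 0.05 of a threshold are flagged
`borderline` for review — mirroring the manual inspection of near-threshold
single-platform calls in practice — but are never altered.

Integration: where several platforms cover a cell, unanimous (non-missing)
calls win; disagreements become `CONFLICT` and are listed in the concordance
report. The published survey resolved most of its 21 discordant cells by
manual inspection, which is not reproducible as a rule; the `CONFLICT` +
report design is the auditable replacement, with an optional deterministic
`priority` policy (ddPCR > MLPA > RD, reflecting assay directness) for
pipelines that need a total call set. Integration is invariant to platform
order.

## Cluster patterns and census

Per accession and cluster, member-gene statuses (in the cluster's canonical
member order) form a status vector. Vectors matching a shipped, editable
definition table receive the published variant names — for the thalianol
cluster, A (loss of *AT5G47980* + *CYP705A5* + *THAS1* with *CYP708A2*
retained, which keeps A distinct from B and D), B (*AT5G47980* +
*CYP705A5* + *CYP708A2*), C (*CYP708A2* only), D (*CYP705A5* + *CYP708A2* +
*THAS1*), E (duplication of *AT5G47980*). Anything else is reported under a
canonical `gene:STATUS` label rather than being forced into the nearest
named variant — new variants were discovered exactly this way. A vector
containing `CONFLICT` is `UNRESOLVED`; a vector with any ungenotyped member
is `NA`.

The census counts an accession as variable only on member genes (intervening
genes are tallied separately), and excludes accessions with any ungenotyped
member from the no-CNV denominator, since their invariability cannot be
asserted. Cluster spans are taken from the cluster definition rather than
derived, so the coverage statistic is explicit about what "the cluster"
means.

## Cryptic duplications from heterozygous SNP excess

In a selfing species, reads from a divergent duplicate that cross-map onto
its reference paralog produce apparent heterozygous calls. The detector
counts, per accession and locus, heterozygous and homozygous-alternate calls
at exonic biallelic single-nucleotide sites (multi-allelic records and
indels excluded; an optional ≥ 1% frequency floor is available and changes
little, matching the published observation). Group classification for the
reference pair (*CYP705A2*, *BARS1*) and its duplicate pair uses both SNP
counts and depth at the pair plus a linked marker gene deleted together with
the reference region (*CYP705A3* role, configurable):

* reference present (marker covered, first locus clearly present) with het
  excess at both loci → PP-PP; without → PP-AA;
* reference absent (marker ≈ 0) but intermediate cross-mapped depth
  (≈ 1.5 / 0.6) with homozygous-alternate excess at both loci → AA-PP;
* nothing anywhere → AA-AA; anything else → INCONCLUSIVE.

The het-excess cutoff `h_min = 3` sites is a package choice — the source
survey reports only the separation (90.6% of duplication carriers vs 10.7%
of others showing het SNPs), not a cutoff. Three sites suppress isolated
genotyping errors while catching divergence well below 1% over a 1.5-kb
exonic target; it is exposed in the function signature. The published
"inconclusive" criteria are likewise unstated; our INCONCLUSIVE conditions
are a reconstruction, not the survey's rule.

## Inversion-call redundancy minimization

Raw inversion calls are kept when 0.5 kb ≤ length ≤ 50 kb and confidence
score > 35 (strict). Within accession and chromosome, calls are grouped by
transitive closure of the 50% reciprocal-overlap criterion; per group the
call with the highest score survives, ties broken by supporting reads, and
full ties are replaced by one call with maximized coordinates (minimum
start, maximum end — reading "maximized coordinates" as the envelope of the
tied variants). The procedure runs twice, regrouping survivors from scratch
in the second pass so that envelopes created in pass one can merge chains
the first pass left unresolved; a third pass changes nothing (idempotence is
property-tested). Processing order within a pass is descending score, then
reads, then leftmost start — the source procedure is silent on order, and a
deterministic order guarantees reproducibility. Survivors overlapping the
thalianol target region by ≥ 1 bp (half-open semantics) mark an accession
as carrying the compact haplotype.

## Statistics

`wilcoxon_ct()` uses exact enumeration when the pooled sample is ≤ 16
without ties, otherwise the normal approximation with tie and continuity
corrections (the approximation tracks the exact null to about 1e-2 in p for
8-vs-8 samples). `kw_dunn_bh()` is the Kruskal–Wallis omnibus (tie-corrected)
followed by Dunn's two-sided z-tests on pooled ranks with Benjamini–Hochberg
step-up over the pairwise family; sidedness is a package choice, as the
source analyses do not state it. The phenotype scan applies the Wilcoxon test
per variable at raw p < α with no multiple-testing correction by default —
deliberately mirroring the exploratory published scan, which relied on a
downstream structure-aware association analysis for confirmation — with BH
adjustment available. The TS–CYP comparison operates on per-gene
variant-carrier fractions (the only per-gene summary the survey names); a
binary variable/invariable mode is available behind a flag.

## The synthetic cohort: what it emulates

Defaults are the study conditions of the population survey re-implemented
here: 1,152 accessions; RD covering everyone, MLPA ~20% and ddPCR ~2%
subsets; thalianol variants A–E planted at 37/4/5/3/5 per 1,152;
arabidiol/baruol events at their published rates (e.g. *CYP702A3* loss in
49%, *CYP702A2* gain in 4.3%); presence/absence groups at 628 : 326 : 14 : 15;
compact-haplotype frequency 65%; paralog divergence 0.09 (the ~91% identity
of the cryptic duplicate) over 1,500 exonic bases with per-site detection
probability 0.8. One event (or none) is drawn per accession per cluster, so
named patterns are mutually exclusive by construction. Noise defaults
(σ_RD = 0.25 additive, σ_MLPA = 0.1 log-normal, σ_ddPCR = 0.1) are
calibration choices — no quantitative noise model is published — and are
exposed in the configuration.

The truth object stores both `cn_true` (biological copies) and
`cn_apparent` (what a mapping-based assay sees). They differ exactly where
the biology says they should: in PP-PP accessions the divergent *BARS1*
duplicate is invisible to RD (apparent 2, true 4), and in AA-PP accessions
cross-mapping produces the intermediate levels 1.5 / 0.6 over a deleted
region. Genotype-recovery checks score calls against
`planted_statuses()` — the status a noiseless assay would report — so
recovery reaches exactly 100% as noise vanishes, while the biological truth
at those loci is scored by the PAV-group classifier instead. Divergent sites
are emitted directly as genotype calls (no read simulation): the signal of
interest is the het-call excess itself, and desk-scale testability wins.

Planted inversions emit 1–4 redundant calls with breakpoints jittered within
±500 bp, scores mostly uniform on [20, 99] and supporting reads 2–40; the
first call of each true event draws its score above the filter cutoff, so
that every true event is in principle recoverable and recovered haplotype
frequency is a clean binomial check against the planted rate. Decoy calls
violating the length or score filters are mixed in and must all be removed.
Genome coordinates throughout the bundled annotation are synthetic
stand-ins with realistic sizes and spacing; no computation depends on the
real genome positions.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: linkage between events and population structure
(events are drawn independently per accession; in real cohorts deletions
cluster geographically), read-level artefacts (GC bias, mappability),
partial-gene deletions, background heterozygosity from residual outcrossing,
and assay batch effects beyond per-probe efficiency. Concordance on
synthetic multi-platform cells is accordingly near 100%, higher than the
98.8% of the real survey, whose discordances arose from exactly the
unmodelled messiness.

## Numerical choices and degenerate inputs

Intervals are 0-based half-open everywhere internally; the ±1 shift to GFF3
happens exactly once in each direction at the I/O boundary. Missing
measurements are an explicit mask (empty cells), never sentinel numbers,
because 0 is a meaningful copy number. Zero-variance inputs to the Pearson
correlation return `NA` with a warning; fully tied Wilcoxon samples return
p = 1; a Kruskal–Wallis group with zero variance is handled by the tie
correction. Readers reject coordinate-inverted records, malformed headers
and unknown status strings with errors naming the file.

## Problem sizes used in validation

The test suite exercises: genotype recovery on 200-accession cohorts at
default noise (and near-zero noise for the exactness check); PAV-group
recovery, het-count correlation and het-excess separation on a
1,000-accession cohort; dedup equivalence against a brute-force oracle on
1,000 random instances of up to 15 calls plus idempotence; interval
arithmetic against per-base counting on 10,000 random instances; the
rank-statistics oracles by full enumeration; and end-to-end byte-identical
reruns of a 300-accession pipeline. These sizes give stable binomial checks
(3 standard errors) at interactive runtimes.

## Known limitations

* The classifier for presence/absence groups assumes the duplicate pair
  travels as one insertion; independently segregating duplicates would
  confuse the two-locus rules.
* Median-based MLPA normalization degrades as a gene's deletion frequency
  approaches 50% of the assayed batch (flagged, not corrected).
* The dedup envelope merge can, by design, produce an interval wider than
  any single supporting call; downstream size statistics should use the
  deduplicated set knowingly.
* Pattern labels match exact status vectors; partially overlapping deletions
  that produce the same gene-level vector are indistinguishable at this
  resolution.
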