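---
title: "Clone-based BSP methylation analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-based BSP methylation analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bspmeth)
```

## The problem

In bisulfite sequencing PCR (BSP), a genomic region is bisulfite-converted,
PCR-amplified, cloned, and individual clones are Sanger-sequenced. Bisulfite
treatment converts unmethylated cytosines to uracil (read as T) while
5-methylcytosine stays C, so each sequenced clone is a single-molecule
readout of the methylation state at every CpG site of the amplicon.
`bspmeth` implements this workflow for promoter studies in which methylation
is then related to gene expression (qPCR, 2^-ddCt) and to a quantitative
phenotype measured over time — the motivating application is the shell-gland
promoter of the avian *SLCO1B3* gene, whose rising methylation across the
laying cycle accompanies falling expression and a fading blue eggshell
color.

## CpG island detection

Islands are detected with the classical sliding-window criteria
(Gardiner-Garden & Frommer, as used by the MethPrimer family of tools):
windows of `window = 100` bp every `step = 1` bp qualify when G+C fraction
is at least `min_gc = 0.50` and the observed/expected CpG ratio
`n_CG * L / (n_C * n_G)` is at least `min_obs_exp = 0.60`. Qualifying
windows are unioned into runs. Published island callers differ in how a run
is consolidated; several dialects exist (trimming one base at a time,
re-scanning, greedy extension). We use a deterministic rule: each run is
reported as its **longest sub-interval of length at least `min_length =
200` bp that itself satisfies all three criteria**, leftmost on ties, and
dropped if none exists. This makes the definition directly checkable by
exhaustive enumeration, which the test suite exploits: the detector is
compared against a brute-force oracle on random sequences up to 2 kb.

`N` bases are never counted as C or G, and windows with more than 10% `N`
are skipped. Only the forward strand is scanned: BSP amplicons are
strand-resolved by primer design. The tool named in the motivating study
does not publish its thresholds; the values above are the field's standard
defaults and are all exposed in `island_params()`.

## Bisulfite-aware alignment and calling

Each clone is aligned globally (amplicons are primer-anchored end to end)
with affine gaps: match +1, mismatch −1, gap of length *k* costs 4 + *k*.
Alignment operates on the **bisulfite-collapsed alphabet**: every C is
replaced by T in both read and reference, so a converted cytosine (read T
over reference C) is a match and CpG columns accept C and T equally — the
methylation call is deferred to the original read base. The asymmetry is
deliberate: collapse is applied to the sequenced strand only, so a read C
over a reference T remains a genuine mismatch, reflecting the direction of
the C→T chemistry.

Reads of the same length as the reference whose best-orientation collapsed
Hamming distance is at most 3 take an ungapped fast path; this is provably
optimal there because any gapped global alignment of equal-length sequences
pays at least two gap runs (cost ≥ 10), more than the 2 × 3 score that
rescuing three mismatches could recover. Everything else goes through the
full dynamic program (Biostrings), and the test suite checks score equality
against an independent exhaustive Gotoh implementation on pairs up to
300 bp. Both orientations are tried; ties prefer forward with a warning.

Per clone, QC computes:

* **conversion efficiency** — the fraction of non-CpG reference cytosines
  read as T (a retained C there is an unconverted cytosine). Default
  threshold 0.95, the convention of QUMA-style BSP tools.
* **identity** — match fraction over aligned columns at non-C reference
  positions (bisulfite-ambiguous columns are excluded; gap columns are not
  aligned columns and are penalized through the score instead, so a clone
  whose insert is a little shorter than the padded amplicon is not unfairly
  failed). Default threshold 0.90.

Failing clones are excluded and logged with reasons, never silently
dropped. Calls at each site's C column are C → methylated, T →
unmethylated, anything else (gap, A, G, N) → missing. Missing calls are
excluded from numerator **and** denominator; counting them as unmethylated
was rejected because it biases rates downward.

The group-level statistic is the **integral methylation rate**: methylated
calls as a fraction of all non-missing calls over every retained clone and
site of a group. It is the valid-call-weighted mean of the per-site rates,
a relation the tests assert on random matrices.

## Phenotype, expression and stages

Eggshell color is measured at the obtuse, medium and acute ends of each
egg; the egg's value is their mean. Weekly summaries use the sample SD
(n−1) — the source table's printed coefficients of variation are
reproduced within printed rounding under this convention, which is how the
convention was chosen. Flagged abnormal eggs are excluded before
averaging.

Group comparison uses classical one-way ANOVA with Tukey HSD behind a
compact letter display (insert-and-absorb on the pairwise p-matrix; groups
share a letter exactly when they do not differ at α). Tukey was chosen for
familywise control since the source states only "one-way ANOVA" with
letters. Laying **stages** are maximal runs of consecutive weeks whose
letter sets keep a non-empty running intersection, ranked by stage mean.
ANOVA is run per egg with week as the factor; the per-egg unit was an open
choice and is the default.

Relative expression uses the standard 2^-ddCt formulation: replicate Cts
are averaged arithmetically before dCt = Ct(target) − Ct(reference), and
ddCt is taken against the calibrator group's mean dCt. The method is
equivariant under global Ct shifts, asserted as a property test.
Efficiency-corrected models (Pfaffl) are out of scope.

## Association and key sites

Correlation is Pearson's r with the two-sided t-transform p-value, at the
per-group (per-week) level, mirroring how such studies report 8- and
9-point series; a per-individual mode is deliberately not the default. The
per-site table reports unadjusted p-values by default — fidelity to common
practice in this literature — with Benjamini–Hochberg adjustment available
(`adjust = "bh"`). **Key regulatory sites** are defined as sites both
significantly negatively correlated with expression and located inside a
predicted transcription-factor binding site; with the reported coverage
pattern (sites 2, 3, 5, 6, 8, 9 inside C/EBP, Sp1 and Oct-1 boxes) and
significant negative sites {1, 5, 8}, the rule returns sites {5, 8}.

A note on reproducibility of published coefficients: recomputing the
methylation-vs-color correlation from the published *week-level* series
gives r ≈ +0.846, while the source reports 0.807 described as a negative
association (smaller colorimeter values are greener). The published values
were evidently computed from per-bird data that are not available; the
package therefore treats week-level correlations as its definition and
documents, rather than asserts, the published coefficients.

## Transcription-factor motif scanning

The prediction server used in the motivating study implements an
unpublished pairwise-similarity algorithm; it is not reimplemented. Motif
scanning here is standard: IUPAC consensus matching under a mismatch
budget (all qualifying windows reported, overlaps allowed), or
position-weight matrices scored as log-odds against a uniform background
with a threshold at 0.85 of the maximum attainable score. The shipped
motif set (Sp1 GC box `GGGGCGGGGC`, Oct-1 octamer `ATGCAAAT`, C/EBP
palindrome `TTGCGCAA`, 1 mismatch each) is an editable approximation of
the factors named in that analysis. A CpG site counts as covered by a hit
only when **both** bases of the CG dinucleotide lie inside the hit
interval. Scanning defaults to the forward strand (promoter orientation
known); both-strand scanning is opt-in and is tested for
reverse-complement consistency.

## The synthetic-study generator

`synth_config()` fixes the study conditions; they are not tuning knobs:

* **Reference**: ~1 kb, AT-rich flanks around a core of 14 20-bp blocks.
  Each block carries exactly one CG at a recorded position; the other
  strong bases are interleaved with weak bases so no stray CG can form and
  G+C stays even (~0.55). The core then satisfies the island criteria by
  construction and the planted sites are the only CpGs — every call is
  scoreable against truth.
* **Clones**: 45 per week (15 clones × 3 shell-gland samples) over weeks
  25–60. Per-site states are Bernoulli(p[week, site]); the default weekly
  overall rates ramp 0.8393 → 0.9133 (the published weekly sequence, used
  as realistic defaults, not as assertions), with per-site offsets echoing
  the published spread including one weakly methylated site. Unmethylated
  cytosines escape conversion with probability 0.01; substitution
  sequencing errors occur at 0.002 per base (indels opt-in); half the
  clones are emitted reverse-complemented. An optional beta-binomial mode
  (`beta_kappa`) adds clone-level mosaicism; off by default since no
  within-week dispersion estimate exists to emulate.
* **Color**: per egg a latent value ~ Normal(week mean, week SD) with the
  published weekly means, SDs and egg counts; the three position readings
  add Normal(0, 0.8) colorimeter noise (a typical repeatability figure for
  tristimulus colorimeters).
* **Expression**: replicate Cts ~ Normal around a reference Ct of 20 with
  SD 0.15; weekly fold-changes default to a falling profile
  (1.00 … 0.25), high in the first two weeks, intermediate mid-cycle, low
  late, echoing the published expression pattern.

All draws come from one seeded stream per output file (`seed`, `seed+1`,
…), so bundles are byte-identical across runs. What the generator does
**not** emulate: chromatogram-level noise, primer bias, clone-sampling
dependence between tissues, PCR recombination, or per-bird phenotype
structure. Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to every
artifact of real Sanger data.

## Verification scale and numerical choices

The test-suite and acceptance-script simulations use the study-scale
conditions above: single bundles for exact zero-error recovery, 100 seeds
for weekly-rate recovery (±0.04, and per-site rates within 3 binomial
SDs), and 200 replicates each for the association checks. For the key-site
simulation, sites 5 and 8 ramp 0.20 → 0.98 while the other sites stay at
0.85 — a strong, clearly regulatory effect; with BH adjustment and the
negative-direction, coverage-restricted flagging rule this yields exact
recovery of {5, 8} in ≈95% of replicates. Unadjusted flagging cannot meet
that bar (twelve null sites at α = 0.05 produce a false flag in about a
quarter of replicates), which is why the multiplicity-controlled mode is
the one validated there while the default table output remains unadjusted.

Other numerical conventions: coordinates are 0-based half-open internally
and 1-based inclusive in human-facing reports; BED output stays 0-based.
Reported tables round means/SDs to 2 decimals and CVs to 4, matching the
source presentation. Degenerate inputs are explicit: zero-variance ANOVA
reports F = 0, p = 1 with a warning; all-missing sites give NA rates, not
zeros; clones without informative non-CpG cytosines fail QC with a stated
reason rather than receiving a conversion rate of zero.

## Known limitations

* Global alignment assumes primer-anchored inserts; fragmentary reads are
  flagged unalignable rather than locally aligned.
* Non-CpG methylation contexts (CHG/CHH) are not called.
* The motif set approximates, and does not reproduce, the hit list of the
  original prediction server.
* Week-level correlations on 8–9 points have wide confidence intervals;
  the per-site screen is descriptive unless BH adjustment is enabled.
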