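---
title: "methylscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscreen)
```

## The problem

A gene expressed preferentially in two dissimilar cell populations — a
proliferative muscle precursor (myoblasts) and a brain region
(cerebellum) being the motivating pair — poses a regulatory puzzle: what
epigenetic configuration permits high transcription in both contexts
while keeping the gene silent elsewhere? Answering it requires three
computations that this package implements as a reusable, fully tested
pipeline: a specificity screen over expression matrices, a differential
methylation caller over per-CpG methylomes, and a TSS-relative
integration step that summarizes where each differentially methylated
region (DMR) sits relative to each gene.

## The specificity screen

The screen is a ratio statistic, not a hypothesis test. For a culture
matrix with samples $c_1,\dots,c_6$ and target $t$:

$$\mathrm{pass}(g) \iff \frac{x_{g,t}}{\tfrac{1}{5}\sum_{j \ne t} x_{g,j}} \ge R
\;\wedge\; x_{g,t} \ge E$$

with ratio threshold $R = 5$ and expression floor $E = 1$ (TPM or FPKM).
Both comparators are **inclusive**: a gene at exactly ratio 5 with
expression exactly 1 passes. For cerebellum the statistic is applied
twice — against the *median* of the 10 other brain regions and against
the *mean* of the 41 non-brain tissues — plus the floor. The median is
used for the brain denominator because the primary description of the
method states it that way (its narrative summary elsewhere says
"average"; the package follows the method description and exposes
`brain_central_tendency` so either reading can be reproduced).

**Zero denominators.** With 41 non-brain tissues a mean of exactly 0
means the gene is fully silent outside the brain, and the ratio is
undefined. The rescue rule implemented here is deliberately
conservative: the zero-denominator criterion passes only when the
cerebellum value is *strictly* the maximum over all 52 tissues, and the
remaining criteria (floor; the brain-region comparison, itself under the
same zero-denominator treatment) must still hold. The source analysis
only says such genes "were added", so the strictest reading that
reproduces its behaviour was chosen; ties at the maximum do not rescue.

**Gene universe.** Before screening, genes are filtered to those present
in both datasets, protein-coding (a whitelist can retain selected
non-coding genes, since "most" rather than all non-coding genes were
removed in the source analysis), not mitochondrially encoded, and with
at least one tissue and one culture at or above the floor.

## DMR calling

The caller is threshold segmentation, intentionally free of smoothing or
beta-binomial modelling (those are explicit non-goals; the published
threshold is the method). Given target replicates $T$ and panel samples
$P$, for each CpG present in **all** tracks (after per-track coverage
filtering where a coverage column exists):

$$\delta_i = \frac{1}{|T|}\sum_{t \in T} m_{t,i} -
             \frac{1}{|P|}\sum_{p \in P} m_{p,i}$$

CpGs with $|\delta_i| \ge \Delta$ are candidates ($\Delta = 0.35$
standard, $0.20$ relaxed; inclusive). A DMR is a maximal run of
sign-consistent candidates with inter-CpG gaps $\le$ 250 bp and at least
3 members; any evaluated CpG that is below threshold or of opposite sign
breaks the run. The segmentation details (mean aggregation over
replicates, gap bound, minimum run) are this package's own concrete
choices — the source delegates them to earlier work — picked as the
simplest scheme consistent with the stated threshold; every knob is in
`run_config()`.

The **LMR** (low-methylated region) caller is a deterministic proxy for
"significantly lower methylation than the rest of the same genome": the
baseline is the track-wide mean; an LMR is a maximal run of $\ge 5$ CpGs
each $\le 0.5$, with run mean $\ge 0.3$ below the baseline. This is
documented as a proxy, not a reimplementation of the cited
segmentation method, because no test statistic is specified in the
source; on a uniformly unmethylated genome it correctly calls nothing.

Note that 5mC and 5hmC are not distinguished — bisulfite-derived tracks
cannot separate them, a caveat inherited from the assays themselves.

## TSS-relative integration

Distances are signed and strand-aware: positive downstream of the TSS in
the direction of transcription, measured from the TSS to the nearest DMR
interval boundary (half-open coordinates), so a DMR ending exactly 1 kb
before a plus-strand TSS is at $-1000$. Classes are assigned with the
precedence promoter_downstream > promoter_upstream > intragenic >
intergenic_near, which makes the classification a partition. The
promoter window $W$ defaults to 2 kb on each side of the TSS: the source
analysis used ad-hoc per-gene windows (−0.7 to +1.3 kb for one gene,
wider for others), so a single configurable $W$ is the generalization;
2 kb covers every per-gene window it discusses. The intergenic horizon
is 25 kb, chosen to cover the farthest promoter-distal DMRs discussed
(about −14.6 kb); beyond it a DMR stays unassigned rather than being
attached to an implausibly distant gene. Nearest-gene assignment uses
|signed TSS distance| with lexicographic gene-id tie-break, making
output deterministic.

One geometric subtlety: with half-open intervals, "mirror all
coordinates and flip the strand" is an exact symmetry of the
classifier — class and signed distance are both preserved. The
minus-strand distance formula is written against the reflected interval
boundaries (`tss + 1 − end`, `tss + 1 − start`) precisely so that this
holds exactly, and a property-style test asserts it.

## The synthetic-data generator

The generator states a world and the tests measure recovery in it; its
parameters were fixed up front and are not tuned against test outcomes.

* **Expression.** 52 tissue samples (1 cerebellum, 10 other brain, 41
  non-brain) and 6 cultures, matching the design of the real datasets.
  Noise is multiplicative log-normal (`value = mean * exp(N(0, sd^2))`,
  default `sd = 0.2`) because expression data are scale-heavy.
  Planted dual-specific genes have a 10× contrast (50 vs 5) — twice the
  decision threshold of 5× — so recovery under noise is informative:
  with `sd = 0.2` the ratio statistic's log-sd is ≈ 0.22, putting the
  threshold ≈ 3 sd below the planted ratio, hence expected sensitivity
  and specificity both near 1 but not forced to 1.
* **Boundary classes.** `boundary_ratio` genes are emitted noise-free at
  exactly ratio $R$ and pin the inclusive comparator. They are planted
  in the *myoblast context only* (cerebellum ratio ≈ 1): making them
  dual would contaminate the dual-recovery false-discovery measurement
  with genes that sit on the decision boundary by construction.
  `zero_denominator_rescue` genes have all 41 non-brain values exactly 0
  (a log-normal multiple of 0 stays 0) and cerebellum as the maximum.
* **Methylation.** Per-CpG fractions are Beta-distributed with the
  planted region mean and concentration 100 (sd ≈ 0.03–0.05 across the
  mean range — tight, as averaged biological replicates are);
  `beta_concentration = Inf` is the noise-free mode used by the exact
  recovery tests. Planted DMR contrasts default to |Δ| = 0.70, twice
  the 0.35 threshold; LMR regions sit at 0.05 against a 0.75 background.
  CpGs lie on a deterministic grid: 20 bp spacing inside planted
  regions, 200 bp in background, approximating CpG-island versus
  open-sea density. A shared grid across samples reflects the fact that
  CpG sites are genomic positions; it also means the simulator does not
  emulate coverage dropout unless a coverage column is requested.

**What a green test does not establish.** The generator draws
independent CpGs and genes: no spatial autocorrelation of methylation
beyond the planted regions, no correlated expression programs, no
mappability or assembly artefacts, no 5hmC. Recovery results on it
validate the *logic* of the screen and caller, not their field
performance on real methylomes.

## Numerical choices

* All comparators at thresholds are inclusive (`>=`), matching the
  stated ">= 5", ">= 1", ">= 0.35".
* Percentages are rounded half-up (`percent(422, 13847, 1)` → 3.0;
  `percent(20, 422, 0)` → 5), since the printed values are inconsistent
  with banker's rounding; an epsilon guards against binary-float
  artefacts at exact .5 boundaries.
* Coordinates are 0-based half-open everywhere internally; GTF input is
  converted at the single read boundary, BED/bedGraph pass through.
* Empty inputs return empty outputs rather than errors in the callers;
  readers are strict (unsorted bedGraph, fractions outside [0, 1],
  negative expression, and missing cells are errors, not warnings).

## Known limitations

* No statistical testing of DMRs; the thresholds are the method.
* No liftover: all inputs of a run must share one assembly.
* Replicate aggregation is an unweighted mean; the optional
  `strict_replicates` mode of `call_dmrs()` additionally demands that
  every target replicate individually support a called region (run-mean
  per-replicate delta of the run's sign, magnitude at least half the
  threshold), guarding against single aberrant replicates.
* The cerebellum column is a single (already aggregated) sample;
  aggregating biological replicates upstream is the data producer's job.
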