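---
title: "Methods: read-depth CNV calling and population differentiation in popcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth CNV calling and population differentiation in popcnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, its tunable
parameters, the numerical choices made where the design was genuinely
open, and what the synthetic cohort does and does not establish about real
data.

## The read-depth model

At low whole-genome coverage, the number of reads overlapping a genomic
bin is, to a good approximation, Poisson with a rate proportional to the
local copy number: a diploid bin at mean depth $\lambda$ yields
$Y \sim \mathrm{Poisson}(\lambda)$, a one-copy loss
$\mathrm{Poisson}(\lambda/2)$, a three-copy gain
$\mathrm{Poisson}(3\lambda/2)$, and so on:
$Y_b \sim \mathrm{Poisson}\!\left(\lambda \cdot \tfrac{CN_b}{2} \cdot g(GC_b)\right)$,
where $g(\cdot)$ is the GC-dependent coverage response. Everything the
caller does follows from this dosage relation. The working unit is a
500-bp bin (configurable); depth is a single scalar per bin, not a
per-base pileup, which keeps the model closed-form and matches the
granularity at which RD methods operate.

Two quantities summarize a sample: its **effective depth** (genome-wide
mean GC-corrected depth over autosomal bins — sex scaffolds are excluded
so hemizygosity cannot bias the diploid baseline) and, per segment, the
**normalized copy number** $CN = 2\,\overline{RD}_{seg}/\overline{RD}_{genome}$.

## GC correction

Bins are grouped by integer GC percent; each bin is rescaled by
(global mean)/(class mean). Classes with fewer than 100 bins fall back to
no correction — with fewer bins the class mean is noisier than the bias it
would remove. When no class falls back, the genome-wide mean is preserved
exactly (the rescaling is a weighted reshuffling), which the tests assert
to $10^{-9}$.

## Segmentation: mean shift with multiplicity-aware boundary selection

Candidate breakpoints come from mean-shift partitioning at bandwidths
$h \in \{2, 4, 8, 16, 32\}$ bins. Each bin receives a drift direction,
the sign of
$\sum_{j \ne i} (j - i)\, e^{-(j-i)^2/2h^2}\, e^{-(r_j - r_i)^2 / 2(s_i^2 + s_j^2)}$
with a Poisson-scale depth-similarity kernel ($s^2 = \max(r, 1)$), so
bins are attracted toward neighbors at their own depth level; a candidate
boundary is placed wherever the drift flips from leftward to rightward.
Candidates are pooled across bandwidths.

The central numerical issue is that candidate boundaries are **proposed by
the data**: a split placed at the most contrasting position in a noise
stretch looks far more significant than its nominal p-value suggests. Two
measures deal with this:

* Boundaries are retained by greedy bottom-up merging — the least
  significant adjacent pair merges first — using a **two-sample z-test
  with Poisson variance evaluated under the pooled null mean**
  ($\mathrm{Var} = \hat{m}_0/n_1 + \hat{m}_0/n_2$). Using the pooled mean
  matters: computing the variance from a short dip's own (small) mean
  overstates its significance several-fold.
* The retention threshold is `boundary_p = 1e-6`, far below the nominal
  0.01. The calibration is a scan-statistic argument: a 10–100 Mb genome
  offers roughly $10^4$–$10^5$ data-selected candidate positions per
  scale, so a family-wise false-boundary rate of order $10^{-2}$ requires
  a per-boundary threshold of order $10^{-6}$. On pure
  $\mathrm{Poisson}(7)$ noise (1,000 bins) the segmenter returns a single
  segment in at least 95% of seeded replicates, which the tests check.

A final pass re-merges adjacent segments whose bin-depth distributions do
not differ by a pooled two-sample **t-test** at $p \ge 0.01$, and the two
criteria are alternated to a fixpoint. Degenerate branches are explicit:
zero pooled variance with equal means merges ($p = 1$), with unequal means
never merges ($p = 0$); segments totalling fewer than 3 bins merge
unconditionally.

## Calling and filters

A segment becomes a call iff all of:

* its bin depths differ from the genome mean (one-sample t-test,
  Benjamini–Hochberg adjusted across the sample's segments,
  $p_{adj} < 0.05$);
* it is at least 1.5 kb long (RD calling is unreliable below ~3 bins);
* its mean multi-mapping fraction $q_0 \le 0.5$ (repetitive regions);
* its dosage deviates by at least half a copy ($CN \le 1.5$ or
  $\ge 2.5$). This effect-size gate — the classic 0.75×/1.25×
  depth-ratio criterion of RD callers — is needed because a
  multi-hundred-bin segment can differ from the genome mean
  *statistically* (standard error $\propto 1/\sqrt{n}$) while sitting at
  $CN = 1.95$, which is not a copy-number change.

Boundaries are already on bin edges. Gains are $CN > 2$, losses $CN < 2$.

## CNVRs

CNV regions are the connected components of the ≥ 1 bp overlap graph over
all samples' calls, spanning each component's min start to max end.
Coordinates are 0-based half-open throughout, so abutting calls
(`[0,500)` and `[500,900)`) do **not** merge. Support counts distinct
samples, not calls; the default filter keeps support ≥ 4. (The support
wording is ambiguous in the field between "more than four" and "at least
four"; this package defaults to ≥ 4 and exposes `min_support`.) The
CNVR × sample matrix is depth-derived for every cell — non-calling samples
contribute their actual dosage, not an imputed 2 — because the
differentiation scan and the heatmaps need continuous per-sample dosage.

## V_ST and the dual selection criterion

For groups $A, B$ with CN vectors $x_A, x_B$:
$V_T$ is the population variance (denominator $n$) of the pooled values,
$V_S = (n_A V_A + n_B V_B)/(n_A + n_B)$, and
$V_{ST} = (V_T - V_S)/V_T \in (-\infty, 1]$. Population rather than
sample variance is the convention in the statistic's definition; a
`var_type` switch provides the $n-1$ variant. $V_T = 0$ (a CNVR identical
in everyone) leaves $V_{ST}$ undefined; such rows are flagged and never
selected. A CNVR is *population-differentiated* when its $V_{ST}$ reaches
the top 5% of all **defined** $V_{ST}$ values (95th percentile by linear
interpolation, ties included) *and* its Student's pooled t-test has
$p < 0.05$ — deliberately with no multiple-testing correction on the
t-side, since the rank criterion already caps the selection fraction.
Welch's test is available behind a flag.

## Annotation and enrichment

A gene is a CNV gene when the union of all CNVRs covers strictly more
than 50% of its span — union, because the rule is about the gene, and
strict, so exactly-half coverage does not qualify. Term enrichment is the
upper-tail hypergeometric probability $P(X \ge k)$ with BH adjustment
across terms at FDR 0.05; terms absent from the background are skipped
rather than reported as undefined. GFF3 input (1-based inclusive) is
converted to half-open on read, and that conversion is tested explicitly.

## SD association

The headline statistic is the fraction of CNVRs longer than 15 kb whose
interval — optionally extended by 5 Mb flanks, clipped at scaffold ends —
touches a segmental duplication. The permutation null re-places every CNVR
uniformly at random **on its own scaffold** (length preserved, placements
independent, overlaps allowed): per-scaffold placement preserves the
genome's length composition, the main confounder at this scale, and
allowing self-overlap keeps the null exact. The empirical p-value uses the
+1 correction and can therefore never be 0. The test is one-sided for
enrichment; depletion via `alternative = "less"`. A near-continuous
bp-overlap statistic (`statistic = "bp"`) is provided alongside the
fraction: with a few dozen CNVRs the fraction statistic takes too few
values for its p-value to be usefully uniform under the null, so
calibration checks use the bp variant.

## Validation math

ΔΔCt: $CN = 2 \cdot 2^{-\Delta\Delta C_t}$ against a diploid reference
locus, with the calibrator a designated diploid control measured with the
same primers — that convention makes the control exactly CN 2 by
construction. cv% between two CN estimates uses the sample (n−1) standard
deviation of the pair, $|a-b|/\sqrt{2}$, over the pair mean (the $n$
variant is a flag); the concordance gate is cv < 0.25. A call is
"supported" by a high-depth call set when an overlapping (≥ 1 bp) call of
the same sample passes that gate; both the overlap requirement and the
gate are exposed, since reasonable analysts differ on the combination.

## The synthetic cohort: what it emulates and what it does not

The generator plants non-overlapping, bin-aligned events with lengths
log-normal around an 8 kb median (truncated to [3 kb, 100 kb]) — matching
the size distribution typical of RD-based CNV catalogs — on a 10 Mb,
5-scaffold genome; carriers are Bernoulli per sample at the event's
population frequency (neutral events: 0.3 in both groups; differentiated:
0.95 vs 0.05); carrier copy numbers are uniform on {0, 1} for losses and
{3, 4, 5, 6} for gains; depth follows the Poisson dosage model at 6.7
reads per diploid bin with a quadratic GC response peaking at GC 0.45
(floor 0.6); repeat regions (2% of the genome) mark bins with q0 = 0.8
vs 0.02 elsewhere, and planted events avoid them with a 2-bin gap. All
stages derive child seeds from one master seed by fixed offsets, so a
fixed configuration reproduces byte-identical outputs.

Real data differ in ways the simulator deliberately omits: alignment
artifacts and reference errors, mappability structure beyond a binary
q0, overdispersed (non-Poisson) coverage, library-size and insert-size
variation between samples, partially overlapping and nested events, and
linkage between nearby CNVs. Passing the truth-recovery tests therefore
demonstrates that the implementation is correct *under the stated model*,
not that these parameters are optimal for any particular organism's data.

Recovery is scored per planted event: an event is recovered when at least
one carrier yields a call with both breakpoints within ±2 bins and CN
error ≤ 0.5. Per-carrier recall is reported too; it is substantially lower
(~0.65 at 6.7×) because a short CN 2→3 gain in a single carrier sits near
the depth's information limit — the expected depth shift over six bins is
about 2.6 standard errors — which is a property of the coverage, not of
the implementation.

## Problem sizes used in the checks

The test suite and the acceptance script run the full caller on the
30-sample / 10 Mb / 50-event cohort, the merging oracle on 500 random
interval sets, the differentiation scan on 210 CNVRs × 40 samples, and
the permutation calibration on 500 replicates at 199 permutations each —
sizes at which every property is measurable in minutes on one CPU while
leaving the statistics enough resolution (e.g., a 199-permutation p-value
has granularity 1/200, and 500 replicates estimate the 5% tail to ±1%).

## Known limitations

* Breakpoints are bin-resolution (±1–2 bins); no split-read refinement.
* CN is a continuous dosage, not a genotype; no likelihood model over
  integer genotypes.
* The q0 filter consumes a per-bin multi-mapping fraction supplied with
  the depth track; the package does not compute mappability from k-mers.
* The two-group scan handles exactly two populations; multi-group
  designs need repeated pairwise runs.
* The permutation null conditions on scaffold lengths only; it is not
  GC- or gap-matched.
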