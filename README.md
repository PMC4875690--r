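# popcnv — population copy-number variation from binned read depth

`popcnv` is an R package plus analysis workflow for mapping copy number
variation (CNV) in a resequenced population and asking which variants
differentiate two groups — e.g. wild vs. domestic animals, or highland vs.
lowland herds. It targets the low-coverage whole-genome setting (~5–10×),
where the copy number of a locus is inferred from binned read depth (RD)
rather than from split reads or assembly.

The pipeline implements, end to end:

1. **Per-sample CNV calling from depth.** Reads are counted in 500-bp bins;
   depth is rescaled per integer-percent GC class to remove GC-coverage
   bias; scaffolds are segmented by multi-bandwidth mean-shift
   partitioning; segments become calls when their depth differs from the
   genome average (one-sample t-test, Benjamini–Hochberg adjusted p <
   0.05), they are at least 1.5 kb long, their multi-mapping fraction q0 is
   at most 50%, and their dosage deviates by at least half a copy. Copy
   number is normalized to the diploid 2: `CN = 2 · RD_segment /
   RD_genome`.
2. **CNVR definition.** Calls from all samples sharing ≥ 1 bp are merged
   into CNV regions (connected components); regions supported by fewer
   than 4 distinct samples are dropped; each CNVR is classed gain / loss /
   both and given a depth-derived CN value for *every* sample.
3. **Population differentiation.** For each CNVR,
   `V_ST = (V_T − V_S) / V_T`, where `V_T` is the CN variance of the
   pooled samples and `V_S` the sample-size-weighted mean of the
   within-group variances (an F_ST analogue for dosage), plus a Student's
   t-test; a CNVR is "differentiated" when it sits in the top 5% of V_ST
   *and* has t-test p < 0.05.
4. **Annotation.** Genes more than 50% covered by the CNVR union, and
   hypergeometric term enrichment of those genes with FDR control.
5. **Segmental-duplication association.** Fraction of large (> 15 kb)
   CNVRs overlapping SDs (directly and with 5 Mb flanks) and a
   random-placement permutation test (lengths preserved, uniform placement
   per scaffold, `p = (1 + #{null ≥ obs}) / (n_perm + 1)`).
6. **Validation math.** qPCR ΔΔCt copy number against a diploid reference
   locus (`CN = 2 · 2^(−ΔΔCt)`) and cv%-based concordance between two CN
   predictions (gate cv < 0.25).
7. **Read QC** (pre-alignment): N-fraction, low-quality-fraction, adapter
   and duplicate-pair filters with quality trimming and a 45-bp length
   cut.

Because real population BAMs are enormous, the package ships a fully
seeded synthetic-cohort generator (`sim_config()`, `simulate_cohort()`)
that plants CNV truth (CN 0–6, two-population frequency structure, GC
bias, high-q0 repeats) so that every stage is testable, with known truth,
on a laptop.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running
it in order reproduces a complete study on a simulated cohort of 15 wild +
15 domestic samples (10 Mb genome, 6.7×, 50 planted events):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_call_cnvs.R
# ... through analysis/08_heatmap_profiles.R
```

Stage 2–6 print, on this cohort:

```
segmented 30 samples into 927 segments; retained 379 CNV calls (12.6 per sample; 197 gain / 182 loss)
truth check: 100% of planted events recovered (breakpoints within 2 bins, |CN error| <= 0.5); 1.3% of calls match no carried event
merged 379 calls into 54 raw regions; 46 CNVRs pass the >= 4-sample support filter (21 gain / 25 loss / 0 both)
CNVRs span 533.5 kb = 5.3% of the 10 Mb genome; mean length 11.6 kb
V_ST threshold (95th pct of defined values): 0.679; 3 of 46 CNVRs selected as wild-vs-domestic differentiated
  cnvr_00019  V_ST = 0.848  t-test p = 5.5e-13
23 of 400 genes are >50% covered by CNVRs (in 20 CNVRs)
64% of >15 kb CNVRs directly overlap an SD (100% within 5 Mb flanks)
permutation test (fraction statistic, 999 perms): observed 0.652 vs null 0.326 +/- 0.068, p = 0.001
```

Reading these numbers: all 50 planted events are found with breakpoints
within ±2 bins (1 kb) and copy numbers within ±0.5, at a ~1% false-call
rate; the merged regions cover about 5% of the genome; the V_ST + t-test
dual criterion flags three regions, all of which coincide with planted
population-differentiated events (the region profiled in stage 8 shows
domestic samples near CN 2 and wild samples near CN 1.5 — a loss
segregating in the wild group); and CNVRs are significantly closer to
segmental duplications than random placement expects (p = 0.001), as the
generator planted them to be.

Equivalent single calls in R:

```r
library(popcnv)
co <- simulate_cohort(sim_config(seed = 1))
res <- call_sample(co$tracks[[1]], co$layout)   # GC-correct, segment, call
cnvrs <- merge_calls(do.call(rbind, lapply(co$tracks, function(tr)
  call_sample(tr, co$layout)$calls)), min_support = 4)
```

`run_pipeline()` executes the same stages from one (YAML) config — see
`inst/extdata/demo_config.yaml` — writing every output and a checksummed
run manifest.

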