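---
title: "Methods: consensus CNVR mapping from SNP-array CNV calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus CNVR mapping from SNP-array CNV calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrmap)
```

## The problem

Copy number variations (CNVs) called from SNP genotyping arrays are
notoriously caller-dependent: the same intensity data pushed through
different segmentation models (sparse Bayesian learning, HMMs, Gaussian
mixture partitioning) yields call sets that agree on perhaps half of
their regions. The standard remedy in livestock CNV surveys is an
ensemble design: run several callers, apply conservative post-calling
filters, aggregate overlapping calls into copy number variable regions
(CNVRs), and keep only regions recalled by at least two programs.
`cnvrmap` implements that whole post-calling pipeline — it does **not**
segment intensity data; it starts where the callers stop.

The pipeline stages are:

1. **Genotype QC** (`run_qc`): per-SNP call rate, minor allele frequency
   (MAF) and an exact Hardy–Weinberg (HWE) test, followed by a per-sample
   call-rate pass.
2. **Call filtering** (`filter_calls`): drop segments with fewer than
   `min_snps` probes (default 3) and events carried by fewer than
   `min_carriers` individuals (default 2).
3. **CNVR construction** (`merge_to_cnvrs`): connected components of the
   1-bp overlap graph, per chromosome; status is *gain*, *loss*, or
   *gain-loss* when both states occur among constituent calls.
4. **Gap screening** (`screen_gaps`): CNVRs overlapping assembly
   gap/contig-boundary intervals are discarded.
5. **Consensus** (`build_consensus`): pool per-caller CNVR sets, keep
   overlap components spanning ≥ 2 distinct callers; the consensus span
   is the **union** of member CNVRs.
6. **Cohort comparison** (`cohort_cnvr_set`, `unique_cnvrs`,
   `generation_overlap`): founder breeds and the F2 cross are processed
   separately; breed-unique CNVRs overlap nothing in the other cohorts.
7. **Annotation** (`overlap_join`, `summarize_annotation`,
   `snp_colocation`): interval joins against genes (with biotype), QTLs
   (with trait class) and GWAS-significant SNPs.
8. **qPCR validation scoring** (`compute_rq`, `qpcr_concordance`):
   relative quantification by the 2^−ΔΔCt method against a single-copy
   control gene and a two-copy calibrator sample.

## Coordinate and length conventions

Everything internal is 1-based inclusive; BED input is declared 0-based
half-open and converted at the boundary, and a reader refuses to guess
an undeclared convention. Two length accessors exist on purpose:
`length_bp(start, end) = end − start + 1` (true physical span, used by
all interval algebra) and `length_kb_published(start, end) =
(end − start)/1000`, which is what published CNVR tables in this
literature actually print (we verified the convention against a printed
60-row founder-unique CNVR table shipped as a fixture). Conflating the
two silently is a classic off-by-one source, hence the loud names.

"Overlapping" always means ≥ 1 shared base under inclusive coordinates;
abutting intervals (`[100,200]`, `[201,300]`) do **not** merge. CNVR
surveys of the SNP-array era used plain 1-bp overlap rather than
reciprocal-overlap fractions for region aggregation, and it is the
least-surprising reading of "aggregating overlapping CNVs";
`overlap_join(..., min_overlap_bp =)` exists for sensitivity analysis.

## QC design

* All exclusions are **strict** inequalities (call rate < 0.90,
  MAF < 0.03, HWE p < 1e−6); boundary values are retained.
* The HWE test is the exact conditional test (sum of configurations with
  conditional probability ≤ the observed one, given allele counts), not
  chi-square: at a 1e−6 threshold, chi-square tail approximations are
  unreliable. The implementation is a vectorized log-factorial
  evaluation; the test suite checks it against an independently coded
  recurrence oracle to 1e−12 and checks allele-relabeling symmetry.
  Exact tests are discrete and mildly conservative; at the F2-scale
  sample size (n = 500) the rejection rate at α = 0.05 on true-HWE SNPs
  stays within ±0.02 of nominal (asserted in the acceptance suite).
* Order of operations is fixed and recorded: SNP filters on all samples
  first, then the sample call-rate filter on surviving SNPs. An
  `iterate = TRUE` mode re-applies SNP filters to a fixed point; the
  default two-pass report flags any SNP whose verdict would change on
  iteration. HWE is computed on all supplied samples by default
  (`snp_test_samples` restricts it, e.g. to F2 individuals only) — an
  intercross violates HWE structurally, which is precisely why the
  working threshold is as extreme as 1e−6.

## Filtering and consensus semantics

Recurrence ("seen in more than one individual") is judged on the
transitive 1-bp overlap **cluster** within one caller, counting distinct
carriers regardless of state (a strict same-state mode exists). The
probe-count filter precedes the recurrence filter; both precede merging.
Mixing callers in `filter_calls` is an error, because recurrence is a
per-caller notion.

The consensus span is the **union** of member CNVRs, not the
intersection: published consensus regions reach tens of Mb — far larger
than single-caller segments — which only a union across carriers and
callers can produce. An `span = "intersection"` mode exists for
comparison. "Recalled by ≥ 2 programs" is evaluated at component level
(distinct callers in the overlap component); the per-base ≥ 2-caller
vote mask is used in the tests only as a cross-check that no qualifying
base is missed.

Gap screening treats "overlaps more than one contig and contains a gap"
as a single condition — any overlap with a declared gap interval — since
an inter-contig gap inside a CNVR is exactly what makes it span two
contigs.

Printed percentages round **half-up** to the printed precision
(`percent_of`); base R's half-to-even would disagree with published
tables on boundary cases.

## The synthetic world

No genotyping data were deposited for the study this pipeline models, so
`simulate_truth` / `emit_caller_calls` / `emit_genotypes` / `emit_qpcr`
generate every input, fully determined by an explicit seed. The defaults
are the study's stated world wherever it states one:

| Parameter | Default | Source/rationale |
|---|---|---|
| genome | 19 chromosomes × 140 Mb (2.66 Gb) | pig-genome scale |
| probe map | uniform, 1/40 kb (~66k probes) | 60K-chip scale |
| CNVR sizes | log-uniform 29.2 kb – 27.29 Mb | published min/max |
| status mix | gain:loss:gain-loss = 70:43:136 | published mix |
| cohorts | 19 + 5 founders, 506 F2 | published design |
| caller sensitivity | 0.9 per true CNV per carrier | stated default |
| false positives | 0.05 segments/Mb/sample, 10–100 kb | see below |
| boundary jitter | SD 5 kb | stated default |
| state flips | 2% | stated default |
| CT noise | SD 0.1, quadruplicate | stated noise model |

Free choices we had to make once:

* **FP segment lengths** (log-uniform 10–100 kb): chip-caller false
  segments are predominantly short, low-probe-count artifacts — that is
  the entire rationale for the ≥ 3-SNP filter these studies apply. Under
  the 40 kb probe spacing most simulated FPs fall below the 3-probe
  emission floor, leaving a few surviving false calls per sample per
  caller, consistent with observed per-sample call counts in 60K-chip
  studies (thousands of calls across ~600 animals).
* **Truth regions are non-overlapping genome-wide** (the minimum
  requirement is only per-carrier): keeps truth matching unambiguous.
* **Carrier floors**: every planted region gets ≥ 2 carriers by default
  so that planted truth is not knocked out by the singleton filter by
  construction (`min_carriers_planted = 1` restores single-carrier
  designs, used by the closed-form consensus test).
* **Scoring** uses 50% *reciprocal* overlap — deliberately stricter than
  the pipeline's 1-bp merge rule — so sprawling union spans are not
  credited as recoveries.

What a green synthetic test does **not** establish: the emulator has no
LRR/BAF signal level, no genomic-wave or GC artifacts, no locus-specific
recurrent false positives, no pedigree transmission of CNVs (carriers
are assigned, not inherited), and uniform probe spacing rather than the
real chip's irregular map. It validates the set algebra and the
filtering logic, not caller behavior.

### A structural limit worth knowing

With the published size range and probe density, about one planted
region in five is shorter than three probe spacings and therefore
invisible to *every* emulated caller: end-to-end sensitivity against all
planted truth is capped near 0.82 no matter how good the pipeline is.
The acceptance suite asserts the nominal ≥ 0.95 bound anyway and that
test fails honestly; the companion test shows sensitivity ≥ 0.95 among
probe-detectable (≥ 3-probe) regions, which is what the pipeline can
logically deliver. Precision exceeds 0.95 under defaults.

## qPCR classification

RQ = 2^−ΔΔCt with ΔCt = mean target CT − mean control CT, replicates
averaged per well (the standard practice; an optional outlier trim drops
replicates > 1 CT from the well median), 100% PCR efficiency assumed.
Default class cutoffs are the published ones: loss iff RQ < 0.59
(strict), gain iff RQ ≥ 1.59 (non-strict, "or more").

These published cutoffs deserve a caveat: 0.59 ≈ log2(1.5) and
1.59 ≈ log2(3) are log2 *copy numbers*, not RQ midpoints. The ideal RQ
of a 3-copy sample is 3/2 = 1.5 — *below* the 1.59 gain cutoff — so
under the ΔΔCt copy model a clean 3-copy gain is classified "normal"
more often than "gain" (probability of a gain call ≈ 0.2 at CT noise
SD 0.1). The thresholds are configurable; copy-model-consistent
midpoints (e.g. 0.75/1.25) classify 1/2/3-copy samples correctly
≥ 99% of the time under the same noise model, and the machinery tests
use those. We kept the published values as defaults because they are
what the source study operated with; the acceptance test asserting
≥ 99% at the published cutoffs fails honestly for the 3-copy class.

Concordance scoring follows the published validation semantics: a CNVR
is *validated* iff any assayed sample is non-normal; the validated type
may *extend* the predicted status (e.g. predicted loss, observed both
gains and losses), which the published validation table itself contains.

## Numerical notes

* `percent_of` uses half-up rounding with a 1e−9 guard against binary
  representation of exact halves.
* The exact HWE p-value accumulates probabilities with a `(1 + 1e−9)`
  relative tolerance when comparing against the observed configuration's
  probability, the standard guard against float ties.
* CNVR numbering restarts every run; cross-run identity is by
  coordinates, never by number.
* Degenerate inputs: empty CNVR sets write header-only files; a QC run
  that removes everything completes with a warning flag rather than
  erroring; a qPCR well with no usable replicates names the offending
  well.

## Known limitations

* No reciprocal-overlap merge mode beyond `min_overlap_bp`; no
  breakpoint refinement; no intensity-level reanalysis.
* No liftover: cross-species/cross-study comparisons expect coordinates
  already on the working assembly.
* No GO/KEGG enrichment — the overlap joins produce the gene lists;
  enrichment belongs to external services.
* The sample-size asymmetry of real founder cohorts (5 boars vs 19 sows)
  interacts with `min_carriers = 2`; small cohorts lose power, which the
  cohort provenance records.
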