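---
title: "Methods: readthrough scoring, null calibration, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: readthrough scoring, null calibration, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(readthroughr)
```

This vignette is the package's own account of its science: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical choices made where the design was
genuinely open, and known limitations. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The readthrough model

Transcription termination failure leaves polymerase transcribing past a
gene's 3' end, so a strand-specific tiling array sees elevated signal in the
region downstream of the annotated terminus. The statistic deliberately skips
the first 100 nt after the 3' end (**DN100**): annotated 3' ends are
imprecise and 3' UTR signal bleeds into this window. The signal window is
**DN200**, the next 200 nt. The reference is the transcript body (**TRAN**,
trimmed by 50 nt at each end to avoid boundary probes). Medians rather than
means are used throughout: tiling probes have heavy-tailed behavior
(cross-hybridization, GC outliers) and the median of 8+ probes is robust to a
few of them.

The per-sample score `med(DN200) − med(TRAN)` is a within-sample quantity, so
any additive (log-scale multiplicative) normalization offset cancels —
score translation invariance is property-tested. The mutant-vs-WT *ratio*
then cancels gene-specific downstream context (a gene sitting near a noisy
region has that noise in both strains). What remains is the mutant-specific
3' signal gain, in log2 units.

### Why a replicate-derived empirical null

Probe noise is not i.i.d. Gaussian across genes: window sizes differ, probe
densities differ, and local genomic context correlates probes. Instead of a
parametric null, the package scores wild-type replicate 2 against replicate 1
with the identical pipeline. Every nuisance term (window geometry, probe
count, local context) appears in the null exactly as in the observed ratios;
only the biological effect is absent. The one-sided p-value uses the
`+1`-corrected counting form `p = (1 + #{null ≥ r}) / (1 + n)`, which is
never 0 and treats ties against the observation — the add-one correction
keeps BH valid with a finite null. The two mutant/WT experiments are paired
by replicate index (experiment 1 = `mut_1` vs `wt_1`, experiment 2 = `mut_2`
vs `wt_2`) and share the single `wt_2 − wt_1` null; the stringent call set
intersects both experiments' BH calls. The reverse-ordered null
(`wt_1 − wt_2`) would simply negate the distribution; since the test is
one-sided on the upper tail, the orientation is a convention, and using one
fixed orientation keeps the pipeline deterministic.

### Filters

Inclusion: length ≥ 200 nt (shorter transcripts leave TRAN with too few
probes after trimming), ≥ 400 nt same-strand downstream clearance (otherwise
DN200 overlaps a neighbor's signal), ≥ 8 probes in each window. The clearance
rule has one exception: an mRNA whose nearest same-strand downstream feature
is a CUT or SUT is retained, because such ncRNA annotations frequently *are*
the mRNA's own readthrough product and excluding these mRNAs would
systematically remove true positives.

Expression filters guard the ratio's interpretability: (i) < 10
cap-binding-complex (Cbc1) CRAC reads in DN100 — capped 5' ends downstream
of a gene indicate independent initiation, not readthrough; (ii) TRAN median
above −4.88 in both strains (mean of replicates) — below this floor the
array signal is noise; (iii) mutant DN100 median > 70% of mutant TRAN and
(iv) mutant TRAN ≥ 70% of WT TRAN — both protect against ratios driven by
expression changes rather than 3' extension. "70% of" is interpreted as a
linear fraction of the log2 median (`fraction_scale = "linear_on_log2"`),
the literal reading of thresholds stated on median probe intensities. This
is logged prominently because log2 medians can be negative, where a linear
fraction inverts its meaning; `fraction_scale = "linear_on_intensity"`
switches to the alternative reading (`x > y + log2(0.7)` on the log scale).
Genes with missing Cbc1 data fail closed by default (`cbc1_missing`
configurable): a reliability filter that cannot be evaluated should not
silently pass.

The bottom-250 exclusion (genes with spuriously negative ratios caused by
increased mutant expression) applies only when constructing the motif gene
set, never to the FDR call set — it is a gene-set curation step, not part of
the statistic.

## The synthetic world

The generator states one fixed world; its defaults were chosen once, from
what the analysis context implies, and are not tuned against test outcomes.

* **Gene geometry** — log-normal transcript lengths (median 1.4 kb, sdlog
  0.35) and intergenic gaps (median 700 nt, sdlog 0.6): yeast-like density
  where most, but not all, genes pass the 400-nt clearance rule.
* **Array model** — probes every 8 nt on both strands (high-density yeast
  tiling design); log2 intensity = background (−7) outside transcripts,
  per-gene expression (Normal(2, 1.5)) inside, plus independent
  Normal(0, 0.5) probe noise per sample. WT replicates differ only by noise.
* **Readthrough injection** — affected genes (30% by default) gain
  `delta · 2^(−d/h)` in the mutant at distance `d` downstream of the 3' end,
  with `delta = 3` log2 units and half-length `h = 500` nt. The exponential
  decay shape is a modeling choice (observed extensions taper over hundreds
  of nt; snoRNA extensions of ~500 nt motivate the half-length); the
  half-length parameterization makes the knob physically interpretable.
* **CRAC reads** — read positions drawn per gene (weights `2^expr`) under a
  Beta(1,3) (5'-biased), Beta(3,1) (3'-biased) or uniform positional law;
  length 30 nt; a configured fraction carries a non-templated 3' oligo(A)
  tail (`"AA"` + geometric extras). When the genome sequence is supplied the
  generator extends any tail that would be templated by a genomic A-run, so
  the config parameter *is* the true non-templated fraction the detector
  must recover — otherwise random-genome templating would bias the truth
  downward by ~6% of tailed reads.
* **Seeding** — each operation draws from `seed + fixed offset`, so adding
  genes or reads to one stage never perturbs another stage's draws.

What the generator does **not** emulate: realistic sequence composition
(beyond planted motifs), splicing, probe GC effects, spatially correlated
array noise, PCR duplication, or mapping artifacts. A green test therefore
establishes the correctness and calibration of the *statistics* under the
stated noise model, not robustness to every artifact of real arrays; the
empirical-null construction is precisely the part designed to absorb such
artifacts in real data.

One consequence of the stated world is worth recording: expression filter
(iii) (mutant DN100 > 70% of mutant TRAN) passes almost no synthetic gene,
because the synthetic background (−7) sits far below gene bodies (~2) and
injected readthrough decays before filling DN100 to body-level signal. On
real arrays, pervasive transcription and widespread readthrough make this
filter meaningful; in the simulation the FDR-calibration and recovery
properties are therefore assessed on the eligible (inclusion-filtered) set
and the intersected FDR call set, which is also what the acceptance criteria
specify.

## Numerical choices

* Internal coordinates are 0-based half-open; GFF3 I/O converts to/from
  1-based inclusive at exactly one boundary. "Downstream" is strand-aware
  everywhere.
* Probe membership in a window: probe *center* in `[start, end)` on the
  matching strand — the natural tiling-array convention.
* Even-length medians are the mean of the central pair (R's default).
* BH is implemented as the explicit step-up rule and is tested for exact
  agreement with `stats::p.adjust(·, "BH")` on 1000 random vectors — the
  reference implementation serves only as the oracle.
* Ties in gene ranking receive average ranks; rank 1 is the largest mean
  ratio over the two experiments.
* The motif z-score is the pooled two-proportion statistic; degenerate pooled
  proportions (0 or 1) report z = 0 with a flag rather than ±Inf. Fisher's
  exact test is kept as the ranking oracle (monotonic agreement is
  property-tested at Spearman ρ ≥ 0.95).
* Quartiles for the motif gene set are assigned by mutant readthrough
  *score* rank by default, with `rank_by = "ratio"` as a switch — the two
  descriptions of the published procedure differ, and the discrepancy is
  surfaced as an explicit option rather than hidden.
* Pol II 3'-end group profiles scale each gene's window to max 1 before
  summing, so one highly-expressed gene cannot dominate; genes without hits
  are dropped with a warning (a 0-max profile cannot be scaled). The window
  defaults to ±500 nt, configurable; the low-readthrough control group is
  deliberately large (1200 vs 200) because the very lowest-ranked genes
  carry spuriously negative ratios.
* Class assignment resolves overlapping annotations by a fixed priority
  (rRNA > tRNA > snoRNA > snRNA > mRNA > intron > CUT > SUT > other) with a
  ≥ 50% read-overlap rule; single-class counting keeps class fractions
  summing to 1.
* The cluster filter for crosslink-site reads tests cluster read counts
  against a uniform within-span Poisson background with BH control — a
  documented stand-in for the original pipeline's unstated background model.
* Config files are JSON (`jsonlite`), lossless for every config field.

## Limitations

* The pipeline assumes one shared coordinate system for arrays, reads,
  annotation and genome; cross-assembly liftover is the user's
  responsibility.
* Differential expression is consumed as an external table (limma-style
  `id`/`log2fc`); the package does not re-derive it.
* `annotate_environment` uses nearest-feature semantics with a 5 kb horizon
  to operationalize "adjacent"; printed tables of curated loci may reflect
  manual judgments a distance rule cannot reproduce, which is why the exact
  environment tallies are checked against the shipped transcription of the
  published table rather than against a re-derivation.
* Full-scale reproduction of genome-wide counts requires the original
  accessions plus upstream normalization and read mapping, both outside this
  package's scope.
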