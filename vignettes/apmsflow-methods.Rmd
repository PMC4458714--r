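---
title: "Methods: AP-MS interactor discovery and interval co-localization statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AP-MS interactor discovery and interval co-localization statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsflow)
```

## The problem

Affinity purification followed by mass spectrometry (AP-MS) identifies the
physical interaction partners of a tagged "bait" protein: the bait is pulled
down, co-purifying proteins are digested with trypsin, and MS2 spectra are
matched to peptide sequences by a database search.  Three statistical
problems stand between raw peptide-spectrum matches (PSMs) and a defensible
interactor list:

1. **Which PSMs are correct?**  Search engines assign a best-matching peptide
   to every spectrum, right or wrong.  The target-decoy strategy appends
   reversed protein sequences to the database; matches to reversed sequences
   estimate how many forward matches at any score are also wrong.
2. **Which proteins do the peptides imply?**  Peptides are often compatible
   with several homologous proteins.  Parsimony reports the smallest protein
   set explaining all confident peptides.
3. **Which proteins are interactors rather than background?**  Spectral
   counts (the number of MS2 spectra per protein) are compared between the
   bait pull-down and negative-control pull-downs with a count model that
   tolerates the overdispersion of replicate IPs.

The package also ships the genomic interval statistics used to ask whether
two sets of chromatin-binding sites (e.g. from ChIP experiments of the bait
and of a candidate partner) co-localize more than chance predicts.

Every stage is driven by a deterministic synthetic-data generator, so the
entire pipeline is exercisable and testable offline.

## Stage 1: target-decoy PSM filtering (`decoydb`, `psmfilter`)

The search database is `organism ∪ contaminants` plus a whole-sequence
reversal of every forward entry, so decoys and targets are equinumerous and
share length and composition statistics.  Decoy accessions carry a
configurable reserved prefix (default `REV_`).

Search scores are combined into one linear discriminant
`D = w1·log(primary/length) + w2·delta + w3·(−log rank) + bias`.  The
original pipeline's coefficients are unpublished; the shipped defaults
(1.0, 8.0, 0.2, 0) are recorded in every filter report, and no downstream
result depends on their specific values — only on the induced ranking.

PSMs are partitioned into classes by charge (1–3), number of tryptic termini
(0–2) and modification state (unmodified / M+16), at most 18 classes.  Per
class, target and decoy score histograms (bin width 0.1) are accumulated,
and the class threshold is the smallest observed-target bin edge `t` with
`#decoys ≥ t / #targets ≥ t ≤ FDR` (default 1%).  Choices worth stating:

* the FDR estimator is `d/t`, not `2d/(t+d)`: decoy counts directly estimate
  false target matches above the threshold;
* comparisons are inclusive (score ≥ threshold survives; the MH+ window
  550–4000 Da is inclusive; the 25-ion minimum is inclusive; the intensity
  gate at 500 is exclusive, "greater than");
* classes with fewer than 50 decoys fall back to the pooled all-class
  histogram — a small-sample guard, since a 1% threshold cannot be located
  from a handful of decoys;
* a PSM mapping to both target and decoy sequences counts as target
  (conservative);
* each input row is one spectrum; spectra are never merged.

## Stage 2: protein inference (`protinfer`)

Confident peptides are mapped back to the database by exact substring search
(I/L distinct by default, switchable).  Proteins with identical peptide sets
merge into one redundant group; groups whose peptide set is a proper subset
of another's are removed (parsimony); a group survives only if at least one
sample shows ≥ 2 distinct peptides with ≥ 1 tryptic terminus.  The
"per sample" wording of the two-peptide rule is read as *in at least one
sample*: requiring it in every sample would erase proteins legitimately
absent from control lanes, contradicting the differential design.  Protein
FDR is surviving decoy groups over surviving target groups.

## Stage 3: spectral counts with shared-peptide splitting (`counts`)

Spectra of peptides unique to one group are unique counts.  A shared peptide
with count `c` in a sample, owned by groups `S`, contributes
`c · u_g / Σ_{h∈S} u_h` to each owner `g`, where `u_g` is the owner's unique
spectral count *in that sample* (a flag switches to distinct-peptide
proportions).  When all owners have zero unique evidence the count splits
equally, and the event is logged.  Corrected counts are kept as reals;
conservation (`Σ corrected = Σ unique + Σ shared` per sample) holds to
numerical tolerance and is asserted property-style in the tests.

## Stage 4: beta-binomial differential interaction (`diffinter`)

A protein's count `x_ij` out of the sample total `n_j` is modeled
beta-binomially: `x ~ Bin(n, p)` with `p ~ Beta(α, β)`, mean fraction
`π = α/(α+β)` and overdispersion `θ = 1/(α+β+1)`; `θ → 0` recovers the
binomial.  Interactors are called by a likelihood-ratio test of common `π`
(bait + pooled empty-vector/GFP controls) against group-specific `π`, with
one shared `θ`, BH adjustment across proteins, and `q < 0.2` plus
bait-over-control direction.

**Reference distribution.**  The classical χ²(1) reference for this LRT is
measurably anticonservative at AP-MS scale (3 replicates, a handful of
expected counts, strong skew) — even with the true `θ` supplied.  The
package therefore keeps the LRT statistic but calibrates its reference by a
parametric bootstrap under the fitted null (default 199 replicates; p-value
floor 1/200), the same reasoning that leads RNA-seq tools to quasi-likelihood
F-tests in place of χ² at small replicate numbers.  In the statistic, `θ` is
fixed at a df-corrected residual (quasi-binomial moment) estimate computed
identically on observed and bootstrap data: subtracting fitted group means
keeps a real effect from inflating it, and the `N−2` correction removes the
small-sample downward bias of maximum likelihood.  `p_method = "chisq"`
restores the textbook test (with `θ` profiled by bounded one-dimensional
optimization, tolerance 1e-8); `theta = 0` with `"chisq"` is the two-sample
binomial LRT, verified against a closed-form oracle.

Counts enter the test rounded half-up (the model is integral); raw reals are
retained in outputs.  Trial totals are per-sample column sums of the
corrected matrix — the cited test's standard use; samples with zero total
carry no evidence and are dropped.

**Treatment effects.**  Before comparing bait-side treatments (MSL2
knockdown, RNase), the treatment samples are rescaled so the bait protein's
mean count matches the untreated reference (`factor = bait_ref/bait_trt`);
effects are labeled Increase/Decrease at `α = 0.05` by direction.  Optional
expression correction divides a protein's treatment counts by a supplied
expression fold-change before testing — multiplicative, then re-rounded;
the original study's exact adjustment arithmetic is unpublished, and this
choice is recorded in the output metadata.  Proteins lacking a ratio are
tested uncorrected and listed.

## Interval co-localization statistics (`intervals`)

Coordinates are 0-based half-open (BED).  Merging unions overlapping and,
by default, book-ended intervals.  The statistics:

* **Jaccard**: intersecting bases / union bases, with a permutation null
  that relocates the query intervals uniformly and independently per
  chromosome (counts and lengths preserved, overlap allowed within the null
  set — the simplest defensible null; the upstream package's exact null is
  unpublished).  Permutation p-values are `(1 + #{null ≥ obs})/(1 + n_perm)`
  and are never printed as zero — the floor `1/(n_perm+1)` is rendered as an
  inequality.
* **Projection**: the count of query midpoints inside the reference versus
  a binomial at the reference's covered fraction of the mappable length
  (full chromosome lengths unless a mask is supplied); two-sided by
  doubling the smaller tail, capped at 1.
* **Relative distance**: each query midpoint's distance to the nearest
  flanking reference midpoint divided by the flanking gap, uniform on
  [0, 0.5] under independence; tested by KS against that uniform.  The
  **area correlation** is `(∫₀^0.5 [ECDF(d) − 2d] dd)/0.25`, normalized so
  coinciding point sets score 1 and independence ~0 (the upstream package
  does not restate its normalization; this one is documented in every
  report).
* **Absolute distance**: distance to the nearest reference midpoint, with
  an ECDF-area permutation test against relocation nulls (equivalent to
  comparing mean distances) and a two-sample KS against pooled null
  distances.

Per-chromosome results are reported alongside a length-weighted pooled
value, since the pooling rule used upstream is unstated.  The gene-model
partition uses CEAS-like precedence TSS(±1 kb) > UTR > exon > intron >
intergenic.

## The synthetic world (`synthgen`)

The generator states one world and the tests measure the pipeline in it:

* **Databases**: proteins are concatenations of random tryptic blocks (each
  ending in K/R, no internal K/R/P), so the in-silico digest is exact; 10%
  of proteins share one identical block to exercise grouping and count
  splitting.  Desk scale is 500 organism proteins + 179 contaminant
  stand-ins (the published contaminant list itself is not redistributable);
  the full-scale 19577+179 world is a parameter change, exercised in the
  acceptance suite.
* **PSMs**: true matches draw discriminant scores from N(3.5, 0.8); false
  target matches and decoy matches draw i.i.d. from N(0, 1) — the exact
  premise of target-decoy estimation.  Raw scores are generated to
  reproduce those discriminants under the default weights.  Hidden truth
  labels go to a sidecar that pipeline code never reads.
* **Counts**: per sample, Dirichlet-multinomial with concentration
  `π(1−θ)/θ` — column sums equal the configured totals exactly and
  per-protein marginals are beta-binomial(π, θ).  Defaults: totals 2000,
  3 replicates per condition, 50 planted interactors at exactly 5× their
  control count fraction (the background absorbs the compensation, as in a
  real IP), bait protein at 25/15/10 background units across
  bait/MSL2kd/RNase so bait normalization matters, and disjoint
  treatment-sensitive subsets attenuated 4-fold.  Overdispersion defaults
  to θ = 0.001: the realism-relevant quantity is the variance inflation
  `1 + (n−1)θ ≈ 3` at totals 2000, matching the 30–60% replicate CVs of
  real AP-MS counts.  (θ = 0.05 at these totals would mean inflation ~100 —
  replicates like 0/183/0 — which is not a sane stated world; the test
  calibration simulations that specify θ = 0.05 use it as specified.)
* **Intervals**: uniform reference; half the query intervals are reference
  copies jittered by N(0, 200 bp) on 1 Mb toy chromosomes.

What a green suite does **not** establish: realistic peptide score
distributions (true SEQUEST scores are not two clean Gaussians), homology
structure beyond planted shared blocks, LC-MS run-to-run drift,
composition-bias between conditions beyond bait/planted mass, or ChIP peak
width/GC structure.  The suite establishes the *statistical contracts*:
FDR control given the decoy premise, count conservation, test calibration
given the count model, recovery under planted truth, and exact agreement of
interval arithmetic with per-base enumeration.

## Numerical choices and degenerate inputs

* Thresholds snap to histogram bin edges (width 0.1 discriminant units).
* π is fitted by bounded 1-D optimization inside a 200×-wide bracket around
  the pooled fraction (a speed bracket, not an accuracy bound); θ profiles
  on [0, 0.95] with tolerance 1e-8; the binomial boundary θ = 0 competes
  explicitly with the interior optimum.
* All-zero counts in both groups: p = 1, no direction.  Zero-total samples
  are dropped.  A zero bait count in a treatment condition is a refusal
  (normalization undefined), not a silent scale of ∞.
* Equal-split fallback when no owner of a shared peptide has unique
  evidence; the event is logged on the experiment.
* Half-up rounding (`floor(x + 0.5)`) wherever reals enter the count model.
* Every stochastic routine takes an explicit seed; generator streams derive
  from the master seed by fixed offsets so regenerating one input leaves
  the others untouched.

## Known limitations

* Substring peptide-to-protein mapping is quadratic in database size; it is
  instant at desk scale and acceptable at full scale, but a real search
  deployment would index digests.
* The bootstrap p-value floor (1/200 by default) bounds attainable
  significance; raise `n_boot` when very small p-values matter.
* No probabilistic protein inference, no NSAF/length normalization, no
  SAINT/CompPASS scoring, no spectrum-level parsing (DTA/mzML), and no
  reproduction of external ChIP peak calling — all outside the artifact's
  contract.
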