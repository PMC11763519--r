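---
title: "Screening odorant-responsive olfactory receptors and their binding-cavity residues"
author: "orsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening odorant-responsive olfactory receptors and their binding-cavity residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orsite)
```

## The problem

Olfactory receptors (ORs) are seven-transmembrane GPCRs; which odorant a
given OR binds is mostly unknown ("orphan" receptors). A practical
de-orphanization strategy combines three computational steps, each of which
this package implements as a tested, reusable stage:

1. **Candidate filtering.** Odor exposure transcriptionally down-regulates
   the ORs that respond to that odor in the olfactory epithelium, so
   candidate receptors are the OR-annotated genes among the down-regulated
   DEGs of a treatment-vs-control RNA-seq experiment
   (`filterDEGs()`, `intersectCandidates()`).
2. **Cavity-site conservation.** If several receptors respond to the same
   odorant, the binding-cavity residues that recognize it should be more
   conserved *within that responsive set* than across the whole OR
   repertoire. Per cavity site, the screen compares mean pairwise Grantham
   distances in the foreground set against the repertoire background
   (`screenSites()`).
3. **Reporter validation.** Dual-luciferase assays quantify receptor
   activation (firefly reporter normalized by co-transfected renilla) for
   wild-type, alanine-scan and natural-variant constructs
   (`normalizeWells()`, `responseTest()`, `relativeResponse()`).

Every stage has a seeded synthetic generator (`genFamily()`,
`genCounts()`, `genPlate()`) so the pipeline can be exercised,
power-checked and regression-tested without any external download.

## The Grantham distance

The physicochemical dissimilarity between residues $a$ and $b$ is

$$D(a,b) = \rho\left[\alpha\,(c_a-c_b)^2 + \beta\,(p_a-p_b)^2 +
\gamma\,(v_a-v_b)^2\right]^{1/2}$$

with composition $c$, polarity $p$ and side-chain volume $v$ from the 1974
property table shipped with the package (`aaProperties()`), and constants
$\alpha = 1.833$, $\beta = 0.1018$, $\gamma = 0.000399$, $\rho = 50.723$
(`granthamParams()`), which scale the mean of the 190 distinct pair
distances to approximately 100.

```{r grantham}
G <- granthamMatrix()
mean(G[upper.tri(G)])
granthamDistance("L", "I")   # conservative pair
granthamDistance("C", "W")   # the most dissimilar pair
```

Distances are kept at full floating precision everywhere; integer rounding
appears only when comparing against the printed 1974 table. A subtlety
worth knowing: the printed integer table is *not* an exact rounding of the
formula. Most cells agree after rounding, a minority of printed values sit
about one unit above the recomputed ones, and the Asp–Trp cell is an
erratum (printed 181; the formula gives about 190.4). No choice of
constants or rounding rule reproduces the printed table exactly — e.g.
matching the printed Leu–Met value requires a larger $\rho$ than matching
the printed Ser–Arg value allows. The package therefore computes from first
principles and ships the printed table separately
(`publishedGranthamMatrix()`) for reference; the unit suite freezes the
agreement structure (145/190 cells exact, 44 off by one, plus the Asp–Trp
erratum). Either version supports the screen equally well: the screen's
default test is rank-based, and rounding perturbs distances by well under
the between-site variation.

Non-standard codes (`B`, `Z`, `X`, `U`, `O`) are rejected by
`granthamDistance()`; how to treat ambiguous residues is a decision for the
alignment layer, not the distance formula.

## The conservation screen

Inputs: a protein multiple sequence alignment of the OR repertoire
(`readAlignment()`, FASTA or Clustal — the alignment itself is produced by
external tools; this package deliberately does not realign), a panel of
cavity positions in ungapped reference coordinates (`sitePanel()`), the
foreground ids, and a `screenConfig()`.

Cavity positions such as F178 are stated in the reference receptor's own
residue numbering, so they are mapped to alignment columns through
`positionMap()`; every interface speaks 1-based coordinates. Columns where
the reference is gapped are never assigned to a reference position. If the
panel states expected residues (e.g. `F` at 178), they are checked against
the reference sequence and mismatches are errors — this catches the common
off-by-one and wrong-isoform mistakes early.

Per site, the usable residues (gaps and `X` dropped residue-wise — pairwise
deletion, with usable counts reported per site) of foreground and
background receptors yield two sets of pairwise Grantham distances
(`sitePairwiseDistances()`); by default the background is the whole
repertoire *including* the foreground, matching the convention of comparing
a responsive subset against "all annotated ORs" (`excludeForeground` flips
this). The default test is a one-sided Mann–Whitney (foreground
distances smaller); Welch's *t* and a subset-permutation test are
selectable. A site is flagged conserved when its (optionally BH-adjusted)
p-value is $\le \alpha$ **and** the foreground mean is below the background
mean; we use $\le$ rather than $<$ so that permutation p-values landing
exactly on $\alpha$ are not silently excluded. Sites with fewer than
`minUngapped` (default 2) usable foreground residues are reported with an
`NA` p-value, never dropped.

```{r screen}
fam <- genFamily(familySpec(seed = 7))
panel <- sitePanel(sort(c(fam$truth$plantedSites, fam$truth$decoySites)))
res <- screenSites(fam$alignment, panel, fam$truth$referenceId,
                   fam$truth$foregroundIds)
res[res$conserved, c("position", "fgMean", "bgMean", "pValue")]
fam$truth$plantedSites
```

### Why the permutation test exists, and what the tests show

Pairwise distances within a receptor set share sequences: the C(5,2) = 10
foreground pairs are built from only five sequences and are not independent
observations, so two-sample tests on pairs are anti-conservative. The
regression suite quantifies this at the default study conditions (5
foreground vs 200-receptor repertoire, 20 null decoy sites, raw
$\alpha = 0.05$): the Mann–Whitney screen flags on average 1.93 decoy sites
per replicate where a calibrated test would flag 1, while the permutation
test — which resamples foreground-sized receptor subsets from the
background, so its null respects the dependence — flags 0.91, matching the
nominal rate, and its null p-values pass a Kolmogorov–Smirnov uniformity
check. Mann–Whitney remains the default because it is the convention this
kind of screen uses in practice; for discovery work we recommend
`screenConfig(test = "permutation", adjust = "BH")`. Note what no
configuration can give you: with 20 null sites at raw $\alpha = 0.05$ the
chance of *zero* false flags in a replicate is about $0.95^{20} \approx
0.36$, so a screen of this size should be read with an expected ~1 spurious
site in mind (or with the BH option switched on).

Planted-site recovery at the defaults is complete (all 3 planted sites
flagged in every one of 100 seeded replicates) and monotone in effect
size: recovery per site is 1.00 at planted Grantham radius 0 and 50, and
0.36 at radius 120, where the planted pool is barely tighter than the
background.

## The candidate filter

`filterDEGs()` applies the conventional cutoffs $|\log_2 FC| \ge 1$
(boundary included, as the "≥" reads) and $p < 0.05$ (boundary excluded),
on a results table computed by real DE software (edgeR/DESeq2) — this
package does not reimplement those models. For synthetic end-to-end runs,
`simpleDETest()` provides a plain Welch-on-log-CPM test (CPM with
pseudocount 0.5; fold change as the log-ratio of group mean CPM).
`intersectCandidates()` partitions the filtered set by an OR / OR-like /
other annotation; the OR vs OR-like distinction follows whatever annotation
source the user supplies, since it is an annotation-naming convention, not
a computable property.

## The reporter assay

Per well, response = firefly / renilla (`normalizeWells()`); wells with
renilla $\le 0$ are invalidated with a warning, and no other outlier
removal is ever applied. `responseTest()` compares each (construct,
concentration) cell against the same construct's no-odor wells — the
dose design is summarized per concentration (0/100/200 µM), not curve-fit,
since two non-zero doses cannot support an EC50. `relativeResponse()`
expresses responses relative to the mean of a no-receptor control at one
stated concentration and tests mutants against the wild type; the control's
relative mean is 1 by construction. Welch's *t* is the default test,
Mann–Whitney selectable; significance tiers are `*` for $p<0.05$ and `**`
for $p<0.01$, with SEM error bars the natural plot companion.

## What the generators emulate — and what they do not

* `genFamily()` draws background residues i.i.d. per column (uniform by
  default, optionally Dirichlet-perturbed per column) and plants
  conservation as a *Grantham-radius residue pool* around an anchor:
  foreground residues at a planted site are uniform over
  $\{a : D(a, \mathrm{anchor}) \le r\}$, default $r = 50$. This models
  exactly the quantity the screen measures, which makes the effect size
  interpretable ($r=0$: monomorphic foreground; $r=120$: barely
  constrained) — it is *not* a phylogenetic substitution process, so
  nothing about tree structure, rate heterogeneity or real OR composition
  is represented. Defaults (200-receptor repertoire including a gap-free
  reference record, 5 foreground receptors, length 310, 3 planted sites,
  gap rate 0.02) are a desk-scale stand-in for a mammalian OR repertoire,
  which numbers in the hundreds to over a thousand.
* `genCounts()` draws negative-binomial counts (dispersion 0.1 by default;
  0 gives the Poisson limit) with a constant baseline mean of 100 and
  planted 4-fold down-regulation in 15 OR, 49 OR-like and 100 unannotated
  genes out of 2000, 4 samples per group — mirroring a two-animal,
  left/right-epithelium two-group design. Real count data have
  gene-specific means, dispersion trends and library-size variation that
  this deliberately omits; conclusions about *this package's filter logic*
  transfer, statements about real-data DE power do not.
* `genPlate()` multiplies a firefly baseline by the construct's true fold
  activation and mean-one lognormal noise (CV 10% default), with renilla an
  independent lognormal channel — multiplicative noise is how reporter
  luminescence actually misbehaves, but plate-position effects and
  transfection batch effects are not modeled. The "loss-of-function mutant
  at 30% of wild type" scenario is modeled as 30% of the wild-type's
  activation *increment* (fold $1 + 0.3\,(3-1) = 1.6$ against the
  wild-type's 3), since a fold below 1 would mean activation below the
  no-receptor control, which loss-of-function data do not show.

All three generators take an explicit seed and are byte-deterministic given
the spec; truth records carry the planted structure so recovery tests
reference the truth rather than re-deriving it.

## Numerical and design notes

* Statistical tests are delegated to `stats::wilcox.test` /
  `stats::t.test` (so tie handling and the exact-vs-normal-approximation
  switch follow R's standard behavior); permutation p-values use the
  add-one estimator $(1 + \#\{\text{perm} \le \text{obs}\})/(1 + n)$ and
  a per-site seed offset so single sites can be recomputed independently.
* No multiple-testing correction is applied by default (raw $p \le 0.05$
  per site, the field convention for small cavity panels);
  `adjust = "BH"` is one flag away and interacts with the conserved flag,
  not just the reported p-values.
* Degenerate inputs are reported, not dropped: all-gap foreground columns,
  all-zero genes, sub-replicated reporter cells all yield rows with `NA`
  p-values and a reason visible in the counts.
* Problem sizes in the regression suite — 100 screen replicates at the
  default family spec, 50-replicate effect-size sweeps, 200-replicate count
  and plate power runs, 50 brute-force comparison alignments — were chosen
  as the smallest sizes at which the frozen rates are stable to re-running;
  they complete in a few minutes on a single core.

## Limitations

The screen tests *relative conservation*, not function: a flagged site is
a hypothesis for mutagenesis, nothing more. The package does not predict
structures, cavities or docking poses (cavity positions are an input), does
not align sequences, and does not replace count-model-based DE callers.
Real repertoires bring paralog structure and alignment uncertainty that the
i.i.d. generator cannot emulate; treat synthetic power numbers as
properties of the method under its own assumptions.
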