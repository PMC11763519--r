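# orsite

Conservation screening of olfactory receptor (OR) ligand-binding-cavity
residues, plus the two flanking stages of a computational OR
de-orphanization pipeline: filtering candidate odor-responsive receptor
genes from differential-expression results, and analyzing dual-luciferase
reporter assays that validate receptor responses and mutant effects.

## Who this is for

Groups that screen odorant-responsive receptors the transcriptomic way:
expose the olfactory epithelium to an odorant, call down-regulated genes,
intersect with the OR annotation, then ask *which cavity residues make the
responsive receptors special* before committing to an alanine scan. The
core question is statistical: at a given binding-cavity site, are the few
co-responsive receptors more conserved than the repertoire at large?

## The statistic at the core

Residue dissimilarity is the Grantham distance, computed from
physicochemical first principles:

D(a,b) = ρ [α (c_a − c_b)² + β (p_a − p_b)² + γ (v_a − v_b)²]^½

with composition *c*, polarity *p*, molecular volume *v* and the published
constants α = 1.833, β = 0.1018, γ = 0.000399, ρ = 50.723 (mean of the 190
distinct pair distances ≈ 100). For a cavity site mapped from reference
coordinates (e.g. F178) to an alignment column, the screen compares all
pairwise distances within the foreground (co-responsive) receptors against
those within the full repertoire, one-sided: a site is *relatively
conserved* when the foreground mean is significantly lower (default
Mann–Whitney at α = 0.05; Welch t and a subset-permutation test — the
statistically safer choice, since pairwise distances share sequences — are
selectable, as is BH adjustment).

Distances are full floating precision. The integer table as printed in
1974 ships separately (`publishedGranthamMatrix()`); it is not an exact
rounding of the formula (most cells agree; a minority are one unit high;
Asp–Trp is a printed erratum), which the package documents and tests
rather than hides.

## Worked example

Everything below is synthetic and seeded — no downloads. Generate a
receptor family with 3 planted conserved cavity sites among a 200-receptor
repertoire, screen a 23-site panel, and look at the calls:

```r
library(orsite)

fam <- genFamily(familySpec(seed = 7))
panel <- sitePanel(sort(c(fam$truth$plantedSites, fam$truth$decoySites)))
res <- screenSites(fam$alignment, panel, fam$truth$referenceId,
                   fam$truth$foregroundIds)
res[res$conserved, c("position", "refResidue", "fgMean", "bgMean", "pValue")]
#>    position  refResidue    fgMean    bgMean      pValue
#> 1       103           R   49.1465   97.4519 8.89806e-04
#> 2       146           Q   41.1884   93.3915 3.51307e-04
#> 3       194           H   16.6516   92.0028 3.52315e-06
#> 4       267           T   61.9388   95.3558 1.95476e-02
#> 5       298           N   17.4223   99.4568 1.13670e-06
fam$truth$plantedSites
#> [1] 103 194 298
```

All three planted sites are flagged (foreground mean pairwise distance
~17–49 vs background ~92–99); sites 146 and 267 are decoy false positives —
at raw α = 0.05 over 20 null sites about one spurious site per screen is
expected, which is why `screenConfig(test = "permutation", adjust = "BH")`
is recommended for discovery.

Candidate filtering on synthetic counts (4-fold planted knock-down, 4
samples per group), using the conventional cutoffs |log2FC| ≥ 1, p < 0.05:

```r
sim <- genCounts(countSpec(seed = 3))
de <- simpleDETest(sim$counts, sim$groups)
cand <- intersectCandidates(filterDEGs(de), sim$annotation)
cand$counts
#>      OR OR-like   other
#>      15      49      98
```

All 15 planted OR genes and all 49 planted OR-like genes are recovered in
this replicate. Reporter analysis of a synthetic plate (n = 6 wells, 10%
multiplicative noise): each construct/concentration is tested against the
same construct's no-odor wells after firefly/renilla normalization:

```r
pl <- genPlate(plateSpec(seed = 5))
responseTest(pl$plate)
#>   construct concentration_uM n meanResponse    sem   pValue signif
#> 1      NoOR                0 6         2.15 0.0452       NA   <NA>
#> 2      NoOR              100 6         2.13 0.1123 8.94e-01     ns
#> 3      NoOR              200 6         2.44 0.0894 2.23e-02      *
#> 4     OR7D4                0 6         2.18 0.1259       NA   <NA>
#> 5     OR7D4              100 6         3.94 0.2404 2.39e-04     **
#> 6     OR7D4              200 6         5.40 0.2108 8.82e-07     **
```

The responder construct is highly significant at both doses (`**`,
p < 0.01); the no-receptor control shows one marginal `*` — the kind of
borderline call real plates produce at nominal α.

For real data, supply your own inputs at the same interfaces: an
edgeR/DESeq2 results TSV (`readDETable()`), an OR annotation TSV
(`readGeneAnnotation()`), a repertoire alignment from your aligner of
choice (`readAlignment()`, FASTA or Clustal), a cavity-site TSV
(`readSitePanel()`), and plate readings (`readPlate()`).

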