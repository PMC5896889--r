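---
title: "Methods: mapping a duplicate-gene hybrid lethality from cross data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a duplicate-gene hybrid lethality from cross data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplimap)
```

## The genetic model

`duplimap` dissects a two-locus recessive-recessive Dobzhansky–Muller
incompatibility of the kind produced by *divergent resolution* of a gene
duplicate: a gene essential for seedling survival is duplicated in one
lineage (loci *hl13* and *hl14*, on chromosomes 13 and 14 of the
*Mimulus guttatus* / *M. nasutus* system that motivates the package), the
ancestral copy degenerates in the duplicated lineage, and the other lineage
never carried the duplicate. A hybrid homozygous for the guttatus allele at
*hl13* (the dead copy) and the nasutus allele at *hl14* (no copy) inherits
no functional gene and dies as a chlorophyll-less ("white") seedling.

With unlinked loci and Mendelian segregation this predicts

* no white seedlings in parental selfs or F1 hybrids,
* $1/16$ white F2 seedlings in both reciprocal cross directions,
* selfed F3 families segregating white seedlings at $1/4$ (parent
  heterozygous at the segregating locus, fixed incompatible at the partner)
  or not at all.

All expectations in `expected_white_fraction()` are computed by exact
enumeration of per-locus offspring genotype distributions (dyadic rationals,
exact in double precision) and the model's deterministic lethality
predicate, so the catalog of alternatives (one-locus recessive,
dominant–recessive, cyto-nuclear) shares a single code path with the focal
model.

## The forward simulator and what it emulates

Every downstream stage is testable against `cross_sim`-style forward
simulations:

* **Founders.** The nasutus parent is a natural selfer, modelled as fully
  homozygous. The guttatus parent derives from an outbred plant selfed for
  $g$ generations (default 3), leaving residual heterozygosity
  $(1/2)^g$ (12.5% at the default) at ordinary loci; the causal loci are
  forced homozygous, mirroring the empirical verification of the real
  mapping line, and SNP-panel loci are forced homozygous for the
  reference-lineage allele because panel SNPs are ascertained as fixed
  interspecific differences. Sites that fix during the selfing simulation
  are labelled guttatus-lineage: only still-heterozygous sites retain a
  nasutus-like allele (standing variation shared through gene flow).
* **Meiosis.** Haldane's map function (no crossover interference):
  recombinant fraction $r(d) = (1 - e^{-d/50})/2$ for $d$ in cM,
  independent assortment across the 14 chromosomes. Mapping studies of
  this kind rarely commit to a map function; Haldane is the simplest
  defensible choice and is asserted against its closed form in the tests.
* **Pooled sequencing.** Per SNP the total depth is Poisson around
  `mean_depth`; alt reads are binomial at the pool's alt-allele frequency
  with a symmetric per-read error (default 0.005, an Illumina-scale
  post-filter rate). The shared-SNP ascertainment assumption (the mapping
  guttatus line shares the reference line's SNPs) fails at a configurable
  fraction of sites (default 2%), which then read alt in every pool.
  Zero-depth SNPs are emitted as missing.
* **Seeding.** Every simulator takes one integer seed; child seeds are
  derived deterministically, so a fixed seed reproduces populations and
  count tables bit-identically.

The simulator does *not* emulate read-level artefacts (FASTQ, alignment,
base quality), segregation distortion, or genotyping error in marker
assays; conclusions about robustness to those features cannot be drawn
from passing tests.

## Model screening

`screen_models()` tests each cross class against each catalog model with a
Pearson chi-squared goodness-of-fit test on the white/green split (1 df, no
continuity correction — two phenotype cells, and the observed cases are far
from the boundary), rejecting a model if any class rejects at
$\alpha = 0.05$ (the analysis level; no level is inherited from the
source data). Boundary expectations (0 or 1) use the exact rule: any
discordant seedling rejects. Reciprocal F2 directions are first checked for
homogeneity with a 2×2 chi-squared test; homogeneous directions are pooled,
heterogeneous ones flag a possible cyto-nuclear asymmetry. Observed counts
for the worked examples are reconstructed from printed population sizes and
white percentages by rounding to whole seedlings.

## Bulked segregant analysis

Round 1 (`marker_bsa()`) is qualitative: a marker is associated when all
white-pool replicates (allowing `tolerance = 1` exception, the "only or
mostly" rule) are fixed for one parental allele while every green pool
shows both alleles.

Round 2 (`window_scan()` / `call_regions()`) computes per-SNP alt-allele
frequencies (`alt/(ref+alt)`, SNPs under `min_depth = 4` in either pool
masked; the depth floor is a package default, logged in output), then
windows of 200 SNPs advancing by 100 SNPs *in SNP-index space* — windows
are defined by SNP count, not physical span, so bp extents are reported
only for interval output. Each window carries the unweighted mean signed
difference (white − green) and the mean absolute difference: the signed
statistic ranks "most divergent" windows (top quantile, default 5%), the
absolute statistic ranks "least divergent" ones (bottom quantile, default
0.5%) where a region fixed in both pools — the partner locus under the
pooling design — stands out against binomial noise. Runs of at least
`min_contiguous = 3` overlapping flagged windows merge into half-open
0-based intervals (BED convention). Both quantiles are configuration, not
inference: the two published variants (5% and 0.5%) are retained side by
side rather than resolved.

The F3 pooling design (`simulate_f3_bsa_pools()`) reproduces the
second-round study structure: green F2s homozygous nasutus at *hl14* are
selfed; the white pool takes one white seedling from each of 34 segregating
families, the green pool one seedling from each of 26 non-segregating
families. One seedling per independent family keeps unlinked SNPs at 50%
expected frequency in both pools while fixing the white pool for guttatus
alleles at *hl13*.

## Fine-mapping

`progeny_test()` classifies a green F2 from its selfed family: any white
offspring proves heterozygosity; an all-green family is decisive for the
compatible homozygote only when $0.75^n < \alpha$ (the exact binomial
tail; the smallest decisive family at $\alpha = 0.05$ is $n = 11$),
otherwise ambiguous. Green records are informative only when the partner
locus is fixed incompatible — otherwise F3 segregation does not isolate the
target locus and the record is left unknown.

`narrow_interval()` places the causal locus in the minimal marker-bounded
interval consistent with every informative record. A candidate position
between two markers is accepted for a record if *either* flanking marker
call matches the record's inferred causal genotype (missing calls are
wildcards). This either-flank rule is deliberately conservative: intervals
can come out slightly wide but are never wrongly narrow. An empty
intersection raises an error listing each record's consistent segments —
the signature of genotyping error, a wrong model, or (in error-free
simulations) a double crossover hugging the causal locus, which occurs at
rate $\sim r_\text{left} r_\text{right}$ per individual and is reported
rather than silently absorbed. Intervals spanning a reference-assembly gap
can carry a `spans_gap` flag, marking their length as a lower bound.

## Copy placement and functionality

`call_haplotypes()` treats a genomic PCR observation as a superposition:
every copy an individual carries contributes its allele states, and a panel
haplotype is called when its full state vector is contained in the observed
union (presence is dominant — a copy on either homolog amplifies).
`infer_placement()` then scores each haplotype against each (locus,
parental allele) candidate by counting individuals whose presence
contradicts the candidate, across a panel spanning the nine two-locus
genotype classes; only a unique zero-mismatch candidate is called placed.
The diagnostic panel itself is data — the published 10-SNP state table is
not machine-readable — so fixtures use synthetic panels of the same shape
(10 positions × 3 haplotypes, each with a private allele).

`detect_frameshift()` globally aligns a query CDS to an intact reference
(affine gaps: open 10, extend 0.5, match 1, mismatch −1 — package
defaults, configurable), flags a net indel offset that is not a multiple of
3, and reports every stop codon of the reference-frame translation falling
before the reference's terminal stop. `expressed_copies()` applies the same
haplotype containment to transcript allele states, after masking positions
under `min_coverage = 5` reads (package default); a sample with every
diagnostic position masked is classified not expressed — the observed state
of lethal seedlings. Which inactivating change came first (the frameshift
or the expression loss) is unknowable from these data and no operation
encodes an ordering.

## Expression summarisation

`intersect_significant()` keeps genes flagged in all three pairwise
white-vs-green comparisons, reporting the unweighted mean log2 fold-change
and its sign; sign-discordant genes are flagged but not excluded
(membership is defined by significance alone). `row_zscore()` standardises
each gene with the population (divisor $n$) standard deviation — the
figure convention is unstated, either divisor is defensible, and the choice
is exposed as an argument; constant rows map to zeros.
`class_misexpression_report()` splits a gene set by transcribing
polymerase (PEP / PEP-and-NEP / NEP): the signature of a disabled
plastid-encoded polymerase is photosynthesis genes down and *rpo* homologs
up. DE testing itself is consumed from upstream tools; significance is
taken from input flags, and `simulate_de_tables()` provides a planted-truth
stand-in with independent false-positive flags so the cubic suppression of
null leakage ($\text{fp}^3$) is testable.

## Problem sizes, tolerances, numerical choices

Stochastic assertions use 3 standard errors of the relevant estimator
throughout. The suite's simulation sizes are chosen to make those checks
sharp while staying desk-scale: $10^5$ individuals for single-rate
checks, 10,000 simulated populations for the F2 white-percentage
consistency intervals, 50 replicates of the 20,000-SNP two-pool design for
scan recovery, 100 seeded replicates for placement round-trips, 200 random
instances for the interval-narrowing brute-force equivalence. Two spec-level
bounds deserve note: model-screen retention is tested within 3 SE of its
nominal 95% rate (a hard ≥95% bound would fail by construction half the
time), and interval-narrowing soundness is asserted for every *returned*
interval, with the rare double-recombinant inconsistency error tolerated
and bounded. Window means are exact cumulative-sum arithmetic
(oracle-checked to 1e−12); quantile thresholds use R's default type-7
quantiles; ties in placement scoring are reported as unplaced rather than
broken arbitrarily.

## Known limitations

* The simulator's linkage maps use a uniform 300 kb/cM scaling; real
  recombination landscapes are heterogeneous, so bp interval *lengths* from
  simulations are not calibrated to real genomes (the published 72.2 kb /
  51.6 kb intervals require the actual assembly and are out of scope).
* Marker-assay genotyping error is not modelled; `narrow_interval` treats
  conflicts as errors to surface rather than data to down-weight.
* The expression module summarises upstream DE calls; it does not model
  count noise, normalisation, or the dependence structure of real RNA-seq.
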