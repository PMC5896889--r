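# duplimap

Genetic dissection of two-locus hybrid incompatibilities caused by
divergently resolved gene duplicates, from cross data.

## The problem

In young species pairs, hybrid lethality often traces to a
Dobzhansky–Muller incompatibility between a pair of loci. One recurring
molecular route is *divergent resolution of a gene duplicate*: an essential
gene is duplicated in lineage A, the ancestral copy degenerates there,
while lineage B never carried (or lost) the duplicate. Hybrids homozygous
for A's dead copy at one locus and for B's empty locus at the other inherit
no functional gene. In the motivating yellow-monkeyflower system
(*Mimulus guttatus* × *M. nasutus*), the gene is the chloroplast
transcription factor *pTAC14*, the loci are *hl13* and *hl14* on
chromosomes 13 and 14, and the doomed genotype — homozygous guttatus at
*hl13*, homozygous nasutus at *hl14* — segregates in 1/16 of F2 seedlings,
which germinate white and die.

`duplimap` is for geneticists running this kind of dissection. It
implements the full inference chain as tested, reusable functions:

| stage | functions |
|---|---|
| forward cross simulation (founders, Haldane meiosis, F1/F2/F3, pooled sequencing) | `make_parental_lines`, `meiosis`, `mate`, `self_cross`, `simulate_f2_population`, `simulate_f3_family`, `pool_counts`, `simulate_f3_bsa_pools` |
| segregation-model screen | `expected_white_fraction`, `chisq_gof`, `reciprocal_homogeneity`, `screen_models` |
| bulked segregant analysis | `marker_bsa`, `per_snp_freq`, `window_scan`, `call_regions` |
| recombinant fine-mapping | `progeny_test`, `concordance`, `infer_causal_genotype`, `classify_records`, `narrow_interval` |
| duplicate-copy placement & functionality | `call_haplotypes`, `infer_placement`, `detect_frameshift`, `expressed_copies` |
| post-DE summarisation | `intersect_significant`, `row_zscore`, `class_misexpression_report`, `simulate_de_tables` |

The central quantities: under the two-locus recessive-recessive model the
expected F2 white fraction is exactly 1/16 and segregating F3 families are
3:1 green:white; meiosis uses Haldane's map function
r(d) = (1 − e^(−d/50))/2; the genome scan averages white−green allele
frequency differences in 200-SNP sliding windows (100-SNP overlap) and
calls regions from the top/bottom divergence quantiles; progeny tests are
exact binomial (an all-green family of n proves homozygosity when
0.75^n < α). See the methods vignette
(`vignettes/duplimap-methods.Rmd`) for the model, defaults and design
choices.

## Worked example

Screen the competing genetic models against observed reciprocal F2 counts
(white/green seedlings, maternal parent `G` = guttatus first):

```r
library(duplimap)
counts <- data.frame(cross_class = "F2", maternal = c("G", "N"),
                     n_green = c(478, 623), n_white = c(38, 38))
screen_models(counts)
#>                           model n_classes_tested        min_p rejected_by      verdict
#> 1 two_locus_recessive_recessive                2 2.956882e-01        <NA> not_rejected
#> 2           one_locus_recessive                2 2.951953e-30   F2:G,F2:N     rejected
#> 3  two_locus_dominant_recessive                2 1.091484e-17   F2:G,F2:N     rejected
#> 4        cyto_nuclear_recessive                2 0.000000e+00   F2:G,F2:N     rejected
```

Only the two-locus recessive-recessive model survives: 38/516 ≈ 7.4% and
38/661 ≈ 5.7% white are both consistent with the 1/16 expectation
(min p ≈ 0.30) and wildly inconsistent with 1/4 or 3/16.

Simulate the second-round BSA design end to end — 34 white / 26 green F3
seedlings, one per independent family, sequenced at depth 30 over a
20,000-SNP panel — then scan and call regions:

```r
panel <- simulate_snp_panel(20000, seed = 42)
sim <- simulate_f3_bsa_pools(panel, seed = 42)
st <- window_scan(per_snp_freq(sim$white_counts),
                  per_snp_freq(sim$green_counts))
reg <- call_regions(st)
reg$top_regions[, c("chrom", "start_bp", "end_bp", "n_windows", "peak_mean_diff")]
#>   chrom start_bp   end_bp n_windows peak_mean_diff
#> 1 chr13  5589290 29483628        10     -0.8281036
reg$bottom_windows[, c("chrom", "start_bp", "end_bp", "mean_absdiff")]
#>     chrom start_bp   end_bp mean_absdiff
#> 176 chr14 12210638 16915054   0.05207007
```

The single top-divergence region sits on chromosome 13 and contains the
causal position planted at 28.5 Mb (the white pool is fixed guttatus
there, the green pool fixed nasutus, hence a peak mean difference near
−0.83); the least-divergent window sits around the partner locus on
chromosome 14 (15 Mb), where both pools are fixed nasutus by design.

Progeny tests then classify green recombinants for interval narrowing:

```r
progeny_test(30, 10)  # "segregating_het"      (3:1 family)
progeny_test(40, 0)   # "homozygous_compatible" (0.75^40 < 0.05)
```

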