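# borderchip

Classification of insulator-associated ChIP-seq binding sites at
heterochromatin borders, with a truth-tracked simulator for end-to-end
validation.

## The problem

Chromatin factors such as the *Drosophila* hybrid-incompatibility protein
HMR bind the genome in two modes: sharply at *gypsy*-type insulator sites
co-occupied by Su(Hw), Mod(mdg4) and CP190, and at the edges of broad
HP1a heterochromatin domains next to the transcription start sites of
active genes. Separating the two classes from ChIP-seq tag data takes a
chain of downstream steps that is usually scattered across ad hoc
scripts. `borderchip` packages that chain for R/Bioconductor users:

* fixed-width peak calling against an input control
  (`call_fixed_width_peaks()`): 200 bp candidate windows on
  midpoint-shifted tag maxima, retained at `count >= min_tags`,
  normalized fold over input `>= 4` and Poisson upper-tail `p <= 1e-4`;
* broad HP1a-type domain segmentation (`call_domains()`);
* replicate consensus with the 2-of-3 support rule (`consensus_peaks()`);
* combinatorial cofactor overlap and the *gypsy*-like flag — a peak
  carrying Su(Hw), Mod(mdg4) **and** CP190 (`cofactor_combinations()`);
* HP1a adjacency: class 1 = peak overlapping or within 1 kb of a domain
  edge, class 2 otherwise (`classify_hp1a_adjacency()`,
  `border_offset()`);
* PWM motif scanning on both strands (`scan_motif()`);
* per-peak knockdown fold changes of normalized tag counts (tags per 10
  million) with a combined `< 50`-tag exclusion and Wilcoxon rank tests
  (`knockdown_foldchange()`, `ranksum_test()`, `signedrank_test()`);
* repeat-consensus enrichment, `RPKM = count * 1e9 / (length * library)`
  and `log2fc` with a 2-fold display filter (`repeat_enrichment()`,
  `consensus_coverage()`);
* anchor-centered composite profiles / heatmap matrices and peak-density
  histograms (`composite_profile()`, `peak_density_histogram()`);
* landmark annotation (promoter/TSS > TTS > exon > intron > intergenic)
  and expression linkage of class-1/class-2 bound genes
  (`annotate_peaks()`, `compare_expression()`).

Every stage is validated against brute-force oracles and by parameter
recovery from a synthetic world (`simulation_spec()`, `build_world()`,
`simulate_tags()`) that plants HP1a domains, border sites paired with
active genes, insulator sites of defined cofactor composition carrying
motif instances, and fragment-based tag samples with known enrichment.
See the methods vignette (`vignettes/borderchip-methods.Rmd`) for the
model and all parameter choices.

## Worked example

Simulate the default study (2 Mb genome, 100 planted sites at 10-fold
enrichment, three IP replicates of 5e5 tags) and run the full pipeline:

```r
library(borderchip)

spec <- simulation_spec(seed = 1)
res  <- run_pipeline(spec)

length(res$consensus)                        # 2-of-3 consensus peaks
#> [1] 100
table(res$classification$peaks$gypsy_like,
      res$classification$peaks$hp1a_class)
#>
#>         class1 class2
#>   FALSE     40     18
#>   TRUE       0     42
profile_fwhm(composite_profile(res$replicates[[1]], res$world$sites))
#> [1] 204.3795
subset(res$repeat_table, displayed)[, c("repeat_id", "log2fc")]
#>   repeat_id   log2fc
#> 1     gypsy 3.000962
#> 2     gtwin 2.599653
res$expression_comparison$mutant[, c("class", "n", "median", "p_value")]
#>          class   n      median      p_value
#> 1    all_genes 200 -0.08365754           NA
#> 2 class1_bound  40 -1.04002556 4.767677e-14
#> 3 class2_bound   9 -0.04301172 6.521695e-01
```

All 100 planted sites are recovered; the 42 *gypsy*-like sites and the
40 HP1a-border (class 1) sites fall into the correct partition; the
composite binding profile is ~200 nt wide (one 10 bp bin above the
fragment length); only the two 5'-enriched retroelements pass the 2-fold
repeat display filter; and genes bound at class-1 promoters are
down-regulated by ~1 log2 unit in the simulated mutant while class-2
genes are unaffected.

A thin command-line front end over the same functions ships in
`inst/scripts/borderchip` (subcommands `simulate`, `callpeaks`,
`calldomains`, `consensus`, `classify`, `quantify`, `profile`,
`repeats`, `annotate`).

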