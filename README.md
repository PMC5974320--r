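# tomoloc

Localization analysis of RNAs and proteins along the animal–vegetal axis of
the amphibian egg, from tomographic (cryosection) profiling data.

A polarized egg is sectioned along its first developmental axis and the
sections are pooled into ordered segments — five (A–E, animal pole first)
for RNA-seq, four (A–D) for proteomics — each measured in several
biological replicates. `tomoloc` turns those segment × replicate tables
into localization biology:

* **qPCR-anchored normalization** — standard count normalization assumes
  most genes are equally distributed between samples, which is false along
  an intracellular axis. Anchor genes quantified by qPCR tomography give
  per-segment size factors `f_s = median_g (q_{g,s} / r_{g,s})` (qPCR
  fraction over RNA-seq fraction, geometric mean 1), applied per replicate;
  genes with mean normalized signal below 15 are dropped.
* **Rule-based classification** of fraction profiles into extremely
  animal / animal / vegetal / extremely vegetal / other (RNA) and
  animal / even / vegetal / other (protein, with a ≥2-of-3 replicate
  quorum), using strict-inequality threshold rules with extreme categories
  taking precedence.
* **Homoeologue concordance** — `.L`/`.S` gene pairs of an allotetraploid
  genome are paired by base symbol, compared by category, and flagged when
  diametrically opposite; per-pair 3′UTR motif counts are reported vegetal
  copy first ("3:0").
* **3′UTR sequence analysis** — k-mer over-representation per category
  (`x² = Σ (O−E)²/E`, `df = n−1`, `E = C(N−t(k−1), t)/4^{tk}`, upper tail,
  raw p < 0.001 plus an excess requirement), uniqueness filtering between
  animal and vegetal groups, motif cross-referencing; exact IUPAC and PWM
  scanning with dynamic-programming match p-values; Fisher enrichment;
  motif similarity by ungapped Pearson alignment with UPGMA family
  clustering and familial consensus profiles.
* **A fully seeded synthetic-data generator** that emulates the study
  structure (archetype profiles, segment distortions, anchor Cq tables,
  planted TTCAC zipcodes, designed homoeologue discordance) so the entire
  pipeline is testable end to end without any external download.

Everything is tidyverse-shaped: data frames in, tibbles out, `ggplot2`
helpers (`plot_profiles()`, `plot_presence_heatmap()`,
`plot_category_summary()`) and `tidy()`/`glance()` methods for derived
objects.

## Worked example

```r
library(tomoloc)

cfg <- synth_config(seed = 1, n_genes = 500)   # desk-scale synthetic study
res <- run_pipeline(cfg, k = 5)
res
#> tomoloc pipeline run (seed 1)
#>   simulate: 760 genes, 250 homoeologue pairs, 750 UTRs
#>   normalize: 759 genes kept (1 below expression threshold)
#>   classify: extremely_animal 4.2%, animal 91.3%, vegetal 1.8%, extremely_vegetal 0.8%, other 1.8%
#>   homoeolog: 93.2% concordant of 250 pairs
#>   kmers: 30 significant animal, 26 vegetal, 56 unique
#>   cluster: 1 motif families
```

The report reads top to bottom like the analysis: 500 base genes were
expanded into 250 `.L`/`.S` pairs (760 gene entries incl. anchors); one
gene fell below the mean-normalized-read threshold of 15; the classified
category proportions track the generator's design (animal-dominated, rare
vegetal classes); pair concordance is estimated from *classified* labels,
so classification noise adds a little false discordance on top of the
designed 3%; and the planted vegetal element surfaces in the k-mer screen:

```r
head(dplyr::filter(res$kmers$vegetal, significant), 2)
#> # A tibble: 2 × 9
#>   kmer      k n_genes obs_total exp_total statistic    df  p_value significant
#>   <chr> <dbl>   <int>     <int>     <dbl>     <dbl> <int>    <dbl> <lgl>
#> 1 TTCAC     5      16        51      21.9      90.2    15 8.93e-13 TRUE
#> 2 CCCCC     5      16        38      21.9      82.0    15 2.99e-11 TRUE

glance(res$homoeolog$concordance)
#> # A tibble: 1 × 5
#>   fraction_concordant n_pairs n_total n_discordant n_opposite
#>                 <dbl>   <int>   <int>        <int>      <int>
#> 1               0.932     250     250           17          3
```

TTCAC was planted at Poisson rate 2 per vegetal UTR: observed 51 copies
across 16 vegetal-side UTRs against 21.9 expected under the uniform
background model. (At this small n a few background k-mers clear the raw
p < 0.001 screen too — the screen is deliberately uncorrected; the
uniqueness filter against the animal set is what isolates real signal.)

Individual stages are ordinary functions on data frames and compose with
the pipe:

```r
sim <- simulate_rna(synth_config(seed = 7))
labels <- compute_size_factors(sim$counts, sim$cq) |>
  (\(sf) apply_size_factors(sim$counts, sf))() |>
  filter_low_expression() |>
  to_fractions() |>
  consensus_fractions() |>
  classify_rna()
summarize_categories(labels, "rna")
```

See `vignettes/tomoloc-methods.Rmd` for the models, parameter meanings and
design decisions, including what the synthetic generator does and does not
emulate.

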