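# locusecho

Genomic-neighborhood co-expression and position-effect analysis for yeast
loci.

## The problem

In compact genomes such as *Saccharomyces cerevisiae*, neighboring genes are
transcriptionally coupled: the Pearson correlation (PCC) between a gene's
expression profile and its neighbors' decays with genomic distance, and
replacing an ORF with a highly expressed marker cassette (KanMX6) can
perturb flanking genes — the "neighboring gene effect". Anyone engineering a
yeast locus (or interpreting a deletion-collection phenotype) therefore
needs to know how strongly a focal gene echoes its neighborhood. `locusecho`
packages that analysis for the six-gene freeze–thaw tolerance set (*AQY1*,
*ATH1*, *CAR1*, *POG1*, *PUT1*, *YCP4*) and for any other locus you point it
at:

- **ordered gene maps**: ±k neighborhoods with signed midpoint distances and
  centromeric/telomeric orientation;
- **co-expression profiles**: focal-vs-flanking PCC per condition block
  (cell cycle, heat shocks, oxidative/osmotic stressors, ...), with
  condition-clustered heatmaps that keep genes in genomic order;
- **decay fits**: nonlinear least-squares fits of
  `PCC(d) = c + a·exp(−|d|/λ)`, giving an amplitude `a`, decay length `λ`
  (bp) and baseline `c` per locus;
- **spotting-assay quantification**: dilution-series growth indices,
  stress/control relative growth, Student's *t* tests against wild type, and
  the −1/FT/+1 locus heatmap;
- **qPCR**: the 2^−ΔΔCt relative-quantification pipeline normalized to
  *ACT1*, with melt-curve filtering and replicate-level testing;
- **synteny**: anchored cross-species gene-order alignment with
  present/lost/insertion calls;
- **a synthetic-data generator** whose ground-truth parameters (`a0`, `λ0`,
  `c0`, fold changes, fitness ratios) make every stage testable end to end
  without downloads.

## Worked example

```r
library(locusecho)

# simulate a genome whose gene-pair correlation follows
# 0.1 + 0.6 * exp(-d / 5000 bp)
cfg  <- sim_config(n_chromosomes = 1, genes_per_chromosome = 41,
                   decay_amplitude = 0.6, decay_length = 5000,
                   baseline_corr = 0.1, n_blocks = 1,
                   samples_per_block = 4000, seed = 1)
ann  <- simulate_genome(cfg)
expr <- simulate_expression(ann, cfg)

focal <- ann$gene_id[ann$feature == "gene"][21]
nb    <- neighborhood(ann, focal, k = 15)
prof  <- locus_profile(expr, nb)
fit   <- fit_decay(prof)
fit
#> <decay_fit> pcc = 0.1033 + 0.575 * exp(-|d| / 5283.5 bp), rss = 0.006319, n = 30
```

The fitted amplitude (0.58), decay length (5.3 kb) and baseline (0.10)
recover the generating parameters (0.6, 5 kb, 0.1) within sampling error:
the locus "echo" has strength `a + c ≈ 0.68` for immediate neighbors and
fades to the genome baseline over a few kilobases. On the packaged
*S. cerevisiae* gene-order map, the same machinery gives the published
flanking pairs:

```r
neighborhood(scer_gene_order(), "YCP4", k = 1)
#> # A tibble: 2 × 6
#>   focal neighbor offset signed_distance direction   is_essential
#> 1 YCP4  MRPL32       -1            -990 centromeric FALSE
#> 2 YCP4  CIT2          1            1620 telomeric   FALSE
```

`autoplot()` renders every result type (correlation heatmaps, decay curves,
locus growth heatmaps, synteny alignments); `tidy()`/`glance()` summarize
fits; `run_all(run_config(...))` drives the whole pipeline and writes a TSV
bundle plus a reproducibility manifest.

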