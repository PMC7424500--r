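# dnbscreen

Early-warning screening for **predisease states** in small-sample
time-course gene expression data, using dynamical network biomarker
(DNB) statistics.

DNB theory predicts that just before a critical transition (e.g. the
onset of metabolic syndrome in a disease-model mouse), a specific gene
module shows a simultaneous burst of expression *fluctuations* and
mutual *correlations* — while its mean expression may not change at all.
`dnbscreen` is for researchers with a gene-by-sample expression matrix
over a few timepoints, two groups (control vs. treated), very few
replicates per cell, and a candidate DNB gene set: it quantifies the
burst, tests whether an intervention suppresses it, and provides the
surrounding analysis steps.

## The statistics

For a gene set *S* within one (group, week) cell of *n* samples:

```
I_s = (1/|S|) ∑_{i∈S} s_i                        (average standard deviation)
I_r = mean over pairs i<j of ( |r_ij| − c(n) )   (average correlation strength)
```

where `s_i` is the sample SD of gene *i* (log2 units), `r_ij` the
Pearson correlation between genes *i* and *j* across the cell's samples,
and `c(n) = 2/[(n−2)·B(1/2,(n−2)/2)]` is the expected absolute
correlation of two *independent* standard normals at sample size *n*
(0.64, 0.50, 0.42 for n = 3, 4, 5). The correction makes `I_r`
fluctuate around 0 for independent genes even at tiny *n*, so a peak is
a real early-warning signal, not a small-sample artifact.

Supporting modules: probe collapse + 2% trimmed-mean normalization +
log2 (`preprocess_expression`), DEG extraction as the intersection of a
strict two-fold-change filter with BH-controlled two-tailed Welch tests
(`extract_degs`), correlation-distance average-linkage clustering of
temporal profiles cut at 0.5 (`cluster_timecourses`), gene-set overlap
vs. the hypergeometric chance level with a one-tailed Fisher exact test
(`overlap_stats`), and a synthetic generator that plants the
variance/correlation spike via a shared latent factor
(`generate_dataset`).

## Worked example

Generate a synthetic five-week study (control n = 5,5,5,4,5; treated
n = 3,4,4,4) with a correlation spike planted at week 5 in the control
group and fully suppressed in the treated group, then score a 147-gene
DNB set:

```r
library(dnbscreen)
ds <- generate_dataset(synth_config(seed = 7))
scores <- score_timecourse(ds$expression, ds$metadata, ds$dnb_genes)
print(scores$scores, digits = 3)
#>     group week n_samples n_genes     c   I_s       I_r
#> 1 control    3         5     147 0.424 0.495  9.43e-04
#> 2 control    4         5     147 0.424 0.460  2.99e-03
#> 3 control    5         5     147 0.424 0.872  2.66e-01
#> 4 control    6         4     147 0.500 0.454  1.02e-03
#> 5 control    7         5     147 0.424 0.461 -2.54e-03
#> 6 treated    4         3     147 0.637 0.436 -2.40e-03
#> 7 treated    5         4     147 0.500 0.453  5.85e-05
#> 8 treated    6         4     147 0.500 0.438  3.09e-03
#> 9 treated    7         4     147 0.500 0.429 -5.22e-03
```

Both scores peak sharply at week 5 in the control group (`I_s` 0.87 vs.
a ~0.46 baseline; `I_r` 0.27 vs. ~0) and the peak is absent in the
treated group — the suppression pattern the method is built to detect.
Quantify it:

```r
unlist(suppression_summary(scores, week = 5))
#>         week      n_genes  n_decreased     n_halved Is_ratio_pct Ir_ratio_pct
#>   5.00000000 147.00000000 134.00000000  69.00000000  51.91473316   0.02201926
```

134 of the 147 DNB genes have a lower SD in the treated group at week 5,
69 are more than halved, and the treated `I_r` is 0.02% of control.
Overlap of a gene set with a DEG union against chance:

```r
ov <- overlap_stats(dnb_set, deg_union, universe_size = 24217)
#> observed 6, expected 4.2, p = 0.25   (for |A|=147, |B|=696)
```

an overlap at chance level — mean expression of the module is untouched
even though its fluctuations collapse.

A command-line front end covers the same pipeline
(`run_cli()` or `inst/exec/dnbscreen`): subcommands
`simulate | preprocess | deg | cluster | score | report`.

## Documentation

The methods vignette (`vignettes/dnbscreen-methods.Rmd`) describes the
model, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and the package's
numerical conventions.
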