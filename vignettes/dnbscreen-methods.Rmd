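---
title: "Detecting predisease states with DNB statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting predisease states with DNB statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnbscreen)
```

## The problem

Complex diseases often pass through a *predisease state*: a window just
before a critical transition in which the system is still reversible but
already unstable. Dynamical network biomarker (DNB) theory predicts that
near such a tipping point a specific group of genes shows (i) elevated
fluctuations of expression and (ii) strengthened mutual correlations,
while its average expression level need not change at all. `dnbscreen`
implements the statistics that quantify these two signals in small-sample
time-course expression designs (for example, weekly microarray profiles
of a disease-model mouse strain with and without an intervention), plus
the supporting preprocessing, differential-expression and clustering
steps, and a synthetic-data generator used for validation.

## The DNB scores

For a gene set $S$ observed in one (group, week) cell with $n$ samples:

$$I_s = \frac{1}{|S|}\sum_{i \in S} s_i, \qquad
  I_r = \binom{|S|}{2}^{-1} \sum_{i<j \in S} \left(|r_{ij}| - c(n)\right),$$

where $s_i$ is the sample standard deviation (log2 units, $n-1$
denominator) of gene $i$ across the cell's samples, $r_{ij}$ the Pearson
correlation between genes $i$ and $j$ across those samples, and $c(n)$ a
correction for the systematic inflation of $|r|$ at tiny $n$:

$$c(n) = E|r| \;\text{under independence}\; =
  \frac{2}{(n-2)\,B\!\left(\tfrac12, \tfrac{n-2}{2}\right)},$$

which evaluates to $2/\pi \approx 0.64$, $1/2$, and $4/(3\pi) \approx
0.42$ for $n = 3, 4, 5$. With this centering, $I_r$ fluctuates around 0
for mutually independent genes at any sample size, so a positive
excursion is interpretable as genuine correlation structure rather than a
small-$n$ artifact. `correction_term()` uses the closed form for any
$n \ge 3$; `correction_term_mc()` is an independent Monte-Carlo estimator
kept as a cross-check oracle in the test suite.

Two conventions deserve emphasis because the defining formula is easy to
misread:

* **Correlation *strength* means $|r_{ij}|$.** The correction term is the
  expected *absolute* correlation under independence — a nonnegative
  quantity — so only the absolute-value reading makes the centered score
  null-mean-zero. A signed mean of $r_{ij}$ would be centered already and
  would need no correction.
* **SDs are computed on log2-normalized values directly**, with no
  per-gene standardization against a reference week. $I_s$ therefore
  carries log2 units and scales homogeneously if the data are rescaled.

`score_timecourse()` evaluates both scores in every (group, week) cell;
cells with fewer than 2 samples (no SD) or 3 samples ($c(n)$ undefined)
are reported as `NA` rows rather than silently dropped. Genes of the set
missing from the matrix, and genes constant within a cell, are excluded
with machine-readable warnings. `suppression_summary()` compares the two
groups at one week: it counts genes with strictly lower treated SD,
genes reduced by strictly more than half, and reports the
treated/control ratios of $I_s$ and $I_r$ as percentages.

## Preprocessing

`preprocess_expression()` fixes the order of operations as: collapse
probes to gene symbols on raw intensities (unannotated probes dropped,
multi-probe genes averaged arithmetically), divide each sample by its 2%
trimmed mean, then log2. The trimmed mean removes $k = \lfloor 0.02 m
\rfloor$ values from each tail by sorted position, so ties at the
boundary may be split — a deterministic convention. After normalization
the trimmed mean of every sample is exactly 1 (log 0), which makes the
chain invariant to per-sample rescaling. Nonpositive intensities are a
hard error naming the gene and sample: background-subtracted intensities
are assumed positive, and a silent pseudo-count would corrupt fold
changes. Whether probe collapse should precede or follow normalization is
not fully determined by the method description this package follows; the
raw-first order is adopted as the documented reading of the listed step
sequence.

## Differential expression

`extract_degs()` applies two independent filters per timepoint and takes
their intersection:

1. **Fold change:** the absolute difference of per-group arithmetic means
   of log2 values must *strictly* exceed 1 (strictly more than two-fold
   in the original scale). "More than" is read as exclusive; a gene at
   exactly 1.0 is not a candidate.
2. **Welch test + BH:** two-tailed Welch $t$-tests per gene (unbiased
   variances, Welch–Satterthwaite df), with the rejection *level*
   adjusted by the Benjamini–Hochberg step-up rule at
   $E(\mathrm{FDR}) \le 0.05$, applied across all genes at that week
   (not pooled across weeks, since each week is its own comparison).

Degenerate inputs follow a documented convention: two groups with zero
variance give $t = 0, p = 1$ when the means agree and $p = 0$ when they
differ. `union_degs()` unions the per-week DEG sets, and
`overlap_stats()` compares any two gene sets against the hypergeometric
chance level $|A||B|/N$ with a one-tailed Fisher exact $p$
($P[X \ge k]$, over-representation). One-tailedness is this package's
documented choice: the scientific question is whether one set is
*enriched* in the other, and the worked-example probability reproduces
the published value under the upper-tail computation. The universe size
defaults to the number of genes in the analyzed matrix.

## Clustering of temporal profiles

`cluster_timecourses()` groups DEGs with similar time evolutions. Each
gene's feature vector is, by default, its per-(group, week) cell means of
log2 expression, concatenated control weeks ascending then treated weeks
ascending; cell means remove unequal-replicate artifacts, and an option
(`use_cell_means = FALSE`) switches to all individual samples. Features
are z-scored per gene (the dynamic range of expression is large),
converted to the dissimilarity $1 - r_{ij}$ (Pearson; the unqualified
"correlation coefficient" default), clustered by unweighted average
linkage, and cut at height 0.5, *inclusive* (a merge at exactly 0.5
stays merged). The linkage is implemented in the package rather than
delegated to `stats::hclust` so that ties at the minimum are broken
reproducibly by the lowest leaf index; the test suite checks it against
both `hclust` and a from-scratch oracle that recomputes every
inter-cluster mean from the raw dissimilarity matrix.

## The synthetic-data generator

`generate_dataset()` plants exactly the structure the scores target. For
gene $g$ and sample $s$ in cell $(\gamma, t)$:

$$x_{gs} = \mu_g
  + a\,\kappa(\gamma)\,\mathbf 1[g \in \mathrm{DNB},\, t = t_{\text{spike}}]\, z_s
  + \Delta\,\mathbf 1[g \in \mathrm{DEG},\, t \ge t_{\text{onset}},\, \gamma = \text{treated}]
  + \varepsilon_{gs},$$

with $z_s \sim N(0,1)$ a per-sample latent factor shared by all DNB genes
with a common loading $a$, $\kappa(\text{control}) = 1$,
$\kappa(\text{treated})$ the attenuation parameter, and
$\varepsilon \sim N(0, \sigma^2)$ independent. The one-factor form is the
simplest generator that raises SDs and pairwise correlations *together*
— at the spike week each DNB gene has SD $\sqrt{a^2\kappa^2 + \sigma^2}$
and each pair correlation $a^2\kappa^2/(a^2\kappa^2 + \sigma^2)$ — which
is precisely the joint signature $I_s$ and $I_r$ measure.

Defaults state the emulated world: five weekly timepoints (3–7), per-cell
sample counts control 5, 5, 5, 4, 5 and treated 3, 4, 4, 4 (the small
replicate numbers typical of this design, deliberately exercising all of
$c(3)$, $c(4)$, $c(5)$); 2,000 genes with baselines uniform on
$[4, 12]$ log2 to mimic microarray dynamic range; a 147-gene DNB set;
$\sigma = 0.5$ and $a = 1$ (spike-week SD $\approx 1.118$, pairwise
correlation $0.8$); spike at week 5 with full suppression
($\kappa = 0$) in the treated group; and 150 shifted genes with
$\Delta = 1.2$ log2 from week 6, applied to the treated group, so the
strict two-fold filter is cleared in expectation. Where the emulated
study states no value (gene counts, $\sigma$, $a$), the defaults were
chosen once as field-realistic and are not tuned against test outcomes.

What a green test does *not* establish: the generator is
Gaussian-on-log2 with homogeneous loadings and a single spike week. Real
microarray noise is heavier-tailed and heteroskedastic, probe effects and
batch structure are absent, and real DNB modules have heterogeneous
loadings. Green acceptance tests establish that the statistics recover
the planted structure under the model's own assumptions, not that the
biological findings replicate; full-data reproduction of the published
counts requires the deposited expression series and original DNB gene
list (see `scripts/external_validation.R`).

Note on power at the defaults: with $\Delta = 1.2$, $\sigma = 0.5$ and
4-vs-4 samples, the per-gene Welch test is underpowered against a BH
threshold across 2,000 genes, so the default dataset yields few DEGs —
a faithful property of small designs, not a defect. Planted-truth DEG
tests therefore use the strong-signal toy configuration
($\Delta = 3$, $\sigma \le 0.2$) under which recovery is essentially
exact.

## Numerical and design choices

* Sample SDs and Welch variances use the $n-1$ denominator throughout.
* $k = \lfloor \text{fraction} \times m \rfloor$ trim counts; at the
  array scale ($\sim$24k genes) rounding is immaterial.
* BH is kept as rejection flags (the step-up rule adjusts the level, not
  the $p$-values); adjusted $p$-values can be obtained with
  `p.adjust(p, "BH")` if wanted, but decisions come from the rule.
* Linkage ties break by lowest contained leaf index; cutoff comparison
  is inclusive at the boundary.
* $c(n)$ is computed from the closed form for any $n \ge 3$; the three
  printed two-decimal values serve as regression tests.
* The suppression comparison week defaults to the control week with
  maximal $I_r$ (the empirical spike), overridable.
* All randomness flows through a single integer seed per generator call;
  identical configurations and seeds are bit-reproducible.

## Known limitations

* `read_geo_series_matrix()` is a best-effort convenience for
  uncompressed series-matrix text; sample characteristics layouts vary,
  so group/week extraction falls back to manual metadata.
* $I_r$ is a mean over all $\binom{|S|}{2}$ pairs; for $|S|$ in the
  thousands the correlation matrix becomes the dominant cost.
* No moderated-variance (limma-style) testing: the method this package
  implements specifies plain Welch tests, and with $n \le 5$ per cell
  the two can disagree; this is intentional fidelity, not an oversight.
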