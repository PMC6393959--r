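---
title: "Methods: organ-specific cold-stress transcriptome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organ-specific cold-stress transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldatlas)
```

`coldatlas` analyses bulk RNA-seq experiments in which several plant
organs are profiled under control conditions and after two durations of
cold treatment, and asks how the transcriptional response differs
between organs.  This vignette documents the statistical models, the
parameters that matter, the synthetic-data generator used to validate
every stage, and the design decisions taken where more than one
defensible choice existed.

## The differential-expression model

Counts for gene $g$ in sample $j$ are modelled as negative binomial
with mean $s_j \mu_{g}$ and variance $\mu + \alpha_g \mu^2$, the
dominant RNA-seq convention: $\alpha_g$ is the gene's dispersion and
$s_j$ a library-size factor.  Size factors are estimated by the
median-of-ratios rule — the median, over genes observed in every
sample, of $c_{gj} / \tilde c_g$ with $\tilde c_g$ the gene's geometric
mean — rescaled to geometric mean one.  This estimator ignores genes
with any zero count and is therefore robust to organ-specific silencing,
but it requires at least one gene detected everywhere;
`estimate_size_factors()` fails with an explicit message otherwise.

For one contrast (an organ's cold samples at one duration versus its
controls), the per-gene statistic is a Wald test on

$$\widehat{\mathrm{LFC}}_g =
  \log_2 \frac{\bar y_{gB} + c}{\bar y_{gA} + c},$$

where $\bar y$ are normalised group means and $c = 0.5$ a pseudocount
that keeps fold changes finite when a gene is absent from one group.
The standard error comes from the delta method with the NB variance,
$\mathrm{Var}(\widehat{\mathrm{LFC}})
 \approx \sum_{G \in \{A,B\}} \frac{\bar y_G + \alpha \bar y_G^2}
 {n_G\, (\bar y_G + c)^2 \ln^2 2}.$

**Dispersion moderation.**  The raw gene-wise estimator is
method-of-moments on normalised counts with group means removed:
$\hat\alpha_g = \max\!\big((v_g - m_g)/m_g^2,\ 10^{-8}\big)$ with $v_g$
the pooled residual variance and $m_g$ the pooled mean
(`estimate_dispersion()` returns exactly this).  At two or three
replicates per group this estimator is extremely noisy, and plugging it
straight into a normal Wald test makes the test anticonservative: genes
whose variance is underestimated by chance get inflated statistics.  The
test therefore blends each gene's residual variance with a trend value
$m + \hat\alpha_{\mathrm{med}} m^2$ (the median raw dispersion of genes
with $m \ge 10$) using `prior_df` pseudo-observations (default 6), and
refers the Wald statistic to a $t$ distribution with residual-plus-prior
degrees of freedom.  This is the same moderation idea used by the
established empirical-Bayes DE frameworks, reduced to its simplest form.
The package's test suite verifies on simulated null data (5000 genes,
3 replicates, $\alpha = 0.05$) that the raw-p rejection rate at 0.05
lies in a narrow band around the nominal level, and on data with planted
4-fold effects that sensitivity and empirical FDR are where they should
be; both checks are rerun by `scripts/acceptance.R`.

**Thresholds.**  A gene is called *up* when its Benjamini–Hochberg
q-value is at most `fdr_max` (default 0.05) **and**
$\widehat{\mathrm{LFC}} \ge \log_2(\texttt{min\_fold\_change})$ (default
fold change 2); *down* symmetrically.  Ties at the q threshold count as
significant.  The fold-change filter is applied to the raw (unshrunken)
fold change.  Genes with zero counts in every sample of a contrast are
excluded from testing and from the BH family $m$, and reported with
`NA` p- and q-values; this mirrors standard independent-filtering
practice.

## Cross-organ response classification

Per-contrast calls are combined over an explicit *scope* of contrasts:
a gene is **Down** if downregulated in at least one scope contrast and
upregulated in none, **Up** in the mirror case, and **Mix** if both
directions occur.  The three categories partition the genes DE anywhere
in the scope — an invariant asserted in the tests.  The scope is a
parameter because both per-timepoint (six organs at 3 h, six at 27 h)
and pooled twelve-contrast analyses are meaningful; `classify_response()`
defaults to everything it is given.  Commonality tables count genes DE
in exactly $k$ contrasts (membership by direction for Down/Up, by any
significant call for Mix), and `unique_genes()` extracts the $k = 1$
stratum of a named contrast.  Down/up ratios are reported rounded
half-up at two decimals, with a one-decimal companion for display,
since plain `round()`'s round-half-even is surprising in summary tables.

## Specificity metrics

Over a transcriptome map of $S$ sample groups, two per-gene statistics
describe expression-pattern width:

* **Shannon entropy** $H = -\sum_i p_i \log_2 p_i$, with $p_i$ the
  replicate-averaged RPKM fraction in group $i$.  No pseudocount is
  added, and genes with zero total expression get `NA` rather than 0:
  entropy measures the *shape* of a pattern, and an unexpressed gene
  has none.  $H$ is invariant to rescaling, bounded by $\log_2 S$, and
  zero exactly for single-group patterns.
* **DE Score**: the number of the $\binom{S}{2}$ pairwise group
  comparisons in which the gene is DE, run with the same test and
  thresholds as the stress contrasts for internal consistency.  Its
  maximum for a 79-sample map is 3081.

Entropy histograms default to bin width 0.3 bits so that the first bin
isolates the narrow-pattern stratum ($H \le 0.3$) where organ-specific
genes accumulate.

## Enrichment

Gene-set enrichment uses the right-tailed Fisher exact test on the
2×2 table of set membership against list membership inside a declared
universe, with BH correction over exactly the tested sets.  Two scores
are reported: the log₂ ratio of target percentages among DE versus
non-DE genes (infinite cases flagged explicitly), and the conventional
fold enrichment $(a/(a{+}b)) / ((a{+}c)/N)$.  Decisions taken here:

* The universe defaults to the genes tested for DE in the relevant
  analysis, not the whole genome — the standard choice that avoids
  inflating enrichment with never-observed genes.
* Term enrichment applies the double threshold q ≤ 0.05 **and** fold ≥ 2
  and uses the plain Fisher test, not the EASE-style $(a-1)$ deflation
  some annotation servers apply; with typical list sizes the difference
  is small, and the plain test has the cleaner null guarantee.
* Sets with fewer than two universe genes are skipped and leave the BH
  family; regulon enrichment (`tf_enrichment()`) keeps singletons but
  drops empty intersections with a warning.

## Quality control

`replicate_correlation()` reports pairwise Pearson $r^2$ on
$\log_2(\mathrm{RPKM}+1)$ with the headline mean taken over
within-replicate-group pairs only; constant profiles yield flagged
`NA`s instead of silent zeros.  `cluster_samples()` builds the sample
tree with `stats::hclust()` on correlation distance $1 - r$, average
linkage by default.  The distance and linkage are explicit parameters:
correlation distance is insensitive to library size, and average
linkage gives monotone merge heights, but neither choice is forced by
the data.  Trees serialise to Newick via `ape`.

RPKM itself is $c_{gj} \cdot 10^9 / (L_g T_j)$ with $L_g$ the exonic
length in bp and $T_j$ the sample's total assigned gene reads — the
only depth denominator available without re-alignment, which is
documented rather than inferred.

## The synthetic-data generator

`simulate_dataset()` produces the package's validation substrate; its
defaults define the study conditions the tests assume.

* **Design**: six organs (cotyledons, hypocotyl, leaf, flower, young
  flower, seeds) × {control, 3 h cold, 27 h cold} × 3 replicates.  The
  motivating experimental design used 2 replicates; the default is 3 so
  that a simple replicate-level test has usable power, and 2 is
  supported and tested.
* **Baselines**: control means are log-normal (natural-log mean 4,
  sd 1.5, i.e. median ≈ 55 counts spanning roughly four orders of
  magnitude).  The three photosynthetic organs share a per-gene block
  deviation (log-sd 0.8) on top of which each organ adds a small
  deviation (log-sd 0.15): photosynthetic samples are strongly
  correlated with each other and separate from flowers and seeds, so
  sample clustering has realistic structure to recover.
* **Expression-pattern spectrum**: a configurable fraction (default
  0.10) of genes is expressed in exactly one organ (mean zero
  elsewhere), creating the low-entropy stratum; all other genes are
  ubiquitous.
* **Stress effects**: per organ × timepoint contrast, a fraction
  (default 0.10 — free in the configuration, since the true proportion
  of responsive genes is unknown) of that organ's expressed genes gets
  a true effect with $|\mathrm{LFC}|$ uniform in [1.5, 4] and random
  sign; the configuration refuses lower bounds below 1 so every true
  effect clears the 2-fold threshold.  A further fraction (default
  0.05) of responsive genes is given explicitly opposite directions in
  two organs, guaranteeing the Mix category is exercised rather than
  left to chance.
* **Counts**: NB draws with $\mathrm{Var} = \mu + \alpha\mu^2$
  (default $\alpha = 0.05$, constant or per-gene; $\alpha = 0$
  degenerates to Poisson), after multiplying group means by per-sample
  size factors drawn log-uniformly from [0.5, 2] so normalisation is
  non-trivially tested.
* **Gene sets**: 219 transcription-factor regulons by default (50–200
  targets each), of which 10 are *active*: their targets oversample
  stress-responsive genes with a weight of 4, so
  $P(\mathrm{target}\mid\mathrm{DE}) / P(\mathrm{target}\mid\mathrm{non\text{-}DE})
  \approx 4$.  Forty functional terms (5 enriched) are generated the
  same way.
* **Determinism**: one integer seed drives every draw; identical
  configurations give bitwise-identical outputs.

What the generator does **not** emulate: positional read coverage or
alignment artefacts, circadian confounding, pooling of individual
plants within a replicate, correlated dispersion across genes, or GO
hierarchy structure (terms are flat sets).  Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

* Dispersion floor $10^{-8}$; variance-trend fallback 0.01 when no gene
  reaches mean 10.
* Pseudocount 0.5 on normalised group means; $0 \log 0 \equiv 0$ in the
  entropy; undefined ratios (no upregulated genes) and undefined
  correlations (constant profiles) are flagged, never coerced to 0.
* BH is `stats::p.adjust(method = "BH")`; the test suite checks it
  against an independently coded step-up rule, and the Fisher tail
  (`stats::phyper`) against exhaustive hypergeometric enumeration over
  all tables with $N \le 30$.
* Readers reject malformed input (negative, fractional or missing
  counts, duplicate identifiers, design/counts mismatches) with the
  offending coordinates; nothing is silently coerced.
* Problem sizes in the test and acceptance suites — 5000-gene single
  contrasts for calibration, 1500-gene six-set simulations repeated
  over ten seeds for enrichment recovery, 250–400-gene maps for
  pairwise-score oracles — were chosen as the smallest sizes at which
  the Monte-Carlo checks are stable.

## Known limitations

* The DE test operates on two groups with replicate-level means; there
  are no covariates, batch terms or shrunken fold-change estimates.
  Dispersion moderation is a single global trend, not the
  mean-dependent curve richer frameworks fit.
* The DE Score reuses the stress-analysis thresholds; whether a given
  published atlas used identical settings for its own score is not
  assumed — scores across maps are comparable only under equal
  thresholds and test.
* Enrichment treats gene sets as flat; no ontology propagation.
* RPKM is the only normalisation offered for expression-level outputs,
  matching the upstream data the package targets.
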