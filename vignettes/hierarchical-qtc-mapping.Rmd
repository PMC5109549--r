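---
title: "Hierarchical QTC mapping: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical QTC mapping: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtcgwas)
```

## The problem

Genome-wide association with $p \gg n$ markers is a sparse high-dimensional
regression problem,

$$ \mathbf{y} = \mathbf{X}\boldsymbol\beta + \boldsymbol\varepsilon, $$

with $\mathbf{y}$ the $n$ phenotypic observations, $\mathbf{X}$ the
$n \times p$ additive dosage matrix and most entries of $\boldsymbol\beta$
equal to zero. Its defining complication is that markers are correlated —
locally through linkage disequilibrium, and globally through population
structure, which correlates physically unlinked markers. Highly correlated
markers are exchangeable members of any "best subset", so no single-marker
answer is well defined, and structure-driven correlation produces false
single-marker associations unless a correction (typically a random effect on
a genomic relationship matrix) is applied — a correction that also removes
real signal.

`qtcgwas` takes the multi-marker route instead: it tests *clusters* of
correlated markers against the phenotype, jointly with all other markers, so
that no correction term is needed. The unit of discovery is the
**quantitative trait cluster (QTC)**: the smallest cluster of highly
correlated markers that is still significantly associated with the
phenotype.

## The procedure

1. **Deduplication.** Perfectly correlated markers ($|r| \ge 1 -$ `tol`,
   default $10^{-12}$; anti-correlated pairs count too) are collapsed onto
   one representative, the first of the class in genome order. They carry
   identical information, so removing them loses nothing — they are
   reinstated into the final QTCs, where they sharpen localization.
   Monomorphic markers are dropped.

2. **Clustering.** One genome-wide hierarchy is built over all markers from
   the dissimilarity $d = 1 - |r|$. The absolute value is deliberate:
   anti-correlated markers explain a phenotype equally well up to the sign
   of the effect, so they must co-cluster. The tree is never built per
   chromosome, because structure correlates unlinked markers and such
   markers must be able to share a cluster. Every node is a candidate
   cluster; leaf heights are 0 and all heights live in $[0,1]$.

3. **Screening and testing (HIT).** Because $p \gg n$, the hierarchy cannot
   be tested on a single joint fit. Instead, individuals are split at
   random: a LASSO with tenfold cross-validation on one half screens a
   manageable marker set $S$; on the other half the hierarchy is tested
   top-down. For cluster $C$ with $C \cap S \neq \emptyset$, an ANOVA
   partial $F$-test (gaussian) or likelihood-ratio $\chi^2$ (binomial)
   contrasts the model on all of $S$ with the model on
   $S \setminus C$ — the cluster is judged *against the background of
   everything else that was selected*, which is what prevents one signal
   from being attributed twice. The raw p-value is multiplied by
   $|S| / |C \cap S|$ (capped at 1) and monotonized against the parent, and
   children are visited only while the current node stays significant.

4. **Aggregation.** The split is repeated $B$ times (default 50) with
   different random halves. Per node, the $B$ adjusted p-values (1 where
   untested) are combined by quantile aggregation:
   $Q(\gamma) = \min\{1, \gamma\text{-quantile of } \{p_b/\gamma\}\}$ and
   $p_{\mathrm{agg}} = \min\{1, (1 - \log\gamma_{\min})
   \inf_{\gamma \in [\gamma_{\min}, 1]} Q(\gamma)\}$ with
   $\gamma_{\min} = 0.05$. The infimum is evaluated on the grid of order
   statistics, where it is attained: between consecutive order statistics
   the empirical quantile is constant while $1/\gamma$ decreases. A final
   monotonization pass down the tree makes "smallest significant cluster"
   well defined. The aggregate controls the family-wise error rate at the
   nominal level across all tested clusters.

5. **QTC calling.** Significant nodes with no significant descendant are
   the candidate results. A candidate is reported as a QTC only if it is
   *localizable*: its height must not exceed `max_height` (default 0.5,
   i.e. its members share a mean absolute correlation of at least 0.5).
   This criterion is part of the QTC concept itself — a QTC combines
   markers that cannot be distinguished for their contribution to the
   phenotype, which is only true of highly correlated markers. It also
   carries the error control over to structured panels: when a phenotype
   depends on population structure, the screened markers genuinely predict
   it out of sample and the top-level tests reject *correctly* — but the
   rejected clusters are huge, weakly correlated collections spanning
   chromosomes. Without the height criterion the procedure would report
   such a cluster as a "discovery" even though nothing is localized. With
   it, diffuse structure signal is recognized as unattributable and
   nothing is reported, while causal markers in tight LD blocks (heights
   near 0) are unaffected. Under island-model nulls at realistic FST even
   the most correlated chance pair sits at $d \approx 0.7$, far above the
   cutoff, so the choice of 0.5 is not delicate.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | family-wise error level; also steers the descent |
| `n_splits` | 50 | sample splittings $B$ |
| `gamma_min` | 0.05 | lower end of the aggregation quantile range |
| `split_fraction` | 0.5 | share of individuals used for screening |
| `cv_folds` | 10 | cross-validation folds of the LASSO screen |
| `max_partition_size` | 2000 | largest set clustered exactly |
| `max_height` | 0.5 | localization cutoff for reportable QTCs |
| `tol` (dedup) | 1e-12 | $1 - |r|$ below which markers are duplicates |
| `window_bp` (evaluation) | 10000 | truth-matching window, closed |

The LASSO penalty is fixed at the cross-validation *minimum*, not the
1-standard-error rule: the screen should err on the liberal side, since the
downstream hierarchical test is what controls the error rate. If the screen
returns more markers than the testing half can support
($|S| \ge$ residual degrees of freedom), $S$ is truncated to the markers
with the largest absolute coefficients, at most $n_{\mathrm{test}}/2$.

## Scalable clustering

Exact average-linkage agglomeration is $O(p^2)$ in memory and is used
whenever $p \le$ `max_partition_size`. Above that, a two-stage scheme is
used: a seeded k-medoids pass on $1 - |r|$ partitions the markers, exact
average linkage runs within each partition, and the partition roots are
joined by average linkage over the partition medoids, with join heights
spliced monotonically. A reunification sweep keeps tightly correlated twins
($|r| \ge 0.5$) in the same partition, since a cluster contract of the tree
is that strongly correlated markers co-cluster. The result is deterministic
given the matrix and the seed.

## The simulators

**Island-model genotypes** (Balding–Nichols): per marker, an ancestral
frequency $p_0 \sim U(0.05, 0.5)$ and subpopulation frequencies
$\mathrm{Beta}$-distributed with mean $p_0$ and variance
$F_{ST}\,p_0(1-p_0)$; individuals are assigned to subpopulations in equal
shares; inbred mode draws one allele (dosages 0/2), outbred two. Marker
positions are uniform over a synthetic genome (default 5 chromosomes of
30 Mb, roughly an *Arabidopsis*-sized genome). This reproduces the feature
of structured panels that matters here — structure-induced correlation of
unlinked markers — but *not* local LD along the chromosome, gene density,
or admixture gradients; power on real panels with extended LD will differ,
mainly in QTC width.

**Phenotypes**: `n_causal` markers drawn uniformly (the synthetic genome
carries no gene annotation, so no gene-density weighting), effects from
Gamma(shape 0.5, scale 1) or standard normal, each applied to a randomly
chosen allele (random sign). Environmental noise is calibrated on the
*realized* genetic variance, $\sigma^2_e = \mathrm{var}(g)(1-h^2)/h^2$, so
the expected realized heritability equals the target. The structured-null
generator makes the phenotype a function of the subpopulation label alone,
with the noise orthogonalized in-sample so the structure share is exact.

**RIL populations**: biparental recombinant inbred lines as fully
homozygous mosaics of two parental haplotypes; crossovers per chromosome
are Poisson with mean `map_expansion` (default 2, approximating the map
expansion accumulated under single-seed descent) times the map length in
Morgans, positions uniform on the genetic map, no interference and no
residual heterozygosity.

**Binary phenotypes** threshold the liability (genetic values plus
calibrated noise) at the empirical $1 - \text{prevalence}$ quantile, so the
case count is exact by construction.

## Numerical choices and degenerate inputs

- Dissimilarities are clamped to $[0,1]$ and hierarchy heights are made
  monotone (cumulative maximum within a build; join nodes at least as high
  as their children).
- Duplicate detection hashes a sign-invariant random projection of the
  standardized columns and verifies candidates exactly, avoiding the
  $O(p^2)$ scan; representatives are the first of each class in genome
  order, and medoid ties break toward genome order with a $10^{-9}$
  tolerance.
- Collinear columns inside the testing models are dropped by the pivoted
  decomposition in `lm`/`glm`; a cluster whose members are all aliased with
  the reduced model is untestable and gets p = 1.
- Zero residual degrees of freedom on the testing half is an error that
  names the remedy (smaller $S$); the screen's truncation rule normally
  prevents it.
- Seeds: one master seed spawns per-split (and per-stage) seeds through a
  counter scheme, so results are independent of execution order and thread
  count, and every run is exactly reproducible.
- Mean imputation of missing dosages preserves observed per-marker means;
  markers with no observed calls are an error rather than a guess.

## Problem sizes used by the test suite

The automated checks run at desk scale, chosen so the full suite completes
in minutes while the statistics remain meaningful: error control on 50
structured-null replicates of 400 individuals x 3,000 markers at 10
splittings; generator calibration on 100 phenotype replicates over a
500 x 5,000 panel; parameter recovery on 20 replicates of 500 x 2,000 with
five causal loci at $h^2 = 0.9$. Runs on real panels would use the default
50 (or more) splittings and whatever $p$ the genotyping provides; the
clustering stage is the only piece whose cost grows quadratically, and it
can be cached and reused across phenotypes (`write_hierarchy()` /
`read_hierarchy()`).

## Known limitations

- The island-model generator has no local LD, so simulated QTCs are almost
  always single markers plus their exact duplicates; real-data QTCs will be
  LD-block sized.
- Screening and testing assume additive dosage effects; dominance and
  epistasis are out of scope, as are random-effect models, effect-size
  confidence intervals, phasing, and LD-based imputation.
- A phenotype driven by non-genetic factors that co-occur with structure
  is indistinguishable from a structure-driven genetic signal; such factors
  must be modelled explicitly as covariates (`phenotype(covariates = ...)`,
  always unpenalized in both halves).
- Binomial support uses the liability-free logistic LRT on the testing
  half; very unbalanced case-control ratios with few individuals can make
  the LASSO screen unstable (the usual small-sample caveats apply).
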