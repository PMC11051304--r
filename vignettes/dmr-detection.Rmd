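---
title: "Calling differentially methylated regions with dmrvote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differentially methylated regions with dmrvote}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrvote)
```

## The statistical problem

Bisulfite sequencing reduces DNA methylation to a pair of counts per
cytosine: of the $N_{ijk}$ reads covering CpG site $i$ in replicate $k$
of group $j$, $X_{ijk}$ support methylation. Two-group comparisons are
hard in exactly the ways small-sample count data are always hard:
coverage is moderate and uneven, the number of replicates is small
(often six per group or fewer), and replicate-to-replicate variation in
the true methylation proportion is real biology, not noise that
averaging makes disappear. A per-CpG test on raw proportions conflates
sampling noise with that biological variability; `dmrvote` separates
them with a hierarchical model, stabilizes the variance estimates with
an empirical-Bayes prior, and only then asks which sites — and which
*regions* of consecutive sites — differ between groups.

## The hierarchical model

$$X_{ijk} \mid p_{ijk} \sim \mathrm{Binomial}(N_{ijk}, p_{ijk}), \qquad
p_{ijk} \sim \mathrm{Beta}(\mu_{ij}, \phi_{ij})$$

with the beta distribution written in its mean/dispersion form
$\mu = \alpha/(\alpha+\beta)$, $\phi = 1/(\alpha+\beta+1)$
(`beta_moments()` / `beta_params_from_moments()`). The dispersion
$\phi \in (0,1)$ measures between-replicate variability of the true
proportion; $\phi \to 0$ recovers a pure binomial. Across the genome
the dispersions are modelled as a log-normal field,

$$\phi_{ij} \sim \mathrm{LogNormal}(m_0 = -3.39,\; r_0 = 1.08),$$

a prior whose density mode is $e^{m_0 - r_0^2} \approx 0.0105$. The two
constants describe the dispersion landscape of typical RRBS data and
are deliberately *not* re-estimated per dataset — with six replicates
there is far too little information per site, and a fixed genome-wide
prior is what makes the per-site estimates stable. Both are exposed in
`dispersion_prior()` and in the pipeline configuration for users whose
platform genuinely differs.

Estimation at one site and group (`fit_all()`):

* **Mean**: the pooled read ratio
  $\hat\mu_{ij} = \sum_k X_{ijk} / \sum_k N_{ijk}$ — reads, not
  replicates, are weighted, so a deeply covered replicate counts more.
* **Dispersion**: $\hat\phi_{ij}$ maximizes the conditional posterior
  $\sum_k \log \mathrm{BetaBin}(X_{ijk} \mid N_{ijk}, \hat\mu, \phi) +
  \log \mathrm{dLogNormal}(\phi)$ with $\hat\mu$ plugged in
  (`estimate_dispersion()`).
* **Variance of the group mean**:
  $\widehat{\mathrm{var}}_{ij} = (\sum_k N_{ijk})^{-2} \sum_k N_{ijk}\,
  \hat\mu(1-\hat\mu)\,[1 + (N_{ijk}-1)\hat\phi]$
  (`estimate_group_variance()`). Note the $(\sum N)^{-2}$ factor: this
  is already the variance *of the pooled mean*, a point that matters
  below.

### Numerical choices

* The posterior is maximized over $\log\phi$ on
  $[10^{-6}, 1-10^{-6}]$ by bounded scalar search (`optimize`,
  tolerance $10^{-8}$ on the log scale); the objective is evaluated
  through log-gamma functions throughout. A 1000-point log-spaced grid
  is the fallback if the search ever returns a non-finite objective.
  The unit tests hold this optimizer to within $10^{-3}$ of an
  independent $10^4$-point grid search on random instances.
* The log-normal prior density is used untruncated even though
  $\phi < 1$; renormalizing a truncated density would multiply the
  posterior by a constant and cannot move the argmax.
* With a **single observed replicate**, between-replicate dispersion is
  unidentifiable (a one-observation beta-binomial likelihood cannot
  separate biological spread from sampling noise), so the estimator
  returns the prior mode $e^{m_0 - r_0^2}$ rather than letting the
  plug-in likelihood drag $\phi$ toward zero. Likewise, when
  $\hat\mu \in \{0, 1\}$ the beta parameters are undefined; the prior
  mode is returned and the variance is 0 (since $\mu(1-\mu) = 0$).
* Shrinkage is visible and intended: at six replicates and 200x
  coverage, median $\hat\phi$ recovers the truth within a factor of
  two, with true dispersions above the prior mode biased downward and
  singleton sites collapsing to the mode exactly.

## Filtering and clustering

Sites observed (total reads ≥ `min_coverage`, default 1) in at least
75% of all samples are *validated*; the rest are discarded as noise
(`filter_validated_cpgs()`, boundary inclusive: 9 of 12 samples
qualifies). Within a chromosome, maximal runs of validated sites whose
successive gaps are strictly under 100 bp form CpG clusters, and runs
with fewer than 5 sites are dropped (`build_clusters()`). The 5-site
floor is applied at cluster construction so that regions which could
never be reported are never fitted. The coverage floor is configurable
because practice varies (10x floors are common); the default of 1 read
is the most permissive reading of "observed in a sample".

## Ranking and the mapping decision

Three statistics score each analyzable CpG (`score_all()`), all
evaluated on the model-based estimates
$\bar x_j := \hat\mu_{ij}$, $\sigma_j^2 := \widehat{\mathrm{var}}_{ij}$:

| statistic | formula | orientation |
|---|---|---|
| Fisher ratio | $(\bar x_1 - \bar x_2)^2 / (\sigma_1^2 + \sigma_2^2)$ | larger = more differential |
| Z-score | $(\bar x_1 - \bar x_2) / \sqrt{\sigma_1^2 + \sigma_2^2}$ | by absolute value |
| Welch t | $(\bar x_1 - \bar x_2) / \sqrt{\sigma_1^2 + \sigma_2^2}$, Satterthwaite df | by absolute value |

The one genuinely open design point is how sample-statistic formulas
should consume model estimates. Because
$\widehat{\mathrm{var}}_{ij}$ is the variance of the group *mean* (it
carries the $(\sum N)^{-2}$ factor), Welch's statistic must **not**
divide it by $n_j$ again; replicate counts enter only the
Welch–Satterthwaite degrees of freedom
$(\sigma_1^2+\sigma_2^2)^2 / [\sigma_1^4/(n_1{-}1) +
\sigma_2^4/(n_2{-}1)]$, floored at 1 (a single-replicate group
contributes infinite variance-uncertainty and forces the conservative
df = 1). A consequence worth stating loudly: with this mapping the
Z-score and the Welch t are numerically identical and the Fisher ratio
is their square, so the three voters carry one ordering at this layer.
They are kept as three separate voters because the ensemble is defined
over the *method list*, and because any user who swaps in a different
variance mapping (or adds voters) immediately gets genuinely distinct
lists. Per-CpG p-values come from the Welch t only — it is the one
statistic of the three with a standard null distribution. Degenerate
sites (both variances zero, means unequal) receive a large sentinel
score ($10^{12}$) and the smallest representable p-value so ranking
remains total.

Under null simulations (no spiked effects, 6 vs 6, 20x, ~2000 sites)
the empirical type-I error of this test at nominal 0.05 sits near
0.06 — approximate, as expected from plug-in shrunken variances, and
within the 0.01–0.10 calibration band the test suite enforces.

## Rank combination and voting

Each statistic's scores become normalized ranks
$(\mathrm{rank}-1)/(m-1) \in [0,1]$, ties averaged, 0 = most
differential (`normalize_ranks()`). Voter $j$ votes for CpG $i$ when
$r_{ij} \le 0.04$, i.e. the site sits in the top 4% of list $j$
(boundary inclusive); a site becomes a candidate when strictly more
than 70% of voters agree — with three voters, unanimity
(`vote()`). Two interpretation decisions deserve record:

* The 0.04 threshold is read as a cutoff on the normalized rank (a
  top-tail membership), not on the raw statistic value: the normalized
  rank is the only [0, 1]-scaled per-list quantity in the scheme, and a
  sweep of the cutoff from 0 to 1 (`sweep_threshold()`) only makes
  sense on that scale.
* Ranking is computed genome-wide rather than within clusters.
  Normalized ranks inside a 10-site cluster would be degenerate (steps
  of 1/9 make a 4% cutoff mean "the single best site"); global lists
  keep the threshold meaningful at any cluster size.

The voting rule is monotone in both knobs, and with three voters it is
exactly the intersection of the three top-4% lists — both facts are
asserted as properties in the test suite.

### The prevalence ceiling

A structural property of top-fraction voting, documented here because
it governs what simulations can show: at most a fraction $\tau$ (= 4%)
of all scored CpGs can ever be candidates, so when truly differential
sites make up more than $\tau$ of the genome, sensitivity is capped
near $\tau/(\text{true fraction})$ *before* segmentation — and the
5-consecutive-significant-CpG rule compresses it much further, since
the surviving candidates scatter across many clusters. At a realistic
genome scale (say $10^4$ DMRs of ~20 CpGs among $8\times 10^6$ sites,
a true-site fraction of ~2.5%) the gate is wide enough; in a compact
simulation where 10% of clusters are spiked, it is binding, and
region-level sensitivity lands near 0.1–0.25 even though the
region-wise p-values separate spiked from null clusters almost
perfectly (AUC > 0.98) and the false-discovery fraction among calls is
essentially zero. Users who want high recall in high-prevalence
settings should raise `rank_threshold` in proportion to the expected
differential fraction; the default stays at the method's published
operating point.

## DMR segmentation and region statistics

Within each cluster, maximal runs of consecutive CpGs that are
candidates, have $p \le 0.05$, and share the sign of the methylation
difference become DMRs; a sign flip, a zero difference or any
intervening non-significant site breaks the run, and runs with fewer
than 5 CpGs are dropped (`segment_dmrs()`). Both gates (vote and
p-value) are required, in either order — a tiny p-value cannot rescue a
site the ensemble did not nominate.

Region statistics (`dmr_statistics()`): group means are
coverage-weighted averages of member means; the fold change
adds a $10^{-3}$ pseudocount to both means so fully unmethylated
control regions stay finite; the region Fisher ratio applies the
site-level formula to region means over summed member variances (one
of several defensible aggregations; it favours long consistent
regions); and member p-values are combined by Fisher's method,
$-2\sum\ln p \sim \chi^2_{2k}$ (`fisher_combine()`), with zeros clamped
to $10^{-300}$. Fisher's method assumes independent inputs, which
adjacent CpGs are not; the combined value is therefore treated as a
region ranking score, and no Brown/Kost-style correlation correction is
applied — by design, matching the method as published. FDR over the
called regions is Benjamini–Hochberg (`adjust_fdr()`); the procedure is
the field default where a specific one is not mandated. The optional
post-filters (`min_length_bp`, `min_fold_change`, `min_abs_diff`,
defaults off) mirror the candidate filters often applied to real-data
call sets (e.g. length > 200 bp, fold change > 20, absolute difference
> 0.1).

## The simulator

`simulate_dataset()` draws data from exactly the hierarchy the
estimator assumes, with known truth:

* **Geometry**: 200 clusters of 10–20 CpGs on one pseudo-chromosome,
  member gaps 5–60 bp (safely under the 100 bp rule), cluster gaps
  300–2000 bp. Cluster counts and gap ranges are configurable.
* **Baselines**: each cluster is mostly-unmethylated or
  mostly-methylated (Beta(2,8) vs Beta(8,2), equal weight), with small
  per-site jitter (SD 0.03) — the bimodality of real methylomes at CpG
  resolution.
* **Dispersion**: per-site $\phi$ from LogNormal(−3.39, 1.08) truncated
  to (0,1) by rejection (the untruncated mass above 1 is < 0.1%).
* **Coverage**: Poisson with mean 20 per site and sample (the 19–24x
  regime of typical RRBS libraries); a negative-binomial option adds
  overdispersed coverage. Zero-coverage cells become missing.
* **Effects**: a configured fraction of whole clusters (default 10%)
  receives a case-group mean shift of ±0.25 (sign random per DMR),
  clamped to [0.01, 0.99] — comparable to the absolute differences of
  top-ranked real-data DMRs. Spiking whole clusters makes region-level
  overlap evaluation unambiguous. A logit-scale effect is available.

What the simulator does *not* emulate: read-level artefacts (bisulfite
conversion error, mapping bias), spatial correlation of methylation
within a cluster beyond the shared baseline, coverage correlation
between neighbouring sites, chromosome-scale structure, and
truth intervals that straddle cluster boundaries. Passing tests on this
generator show that the estimation, ranking, voting and segmentation
machinery is correct under the model's own assumptions — not that the
model is adequate for any particular real library.

`punch_missingness()` blanks cells at a configured rate to exercise the
75% presence filter.

## Evaluation

The harness evaluates at region level (`evaluate_calls()`): the tested
units are the pipeline's CpG clusters; a cluster counts as significant
when it contains a called DMR with combined $p \le 0.05$ (calls satisfy
the ≥ 5 CpG rule by construction); truth overlap of ≥ 1 bp classifies
each cluster as TP/FP/FN/TN (`region_confusion()`), and the universe of
negatives is the tested-but-nonsignificant clusters without truth
overlap. Metrics follow the standard formulas (`confusion_metrics()`),
with zero denominators reported as `NaN` plus a warning rather than
silently patched. ROC curves sweep the cluster-level Fisher-combined
p-value with ties grouped; the trapezoidal AUC equals the
rank/Mann–Whitney AUC, which the tests assert against an independent
implementation.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at 200 clusters (~3000 CpGs,
6 vs 6, 20x), the null-calibration check at ~2000 CpGs, dispersion
oracle comparisons on 100 random small instances against $10^4$-point
grids, and parameter recovery at 500 sites per $(\mu, \phi)$ cell —
sizes chosen so the whole suite completes in about a minute on one core
while leaving every statistical band meaningfully powered.

## Known limitations

* The three default voters are rank-identical under the shipped
  variance mapping; the ensemble's value appears when voters are
  swapped or extended.
* Fisher's method over correlated neighbours makes combined p-values
  optimistic in absolute terms; rely on the q-value ordering and the
  empirical FDR rather than the nominal scale.
* The top-4% voting gate bounds recall when differential sites are
  dense (see the prevalence ceiling above).
* Strand is ignored; opposite-strand calls at one CpG must be merged
  upstream if that is the desired unit.
* No covariates, no smoothing across clusters, no annotation of calls
  into island/shore/shelf/promoter classes — the output is the interval
  table and BED track.
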