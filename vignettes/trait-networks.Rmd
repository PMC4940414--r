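---
title: "Correlation-based trait networks from replicated inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based trait networks from replicated inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

traitnet reconstructs co-regulation structure among metabolite and enzyme
traits measured on a replicated panel of inbred lines. This vignette explains
the statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the procedure is genuinely open.

## The model

Observations are raw trait values on samples indexed by line, replicate and
feature. Metabolite intensities from GC-MS are only meaningful relative to an
internal standard recorded per chromatogram, so the first step divides each
metabolite value by its sample's control value. Enzyme activities are assayed
on plates with batch offsets; they are standardized by their plate mean and
then centered per enzyme, so every enzyme column ends with mean zero.

For each feature the replicated design is summarized by the one-way
random-effects model

$$y_{ij} = \mu + g_i + \varepsilon_{ij}, \qquad
  g_i \sim N(0, \sigma^2_g), \quad \varepsilon_{ij} \sim N(0, \sigma^2_e),$$

with line effects $g_i$ and residuals independent. Fitting is by REML (one
`lme4::lmer` fit per feature), which clips negative variance components at
zero. Broad-sense heritability is reported on the per-observation basis,
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$, so it always lies in
$[0, 1]$; a line-mean basis
($\sigma^2_g / (\sigma^2_g + \sigma^2_e / r)$) is available as an option
because the literature uses both and the entry-mean variant is not always
stated. The per-line trait value used by all downstream stages is the BLUP
of the line effect,

$$\hat g_i = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e / n_i}
  \left(\bar y_{i\cdot} - \hat\mu\right),$$

with $n_i$ the line's replicate count and $\hat\mu$ the GLS grand mean. The
closed form is the direct code path; tests assert equality with `lme4`'s
conditional modes.

The coefficient of variation is computed on `blup + grand_mean`, i.e. back
on the measurement scale, because raw BLUP deviations are centered at zero
and `sd/mean` would be ill-defined. A consequence worth knowing: enzyme
profiles are mean-centered by the normalization itself, so their CV is
undefined (reported missing, with a warning) under the default
divide-then-center plate standardization. CV comparisons are therefore most
meaningful for metabolites or for un-centered inputs.

## Missing values

Panels of this kind typically have a few percent of missing cells. The
imputation is an EM-style low-rank completion: columns are standardized on
their observed cells, missing entries start at zero (the column mean), and
the algorithm alternates a rank-$k$ truncated SVD reconstruction with
re-imputation of the missing cells until the relative change of the imputed
values drops below `tol`. Defaults: $k = 3$ components, `tol = 1e-6`, at
most 500 iterations (non-convergence returns the best iterate with a
warning). Observed cells are never modified — this is asserted bitwise in
the tests. The procedure is deterministic; it needs no seed. The internal
column standardization matters: features here span several orders of
magnitude, and an unstandardized SVD would spend all its rank on the largest
columns.

## Network construction

Because trait distributions across inbred panels are generally non-normal,
association is measured by the Spearman rank correlation (average ranks for
ties) over the line-level BLUPs, with a two-sided p-value from the
$t$-approximation on $n - 2$ degrees of freedom — at $n \approx 100$ lines
the exact permutation distribution is both impractical and unnecessary.

Two thresholds gate an edge:

* **p-value cutoff.** The Benjamini–Hochberg step-up rule over all feature
  pairs at a target q-value of 0.05: the cutoff is the largest order
  statistic $p_{(i)} \le (i/m)\,q$. Filtering at `p <= p_cutoff` retains
  exactly the pairs with BH q-value at most the target.
* **correlation cutoff.** Calibrated by stability: for each candidate
  $|\rho|$ cutoff (default grid 0.10–0.60 by 0.05) the network is rebuilt at
  every p-value in a scan grid (default 0.01–0.05 by 0.01) and four global
  properties are computed — average degree, average local clustering,
  density, diameter. A candidate is stable when the relative range of the
  first three across the grid is at most `tolerance` (default 1%) and the
  integer diameter does not change at all; the smallest stable candidate
  wins. The quantitative meaning of "stable" and the candidate granularity
  are our choices; the scan grid matches the conventional 0.01–0.05 range.
  A useful intuition: with $n$ lines the p-threshold corresponds to an
  implicit $|\rho|$ threshold (about 0.26 at $p = 0.01$, $n = 101$), so the
  smallest candidate dominating that implicit threshold is typically the
  first stable one — at panel size ~100 this lands at 0.30.

Edges keep the signed correlation; the criterion is $|\rho| \ge$ cutoff, as
negative co-regulation is as informative as positive. Isolated features are
dropped from the node set.

## Communities and their significance

Communities are detected with walktrap (random-walk length 4, dendrogram cut
at maximum modularity — the algorithm authors' defaults) on the *unweighted*
graph; correlation magnitudes deliberately do not enter.

Each community with more than four nodes is tested for structural
significance: for every member, its *internal* degree (in the community's
induced subgraph) is paired with its *residual* degree (in the full network
after deleting all community-internal edges), and a one-sided Wilcoxon
signed-rank test asks whether internal exceeds residual. The test is
directional because the question is directional — is the community denser
inside than its members' remaining connectivity? Zero differences are
dropped. Degree data are heavily tied, and `stats::wilcox.test` cannot
compute an exact p-value under ties, so the package implements the exact
conditional null distribution (a subset-sum recursion over tie-averaged
ranks, doubled to stay integer) for up to 25 informative pairs, switching to
the normal approximation with continuity and tie correction above; both
paths reproduce `wilcox.test` exactly where it is applicable.

Non-significant ($p > \alpha$, default 0.05) or untestable (size $\le 4$)
communities are merged into the significant community to which they have the
most inter-community edges, ties broken toward the larger community and then
the lowest id, one merge at a time with re-testing after each; communities
with no edge to any significant community are left standalone and flagged.
The merge target rule is our formalization — the motivating practice merged
by adjacency without stating a rule — and every tie-break is deterministic
so runs are reproducible.

## Node statistics and edge validation

Node importance is summarized by degree and unnormalized Freeman
betweenness, counted once per unordered pair with fractional attribution
over equally shortest paths (the convention under which a 50-node network
yields values like 185.25). Significance comes from a permutation null: each
iteration independently permutes every feature's BLUP vector across lines —
destroying all inter-feature association while preserving marginals —
rebuilds the network at the same fixed cutoffs, and records each original
node's degree and betweenness (zero when it drops out). P-values use the
add-one estimator $(1 + \#\{\text{permuted} \ge \text{observed}\}) /
(1 + B)$, so the smallest attainable value is $1/(1+B)$ and a statistic of
zero gets $p = 1$. What exactly to permute is ambiguous in practice — data
rows or graph wiring — so a degree-preserving rewiring mode is provided as
an alternative; row permutation is the default because it targets precisely
the null of no inter-feature association. Note that degree is a small
discrete statistic: its permutation p-values are *valid* (super-uniform) but
not exactly uniform, which is the property the test suite checks.

Finally, each retained edge is validated on the linear scale: the Pearson
correlation of the two BLUP profiles, its square as shared variance, and the
conventional bins ($|r| \le 0.4$, $(0.4, 0.6]$, $> 0.6$; shared variance
$\le 20\%$, $(20\%, 40\%]$, $> 40\%$).

## The synthetic-data generator

`generate_panel()` draws a complete panel with known ground truth so that
every stage can be tested against what was planted. Line-level genetic
values are multivariate normal with an equicorrelated block structure
(planted communities); replicate values add independent normal residuals
scaled so $\sigma^2_g/(\sigma^2_g+\sigma^2_e)$ hits each feature's target
$H^2$; metabolite observations are multiplied by a lognormal
internal-standard value per chromatogram (so normalization must divide it
out, and division is always defined); enzyme observations receive additive
per-plate offsets (so plate standardization is consequential); missingness
is completely at random. Normality of the latents is a generator
convenience, not a pipeline assumption — the pipeline uses rank
correlations precisely because real panels violate normality.

Defaults emulate a maize inbred-panel leaf study: 101 lines, 5 replicates,
43 metabolites + 13 enzymes, 5.7% missing cells. Values the emulated design
does not fix were chosen once: 6 plates; a right-skewed target-$H^2$
spectrum `qbeta(ppoints(56), 2, 3)` (about three quarters below 0.5,
matching the skew such panels show); three planted blocks (9 enzymes + 3
metabolites at $r = 0.5$; 16 metabolites at 0.55; 8 metabolites at 0.6)
mirroring an enzyme-dominated community and two metabolite communities;
lognormal feature baselines with class-specific phenotypic CV (0.30
metabolites, 0.25 enzymes); plate offset SD at 10% of the median enzyme
baseline. The generator does not emulate GC-MS chromatography, retention
indices, enzyme kinetics, population genetic structure, or structured
(non-MCAR) missingness — the missingness mechanism in real data is unknown,
and MCAR is an explicit assumption. Passing tests on synthetic panels
therefore certify the statistical machinery, not robustness to instrument
artifacts or informative missingness.

## Numerical choices and degenerate inputs

* Constant features: flagged degenerate in variance-component fitting
  ($H^2$ missing, not zero) and excluded from correlation with a warning;
  a feature whose $\sigma^2_g$ estimate is zero has all-zero BLUPs and is
  likewise excluded downstream.
* Control values $\le 0$ or missing on metabolite records, missing plate
  ids, zero plate means, and fully missing features are hard errors naming
  the offending records.
* $H^2$ bins are $[0, 0.1), \ldots, [0.9, 1]$ — the top bin is closed so a
  heritability of exactly 1 is counted.
* Stability verdicts treat an empty network (property undefined) as
  unstable; a property that is constant across the grid is stable even when
  its mean is zero.
* All tie-breaks (merge targets, node orderings) are lexicographic or
  by explicit rule, so identical seeds give bit-identical outputs.

## Problem sizes used in the test suite

Unit tests run on panels of 10–101 lines and up to 24 features. The
end-to-end checks use: the full default panel (101 × 5, 56 features) for the
fixed-threshold track; all 1024 graphs on five labelled nodes plus 200
random 6–7-node graphs for the betweenness oracle; 10 panels of 100 lines ×
5 replicates × 50 features for heritability recovery; 50 stochastic
block-model draws (two 15-node blocks, edge probabilities 0.4 within / 0.02
between) for walktrap recovery plus 1000 rewired-null draws for test
calibration; 20 null panels for false-discovery control and 60 replicate
panels at 1000 permutations each for permutation-p validity.

## Known limitations

* The one-way REML model assumes a completely randomized design; block or
  spatial greenhouse effects are not modeled.
* Imputation assumes the line-level structure is approximately low-rank;
  with rank mismatched to the true structure its error grows (the tests use
  the matched rank on rank-1 planted panels).
* The community-significance test conditions on the detected partition;
  p-values are calibrated under the rewired null but are not corrected for
  the selection of communities by walktrap itself.
* Permutation p-values for discrete statistics are conservative near the
  top of their range; with the add-one rule they can never be zero.
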