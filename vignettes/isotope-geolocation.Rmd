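---
title: "Closed-population geolocation from hair and toenail stable isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-population geolocation from hair and toenail stable isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Stable hydrogen and oxygen isotope ratios in human keratinous tissues
(scalp hair, toenails) track the water a person drank while the tissue was
forming, and drinking-water isotopes vary geographically.  `isogeoloc`
implements a desk analysis for the *closed-population* version of the
forensic question: given individuals known to come from one of a small,
fixed set of sites, assign each individual to a site from the delta values
of their tissues alone.

Values are delta notation in per mil versus VSMOW,
$\delta = (R_{sample}/R_{standard} - 1) \times 1000$.  (The conventional
definition is the bare relative difference; we apply the $\times 1000$
scaling because every tissue and water value in this domain is reported in
per mil.)

The package covers four connected analyses:

1. **Tissue–water regression.** Simple OLS of tissue delta values on
   location-level drinking-water values, the Global Meteoric Water Line
   ($\delta^2H = 8\,\delta^{18}O + 10$) as a comparison line, and a fixed
   20-slot battery: tissue vs tissue, tissue vs tap/surface water, tissue
   vs OIPC-modeled precipitation, each water set repeated with the
   northernmost site excluded, plus paired hair-vs-toenail fits.
2. **Group comparison.** One-way MANOVA of the bivariate
   $(\delta^2H, \delta^{18}O)$ response across sites (Pillai trace as the
   multivariate gate, univariate F tests with df $(k-1, n-k)$ as the
   reported form), Tukey HSD post-hoc pairs, and Shapiro–Wilk-gated paired
   tests for hair-vs-toenail offsets within individuals.
3. **Outlier screening.** Squared Mahalanobis distance of each complete
   bivariate tissue measurement from the pooled mean, against a
   $\chi^2_2$ quantile.
4. **CART classification.** A from-scratch Gini-impurity decision tree:
   exhaustive midpoint threshold search, recursive binary partitioning,
   one-vs-rest confusion matrices and the five standard performance
   measures on an 80/20 holdout.

## The synthetic cohort: a stated world

The per-sample measurements behind the published four-site Canadian cohort
are not publicly released, so the package carries a generator that
reproduces the cohort's *printed summary structure* and makes every stage
testable:

* Four sites (Metro Vancouver; the Orillia area of Simcoe County; Iqaluit;
  the Wolfville area of the Annapolis Valley), per-site/per-tissue Gaussian
  distributions with the published means and standard deviations, e.g.
  hair $\delta^2H$ at Site 1: mean $-82.5$, sd $8.25$, $n = 23$.
* Sample counts 23/25/6/28 (hair) and 13/10/6/10 (toenail); one hair
  sample in Site 2 with $\delta^2H$ missing, so measurable hair
  $\delta^2H$ has $n = 81$.
* Paired individuals: toenail values drawn from the site marginals, hair =
  toenail + Gaussian offset ($13.0 \pm 8.4$ per mil for $\delta^2H$,
  $1.5 \pm 4.6$ for $\delta^{18}O$).  Deriving hair from toenail makes the
  paired-offset statistics exact by construction; the cost is that
  paired-derived hair marginals are wider than the published hair
  standard deviations (the printed hair/toenail/offset parameters are not
  mutually consistent — no generator can satisfy all three).  We keep the
  offsets exact and let the composite hair pool inherit the extra spread.
* An injectable literal outlier (`h2_analog()`: $\delta^2H = -58.3$,
  $\delta^{18}O = 6.4$) reproducing the published Mahalanobis-flagged hair
  sample.

What the generator does **not** emulate: within-site correlation between
the two isotopes (default 0; configurable — the source reports no per-site
correlations and the tissue-level coupling is weak, $R^2 \le 0.19$),
heavy tails, diet- or physiology-driven structure, and the true
sample-to-municipality assignment inside each site (unpublished; we cycle
samples round-robin over the site's reference locations).  A green test
therefore establishes that the *methods* behave correctly in this stated
world, not that the published per-sample numbers are reproduced.

## Water references

The packaged table (`water_references()`) carries the 18 published
locations with their drinking-water $\delta^2H$/$\delta^{18}O$ values and
provenance: measured tap water, surface water of the supplying body, or
OIPC-modeled precipitation.  OIPC values exist for only four locations
(Horseshoe Valley, Lafontaine, Midland, Iqaluit); the OIPC regression
slots therefore run on that subset via a tolerant join, and with Iqaluit
excluded the remaining OIPC $\delta^{18}O$ values are a single constant
($-11.1$), so those two slots fail with "degenerate predictor".  The
battery reports such failures per slot rather than aborting — this mirrors
the data's real information content rather than hiding it.

## Numerical and design choices

* **OLS**: closed-form normal equations; pairwise deletion per regression
  slot (each fit keeps its own realized $n$); two-sided slope t-test with
  $n-2$ df; $R^2$ defined as 0 for a constant response.  Water values are
  ecological regressors: constant within a location, one $(x, y)$ pair per
  sample, no aggregation.
* **Normality gate**: Shapiro–Wilk at $\alpha = 0.05$; a constant series
  is reported `non_normal` (a point mass is not Gaussian) rather than an
  error, so degenerate paired data route to the rank test.  Above the
  test's $n = 5000$ limit the gate sees a deterministic evenly-thinned
  subsample.
* **Paired tests**: differences are hair minus toenail; paired t when the
  gate passes, otherwise Wilcoxon signed-rank with zeros dropped, average
  ranks for ties, exact null below 20 usable pairs and the
  continuity-corrected normal approximation from 20 up.  All differences
  zero yields $p = 1$ (the signed-rank statistic is degenerate; there is
  no evidence of a shift).
* **Mahalanobis screen**: per tissue, pooled across sites, complete
  bivariate cases; cutoff $\chi^2_2(0.975)$ on the squared distance.  The
  source states neither pooling nor cutoff; both are the common
  convention and configurable.
* **MANOVA**: the published numbers are per-response univariate Fs, but
  they are labelled a MANOVA; we compute the Pillai trace as the
  multivariate gate *and* the univariate Fs, and report both.
* **CART**: candidate thresholds at midpoints of consecutive distinct
  sorted values; left branch takes values strictly below the threshold
  (equality routes right, matching the published "values less than"
  wording).  Equal-gain ties: earlier feature in the declared order wins,
  then the smaller threshold — with the model-3 feature order
  (toenail $\delta^2H$, toenail $\delta^{18}O$, hair $\delta^2H$, hair
  $\delta^{18}O$) this prefers toenail splits, consistent with the
  published model-3 behavior.  Leaf prediction is the argmax of class
  proportions with site-order tie-break.  Stopping defaults
  (`min_samples_split = 5`, `max_depth = 5`, `min_gini_gain = 0.01`) give
  shallow trees appropriate to cohorts of 32–65 training rows; there is no
  cost-complexity pruning.  The published impurity formula's caption
  defines $p$ as a misclassification proportion; the formula as written
  requires class proportions $p_i$, which is what we implement.
* **Holdout**: train size $\lceil 0.8 n \rceil$ — the only rounding rule
  that reproduces all three published size pairs (65/16, 32/7, 28/7);
  simple (not stratified) random sampling; calls use the 0.5
  proportion threshold with argmax fallback (the source states no
  fallback; one is required whenever no class clears 0.5).  Overall
  accuracy is the correct-call fraction — the published 71.4% is $5/7$,
  reachable only on that definition.  Note that with one call per row and
  four one-vs-rest matrices, $\Sigma TP + \Sigma TN = 4c + 2(n-c)$ for $c$
  correct calls, *not* $4n \cdot \text{accuracy}$.
* **Chance level**: with class priors $13/10/6/10$ of 39, the chance
  agreement of a prior-following classifier on exchangeable labels is
  $\sum_c p_c^2 = 0.266$, slightly above the uniform $1/4$; the
  acceptance test uses this value.
* **Seeds**: every stochastic operation takes an explicit integer seed and
  restores the caller's RNG state (`withr::local_seed`), so module order
  cannot change draws.

## Known limitations

* The published regression coefficients, F statistics and the single
  71.4% holdout accuracy were computed on the unreleased per-sample data;
  at desk scale they are recoverable only as distributional targets
  (median split thresholds, calibrated offsets), not bit-for-bit.
* Model-1 (hair) trees recover the published root threshold near $-82$
  per mil, but the published deeper hair-tree structure is not fully
  reconstructable from the text (one printed branch value even has an
  impossible sign, $\ge 76$ per mil where $-76$ is meant), so only the
  root is treated as an anchor.
* OIPC regressions with Iqaluit excluded are structurally degenerate
  given the published water table (see above).
* No spatial interpolation/isoscape construction, no live OIPC queries,
  no surrogate splits or ensembles, no cross-validation.
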