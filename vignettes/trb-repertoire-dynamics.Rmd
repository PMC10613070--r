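---
title: "Modelling age- and sex-specific TRB repertoire dynamics with trbdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling age- and sex-specific TRB repertoire dynamics with trbdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trbdiv)
```

## The scientific problem

V(D)J recombination assembles the T-cell receptor β-chain (TRB) locus from
variable, diversity and joining gene segments. Because junctional processing
is essentially random, roughly one in three rearrangements keeps an open
reading frame through the CDR3 ("productive"); peripheral T cells therefore
carry either one productive rearrangement with the second allele in germ-line
configuration, or one productive plus one non-productive rearrangement.
High-throughput TRB sequencing of blood gives, per donor, a table of unique
rearranged nucleotide sequences with template copy counts — a *repertoire* —
from which two evenness summaries can be computed:

* **Status Diversity** — evenness of the split of *copies* between productive
  and non-productive rearrangements (a two-class scheme). A decline means
  productive copies dominate more, i.e. cells that succeeded at their first
  rearrangement attempt have expanded preferentially.
* **Sequence Diversity** — evenness of the clone-size distribution
  (one class per unique nucleotide sequence, restricted by convention to
  productive clones). A decline means a more clonal repertoire.

`trbdiv` implements the full analysis chain around these two indices:
reading immunoSEQ-style and AIRR rearrangement tables, curation, evenness
estimation with finite-sample bias correction, depth subsampling and CD4/CD8
"whole-blood reconstitution", cross-sectional weighted and piecewise
regression against age and sex, and longitudinal linear mixed-effects models
— plus a synthetic-data generator with the same statistical structure, so
the whole chain is testable without any external download.

## Evenness with entropy bias correction

For class counts $n_1,\dots,n_S$ with $N=\sum_i n_i$ and $p_i=n_i/N$,

$$H \;=\; -\sum_{i=1}^{S} p_i \ln p_i \;-\; \frac{S-1}{2N}, \qquad
J \;=\; \frac{H}{\ln S},$$

the second term of $H$ being the first-order (Miller–Madow/Basharin) bias
correction of the plug-in entropy estimator. $J$ ("Pielou's evenness") lives
in $[0,1]$: 0 when one class dominates, 1 when all classes are even. The
correction matters because shallow sequencing inflates the *uncorrected*
index; with it, the index is stable across a wide range of coverages (see
the depth study below).

Numerical conventions, all covered by tests:

* zero-count classes contribute $0$ to the sum ($0\ln 0 = 0$) but still
  count in $S$ when the scheme fixes it (the status scheme always has
  $S=2$); for the sequence scheme $S$ is the observed clone count — no
  unseen-species correction is attempted, matching the normalization by
  observed classes;
* the correction can push near-degenerate cases below 0, so $H$ and $J$ are
  clamped at 0 (and $J$ at 1); the raw value is kept in an attribute for
  diagnostics;
* natural logarithms throughout.

## Curation

Sample-level filters: samples without donor age or sex are dropped, then
outlying total copy counts are screened with a generalized boxplot for
skewed, heavy-tailed data — a Tukey g-and-h distribution is quantile-matched
to the bulk of the counts (median anchor; asymmetry parameter $g$ from the
75th–90th percentile band; $B$ and $h$ from the log half-spread regressed on
normal-quantile curvature) and fences are placed at its $\alpha/2$ and
$1-\alpha/2$ quantiles. The default $\alpha = 0.007$ matches the nominal
outside-fence coverage of the classical 1.5-IQR boxplot on Gaussian data, so
on symmetric data the screen reduces to the familiar rule; the parameter and
one- versus two-sidedness are configurable because no single convention is
canonical for this screen.

Sequence-level filters run in a fixed order, each record attributed to the
*first* rule it violates, so that reports are comparable across datasets:
orphon V call; unresolved V; unresolved J; indexing error (the annotated
non-templated N2 region starting before the CDR3 start — records missing
either annotation are *not* counted, since the rule compares two annotated
positions); V or J gene outside the functional set; and the excluded gene
TRBV03-01 (extremely rare and absent from many samples, hence removed
outright — no other gene is excluded for rarity; per-sample gene presence is
reported instead via `gene_presence()`). Copy counts are conserved exactly:
input = retained + sum of per-filter removals, a property the tests assert on
every generated repertoire. After filtering, records sharing one nucleotide
sequence are collapsed into clones with summed counts; every diversity
denominator thereafter is copy-weighted.

The bundled gene list (`inst/extdata/trb_gene_reference_synthetic.json`) is
a *constructed synthetic snapshot* — 43 functional V (42 usable after the
exclusion), 13 J, 2 D, and an orphon set — shaped like an IMGT-derived
functionality table but not copied from one; production analyses should
supply their own snapshot via `load_gene_reference(path)`.

## Subsampling and whole-blood reconstitution

`subsample_to_depth()` draws exactly the requested number of copies *without
replacement* from the observed pool (multivariate hypergeometric over
clones, implemented in C for repertoires with $10^5$–$10^6$ clones).
Without-replacement semantics make full-depth subsampling the identity and
never inflate a clone's count — both asserted in tests. `depth_profile()`
repeats this over a coverage grid (the study grid is 10^4^, 8×10^4^,
1.5×10^5^, 5×10^5^, 1, 2 and 4 million copies), 100 replicates per depth,
averaging both indices; depths beyond a sample's total are skipped and
recorded.

Sorted CD4/CD8 repertoires are merged into a "reconstituted" whole-blood
sample driven by the measured blood CD4/CD8 ratio $r$: the target CD4 copy
fraction is $r/(1+r)$; whichever compartment is overrepresented relative to
that is subsampled (draw $\mathrm{round}(r\,n_{CD8})$ from CD4, or
$\mathrm{round}(n_{CD4}/r)$ from CD8 — round-half-to-even, unbiased over
ratios), the other kept whole; the merged table is re-curated and collapsed;
and the procedure is repeated 100 times with the replicate *mean* of each
index as the final estimate. One master seed spawns recorded per-replicate
streams, so every replicate is bit-reproducible.

## Cross-sectional models

Diversity is regressed on age by weighted least squares with per-sample
total copy counts as weights — deeper samples carry more information, i.e.
residual variance is taken inversely proportional to coverage. The starting
model is `diversity ~ age + sex + age:sex` (male reference) and terms are
removed backward by BIC, respecting hierarchy, until no removal lowers the
criterion. The overall F-test p (full model against intercept-only) and the
plain unweighted Pearson correlation between age and the response are
reported alongside; since the F-test convention is not uniquely determined
for sex-containing models, per-coefficient t-tests are available from
`summary()` as well.

Two numerical choices deserve a note:

* **BIC weight convention.** The Gaussian log-likelihood of a weighted fit
  contains $\tfrac12\sum_i \log w_i$. Weights are normalized to mean 1
  *once, at the cohort level*, before any split search: normalizing within
  each subgroup instead would make that term depend on which samples land in
  which subgroup, adding pure noise to the split criterion. Cohort-level
  normalization keeps BIC magnitudes scale-stable and comparable across
  splits while leaving coefficients, standard errors and F-tests untouched.
* **Piecewise search.** Every age split is tried (brute force), the younger
  group containing ages $\le$ the split; both subgroups must keep at least 5
  donors (the smallest group size for which a regression model is taken
  seriously); within each subgroup the model is re-selected by backward BIC;
  the best split minimizes the *sum* of the two selected BICs, with ties
  broken toward the youngest split age (configurable tie policy,
  deterministic either way). The tests re-implement the scan independently
  with `stats::lm` + `stats::BIC` and require identical argmins.

Slope equality between two fitted groups is tested with
$t = (\hat\beta_a - \hat\beta_b)/\sqrt{SE_a^2+SE_b^2}$ and
Welch–Satterthwaite degrees of freedom from the two residual dfs (the df
convention is not canonical; Welch is the conservative default).

## Longitudinal models

Repeated measures (6 donors, 3 visits ~10 years apart, sorted CD4/CD8)
are modelled with linear mixed effects: fixed age, sex and their interaction
(plus cell type and age:celltype for sorted analyses), random intercepts for
donor and — for sorted analyses — donor-by-cell-type, fitted by **maximum
likelihood** rather than REML because backward selection compares nested
*fixed* structures by likelihood-ratio tests (removal threshold
$\alpha = 0.05$, configurable; the random structure is held fixed).
Intraclass correlations are variance shares: each grouping's component over
the total (all components + residual), so the shares plus the residual share
sum to 1.

"Initial" diversity for donor $i$ is the model intercept at age 0:
$\beta_0 + \beta_{sex}\,[\text{female}] + u_i$ (plus the donor's CD8 offset
for cell-type models); group summaries report the mean and $n-1$ standard
deviation of these per-donor intercepts, and group slopes are
$\beta_{age} + \beta_{age:sex}[\text{female}] + \beta_{age:ct}[\text{CD8}]$.
These summary operations are **pure functions of a coefficient surface**
(`mixed_coefs()`), so a published coefficient table can be fed through them
directly, without refitting — that is exactly what `scripts/acceptance.R`
does. Per-donor offsets extracted from a fit are the conditional-mode
(predicted) random intercepts, which are shrunken toward zero; with 3
observations per donor and small residual variance the shrinkage is mild,
and the tests bound it explicitly.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
*assumes*, which is what makes parameter-recovery testing meaningful:

* **Cohort shape.** 487 donors, integer ages uniform on 1–74, 47% female,
  per-sample depth log-uniform over 5×10^5^–8×10^6^ copies — the observed
  post-curation coverage range.
* **Status evenness** is parameterized on the $J$ scale (the modelled
  quantity) and converted to a productive copy fraction by numerically
  inverting the two-class corrected entropy (bisection, tolerance 10^-10^);
  the realized productive count is binomial around that fraction.
* **Clone sizes** follow a discretized power law, $p_i \propto i^{-s}$ over
  $K$ clones ($K$ = depth/4 by default, i.e. mean clone size 4). The default
  exponent 0.65 gives full-depth Sequence Diversity ≈ 0.93, mid-range of the
  observed adult values (≈0.89–0.97); per-sample exponents are obtained by
  inverting the target $J$ through the expected power-law evenness.
* **Noise** on the diversity scale has variance proportional to
  1/normalized-coverage — precisely the heteroskedasticity the weighted
  regression assumes — with `sigma_status = 0.03` chosen so that the
  young-segment age correlation lands near the observed −0.6, and
  `sigma_sequence = 0.02` on the same calibration logic.
* **Breakpoints** are embedded segment-wise: each side of the split has its
  own intercept and slope (defaults 0.6817 − 0.0060·age before 18 and
  0.6227 − 0.0003·age after), matching the fitted young/old models, which do
  not meet at the split. A continuous kink would make ±1-year split
  localization impossible at realistic noise; the discontinuous pattern is
  what the two-submodel search actually estimates.
* **Longitudinal designs** embed the mixed-model coefficient surfaces
  directly, with Gaussian donor intercepts (SD 0.05), per-donor CD8 offsets
  (SD 0.04) and residual SD 0.005, first visits at ages 24–45 so all ages
  stay within 24–65.

By default the generators return the per-sample *diversity table* — the
sufficient input for every modelling stage — because recovery studies fit
thousands of cohorts and materializing millions of rearrangement records for
each would add nothing. With `records = TRUE` they materialize full
rearrangement tables (unique per-sample nucleotide sequences, valid gene
calls and annotations, and optional curation-violating records injected at
chosen copy-share rates) so the I/O, curation and resampling stages are
exercised end to end on smaller problems.

What the generator does **not** emulate: biophysically realistic V(D)J
junction sequences, clone sharing between donors, V/J usage biases, and any
dependence of clone-size shape on depth beyond the power-law family. Passing
recovery tests therefore demonstrate that the estimators are correct and
calibrated *under the model's assumptions*, not that those assumptions hold
for any particular real dataset.

## Problem sizes and numerical tolerances used by the test suite

The suite checks the evenness formulas against independent direct evaluation
on 1000 random count vectors at 10^-10^; runs curation conservation
exactly (integer identity) with injected violation shares checked at 3
binomial standard errors; verifies merge fractions within 1/min(n) of
$r/(1+r)$ over randomized inputs; measures corrected Sequence Diversity
drift below 0.01 across the 10^4^–5×10^5^ coverage grid on the default
repertoire (100 replicates per depth, ≈1 minute); recovers the embedded
age-18 breakpoint within ±1 year in ≥95% of 200 cohorts of n = 480 with the
search output equal to the independent exhaustive oracle on every run
(≈7 minutes, the dominant cost); and checks mixed-model CI coverage and
LRT selection behaviour over 200 replicates of the 6 × 3 design. These sizes
keep the default run complete on a single CPU while leaving each stochastic
assertion at least 3 simulation standard errors of headroom.

## Known limitations

* The outlier screen's fence parameters are a reconstruction of the cited
  generalized-boxplot method's defaults, not a byte-level port; both the
  tail probability and sidedness are exposed.
* The expected-count formula for CD4/CD8 merging (rounding convention
  included) is the ratio-consistent reconstruction; the merged CD4 fraction
  property, not a specific reference implementation, is the contract.
* `expected_sequence_J()` approximates the observed class count by the clone
  count $K$, accurate when depth ≫ $K$; at depth close to $K$ the realized
  evenness sits slightly below the target, which the recovery tests absorb
  in their tolerances.
* Cross-sectional coefficient *values* from the public 587-donor cohort and
  the longitudinal ICC percentages are functions of external raw data; the
  package validates the machinery on synthetic cohorts and reproduces the
  published longitudinal summary arithmetic instead.

## A minimal worked run

```{r example, eval = FALSE}
library(trbdiv)

# cross-sectional: synthesize, model, inspect
co <- simulate_cohort(cohort_params(
  n_donors = 480,
  breakpoint = list(age = 18, young = c(0.6817, -0.0060),
                    old = c(0.6227, -0.0003), response = "status_J")),
  seed = 1)
out <- run_cross_sectional(co$samples)
out$tables$status_J

# longitudinal: reconstitute and fit
lg <- simulate_longitudinal(seed = 1)
fit <- lrt_backward_select(lg$merged, "status_J")$fit
summarize_initial_diversity(fit, "female")
slope_for_group(fit, "female")
```
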