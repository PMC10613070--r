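# trbdiv — age- and sex-specific dynamics of TRB repertoire diversity

`trbdiv` is an R package for analysing rearranged T-cell receptor β-chain
(TRB) repertoires — the tables of unique V(D)J nucleotide sequences with
template copy counts produced by immunoSEQ-style or AIRR-standard
sequencing of blood T cells. It is aimed at immunologists and statisticians
studying how the repertoire reshapes with age, and at anyone who needs a
tested, reproducible implementation of the evenness-based analysis chain:
curation → diversity estimation → depth subsampling / CD4-CD8
reconstitution → cross-sectional and longitudinal modelling.

## The statistic at the core

For class counts $n_1,\dots,n_S$ with $N = \sum_i n_i$, $p_i = n_i/N$:

$$H = -\sum_{i=1}^S p_i \ln p_i - \frac{S-1}{2N}, \qquad J = \frac{H}{\ln S}$$

— Shannon entropy with the first-order (Basharin) finite-sample bias
correction, normalized to Pielou's evenness $J \in [0,1]$. Two class schemes
carry the biology:

* **Status Diversity** ($S = 2$): evenness of copies between productive and
  non-productive rearrangements. Lower values mean productive copies
  dominate more — T cells that rearranged successfully on the first attempt
  have expanded preferentially.
* **Sequence Diversity** ($S$ = number of clones): evenness of the
  clone-size distribution over productive clones. Lower values mean a more
  clonal repertoire.

Both indices are modelled against age and sex: cross-sectionally by
weighted linear regression (per-sample total copies as weights) with
BIC-backward term selection and a brute-force piecewise split search, and
longitudinally by ML-fitted linear mixed models with donor (and
donor-by-cell-type) random intercepts, likelihood-ratio backward selection,
and intraclass correlations.

## Worked example

```r
library(trbdiv)

## one synthetic repertoire at sequencing scale
rep <- simulate_repertoire(depth = 1e6, productive_fraction = 0.85, seed = 1)
status_diversity(rep)
#> Status diversity: J = 0.609800 (H = 0.422681 nats, S = 2, N = 1e+06)
sequence_diversity(rep)
#> Sequence diversity: J = 0.929141 (H = 11.289820 nats, S = 189247, N = 850,016)
```

`J = 0.6098` says productive copies strongly outweigh non-productive ones
(≈85/15); `J = 0.9291` says the million copies spread rather evenly over
≈190k productive clones.

```r
## cross-sectional cohort with an embedded age-18 breakpoint in status
## diversity (young slope -0.0060/yr, flat thereafter), n = 480
co <- simulate_cohort(cohort_params(
  n_donors = 480,
  breakpoint = list(age = 18, young = c(0.6817, -0.0060),
                    old = c(0.6227, -0.0003), response = "status_J")),
  seed = 1)
piecewise_search(co$samples, "status_J")
#> Piecewise weighted regression of status_J: best split at age 18
#>   younger (n = 104): status_J ~ age
#>   older   (n = 376): status_J ~ 1
#>   BIC sum = -1813.17 over 73 candidate splits
```

The brute-force scan recovers the embedded break exactly: a declining young
segment up to age 18, then a flat adult segment.

```r
## longitudinal design: 3 men + 3 women, 3 visits ~10 years apart
lg <- simulate_longitudinal(seed = 1)
fit <- lrt_backward_select(lg$merged, "status_J")$fit
summarize_initial_diversity(fit, "female")   # mean 0.7168, sd 0.0614 (n = 3)
slope_for_group(fit, "female")               # -0.0007 per year
slope_for_group(fit, "male")                 #  0.0000 per year
icc(fit, "donor")                            #  0.983
```

The fitted surface recovers the embedded pattern: initial status diversity
higher in women, declining ≈0.0007 per year in women and flat in men, with
nearly all remaining variance attributable to stable donor differences.

Real data enter through `read_manifest()` + `load_cohort()` (immunoSEQ or
AIRR TSV dialects, configurable column maps), then `curate_cohort()`,
`cohort_diversity()` and the same modelling calls; `run_cross_sectional()`
and `run_longitudinal()` chain the stages from a single entry point.

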