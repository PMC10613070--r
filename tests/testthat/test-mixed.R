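table5_status <- function() {
  mixed_coefs(beta0 = 0.5823, beta_age = 0.0004, beta_sex = 0.0829,
              beta_age_sex = -0.0011,
              donor_offset = c(M1 = -0.0547, M2 = 0.0569, M3 = -0.0022,
                               F1 = 0.0123, F2 = -0.0044, F3 = -0.0080),
              donor_sex = c(M1 = "male", M2 = "male", M3 = "male",
                            F1 = "female", F2 = "female", F3 = "female"))
}

test_that("initial-diversity summaries are pure arithmetic over the coefficient surface", {
  cc <- table5_status()
  men <- summarize_initial_diversity(cc, "male")
  expect_equal(men$intercepts,
               0.5823 + c(M1 = -0.0547, M2 = 0.0569, M3 = -0.0022))
  expect_equal(round(men$mean, 4), 0.5823)
  expect_equal(round(men$sd, 4), 0.0558)
  women <- summarize_initial_diversity(cc, "female")
  expect_equal(round(women$mean, 4), 0.6652)
  expect_equal(round(women$sd, 4), 0.0108)
  expect_equal(round(slope_for_group(cc, "male"), 4), 0.0004)
  expect_equal(round(slope_for_group(cc, "female"), 4), -0.0007)
  expect_error(summarize_initial_diversity(cc, "male", "CD8"), "cell-type")
})

test_that("cell-type offsets shift per-donor intercepts and slopes as coded", {
  cc <- mixed_coefs(beta0 = 0.9, beta_age = 0.001, beta_sex = -0.01,
                    beta_age_sex = -0.0005, beta_age_celltype = -0.004,
                    donor_offset = c(A = 0.02, B = -0.02, C = 0.01,
                                     D = -0.01),
                    celltype_offset = c(A = 0.05, B = 0.03, C = -0.04,
                                        D = -0.02),
                    donor_sex = c(A = "male", B = "male", C = "female",
                                  D = "female"))
  cd4 <- summarize_initial_diversity(cc, "male", "CD4")
  cd8 <- summarize_initial_diversity(cc, "male", "CD8")
  expect_equal(cd8$intercepts - cd4$intercepts, c(A = 0.05, B = 0.03))
  expect_equal(slope_for_group(cc, "female", "CD8"),
               0.001 - 0.0005 - 0.004)
  expect_equal(slope_for_group(cc, "female", "CD4"), 0.001 - 0.0005)
})

test_that("ICC is the variance share of a grouping", {
  fit <- structure(list(varcomp = c(donor = 3, residual = 1)),
                   class = "div_lmm")
  expect_equal(icc(fit, "donor"), 0.75)
  fit2 <- structure(list(varcomp = c(donor = 8, donor_celltype = 3,
                                     residual = 1)), class = "div_lmm")
  expect_equal(icc(fit2, "donor"), 8 / 12)
  expect_equal(icc(fit2, "donor_celltype"), 3 / 12)
  expect_equal(icc(structure(list(varcomp = c(donor = 0, residual = 2)),
                             class = "div_lmm"), "donor"), 0)
  expect_error(icc(fit, "celltype"), "grouping")
})

test_that("near-noiseless donor structure yields ICC near 1 and recovered fixed effects", {
  set.seed(31)
  lg <- simulate_longitudinal(longitudinal_params(donor_sd = 0.05,
                                                  resid_sd = 1e-4),
                              seed = 31)
  fit <- quiet(fit_lmm(lg$merged, "status_J"))
  expect_gt(icc(fit, "donor"), 0.99)
  expect_equal(unname(fit$coefficients["age"]), 0.0004, tolerance = 0.15)
  # ICC shares over all groupings sum to at most 1
  expect_lte(sum(fit$icc), 1)
})

test_that("fixed effects of the embedded design are recovered within their confidence intervals", {
  hits <- 0L
  for (s in 1:20) {
    lg <- simulate_longitudinal(seed = 400 + s)
    fit <- quiet(fit_lmm(lg$merged, "status_J"))
    ci <- confint(fit)["age", ]
    hits <- hits + (0.0004 >= ci[1] && 0.0004 <= ci[2])
  }
  expect_gte(hits, 16L)
})

test_that("LRT backward selection keeps strong interactions and strips null terms", {
  # opposite-sign slope pattern: interaction retained
  set.seed(32)
  lg <- simulate_longitudinal(longitudinal_params(
    status = list(beta0 = 0.58, beta_age = 0.004, beta_sex = 0.08,
                  beta_age_sex = -0.011), resid_sd = 0.005), seed = 32)
  sel <- quiet(lrt_backward_select(lg$merged, "status_J"))
  expect_true("age:sex" %in% sel$fixed)
  # common slope with a sex offset: interaction dropped, sex retained
  # donor spread set to the scale of the printed sequence offsets (~0.02)
  # so the sex contrast is identifiable from 3 donors per sex
  lg2 <- simulate_longitudinal(longitudinal_params(
    sequence = list(beta0 = 0.9597, beta_age = -0.0008, beta_sex = -0.0698,
                    beta_age_sex = 0), donor_sd = 0.02), seed = 33)
  sel2 <- quiet(lrt_backward_select(lg2$merged, "sequence_J"))
  expect_false("age:sex" %in% sel2$fixed)
  expect_true("sex" %in% sel2$fixed)
  # no signal at all: only the intercept and random structure remain
  lg3 <- simulate_longitudinal(longitudinal_params(
    status = list(beta0 = 0.6, beta_age = 0, beta_sex = 0, beta_age_sex = 0),
    donor_sd = 0.02, resid_sd = 0.01), seed = 37)
  sel3 <- quiet(lrt_backward_select(lg3$merged, "status_J"))
  expect_length(sel3$fixed, 0L)
})

test_that("coefficient surfaces extracted from fits reproduce group summaries", {
  set.seed(35)
  lg <- simulate_longitudinal(seed = 35)
  fit <- quiet(fit_lmm(lg$merged, "status_J"))
  cc <- as_mixed_coefs(fit)
  sm <- summarize_initial_diversity(cc, "female")
  # per-donor intercepts mirror the embedded donor draws (shrinkage-limited)
  truth <- 0.5823 + 0.0829 + lg$truth$b4_status[c("F1", "F2", "F3")]
  expect_equal(unname(sm$intercepts), unname(truth), tolerance = 0.06)
  expect_equal(sm$n, 3L)
  # slopes are linear combinations of the fitted fixed effects
  expect_equal(slope_for_group(cc, "female"),
               unname(fit$coefficients["age"] +
                        fit$coefficients["age:sexfemale"]))
})

test_that("cell-type models fit with both random groupings and expose CD8 offsets", {
  set.seed(36)
  lg <- simulate_longitudinal(seed = 36)
  fit <- suppressWarnings(
    fit_lmm(lg$celltype, "sequence_J",
            fixed = c("age", "sex", "age:sex", "celltype", "age:celltype"),
            random = c("donor", "donor_celltype")))
  expect_setequal(names(fit$icc), c("donor", "donor_celltype"))
  cc <- as_mixed_coefs(fit)
  expect_false(is.null(cc$celltype_offset))
  # embedded CD8 age decline (beta_age_celltype = -0.0037) is recovered
  expect_lt(abs(slope_for_group(cc, "male", "CD8") -
                  slope_for_group(cc, "male", "CD4") - (-0.0037)), 0.0012)
})
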