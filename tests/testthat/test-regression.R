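make_cohort_df <- function(n = 40, seed = 1, slope = -0.001, intercept = 0.9,
                           noise = 0) {
  set.seed(seed)
  age <- sample(1:74, n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  data.frame(age = age, sex = sex,
             status_J = intercept + slope * age + rnorm(n, 0, noise),
             total_copies = exp(runif(n, log(5e5), log(8e6))))
}

test_that("exact linear data is interpolated with zero residuals", {
  d <- make_cohort_df(n = 30, slope = -0.001, intercept = 0.9)
  fit <- suppressWarnings(weighted_fit(status_J ~ age, d))
  expect_equal(unname(coef(fit)["age"]), -0.001, tolerance = 1e-10)
  expect_equal(unname(coef(fit)["(Intercept)"]), 0.9, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("equal weights coincide with the closed-form OLS solution", {
  d <- data.frame(age = c(1, 5, 9, 13, 20),
                  sex = "male",
                  status_J = c(0.91, 0.88, 0.90, 0.84, 0.86),
                  total_copies = rep(1e6, 5))
  fit <- weighted_fit(status_J ~ age, d)
  X <- cbind(1, d$age)
  beta <- oracle_wls(X, d$status_J, rep(1, 5))
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-10)
})

test_that("a sample at weight w equals two half-weight copies", {
  d <- make_cohort_df(n = 12, noise = 0.02, seed = 2)
  dup <- rbind(d, d[3, ]); dup$total_copies[c(3, 13)] <- d$total_copies[3] / 2
  f1 <- weighted_fit(status_J ~ age, d)
  f2 <- weighted_fit(status_J ~ age, dup, normalize_weights = FALSE,
                     weights = dup$total_copies)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("singular designs raise an error naming the collinear term", {
  d <- make_cohort_df(n = 20, noise = 0.01, seed = 3)
  d$sex <- "male"
  expect_error(weighted_fit(status_J ~ age * sex, d), "sexfemale")
})

test_that("fit reports overall F-test p, unweighted r and a BIC matching stats::BIC", {
  d <- make_cohort_df(n = 50, noise = 0.02, seed = 4)
  fit <- weighted_fit(status_J ~ age, d)
  expect_equal(fit$r, cor(d$age, d$status_J))
  w <- d$total_copies / mean(d$total_copies)
  ref <- lm(status_J ~ age, data = d, weights = w)
  expect_equal(fit$bic, BIC(ref), tolerance = 1e-9)
  expect_equal(fit$model_p,
               anova(lm(status_J ~ 1, data = d, weights = w), ref)$`Pr(>F)`[2],
               tolerance = 1e-9)
  # fast-path BIC equals stats::BIC for every submodel
  X <- trbdiv:::.design_matrix(d)
  for (tt in list("age", c("age", "sex"), c("age", "sex", "age:sex"))) {
    cols <- unlist(trbdiv:::.term_columns[c("(Intercept)", tt)])
    got <- trbdiv:::.wls_bic(X[, cols, drop = FALSE], d$status_J, w)
    want <- BIC(lm(reformulate(tt, "status_J"),
                   data = transform(d, sex = factor(sex,
                                                    c("male", "female"))),
                   weights = w))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("backward BIC selection matches the lm-based oracle and honours hierarchy", {
  set.seed(5)
  # strong age effect only
  d <- make_cohort_df(n = 150, slope = -0.004, noise = 0.01, seed = 5)
  sel <- bic_backward_select(d, "status_J")
  expect_equal(sort(sel$terms), "age")
  # pure noise: intercept-only, and agreement with the oracle
  for (s in 1:5) {
    d0 <- make_cohort_df(n = 60, slope = 0, noise = 0.03, seed = 100 + s)
    sel0 <- bic_backward_select(d0, "status_J")
    ora <- oracle_backward(d0, "status_J",
                           d0$total_copies / mean(d0$total_copies))
    expect_setequal(sel0$terms, ora$terms)
    expect_equal(sel0$bic, ora$bic, tolerance = 1e-8)
  }
  # an embedded interaction keeps its main effects
  set.seed(6)
  d2 <- make_cohort_df(n = 200, noise = 0.005, seed = 6)
  d2$status_J <- 0.9 - 0.002 * d2$age +
    ifelse(d2$sex == "female", 0.004 * d2$age, 0) + rnorm(200, 0, 0.005)
  sel2 <- bic_backward_select(d2, "status_J")
  expect_true("age:sex" %in% sel2$terms)
  expect_true(all(c("age", "sex") %in% sel2$terms))
})

test_that("piecewise search equals the exhaustive lm-based scan and honours min_group", {
  d <- breakpoint_cohort(n = 200, seed = 7)
  ps <- piecewise_search(d, "status_J")
  ora <- oracle_piecewise(d, "status_J")
  expect_equal(ps$split_age, ora$split)
  expect_equal(ps$bic_sum, ora$bic, tolerance = 1e-8)
  expect_true(all(ps$trace$n_young >= 5 & ps$trace$n_old >= 5))
  # min_group is honoured for any requested size
  ps8 <- piecewise_search(d, "status_J", min_group = 20L)
  expect_true(all(ps8$trace$n_young >= 20 & ps8$trace$n_old >= 20))
  expect_error(piecewise_search(d[1:8, ], "status_J", min_group = 5L),
               "no feasible split")
})

test_that("slope comparison: identity, separation, and null calibration", {
  d <- make_cohort_df(n = 60, noise = 0.02, seed = 8)
  f <- weighted_fit(status_J ~ age, d)
  same <- compare_slopes(f, f)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # slopes 10+ SE apart are overwhelmingly significant
  d2 <- make_cohort_df(n = 60, slope = -0.001, noise = 0.001, seed = 9)
  d3 <- make_cohort_df(n = 60, slope = -0.005, noise = 0.001, seed = 10)
  far <- compare_slopes(weighted_fit(status_J ~ age, d2),
                        weighted_fit(status_J ~ age, d3))
  expect_lt(far$p, 1e-6)
  expect_error(compare_slopes(weighted_fit(status_J ~ 1, d), f), "age")
  # under equal slopes the p-value is approximately uniform
  set.seed(11)
  ps <- replicate(400, {
    da <- data.frame(age = sample(1:74, 30, TRUE), sex = "male",
                     total_copies = 1e6)
    db <- data.frame(age = sample(1:74, 30, TRUE), sex = "male",
                     total_copies = 1e6)
    da$status_J <- 0.9 - 0.001 * da$age + rnorm(30, 0, 0.02)
    db$status_J <- 0.9 - 0.001 * db$age + rnorm(30, 0, 0.02)
    compare_slopes(weighted_fit(status_J ~ age, da),
                   weighted_fit(status_J ~ age, db))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})
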