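#' Linear mixed-effects model for longitudinal diversity
#'
#' Fits diversity against age and sex (and optionally cell type) with random
#' intercepts for donors and, when requested, for donor-by-cell-type, by
#' maximum likelihood (ML rather than REML, so that likelihood-ratio tests
#' between fixed-effect structures are valid). References: male sex, CD4
#' cells.
#'
#' @param data longitudinal diversity table with columns `donor_id`, `age`,
#'   `sex`, the response, and `celltype` when cell-type terms are used.
#' @param response response column name (`"status_J"` or `"sequence_J"`).
#' @param fixed fixed-effect terms, subset of
#'   `c("age", "sex", "age:sex", "celltype", "age:celltype")`.
#' @param random random-intercept groupings, subset of
#'   `c("donor", "donor_celltype")` (at least one).
#' @return Object of class `div_lmm`: the `lmerMod` fit plus extracted fixed
#'   effects with standard errors and Satterthwaite degrees of freedom,
#'   variance components, per-grouping intraclass correlation coefficients,
#'   and predicted random intercepts. Supports `print`, `coef`, `summary`,
#'   `predict`, `residuals`, `confint`.
#' @export
fit_lmm <- function(data, response = "status_J",
                    fixed = c("age", "sex", "age:sex"),
                    random = "donor") {
  data <- as.data.frame(data)
  stopifnot(length(random) >= 1L)
  if (!is.factor(data$sex)) data$sex <- factor(data$sex,
                                               levels = c("male", "female"))
  if ("celltype" %in% names(data) && !is.factor(data$celltype))
    data$celltype <- factor(data$celltype, levels = c("CD4", "CD8"))
  if (length(unique(data$donor_id[data$sex == "male"])) < 2L ||
      length(unique(data$donor_id[data$sex == "female"])) < 2L)
    if ("sex" %in% fixed) stop("need at least 2 donors per sex")
  rterms <- c(donor = "(1 | donor_id)",
              donor_celltype = "(1 | donor_id:celltype)")[random]
  fstr <- paste(response, "~",
                paste(c(if (length(fixed)) fixed else "1", rterms),
                      collapse = " + "))
  fit <- lmerTest::lmer(as.formula(fstr), data = data, REML = FALSE)
  if (isSingular(fit))
    warning("singular random-effects fit: a variance component is pinned at 0")
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  vars <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                   ifelse(vc$grp == "donor_id", "donor",
                                          "donor_celltype")))
  iccs <- vars[setdiff(names(vars), "residual")] / sum(vars)
  structure(list(lmer = fit, response = response, fixed = fixed,
                 random = random, formula = fstr,
                 coefficients = co[, "Estimate"],
                 se = co[, "Std. Error"], df = co[, "df"],
                 varcomp = vars, icc = iccs,
                 ranef = lme4::ranef(fit),
                 logLik = as.numeric(logLik(fit)),
                 data = data),
            class = "div_lmm")
}

#' @importFrom lme4 isSingular
NULL

#' @export
print.div_lmm <- function(x, digits = 4, ...) {
  cat("Linear mixed model (ML):", x$formula, "\n")
  print(round(x$coefficients, digits))
  cat("variance components:\n")
  print(signif(x$varcomp, 4))
  cat("ICC:", paste(sprintf("%s = %.3f", names(x$icc), x$icc),
                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.div_lmm <- function(object, ...) object$coefficients

#' @export
summary.div_lmm <- function(object, ...) summary(object$lmer, ...)

#' @export
predict.div_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$lmer, ...) else
    predict(object$lmer, newdata = newdata, ...)
}

#' @export
residuals.div_lmm <- function(object, ...) residuals(object$lmer, ...)

#' @export
confint.div_lmm <- function(object, parm = NULL, level = 0.95, ...) {
  a <- (1 - level) / 2
  est <- object$coefficients; se <- object$se; df <- object$df
  out <- cbind(est + qt(a, df) * se, est + qt(1 - a, df) * se)
  colnames(out) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Backward fixed-effect selection by likelihood-ratio test
#'
#' Iteratively removes the least significant removable fixed term: at each
#' step every term not protected by a retained interaction is dropped in turn,
#' the reduced ML fit is compared with the current fit by a likelihood-ratio
#' test, and the term with the largest p-value above `alpha` is removed. The
#' random structure is held fixed throughout.
#'
#' @inheritParams fit_lmm
#' @param alpha removal threshold (default 0.05).
#' @return List with `fixed` (selected terms), `fit` (final `div_lmm`) and
#'   `trace` (data frame of the removals tested).
#' @export
lrt_backward_select <- function(data, response = "status_J",
                                fixed = c("age", "sex", "age:sex"),
                                random = "donor", alpha = 0.05) {
  needs <- list("age:sex" = c("age", "sex"),
                "age:celltype" = c("age", "celltype"))
  protected <- function(terms) unique(unlist(needs[intersect(names(needs),
                                                             terms)]))
  cur <- fit_lmm(data, response, fixed, random)
  trace <- list()
  repeat {
    removable <- setdiff(cur$fixed, protected(cur$fixed))
    if (!length(removable)) break
    ps <- vapply(removable, function(t) {
      red <- fit_lmm(data, response, setdiff(cur$fixed, t), random)
      stat <- 2 * (cur$logLik - red$logLik)
      pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(ps)
    trace[[length(trace) + 1L]] <-
      data.frame(term = removable[worst], p = ps[worst],
                 removed = ps[worst] > alpha, stringsAsFactors = FALSE)
    if (ps[worst] > alpha) {
      cur <- fit_lmm(data, response, setdiff(cur$fixed, removable[worst]),
                     random)
    } else break
  }
  list(fixed = cur$fixed, fit = cur,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

#' Intraclass correlation coefficient of a random grouping
#'
#' The share of total variance (all random-intercept components plus
#' residual) attributable to one grouping.
#'
#' @param fit a `div_lmm`.
#' @param grouping `"donor"` or `"donor_celltype"`.
#' @return Proportion in `[0, 1]`.
#' @export
icc <- function(fit, grouping = "donor") {
  stopifnot(inherits(fit, "div_lmm"))
  if (!grouping %in% names(fit$varcomp))
    stop("grouping '", grouping, "' not in fit (has: ",
         paste(names(fit$varcomp), collapse = ", "), ")")
  unname(fit$varcomp[grouping] / sum(fit$varcomp))
}

#' Mixed-model coefficient surface
#'
#' A plain representation of a fitted (or published) longitudinal model's
#' coefficients: the fixed effects plus per-donor intercept offsets and,
#' for cell-type models, per-donor CD8-vs-CD4 intercept offsets. The
#' group-summary operations ([summarize_initial_diversity()],
#' [slope_for_group()]) are pure functions of this object, so coefficient
#' tables can be fed in directly without refitting.
#'
#' @param beta0 intercept (reference: male, CD4, age 0).
#' @param beta_age age slope per year.
#' @param beta_sex female intercept offset.
#' @param beta_age_sex female age-slope offset.
#' @param beta_age_celltype CD8 age-slope offset.
#' @param donor_offset named numeric vector of per-donor intercept offsets
#'   (deviations; at CD4 for cell-type models).
#' @param celltype_offset optional named numeric vector (same donors) of
#'   per-donor CD8 intercept offsets.
#' @param donor_sex named character vector giving each donor's sex.
#' @return Object of class `mixed_coefs`.
#' @export
mixed_coefs <- function(beta0, beta_age = 0, beta_sex = 0, beta_age_sex = 0,
                        beta_age_celltype = 0, donor_offset,
                        celltype_offset = NULL, donor_sex) {
  stopifnot(!is.null(names(donor_offset)), !is.null(names(donor_sex)))
  if (!all(names(donor_offset) %in% names(donor_sex)))
    stop("every donor in donor_offset needs a sex in donor_sex")
  if (!is.null(celltype_offset) &&
      !setequal(names(celltype_offset), names(donor_offset)))
    stop("celltype_offset must cover the same donors as donor_offset")
  structure(list(beta0 = beta0, beta_age = beta_age, beta_sex = beta_sex,
                 beta_age_sex = beta_age_sex,
                 beta_age_celltype = beta_age_celltype,
                 donor_offset = donor_offset,
                 celltype_offset = celltype_offset,
                 donor_sex = donor_sex[names(donor_offset)]),
            class = "mixed_coefs")
}

#' Extract the coefficient surface from a fitted mixed model
#'
#' Per-donor intercept offsets are the predicted (conditional-mode) random
#' intercepts. For cell-type fits with a donor-by-cell-type random intercept,
#' the per-donor offset at CD4 is `u_donor + u_donor:CD4` and the CD8 offset
#' is the fixed cell-type effect (if retained) plus `u_donor:CD8 -
#' u_donor:CD4`.
#'
#' @param fit a `div_lmm`.
#' @return A [mixed_coefs()] object.
#' @export
as_mixed_coefs <- function(fit) {
  stopifnot(inherits(fit, "div_lmm"))
  co <- fit$coefficients
  g <- function(nm) if (nm %in% names(co)) unname(co[nm]) else 0
  data <- fit$data
  donors <- sort(unique(as.character(data$donor_id)))
  donor_sex <- setNames(
    as.character(data$sex[match(donors, as.character(data$donor_id))]), donors)
  u_donor <- setNames(rep(0, length(donors)), donors)
  if ("donor_id" %in% names(fit$ranef)) {
    re <- fit$ranef$donor_id
    u_donor[rownames(re)] <- re[["(Intercept)"]]
  }
  ct_off <- NULL
  if ("donor_id:celltype" %in% names(fit$ranef)) {
    re <- fit$ranef$`donor_id:celltype`
    key <- rownames(re)
    val <- setNames(re[["(Intercept)"]], key)
    u4 <- setNames(rep(0, length(donors)), donors)
    u8 <- setNames(rep(0, length(donors)), donors)
    k4 <- paste0(donors, ":CD4"); k8 <- paste0(donors, ":CD8")
    u4[k4 %in% key] <- val[k4[k4 %in% key]]
    u8[k8 %in% key] <- val[k8[k8 %in% key]]
    ct_off <- g("celltypeCD8") + u8 - u4
    u_donor <- u_donor + u4
  } else if ("celltypeCD8" %in% names(co)) {
    ct_off <- setNames(rep(g("celltypeCD8"), length(donors)), donors)
  }
  mixed_coefs(beta0 = g("(Intercept)"), beta_age = g("age"),
              beta_sex = g("sexfemale"), beta_age_sex = g("age:sexfemale"),
              beta_age_celltype = g("age:celltypeCD8"),
              donor_offset = u_donor, celltype_offset = ct_off,
              donor_sex = donor_sex)
}

per_donor_intercepts <- function(coefs, sex, cell_type = NULL) {
  stopifnot(inherits(coefs, "mixed_coefs"))
  donors <- names(coefs$donor_offset)[coefs$donor_sex == sex]
  if (length(donors) < 2L)
    stop("fewer than 2 donors of sex '", sex, "': SD undefined")
  I <- coefs$beta0 + (sex == "female") * coefs$beta_sex +
    coefs$donor_offset[donors]
  if (!is.null(cell_type) && cell_type == "CD8") {
    if (is.null(coefs$celltype_offset))
      stop("model has no cell-type offsets")
    I <- I + coefs$celltype_offset[donors]
  }
  I
}

#' Mean and spread of initial diversity for a donor group
#'
#' "Initial" diversity is the model intercept at age 0: for donor `i` it is
#' `beta0 + beta_sex * [female] + donor offset` (plus the donor's CD8 offset
#' for cell-type models). Returns the mean and sample standard deviation
#' (n - 1 denominator) over the donors of the requested sex.
#'
#' @param coefs a [mixed_coefs()] object (or a `div_lmm`, converted via
#'   [as_mixed_coefs()]).
#' @param sex `"male"` or `"female"`.
#' @param cell_type `NULL` (whole blood / merged), `"CD4"` or `"CD8"`.
#' @return List with `sex`, `cell_type`, `mean`, `sd`, `n`, and the per-donor
#'   `intercepts`.
#' @export
summarize_initial_diversity <- function(coefs, sex, cell_type = NULL) {
  if (inherits(coefs, "div_lmm")) coefs <- as_mixed_coefs(coefs)
  I <- per_donor_intercepts(coefs, sex, cell_type)
  list(sex = sex, cell_type = cell_type, mean = mean(I), sd = sd(I),
       n = length(I), intercepts = I)
}

#' Age slope of diversity for a donor group
#'
#' `d(diversity)/d(age) = beta_age + beta_age_sex * [female] +
#' beta_age_celltype * [CD8]`.
#'
#' @inheritParams summarize_initial_diversity
#' @return Slope per year of age.
#' @export
slope_for_group <- function(coefs, sex, cell_type = NULL) {
  if (inherits(coefs, "div_lmm")) coefs <- as_mixed_coefs(coefs)
  coefs$beta_age + (sex == "female") * coefs$beta_age_sex +
    (!is.null(cell_type) && cell_type == "CD8") * coefs$beta_age_celltype
}
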