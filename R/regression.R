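#' Weighted linear regression of diversity on age and sex
#'
#' Fits `response ~ terms` by weighted least squares, with per-sample total
#' copy counts as weights (samples with deeper sequencing count more, i.e.
#' residual variance is assumed inversely proportional to coverage). Weights
#' are normalized to mean 1 so that information-criterion magnitudes are
#' scale-stable; normalization changes neither coefficients nor standard
#' errors. The sex reference level is male.
#'
#' @param formula model formula, e.g. `status_J ~ age` or
#'   `sequence_J ~ age * sex`.
#' @param data cohort diversity table (see [cohort_diversity()] or
#'   [simulate_cohort()]); must contain the model variables and, unless
#'   `weights` is given, a `total_copies` column.
#' @param weights positive per-sample weights; defaults to
#'   `data$total_copies`.
#' @param normalize_weights divide weights by their mean (default `TRUE`).
#'   [piecewise_search()] normalizes once at the cohort level and disables
#'   per-fit normalization so subgroup criteria stay comparable.
#' @return Object of class `div_wls`: the underlying `lm` fit plus the overall
#'   F-test p-value (`model_p`, full model against intercept-only), the
#'   unweighted Pearson correlation `r` between age and the response, `bic`,
#'   and the coefficient table. Supports `print`, `summary`, `coef`,
#'   `predict`, `residuals`.
#' @export
weighted_fit <- function(formula, data, weights = NULL,
                         normalize_weights = TRUE) {
  stopifnot(inherits(formula, "formula"))
  if (is.null(weights)) {
    if (!"total_copies" %in% names(data))
      stop("no weights given and no total_copies column in data")
    weights <- data$total_copies
  }
  if (any(weights <= 0)) stop("weights must be positive")
  if (normalize_weights) weights <- weights / mean(weights)
  data <- as.data.frame(data)
  if ("sex" %in% names(data) && !is.factor(data$sex))
    data$sex <- factor(data$sex, levels = c("male", "female"))
  if ("sex" %in% all.vars(formula) &&
      length(unique(data$sex[!is.na(data$sex)])) < 2L)
    stop("singular design: collinear term(s) sexfemale (single sex level)")
  data$.w <- weights
  fit <- lm(formula, data = data, weights = .w)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("singular design: collinear term(s) ", paste(bad, collapse = ", "))
  }
  response <- all.vars(formula)[1L]
  n <- nrow(data)
  if (n <= length(coef(fit)))
    stop("need more observations than model terms")
  fs <- summary(fit)$fstatistic
  model_p <- if (is.null(fs)) NA_real_ else
    unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  r <- if ("age" %in% names(data)) cor(data$age, data[[response]]) else NA_real_
  structure(list(lm = fit, formula = formula, response = response, n = n,
                 coefficients = coef(fit),
                 se = summary(fit)$coefficients[, "Std. Error"],
                 model_p = model_p, r = r, bic = BIC(fit),
                 weights = weights),
            class = "div_wls")
}

#' @export
print.div_wls <- function(x, digits = 4, ...) {
  cat("Weighted linear model:", deparse(x$formula), "\n")
  print(round(x$coefficients, digits))
  cat(sprintf("n = %d, model p = %.4g, r(age, %s) = %.3f, BIC = %.2f\n",
              x$n, x$model_p, x$response, x$r, x$bic))
  invisible(x)
}

#' @export
summary.div_wls <- function(object, ...) summary(object$lm, ...)

#' @export
coef.div_wls <- function(object, ...) object$coefficients

#' @export
predict.div_wls <- function(object, newdata = NULL, ...) {
  if (!is.null(newdata) && "sex" %in% names(newdata) &&
      !is.factor(newdata$sex))
    newdata$sex <- factor(newdata$sex, levels = c("male", "female"))
  if (is.null(newdata)) predict(object$lm, ...) else
    predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.div_wls <- function(object, ...) residuals(object$lm, ...)

# Gaussian WLS log-likelihood / BIC on a model-matrix column subset;
# matches stats::BIC(lm(...)) exactly (sigma counted as a parameter).
.wls_bic <- function(X, y, w) {
  fit <- lm.wfit(X, y, w)
  rss <- sum(w * fit$residuals^2)
  n <- length(y)
  ll <- 0.5 * sum(log(w)) - 0.5 * n * (log(2 * pi) + log(rss / n) + 1)
  -2 * ll + (fit$rank + 1) * log(n)
}

.term_columns <- list(
  "(Intercept)" = "(Intercept)", age = "age", sex = "sexfemale",
  "age:sex" = "age:sexfemale")

.design_matrix <- function(data) {
  sex <- factor(data$sex, levels = c("male", "female"))
  cbind("(Intercept)" = 1, age = data$age,
        sexfemale = as.numeric(sex == "female"),
        "age:sexfemale" = data$age * as.numeric(sex == "female"))
}

# Backward BIC selection on precomputed design columns. Returns terms and BIC.
.bic_backward <- function(X, y, w, terms) {
  bic_of <- function(tt) {
    cols <- unlist(.term_columns[c("(Intercept)", tt)], use.names = FALSE)
    .wls_bic(X[, cols, drop = FALSE], y, w)
  }
  repeat {
    cur <- bic_of(terms)
    removable <- setdiff(terms,
                         if ("age:sex" %in% terms) c("age", "sex") else character())
    if (!length(removable)) return(list(terms = terms, bic = cur))
    cand <- vapply(removable, function(t) bic_of(setdiff(terms, t)), numeric(1))
    if (min(cand) < cur) {
      terms <- setdiff(terms, removable[which.min(cand)])
    } else {
      return(list(terms = terms, bic = cur))
    }
  }
}

#' Backward model selection by BIC
#'
#' Starting from `response ~ age + sex + age:sex` (or `~ age` when the data
#' contain a single sex), iteratively removes the single term whose removal
#' lowers the Bayesian Information Criterion the most, respecting model
#' hierarchy (the interaction must go before its main effects), until no
#' removal lowers BIC. Deterministic.
#'
#' @param data cohort diversity table.
#' @param response `"status_J"` or `"sequence_J"` (any numeric column).
#' @param terms starting fixed terms, subset of `c("age", "sex", "age:sex")`.
#' @param weights per-sample weights; defaults to `data$total_copies`,
#'   normalized to mean 1.
#' @param normalize_weights see [weighted_fit()].
#' @return List with `terms` (selected), `bic`, and `fit` (a [weighted_fit()]
#'   object for the selected model).
#' @export
bic_backward_select <- function(data, response = "status_J",
                                terms = c("age", "sex", "age:sex"),
                                weights = NULL, normalize_weights = TRUE) {
  data <- as.data.frame(data)
  if (is.null(weights)) weights <- data$total_copies
  if (normalize_weights) weights <- weights / mean(weights)
  if (length(unique(data$sex[!is.na(data$sex)])) < 2L)
    terms <- intersect(terms, "age")
  X <- .design_matrix(data)
  sel <- .bic_backward(X, data[[response]], weights, terms)
  f <- if (length(sel$terms)) reformulate(sel$terms, response)
       else as.formula(paste(response, "~ 1"))
  fit <- weighted_fit(f, data, weights = weights, normalize_weights = FALSE)
  list(terms = sel$terms, bic = sel$bic, fit = fit)
}

#' Brute-force piecewise regression split search
#'
#' Tests every age split (the younger group contains ages `<=` the split age)
#' for which both subgroups hold at least `min_group` donors. Within each
#' subgroup, the model is chosen by [bic_backward_select()]; the best split
#' minimizes the sum of the two selected models' BIC values. Weights are
#' normalized to mean 1 once, over the whole cohort, before the search, so
#' that BIC sums are comparable across splits. Ties are broken toward the
#' youngest split age.
#'
#' @param data cohort diversity table with integer `age`.
#' @param response response column name.
#' @param min_group minimum donors per subgroup (default 5).
#' @param terms starting terms for within-group selection.
#' @param weights per-sample weights; defaults to `data$total_copies`.
#' @return Object of class `div_piecewise`: `split_age` (last age of the
#'   younger group), `young` and `old` (selected [weighted_fit()] objects and
#'   terms), `bic_sum`, and the full search `trace`.
#' @export
piecewise_search <- function(data, response = "status_J", min_group = 5L,
                             terms = c("age", "sex", "age:sex"),
                             weights = NULL) {
  data <- as.data.frame(data)
  if (is.null(weights)) weights <- data$total_copies
  w <- weights / mean(weights)
  ages <- sort(unique(data$age))
  if (length(ages) < 2L) stop("need at least two distinct ages")
  X <- .design_matrix(data)
  y <- data[[response]]
  single_sex <- length(unique(data$sex[!is.na(data$sex)])) < 2L
  trace <- list()
  for (a in ages[-length(ages)]) {
    iy <- data$age <= a
    if (sum(iy) < min_group || sum(!iy) < min_group) next
    tt <- function(idx) {
      t0 <- if (single_sex || length(unique(data$sex[idx])) < 2L)
        intersect(terms, "age") else terms
      .bic_backward(X[idx, , drop = FALSE], y[idx], w[idx], t0)
    }
    sy <- tt(iy); so <- tt(!iy)
    trace[[length(trace) + 1L]] <-
      data.frame(split_age = a, n_young = sum(iy), n_old = sum(!iy),
                 bic_young = sy$bic, bic_old = so$bic,
                 bic_sum = sy$bic + so$bic,
                 terms_young = paste(sy$terms, collapse = "+"),
                 terms_old = paste(so$terms, collapse = "+"),
                 stringsAsFactors = FALSE)
  }
  if (!length(trace))
    stop("no feasible split: every candidate leaves a subgroup below ",
         min_group, " donors")
  trace <- do.call(rbind, trace)
  best <- trace[which.min(trace$bic_sum), ]  # first minimum = youngest split
  refit <- function(idx) {
    sub <- data[idx, , drop = FALSE]
    bic_backward_select(sub, response, terms = terms, weights = w[idx],
                        normalize_weights = FALSE)
  }
  young <- refit(data$age <= best$split_age)
  old <- refit(data$age > best$split_age)
  structure(list(split_age = best$split_age, young = young, old = old,
                 bic_sum = best$bic_sum, min_group = min_group,
                 response = response, trace = trace),
            class = "div_piecewise")
}

#' @export
print.div_piecewise <- function(x, digits = 4, ...) {
  cat(sprintf("Piecewise weighted regression of %s: best split at age %d\n",
              x$response, as.integer(x$split_age)))
  cat(sprintf("  younger (n = %d): %s\n", x$young$fit$n,
              paste(deparse(x$young$fit$formula), collapse = "")))
  cat(sprintf("  older   (n = %d): %s\n", x$old$fit$n,
              paste(deparse(x$old$fit$formula), collapse = "")))
  cat(sprintf("  BIC sum = %.2f over %d candidate splits\n",
              x$bic_sum, nrow(x$trace)))
  invisible(x)
}

#' @export
plot.div_piecewise <- function(x, data, ...) {
  plot(data$age, data[[x$response]], xlab = "age (years)", ylab = x$response,
       ...)
  abline(v = x$split_age + 0.5, lty = 2)
  for (side in c("young", "old")) {
    fit <- x[[side]]$fit
    idx <- if (side == "young") data$age <= x$split_age else
      data$age > x$split_age
    sub <- data[idx, , drop = FALSE]
    ord <- order(sub$age)
    points(sub$age[ord], predict(fit, newdata = sub)[ord], type = "l",
           col = 2, lwd = 2)
  }
  invisible(x)
}

#' Compare age slopes of two fitted models
#'
#' Two-sample t-statistic for the equality of the `age` coefficients of two
#' weighted fits: `t = (b1 - b1') / sqrt(se^2 + se'^2)` with
#' Welch-Satterthwaite degrees of freedom from the two fits' residual degrees
#' of freedom.
#'
#' @param a,b `div_wls` objects whose models contain `age`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
compare_slopes <- function(a, b) {
  for (f in list(a, b))
    if (!inherits(f, "div_wls") || !"age" %in% names(f$coefficients))
      stop("both fits must be div_wls models containing an age term")
  d <- a$coefficients[["age"]] - b$coefficients[["age"]]
  va <- a$se[["age"]]^2; vb <- b$se[["age"]]^2
  dfa <- a$lm$df.residual; dfb <- b$lm$df.residual
  se <- sqrt(va + vb)
  if (se == 0) return(list(t = 0, df = dfa + dfb, p = 1))
  t <- d / se
  df <- (va + vb)^2 / (va^2 / dfa + vb^2 / dfb)
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cross-sectional fit table in the reporting layout
#'
#' Convenience: formats general and piecewise fits as a table with columns
#' `N`, `b_0`, `b_1`, `b_2`, `model_p`, `r` (coefficients rounded to 4
#' decimals), one row per fitted (sub)model.
#'
#' @param fits named list of `div_wls` and/or `div_piecewise` objects.
#' @return Data frame.
#' @export
fit_table <- function(fits) {
  row_of <- function(fit, label) {
    co <- fit$coefficients
    data.frame(model = label, N = fit$n,
               b_0 = round(unname(co["(Intercept)"]), 4),
               b_1 = round(unname(co["age"]), 4),
               b_2 = if ("sexfemale" %in% names(co))
                 round(unname(co["sexfemale"]), 4) else 0,
               model_p = fit$model_p, r = round(fit$r, 3),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (inherits(f, "div_wls")) {
      rows[[length(rows) + 1L]] <- row_of(f, nm)
    } else if (inherits(f, "div_piecewise")) {
      rows[[length(rows) + 1L]] <-
        row_of(f$young$fit, sprintf("%s (age <= %d)", nm, f$split_age))
      rows[[length(rows) + 1L]] <-
        row_of(f$old$fit, sprintf("%s (age > %d)", nm, f$split_age))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
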