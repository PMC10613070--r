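# Shared fixtures and independent oracle implementations.

# Build a small repertoire from explicit copy counts / frames / gene calls.
toy_repertoire <- function(copies, frames = rep("in_frame", length(copies)),
                           v = rep("TRBV19-01", length(copies)),
                           j = rep("TRBJ01-01", length(copies)),
                           cdr3 = rep(24L, length(copies)),
                           n2 = rep(33L, length(copies)),
                           nt = NULL, ...) {
  n <- length(copies)
  if (is.null(nt))
    nt <- vapply(seq_len(n), function(i)
      paste0(strrep("ACGT", 10), paste(c("A", "C", "G", "T")[
        1 + (i %/% 4^(0:4)) %% 4], collapse = "")), character(1))
  new_repertoire(data.frame(
    nucleotide = nt, copy_count = as.integer(copies),
    v_call = v, d_call = "TRBD01-01", j_call = j,
    frame_status = frames, cdr3_start = cdr3, n2_start = n2,
    stringsAsFactors = FALSE), sample_id = "TOY", ...)
}

# Direct evaluation of the corrected evenness formulas, independent of the
# package's count_vector path.
oracle_entropy <- function(counts, S = length(counts)) {
  N <- sum(counts)
  p <- counts[counts > 0] / N
  -sum(p * log(p)) - (S - 1) / (2 * N)
}
oracle_pielou <- function(counts, S = length(counts)) {
  oracle_entropy(counts, S) / log(S)
}

# Weighted least squares by the normal equations (closed form).
oracle_wls <- function(X, y, w) solve(t(X) %*% (w * X), t(X) %*% (w * y))

# BIC backward selection re-implemented with stats::lm + stats::BIC.
oracle_backward <- function(data, response, weights) {
  data$.ww <- weights
  terms <- c("age", "sex", "age:sex")
  if (length(unique(data$sex)) < 2L) terms <- "age"
  bic_of <- function(tt) {
    f <- if (length(tt)) reformulate(tt, response) else
      as.formula(paste(response, "~ 1"))
    BIC(lm(f, data = data, weights = .ww))
  }
  repeat {
    cur <- bic_of(terms)
    removable <- setdiff(terms, if ("age:sex" %in% terms)
      c("age", "sex") else character())
    if (!length(removable)) return(list(terms = terms, bic = cur))
    cand <- vapply(removable, function(t) bic_of(setdiff(terms, t)),
                   numeric(1))
    if (min(cand) < cur) terms <- setdiff(terms, removable[which.min(cand)])
    else return(list(terms = terms, bic = cur))
  }
}

# Exhaustive split scan with the lm-based selection above; ties toward the
# youngest split age. Weights are normalized once over the whole cohort.
oracle_piecewise <- function(data, response, min_group = 5L) {
  w <- data$total_copies / mean(data$total_copies)
  ages <- sort(unique(data$age))
  best <- NULL
  for (a in ages[-length(ages)]) {
    iy <- data$age <= a
    if (sum(iy) < min_group || sum(!iy) < min_group) next
    b <- oracle_backward(data[iy, , drop = FALSE], response, w[iy])$bic +
      oracle_backward(data[!iy, , drop = FALSE], response, w[!iy])$bic
    if (is.null(best) || b < best$bic - 1e-9) best <- list(split = a, bic = b)
  }
  best
}

# Fences of the skew-adjusted boxplot recomputed step by step (no shared
# helpers with the package implementation).
oracle_gh_fences <- function(x, alpha = 0.007) {
  A <- median(x)
  pg <- c(0.75, 0.80, 0.85, 0.90)
  up <- as.numeric(quantile(x, pg, type = 8))
  lo <- as.numeric(quantile(x, 1 - pg, type = 8))
  zp <- qnorm(pg)
  g <- median(log((up - A) / (A - lo)) / zp)
  if (abs(g) < 1e-8) g <- 0
  half <- if (g == 0) (up - lo) / (2 * zp) else
    (up - lo) * g / (exp(g * zp) - exp(-g * zp))
  # solve the two-parameter log-linear system by explicit least squares
  u <- zp^2 / 2; v <- log(half)
  slope <- sum((u - mean(u)) * (v - mean(v))) / sum((u - mean(u))^2)
  h <- max(0, slope)
  B <- exp(mean(v) - slope * mean(u))
  qgh <- function(z) {
    core <- if (g == 0) z else (exp(g * z) - 1) / g
    A + B * core * exp(h * z^2 / 2)
  }
  c(qgh(qnorm(alpha / 2)), qgh(qnorm(1 - alpha / 2)))
}

# One cross-sectional cohort with the study's embedded age-18 breakpoint.
breakpoint_cohort <- function(n = 480L, seed = 1L) {
  simulate_cohort(cohort_params(
    n_donors = n,
    breakpoint = list(age = 18L, young = c(0.6817, -0.0060),
                      old = c(0.6227, -0.0003), response = "status_J")),
    seed = seed)$samples
}

# evaluate an expression with lme4 boundary messages and warnings silenced
quiet <- function(expr) suppressWarnings(suppressMessages(expr))
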