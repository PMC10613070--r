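#' Invert the two-class evenness index to a productive copy fraction
#'
#' The synthetic generator parameterizes Status Diversity on the J scale
#' (the modelled quantity) and converts each target to a productive-copy
#' fraction by numerically inverting the corrected two-class entropy:
#' find `f >= 0.5` with `-(f ln f + (1-f) ln(1-f)) - 1/(2N) = J ln 2`.
#' Bisection to absolute tolerance 1e-10.
#'
#' @param J target Status Diversity in (0, 1).
#' @param N total copy count entering the correction term.
#' @return Productive fraction in `[0.5, 1)`.
#' @export
invert_status_J <- function(J, N = 1e6) {
  if (J <= 0 || J >= 1) stop("target J must be inside (0, 1)")
  target_H <- J * log(2) + 1 / (2 * N)
  if (target_H >= log(2)) return(0.5)
  H <- function(f) {
    g <- 1 - f
    -(f * log(f) + ifelse(g > 0, g * log(g), 0))
  }
  lo <- 0.5; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (H(mid) > target_H) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

power_probs <- function(n_clones, exponent) {
  p <- (seq_len(n_clones))^(-exponent)
  p / sum(p)
}

#' Expected clone-distribution evenness of a discretized power law
#'
#' Population-level evenness of `n_clones` clones with abundances
#' proportional to `rank^-exponent`, including the finite-sample correction
#' at total depth `N` (the observed class count is approximated by
#' `n_clones`, accurate when `N` well exceeds `n_clones`).
#'
#' @param exponent power-law exponent (larger = more clonal).
#' @param n_clones number of clones.
#' @param N total copies.
#' @return Expected Sequence Diversity.
#' @export
expected_sequence_J <- function(exponent, n_clones, N) {
  p <- power_probs(n_clones, exponent)
  (-sum(p * log(p)) - (n_clones - 1) / (2 * N)) / log(n_clones)
}

#' Invert a Sequence Diversity target to a power-law exponent
#'
#' @inheritParams expected_sequence_J
#' @param J target Sequence Diversity.
#' @return Exponent such that [expected_sequence_J()] equals `J`.
#' @export
invert_sequence_J <- function(J, n_clones, N) {
  if (J >= expected_sequence_J(1e-8, n_clones, N)) return(1e-8)
  uniroot(function(s) expected_sequence_J(s, n_clones, N) - J,
          c(1e-8, 5), tol = 1e-9)$root
}

.contam_cats <- c("orphon_v", "unresolved_v", "unresolved_j",
                  "indexing_error", "nonfunctional_or_orf_gene",
                  "excluded_gene")

# deterministic unique ACGT strings: sample-specific 5'-region (so clones are
# never shared across simulated samples) + base-4 encoded clone index
nt_encode <- function(idx, width = 14L, prefix = strrep("ACGT", 8L)) {
  stopifnot(all(idx < 4^width))
  digits <- matrix(0L, length(idx), width)
  x <- idx
  for (j in width:1) { digits[, j] <- x %% 4L; x <- x %/% 4L }
  codes <- matrix(c("A", "C", "G", "T")[digits + 1L], length(idx), width)
  paste0(prefix, do.call(paste0, as.data.frame(codes)))
}

# encode a sample id as a nucleotide prefix (4 bases per byte), padded so
# cdr3/n2 annotations at positions 24/33 stay in range
nt_prefix <- function(sample_id) {
  bytes <- utf8ToInt(substr(sample_id, 1L, 12L))
  digits <- as.vector(vapply(bytes, function(b)
    as.integer((b %/% 4L^(3:0)) %% 4L), integer(4)))
  paste0(paste(c("A", "C", "G", "T")[digits + 1L], collapse = ""),
         strrep("A", max(0L, 40L - 4L * length(bytes))))
}

#' Simulate one rearranged TRB repertoire
#'
#' Draws clone copy counts from a discretized power-law clone-size law
#' (separately for productive and non-productive clones, with the productive
#' copy share binomially sampled around `productive_fraction`) and optionally
#' injects curation-violating records (orphon V, unresolved V/J, indexing
#' errors, non-functional genes, TRBV03-01) at given copy-share rates.
#' Nucleotide sequences are deterministic unique ACGT strings with valid CDR3
#' and N2 annotations (except for injected indexing errors).
#'
#' @param depth total copies (default 2e6, a mid-range study coverage).
#' @param productive_fraction expected productive copy share.
#' @param clone_law list with `exponent` (default 0.65) and `n_clones`
#'   (default `depth / 4`); see [expected_sequence_J()].
#' @param contamination named numeric vector of copy-share rates for the
#'   violation categories `r .contam_cats`; missing names default to 0.
#' @param seed optional integer seed.
#' @param sample_id,donor_id,age,sex,compartment,timepoint,cd4_cd8_ratio
#'   metadata for the repertoire.
#' @return A `trb_repertoire`; attribute `"truth"` records the generating
#'   parameters.
#' @export
simulate_repertoire <- function(depth = 2e6, productive_fraction = 0.85,
                                clone_law = list(), contamination = NULL,
                                seed = NULL, sample_id = "SYN1",
                                donor_id = sample_id, age = NA, sex = NA,
                                compartment = "whole_blood", timepoint = NA,
                                cd4_cd8_ratio = NA) {
  if (!is.null(seed)) set.seed(seed)
  law <- modifyList(list(exponent = 0.65, n_clones = max(4L, round(depth / 4))),
                    clone_law)
  if (productive_fraction <= 0 || productive_fraction >= 1)
    stop("productive_fraction must be inside (0, 1)")
  q <- setNames(rep(0, length(.contam_cats)), .contam_cats)
  if (!is.null(contamination)) {
    bad <- setdiff(names(contamination), .contam_cats)
    if (length(bad)) stop("unknown contamination categories: ",
                          paste(bad, collapse = ", "))
    q[names(contamination)] <- contamination
  }
  if (sum(q) >= 1) stop("contamination rates must sum to < 1")
  split <- as.vector(rmultinom(1, depth, c(clean = 1 - sum(q), q)))
  names(split) <- c("clean", .contam_cats)
  ref_raw <- jsonlite::read_json(
    system.file("extdata", "trb_gene_reference_synthetic.json",
                package = "trbdiv", mustWork = TRUE), simplifyVector = TRUE)
  usable_v <- setdiff(ref_raw$functional_v, ref_raw$excluded)
  next_idx <- 0L
  prefix <- nt_prefix(sample_id)
  mk_block <- function(n_copies, n_clones_target, v, j, frame,
                       cdr3 = 24L, n2 = 33L) {
    if (n_copies < 1) return(NULL)
    k <- max(1L, min(n_copies, n_clones_target))
    counts <- if (k == 1L) n_copies else
      as.vector(rmultinom(1, n_copies, power_probs(k, law$exponent)))
    keep <- counts > 0L
    counts <- counts[keep]
    idx <- next_idx + seq_along(counts)
    next_idx <<- next_idx + length(counts)
    data.frame(nucleotide = nt_encode(idx - 1L, prefix = prefix),
               copy_count = counts,
               v_call = sample(v, length(counts), replace = TRUE),
               d_call = sample(ref_raw$functional_d, length(counts),
                               replace = TRUE),
               j_call = sample(j, length(counts), replace = TRUE),
               frame_status = rep_len(frame, length(counts)),
               cdr3_start = cdr3, n2_start = n2,
               stringsAsFactors = FALSE)
  }
  n_prod <- rbinom(1, split[["clean"]], productive_fraction)
  n_nonp <- split[["clean"]] - n_prod
  kp <- max(2L, round(law$n_clones * productive_fraction))
  kn <- max(2L, round(law$n_clones * (1 - productive_fraction)))
  blocks <- list(
    mk_block(n_prod, kp, usable_v, ref_raw$functional_j, "in_frame"),
    mk_block(n_nonp, kn, usable_v, ref_raw$functional_j,
             c("out_of_frame", "stop_codon")),
    mk_block(split[["orphon_v"]], max(1L, round(split[["orphon_v"]] / 50)),
             ref_raw$orphon_v, ref_raw$functional_j, "in_frame"),
    mk_block(split[["unresolved_v"]],
             max(1L, round(split[["unresolved_v"]] / 50)),
             "unresolved", ref_raw$functional_j, "in_frame"),
    mk_block(split[["unresolved_j"]],
             max(1L, round(split[["unresolved_j"]] / 50)),
             usable_v, "unresolved", "in_frame"),
    mk_block(split[["indexing_error"]],
             max(1L, round(split[["indexing_error"]] / 50)),
             usable_v, ref_raw$functional_j, "in_frame", cdr3 = 24L, n2 = 10L),
    mk_block(split[["nonfunctional_or_orf_gene"]],
             max(1L, round(split[["nonfunctional_or_orf_gene"]] / 50)),
             "TRBV05-02", ref_raw$functional_j, "in_frame"),
    mk_block(split[["excluded_gene"]],
             max(1L, round(split[["excluded_gene"]] / 50)),
             "TRBV03-01", ref_raw$functional_j, "in_frame")
  )
  records <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  rep <- new_repertoire(records, sample_id = sample_id, donor_id = donor_id,
                        age = age, sex = sex, compartment = compartment,
                        timepoint = timepoint, cd4_cd8_ratio = cd4_cd8_ratio)
  attr(rep, "truth") <- list(depth = depth,
                             productive_fraction = productive_fraction,
                             clone_law = law, contamination = q,
                             copies_per_category = split)
  rep
}

#' Cross-sectional cohort generator settings
#'
#' Defaults emulate the study conditions: 487 donors aged 1-74, near-even sex
#' ratio, per-sample depth log-uniform over 5e5 to 8e6 copies, Status and
#' Sequence Diversity linear in age with sex-specific coefficients of the
#' magnitudes seen in the cross-sectional fits, and residual noise whose
#' variance is inversely proportional to normalized coverage (the
#' heteroskedasticity the weighted regression assumes), with
#' `sigma_status = 0.03` calibrated to reproduce a young-segment age
#' correlation near -0.6.
#'
#' @param n_donors cohort size.
#' @param age_range inclusive integer age range.
#' @param female_fraction probability a donor is female.
#' @param depth_range copy-depth range (log-uniform).
#' @param status_model,sequence_model per-sex `c(intercept, slope)` lists
#'   with elements `male` and `female`.
#' @param breakpoint `NULL`, or a list `list(age =, young = c(intercept,
#'   slope), old = c(intercept, slope), response = "status_J")` replacing the
#'   linear model for that response by two age segments (younger group
#'   includes the split age).
#' @param sigma_status,sigma_sequence residual scale on the J scale at mean
#'   coverage.
#' @param heteroskedastic scale residual SD by `1/sqrt(normalized coverage)`.
#' @param clone_exponent reference power-law exponent (records mode).
#' @param n_clones_frac clones per copy (records mode).
#' @param contamination copy-share rates of curation-violating records
#'   (records mode); defaults to none.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n_donors = 487L, age_range = c(1L, 74L),
                          female_fraction = 228 / 487,
                          depth_range = c(5e5, 8e6),
                          status_model = list(male = c(0.6183, -0.0002),
                                              female = c(0.6367, -0.0006)),
                          sequence_model = list(male = c(0.9498, -0.0015),
                                                female = c(0.9559, -0.0013)),
                          breakpoint = NULL,
                          sigma_status = 0.03, sigma_sequence = 0.02,
                          heteroskedastic = TRUE,
                          clone_exponent = 0.65, n_clones_frac = 0.25,
                          contamination = NULL) {
  structure(as.list(environment()), class = "cohort_params")
}

#' Simulate a cross-sectional cohort
#'
#' Generates per-donor whole-blood samples whose Status and Sequence
#' Diversity follow the embedded linear (or piecewise) age-sex models plus
#' coverage-scaled noise. By default only the per-sample diversity table is
#' produced (the modelling stages need nothing more); with `records = TRUE`
#' full rearrangement tables are materialized per donor by inverting each
#' diversity target to a productive fraction and clone-law exponent.
#'
#' @param params a [cohort_params()] object.
#' @param records materialize full `trb_repertoire` objects (slow at study
#'   depths; intended for small integration runs).
#' @param seed integer seed; the generator is seed-deterministic end to end.
#' @return List with `samples` (diversity table: `sample_id`, `donor_id`,
#'   `age`, `sex`, `total_copies`, `status_J`, `sequence_J`), `repertoires`
#'   (list or `NULL`), and `truth` (every generating coefficient).
#' @export
simulate_cohort <- function(params = cohort_params(), records = FALSE,
                            seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  n <- params$n_donors
  age <- sample(seq(params$age_range[1L], params$age_range[2L]), n,
                replace = TRUE)
  sex <- ifelse(runif(n) < params$female_fraction, "female", "male")
  depth <- round(exp(runif(n, log(params$depth_range[1L]),
                           log(params$depth_range[2L]))))
  wt <- depth / mean(depth)
  noise_scale <- if (params$heteroskedastic) 1 / sqrt(wt) else rep(1, n)
  mu_of <- function(model, breakpoint, response) {
    mu <- vapply(seq_len(n), function(i) {
      co <- model[[sex[i]]]
      co[1L] + co[2L] * age[i]
    }, numeric(1))
    bp <- breakpoint
    if (!is.null(bp) && identical(bp$response, response)) {
      young <- age <= bp$age
      mu[young] <- bp$young[1L] + bp$young[2L] * age[young]
      mu[!young] <- bp$old[1L] + bp$old[2L] * age[!young]
    }
    mu
  }
  clamp <- function(x) pmin(0.98, pmax(0.02, x))
  mu_s <- mu_of(params$status_model, params$breakpoint, "status_J")
  mu_q <- mu_of(params$sequence_model, params$breakpoint, "sequence_J")
  status_J <- clamp(mu_s + rnorm(n, 0, params$sigma_status) * noise_scale)
  sequence_J <- clamp(mu_q + rnorm(n, 0, params$sigma_sequence) * noise_scale)
  samples <- data.frame(
    sample_id = sprintf("SYN%03d", seq_len(n)),
    donor_id = sprintf("D%03d", seq_len(n)),
    age = age, sex = sex, compartment = "whole_blood",
    total_copies = depth, status_J = status_J, sequence_J = sequence_J,
    stringsAsFactors = FALSE)
  reps <- NULL
  if (records) {
    reps <- lapply(seq_len(n), function(i) {
      k <- max(4L, round(depth[i] * params$n_clones_frac))
      simulate_repertoire(
        depth = depth[i],
        productive_fraction = invert_status_J(status_J[i], depth[i]),
        clone_law = list(exponent = invert_sequence_J(sequence_J[i], k,
                                                      depth[i]),
                         n_clones = k),
        contamination = params$contamination,
        sample_id = samples$sample_id[i], donor_id = samples$donor_id[i],
        age = age[i], sex = sex[i])
    })
    names(reps) <- samples$sample_id
  }
  list(samples = samples, repertoires = reps,
       truth = c(unclass(params), list(seed = seed, mu_status = mu_s,
                                       mu_sequence = mu_q)))
}

#' Longitudinal design generator settings
#'
#' Defaults emulate the longitudinal arm: 3 male and 3 female donors sampled
#' at 3 timepoints about 10 years apart, first visit between ages 24 and 45
#' (so all ages fall in 24-65), sorted CD4/CD8 compartments with a known
#' blood CD4/CD8 ratio, and diversity following the longitudinal
#' fixed-effect models with Gaussian donor intercepts (SD 0.05) and residual
#' SD 0.005.
#'
#' @param n_per_sex donors per sex.
#' @param n_timepoints visits per donor.
#' @param interval years between visits.
#' @param start_age_range inclusive range of first-visit ages.
#' @param status,sequence whole-blood (merged) model coefficients:
#'   `beta0`, `beta_age`, `beta_sex`, `beta_age_sex`.
#' @param status_ct,sequence_ct cell-type model coefficients (additionally
#'   `beta_age_celltype`).
#' @param donor_sd SD of per-donor intercept offsets.
#' @param celltype_sd SD of per-donor CD8 intercept offsets.
#' @param resid_sd residual SD.
#' @param ratio_range CD4/CD8 blood-ratio range per donor-timepoint.
#' @param depth_range per-compartment copy depth (log-uniform, records mode).
#' @param clone_frac clones per copy (records mode).
#' @return List of class `longitudinal_params`.
#' @export
longitudinal_params <- function(n_per_sex = 3L, n_timepoints = 3L,
                                interval = 10L, start_age_range = c(24L, 45L),
                                status = list(beta0 = 0.5823,
                                              beta_age = 0.0004,
                                              beta_sex = 0.0829,
                                              beta_age_sex = -0.0011),
                                sequence = list(beta0 = 0.9597,
                                                beta_age = -0.0008,
                                                beta_sex = -0.0698,
                                                beta_age_sex = 0),
                                status_ct = list(beta0 = 0.5712,
                                                 beta_age = 0.0006,
                                                 beta_sex = 0.0961,
                                                 beta_age_sex = -0.0014,
                                                 beta_age_celltype = 0),
                                sequence_ct = list(beta0 = 0.9468,
                                                   beta_age = 0.0002,
                                                   beta_sex = -0.0132,
                                                   beta_age_sex = -0.0003,
                                                   beta_age_celltype = -0.0037),
                                donor_sd = 0.05, celltype_sd = 0.04,
                                resid_sd = 0.005,
                                ratio_range = c(1.2, 3),
                                depth_range = c(5e5, 2e6),
                                clone_frac = 0.25) {
  structure(as.list(environment()), class = "longitudinal_params")
}

#' Simulate a longitudinal CD4/CD8 design
#'
#' Generates the repeated-measures design: per donor-timepoint, diversity
#' values following the embedded mixed-model coefficient surfaces (merged
#' whole-blood models with donor random intercepts; cell-type models with
#' additional per-donor CD8 offsets). With `records = TRUE`, sorted CD4 and
#' CD8 `trb_repertoire` pairs are materialized so that the reconstitution
#' pipeline can be exercised end to end.
#'
#' @param params a [longitudinal_params()] object.
#' @param records materialize CD4/CD8 rearrangement tables.
#' @param seed integer seed.
#' @return List with `merged` (donor x timepoint whole-blood diversity
#'   table), `celltype` (donor x timepoint x compartment table), `pairs`
#'   (list of `list(cd4 =, cd8 =, ratio =)` or `NULL`), and `truth`
#'   (embedded coefficients and drawn donor offsets).
#' @export
simulate_longitudinal <- function(params = longitudinal_params(),
                                  records = FALSE, seed = 1L) {
  stopifnot(inherits(params, "longitudinal_params"))
  set.seed(seed)
  donors <- c(paste0("M", seq_len(params$n_per_sex)),
              paste0("F", seq_len(params$n_per_sex)))
  sexes <- setNames(rep(c("male", "female"), each = params$n_per_sex), donors)
  start <- setNames(sample(seq(params$start_age_range[1L],
                               params$start_age_range[2L]),
                           length(donors), replace = TRUE), donors)
  off <- function(sd) setNames(rnorm(length(donors), 0, sd), donors)
  b4_status <- off(params$donor_sd); b4_seq <- off(params$donor_sd)
  b5_status <- off(params$donor_sd); b5_seq <- off(params$donor_sd)
  b6_status <- off(params$celltype_sd); b6_seq <- off(params$celltype_sd)
  eta <- function(co, age, female, cd8 = 0) {
    co$beta0 + co$beta_age * age + co$beta_sex * female +
      co$beta_age_sex * age * female +
      (co$beta_age_celltype %||% 0) * age * cd8
  }
  grid <- expand.grid(donor_id = donors,
                      timepoint = seq_len(params$n_timepoints),
                      stringsAsFactors = FALSE)
  grid$sex <- sexes[grid$donor_id]
  grid$age <- start[grid$donor_id] + (grid$timepoint - 1L) * params$interval
  grid$ratio <- runif(nrow(grid), params$ratio_range[1L],
                      params$ratio_range[2L])
  fem <- as.numeric(grid$sex == "female")
  merged <- grid
  merged$status_J <- eta(params$status, grid$age, fem) +
    b4_status[grid$donor_id] + rnorm(nrow(grid), 0, params$resid_sd)
  merged$sequence_J <- eta(params$sequence, grid$age, fem) +
    b4_seq[grid$donor_id] + rnorm(nrow(grid), 0, params$resid_sd)
  ct <- rbind(cbind(grid, celltype = "CD4"), cbind(grid, celltype = "CD8"))
  cd8 <- as.numeric(ct$celltype == "CD8")
  fem_ct <- as.numeric(ct$sex == "female")
  ct$status_J <- eta(params$status_ct, ct$age, fem_ct, cd8) +
    b5_status[ct$donor_id] + cd8 * b6_status[ct$donor_id] +
    rnorm(nrow(ct), 0, params$resid_sd)
  ct$sequence_J <- eta(params$sequence_ct, ct$age, fem_ct, cd8) +
    b5_seq[ct$donor_id] + cd8 * b6_seq[ct$donor_id] +
    rnorm(nrow(ct), 0, params$resid_sd)
  pairs <- NULL
  if (records) {
    pairs <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      row4 <- ct[ct$donor_id == g$donor_id & ct$timepoint == g$timepoint &
                   ct$celltype == "CD4", ]
      row8 <- ct[ct$donor_id == g$donor_id & ct$timepoint == g$timepoint &
                   ct$celltype == "CD8", ]
      mk <- function(row, comp) {
        depth <- round(exp(runif(1, log(params$depth_range[1L]),
                                 log(params$depth_range[2L]))))
        k <- max(4L, round(depth * params$clone_frac))
        simulate_repertoire(
          depth = depth,
          productive_fraction = invert_status_J(
            min(0.98, max(0.02, row$status_J)), depth),
          clone_law = list(exponent = invert_sequence_J(
            min(0.995, max(0.02, row$sequence_J)), k, depth), n_clones = k),
          sample_id = sprintf("%s_T%d_%s", g$donor_id, g$timepoint, comp),
          donor_id = g$donor_id, age = g$age, sex = g$sex,
          compartment = comp, timepoint = g$timepoint,
          cd4_cd8_ratio = g$ratio)
      }
      list(cd4 = mk(row4, "CD4"), cd8 = mk(row8, "CD8"), ratio = g$ratio)
    })
    names(pairs) <- sprintf("%s_T%d", grid$donor_id, grid$timepoint)
  }
  truth <- c(unclass(params),
             list(seed = seed, donor_sex = sexes, start_age = start,
                  b4_status = b4_status, b4_sequence = b4_seq,
                  b5_status = b5_status, b5_sequence = b5_seq,
                  b6_status = b6_status, b6_sequence = b6_seq))
  list(merged = merged, celltype = ct, pairs = pairs, truth = truth)
}
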