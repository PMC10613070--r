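test_that("frame status maps onto productive/non-productive as the CDR3 frame dictates", {
  expect_equal(classify_functionality(c("in_frame", "stop_codon",
                                        "out_of_frame")),
               c("productive", "nonproductive", "nonproductive"))
  expect_error(classify_functionality("unknown"), "upstream")
})

test_that("each sequence filter removes exactly its violating record, first rule wins", {
  rep <- toy_repertoire(
    copies = c(10L, 20L, 30L, 40L, 50L, 60L, 70L),
    v = c("TRBV21/OR9-2", "unresolved", "TRBV19-01", "TRBV19-01",
          "TRBV99-09", "TRBV03-01", "TRBV19-01"),
    j = c("TRBJ01-01", "TRBJ01-01", "unresolved", "TRBJ01-01",
          "TRBJ01-01", "TRBJ01-01", "TRBJ01-01"),
    n2 = c(33L, 33L, 33L, 10L, 33L, 33L, 33L))
  out <- curate_records(rep)
  rm <- setNames(out$report$removed_copies[1:6], out$report$filter[1:6])
  expect_equal(rm, c(orphon_v = 10, unresolved_v = 20, unresolved_j = 30,
                     indexing_error = 40, nonfunctional_or_orf_gene = 50,
                     excluded_gene = 60))
  expect_equal(out$report$retained_copies[7], 70)
  expect_equal(nrow(out$curated$records), 1L)
  # conservation
  expect_equal(sum(rm) + 70, attr(out$report, "input_copies"))

  # a record violating several rules is attributed to the first one only
  multi <- toy_repertoire(5L, v = "unresolved", j = "unresolved", n2 = 1L)
  rep2 <- curate_records(multi)$report
  expect_equal(rep2$removed_copies[rep2$filter == "unresolved_v"], 5)
  expect_equal(sum(rep2$removed_copies[rep2$filter != "unresolved_v"],
                   na.rm = TRUE), 0)
})

test_that("gene-call normalization makes vendor spellings match", {
  expect_equal(normalize_gene_call(c(" TCRBV03-01*02 ", "TRBV3-1",
                                     "TRBJ01-02")),
               c("TRBV3-1", "TRBV3-1", "TRBJ1-2"))
})

test_that("missing cdr3/n2 annotations are not indexing errors", {
  rep <- toy_repertoire(c(5L, 7L), cdr3 = c(NA, 24L), n2 = c(10L, NA))
  report <- curate_records(rep)$report
  expect_equal(report$removed_copies[report$filter == "indexing_error"], 0)
  expect_equal(report$retained_copies[report$filter == "retained"], 12)
})

test_that("curation conserves copies, is idempotent, and collapses clones", {
  set.seed(42)
  rep <- simulate_repertoire(depth = 2e4, productive_fraction = 0.8,
                             clone_law = list(n_clones = 500),
                             contamination = c(orphon_v = 0.02,
                                               unresolved_v = 0.1,
                                               unresolved_j = 0.02,
                                               indexing_error = 0.02,
                                               nonfunctional_or_orf_gene = 0.03,
                                               excluded_gene = 0.01))
  out <- curate_records(rep)
  rm_tot <- sum(out$report$removed_copies, na.rm = TRUE)
  kept <- out$report$retained_copies[out$report$filter == "retained"]
  expect_identical(rm_tot + kept, attr(out$report, "input_copies"))
  expect_identical(kept, total_copies(out$curated))
  expect_false(anyDuplicated(out$curated$records$nucleotide) > 0)
  # idempotence: a second pass removes nothing
  again <- curate_records(out$curated)
  expect_equal(sum(again$report$removed_copies, na.rm = TRUE), 0)
  expect_equal(again$curated$records, out$curated$records)
})

test_that("metadata filter drops exactly the samples lacking age or sex", {
  cohort <- list(toy_repertoire(5L, age = 30L, sex = "male"),
                 toy_repertoire(5L, age = NA, sex = "male"),
                 toy_repertoire(5L, age = 20L, sex = "female"))
  fm <- filter_metadata(cohort)
  expect_length(fm$kept, 2L)
  expect_length(fm$dropped, 1L)
  expect_true(is.na(fm$dropped[[1]]$age))
  all_ok <- filter_metadata(cohort[c(1, 3)])
  expect_length(all_ok$dropped, 0L)
  expect_equal(all_ok$kept, cohort[c(1, 3)])
})

test_that("outlier screen flags extreme totals and matches a step-by-step fence oracle", {
  set.seed(7)
  x <- c(round(rlnorm(20, log(1e6), 0.3)), 1e9)
  flags <- detect_outlier_samples(x)
  expect_true(flags[21])
  expect_equal(sum(flags), 1L)
  fences <- oracle_gh_fences(x)
  expect_equal(flags, x < fences[1] | x > fences[2])
})

test_that("outlier screen degenerates gracefully and agrees with a classical boxplot on symmetric data", {
  expect_equal(detect_outlier_samples(rep(1e6, 10)), rep(FALSE, 10))
  expect_error(detect_outlier_samples(c(1, 2, 3)), "at least 8")
  set.seed(8)
  # bulk truncated at 2.2 sigma so no borderline points sit near the fences
  bulk <- 100 + 5 * pmax(pmin(rnorm(60), 2.2), -2.2)
  x <- c(bulk, 160, 40)  # clear 12-sigma outliers
  flags <- detect_outlier_samples(x)
  q <- quantile(x, c(0.25, 0.75)); iqr <- diff(q)
  tukey <- x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
  expect_equal(flags, tukey)
})

test_that("cohort curation chains metadata, outlier and sequence filters with full accounting", {
  set.seed(9)
  cohort <- c(
    lapply(1:9, function(i)
      simulate_repertoire(depth = 5e3, clone_law = list(n_clones = 200),
                          sample_id = paste0("S", i), age = 20 + i,
                          sex = "male",
                          contamination = c(unresolved_v = 0.1))),
    list(simulate_repertoire(depth = 5e3, clone_law = list(n_clones = 200),
                             sample_id = "NOMETA")))
  out <- curate_cohort(cohort, outlier_alpha = 0.007)
  s <- out$summary
  expect_equal(s$removed_samples[s$filter == "missing_metadata"], 1)
  input <- sum(vapply(cohort, total_copies, numeric(1)))
  expect_equal(sum(s$removed_copies, na.rm = TRUE) +
                 s$retained_copies[s$filter == "retained"], input)
  expect_length(out$curated, s$retained_samples[s$filter == "retained"])
})
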