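test_that("subsampling at full depth is the identity and draws are exact in size", {
  rep <- toy_repertoire(c(50L, 30L, 20L))
  expect_identical(subsample_to_depth(rep, 100, seed = 1), rep)
  sub <- subsample_to_depth(rep, 37, seed = 1)
  expect_equal(total_copies(sub), 37)
  one <- subsample_to_depth(rep, 1, seed = 2)
  expect_equal(total_copies(one), 1)
  expect_equal(nrow(one$records), 1L)
  expect_error(subsample_to_depth(rep, 101), "exceeds total copies")
})

test_that("per-clone draws follow hypergeometric moments and never inflate counts", {
  rep <- toy_repertoire(c(60L, 30L, 10L))
  set.seed(3)
  draws <- t(replicate(1000, {
    s <- subsample_to_depth(rep, 20)
    out <- setNames(rep(0, 3), rep$records$nucleotide)
    out[s$records$nucleotide] <- s$records$copy_count
    out
  }))
  expect_true(all(draws <= matrix(c(60, 30, 10), 1000, 3, byrow = TRUE)))
  # E[k_i] = depth * p_i; SE of the replicate mean from the hypergeometric SD
  for (i in 1:3) {
    p <- c(0.6, 0.3, 0.1)[i]
    expv <- 20 * p
    sdv <- sqrt(20 * p * (1 - p) * (100 - 20) / (100 - 1))
    expect_lt(abs(mean(draws[, i]) - expv), 3 * sdv / sqrt(1000))
  }
})

test_that("depth subsampling with a fixed seed is reproducible", {
  rep <- toy_repertoire(c(500L, 300L, 200L))
  a <- subsample_to_depth(rep, 123, seed = 99)
  b <- subsample_to_depth(rep, 123, seed = 99)
  expect_identical(a, b)
  prof1 <- depth_profile(rep, depths = c(50, 200), n_replicates = 10, seed = 5)
  prof2 <- depth_profile(rep, depths = c(50, 200), n_replicates = 10, seed = 5)
  expect_identical(as.data.frame(prof1), as.data.frame(prof2))
})

test_that("depth profiles skip unreachable coverages and record replicate spread", {
  set.seed(6)
  rep <- simulate_repertoire(depth = 3e4, clone_law = list(n_clones = 5e3))
  prof <- depth_profile(rep, depths = c(1e3, 1e4, 1e5), n_replicates = 20,
                        seed = 6)
  expect_equal(prof$skipped, c(FALSE, FALSE, TRUE))
  expect_true(all(is.na(prof$status_J_mean[3])))
  expect_true(all(prof$status_J_sd[1:2] >= 0))
  # replicate SD shrinks with depth roughly as 1/sqrt(depth)
  expect_gt(prof$status_J_sd[1], prof$status_J_sd[2])
})

test_that("merge planning reproduces the ratio arithmetic", {
  plan <- plan_merge(1000, 1000, 3)
  expect_equal(plan$overrepresented, "CD8")
  expect_equal(plan$take_cd4, 1000)
  expect_equal(plan$take_cd8, round(1000 / 3))
  expect_equal(plan$target_cd4_fraction, 0.75)
  expect_equal(1000 / (1000 + plan$take_cd8), 0.75, tolerance = 1e-3)

  bal <- plan_merge(300, 100, 3)
  expect_equal(bal$overrepresented, "none")
  expect_equal(c(bal$take_cd4, bal$take_cd8), c(300, 100))

  p2 <- plan_merge(200, 100, 1)
  expect_equal(p2$overrepresented, "CD4")
  expect_equal(c(p2$take_cd4, p2$take_cd8), c(100, 100))
  expect_error(plan_merge(10, 10, -1), "positive")
})

test_that("merged CD4 fraction hits r/(1+r) within rounding for random inputs", {
  set.seed(20)
  for (i in 1:200) {
    n4 <- sample(100:10000, 1); n8 <- sample(100:10000, 1)
    r <- runif(1, 0.2, 5)
    plan <- plan_merge(n4, n8, r)
    frac <- plan$take_cd4 / (plan$take_cd4 + plan$take_cd8)
    expect_lt(abs(frac - r / (1 + r)),
              1 / min(plan$take_cd4, plan$take_cd8))
  }
})

test_that("reconstitution preserves totals, averages replicates, and is symmetric at balance", {
  set.seed(21)
  base <- simulate_repertoire(depth = 2e4, productive_fraction = 0.8,
                              clone_law = list(n_clones = 2e3))
  cd4 <- base; cd4$compartment <- "CD4"
  cd8 <- base; cd8$compartment <- "CD8"
  rec <- reconstitute_whole_blood(cd4, cd8, ratio = 1, n_replicates = 20,
                                  seed = 8)
  expect_equal(nrow(rec$replicates), 20L)
  # identical compartments at r = 1: merged indices equal the common values
  expect_equal(rec$status_J, status_diversity(base)$J, tolerance = 5e-3)
  expect_equal(rec$sequence_J, sequence_diversity(base)$J, tolerance = 2e-2)
  # exact copy accounting every replicate: merged total = kept + drawn
  expect_true(all(rec$replicates$copies == rec$plan$take_cd4 +
                    rec$plan$take_cd8))
  mism <- cd8; mism$donor_id <- "OTHER"
  expect_error(reconstitute_whole_blood(cd4, mism, ratio = 1),
               "mismatched donor ids")
  expect_error(reconstitute_whole_blood(cd8, cd4, ratio = 1), "compartments")
})

test_that("merged status evenness matches the copy-weighted mixture prediction", {
  set.seed(22)
  cd4 <- simulate_repertoire(depth = 3e4, productive_fraction = 0.9,
                             clone_law = list(n_clones = 3e3),
                             compartment = "CD4", sample_id = "D1_CD4",
                             donor_id = "D1")
  cd8 <- simulate_repertoire(depth = 3e4, productive_fraction = 0.7,
                             clone_law = list(n_clones = 3e3),
                             compartment = "CD8", sample_id = "D1_CD8",
                             donor_id = "D1")
  r <- 2
  rec <- reconstitute_whole_blood(cd4, cd8, ratio = r, n_replicates = 40,
                                  seed = 9)
  f4 <- sum(cd4$records$copy_count[cd4$records$frame_status == "in_frame"]) /
    total_copies(cd4)
  f8 <- sum(cd8$records$copy_count[cd8$records$frame_status == "in_frame"]) /
    total_copies(cd8)
  w4 <- r / (1 + r)
  fmix <- w4 * f4 + (1 - w4) * f8
  pred <- as.numeric(pielou_index(count_vector(
    round(c(fmix, 1 - fmix) * 1e5), S = 2)))
  se <- sd(rec$replicates$status_J) / sqrt(nrow(rec$replicates))
  expect_lt(abs(rec$status_J - pred), 3 * se + 2e-3)
})
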