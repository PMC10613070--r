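#' Subsample a repertoire to a fixed depth without replacement
#'
#' Draws exactly `depth` copies from the finite pool of observed copies
#' (a multivariate hypergeometric draw over clones). Clones drawn to zero
#' copies disappear; metadata is preserved. Without-replacement semantics make
#' subsampling at the full depth the identity.
#'
#' @param rep a `trb_repertoire`.
#' @param depth target total copy count, `1 <= depth <= total_copies(rep)`.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A `trb_repertoire` with total copies exactly `depth`.
#' @export
subsample_to_depth <- function(rep, depth, seed = NULL) {
  stopifnot(inherits(rep, "trb_repertoire"))
  depth <- as.numeric(depth)
  if (depth < 1) stop("depth must be >= 1")
  tot <- total_copies(rep)
  if (depth > tot)
    stop("depth (", depth, ") exceeds total copies (", tot,
         "); samples below a threshold must be excluded by the caller")
  if (!is.null(seed)) set.seed(seed)
  if (depth == tot) return(rep)
  drawn <- .rmvhyper_cpp(rep$records$copy_count, depth)
  keep <- drawn > 0L
  out <- rep
  out$records <- rep$records[keep, , drop = FALSE]
  out$records$copy_count <- drawn[keep]
  rownames(out$records) <- NULL
  out
}

#' Diversity across fixed subsampling depths
#'
#' For each target coverage, subsamples the repertoire `n_replicates` times
#' and averages Status and Sequence Diversity across replicates. Depths
#' exceeding the repertoire's total copies are skipped and recorded, mirroring
#' the fact that only a fraction of samples reaches the deepest thresholds.
#'
#' @param rep a curated `trb_repertoire`.
#' @param depths ascending vector of target coverages. The study grid is
#'   `c(1e4, 8e4, 1.5e5, 5e5, 1e6, 2e6, 4e6)`.
#' @param n_replicates subsampling repeats per depth (default 100).
#' @param seed master seed; per-replicate stream seeds are derived from it and
#'   recorded in the result.
#' @return A data frame of class `depth_profile`: per depth, replicate count,
#'   mean and SD of `status_J` and `sequence_J`, and a `skipped` flag.
#' @export
depth_profile <- function(rep, depths = c(1e4, 8e4, 1.5e5, 5e5, 1e6, 2e6, 4e6),
                          n_replicates = 100L, seed = 1L) {
  stopifnot(inherits(rep, "trb_repertoire"))
  if (is.unsorted(depths)) stop("depths must be sorted ascending")
  tot <- total_copies(rep)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  rows <- lapply(depths, function(d) {
    if (d > tot)
      return(data.frame(depth = d, n_replicates = 0L, skipped = TRUE,
                        status_J_mean = NA, status_J_sd = NA,
                        sequence_J_mean = NA, sequence_J_sd = NA))
    js <- vapply(rep_seeds, function(s) {
      sub <- subsample_to_depth(rep, d, seed = s)
      c(status_diversity(sub)$J, sequence_diversity(sub)$J)
    }, numeric(2))
    data.frame(depth = d, n_replicates = n_replicates, skipped = FALSE,
               status_J_mean = mean(js[1L, ]), status_J_sd = sd(js[1L, ]),
               sequence_J_mean = mean(js[2L, ]), sequence_J_sd = sd(js[2L, ]))
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "replicate_seeds") <- rep_seeds
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Plan a ratio-consistent CD4/CD8 merge
#'
#' Computes how many copies to draw from the overrepresented sorted
#' compartment so that the merged sample's CD4 copy fraction equals
#' `r / (1 + r)` for blood CD4/CD8 ratio `r`, up to integer rounding
#' (round-half-to-even). If `n_cd4 / n_cd8 > r`, CD4 is overrepresented:
#' draw `round(r * n_cd8)` copies from CD4 and keep all of CD8; otherwise
#' draw `round(n_cd4 / r)` from CD8 and keep all of CD4.
#'
#' @param n_cd4,n_cd8 total copies observed in the sorted CD4 and CD8 samples.
#' @param ratio blood CD4/CD8 ratio `r > 0`.
#' @return List with `target_cd4_fraction`, `overrepresented`, `take_cd4`,
#'   `take_cd8` (copies to retain from each compartment).
#' @export
plan_merge <- function(n_cd4, n_cd8, ratio) {
  if (ratio <= 0) stop("CD4/CD8 ratio must be positive")
  if (n_cd4 < 1 || n_cd8 < 1) stop("both compartments need at least one copy")
  if (n_cd4 / n_cd8 > ratio) {
    take_cd4 <- round(ratio * n_cd8); take_cd8 <- n_cd8
    over <- "CD4"
  } else if (n_cd4 / n_cd8 < ratio) {
    take_cd4 <- n_cd4; take_cd8 <- round(n_cd4 / ratio)
    over <- "CD8"
  } else {
    take_cd4 <- n_cd4; take_cd8 <- n_cd8
    over <- "none"
  }
  list(target_cd4_fraction = ratio / (1 + ratio), overrepresented = over,
       take_cd4 = take_cd4, take_cd8 = take_cd8)
}

#' Reconstitute a whole-blood repertoire from sorted CD4/CD8 samples
#'
#' Each replicate draws the planned number of copies from the overrepresented
#' compartment without replacement ([subsample_to_depth()]), concatenates the
#' two compartments, re-runs sequence-level curation and clone collapsing on
#' the merged sample, and computes Status and Sequence Diversity. The final
#' diversity estimates are the means over replicates; one representative
#' merged repertoire (first replicate) is returned for inspection.
#'
#' @param cd4,cd8 `trb_repertoire` objects of compartments `"CD4"` and
#'   `"CD8"` from the same donor and timepoint.
#' @param ratio blood CD4/CD8 ratio; defaults to the `cd4_cd8_ratio` metadata
#'   of the CD4 sample.
#' @param n_replicates merge repeats (default 100).
#' @param seed master seed for the replicate streams.
#' @param ref gene reference for the re-curation pass; `NULL` skips
#'   re-curation (useful when inputs are already curated and synthetic).
#' @return List of class `reconstitution`: `status_J`, `sequence_J`
#'   (replicate means), `replicates` (per-replicate data frame), `plan`,
#'   `merged` (representative merged repertoire).
#' @export
reconstitute_whole_blood <- function(cd4, cd8, ratio = cd4$cd4_cd8_ratio,
                                     n_replicates = 100L, seed = 1L,
                                     ref = NULL) {
  stopifnot(inherits(cd4, "trb_repertoire"), inherits(cd8, "trb_repertoire"))
  if (!identical(cd4$donor_id, cd8$donor_id))
    stop("mismatched donor ids: '", cd4$donor_id, "' vs '", cd8$donor_id, "'")
  if (!identical(cd4$compartment, "CD4") || !identical(cd8$compartment, "CD8"))
    stop("inputs must be the CD4 and CD8 compartments, in that order")
  if (is.na(ratio)) stop("no CD4/CD8 ratio available")
  plan <- plan_merge(total_copies(cd4), total_copies(cd8), ratio)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  merged_example <- NULL
  rows <- lapply(seq_len(n_replicates), function(i) {
    set.seed(rep_seeds[i])
    a <- if (plan$take_cd4 < total_copies(cd4))
      subsample_to_depth(cd4, plan$take_cd4) else cd4
    b <- if (plan$take_cd8 < total_copies(cd8))
      subsample_to_depth(cd8, plan$take_cd8) else cd8
    merged <- a
    merged$records <- rbind(a$records, b$records)
    merged$compartment <- "whole_blood"
    merged <- if (is.null(ref)) collapse_clones(merged)
              else curate_records(merged, ref)$curated
    if (i == 1L) merged_example <<- merged
    data.frame(replicate = i, seed = rep_seeds[i],
               copies = total_copies(merged),
               status_J = status_diversity(merged)$J,
               sequence_J = sequence_diversity(merged)$J)
  })
  replicates <- do.call(rbind, rows)
  structure(list(status_J = mean(replicates$status_J),
                 sequence_J = mean(replicates$sequence_J),
                 replicates = replicates, plan = plan,
                 merged = merged_example, seed = seed),
            class = "reconstitution")
}

#' @export
print.reconstitution <- function(x, ...) {
  cat(sprintf(paste0("Reconstituted whole blood (%d replicates): ",
                     "status_J = %.4f, sequence_J = %.4f\n"),
              nrow(x$replicates), x$status_J, x$sequence_J))
  cat(sprintf("  merge plan: keep %s CD4 / %s CD8 (target CD4 fraction %.3f)\n",
              format(x$plan$take_cd4), format(x$plan$take_cd8),
              x$plan$target_cd4_fraction))
  invisible(x)
}
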