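#' Class-count vector for diversity computations
#'
#' Holds per-class counts together with the number of classes `S`, which may
#' exceed the number of non-zero classes when the scheme fixes `S` (the
#' two-class productive/non-productive status scheme always has `S = 2`).
#'
#' @param counts non-negative integer vector of per-class counts.
#' @param S number of classes; defaults to `length(counts)`.
#' @return An object of class `count_vector` with fields `counts`, `S`, `N`.
#' @export
count_vector <- function(counts, S = length(counts)) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-empty")
  if (S < length(counts)) stop("S cannot be smaller than length(counts)")
  N <- sum(counts)
  if (N < 1) stop("total count N must be >= 1")
  structure(list(counts = counts, S = as.integer(S), N = N),
            class = "count_vector")
}

#' Bias-corrected Shannon entropy
#'
#' Computes the finite-sample corrected Shannon entropy, in nats:
#' \deqn{H = -\sum_i p_i \ln p_i - (S - 1)/(2N)}
#' with `p_i = counts_i / N`. Zero-count classes contribute nothing to the sum
#' (the `0 ln 0 = 0` convention) but do count in `S` when the scheme fixes
#' `S`. The correction can push near-degenerate cases below zero; the returned
#' value is clamped at 0, with the unclamped value in attribute `"raw"`.
#'
#' @param cv a [count_vector()] (a bare numeric vector is promoted).
#' @return Entropy in nats (clamped at 0; `attr(, "raw")` holds the raw
#'   value).
#' @export
shannon_basharin <- function(cv) {
  if (!inherits(cv, "count_vector")) cv <- count_vector(cv)
  p <- cv$counts[cv$counts > 0] / cv$N
  raw <- -sum(p * log(p)) - (cv$S - 1) / (2 * cv$N)
  structure(max(0, raw), raw = raw)
}

#' Pielou's evenness index
#'
#' \deqn{J = H / \ln S} with `H` the Basharin-corrected Shannon entropy
#' ([shannon_basharin()]). `J` ranges from 0 (one class dominates) to 1 (all
#' classes evenly represented) and is clamped to that interval; the unclamped
#' value is kept in attribute `"raw"`.
#'
#' @param cv a [count_vector()] (a bare numeric vector is promoted).
#' @return Evenness in `[0, 1]`.
#' @export
pielou_index <- function(cv) {
  if (!inherits(cv, "count_vector")) cv <- count_vector(cv)
  if (cv$S < 2L) stop("evenness undefined for a single class")
  H <- shannon_basharin(cv)
  raw <- attr(H, "raw") / log(cv$S)
  structure(min(1, max(0, raw)), raw = raw)
}

div_result <- function(H, J, S, N, scheme) {
  structure(list(H = as.numeric(H), J = as.numeric(J),
                 H_raw = attr(H, "raw"), J_raw = attr(J, "raw"),
                 S = S, N = N, scheme = scheme),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("%s diversity: J = %.6f (H = %.6f nats, S = %d, N = %s)\n",
              switch(x$scheme, status = "Status", sequence = "Sequence"),
              x$J, x$H, x$S, format(x$N, big.mark = ",")))
  invisible(x)
}

#' Status Diversity: evenness of productive vs non-productive copies
#'
#' Pielou's J over the two-class scheme (productive, non-productive), with
#' every copy of every rearrangement counted; `S` is fixed at 2 regardless of
#' whether one class is empty. Low values mean productive copies dominate.
#'
#' @param rep a curated `trb_repertoire`.
#' @return A `diversity_result`.
#' @export
status_diversity <- function(rep) {
  stopifnot(inherits(rep, "trb_repertoire"))
  if (nrow(rep$records) == 0L || total_copies(rep) == 0)
    stop("zero total copies")
  cls <- classify_functionality(rep$records$frame_status)
  copies <- as.numeric(rep$records$copy_count)
  counts <- c(productive = sum(copies[cls == "productive"]),
              nonproductive = sum(copies[cls == "nonproductive"]))
  cv <- count_vector(counts, S = 2L)
  div_result(shannon_basharin(cv), pielou_index(cv), 2L, cv$N, "status")
}

#' Sequence Diversity: evenness of the clone-size distribution
#'
#' Pielou's J over clone copy counts: classes are unique rearranged TRB
#' nucleotide sequences (clones), `S` the observed clone count. By convention
#' the index is computed on productive clones only; set
#' `productive_only = FALSE` to use all clones. Low values mean a more uneven
#' (more clonal) repertoire.
#'
#' @param rep a curated `trb_repertoire` (clone-collapsed; collapsing is
#'   applied if needed).
#' @param productive_only restrict to productive clones (default `TRUE`).
#' @return A `diversity_result`.
#' @export
sequence_diversity <- function(rep, productive_only = TRUE) {
  stopifnot(inherits(rep, "trb_repertoire"))
  rep <- collapse_clones(rep)
  rec <- rep$records
  if (productive_only)
    rec <- rec[classify_functionality(rec$frame_status) == "productive", ,
               drop = FALSE]
  if (nrow(rec) < 2L)
    stop("fewer than 2 clones: evenness undefined for a single class")
  cv <- count_vector(as.numeric(rec$copy_count))
  div_result(shannon_basharin(cv), pielou_index(cv), cv$S, cv$N, "sequence")
}

#' Per-sample diversity table for a cohort
#'
#' @param cohort list of curated `trb_repertoire` objects.
#' @param productive_only passed to [sequence_diversity()].
#' @return Data frame with one row per sample: metadata, `N` (total copies),
#'   `S` (clone count), `status_J`, `sequence_J`.
#' @export
cohort_diversity <- function(cohort, productive_only = TRUE) {
  rows <- lapply(cohort, function(r) {
    sdiv <- status_diversity(r)
    qdiv <- sequence_diversity(r, productive_only = productive_only)
    data.frame(sample_id = r$sample_id, donor_id = r$donor_id,
               age = r$age, sex = r$sex, compartment = r$compartment,
               timepoint = r$timepoint,
               N = sdiv$N, S = qdiv$S,
               status_J = sdiv$J, sequence_J = qdiv$J,
               total_copies = total_copies(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
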