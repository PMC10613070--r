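#' Construct a TRB repertoire
#'
#' A repertoire is one donor-sample's collection of rearranged TRB nucleotide
#' sequences ("records") plus sample metadata. Records are held as a data frame
#' with one row per unique rearrangement as reported by the sequencing
#' platform; identical nucleotide sequences are *not* merged at construction
#' time (clone collapsing is a curation step, see [collapse_clones()]).
#'
#' @param records data frame with columns `nucleotide` (uppercase ACGTN),
#'   `copy_count` (positive integer template/read count), `v_call`, `d_call`,
#'   `j_call` (gene-name strings; `""` allowed for D, `"unresolved"` sentinel
#'   for V/J), `frame_status` (one of `"in_frame"`, `"out_of_frame"`,
#'   `"stop_codon"`, `"unknown"`) and optionally `cdr3_start`, `n2_start`
#'   (0-based indices into `nucleotide`, `NA` when not annotated).
#' @param sample_id,donor_id sample and donor identifiers.
#' @param age donor age in completed years (`NA` when unknown).
#' @param sex `"male"`, `"female"` or `NA`.
#' @param compartment `"whole_blood"`, `"CD4"` or `"CD8"`.
#' @param timepoint integer visit index or `NA`.
#' @param cd4_cd8_ratio blood CD4/CD8 ratio measured for the sample, or `NA`.
#'
#' @return An object of class `trb_repertoire`.
#' @export
new_repertoire <- function(records, sample_id, donor_id = sample_id,
                           age = NA_integer_, sex = NA_character_,
                           compartment = "whole_blood",
                           timepoint = NA_integer_,
                           cd4_cd8_ratio = NA_real_) {
  records <- validate_records(records)
  if (!is.na(sex) && !sex %in% c("male", "female"))
    stop("sex must be 'male', 'female' or NA")
  compartment <- match.arg(compartment, .compartments)
  if (!is.na(cd4_cd8_ratio) && cd4_cd8_ratio <= 0)
    stop("cd4_cd8_ratio must be positive")
  structure(list(
    records = records,
    sample_id = as.character(sample_id),
    donor_id = as.character(donor_id),
    age = if (is.na(age)) NA_integer_ else as.integer(age),
    sex = as.character(sex),
    compartment = compartment,
    timepoint = if (is.na(timepoint)) NA_integer_ else as.integer(timepoint),
    cd4_cd8_ratio = as.numeric(cd4_cd8_ratio)
  ), class = "trb_repertoire")
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("nucleotide", "copy_count", "v_call", "d_call", "j_call",
              "frame_status")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  if (!"cdr3_start" %in% names(records)) records$cdr3_start <- NA_integer_
  if (!"n2_start" %in% names(records)) records$n2_start <- NA_integer_
  records$copy_count <- as.integer(records$copy_count)
  if (nrow(records)) {
    if (anyNA(records$copy_count) || any(records$copy_count < 1L))
      stop("copy_count must be a positive integer for every record")
    bad <- !records$frame_status %in% .frame_levels
    if (any(bad))
      stop("unknown frame_status value(s): ",
           paste(unique(records$frame_status[bad]), collapse = ", "))
    len <- nchar(records$nucleotide)
    for (col in c("cdr3_start", "n2_start")) {
      idx <- records[[col]]
      out <- !is.na(idx) & (idx < 0L | idx > len)
      if (any(out)) stop(col, " outside [0, nchar(nucleotide)] for some records")
    }
  }
  rownames(records) <- NULL
  records[c(needed, "cdr3_start", "n2_start")]
}

#' Total sequence copies in a repertoire
#'
#' The copy (template) count is the unit of "sequences" throughout: every
#' diversity denominator is copy-weighted, not clone-weighted.
#'
#' @param rep a `trb_repertoire`.
#' @return Total copy count (numeric, to avoid integer overflow at deep
#'   coverage).
#' @export
total_copies <- function(rep) {
  stopifnot(inherits(rep, "trb_repertoire"))
  sum(as.numeric(rep$records$copy_count))
}

#' Collapse records into clones
#'
#' A clone is the set of copies sharing one rearranged TRB nucleotide sequence.
#' Records with identical `nucleotide` are merged and their copy counts summed;
#' gene calls and annotations are taken from the first record of each clone
#' (identical nucleotide implies identical annotation in practice).
#'
#' @param rep a `trb_repertoire`.
#' @return A `trb_repertoire` with one record per clone.
#' @export
collapse_clones <- function(rep) {
  stopifnot(inherits(rep, "trb_repertoire"))
  rec <- rep$records
  if (nrow(rec) < 2L || !anyDuplicated(rec$nucleotide)) return(rep)
  first <- !duplicated(rec$nucleotide)
  tot <- rowsum(as.numeric(rec$copy_count), rec$nucleotide, reorder = FALSE)
  out <- rec[first, , drop = FALSE]
  out$copy_count <- as.integer(tot[match(out$nucleotide, rownames(tot)), 1L])
  rownames(out) <- NULL
  rep$records <- out
  rep
}

#' @export
print.trb_repertoire <- function(x, ...) {
  cat("TRB repertoire '", x$sample_id, "' (donor ", x$donor_id, ")\n", sep = "")
  cat("  compartment:", x$compartment,
      " age:", ifelse(is.na(x$age), "<absent>", x$age),
      " sex:", ifelse(is.na(x$sex), "<absent>", x$sex), "\n")
  cat("  records:", nrow(x$records),
      " total copies:", format(total_copies(x), big.mark = ","), "\n")
  invisible(x)
}

#' @export
summary.trb_repertoire <- function(object, ...) {
  st <- table(factor(object$records$frame_status, levels = .frame_levels))
  cat("TRB repertoire summary for", object$sample_id, "\n")
  print(st)
  cat("total copies:", total_copies(object), "\n")
  invisible(object)
}
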