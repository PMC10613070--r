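#' Default column mappings for the supported TSV dialects
#'
#' immunoSEQ export column names vary across export versions; the mapping is
#' therefore fully user-overridable. Index columns are taken to be 0-based for
#' the immunoSEQ dialect and 1-based for AIRR (converted to the internal
#' 0-based convention on read).
#'
#' @param dialect `"immunoseq"` or `"airr"`.
#' @return Named list mapping schema roles to column names.
#' @export
default_column_map <- function(dialect = c("immunoseq", "airr")) {
  dialect <- match.arg(dialect)
  if (dialect == "immunoseq") {
    list(nucleotide = "nucleotide", copy_count = "templates",
         v_call = "vGeneName", d_call = "dGeneName", j_call = "jGeneName",
         frame = "sequenceStatus", cdr3_start = "cdr3Index",
         n2_start = "n2Index", index_base = 0L)
  } else {
    list(nucleotide = "sequence", copy_count = "duplicate_count",
         v_call = "v_call", d_call = "d_call", j_call = "j_call",
         frame = "productive", stop_codon = "stop_codon",
         cdr3_start = "cdr3_start", n2_start = "n2_start", index_base = 1L)
  }
}

parse_frame_immunoseq <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("in", "in-frame", "inframe", "productive")] <- "in_frame"
  out[x %in% c("out", "out-of-frame", "outofframe")] <- "out_of_frame"
  out[x %in% c("stop", "has stop", "stop codon")] <- "stop_codon"
  out
}

parse_frame_airr <- function(productive, stop_codon = NULL) {
  p <- tolower(trimws(productive)) %in% c("t", "true", "1", "yes")
  s <- if (is.null(stop_codon)) rep(FALSE, length(p)) else
    tolower(trimws(stop_codon)) %in% c("t", "true", "1", "yes")
  ifelse(p, "in_frame", ifelse(s, "stop_codon", "out_of_frame"))
}

#' Read a rearrangement table into a repertoire
#'
#' Parses a tab-separated rearrangement table (immunoSEQ export dialect or
#' AIRR Rearrangement TSV) into a [new_repertoire()] object. Rows are kept
#' as-is: identical nucleotide sequences are not merged at read time.
#'
#' @param path path to the TSV file.
#' @param dialect `"immunoseq"` or `"airr"`.
#' @param column_map overrides merged over [default_column_map()]. Set
#'   `index_base = 1L` for files whose index columns are 1-based.
#' @param sample_id,donor_id,age,sex,compartment,timepoint,cd4_cd8_ratio sample
#'   metadata attached to the repertoire (usually taken from a manifest).
#' @return A `trb_repertoire`.
#' @export
read_repertoire <- function(path, dialect = c("immunoseq", "airr"),
                            column_map = list(),
                            sample_id = basename(path), donor_id = sample_id,
                            age = NA, sex = NA, compartment = "whole_blood",
                            timepoint = NA, cd4_cd8_ratio = NA) {
  dialect <- match.arg(dialect)
  map <- modifyList(default_column_map(dialect), column_map)
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE,
                    colClasses = "character")
  if (nrow(tab) == 0L) stop("empty repertoire: ", path)
  roles <- c("nucleotide", "copy_count", "v_call", "d_call", "j_call", "frame")
  for (role in roles) {
    col <- map[[role]]
    if (!col %in% names(tab))
      stop("schema error: mapped column '", col, "' (role '", role,
           "') not found in ", path)
  }
  cc <- suppressWarnings(as.numeric(tab[[map$copy_count]]))
  if (anyNA(cc)) {
    bad <- which(is.na(cc))[1L]
    stop("non-numeric copy count '", tab[[map$copy_count]][bad],
         "' at data line ", bad, " of ", path)
  }
  get_idx <- function(role) {
    col <- map[[role]]
    if (is.null(col) || !col %in% names(tab)) return(rep(NA_integer_, nrow(tab)))
    v <- suppressWarnings(as.integer(tab[[col]]))
    v[tab[[col]] %in% c("", "NA", "-1")] <- NA_integer_
    v - map$index_base
  }
  frame <- if (dialect == "immunoseq") {
    parse_frame_immunoseq(tab[[map$frame]])
  } else {
    sc <- if (!is.null(map$stop_codon) && map$stop_codon %in% names(tab))
      tab[[map$stop_codon]] else NULL
    parse_frame_airr(tab[[map$frame]], sc)
  }
  records <- data.frame(
    nucleotide = toupper(trimws(tab[[map$nucleotide]])),
    copy_count = as.integer(round(cc)),
    v_call = trimws(tab[[map$v_call]]),
    d_call = trimws(tab[[map$d_call]]),
    j_call = trimws(tab[[map$j_call]]),
    frame_status = frame,
    cdr3_start = get_idx("cdr3_start"),
    n2_start = get_idx("n2_start"),
    stringsAsFactors = FALSE
  )
  new_repertoire(records, sample_id = sample_id, donor_id = donor_id,
                 age = if (is.na(age)) NA_integer_ else as.integer(age),
                 sex = as.character(sex),
                 compartment = compartment,
                 timepoint = if (is.na(timepoint)) NA_integer_ else as.integer(timepoint),
                 cd4_cd8_ratio = as.numeric(cd4_cd8_ratio))
}

#' Write a repertoire to a rearrangement TSV
#'
#' Round-trip stable: `read_repertoire(write_repertoire(rep))` reproduces the
#' records, copy counts and metadata exactly. A JSON metadata sidecar
#' (`<path>.meta.json`) carries the sample metadata.
#'
#' @param rep a `trb_repertoire` with at least one record.
#' @param path output file path.
#' @param dialect `"immunoseq"` or `"airr"`.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path, dialect = c("immunoseq", "airr")) {
  stopifnot(inherits(rep, "trb_repertoire"))
  dialect <- match.arg(dialect)
  if (nrow(rep$records) == 0L)
    stop("refusing to write a repertoire with 0 records")
  rec <- rep$records
  if (dialect == "immunoseq") {
    frame <- c(in_frame = "In", out_of_frame = "Out", stop_codon = "Stop",
               unknown = "Unknown")[rec$frame_status]
    out <- data.frame(nucleotide = rec$nucleotide, templates = rec$copy_count,
                      vGeneName = rec$v_call, dGeneName = rec$d_call,
                      jGeneName = rec$j_call, sequenceStatus = frame,
                      cdr3Index = rec$cdr3_start, n2Index = rec$n2_start,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(sequence = rec$nucleotide,
                      duplicate_count = rec$copy_count,
                      v_call = rec$v_call, d_call = rec$d_call,
                      j_call = rec$j_call,
                      productive = rec$frame_status == "in_frame",
                      stop_codon = rec$frame_status == "stop_codon",
                      cdr3_start = rec$cdr3_start + 1L,
                      n2_start = rec$n2_start + 1L,
                      stringsAsFactors = FALSE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  meta <- rep[setdiff(names(rep), "records")]
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a TSV with one row per sample: required columns `sample_id`
#' and `path`, optional `donor_id`, `age`, `sex`, `compartment`,
#' `cd4_cd8_ratio`, `timepoint`. Absent age/sex are stored as `NA` (never
#' imputed); metadata filtering happens downstream in curation.
#'
#' @param path manifest TSV path.
#' @param check_paths verify that every referenced repertoire file exists
#'   (paths are resolved relative to the manifest's directory).
#' @return A data frame of class `trb_manifest`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  for (col in c("sample_id", "path"))
    if (!col %in% names(tab)) stop("manifest lacks required column '", col, "'")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  if (!"donor_id" %in% names(tab)) tab$donor_id <- tab$sample_id
  for (col in c("age", "timepoint"))
    tab[[col]] <- if (col %in% names(tab))
      suppressWarnings(as.integer(tab[[col]])) else NA_integer_
  tab$sex <- if ("sex" %in% names(tab)) {
    s <- tolower(trimws(tab$sex)); s[!s %in% c("male", "female")] <- NA
    s
  } else NA_character_
  tab$compartment <- if ("compartment" %in% names(tab))
    tab$compartment else "whole_blood"
  tab$cd4_cd8_ratio <- if ("cd4_cd8_ratio" %in% names(tab))
    suppressWarnings(as.numeric(tab$cd4_cd8_ratio)) else NA_real_
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", tab$path), tab$path,
                     file.path(dirname(path), tab$path))
  if (check_paths) {
    missing <- resolved[!file.exists(resolved)]
    if (length(missing))
      stop("manifest references missing file(s): ",
           paste(missing, collapse = ", "))
  }
  tab$path <- resolved
  class(tab) <- c("trb_manifest", "data.frame")
  tab
}

#' Load all repertoires referenced by a manifest
#'
#' @param manifest a `trb_manifest` from [read_manifest()].
#' @param dialect,column_map passed to [read_repertoire()].
#' @return A named list of `trb_repertoire` objects.
#' @export
load_cohort <- function(manifest, dialect = "immunoseq", column_map = list()) {
  stopifnot(inherits(manifest, "trb_manifest"))
  reps <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    read_repertoire(m$path, dialect = dialect, column_map = column_map,
                    sample_id = m$sample_id, donor_id = m$donor_id,
                    age = m$age, sex = m$sex, compartment = m$compartment,
                    timepoint = m$timepoint, cd4_cd8_ratio = m$cd4_cd8_ratio)
  })
  names(reps) <- manifest$sample_id
  reps
}
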