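#' Normalize a TRB gene call for matching
#'
#' Trims whitespace, uppercases, drops the allele suffix (`*01` etc.), maps the
#' `TCRB` vendor prefix to `TRB` and strips zero padding from family and member
#' numbers, so that `"TCRBV03-01*02"` and `"TRBV3-1"` match the same key.
#' Allele information is preserved in the stored record; only matching uses the
#' normalized key.
#'
#' @param x character vector of gene names.
#' @return Normalized gene keys.
#' @export
normalize_gene_call <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("\\*.*$", "", x)
  x <- sub("^TCRB", "TRB", x)
  # strip zero padding in family and member numbers: TRBV03-01 -> TRBV3-1
  x <- gsub("([VDJ])0+([1-9])", "\\1\\2", x)
  x <- gsub("-0+([1-9])", "-\\1", x)
  x
}

#' Load a TRB germline functionality reference
#'
#' The reference lists the functional V/J/D gene sets used for the
#' "non-functional or ORF" curation filter, the orphon V paralogs, and genes
#' excluded outright (TRBV03-01). The bundled default is a constructed
#' synthetic snapshot (see `inst/extdata/trb_gene_reference_synthetic.json`);
#' supply your own IMGT-derived list for production analyses.
#'
#' @param path JSON file with fields `functional_v`, `functional_j`,
#'   `functional_d`, `orphon_v`, `excluded`. Defaults to the bundled synthetic
#'   snapshot.
#' @return A list of class `gene_reference` whose sets are normalized with
#'   [normalize_gene_call()].
#' @export
load_gene_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trb_gene_reference_synthetic.json",
                        package = "trbdiv", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- list(
    functional_v = normalize_gene_call(raw$functional_v),
    functional_j = normalize_gene_call(raw$functional_j),
    functional_d = normalize_gene_call(raw$functional_d),
    orphon_v = normalize_gene_call(raw$orphon_v %||% character()),
    excluded = normalize_gene_call(raw$excluded %||% character()),
    version = raw$version %||% "unversioned"
  )
  if (!length(ref$functional_v) || !length(ref$functional_j))
    stop("gene reference must define non-empty functional V and J sets")
  class(ref) <- "gene_reference"
  ref
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Report functional genes absent from a sample
#'
#' Some repertoires lack particular functional genes entirely (small samples,
#' rare genes). No gene other than TRBV03-01 is excluded for that reason; this
#' report makes per-sample gene presence auditable instead.
#'
#' @param rep a `trb_repertoire`.
#' @param ref a `gene_reference`.
#' @return List with `absent_v` and `absent_j` character vectors.
#' @export
gene_presence <- function(rep, ref = load_gene_reference()) {
  v <- unique(normalize_gene_call(rep$records$v_call))
  j <- unique(normalize_gene_call(rep$records$j_call))
  list(absent_v = setdiff(setdiff(ref$functional_v, ref$excluded), v),
       absent_j = setdiff(ref$functional_j, j))
}
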