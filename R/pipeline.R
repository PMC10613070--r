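provenance <- function(seed, params = list()) {
  list(package = "trbdiv",
       version = as.character(utils::packageVersion("trbdiv")),
       r_version = R.version.string,
       seed = seed, params = params,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables))
    write.table(bundle$tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", na = "null",
                       digits = NA)
  invisible(out_dir)
}

#' Cross-sectional analysis pipeline
#'
#' Runs the whole cross-sectional chain: (when given repertoires or a
#' manifest) curation with Table-style accounting, per-sample diversity, then
#' for each response the BIC-selected weighted regression and the brute-force
#' piecewise search, each for all donors and for men and women separately.
#'
#' @param input one of: a cohort diversity table (data frame with `age`,
#'   `sex`, `total_copies`, `status_J`, `sequence_J`); a list of
#'   `trb_repertoire` objects; or a manifest path / `trb_manifest`.
#' @param responses responses to model.
#' @param min_group minimum subgroup size for the piecewise search.
#' @param outlier_alpha tail probability for the sample outlier screen
#'   (repertoire inputs only); `NULL` skips it.
#' @param ref gene reference for curation (repertoire inputs only).
#' @param seed recorded in the provenance block (the cross-sectional stages
#'   are deterministic).
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return List with `diversity` (per-sample table), `fits` (per response:
#'   `all`, `men`, `women` selections and piecewise fits), `tables`
#'   (report-shaped data frames), `curation` (cohort accounting or `NULL`)
#'   and `provenance`.
#' @export
run_cross_sectional <- function(input, responses = c("status_J", "sequence_J"),
                                min_group = 5L, outlier_alpha = 0.007,
                                ref = load_gene_reference(), seed = 1L,
                                out_dir = NULL) {
  curation <- NULL
  if (inherits(input, "trb_manifest") ||
      (is.character(input) && length(input) == 1L)) {
    input <- load_cohort(if (is.character(input)) read_manifest(input)
                         else input)
  }
  if (is.list(input) && !is.data.frame(input) &&
      all(vapply(input, inherits, logical(1), "trb_repertoire"))) {
    cur <- curate_cohort(input, ref = ref, outlier_alpha = outlier_alpha)
    curation <- cur$summary
    div <- cohort_diversity(cur$curated)
  } else if (is.data.frame(input)) {
    div <- as.data.frame(input)
    keep <- !is.na(div$age) & !is.na(div$sex)
    div <- div[keep, , drop = FALSE]
  } else stop("unsupported input type")
  if (!nrow(div)) stop("no samples left after filtering")
  fits <- list()
  tables <- list()
  for (resp in responses) {
    by_group <- list(all = div,
                     men = div[div$sex == "male", , drop = FALSE],
                     women = div[div$sex == "female", , drop = FALSE])
    res <- list()
    for (g in names(by_group)) {
      d <- by_group[[g]]
      res[[g]] <- list(
        general = bic_backward_select(d, resp),
        piecewise = tryCatch(piecewise_search(d, resp,
                                              min_group = min_group),
                             error = function(e) e)
      )
    }
    fits[[resp]] <- res
    flat <- list()
    for (g in names(res)) {
      flat[[g]] <- res[[g]]$general$fit
      if (inherits(res[[g]]$piecewise, "div_piecewise"))
        flat[[paste0(g, "_piecewise")]] <- res[[g]]$piecewise
    }
    tables[[resp]] <- fit_table(flat)
  }
  bundle <- list(diversity = div, fits = fits, tables = tables,
                 curation = curation,
                 provenance = provenance(seed, list(responses = responses,
                                                    min_group = min_group)))
  if (!is.null(out_dir)) {
    out_tabs <- tables
    names(out_tabs) <- paste0("fits_", names(out_tabs))
    out_tabs$diversity <- div
    if (!is.null(curation)) out_tabs$curation <- curation
    write_outputs(list(tables = out_tabs, provenance = bundle$provenance),
                  out_dir)
  }
  bundle
}

#' Longitudinal analysis pipeline
#'
#' For sorted CD4/CD8 repertoire pairs: reconstitutes whole-blood samples by
#' ratio-driven merging (averaging diversity over replicates), then fits the
#' mixed-effects models with likelihood-ratio backward selection — on the
#' merged samples with donor random intercepts, and on the sorted samples
#' with cell-type terms and donor plus donor-by-cell-type random intercepts —
#' and derives per-group initial-diversity summaries, slopes and ICCs.
#'
#' @param input either a list of `list(cd4 =, cd8 =, ratio =)` repertoire
#'   pairs (as from [simulate_longitudinal()] with `records = TRUE`), or a
#'   list with precomputed `merged` and `celltype` diversity tables.
#' @param responses responses to model.
#' @param n_replicates merge replicates per sample (default 100).
#' @param alpha LRT removal threshold.
#' @param seed master seed for the merge replicates.
#' @param ref gene reference used when re-curating merged repertoires
#'   (`NULL` skips re-curation).
#' @param out_dir optional output directory.
#' @return List with `merged_table`, `celltype_table`, per-response `merged`
#'   and `celltype` model selections, `summaries` (per sex and cell type:
#'   initial mean, SD, slope), `icc`, `tables` and `provenance`.
#' @export
run_longitudinal <- function(input, responses = c("status_J", "sequence_J"),
                             n_replicates = 100L, alpha = 0.05, seed = 1L,
                             ref = NULL, out_dir = NULL) {
  if (!is.null(input$merged) && is.data.frame(input$merged)) {
    merged_tab <- input$merged
    ct_tab <- input$celltype
  } else {
    pairs <- input
    bad <- names(pairs)[!vapply(pairs, function(p)
      inherits(p$cd4, "trb_repertoire") && inherits(p$cd8, "trb_repertoire"),
      logical(1))]
    if (length(bad))
      stop("unpaired CD4/CD8 compartments for: ", paste(bad, collapse = ", "))
    set.seed(seed)
    pair_seeds <- sample.int(.Machine$integer.max, length(pairs))
    rows <- lapply(seq_along(pairs), function(i) {
      p <- pairs[[i]]
      rec <- reconstitute_whole_blood(p$cd4, p$cd8, ratio = p$ratio,
                                      n_replicates = n_replicates,
                                      seed = pair_seeds[i], ref = ref)
      data.frame(donor_id = p$cd4$donor_id, sex = p$cd4$sex,
                 age = p$cd4$age, timepoint = p$cd4$timepoint,
                 ratio = p$ratio, status_J = rec$status_J,
                 sequence_J = rec$sequence_J, stringsAsFactors = FALSE)
    })
    merged_tab <- do.call(rbind, rows)
    ct_tab <- cohort_diversity(unlist(lapply(pairs, function(p)
      list(p$cd4, p$cd8)), recursive = FALSE))
    ct_tab$celltype <- ct_tab$compartment
  }
  fits <- list(); summaries <- list(); iccs <- list()
  for (resp in responses) {
    m <- lrt_backward_select(merged_tab, resp,
                             fixed = c("age", "sex", "age:sex"),
                             random = "donor", alpha = alpha)
    ct <- lrt_backward_select(ct_tab, resp,
                              fixed = c("age", "sex", "age:sex", "celltype",
                                        "age:celltype"),
                              random = c("donor", "donor_celltype"),
                              alpha = alpha)
    fits[[resp]] <- list(merged = m, celltype = ct)
    co_m <- as_mixed_coefs(m$fit)
    co_ct <- as_mixed_coefs(ct$fit)
    rows <- list()
    for (sx in c("male", "female")) {
      sm <- summarize_initial_diversity(co_m, sx)
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, sex = sx, cell_type = "merged",
        mean_initial = round(sm$mean, 4), sd_initial = round(sm$sd, 4),
        slope = round(slope_for_group(co_m, sx), 4),
        stringsAsFactors = FALSE)
      for (cty in c("CD4", "CD8")) {
        sc <- summarize_initial_diversity(co_ct, sx, cty)
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp, sex = sx, cell_type = cty,
          mean_initial = round(sc$mean, 4), sd_initial = round(sc$sd, 4),
          slope = round(slope_for_group(co_ct, sx, cty), 4),
          stringsAsFactors = FALSE)
      }
    }
    summaries[[resp]] <- do.call(rbind, rows)
    iccs[[resp]] <- list(merged = m$fit$icc, celltype = ct$fit$icc)
  }
  bundle <- list(merged_table = merged_tab, celltype_table = ct_tab,
                 fits = fits, summaries = summaries, icc = iccs,
                 provenance = provenance(seed,
                                         list(n_replicates = n_replicates,
                                              alpha = alpha)))
  if (!is.null(out_dir)) {
    out_tabs <- list(merged_diversity = merged_tab,
                     celltype_diversity = ct_tab)
    for (resp in names(summaries))
      out_tabs[[paste0("summaries_", resp)]] <- summaries[[resp]]
    write_outputs(list(tables = out_tabs, provenance = bundle$provenance),
                  out_dir)
  }
  bundle
}
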