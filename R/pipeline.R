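# Orchestration helpers: the per-gene region report combining merged MRE
# regions with enrichment results, and the run manifest that makes any
# stage reproducible.

#' Combined region/enrichment report for one gene
#'
#' Joins merged MRE regions with per-site enrichment fits: each region
#' inherits the significant tissues of its member sites (split into
#' cancer/normal when the fits were histology-stratified), its repression
#' range and highly-repressive flag, and the strongest per-tissue
#' two-tailed P among its members as `-log10` evidence.  Aggregate counts
#' from [region_report()] are attached.
#'
#' @param regions a [merge_regions()] result.
#' @param enrichments optional named list of [enrich_mre()] fits, keyed by
#'   member `site_id`; every member site must have a fit when the list is
#'   given.  When omitted, supported tissues come from the catalog's
#'   annotation columns.
#' @param repression_threshold percent threshold for the
#'   highly-repressive call (default 30).
#' @return Object of class `mre_report`: list with `table` (one row per
#'   region) and `counts` (the [region_report()] aggregates).
#' @export
pipeline_report <- function(regions, enrichments = NULL,
                            repression_threshold = 30) {
  if (!is.null(enrichments) && nrow(regions) > 0L) {
    member_ids <- unique(unlist(lapply(regions$members,
                                       function(m) m$site_id)))
    missing <- setdiff(member_ids, names(enrichments))
    if (length(missing) > 0L)
      stop("no enrichment fit for site id(s): ",
           paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, , drop = FALSE]
    smry <- summarize_region(reg, repression_threshold)
    sup_c <- reg$supported_cancer; sup_n <- reg$supported_normal
    best_p <- NA_real_
    if (!is.null(enrichments)) {
      sig <- do.call(rbind, lapply(reg$members[[1L]]$site_id, function(id)
        enrichments[[id]]$significant_tissues))
      ps <- unlist(lapply(reg$members[[1L]]$site_id, function(id) {
        r <- enrichments[[id]]$results
        r$p_twotail[r$tested]
      }))
      if (length(ps) > 0L) best_p <- min(ps)
      pick <- function(strata) {
        x <- unique(sig$tissue[sig$stratum %in% strata])
        if (length(x) == 0L) NA_character_ else paste(x, collapse = ";")
      }
      if (!is.null(sig) && nrow(sig) > 0L) {
        sup_c <- pick(c("cancer", "pooled"))
        sup_n <- pick("normal")
      } else sup_c <- sup_n <- NA_character_
    }
    data.frame(region_index = reg$region_index,
               reference_id = reg$reference_id,
               start = reg$start, end = reg$end,
               n_sites = reg$n_sites, n_mirnas = reg$n_mirnas,
               repression_min = smry$repression_min,
               repression_max = smry$repression_max,
               highly_repressive = smry$highly_repressive,
               supported_cancer = sup_c, supported_normal = sup_n,
               best_p = best_p,
               neg_log10_p = if (is.na(best_p)) NA_real_
                             else -log10(best_p),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(region_index = integer(0))
  # aggregate over the (possibly enrichment-updated) supported columns
  reg2 <- regions
  if (nrow(regions) > 0L && !is.null(enrichments)) {
    reg2$supported_cancer <- tab$supported_cancer
    reg2$supported_normal <- tab$supported_normal
  }
  out <- list(table = tab,
              counts = region_report(reg2, repression_threshold))
  class(out) <- "mre_report"
  out
}

#' @export
print.mre_report <- function(x, ...) {
  ct <- x$counts
  cat("MRE region report\n")
  cat(sprintf("  regions: %d;  highly repressive: %d\n",
              ct$n_regions, ct$n_highly_repressive))
  cat(sprintf(
    "  supported (any/cancer/normal): %d / %d / %d;  supported & highly repressive: %d\n",
    ct$n_supported_any, ct$n_supported_cancer, ct$n_supported_normal,
    ct$n_supported_and_repressive))
  if (nrow(x$table) > 0L) {
    show <- x$table[, c("region_index", "start", "end", "n_mirnas",
                        "repression_min", "repression_max",
                        "highly_repressive")]
    show$start <- show$start + 1L  # print 1-based inclusive
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' Write a run manifest
#'
#' Records inputs, parameters, seed and package version beside the
#' outputs of a pipeline stage, sufficient to re-run the stage exactly.
#'
#' @param path output JSON path.
#' @param stage stage name.
#' @param inputs named list/character of input paths.
#' @param params named list of parameters.
#' @param seed integer seed (or NULL for deterministic stages).
#' @export
write_manifest <- function(path, stage, inputs = list(),
                           params = list(), seed = NULL) {
  manifest <- list(
    stage = stage,
    package = "splicemre",
    version = as.character(utils::packageVersion("splicemre")),
    inputs = inputs, params = params, seed = seed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
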