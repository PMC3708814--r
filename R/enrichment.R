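# Tissue-wise contingency tables and the splicing-regulation call for one
# MRE site.  This is the analytic core of the package: for every tissue
# (optionally stratified into normal/cancer histology) the MRE-free and
# MRE-containing isoform counts are compared against all other tissues
# with the Fisher exact test.

#' Build per-tissue contingency tables from classified ESTs
#'
#' Only informative ESTs (configurations II, III, IV) are counted;
#' configurations I and V are excluded.  For each tissue, `a`/`b` are the
#' MRE-free/MRE-containing counts in that tissue and `c`/`d` the same over
#' all other tissues.  With `stratify_histology = TRUE` tissues are split
#' into normal and cancer strata, and "all other tissues" is restricted to
#' the same stratum.
#'
#' @param classified a [classify_all()] result.
#' @param stratify_histology split tissues by histology (default FALSE:
#'   one pooled stratum).
#' @return data.frame with columns `tissue`, `stratum`, `a`, `b`, `c`,
#'   `d`.
#' @export
build_tables <- function(classified, stratify_histology = FALSE) {
  inf <- classified[classified$isoform_class %in% c("free", "containing"), ,
                    drop = FALSE]
  strata <- if (stratify_histology) inf$histology
            else rep("pooled", nrow(inf))
  empty <- data.frame(tissue = character(0), stratum = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), stringsAsFactors = FALSE)
  if (nrow(inf) == 0L) return(empty)
  out <- lapply(unique(strata), function(st) {
    sub <- inf[strata == st, , drop = FALSE]
    free_tot <- sum(sub$isoform_class == "free")
    cont_tot <- sum(sub$isoform_class == "containing")
    tissues <- sort(unique(sub$tissue))
    do.call(rbind, lapply(tissues, function(ti) {
      a <- sum(sub$tissue == ti & sub$isoform_class == "free")
      b <- sum(sub$tissue == ti & sub$isoform_class == "containing")
      data.frame(tissue = ti, stratum = st, a = a, b = b,
                 c = free_tot - a, d = cont_tot - b,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

#' Test one MRE site for tissue-specific splicing regulation
#'
#' Classifies every EST relative to the MRE, builds per-tissue contingency
#' tables, applies the Fisher exact test to each tissue with at least
#' `min_tissue_ests` informative ESTs, and calls the site
#' splicing-regulated when any tested tissue reaches `p_twotail < alpha`.
#' A gene with fewer than `min_gene_ests` informative ESTs in total is not
#' tested at all.
#'
#' @param ests an [est_set()] aligned to the MRE's reference.
#' @param mre the MRE interval: `c(start, end)` 0-based half-open, or a
#'   single-row [mre_catalog()].
#' @param libraries a [library_table()].
#' @param alpha per-tissue significance level (default 0.05).
#' @param min_gene_ests minimum informative ESTs for the gene to be tested
#'   (default 10).
#' @param min_tissue_ests minimum informative ESTs for a tissue to be
#'   tested (default 10).
#' @param stratify_histology split tissues into normal/cancer strata
#'   (default FALSE).
#' @return An object of class `mre_enrichment`: list with `site_id`,
#'   `results` (data.frame: tissue, stratum, a, b, c, d, p_left, p_right,
#'   p_twotail, tested, significant, tail), `tested` (gene-level flag),
#'   `is_regulated`, `significant_tissues` (data.frame tissue, stratum,
#'   tail), counts of informative/excluded ESTs and the settings used.
#' @export
enrich_mre <- function(ests, mre, libraries, alpha = 0.05,
                       min_gene_ests = 10, min_tissue_ests = 10,
                       stratify_histology = FALSE) {
  site_id <- if (is.data.frame(mre)) mre$site_id[1L] else NA_character_
  classified <- classify_all(ests, mre, libraries)
  n_informative <- sum(classified$isoform_class != "excluded")
  n_excluded <- sum(classified$isoform_class == "excluded")
  tables <- build_tables(classified, stratify_histology)
  gene_tested <- n_informative >= min_gene_ests
  res <- tables
  if (nrow(res) > 0L) {
    ps <- lapply(seq_len(nrow(res)), function(i)
      fisher_exact(res$a[i], res$b[i], res$c[i], res$d[i]))
    res$p_left <- vapply(ps, `[[`, numeric(1L), "p_left")
    res$p_right <- vapply(ps, `[[`, numeric(1L), "p_right")
    res$p_twotail <- vapply(ps, `[[`, numeric(1L), "p_twotail")
    res$tested <- gene_tested & (res$a + res$b) >= min_tissue_ests
    res$significant <- res$tested & res$p_twotail < alpha
    res$tail <- ifelse(res$significant,
                       ifelse(res$p_left < alpha, "left", "right"),
                       NA_character_)
  } else {
    res$p_left <- res$p_right <- res$p_twotail <- numeric(0)
    res$tested <- res$significant <- logical(0)
    res$tail <- character(0)
  }
  sig <- res[which(res$significant),
             c("tissue", "stratum", "tail"), drop = FALSE]
  rownames(sig) <- NULL
  out <- list(site_id = site_id, results = res,
              tested = gene_tested,
              is_regulated = gene_tested && nrow(sig) > 0L,
              significant_tissues = sig,
              n_informative = n_informative, n_excluded = n_excluded,
              alpha = alpha, min_gene_ests = min_gene_ests,
              min_tissue_ests = min_tissue_ests,
              stratify_histology = stratify_histology)
  class(out) <- "mre_enrichment"
  out
}

#' @export
print.mre_enrichment <- function(x, ...) {
  cat("Tissue-specific splicing enrichment",
      if (!is.na(x$site_id)) paste0("for MRE ", x$site_id) else "", "\n")
  cat(sprintf("  informative ESTs: %d (excluded: %d)\n",
              x$n_informative, x$n_excluded))
  if (!x$tested) {
    cat(sprintf("  gene not tested (< %d informative ESTs)\n",
                x$min_gene_ests))
    return(invisible(x))
  }
  cat(sprintf("  splicing-regulated: %s (alpha = %g, two-tailed)\n",
              if (x$is_regulated) "yes" else "no", x$alpha))
  if (nrow(x$significant_tissues) > 0L) {
    cat("  significant tissues:\n")
    tt <- x$significant_tissues
    for (i in seq_len(nrow(tt)))
      cat(sprintf("    %s [%s] (%s tail: %s isoforms enriched)\n",
                  tt$tissue[i], tt$stratum[i], tt$tail[i],
                  if (tt$tail[i] == "left") "MRE-containing"
                  else "MRE-free"))
  }
  invisible(x)
}

#' @export
summary.mre_enrichment <- function(object, ...) {
  print(object)
  tested <- object$results[object$results$tested, , drop = FALSE]
  if (nrow(tested) > 0L) {
    cat("\nPer-tissue Fisher exact tests (tested tissues):\n")
    show <- tested[, c("tissue", "stratum", "a", "b", "c", "d",
                       "p_left", "p_right", "p_twotail")]
    show$p_left <- signif(show$p_left, 4L)
    show$p_right <- signif(show$p_right, 4L)
    show$p_twotail <- signif(show$p_twotail, 4L)
    print(show, row.names = FALSE)
  }
  invisible(object)
}

#' Plot per-tissue enrichment as -log10 P values
#'
#' One bar per tested tissue, in the style of per-region enrichment
#' panels; the dashed line marks the significance level.
#'
#' @param x an `mre_enrichment` object.
#' @param which which P value to plot (default two-tailed).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.mre_enrichment <- function(x, which = c("p_twotail", "p_left",
                                             "p_right"), ...) {
  which <- match.arg(which)
  res <- x$results[x$results$tested, , drop = FALSE]
  if (nrow(res) == 0L) {
    warning("no tested tissues to plot")
    return(invisible(x))
  }
  vals <- -log10(res[[which]])
  labs <- if (x$stratify_histology)
    paste0(res$tissue, " [", res$stratum, "]") else res$tissue
  graphics::barplot(vals, names.arg = labs, las = 2,
                    ylab = expression(-log[10] ~ P), ...)
  graphics::abline(h = -log10(x$alpha), lty = 2, col = "red")
  invisible(x)
}

#' Fraction of splicing-regulated sites in an MRE catalog
#'
#' Catalog rows sharing one `(reference_id, start, end)` interval (the
#' same element targeted by several microRNAs) are collapsed to a single
#' unique site before counting.  The fraction is the number of regulated
#' unique sites over the number of tested unique sites.
#'
#' @param catalog an [mre_catalog()].
#' @param ests an [est_set()] covering the catalog's references.
#' @param libraries a [library_table()].
#' @param ... settings passed to [enrich_mre()].
#' @return list with `fraction`, `n_tested`, `n_regulated` and `calls`
#'   (data.frame per unique site: site_id, reference_id, start, end,
#'   tested, is_regulated, n_significant_tissues).
#' @export
fraction_regulated <- function(catalog, ests, libraries, ...) {
  if (nrow(catalog) == 0L) stop("empty MRE catalog")
  key <- paste(catalog$reference_id, catalog$start, catalog$end, sep = "\r")
  uniq <- catalog[!duplicated(key), , drop = FALSE]
  calls <- do.call(rbind, lapply(seq_len(nrow(uniq)), function(i) {
    sub <- ests[ests$reference_id == uniq$reference_id[i], , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(site_id = uniq$site_id[i],
                        reference_id = uniq$reference_id[i],
                        start = uniq$start[i], end = uniq$end[i],
                        tested = FALSE, is_regulated = FALSE,
                        n_significant_tissues = 0L,
                        stringsAsFactors = FALSE))
    fit <- enrich_mre(sub, c(uniq$start[i], uniq$end[i]), libraries, ...)
    data.frame(site_id = uniq$site_id[i],
               reference_id = uniq$reference_id[i],
               start = uniq$start[i], end = uniq$end[i],
               tested = fit$tested, is_regulated = fit$is_regulated,
               n_significant_tissues = nrow(fit$significant_tissues),
               stringsAsFactors = FALSE)
  }))
  n_tested <- sum(calls$tested)
  if (n_tested == 0L) stop("no testable site in the catalog")
  n_reg <- sum(calls$is_regulated)
  list(fraction = n_reg / n_tested, n_tested = n_tested,
       n_regulated = n_reg, calls = calls)
}
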