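# Placement of MRE sites on reference transcripts and merging of
# overlapping sites into MRE regions.

#' Locate an MRE sequence on a reference by perfect full-length match
#'
#' Every maximal exact occurrence of the site sequence on the sense strand
#' is reported; partial matches are not.  Both sequences are normalized
#' (U -> T, uppercase) before matching, and `N` never matches anything, so
#' a site containing `N`, or an occurrence overlapping an `N` in the
#' reference, is rejected.
#'
#' @param reference a single-row [reference_set()] (or a list/row with
#'   `id`, `sequence`).
#' @param site_sequence the MRE sequence to place (DNA or RNA alphabet).
#' @return Integer matrix with columns `start`, `end`: 0-based half-open
#'   intervals of every perfect occurrence (zero rows when none).
#' @export
locate_mre <- function(reference, site_sequence) {
  site_sequence <- normalize_nt(as.character(site_sequence))
  if (length(site_sequence) != 1L || !nzchar(site_sequence))
    stop("site_sequence must be a single non-empty string")
  subj <- reference$sequence[1L]
  empty <- cbind(start = integer(0), end = integer(0))
  if (grepl("N", site_sequence, fixed = TRUE)) return(empty)
  m <- Biostrings::matchPattern(site_sequence, Biostrings::BString(subj),
                                fixed = TRUE)
  if (length(m) == 0L) return(empty)
  start0 <- BiocGenerics::start(m) - 1L
  end0 <- BiocGenerics::end(m)
  # drop occurrences that cover an N in the reference
  keep <- !vapply(seq_along(start0), function(i) {
    grepl("N", substr(subj, start0[i] + 1L, end0[i]), fixed = TRUE)
  }, logical(1L))
  cbind(start = start0[keep], end = end0[keep])
}

#' Find canonical seed matches for a microRNA on a target
#'
#' The seed is the 7-nt target feature complementary to microRNA
#' nucleotides 2-8 (counted 1-based from the 5' end), i.e. the target
#' carries the reverse complement of those seven bases.  All (possibly
#' overlapping) occurrences are reported.
#'
#' @param mirna_sequence the microRNA sequence, 5'->3', at least 8 nt
#'   (RNA or DNA alphabet).
#' @param target a single-row [reference_set()].
#' @param search_interval optional 0-based half-open `c(start, end)`
#'   restriction; only matches fully inside it are kept.
#' @return data.frame with columns `mirna_id` (NA unless supplied via
#'   `names(mirna_sequence)`), `start`, `end`, `heptamer`.
#' @export
find_seed_matches <- function(mirna_sequence, target,
                              search_interval = NULL) {
  mirna_id <- if (!is.null(names(mirna_sequence)))
    names(mirna_sequence)[1L] else NA_character_
  mir <- normalize_nt(as.character(mirna_sequence)[1L])
  if (nchar(mir) < 8L)
    stop("microRNA sequence must be at least 8 nt")
  seed27 <- substr(mir, 2L, 8L)
  heptamer <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seed27)))
  hits <- locate_mre(target, heptamer)
  if (!is.null(search_interval)) {
    keep <- hits[, "start"] >= search_interval[1L] &
      hits[, "end"] <= search_interval[2L]
    hits <- hits[keep, , drop = FALSE]
  }
  out <- data.frame(mirna_id = rep(mirna_id, nrow(hits)),
                    start = hits[, "start"], end = hits[, "end"],
                    heptamer = rep(heptamer, nrow(hits)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge overlapping MRE sites into MRE regions
#'
#' Two sites overlap at fraction `|intersection| / min(|a|, |b|)`; pairs at
#' or above `overlap_threshold` are connected, and connected components
#' under single-linkage transitive closure become one MRE region.  With the
#' shorter-site denominator, a short site fully contained in a longer one
#' always counts as complete overlap.  Regions are numbered 1..K by
#' ascending start.
#'
#' @param sites an [mre_catalog()]; all rows must share one
#'   `reference_id`.
#' @param overlap_threshold minimum pairwise overlap fraction
#'   (default 0.90).
#' @return An `mre_region_set`: data.frame with one row per region
#'   (`region_index`, `reference_id`, `start`, `end`, `n_sites`,
#'   `n_mirnas`, `site_ids`, `mirna_ids`, member ratio columns and
#'   supported-tissue columns) plus a `members` list-column of the member
#'   catalog rows.
#' @export
merge_regions <- function(sites, overlap_threshold = 0.90) {
  if (nrow(sites) == 0L) {
    out <- data.frame(region_index = integer(0), reference_id = character(0),
                      start = integer(0), end = integer(0),
                      n_sites = integer(0))
    class(out) <- c("mre_region_set", "data.frame")
    return(out)
  }
  if (length(unique(sites$reference_id)) > 1L)
    stop("merge_regions requires sites from a single reference")
  n <- nrow(sites)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  len <- sites$end - sites$start
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      inter <- min(sites$end[i], sites$end[j]) -
        max(sites$start[i], sites$start[j])
      if (inter <= 0L) next
      if (inter / min(len[i], len[j]) >= overlap_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  groups <- split(seq_len(n), comp)
  starts <- vapply(groups, function(ix) min(sites$start[ix]), integer(1L))
  groups <- groups[order(starts)]
  collapse_tissues <- function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (length(x) == 0L) return(NA_character_)
    paste(unique(unlist(strsplit(x, ";", fixed = TRUE))), collapse = ";")
  }
  rows <- lapply(seq_along(groups), function(k) {
    ix <- groups[[k]]
    m <- sites[ix, , drop = FALSE]
    data.frame(
      region_index = k,
      reference_id = m$reference_id[1L],
      start = min(m$start), end = max(m$end),
      n_sites = nrow(m),
      n_mirnas = length(unique(m$mirna_id)),
      site_ids = paste(m$site_id, collapse = ";"),
      mirna_ids = paste(m$mirna_id, collapse = ";"),
      supported_cancer = collapse_tissues(m$supported_cancer),
      supported_normal = collapse_tissues(m$supported_normal),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(groups, function(ix) sites[ix, , drop = FALSE])
  class(out) <- c("mre_region_set", "data.frame")
  out
}

#' Summarize the repressiveness of one MRE region
#'
#' The region's repression range is the min/max of the member sites'
#' repressive ratios; the region is highly repressive when the maximum
#' reaches `repression_threshold` (inclusive, default 30 percent).
#'
#' @param region one row of a [merge_regions()] result (data.frame with a
#'   `members` list-column), or a member catalog directly.
#' @param repression_threshold percent threshold for the highly-repressive
#'   call.
#' @return list with `repression_min`, `repression_max`,
#'   `highly_repressive`, `n_mirnas`, and `available` (FALSE when no member
#'   carries a ratio, in which case the other fields are NA).
#' @export
summarize_region <- function(region, repression_threshold = 30) {
  members <- if (!is.null(region$members)) region$members[[1L]] else region
  ratios <- members$repressive_ratio
  ratios <- ratios[!is.na(ratios)]
  n_mirnas <- length(unique(members$mirna_id))
  if (length(ratios) == 0L)
    return(list(repression_min = NA_real_, repression_max = NA_real_,
                highly_repressive = NA, n_mirnas = n_mirnas,
                available = FALSE))
  list(repression_min = min(ratios), repression_max = max(ratios),
       highly_repressive = max(ratios) >= repression_threshold,
       n_mirnas = n_mirnas, available = TRUE)
}

#' Aggregate counts over the MRE regions of one gene
#'
#' @param regions a [merge_regions()] result.
#' @param repression_threshold percent threshold passed to
#'   [summarize_region()].
#' @return list with `n_regions`, `n_highly_repressive`,
#'   `n_supported_any` (regions with at least one supported tissue in
#'   either histology), `n_supported_cancer`, `n_supported_normal`, and
#'   `n_supported_and_repressive` (overlap of the supported and highly
#'   repressive sets).
#' @export
region_report <- function(regions, repression_threshold = 30) {
  if (nrow(regions) == 0L)
    return(list(n_regions = 0L, n_highly_repressive = 0L,
                n_supported_any = 0L, n_supported_cancer = 0L,
                n_supported_normal = 0L, n_supported_and_repressive = 0L))
  has <- function(x) !is.na(x) & nzchar(x)
  hr <- vapply(seq_len(nrow(regions)), function(i) {
    isTRUE(summarize_region(regions[i, , drop = FALSE],
                            repression_threshold)$highly_repressive)
  }, logical(1L))
  sc <- has(regions$supported_cancer)
  sn <- has(regions$supported_normal)
  list(n_regions = nrow(regions),
       n_highly_repressive = sum(hr),
       n_supported_any = sum(sc | sn),
       n_supported_cancer = sum(sc),
       n_supported_normal = sum(sn),
       n_supported_and_repressive = sum(hr & (sc | sn)))
}
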