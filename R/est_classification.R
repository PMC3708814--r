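# Classification of each EST alignment relative to a specified MRE.
#
# Five mutually exclusive configurations:
#   I   partial or no overlap with the MRE (uninformative);
#   II  MRE fully inside one aligned exon block (MRE-containing isoform);
#   III MRE fully inside one inter-block gap, a putative intron
#       (MRE-free isoform);
#   IV  MRE split across an exon-intron junction: only a partial, likely
#       non-functional MRE is retained (counted as MRE-free);
#   V   structurally anomalous alignments (defensive catch-all; excluded
#       from counting, like I).

CONFIGURATIONS <- c("I", "II", "III", "IV", "V")

config_to_class <- c(I = "excluded", II = "containing", III = "free",
                     IV = "free", V = "excluded")

#' Classify one EST alignment relative to an MRE interval
#'
#' The EST footprint is `[first block start, last block end)`.  An MRE not
#' fully contained in the footprint is configuration I; fully inside one
#' exon block, II; fully inside one gap, III; otherwise (straddling at
#' least one junction inside the footprint), IV.  V is reserved for
#' alignments that violate structural assumptions detected here.  An MRE
#' abutting a block boundary (shared half-open endpoint) counts as
#' contained, not straddling.
#'
#' @param blocks two-column matrix of sorted, non-overlapping 0-based
#'   half-open exon blocks (one EST).
#' @param mre_interval `c(start, end)`, 0-based half-open.
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @export
classify_est <- function(blocks, mre_interval) {
  blocks <- validate_blocks(blocks)
  s <- as.integer(mre_interval[1L]); e <- as.integer(mre_interval[2L])
  if (is.na(s) || is.na(e) || e <= s) stop("invalid MRE interval")
  foot_s <- blocks[1L, 1L]; foot_e <- blocks[nrow(blocks), 2L]
  if (s < foot_s || e > foot_e) return("I")
  if (any(s >= blocks[, 1L] & e <= blocks[, 2L])) return("II")
  if (nrow(blocks) > 1L) {
    gap_s <- blocks[-nrow(blocks), 2L]
    gap_e <- blocks[-1L, 1L]
    if (any(s >= gap_s & e <= gap_e)) return("III")
  }
  "IV"
}

#' Classify every EST for one MRE and attach tissue annotations
#'
#' @param ests an [est_set()].
#' @param mre_interval `c(start, end)` 0-based half-open, or a single-row
#'   [mre_catalog()].
#' @param libraries a [library_table()]; every EST's `library_id` must be
#'   present.
#' @return data.frame of class `classified_est_set` with columns `est_id`,
#'   `library_id`, `tissue`, `histology`, `configuration`, `isoform_class`
#'   (`containing`, `free` or `excluded`).
#' @export
classify_all <- function(ests, mre_interval, libraries) {
  if (is.data.frame(mre_interval))
    mre_interval <- c(mre_interval$start[1L], mre_interval$end[1L])
  missing <- setdiff(unique(ests$library_id), libraries$library_id)
  if (length(missing) > 0L)
    stop("unknown library_id(s): ", paste(missing, collapse = ", "))
  config <- vapply(ests$blocks, classify_est, character(1L),
                   mre_interval = mre_interval)
  idx <- match(ests$library_id, libraries$library_id)
  out <- data.frame(
    est_id = ests$est_id,
    library_id = ests$library_id,
    tissue = libraries$tissue[idx],
    histology = libraries$histology[idx],
    configuration = config,
    isoform_class = unname(config_to_class[config]),
    stringsAsFactors = FALSE)
  class(out) <- c("classified_est_set", "data.frame")
  out
}
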