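# File readers/writers shared by the whole pipeline.
#
# Coordinate conventions: every interval held in memory is 0-based,
# half-open [start, end).  Every TSV read or written by the package uses
# 1-based inclusive coordinates (printed start = internal start + 1,
# printed end = internal end).  BED12 keeps its native 0-based half-open
# convention.  Strand is ignored throughout: ESTs and MRE sites are assumed
# to be oriented to the mRNA sense strand already.

#' Construct a reference-sequence set
#'
#' @param id character vector of unique sequence identifiers.
#' @param sequence character vector of nucleotide sequences; normalized to
#'   uppercase DNA alphabet (U is mapped to T).  `N` is accepted but never
#'   matches in exact-match searches.
#' @return A `reference_set`: a data.frame with columns `id`, `sequence`,
#'   `length`.
#' @export
reference_set <- function(id, sequence) {
  id <- as.character(id)
  sequence <- normalize_nt(as.character(sequence))
  if (length(id) != length(sequence))
    stop("id and sequence must have the same length")
  if (anyDuplicated(id))
    stop("duplicate reference id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for reference ", id[!nzchar(sequence)][1L])
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("non-nucleotide characters in reference ", id[bad][1L])
  structure(
    data.frame(id = id, sequence = sequence,
               length = nchar(sequence), stringsAsFactors = FALSE),
    class = c("reference_set", "data.frame"))
}

# Uppercase and map RNA U to DNA T.
normalize_nt <- function(x) chartr("U", "T", toupper(x))

#' Read reference transcript sequences from a FASTA file
#'
#' Sequences are normalized to the uppercase DNA alphabet (U mapped to T).
#' Records with duplicate identifiers or characters outside ACGTN are
#' rejected with an error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return A [reference_set()] with one row per record, input order kept.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  reference_set(ids, as.character(seqs))
}

#' Write a reference set to FASTA
#' @param refs a [reference_set()].
#' @param path output path.
#' @export
write_fasta <- function(refs, path) {
  x <- Biostrings::BStringSet(refs$sequence)
  names(x) <- refs$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read EST library annotations
#'
#' Expects a TSV with header `library_id`, `tissue`, `histology`
#' (histology is `normal` or `cancer`, as annotated for CGAP-style cDNA
#' libraries).
#'
#' @param path path to the TSV file.
#' @return data.frame with the three columns, class `library_table`.
#' @export
read_library_table <- function(path) {
  tab <- read_tsv_checked(path, c("library_id", "tissue", "histology"))
  library_table(tab$library_id, tab$tissue, tab$histology)
}

#' @rdname read_library_table
#' @param library_id,tissue,histology vectors defining one library per
#'   element.
#' @export
library_table <- function(library_id, tissue, histology) {
  library_id <- as.character(library_id)
  tissue <- as.character(tissue)
  histology <- as.character(histology)
  if (anyDuplicated(library_id))
    stop("duplicate library_id(s): ",
         paste(unique(library_id[duplicated(library_id)]), collapse = ", "))
  if (any(!nzchar(tissue))) stop("empty tissue label")
  bad <- !histology %in% c("normal", "cancer")
  if (any(bad))
    stop("histology must be 'normal' or 'cancer'; got: ",
         paste(unique(histology[bad]), collapse = ", "))
  structure(
    data.frame(library_id = library_id, tissue = tissue,
               histology = histology, stringsAsFactors = FALSE),
    class = c("library_table", "data.frame"))
}

#' Read the EST-to-library map
#'
#' Two-column TSV with header `est_id`, `library_id`.  Kept separate from
#' the BED12 alignments so the BED file stays standard-compliant.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `est_id`, `library_id`.
#' @export
read_est_library_map <- function(path) {
  tab <- read_tsv_checked(path, c("est_id", "library_id"))
  if (anyDuplicated(tab$est_id))
    stop("duplicate est_id(s) in library map: ",
         paste(unique(tab$est_id[duplicated(tab$est_id)]), collapse = ", "))
  tab
}

#' Construct a set of spliced EST alignments
#'
#' @param est_id,reference_id,library_id character vectors, one element per
#'   EST.
#' @param blocks list of two-column integer matrices; each row one aligned
#'   exon block as a 0-based half-open `[start, end)` interval on the
#'   reference.  Blocks must be sorted, non-overlapping, with strictly
#'   positive gaps between consecutive blocks.
#' @return An `est_set`: a data.frame with a `blocks` list-column.
#' @export
est_set <- function(est_id, reference_id, library_id, blocks) {
  est_id <- as.character(est_id)
  reference_id <- as.character(reference_id)
  library_id <- as.character(library_id)
  stopifnot(length(est_id) == length(blocks))
  blocks <- lapply(seq_along(blocks), function(i) {
    validate_blocks(blocks[[i]], est_id[i])
  })
  out <- data.frame(est_id = est_id, reference_id = reference_id,
                    library_id = library_id, stringsAsFactors = FALSE)
  out$blocks <- blocks
  class(out) <- c("est_set", "data.frame")
  out
}

validate_blocks <- function(b, est_id = "<est>") {
  b <- matrix(as.integer(b), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(b) == 0L) stop("EST ", est_id, ": empty block list")
  if (any(is.na(b)) || any(b[, 1L] < 0L))
    stop("EST ", est_id, ": invalid block coordinates")
  if (any(b[, 2L] <= b[, 1L]))
    stop("EST ", est_id, ": block with end <= start")
  if (nrow(b) > 1L) {
    if (is.unsorted(b[, 1L], strictly = TRUE))
      stop("EST ", est_id, ": blocks not sorted by start")
    gaps <- b[-1L, 1L] - b[-nrow(b), 2L]
    if (any(gaps <= 0L))
      stop("EST ", est_id, ": overlapping or abutting blocks")
  }
  b
}

#' Read spliced EST alignments from a BED12 file
#'
#' Each BED12 line is one EST aligned to a reference transcript: `chrom` is
#' the reference id, `name` the EST id, and the block fields give the exon
#' blocks.  Every EST must be present in the EST-to-library map.
#'
#' @param path path to a BED12 file.
#' @param library_map data.frame with columns `est_id`, `library_id` (see
#'   [read_est_library_map()]), or a named character vector est_id ->
#'   library_id.
#' @return An [est_set()].
#' @export
read_est_bed12 <- function(path, library_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.data.frame(library_map)) {
    lm <- library_map$library_id
    names(lm) <- library_map$est_id
  } else lm <- library_map
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) stop("no records in BED file: ", path)
  est_id <- as.character(gr$name)
  missing <- setdiff(unique(est_id), names(lm))
  if (length(missing) > 0L)
    stop("est_id(s) missing from library map: ",
         paste(missing, collapse = ", "))
  chrom_start <- BiocGenerics::start(gr) - 1L  # back to BED 0-based
  if (!is.null(gr$blocks)) {
    blocks <- lapply(seq_along(gr), function(i) {
      rel <- gr$blocks[[i]]  # 1-based within the chromStart-anchored span
      cbind(start = chrom_start[i] + BiocGenerics::start(rel) - 1L,
            end   = chrom_start[i] + BiocGenerics::end(rel))
    })
  } else {
    blocks <- lapply(seq_along(gr), function(i) {
      cbind(start = chrom_start[i], end = BiocGenerics::end(gr)[i])
    })
  }
  est_set(est_id, as.character(GenomicRanges::seqnames(gr)),
          unname(lm[est_id]), blocks)
}

#' Write spliced EST alignments to BED12
#' @param ests an [est_set()].
#' @param path output path.
#' @export
write_est_bed12 <- function(ests, path) {
  lines <- vapply(seq_len(nrow(ests)), function(i) {
    b <- ests$blocks[[i]]
    cs <- b[1L, 1L]; ce <- b[nrow(b), 2L]
    paste(ests$reference_id[i], cs, ce, ests$est_id[i], 0L, "+",
          cs, ce, "0", nrow(b),
          paste0(paste(b[, 2L] - b[, 1L], collapse = ","), ","),
          paste0(paste(b[, 1L] - cs, collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an MRE site catalog
#'
#' @param reference_id,mirna_id character vectors.
#' @param start,end integer vectors; 0-based half-open internal coordinates.
#' @param site_id optional site identifiers (generated when `NULL`).
#' @param site_sequence optional site sequences (NA allowed); when present a
#'   sequence must have length `end - start`.
#' @param repressive_ratio optional percent repression of protein output
#'   attributed to the site, on a 0-100 scale (NA allowed).
#' @param validation one of `true`, `false`, `random`, `unknown` per site.
#' @param supported_cancer,supported_normal optional semicolon-separated
#'   tissue lists from prior enrichment analyses.
#' @param set_id optional random-set identifier (used by randomized
#'   catalogs).
#' @return An `mre_catalog` data.frame.
#' @export
mre_catalog <- function(reference_id, mirna_id, start, end,
                        site_id = NULL, site_sequence = NA_character_,
                        repressive_ratio = NA_real_,
                        validation = "unknown",
                        supported_cancer = NA_character_,
                        supported_normal = NA_character_,
                        set_id = NA_character_) {
  n <- max(length(reference_id), length(mirna_id), length(start),
           length(end))
  reference_id <- rep_len(as.character(reference_id), n)
  mirna_id <- rep_len(as.character(mirna_id), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer MRE coordinates")
  if (any(end - start < 1L))
    stop("MRE site with end <= start")
  if (is.null(site_id))
    site_id <- sprintf("%s|%s|%d-%d", reference_id, mirna_id,
                       start + 1L, end)
  site_sequence <- rep_len(as.character(site_sequence), n)
  has_seq <- !is.na(site_sequence)
  site_sequence[has_seq] <- normalize_nt(site_sequence[has_seq])
  if (any(has_seq & nchar(site_sequence) != end - start))
    stop("site_sequence length does not match the interval width")
  repressive_ratio <- rep_len(as.numeric(repressive_ratio), n)
  if (any(!is.na(repressive_ratio) &
          (repressive_ratio < 0 | repressive_ratio > 100)))
    stop("repressive_ratio outside [0, 100]")
  validation <- rep_len(as.character(validation), n)
  bad <- !validation %in% c("true", "false", "random", "unknown")
  if (any(bad)) stop("invalid validation label: ",
                     paste(unique(validation[bad]), collapse = ", "))
  out <- data.frame(
    site_id = rep_len(as.character(site_id), n),
    reference_id = reference_id,
    mirna_id = mirna_id,
    start = start, end = end,
    site_sequence = site_sequence,
    repressive_ratio = repressive_ratio,
    validation = validation,
    supported_cancer = rep_len(as.character(supported_cancer), n),
    supported_normal = rep_len(as.character(supported_normal), n),
    set_id = rep_len(as.character(set_id), n),
    stringsAsFactors = FALSE)
  class(out) <- c("mre_catalog", "data.frame")
  out
}

#' Read an MRE catalog
#'
#' TSV with header columns `gene_id`, `mirna_id`, `start`, `end` (1-based
#' inclusive) and optional `site_id`, `sequence`, `repressive_ratio`
#' (percent, 0-100), `validation`, `supported_cancer`, `supported_normal`,
#' `set_id`.
#'
#' @param path path to the TSV file.
#' @return An [mre_catalog()] with internal 0-based half-open coordinates.
#' @export
read_mre_table <- function(path) {
  tab <- read_tsv_checked(path, c("gene_id", "mirna_id", "start", "end"))
  start1 <- as.integer(tab$start); end1 <- as.integer(tab$end)
  if (any(is.na(start1)) || any(is.na(end1)))
    stop("non-integer coordinates in MRE table")
  if (any(end1 < start1))
    stop("MRE row with end < start (1-based inclusive expected)")
  if (any(start1 < 1L)) stop("MRE start below 1")
  opt <- function(nm, default) if (nm %in% names(tab)) tab[[nm]] else default
  mre_catalog(
    reference_id = tab$gene_id, mirna_id = tab$mirna_id,
    start = start1 - 1L, end = end1,
    site_id = if ("site_id" %in% names(tab)) tab$site_id else NULL,
    site_sequence = opt("sequence", NA_character_),
    repressive_ratio = opt("repressive_ratio", NA_real_),
    validation = opt("validation", "unknown"),
    supported_cancer = opt("supported_cancer", NA_character_),
    supported_normal = opt("supported_normal", NA_character_),
    set_id = opt("set_id", NA_character_))
}

#' Write an MRE catalog (1-based inclusive coordinates)
#' @param catalog an [mre_catalog()].
#' @param path output path.
#' @export
write_mre_table <- function(catalog, path) {
  out <- data.frame(
    gene_id = catalog$reference_id, mirna_id = catalog$mirna_id,
    start = catalog$start + 1L, end = catalog$end,
    site_id = catalog$site_id, sequence = catalog$site_sequence,
    repressive_ratio = catalog$repressive_ratio,
    validation = catalog$validation,
    supported_cancer = catalog$supported_cancer,
    supported_normal = catalog$supported_normal,
    set_id = catalog$set_id, stringsAsFactors = FALSE)
  write_results_tsv(out, path, convert_coords = FALSE)
}

#' Read a protein differential-expression table
#'
#' TSV with header `gene_symbol`, `log2fc`, `has_seed`, `predicted_target`,
#' `splicing_regulated`; the three flags are 0/1.  `log2fc` is the log2
#' protein fold change (e.g. from SILAC ratios).
#'
#' @param path path to the TSV file.
#' @return data.frame with logical flag columns, class `protein_table`.
#' @export
read_protein_table <- function(path) {
  tab <- read_tsv_checked(path, c("gene_symbol", "log2fc", "has_seed",
                                  "predicted_target", "splicing_regulated"))
  protein_table(tab$gene_symbol, tab$log2fc, tab$has_seed,
                tab$predicted_target, tab$splicing_regulated)
}

#' @rdname read_protein_table
#' @param gene_symbol character vector of unique protein symbols.
#' @param log2fc finite numeric log2 fold changes.
#' @param has_seed,predicted_target,splicing_regulated membership flags
#'   (logical, or 0/1).
#' @export
protein_table <- function(gene_symbol, log2fc, has_seed, predicted_target,
                          splicing_regulated) {
  gene_symbol <- as.character(gene_symbol)
  if (anyDuplicated(gene_symbol))
    stop("duplicate gene_symbol(s): ",
         paste(unique(gene_symbol[duplicated(gene_symbol)]), collapse = ", "))
  lfc <- suppressWarnings(as.numeric(log2fc))
  if (any(!is.finite(lfc)))
    stop("non-numeric or non-finite log2fc for ",
         paste(gene_symbol[!is.finite(lfc)], collapse = ", "))
  as_flag <- function(x, nm) {
    if (is.logical(x)) return(x)
    x <- as.character(x)
    if (any(!x %in% c("0", "1")))
      stop(nm, " flag must be 0 or 1")
    x == "1"
  }
  out <- data.frame(
    gene_symbol = gene_symbol, log2fc = lfc,
    has_seed = as_flag(has_seed, "has_seed"),
    predicted_target = as_flag(predicted_target, "predicted_target"),
    splicing_regulated = as_flag(splicing_regulated, "splicing_regulated"),
    stringsAsFactors = FALSE)
  class(out) <- c("protein_table", "data.frame")
  out
}

#' Write a protein table
#' @param tab a `protein_table`.
#' @param path output path.
#' @export
write_protein_table <- function(tab, path) {
  out <- data.frame(gene_symbol = tab$gene_symbol, log2fc = tab$log2fc,
                    has_seed = as.integer(tab$has_seed),
                    predicted_target = as.integer(tab$predicted_target),
                    splicing_regulated = as.integer(tab$splicing_regulated),
                    stringsAsFactors = FALSE)
  write_results_tsv(out, path, convert_coords = FALSE)
}

#' Write a result table as TSV
#'
#' Columns named `start` (or ending in `_start`) are shifted from internal
#' 0-based to printed 1-based coordinates; `end` columns are printed
#' unchanged (half-open end equals inclusive 1-based end).  P-value columns
#' (named `p`, starting with `p_`, or ending in `_p`) are rendered with 4
#' significant digits.
#'
#' @param records data.frame of results.
#' @param path output path.
#' @param convert_coords shift `start` columns by +1 (default TRUE).
#' @export
write_results_tsv <- function(records, path, convert_coords = TRUE) {
  records <- as.data.frame(records)
  if (convert_coords) {
    sc <- grep("(^|_)start$", names(records), value = TRUE)
    for (nm in sc) records[[nm]] <- records[[nm]] + 1L
  }
  pc <- grep("^(p|p_.*|.*_p)$", names(records), value = TRUE)
  for (nm in pc)
    records[[nm]] <- ifelse(is.na(records[[nm]]), NA,
                            formatC(signif(records[[nm]], 4L),
                                    format = "g", digits = 4L))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Strict TSV reader: header must contain `required`; returns character-safe
# data.frame.
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", na.strings = "NA",
                           check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  tab
}
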