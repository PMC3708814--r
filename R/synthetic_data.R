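# Seeded synthetic data with known ground truth: reference transcripts
# carrying one MRE inside a cassette exon, tissue-labelled EST libraries
# whose isoform choice follows per-tissue inclusion probabilities, and
# protein fold-change tables with planted repression shifts.
#
# Each simulated EST is a footprint window over the chosen isoform, not a
# full-length clone, so uninformative (configuration I) ESTs arise
# naturally when the window misses the MRE.  A retained cassette exon
# puts the MRE inside an exon block; a skipped exon leaves the MRE inside
# the inter-block gap.

#' Build a simulation configuration
#'
#' Defaults describe a desk-scale EST survey: single-MRE genes of 3000 nt
#' with a 200-nt cassette exon carrying a 22-nt MRE, five tissues (mixed
#' normal/cancer histology) with two libraries of 25 ESTs each, EST
#' footprints of 300-800 nt, and a shared exon-inclusion probability of
#' 0.5.
#'
#' @param n_genes number of reference genes.
#' @param gene_length reference length in nt.
#' @param exon_start,exon_end cassette exon (0-based half-open).
#' @param mre_start,mre_end MRE interval inside the cassette exon.
#' @param tissues data.frame with columns `name`, `histology`,
#'   `n_libraries`, `n_ests` (ESTs per tissue, spread over its
#'   libraries).
#' @param inclusion_prob probability that a sampled EST's isoform retains
#'   the cassette exon: a single number, a named vector by tissue, or an
#'   `n_genes` x n_tissues matrix (rows = genes) for per-gene planting.
#' @param est_window `c(min, max)` EST footprint length in nt (truncated
#'   to the isoform length).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1L, gene_length = 3000L,
                       exon_start = 1400L, exon_end = 1600L,
                       mre_start = 1489L, mre_end = 1511L,
                       tissues = data.frame(
                         name = c("brain", "embryo", "colon", "lung",
                                  "liver"),
                         histology = c("normal", "normal", "cancer",
                                       "cancer", "normal"),
                         n_libraries = 2L, n_ests = 50L,
                         stringsAsFactors = FALSE),
                       inclusion_prob = 0.5,
                       est_window = c(300L, 800L), seed = 1L) {
  stopifnot(n_genes >= 1, gene_length >= 1,
            exon_start >= 0, exon_start < exon_end,
            exon_end <= gene_length,
            mre_start >= exon_start, mre_start < mre_end,
            mre_end <= exon_end,
            est_window[1L] >= 1, est_window[1L] <= est_window[2L])
  if (est_window[2L] > gene_length)
    stop("est_window maximum exceeds gene_length")
  nt <- nrow(tissues)
  p <- inclusion_prob
  if (is.matrix(p)) {
    if (nrow(p) != n_genes || ncol(p) != nt)
      stop("inclusion_prob matrix must be n_genes x n_tissues")
  } else if (!is.null(names(p))) {
    if (!all(tissues$name %in% names(p)))
      stop("inclusion_prob vector must name every tissue")
    p <- matrix(rep(p[tissues$name], each = n_genes), nrow = n_genes)
  } else {
    p <- matrix(p[1L], nrow = n_genes, ncol = nt)
  }
  if (any(p < 0 | p > 1)) stop("inclusion probabilities outside [0, 1]")
  colnames(p) <- tissues$name
  rownames(p) <- sprintf("gene%d", seq_len(n_genes))
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 exon_start = as.integer(exon_start),
                 exon_end = as.integer(exon_end),
                 mre_start = as.integer(mre_start),
                 mre_end = as.integer(mre_end),
                 tissues = tissues, inclusion = p,
                 est_window = as.integer(est_window),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an EST dataset with known ground truth
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with `references`
#'   ([reference_set()]), `ests` ([est_set()]), `libraries`
#'   ([library_table()]), `mre` ([mre_catalog()], one site per gene) and
#'   `truth` (list: `inclusion` matrix, `regulated_sites` = site ids of
#'   genes whose inclusion differs across tissues).
#' @export
simulate_est_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    gene_ids <- rownames(cf$inclusion)
    refs <- reference_set(gene_ids, vapply(gene_ids, function(g)
      paste(sample(c("A", "C", "G", "T"), cf$gene_length,
                   replace = TRUE), collapse = ""), character(1L)))
    # libraries
    libs <- do.call(rbind, lapply(seq_len(nrow(cf$tissues)), function(i) {
      data.frame(
        library_id = sprintf("lib_%s_%d", cf$tissues$name[i],
                             seq_len(cf$tissues$n_libraries[i])),
        tissue = cf$tissues$name[i],
        histology = cf$tissues$histology[i],
        stringsAsFactors = FALSE)
    }))
    libraries <- library_table(libs$library_id, libs$tissue,
                               libs$histology)
    exlen <- cf$exon_end - cf$exon_start
    est_rows <- list(); est_n <- 0L
    for (g in seq_len(cf$n_genes)) {
      for (i in seq_len(nrow(cf$tissues))) {
        nk <- cf$tissues$n_ests[i]
        tlibs <- libs$library_id[libs$tissue == cf$tissues$name[i]]
        lib_of <- sample(tlibs, nk, replace = TRUE)
        retained <- stats::runif(nk) < cf$inclusion[g, i]
        iso_len <- ifelse(retained, cf$gene_length,
                          cf$gene_length - exlen)
        w <- cf$est_window[1L] +
          floor(stats::runif(nk) *
                  (pmin(cf$est_window[2L], iso_len) -
                     cf$est_window[1L] + 1L))
        s <- floor(stats::runif(nk) * (iso_len - w + 1L))
        for (k in seq_len(nk)) {
          est_n <- est_n + 1L
          blocks <- iso_window_to_blocks(s[k], s[k] + w[k], retained[k],
                                         cf$exon_start, cf$exon_end)
          est_rows[[est_n]] <- list(
            est_id = sprintf("est%06d", est_n),
            reference_id = gene_ids[g],
            library_id = lib_of[k], blocks = blocks)
        }
      }
    }
    ests <- est_set(
      vapply(est_rows, `[[`, character(1L), "est_id"),
      vapply(est_rows, `[[`, character(1L), "reference_id"),
      vapply(est_rows, `[[`, character(1L), "library_id"),
      lapply(est_rows, `[[`, "blocks"))
    mre <- mre_catalog(
      reference_id = gene_ids,
      mirna_id = sprintf("mir-sim-%d", seq_len(cf$n_genes)),
      start = cf$mre_start, end = cf$mre_end,
      site_id = sprintf("site_%s", gene_ids),
      site_sequence = substr(refs$sequence, cf$mre_start + 1L,
                             cf$mre_end))
    regulated <- mre$site_id[apply(cf$inclusion, 1L, function(r)
      max(r) - min(r) > 0)]
    structure(list(references = refs, ests = ests,
                   libraries = libraries, mre = mre,
                   truth = list(inclusion = cf$inclusion,
                                regulated_sites = regulated),
                   config = cf),
              class = "sim_dataset")
  })
}

# Map an isoform-coordinate window [s, e) to reference exon blocks.
# When the cassette exon is skipped, isoform coordinate u >= exon_start
# maps to reference u + exon length, so a window spanning the splice
# junction becomes two blocks around the excised exon.
iso_window_to_blocks <- function(s, e, retained, exon_start, exon_end) {
  if (retained) return(cbind(start = s, end = e))
  exlen <- exon_end - exon_start
  if (e <= exon_start) return(cbind(start = s, end = e))
  if (s >= exon_start) return(cbind(start = s + exlen, end = e + exlen))
  cbind(start = c(s, exon_end),
        end = c(exon_start, exon_end + (e - exon_start)))
}

#' Simulate a null EST dataset (no splicing regulation)
#'
#' Requires a configuration whose inclusion probability is identical
#' across tissues; the ground truth lists no regulated site.
#'
#' @param config a [sim_config()] with constant inclusion.
#' @return A `sim_dataset` (see [simulate_est_dataset()]).
#' @export
simulate_null_est_dataset <- function(config) {
  rng <- apply(config$inclusion, 1L, function(r) max(r) - min(r))
  if (any(rng > 0))
    stop("null dataset requires identical inclusion probability ",
         "across tissues")
  out <- simulate_est_dataset(config)
  stopifnot(length(out$truth$regulated_sites) == 0L)
  out
}

#' Simulate a protein fold-change table with planted repression shifts
#'
#' Background log2 fold changes are Normal(0, sigma^2).  Proteins with a
#' seed match are shifted by `-delta_seed`; proteins additionally flagged
#' as splicing-regulated (the innermost nested set) are shifted by
#' `-(delta_seed + delta_as)`.
#'
#' @param n_background proteins without a seed match.
#' @param n_seed proteins with a seed match (includes the predicted
#'   ones).
#' @param n_predicted seed proteins also supported by target prediction
#'   (includes the AS ones).
#' @param n_as predicted proteins also associated with alternative
#'   splicing.
#' @param sigma background standard deviation of log2 fold change.
#' @param delta_seed,delta_as planted negative shifts (log2 units).
#' @param seed integer seed.
#' @return list with `table` (a `protein_table`) and `truth` (the planted
#'   shift per nested set).
#' @export
simulate_protein_table <- function(n_background = 600L, n_seed = 200L,
                                   n_predicted = 120L, n_as = 60L,
                                   sigma = 0.3, delta_seed = 0.5,
                                   delta_as = 0.5, seed = 1L) {
  if (n_as > n_predicted || n_predicted > n_seed)
    stop("nesting requires n_as <= n_predicted <= n_seed")
  if (sigma < 0 || delta_seed < 0 || delta_as < 0)
    stop("sigma and deltas must be non-negative")
  with_seed(seed, {
    n <- n_background + n_seed
    has_seed <- c(rep(FALSE, n_background), rep(TRUE, n_seed))
    predicted <- c(rep(FALSE, n_background + n_seed - n_predicted),
                   rep(TRUE, n_predicted))
    as_flag <- c(rep(FALSE, n - n_as), rep(TRUE, n_as))
    shift <- ifelse(as_flag, -(delta_seed + delta_as),
                    ifelse(has_seed, -delta_seed, 0))
    lfc <- stats::rnorm(n, mean = shift, sd = sigma)
    tab <- protein_table(sprintf("P%06d", seq_len(n)), lfc, has_seed,
                         predicted, as_flag)
    list(table = tab,
         truth = list(delta_seed = delta_seed, delta_as = delta_as,
                      sigma = sigma,
                      n = c(background = n_background, seed = n_seed,
                            predicted = n_predicted, as = n_as)))
  })
}

#' Write a simulated EST dataset to a directory
#'
#' Emits `references.fasta`, `ests.bed` (BED12), `libraries.tsv`,
#' `est2lib.tsv`, `mre_catalog.tsv` and `ground_truth.tsv`, all readable
#' back with the package's readers.
#'
#' @param dataset a [simulate_est_dataset()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_est_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(dataset$references, file.path(dir, "references.fasta"))
  write_est_bed12(dataset$ests, file.path(dir, "ests.bed"))
  write_results_tsv(as.data.frame(dataset$libraries),
                    file.path(dir, "libraries.tsv"),
                    convert_coords = FALSE)
  write_results_tsv(data.frame(est_id = dataset$ests$est_id,
                               library_id = dataset$ests$library_id,
                               stringsAsFactors = FALSE),
                    file.path(dir, "est2lib.tsv"),
                    convert_coords = FALSE)
  write_mre_table(dataset$mre, file.path(dir, "mre_catalog.tsv"))
  truth <- data.frame(site_id = dataset$mre$site_id,
                      regulated = as.integer(
                        dataset$mre$site_id %in%
                          dataset$truth$regulated_sites),
                      stringsAsFactors = FALSE)
  inc <- as.data.frame(dataset$truth$inclusion)
  names(inc) <- paste0("inclusion_", names(inc))
  write_results_tsv(cbind(truth, inc),
                    file.path(dir, "ground_truth.tsv"),
                    convert_coords = FALSE)
  invisible(dir)
}
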