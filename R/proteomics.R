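# Cumulative repression curves over differentially expressed proteins and
# two-sample Kolmogorov-Smirnov shift tests between nested target sets.
#
# Set nesting (from the protein table flags):
#   seed_free        : detected proteins without a seed match
#   seed_all         : proteins whose transcript carries a seed match
#   seed_predicted   : seed_all further supported by target prediction
#   seed_predicted_as: seed_predicted further associated with alternative
#                      splicing
# predicted implies seed, and AS implies predicted; violations are
# rejected as data errors.

#' Convert a log2 fold change to percent change in the expression ratio
#'
#' `(2^lfc - 1) * 100`: a log2 fold change of -1 is -50 percent, 0 is 0,
#' +1 is +100.  Repression is negative by this convention.
#'
#' @param log2_fold_change numeric vector of log2 fold changes.
#' @return Percent changes.
#' @export
percent_change <- function(log2_fold_change) {
  (2^log2_fold_change - 1) * 100
}

#' Partition a protein table into nested target sets
#'
#' @param records a `protein_table` (see [read_protein_table()]).
#' @return An object of class `protein_partition`: list of data.frames
#'   `seed_free`, `seed_all`, `seed_predicted`, `seed_predicted_as`.
#' @export
partition_sets <- function(records) {
  bad <- records$predicted_target & !records$has_seed
  if (any(bad))
    stop("predicted_target without has_seed for: ",
         paste(records$gene_symbol[bad], collapse = ", "))
  bad <- records$splicing_regulated & !records$predicted_target
  if (any(bad))
    stop("splicing_regulated without predicted_target for: ",
         paste(records$gene_symbol[bad], collapse = ", "))
  out <- list(
    seed_free = records[!records$has_seed, , drop = FALSE],
    seed_all = records[records$has_seed, , drop = FALSE],
    seed_predicted = records[records$predicted_target, , drop = FALSE],
    seed_predicted_as = records[records$splicing_regulated, , drop = FALSE])
  if (nrow(out$seed_all) == 0L)
    warning("no seed-containing proteins; shift tests will be skipped")
  class(out) <- "protein_partition"
  out
}

#' Empirical cumulative curve of percent expression changes
#'
#' @param values numeric percent changes (at least one).
#' @return data.frame with strictly increasing `x` (distinct values) and
#'   nondecreasing `y` = fraction of values <= x; the final y is 1.
#' @export
cumulative_curve <- function(values) {
  if (length(values) == 0L) stop("no values for cumulative curve")
  x <- sort(unique(values))
  y <- vapply(x, function(v) mean(values <= v), numeric(1L))
  data.frame(x = x, y = y)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic D is the supremum over the pooled sample points of the
#' absolute ECDF difference.  The P value uses the asymptotic Kolmogorov
#' series `2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2)` with the
#' small-sample correction `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) *
#' D`, `ne = n1*n2/(n1+n2)`, clamped to (0, 1].
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `D`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty sample in KS test")
  pooled <- sort(unique(c(x, y)))
  Fx <- vapply(pooled, function(v) mean(x <= v), numeric(1L))
  Fy <- vapply(pooled, function(v) mean(y <= v), numeric(1L))
  D <- max(abs(Fx - Fy))
  if (D == 0) return(list(D = 0, p_value = 1, n1 = n1, n2 = n2))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  j <- seq_len(101L)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  list(D = D, p_value = min(1, max(p, .Machine$double.xmin)),
       n1 = n1, n2 = n2)
}

#' Repression-shift analysis across nested protein sets
#'
#' Tests each seed-derived set against the seed-free proteins with the
#' two-sample KS test on percent expression changes, reporting per-set
#' medians so the direction of any shift is explicit (a more negative
#' median means stronger repression).
#'
#' @param partition a [partition_sets()] result.
#' @return data.frame of class `mre_shift_analysis` with one row per
#'   comparison (`seed_all`, `seed_predicted`, `seed_predicted_as`, each
#'   vs `seed_free`): `comparison`, `D`, `p`, `n1`, `n2`,
#'   `median_set`, `median_seed_free`.  Empty comparison sets are skipped
#'   with a warning.
#' @export
shift_analysis <- function(partition) {
  ref <- percent_change(partition$seed_free$log2fc)
  ref_med <- if (length(ref)) stats::median(ref) else NA_real_
  rows <- lapply(c("seed_all", "seed_predicted", "seed_predicted_as"),
                 function(nm) {
    vals <- percent_change(partition[[nm]]$log2fc)
    if (length(vals) == 0L || length(ref) == 0L) {
      warning("comparison ", nm, " vs seed_free skipped (empty set)")
      return(NULL)
    }
    ks <- ks_two_sample(vals, ref)
    data.frame(comparison = paste0(nm, "_vs_seed_free"),
               D = ks$D, p = ks$p_value, n1 = ks$n1, n2 = ks$n2,
               median_set = stats::median(vals),
               median_seed_free = ref_med,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(comparison = character(0), D = numeric(0),
                      p = numeric(0), n1 = integer(0), n2 = integer(0),
                      median_set = numeric(0),
                      median_seed_free = numeric(0))
  class(out) <- c("mre_shift_analysis", "data.frame")
  out
}

#' Plot cumulative repression curves for the nested protein sets
#'
#' @param x a [partition_sets()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.protein_partition <- function(x, ...) {
  sets <- list(seed_free = x$seed_free, seed_all = x$seed_all,
               seed_predicted = x$seed_predicted,
               seed_predicted_as = x$seed_predicted_as)
  sets <- sets[vapply(sets, nrow, integer(1L)) > 0L]
  cols <- c(seed_free = "blue", seed_all = "red",
            seed_predicted = "purple", seed_predicted_as = "darkgreen")
  xs <- range(unlist(lapply(sets, function(s)
    percent_change(s$log2fc))))
  graphics::plot(NA, xlim = xs, ylim = c(0, 1),
                 xlab = "percent change in expression ratio",
                 ylab = "cumulative fraction", ...)
  for (nm in names(sets)) {
    cc <- cumulative_curve(percent_change(sets[[nm]]$log2fc))
    graphics::lines(stats::stepfun(cc$x, c(0, cc$y)), col = cols[nm],
                    do.points = FALSE)
  }
  graphics::legend("bottomright", legend = names(sets),
                   col = cols[names(sets)], lty = 1, bty = "n")
  invisible(x)
}
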