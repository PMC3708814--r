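# Randomized MRE catalogs as a background model, and the one-sample
# Wilcoxon signed-rank test used to compare observed splicing-regulated
# fractions against the random-set fractions.

# Evaluate expr with a temporary RNG state seeded from `seed`; the
# caller's global RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate sets of random MRE sites on reference transcripts
#'
#' Each random site is drawn by randomizing the source sequence (uniform
#' over eligible references), the site length (uniform over 18-22 nt by
#' default, truncated to what the source can hold) and the start position
#' (uniform over valid starts).  Sites are emitted as coordinates on the
#' source references, so they feed directly into the isoform enrichment
#' analysis; the site sequence is the corresponding substring.
#'
#' @param references a [reference_set()].
#' @param n_sets number of random sets.
#' @param set_size sites per set (default 100).
#' @param length_range integer `c(min, max)` site length in nt (default
#'   `c(18, 22)`).
#' @param utr3 optional data.frame (`id`, `start`, `end`; 0-based
#'   half-open) restricting sampling to 3'UTR sub-intervals of the
#'   references; when given, only annotated references are sampled.
#' @param seed integer seed; identical seeds give identical catalogs.
#' @return An [mre_catalog()] with `validation = "random"`, `mirna_id =
#'   "random"` and a `set_id` column (`set1` ... `set<n_sets>`).
#' @export
generate_random_mres <- function(references, n_sets, set_size = 100,
                                 length_range = c(18L, 22L), utr3 = NULL,
                                 seed = 1L) {
  stopifnot(n_sets >= 1, set_size >= 1,
            length_range[1L] >= 1, length_range[1L] <= length_range[2L])
  if (is.null(utr3)) {
    regions <- data.frame(id = references$id, start = 0L,
                          end = references$length,
                          stringsAsFactors = FALSE)
  } else {
    regions <- data.frame(id = as.character(utr3$id),
                          start = as.integer(utr3$start),
                          end = as.integer(utr3$end),
                          stringsAsFactors = FALSE)
    if (any(!regions$id %in% references$id))
      stop("utr3 annotation for unknown reference id")
  }
  regions <- regions[regions$end - regions$start >= length_range[1L], ,
                     drop = FALSE]
  if (nrow(regions) == 0L)
    stop("no source region long enough for the minimum site length")
  seqs <- references$sequence[match(regions$id, references$id)]
  with_seed(seed, {
    total <- n_sets * set_size
    src <- sample.int(nrow(regions), total, replace = TRUE)
    rlen <- regions$end[src] - regions$start[src]
    lens <- length_range[1L] +
      floor(stats::runif(total) *
              (pmin(length_range[2L], rlen) - length_range[1L] + 1L))
    starts <- regions$start[src] +
      floor(stats::runif(total) * (rlen - lens + 1L))
    mre_catalog(
      reference_id = regions$id[src], mirna_id = "random",
      start = starts, end = starts + lens,
      site_id = sprintf("rnd%06d", seq_len(total)),
      site_sequence = substr(seqs[src], starts - regions$start[src] + 1L,
                             starts - regions$start[src] + lens),
      validation = "random",
      set_id = rep(sprintf("set%d", seq_len(n_sets)), each = set_size))
  })
}

#' Splicing-regulated fraction of each random MRE set
#'
#' @param random_catalog an [mre_catalog()] with a `set_id` column, as
#'   produced by [generate_random_mres()].
#' @param ests an [est_set()] covering the sources.
#' @param libraries a [library_table()].
#' @param ... settings passed through to [fraction_regulated()].
#' @return Named numeric vector, one fraction per set; a set with no
#'   testable site yields NA with a warning.
#' @export
set_fractions <- function(random_catalog, ests, libraries, ...) {
  sets <- split(seq_len(nrow(random_catalog)), random_catalog$set_id)
  # keep the original set order
  sets <- sets[unique(random_catalog$set_id)]
  vapply(names(sets), function(sid) {
    sub <- random_catalog[sets[[sid]], , drop = FALSE]
    fr <- tryCatch(fraction_regulated(sub, ests, libraries, ...)$fraction,
                   error = function(e) {
                     warning("set ", sid, " has no testable site; ",
                             "excluded from the null comparison")
                     NA_real_
                   })
    fr
  }, numeric(1L))
}

#' One-sample Wilcoxon signed-rank test
#'
#' Differences equal to the hypothesized value are dropped (standard
#' signed-rank convention) and tied absolute differences receive average
#' ranks.  With 25 or fewer nonzero differences the P value is exact,
#' from the full distribution of the positive-rank sum over all 2^n sign
#' assignments (computed by convolution, which enumerates that
#' distribution without listing the assignments); above 25 a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param values numeric sample.
#' @param hypothesized the location under the null hypothesis.
#' @param alternative `two_sided` (default), `less` or `greater`.
#' @return list with `W` (sum of positive-difference ranks), `p_value`,
#'   `n` (nonzero differences) and `exact`.
#' @export
wilcoxon_one_sample <- function(values, hypothesized = 0,
                                alternative = c("two_sided", "less",
                                                "greater")) {
  alternative <- match.arg(alternative)
  values <- values[!is.na(values)]
  d <- values - hypothesized
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all values equal the hypothesized value; ",
                    "signed-rank test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null distribution of 2*W via generating-function convolution;
    # doubling makes half-integer average ranks integral
    r2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(r2)))  # counts[s+1] = #assignments with 2W=s
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(length(counts) - rr)])
      counts <- counts + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * W))
    s <- seq_along(counts) - 1L
    p_le <- sum(counts[s <= w2]) / total
    p_ge <- sum(counts[s >= w2]) / total
    p <- switch(alternative,
                two_sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le, greater = p_ge)
    return(list(W = W, p_value = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(ties^3 - ties) / 48)
  corr <- switch(alternative,
                 two_sided = sign(W - mu) * 0.5,
                 less = -0.5, greater = 0.5)
  z <- (W - mu - corr) / sigma
  p <- switch(alternative,
              two_sided = min(1, 2 * min(stats::pnorm(z),
                                         stats::pnorm(z, lower.tail = FALSE))),
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE))
  list(W = W, p_value = p, n = n, exact = FALSE)
}

#' Compare an observed regulated fraction against random-set fractions
#'
#' The observed fraction of splicing-regulated sites (from a true or
#' false MRE catalog) is the hypothesized value of a one-sample Wilcoxon
#' signed-rank test over the per-set random fractions (two-sided).
#'
#' @param observed_fraction the observed splicing-regulated fraction.
#' @param fractions per-set random fractions ([set_fractions()]); NAs are
#'   dropped.
#' @param alternative passed to [wilcoxon_one_sample()].
#' @return An object of class `mre_null_test`: list with
#'   `observed_fraction`, `set_fractions`, `mean_random_fraction`, `W`,
#'   `p_value`, `n_sets`.
#' @export
null_comparison <- function(observed_fraction, fractions,
                            alternative = "two_sided") {
  fr <- fractions[!is.na(fractions)]
  if (length(fr) == 0L) stop("no usable random-set fractions")
  wt <- wilcoxon_one_sample(fr, observed_fraction, alternative)
  out <- list(observed_fraction = observed_fraction, set_fractions = fr,
              mean_random_fraction = mean(fr), W = wt$W,
              p_value = wt$p_value, n_sets = length(fr),
              exact = wt$exact)
  class(out) <- "mre_null_test"
  out
}

#' @export
print.mre_null_test <- function(x, ...) {
  cat("Observed vs random splicing-regulated fractions\n")
  cat(sprintf("  observed fraction: %.4f\n", x$observed_fraction))
  cat(sprintf("  random sets: %d (mean fraction %.4f)\n",
              x$n_sets, x$mean_random_fraction))
  cat(sprintf("  one-sample Wilcoxon signed-rank: W = %g, P = %s (%s)\n",
              x$W, formatC(signif(x$p_value, 4L), format = "g", digits = 4L),
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}
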