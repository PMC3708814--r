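# Shared fixtures and independent brute-force oracles.

# The worked EST example: one MRE at [200, 220) on a 600-nt reference.
# Brain has 7 MRE-containing and 3 MRE-free informative ESTs; all other
# tissues (colon, lung) contribute 1 containing and 6 free; two liver
# ESTs do not cover the whole MRE and are uninformative.
worked_example_fixture <- function() {
  blocks_II <- cbind(start = 150L, end = 300L)
  blocks_III <- cbind(start = c(100L, 220L), end = c(200L, 300L))
  blocks <- c(rep(list(blocks_II), 7),          # brain containing
              rep(list(blocks_III), 3),         # brain free
              list(blocks_II),                  # colon containing
              rep(list(blocks_III), 3),         # colon free
              rep(list(blocks_III), 3),         # lung free
              list(cbind(start = 300L, end = 400L)),  # liver, no overlap
              list(cbind(start = 100L, end = 210L)))  # liver, partial
  lib <- c(rep("libBrain", 10), rep("libColon", 4), rep("libLung", 3),
           rep("libLiver", 2))
  ests <- est_set(sprintf("est%02d", seq_along(blocks)),
                  rep("g1", length(blocks)), lib, blocks)
  libraries <- library_table(
    c("libBrain", "libColon", "libLung", "libLiver"),
    c("brain", "colon", "lung", "liver"),
    c("normal", "normal", "normal", "normal"))
  list(ests = ests, libraries = libraries, mre = c(200L, 220L))
}

vegf_catalog <- function() {
  read_mre_table(system.file("extdata", "vegf_mre_catalog.tsv",
                             package = "splicemre"))
}

# Build an est_set with the requested containing/free/uninformative
# counts per tissue (one library per tissue, normal histology unless
# given).  Containing ESTs span the MRE in one exon; free ESTs skip it.
make_counted_ests <- function(counts, mre = c(200L, 220L),
                              histology = NULL) {
  # counts: data.frame(tissue, containing, free)
  blocks <- list(); lib <- character(0)
  for (i in seq_len(nrow(counts))) {
    blocks <- c(blocks,
                rep(list(cbind(start = 150L, end = 300L)),
                    counts$containing[i]),
                rep(list(cbind(start = c(100L, mre[2L]),
                               end = c(mre[1L], 300L))),
                    counts$free[i]))
    lib <- c(lib, rep(paste0("lib_", counts$tissue[i]),
                      counts$containing[i] + counts$free[i]))
  }
  ests <- est_set(sprintf("e%04d", seq_along(blocks)),
                  rep("g1", length(blocks)), lib, blocks)
  if (is.null(histology)) histology <- rep("normal", nrow(counts))
  libraries <- library_table(paste0("lib_", counts$tissue),
                             counts$tissue, histology)
  list(ests = ests, libraries = libraries, mre = mre)
}

# ---- independent oracles -------------------------------------------------

# Hypergeometric tail enumeration using stats::dhyper.
oracle_fisher <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  if (N < 1 || K == 0 || K == N || n == 0 || n == N)
    return(list(p_left = 1, p_right = 1, p_twotail = 1))
  ks <- max(0, n - (N - K)):min(n, K)
  p <- stats::dhyper(ks, K, N - K, n)
  p_obs <- p[ks == a]
  list(p_left = sum(p[ks <= a]), p_right = sum(p[ks >= a]),
       p_twotail = sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Per-base EST configuration oracle: label every MRE base from the block
# list, then apply the containment rules.
oracle_classify <- function(blocks, mre) {
  pos <- mre[1L]:(mre[2L] - 1L)
  lab <- vapply(pos, function(p) {
    if (any(p >= blocks[, 1L] & p < blocks[, 2L])) return("exon")
    if (p >= blocks[1L, 1L] && p < blocks[nrow(blocks), 2L])
      return("intron")
    "outside"
  }, character(1L))
  if (any(lab == "outside")) return("I")
  if (all(lab == "exon")) {
    # fully in one exon block?
    if (any(mre[1L] >= blocks[, 1L] & mre[2L] <= blocks[, 2L]))
      return("II")
    return("IV")
  }
  if (all(lab == "intron")) {
    gs <- blocks[-nrow(blocks), 2L]; ge <- blocks[-1L, 1L]
    if (any(mre[1L] >= gs & mre[2L] <= ge)) return("III")
    return("IV")
  }
  "IV"
}

# Random valid block list on [0, len).
random_blocks <- function(len = 400L, max_blocks = 4L) {
  k <- sample.int(max_blocks, 1L)
  cuts <- sort(sample.int(len - 1L, 2L * k))
  cbind(start = cuts[seq(1L, 2L * k, by = 2L)],
        end = cuts[seq(2L, 2L * k, by = 2L)])
}

# Signed-rank test by literal enumeration of all 2^n sign vectors.
oracle_wilcoxon <- function(values, mu = 0) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  list(W = W, p_two = min(1, 2 * min(p_le, p_ge)),
       p_le = p_le, p_ge = p_ge)
}

# KS statistic by double-loop ECDF comparison at every pooled point.
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(v)
    abs(mean(x <= v) - mean(y <= v)), numeric(1L)))
}
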