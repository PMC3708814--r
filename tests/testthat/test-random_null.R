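test_that("random MRE generation is seeded, bounded, and on-sequence", {
  refs <- reference_set(c("g1", "g2"),
                        c(paste(rep("ACGT", 200), collapse = ""),
                          paste(rep("TTGCA", 100), collapse = "")))
  c1 <- generate_random_mres(refs, n_sets = 2, set_size = 100, seed = 7)
  c2 <- generate_random_mres(refs, n_sets = 2, set_size = 100, seed = 7)
  expect_identical(c1, c2)
  c3 <- generate_random_mres(refs, n_sets = 2, set_size = 100, seed = 8)
  expect_false(identical(c1$start, c3$start))

  lens <- c1$end - c1$start
  expect_true(all(lens >= 18L & lens <= 22L))
  expect_true(all(c1$start >= 0L))
  # substring property: recorded sequence is the source substring
  src <- refs$sequence[match(c1$reference_id, refs$id)]
  expect_equal(substr(src, c1$start + 1L, c1$end), c1$site_sequence)
  expect_equal(unique(c1$validation), "random")
  expect_equal(sort(unique(c1$set_id)), c("set1", "set2"))
})

test_that("short sources constrain or forbid sampling", {
  tiny <- reference_set("s", paste(rep("A", 18), collapse = ""))
  cat1 <- generate_random_mres(tiny, n_sets = 1, set_size = 20, seed = 1)
  expect_true(all(cat1$start == 0L & cat1$end == 18L))
  too_short <- reference_set("s", "ACGTACGTACGT")
  expect_error(generate_random_mres(too_short, n_sets = 1), "long enough")
})

test_that("3'UTR mode samples only inside the annotated interval", {
  refs <- reference_set("g1", paste(rep("ACGT", 200), collapse = ""))
  utr <- data.frame(id = "g1", start = 700L, end = 800L)
  cat1 <- generate_random_mres(refs, n_sets = 1, set_size = 50,
                               utr3 = utr, seed = 2)
  expect_true(all(cat1$start >= 700L & cat1$end <= 800L))
})

test_that("wilcoxon_one_sample exact values and conventions", {
  w <- wilcoxon_one_sample(1:6, 0)
  expect_equal(w$W, 21)
  expect_equal(w$p_value, 2 / 64)
  expect_true(w$exact)

  # perfect symmetry around the hypothesized value
  expect_equal(wilcoxon_one_sample(c(4, 6), 5)$p_value, 1)

  expect_error(wilcoxon_one_sample(rep(3, 5), 3), "undefined")

  # agrees with stats::wilcox.test where the latter is exact
  set.seed(13)
  for (i in 1:20) {
    v <- round(stats::rnorm(sample(4:15, 1)), 3)
    v <- v[v != 0]
    ours <- wilcoxon_one_sample(v, 0)
    ref <- suppressWarnings(stats::wilcox.test(v, mu = 0, exact = TRUE))
    if (!anyDuplicated(abs(v)))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(ours$W, unname(ref$statistic))
  }
})

test_that("exact signed-rank matches literal 2^n enumeration", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    v <- round(stats::rnorm(n), 1)
    v <- v[v != 0]
    if (length(v) == 0L) next
    ours <- wilcoxon_one_sample(v, 0)
    bf <- oracle_wilcoxon(v, 0)
    expect_equal(ours$W, bf$W)
    expect_equal(ours$p_value, bf$p_two, tolerance = 1e-12)
    expect_equal(wilcoxon_one_sample(v, 0, "less")$p_value, bf$p_le,
                 tolerance = 1e-12)
    expect_equal(wilcoxon_one_sample(v, 0, "greater")$p_value, bf$p_ge,
                 tolerance = 1e-12)
  }
})

test_that("two-sided P is invariant under reflection", {
  set.seed(19)
  for (i in 1:20) {
    v <- stats::rnorm(10, mean = 0.3)
    m <- 0.1
    p1 <- wilcoxon_one_sample(v, m)$p_value
    p2 <- wilcoxon_one_sample(2 * m - v, m)$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("the large-sample branch approximates the exact branch", {
  set.seed(23)
  v <- stats::rnorm(26, 0.15)  # just over the exact cutoff
  approx <- wilcoxon_one_sample(v, 0)
  expect_false(approx$exact)
  ref <- suppressWarnings(stats::wilcox.test(v, mu = 0, exact = FALSE,
                                             correct = TRUE))
  expect_equal(approx$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("set_fractions reuses the enrichment machinery per set", {
  sim <- simulate_est_dataset(sim_config(seed = 31))
  # two identical sets built from the simulated site's interval
  cat1 <- mre_catalog(rep(sim$mre$reference_id, 2), c("r1", "r2"),
                      rep(sim$mre$start, 2), rep(sim$mre$end, 2),
                      validation = "random",
                      set_id = c("setA", "setB"))
  fr <- set_fractions(cat1, sim$ests, sim$libraries)
  expect_equal(unname(fr["setA"]), unname(fr["setB"]))

  # an untestable set contributes NA with a warning
  cat2 <- cat1
  cat2$reference_id <- c(cat1$reference_id[1], "absent_gene")
  expect_warning(fr2 <- set_fractions(cat2, sim$ests, sim$libraries),
                 "no testable site")
  expect_true(is.na(fr2["setB"]))
})

test_that("null_comparison wraps the signed-rank test", {
  fr <- c(0.02, 0.05, 0.03, 0.06, 0.04, 0.05, 0.07, 0.01)
  nc <- null_comparison(0.35, fr)
  expect_s3_class(nc, "mre_null_test")
  expect_equal(nc$n_sets, 8L)
  # all fractions below the observed value: strongest possible evidence
  expect_equal(nc$p_value, 2 / 2^8)
  expect_output(print(nc), "Wilcoxon")
  # symmetric fractions around the observed value are not significant
  sym <- 0.35 + c(-0.02, 0.02, -0.01, 0.01)
  expect_gt(null_comparison(0.35, sym)$p_value, 0.5)
})
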