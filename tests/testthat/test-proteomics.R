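test_that("percent_change converts log2 ratios", {
  expect_equal(percent_change(-1), -50)
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(1), 100)
})

test_that("partition_sets enforces the nesting invariant", {
  tab <- protein_table(sprintf("P%02d", 1:10), stats::rnorm(10),
                       has_seed = c(rep(0, 6), rep(1, 4)),
                       predicted_target = c(rep(0, 7), rep(1, 3)),
                       splicing_regulated = c(rep(0, 8), rep(1, 2)))
  pt <- partition_sets(tab)
  expect_equal(vapply(pt, nrow, integer(1L)),
               c(seed_free = 6L, seed_all = 4L, seed_predicted = 3L,
                 seed_predicted_as = 2L))
  expect_equal(nrow(pt$seed_free) + nrow(pt$seed_all), 10L)
  expect_true(all(pt$seed_predicted_as$gene_symbol %in%
                    pt$seed_predicted$gene_symbol))

  bad <- protein_table("X", 0.1, has_seed = 0, predicted_target = 1,
                       splicing_regulated = 0)
  expect_error(partition_sets(bad), "predicted_target without has_seed")
  bad2 <- protein_table("X", 0.1, has_seed = 1, predicted_target = 0,
                        splicing_regulated = 1)
  expect_error(partition_sets(bad2), "without predicted_target")

  none <- protein_table(c("A", "B"), c(0.1, 0.2), c(0, 0), c(0, 0),
                        c(0, 0))
  expect_warning(partition_sets(none), "skipped")
})

test_that("cumulative_curve is a proper ECDF", {
  cc <- cumulative_curve(c(-10, 0, 10))
  expect_equal(cc$x, c(-10, 0, 10))
  expect_equal(cc$y, c(1, 2, 3) / 3)
  expect_equal(cumulative_curve(c(0, 0)),
               data.frame(x = 0, y = 1))
  expect_error(cumulative_curve(numeric(0)), "no values")

  set.seed(2)
  v <- stats::rnorm(50)
  cc2 <- cumulative_curve(v)
  expect_true(all(diff(cc2$x) > 0))
  expect_true(all(diff(cc2$y) >= 0))
  expect_true(all(cc2$y >= 1 / 50 & cc2$y <= 1))
  expect_equal(cc2$y[nrow(cc2)], 1)
})

test_that("ks_two_sample statistic, symmetry, and P-value series", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  k0 <- ks_two_sample(x, y)
  expect_equal(k0$D, 0)
  expect_equal(k0$p_value, 1)

  k1 <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(k1$D, 1)
  # the asymptotic series evaluated independently at ne = 1
  lam <- (sqrt(1) + 0.12 + 0.11) * 1
  j <- 1:100
  expect_equal(k1$p_value, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2)),
               tolerance = 1e-12)

  expect_error(ks_two_sample(numeric(0), 1:3), "empty")

  set.seed(29)
  for (i in 1:30) {
    a <- stats::rnorm(sample(2:12, 1))
    b <- stats::rnorm(sample(2:12, 1), 0.5)
    ka <- ks_two_sample(a, b)
    kb <- ks_two_sample(b, a)
    expect_identical(ka$D, kb$D)
    expect_identical(ka$p_value, kb$p_value)
    # brute-force D oracle and stats::ks.test agreement
    expect_equal(ka$D, oracle_ks_D(a, b), tolerance = 1e-12)
    expect_equal(ka$D,
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("a constant negative shift increases D monotonically", {
  set.seed(37)
  base <- stats::rnorm(100)
  ref <- stats::rnorm(300)
  D <- vapply(c(0, 0.3, 0.8, 1.5), function(sh)
    ks_two_sample(base - sh, ref)$D, numeric(1L))
  expect_true(all(diff(D) > 0))
})

test_that("shift_analysis detects planted repression and orders medians", {
  sp <- simulate_protein_table(n_background = 600, n_seed = 200,
                               n_predicted = 120, n_as = 60,
                               sigma = 0.3, delta_seed = 0.5,
                               delta_as = 0.5, seed = 41)
  sa <- shift_analysis(partition_sets(sp$table))
  expect_equal(nrow(sa), 3L)
  expect_true(all(sa$p < 0.001))
  med <- sa$median_set
  names(med) <- sa$comparison
  expect_lt(med[["seed_predicted_as_vs_seed_free"]],
            med[["seed_all_vs_seed_free"]])
  expect_true(all(med < sa$median_seed_free[1]))
})

test_that("shift_analysis stays null without planted shifts", {
  hits <- 0L
  for (s in 1:40) {
    sp <- simulate_protein_table(n_background = 300, n_seed = 100,
                                 n_predicted = 60, n_as = 30,
                                 sigma = 0.3, delta_seed = 0,
                                 delta_as = 0, seed = 1000 + s)
    sa <- suppressWarnings(shift_analysis(partition_sets(sp$table)))
    if (any(sa$p < 0.001)) hits <- hits + 1L
  }
  expect_lte(hits, 2L)
})

test_that("empty comparison sets are skipped with a warning", {
  tab <- protein_table(sprintf("P%02d", 1:10), stats::rnorm(10),
                       has_seed = c(rep(0, 5), rep(1, 5)),
                       predicted_target = c(rep(0, 7), rep(1, 3)),
                       splicing_regulated = 0)
  pt <- partition_sets(tab)
  expect_warning(sa <- shift_analysis(pt), "skipped")
  expect_equal(nrow(sa), 2L)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(pt))
})
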