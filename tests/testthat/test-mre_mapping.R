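test_that("locate_mre finds exact full-length matches only", {
  ref <- reference_set("g1", "AAACGTACGTAAA")
  expect_equal(locate_mre(ref, "CGTACGT"), cbind(start = 3L, end = 10L))
  # RNA alphabet and lowercase normalize to the same hit
  expect_equal(locate_mre(ref, "cguacgu"), cbind(start = 3L, end = 10L))
  # a single mismatch yields no partial match
  expect_equal(nrow(locate_mre(ref, "CGTACGA")), 0L)
  expect_error(locate_mre(ref, ""), "non-empty")
})

test_that("N never matches in exact-match search", {
  refN <- reference_set("g", "AAACGTNCGTAAA")
  expect_equal(nrow(locate_mre(refN, "CGTNCGT")), 0L)  # N in pattern
  expect_equal(nrow(locate_mre(refN, "GTNCG")), 0L)
  # flanking regions without N still match
  expect_equal(locate_mre(refN, "AAACGT"), cbind(start = 0L, end = 6L))
})

test_that("locate_mre hits satisfy the substring identity", {
  set.seed(7)
  for (i in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    ref <- reference_set("r", seq)
    pat <- substr(seq, 101, 118)
    hits <- locate_mre(ref, pat)
    expect_gte(nrow(hits), 1L)
    for (j in seq_len(nrow(hits)))
      expect_equal(substr(seq, hits[j, "start"] + 1L, hits[j, "end"]), pat)
  }
})

test_that("find_seed_matches reports complements of miRNA nt 2-8", {
  target <- reference_set("t", "AAACTACCTCAAA")
  m <- find_seed_matches("UGAGGUAGUAGGUUGUAUAGUU", target)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 3L)
  expect_equal(m$end, 10L)
  expect_equal(m$heptamer, "CTACCTC")
  # no complement present
  expect_equal(nrow(find_seed_matches("UGAGGUAGUAGGUUGUAUAGUU",
                                      reference_set("t", "GGGGGGGGGGGG"))), 0L)
  expect_error(find_seed_matches("UGAGGUA", target), "at least 8")
})

test_that("find_seed_matches equals a brute-force 7-mer window scan", {
  set.seed(11)
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  hept <- "CTACCTC"
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "T", "G"), 200,
                        TRUE, prob = c(.4, .3, .2, .1)), collapse = "")
    # brute force: every length-7 window
    starts0 <- which(vapply(1:(200 - 6), function(s)
      substr(seq, s, s + 6) == hept, logical(1L))) - 1L
    m <- find_seed_matches(mir, reference_set("r", seq))
    expect_equal(m$start, as.integer(starts0))
  }
})

test_that("merge_regions groups by >= 90% overlap of the shorter site", {
  cat2 <- mre_catalog(rep("g", 2), c("m1", "m2"),
                      c(100L, 101L), c(120L, 121L))
  r <- merge_regions(cat2)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(100L, 121L))

  cat2b <- mre_catalog(rep("g", 2), c("m1", "m2"),
                       c(100L, 110L), c(120L, 130L))
  expect_equal(nrow(merge_regions(cat2b)), 2L)

  # transitive chain merges into one region
  chain <- mre_catalog(rep("g", 3), c("a", "b", "c"),
                       c(0L, 1L, 2L), c(20L, 21L, 22L))
  rc <- merge_regions(chain)
  expect_equal(nrow(rc), 1L)
  expect_equal(c(rc$start, rc$end), c(0L, 22L))

  # containment of a short site counts as full overlap
  cont <- mre_catalog(rep("g", 2), c("a", "b"), c(100L, 105L),
                      c(140L, 112L))
  expect_equal(nrow(merge_regions(cont)), 1L)

  expect_error(merge_regions(mre_catalog(c("g1", "g2"), c("a", "b"),
                                         c(0L, 0L), c(20L, 20L))),
               "single reference")
})

test_that("merge_regions is idempotent, order-invariant, and a partition", {
  set.seed(3)
  for (i in 1:10) {
    n <- 12L
    s <- sample.int(300L, n, replace = TRUE)
    len <- sample(18:25, n, replace = TRUE)
    cat1 <- mre_catalog(rep("g", n), sprintf("m%d", 1:n), s, s + len)
    r1 <- merge_regions(cat1)
    # partition: every site in exactly one region
    ids <- unlist(lapply(r1$members, function(m) m$site_id))
    expect_setequal(ids, cat1$site_id)
    expect_equal(length(ids), n)
    expect_equal(sum(r1$n_sites), n)
    # order invariance
    perm <- sample.int(n)
    r2 <- merge_regions(cat1[perm, ])
    expect_equal(r2[, c("start", "end", "n_sites")],
                 r1[, c("start", "end", "n_sites")])
    # idempotence: merging the region spans changes nothing
    spans <- mre_catalog(rep("g", nrow(r1)), sprintf("r%d", r1$region_index),
                         r1$start, r1$end)
    r3 <- merge_regions(spans)
    expect_equal(nrow(r3), nrow(r1))
    expect_equal(r3[, c("start", "end")], r1[, c("start", "end")])
  }
})

test_that("summarize_region ranges and the inclusive 30% threshold", {
  mk <- function(ratios) mre_catalog(rep("g", length(ratios)),
                                     sprintf("m%d", seq_along(ratios)),
                                     100L, 120L,
                                     site_id = sprintf("s%d", seq_along(ratios)),
                                     repressive_ratio = ratios)
  s <- summarize_region(mk(c(35, 39, 41, 21, 35, 30, 30, 19, 28)))
  expect_equal(s$repression_min, 19)
  expect_equal(s$repression_max, 41)
  expect_true(s$highly_repressive)

  s2 <- summarize_region(mk(13))
  expect_equal(c(s2$repression_min, s2$repression_max), c(13, 13))
  expect_false(s2$highly_repressive)

  expect_true(summarize_region(mk(30))$highly_repressive)

  # no ratios: unavailable, not an error
  s3 <- summarize_region(mk(NA_real_))
  expect_false(s3$available)
  expect_true(is.na(s3$highly_repressive))
})

test_that("region_report on the VEGF catalog reproduces printed counts", {
  regions <- merge_regions(vegf_catalog())
  expect_equal(nrow(regions), 13L)
  rep13 <- region_report(regions)
  expect_equal(rep13$n_regions, 13L)
  expect_equal(rep13$n_highly_repressive, 9L)
  expect_equal(rep13$n_supported_any, 5L)
  expect_equal(rep13$n_supported_cancer, 4L)
  expect_equal(rep13$n_supported_normal, 2L)
  # every supported region is also highly repressive
  expect_equal(rep13$n_supported_and_repressive, 5L)
  # region 2 repression range
  s2 <- summarize_region(regions[2, ])
  expect_equal(c(s2$repression_min, s2$repression_max), c(19, 41))

  empty <- merge_regions(vegf_catalog()[0, ])
  expect_equal(region_report(empty)$n_regions, 0L)
  expect_equal(region_report(empty)$n_supported_any, 0L)
})
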