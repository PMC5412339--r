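# positional percent-deletion profile, window fractions, skew

test_that("deletion footprints map reference positions to signed offsets", {
  cut <- 30L
  r1 <- make_record("a", dels = matrix(c(27, 30), 1))   # [cut-3, cut)
  expect_identical(deletion_footprint(r1, cut), c(1L, 2L, 3L))
  r2 <- make_record("b", dels = matrix(c(30, 32), 1))   # [cut, cut+2)
  expect_identical(deletion_footprint(r2, cut), c(-2L, -1L))
  expect_identical(deletion_footprint(make_record("c"), cut), integer(0))
  # insertions never contribute
  r4 <- make_record("d", ins = list(point = 30L, seq = "GG"))
  expect_identical(deletion_footprint(r4, cut), integer(0))
})

test_that("profile percentages equal brute-force per-offset recounting", {
  set.seed(31)
  mk <- make_reference(40, guide_rna("g", random_dna(20)), flank3 = 40)
  cut <- mk$cut$interbase
  sim <- simulate_cohort(mk$ref, mk$cut, nhej_model(), n = 60)
  records <- call_edits_many(mk$ref, sim$clones)
  flank <- 12L
  pp <- positional_profile(records, cut, flank)

  # independent recount: per offset, walk every record's deletion intervals
  for (k in seq_len(nrow(pp$profile))) {
    off <- pp$profile$offset[k]
    refpos <- if (off > 0) cut - off else cut + (-off) - 1L
    n_cover <- sum(vapply(records, function(r) {
      d <- r$calls[r$calls$kind == "deletion", , drop = FALSE]
      any(d$start <= refpos & refpos < d$end)
    }, TRUE))
    expect_equal(pp$profile$percent_deleted[k], 100 * n_cover / length(records))
  }
})

test_that("single-clone and saturated profiles hit 100 percent exactly", {
  cut <- 30L
  r <- make_record("a", dels = matrix(c(30, 33), 1))  # offsets -1..-3
  pp <- positional_profile(list(r), cut, flank = 5)
  expect_equal(pp$profile$percent_deleted[pp$profile$offset %in% -1:-3],
               c(100, 100, 100))
  expect_equal(sum(pp$profile$percent_deleted), 300)

  # every clone covering offset -2: downstream-anchored deletions of
  # size >= 2 on a reference built for shift-free placement (the base 5'
  # of the cut is A; everything 3' of it is A-free, so no left-alignment
  # can move a cut-anchored deletion)
  set.seed(32)
  proto <- "CCGTCGTCGTCGTCGTACGT"        # A at position 17, none after
  ref <- ref_amplicon(paste0(random_dna(40), proto, "TGG", dna_noA(80)))
  cut <- predict_cut_site(locate_protospacer(proto, ref))
  model <- nhej_model(p_unmodified = 0, p_insertion_only = 0, p_both = 0,
                      alpha = 1, small_mean = 3)
  sim <- simulate_cohort(ref, cut, model, n = 30)
  keep <- sim$truth$del_len >= 2          # size-1 deletions only reach -1
  records <- call_edits_many(ref, sim$clones[keep])
  expect_gte(length(records), 20L)
  pp2 <- positional_profile(records, cut, flank = 3)
  expect_equal(pp2$profile$percent_deleted[pp2$profile$offset == -2L], 100)
  expect_error(positional_profile(records, cut, flank = 0), "flank")
})

test_that("footprint mass within the flank is conserved against per-clone totals", {
  set.seed(33)
  mk <- make_reference(30, guide_rna("g", random_dna(20)), flank3 = 30)
  cut <- mk$cut$interbase
  sim <- simulate_cohort(mk$ref, mk$cut, nhej_model(), n = 50)
  records <- call_edits_many(mk$ref, sim$clones)
  flank <- 10L
  pp <- positional_profile(records, cut, flank)
  # sum of percentages * n / 100 = total covered (clone, offset) pairs
  lhs <- sum(pp$profile$percent_deleted) * length(records) / 100
  rhs <- sum(vapply(records, function(r) {
    fp <- deletion_footprint(r, cut)
    sum(abs(fp) <= flank)
  }, 0))
  expect_equal(lhs, rhs)
})

test_that("profile is invariant under clone order and cohort duplication", {
  set.seed(34)
  mk <- make_reference(30, guide_rna("g", random_dna(20)), flank3 = 30)
  sim <- simulate_cohort(mk$ref, mk$cut, nhej_model(), n = 30)
  records <- call_edits_many(mk$ref, sim$clones)
  p1 <- positional_profile(records, mk$cut, 8)
  p2 <- positional_profile(records[sample(length(records))], mk$cut, 8)
  expect_equal(p1$profile, p2$profile)
  p3 <- positional_profile(c(records, records), mk$cut, 8)
  expect_equal(p1$profile$percent_deleted, p3$profile$percent_deleted)
})

test_that("offset labels are exactly +flank..+1,-1..-flank and flip under the genomic convention", {
  ref <- random_dna(40)
  r <- call_edits(ref, ref)
  pp <- positional_profile(list(r), 20L, 4)
  expect_identical(pp$profile$offset, c(4L, 3L, 2L, 1L, -1L, -2L, -3L, -4L))
  pg <- positional_profile(list(r), 20L, 4, convention = "genomic")
  expect_identical(pg$profile$offset, -c(4L, 3L, 2L, 1L, -1L, -2L, -3L, -4L))
})

test_that("window fractions reproduce constructed cohort compositions", {
  cut <- 40L
  # 19 of 20 clones delete within -1..-3; 14 of 20 within +1..+3
  touch_down <- c(rep(TRUE, 19), FALSE)
  touch_up <- c(rep(TRUE, 14), rep(FALSE, 6))
  records <- lapply(1:20, function(i) {
    s <- if (touch_up[i]) cut - 2L else cut
    e <- if (touch_down[i]) cut + 2L else cut
    if (s == e) make_record(paste0("c", i))
    else make_record(paste0("c", i), dels = matrix(c(s, e), 1))
  })
  expect_equal(window_fraction(records, cut, c(-3, -1))$fraction, 95)
  expect_equal(window_fraction(records, cut, c(1, 3))$fraction, 70)
  # no clone deletes at offsets beyond the edits
  expect_equal(window_fraction(records, cut, c(-20, -10))$fraction, 0)
})

test_that("skew statistic separates symmetric and downstream-heavy cohorts", {
  set.seed(35)
  mk <- make_reference(90, guide_rna("g", random_dna(20)), flank3 = 90)

  # symmetric generator: sides agree within sampling error
  sym <- simulate_cohort(mk$ref, mk$cut,
                         nhej_model(p_unmodified = 0, p_insertion_only = 0,
                                    p_both = 0, alpha = 0.5), n = 500)
  rs <- call_edits_many(mk$ref, sym$clones)
  sk <- skew_statistic(rs, mk$cut, flank = 10)
  expect_lt(abs(sk$upstream_mean - sk$downstream_mean), 8)

  # alpha = 0.8, large deletions only: downstream side dominates
  big <- simulate_cohort(mk$ref, mk$cut,
                         nhej_model(p_unmodified = 0, p_insertion_only = 0,
                                    p_both = 0, alpha = 0.8, w_small = 0),
                         n = 500)
  rb <- call_edits_many(mk$ref, big$clones)
  skb <- skew_statistic(rb, mk$cut, flank = 10, large_threshold = 20)
  expect_gt(skb$large$downstream_mean, skb$large$upstream_mean)

  # single clone deleting only +1: upstream positive, downstream zero
  one <- make_record("x", dels = matrix(c(mk$cut$interbase - 1L,
                                          mk$cut$interbase), 1))
  sk1 <- skew_statistic(list(one), mk$cut, flank = 5)
  expect_gt(sk1$upstream_mean, 0)
  expect_equal(sk1$downstream_mean, 0)
  expect_null(sk1$large)   # absent, not zero
})

test_that("alpha-hat recovers the generator's downstream fraction", {
  set.seed(36)
  mk <- make_reference(90, guide_rna("g", random_dna(20)), flank3 = 90)
  for (alpha in c(0.2, 0.8)) {
    sim <- simulate_cohort(mk$ref, mk$cut,
                           nhej_model(p_unmodified = 0, p_insertion_only = 0,
                                      p_both = 0, alpha = alpha), n = 400)
    records <- call_edits_many(mk$ref, sim$clones)
    expect_lt(abs(estimate_alpha(records, mk$cut) - alpha), 0.06)
  }
})

test_that("insertion points are histogrammed relative to the cut", {
  set.seed(38)
  ref <- random_dna(60); cut <- 30L
  clone <- paste0(substr(ref, 1, 30), "TTTTTTTT", substring(ref, 31))
  rec <- call_edits(ref, clone)
  h <- insertion_points(list(rec, rec), cut)
  expect_identical(nrow(h), 1L)
  expect_identical(h$n_clones, 2L)
  expect_identical(nrow(insertion_points(list(call_edits(ref, ref)), cut)), 0L)
})
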