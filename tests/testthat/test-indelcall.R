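# alignment, indel normalization, per-clone calling, cohort summary

test_that("global alignment reproduces identity, single-deletion and all-mismatch optima", {
  s <- sc()
  aln <- global_align("ACGTACGT", "ACGTACGT", s)
  expect_identical(aln$ref_aln, aln$query_aln)
  expect_equal(aln$score, 2 * 8)

  # one base deleted: exactly one 1-nt gap in the query row
  aln2 <- global_align("ACGTACGT", "ACGACGT", s)
  expect_equal(aln2$score, gotoh_score("ACGTACGT", "ACGACGT"))
  gaps <- gregexpr("-+", aln2$query_aln)[[1]]
  expect_identical(length(gaps), 1L)
  expect_identical(attr(gaps, "match.length"), 1L)
  expect_false(grepl("-", aln2$ref_aln))

  # all-mismatch beats gapping under the default scheme
  aln3 <- global_align("AAA", "TTT", s)
  expect_equal(aln3$score, gotoh_score("AAA", "TTT"))
  expect_identical(aln3$score, -9)
  expect_false(grepl("-", paste0(aln3$ref_aln, aln3$query_aln)))

  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("alignment scores match an independent affine-gap DP oracle on random pairs", {
  set.seed(21)
  for (i in 1:100) {
    ref <- random_dna(sample(8:20, 1))
    # random edit: substitution, deletion or insertion on top of ref
    q <- ref
    for (e in seq_len(sample(0:3, 1))) {
      p <- sample(nchar(q), 1)
      q <- switch(sample(3, 1),
                  paste0(substr(q, 1, p - 1), random_dna(1), substring(q, p + 1)),
                  paste0(substr(q, 1, p - 1), substring(q, p + 1)),
                  paste0(substr(q, 1, p), random_dna(1), substring(q, p + 1)))
    }
    if (!nzchar(q)) next
    expect_equal(global_align(ref, q, sc())$score, gotoh_score(ref, q),
                 info = paste(ref, q))
  }
})

test_that("self-alignment scores at least as high as any equal-length query (optimality)", {
  set.seed(22)
  ref <- random_dna(30)
  self <- global_align(ref, ref, sc())$score
  for (i in 1:25) {
    q <- random_dna(30)
    expect_lte(global_align(ref, q, sc())$score, self)
  }
})

test_that("indel calls are left-aligned into repeat tracts (canonical placement)", {
  aln <- global_align("AAATTTCCC", "AAATCCC", sc())
  calls <- normalize_indels(aln)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$kind, "deletion")
  expect_identical(calls$length, 2L)
  # leftmost of the equivalence class {[3,5),[4,6)}
  plc <- enum_del_placements("AAATTTCCC", "AAATCCC")
  expect_identical(calls$start, min(plc[, "start"]))
  expect_identical(c(calls$start, calls$end), c(3L, 5L))

  # gapless alignment -> no calls
  expect_identical(nrow(normalize_indels(global_align("ACGT", "ACGT", sc()))), 0L)

  # unique placement at a non-repetitive locus: interval is the gapped columns
  ref <- "AAACGTGCTT"
  clone <- "AAAGCTT"   # remove CGT at [3,6); no other placement works
  expect_identical(nrow(enum_del_placements(ref, clone)), 1L)
  calls3 <- normalize_indels(global_align(ref, clone, sc()))
  expect_identical(nrow(calls3), 1L)
  expect_identical(c(calls3$start, calls3$end), c(3L, 6L))
})

test_that("left-alignment is canonical: shifting any reported deletion left changes the clone", {
  set.seed(23)
  for (i in 1:100) {
    ref <- random_dna(40)
    k <- sample(1:6, 1); s0 <- sample(0:(40 - k), 1)
    clone <- paste0(substr(ref, 1, s0), substring(ref, s0 + k + 1))
    calls <- normalize_indels(global_align(ref, clone, sc()))
    dels <- calls[calls$kind == "deletion", ]
    if (nrow(dels) != 1L) next          # rare repeat-collapse draws
    s <- dels$start[1]; e <- dels$end[1]
    if (s == 0) next
    # removing [s-1, e-1) instead must imply a different clone sequence
    left_shift <- paste0(substr(ref, 1, s - 1), substring(ref, e))
    expect_false(identical(left_shift, clone),
                 label = sprintf("deletion [%d,%d) is not left-aligned", s, e))
  }
})

test_that("calls round-trip: applying them to the reference rebuilds the clone", {
  set.seed(24)
  mk <- make_reference(40, guide_rna("g", random_dna(20)), flank3 = 40)
  sim <- simulate_cohort(mk$ref, mk$cut, nhej_model(), n = 300)
  records <- call_edits_many(mk$ref, sim$clones)
  for (i in seq_along(records)) {
    rebuilt <- apply_calls(mk$ref, records[[i]]$calls)
    # calls carry indels only; substitutions are the only admissible diff
    expect_identical(nchar(rebuilt), nchar(sim$clones[[i]]))
    if (records[[i]]$substitutions == 0L)
      expect_identical(rebuilt, unname(sim$clones[[i]]))
    expect_identical(records[[i]]$net_change,
                     nchar(sim$clones[[i]]) - nchar(mk$ref$seq))
  }
})

test_that("call_edits classifies clones and reports parsimony-canonical combined events", {
  set.seed(25)
  ref <- random_dna(100)
  cut <- 50L

  rec0 <- call_edits(ref, ref, clone_id = "same")
  expect_identical(rec0$edit_class, "unmodified")
  expect_identical(rec0$net_change, 0L)
  expect_identical(nrow(rec0$calls), 0L)

  # 72 contiguous nt removed around the cut -> one deletion of 72
  ref72 <- random_dna(200)
  clone72 <- paste0(substr(ref72, 1, 100 - 36), substring(ref72, 100 + 37))
  rec72 <- call_edits(ref72, clone72)
  expect_identical(rec72$edit_class, "deletion")
  expect_identical(total_deleted(rec72), 72L)
  expect_identical(rec72$net_change, -72L)
  expect_identical(sum(rec72$calls$kind == "deletion"), 1L)

  # 5 nt deleted at the cut + GG inserted: parsimony reports the equivalent
  # 3-nt deletion with 2 substitutions; the optimum was confirmed against
  # the DP oracle and net change is preserved
  cloneb <- paste0(substr(ref, 1, cut - 5), "GG", substring(ref, cut + 1))
  recb <- call_edits(ref, cloneb)
  expect_equal(global_align(ref, cloneb, sc())$score, gotoh_score(ref, cloneb))
  expect_identical(recb$net_change, -3L)
  expect_identical(recb$edit_class, "deletion")
  expect_identical(total_deleted(recb), 3L)
  expect_identical(recb$substitutions, 2L)

  # a long insertion (> 5 nt) far from any deletion survives as its own call
  ins <- random_dna(8)
  clonei <- paste0(substr(ref, 1, 20), ins, substring(ref, 21))
  cloneboth <- paste0(substr(clonei, 1, cut - 5 + 8), substring(clonei, cut + 1 + 8))
  recboth <- call_edits(ref, cloneboth)
  expect_identical(recboth$edit_class, "both")
  expect_identical(recboth$net_change, 8L - 5L)
})

test_that("over-truncated clones are flagged but still called", {
  ref <- random_dna(100)
  short <- substr(ref, 1, 8)
  expect_warning(rec <- call_edits(ref, short, clone_id = "trunc"),
                 "truncated")
  expect_true(rec$flagged)
  expect_identical(rec$net_change, -92L)
})

test_that("cohort summary reports deletion extremes and complete class counts", {
  ref <- random_dna(200)
  cut <- 100L
  sizes <- seq(3, 72, by = 3)                       # 24 clones spanning 3..72
  clones <- vapply(sizes, function(k) {
    d <- k %/% 2
    paste0(substr(ref, 1, cut - (k - d)), substring(ref, cut + d + 1))
  }, "")
  names(clones) <- paste0("c", sizes)
  records <- call_edits_many(ref, clones)
  s <- summarize_cohort(records)
  expect_identical(s$n_clones, 24L)
  expect_identical(s$min_deletion, 3L)
  expect_identical(s$max_deletion, 72L)
  expect_identical(sum(s$class_counts), 24L)
  expect_identical(as.integer(s$class_counts[["deletion"]]), 24L)

  # single unmodified clone: no deletion extremes
  s1 <- summarize_cohort(list(call_edits(ref, ref)))
  expect_identical(as.integer(s1$class_counts[["unmodified"]]), 1L)
  expect_true(is.na(s1$min_deletion))

  # printed-extreme style pair: deletions of 1 and 61
  mk2 <- vapply(c(1, 61), function(k)
    paste0(substr(ref, 1, cut - k), substring(ref, cut + 1)), "")
  s2 <- summarize_cohort(call_edits_many(ref, setNames(mk2, c("a", "b"))))
  expect_identical(s2$min_deletion, 1L)
  expect_identical(s2$max_deletion, 61L)

  expect_error(summarize_cohort(list()), "empty")
})

test_that("cohort summary is invariant under record permutation", {
  set.seed(26)
  mk <- make_reference(30, guide_rna("g", random_dna(20)), flank3 = 30)
  sim <- simulate_cohort(mk$ref, mk$cut, nhej_model(), n = 40)
  records <- call_edits_many(mk$ref, sim$clones)
  s1 <- summarize_cohort(records)
  s2 <- summarize_cohort(records[sample(length(records))])
  expect_identical(s1$class_counts, s2$class_counts)
  expect_identical(s1$min_deletion, s2$min_deletion)
  expect_identical(s1$max_deletion, s2$max_deletion)
})
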