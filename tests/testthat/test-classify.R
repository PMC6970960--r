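test_that("frame adjustment finds the clean reading frame", {
  orf <- "ATGGCTGCAGATGAAGCTTGCGGTCATATCAAA"  # 33 nt, 11 codons, no stops
  fr <- adjust_frame(orf)
  expect_equal(c(fr$left, fr$right), c(0L, 0L))
  expect_true(fr$clean)
  expect_equal(fr$aa, translate_dna(orf))
  # one leading base shifts the clean frame to (1, r)
  fr1 <- adjust_frame(paste0("T", orf))
  expect_equal(fr1$left, 1L)
  expect_equal(fr1$aa, fr$aa)
})

test_that("sequences with stops in all frames are flagged, not dropped", {
  junk <- strrep("TAAA", 12)  # TAA stop codons recur in every frame
  fr <- adjust_frame(junk)
  expect_false(fr$clean)
  expect_gt(fr$internal_stops, 0L)
  expect_error(adjust_frame("ATGAAA"), "too short")
})

test_that("local alignment reports identity and similarity as documented", {
  al <- align_pair("ACGTACGT", "ACGTACGT", type = "nt")
  expect_equal(al$identity, 100)
  expect_equal(al$similarity, 100)
  # K/R scores positive in BLOSUM62: 75% identical, 100% similar
  al <- align_pair("MKLV", "MRLV", type = "aa")
  expect_equal(al$identity, 75)
  expect_equal(al$similarity, 100)
  # disjoint alphabets: empty local alignment, identity 0
  al <- align_pair("AAAA", "CCCC", type = "nt")
  expect_equal(al$identity, 0)
  expect_equal(al$score, 0)
})

test_that("local alignment score matches the exhaustive substring oracle", {
  sub <- test_nt_submat()[1:2, 1:2]
  seqs <- unlist(lapply(1:3, function(l)
    apply(expand.grid(rep(list(c("A", "C")), l)), 1L, paste, collapse = "")))
  for (a in seqs) for (b in seqs) {
    got <- align_pair(a, b, type = "nt")
    want <- oracle_local_score(a, b, test_nt_submat())
    expect_equal(got$score, want,
                 info = sprintf("%s vs %s", a, b))
    if (got$score > 0) {
      expect_equal(score_alignment(got$aligned_a, got$aligned_b,
                                   test_nt_submat()), got$score)
    }
  }
})

test_that("amplicon slicing removes primers, by exact match or alignment", {
  sc <- default_primer_scheme()
  lib <- synthetic_reference_library()
  nt <- lib$nt[lib$name == "Sasa-DAA*02:01"]
  sl <- slice_amplicon(nt, "DAA", sc)
  fwd <- sc$sequence[sc$label == "DAA"]
  expect_equal(substr(nt, sl$start - nchar(fwd), sl$start - 1L), fwd)
  expect_equal(nchar(sl$seq), 450L)
  # a reference whose primer site carries one mismatch still slices via alignment
  nt2 <- nt
  substr(nt2, 3L, 3L) <- if (substr(nt2, 3L, 3L) == "A") "C" else "A"
  sl2 <- slice_amplicon(nt2, "DAA", sc)
  expect_equal(sl2$seq, sl$seq)
})

test_that("the closest allele is found by identity with an agreeing NJ sibling", {
  ref <- fixture_reference()
  daa <- ref[ref$locus == "DAA", ]
  fc <- find_closest(get_slice("Sasa-DAA*04:01", daa), daa)
  expect_equal(fc$closest$name[1L], "Sasa-DAA*04:01")
  expect_equal(fc$closest$nt_identity[1L], 100)
  expect_equal(fc$nj_sibling, "Sasa-DAA*04:01")
  expect_false(fc$discordant)
  expect_error(find_closest("ACGT", daa[1, ]), ">= 2 library alleles")
})

test_that("equidistant alleles are both reported as co-closest", {
  ref <- fixture_reference()
  daa <- ref[ref$locus == "DAA", ]
  # DAA*01:01 and DAA*01:02 have identical amplified regions
  fc <- find_closest(get_slice("Sasa-DAA*01:01", daa), daa)
  expect_setequal(fc$closest_names, c("Sasa-DAA*01:01", "Sasa-DAA*01:02"))
})

test_that("NJ sibling and identity criterion agree on every fixture allele", {
  ref <- fixture_reference()
  for (locus in c("UBA", "DAA", "DAB")) {
    sub <- ref[ref$locus == locus, ]
    for (i in seq_len(nrow(sub))) {
      fc <- find_closest(sub$nt[i], sub)
      expect_false(fc$discordant, info = sub$name[i])
    }
  }
})

test_that("classification reports compose frame, alignment, tree and proposal", {
  ref <- fixture_reference()
  uba <- ref[ref$locus == "UBA", ]
  rep1 <- classify_candidate("known", get_slice("Sasa-UBA*13:01", uba),
                             uba, "UBA")
  expect_equal(rep1$proposal$status, "known")
  expect_equal(rep1$closest$aa_identity[1L], 100)
  expect_true(any(grepl("extracellular", rep1$notes)))  # class I caveat
  daa <- ref[ref$locus == "DAA", ]
  rep2 <- classify_candidate("ambig", get_slice("Sasa-DAA*01:02", daa),
                             daa, "DAA")
  expect_equal(rep2$proposal$status, "ambiguous_within_amplicon")
  nov <- synthetic_novel_alleles()
  cand <- slice_amplicon(nov$nt[nov$name == "AS2UBAs1"], "UBA",
                         default_primer_scheme())$seq
  rep3 <- classify_candidate("novel", cand, uba, "UBA")
  expect_equal(rep3$proposal$status, "new_group")
  expect_gte(rep3$proposal$aa_diff_to_closest, 4L)
  # similarity >= identity in every closest row with both defined
  ok <- !is.na(rep1$closest$nt_similarity)
  expect_true(all(rep1$closest$nt_similarity[ok] >= rep1$closest$nt_identity[ok] - 1e-9))
})
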