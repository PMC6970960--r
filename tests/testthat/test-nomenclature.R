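test_that("new-style colon names parse into their fields", {
  x <- parse_allele_name("Sasa-UBA*01:01:01:01")
  expect_equal(x$species, "Sasa")
  expect_equal(x$locus, "UBA")
  expect_equal(c(x$group, x$protein, x$synonymous, x$noncoding),
               c(1L, 1L, 1L, 1L))
  y <- parse_allele_name("MHC-Sasa-DAB*09:02")
  expect_equal(y$locus, "DAB")
  expect_equal(y$group, 9L)
  expect_equal(y$protein, 2L)
  expect_true(is.na(y$synonymous))
  z <- parse_allele_name("UBA*07:01")  # species prefix optional
  expect_true(is.na(z$species))
  expect_equal(format_allele_name(z), "UBA*07:01")
})

test_that("old concatenated names convert (2 group, 2 protein, 2-3 synonymous digits)", {
  x <- parse_allele_name("Sasa-DAA*0101")
  expect_equal(c(x$group, x$protein), c(1L, 1L))
  expect_true(is.na(x$synonymous))
  y <- parse_allele_name("Sasa-DAA*010102")
  expect_equal(c(y$group, y$protein, y$synonymous), c(1L, 1L, 2L))
  z <- parse_allele_name("Sasa-UBA*0101103")
  expect_equal(z$synonymous, 103L)
  expect_equal(format_allele_name(y), "Sasa-DAA*01:01:02")
})

test_that("malformed names are parse errors", {
  expect_error(parse_allele_name("Sasa-DAA*01011"), "parse error")   # 5 digits
  expect_error(parse_allele_name("Sasa-DAA*01-01"), "parse error")   # separator
  expect_error(parse_allele_name("Sasa-DAA-0101"), "parse error")    # no '*'
  expect_error(parse_allele_name("Sasa-DAA*1:01"), "field width")
})

test_that("parse/format round-trips to the canonical style for all fixture names", {
  lib <- synthetic_reference_library()
  for (nm in lib$name)
    expect_equal(format_allele_name(parse_allele_name(nm)), nm)
})

test_that("aa_difference counts mismatches and residue-vs-gap columns", {
  expect_equal(aa_difference("MKL", "MKL"), 0L)
  expect_equal(aa_difference("MKL", "MQL"), 1L)
  expect_equal(aa_difference("MKL-", "MQLV"), 2L)   # mismatch + gap
  expect_equal(aa_difference("M-L", "M-L"), 0L)     # gap-gap not a difference
  expect_error(aa_difference("MK", "MKL"), "pre-aligned")
  expect_error(aa_difference("", ""), "zero-length")
})

test_that("proposal statuses cover known, ambiguous, synonymous", {
  ref <- fixture_reference()
  uba <- ref[ref$locus == "UBA", ]
  daa <- ref[ref$locus == "DAA", ]
  # exact library sequence -> known
  pr <- propose_name(get_slice("Sasa-UBA*07:01", uba), "UBA", uba)
  expect_equal(pr$status, "known")
  expect_equal(format_allele_name(pr$proposed), "Sasa-UBA*07:01")
  # DAA*01:01 and DAA*01:02 are indistinguishable over the amplicon
  pr <- propose_name(get_slice("Sasa-DAA*01:01", daa), "DAA", daa)
  expect_equal(pr$status, "ambiguous_within_amplicon")
  expect_setequal(pr$co_closest, c("Sasa-DAA*01:01", "Sasa-DAA*01:02"))
  # a synonymous change -> same protein, new synonymous number
  pr <- propose_name(syn_mutate(get_slice("Sasa-DAA*02:01", daa)), "DAA", daa)
  expect_equal(pr$status, "new_synonymous")
  expect_equal(pr$aa_diff_to_closest, 0L)
  expect_equal(format_allele_name(pr$proposed), "Sasa-DAA*02:01:02")
})

test_that("class thresholds sit exactly at 4 (class I) and 3 (class II)", {
  ref <- fixture_reference()
  uba <- ref[ref$locus == "UBA", ]
  dab <- ref[ref$locus == "DAB", ]
  base_u <- get_slice("Sasa-UBA*02:01", uba)
  base_b <- get_slice("Sasa-DAB*02:01", dab)
  # class I: d = 3 -> new protein within the closest group
  pr <- propose_name(mutate_codons(base_u, c(100L, 105L, 110L)), "UBA", uba)
  expect_equal(pr$aa_diff_to_closest, 3L)
  expect_equal(pr$status, "new_protein")
  expect_equal(format_allele_name(pr$proposed), "Sasa-UBA*02:02")
  # class I: d = 4 -> new group, protein 01
  pr <- propose_name(mutate_codons(base_u, c(100L, 105L, 110L, 115L)), "UBA", uba)
  expect_equal(pr$aa_diff_to_closest, 4L)
  expect_equal(pr$status, "new_group")
  expect_equal(format_allele_name(pr$proposed), "Sasa-UBA*36:01")
  # class II: d = 2 -> new protein
  pr <- propose_name(mutate_codons(base_b, c(100L, 105L)), "DAB", dab)
  expect_equal(pr$aa_diff_to_closest, 2L)
  expect_equal(pr$status, "new_protein")
  expect_equal(format_allele_name(pr$proposed), "Sasa-DAB*02:02")
  # class II: d = 3 -> new group
  pr <- propose_name(mutate_codons(base_b, c(100L, 105L, 110L)), "DAB", dab)
  expect_equal(pr$status, "new_group")
  expect_equal(format_allele_name(pr$proposed), "Sasa-DAB*21:01")
})

test_that("a candidate two amino acids from UBA*35:01 is proposed as UBA*35:02", {
  ref <- fixture_reference()
  uba <- ref[ref$locus == "UBA", ]
  nov <- synthetic_novel_alleles()
  as7 <- slice_amplicon(nov$nt[nov$name == "AS7UBAs1"], "UBA",
                        default_primer_scheme())$seq
  pr <- propose_name(as7, "UBA", uba)
  expect_equal(pr$aa_diff_to_closest, 2L)
  expect_equal(pr$status, "new_protein")
  expect_equal(pr$co_closest[1L], "Sasa-UBA*35:01")
  expect_equal(format_allele_name(pr$proposed), "Sasa-UBA*35:02")
  expect_true(pr$needs_full_length)
})

test_that("proposals are invariant under library permutation", {
  ref <- fixture_reference()
  uba <- ref[ref$locus == "UBA", ]
  cand <- mutate_codons(get_slice("Sasa-UBA*13:01", uba), c(101L, 107L))
  base <- propose_name(cand, "UBA", uba)
  set.seed(99)
  for (i in 1:5) {
    perm <- propose_name(cand, "UBA", uba[sample(nrow(uba)), ])
    expect_equal(perm$status, base$status)
    expect_equal(format_allele_name(perm$proposed),
                 format_allele_name(base$proposed))
    expect_setequal(perm$co_closest, base$co_closest)
  }
})

test_that("an empty library is a configuration error", {
  ref <- fixture_reference()
  expect_error(propose_name("ACGT", "UBA", ref[0, ]), "configuration error")
})
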