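test_that("FASTA reading splits headers and preserves record order", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x desc here", "ACGT", ">y", "GGGTTT", ">z", "AAAA"), path)
  recs <- read_fasta(path)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$id, c("x", "y", "z"))
  expect_equal(recs$desc[1L], "desc here")
  expect_equal(recs$seq[1L], "ACGT")
})

test_that("empty FASTA gives an empty seqset; malformed input errors", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), path)
  expect_equal(nrow(read_fasta(path)), 0L)
  writeLines(c("ACGT", ">x"), path)
  expect_error(read_fasta(path), "format error")
  writeLines(c(">x", "ACGT", ">empty", ">y", "GG"), path)
  expect_error(read_fasta(path), "empty sequence")
})

test_that("FASTA round trip is identical modulo the 60-column wrap", {
  path <- withr::local_tempfile(fileext = ".fasta")
  set.seed(42)
  recs <- seqset(c("a", "b"), random_nt(2, 137), desc = c("first", ""))
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(back$seq, recs$seq)
  expect_equal(back$id, recs$id)
  expect_equal(max(nchar(readLines(path))), 60L)
})

test_that("FASTQ pairs read with matching ids; mismatches are pairing errors", {
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1/1", "ACGT", "+", "IIII", "@r2/1", "GGTT", "+", "!!#I"), p1)
  writeLines(c("@r1/2", "TTTT", "+", "IIII", "@r2/2", "CCCC", "+", "IIII"), p2)
  prs <- read_fastq_pairs(p1, p2)
  expect_equal(nrow(prs$r1), 2L)
  expect_equal(qual_to_int(prs$r1$qual[1L])[[1L]], rep(40L, 4L))
  expect_equal(qual_to_int(prs$r1$qual[2L])[[1L]], c(0L, 0L, 2L, 40L))
  # count mismatch
  writeLines(c("@r1/2", "TTTT", "+", "IIII"), p2)
  expect_error(read_fastq_pairs(p1, p2), "pairing error")
  # id mismatch
  writeLines(c("@r1/2", "TTTT", "+", "IIII", "@zz/2", "CCCC", "+", "IIII"), p2)
  expect_error(read_fastq_pairs(p1, p2), "pairing error.*zz")
})

test_that("FASTQ round trip preserves sequence and qualities", {
  path <- withr::local_tempfile(fileext = ".fastq")
  recs <- seqset("r", "ACGTN", qual = "IA!:h")
  write_fastq(recs, path)
  back <- read_fastq(path)
  expect_equal(back$seq, recs$seq)
  expect_equal(back$qual, recs$qual)
})

test_that("reverse complement is the standard complement, reversed, and an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAC"), "GTT")
  expect_equal(reverse_complement("ANNG"), "CNNT")
  expect_error(reverse_complement("ACGU1"), "non-nucleotide")
  set.seed(7)
  seqs <- random_nt(25, 60, alphabet = c("A", "C", "G", "T", "N"))
  expect_equal(reverse_complement(reverse_complement(seqs)), seqs)
})

test_that("translation follows the standard code with frames, stops and Ns", {
  expect_equal(translate_dna("ATGAAA"), "MK")
  expect_equal(translate_dna("TATGAAA", 1L), "MK")
  expect_equal(translate_dna("TAA"), "*")
  expect_equal(translate_dna("ATGNAA"), "MX")
  set.seed(8)
  for (s in random_nt(10, 31))
    expect_equal(nchar(translate_dna(s)), nchar(s) %/% 3L)
})

test_that("reference libraries load with name normalisation and duplicate detection", {
  path <- withr::local_tempfile(fileext = ".fasta")
  lib <- synthetic_reference_library()
  nt01 <- lib$nt[lib$name == "Sasa-DAA*01:01"]
  ntu <- lib$nt[lib$name == "Sasa-UBA*07:01"]
  writeLines(c(">Sasa-DAA*0101", nt01, ">Sasa-UBA*07:01", ntu), path)
  loaded <- load_reference_library(path)
  expect_setequal(loaded$name, c("Sasa-DAA*01:01", "Sasa-UBA*07:01"))
  expect_equal(loaded$mhc_class[loaded$locus == "UBA"], "I")
  expect_equal(loaded$mhc_class[loaded$locus == "DAA"], "II")
  expect_equal(loaded$aa[loaded$locus == "DAA"],
               lib$aa[lib$name == "Sasa-DAA*01:01"])
  writeLines(c(">Sasa-DAA*0101", nt01, ">Sasa-DAA*01:01", nt01), path)
  expect_error(load_reference_library(path), "duplicate")
  writeLines(c(">not a name", nt01), path)
  expect_error(load_reference_library(path), "name-format error")
})

test_that("the bundled synthetic library FASTA matches the generator", {
  path <- system.file("extdata", "synthetic_reference_alleles.fasta",
                      package = "mhctyper")
  loaded <- load_reference_library(path)
  lib <- synthetic_reference_library()
  lib <- lib[order(lib$locus, lib$name), ]
  expect_equal(loaded$name, lib$name)
  expect_equal(loaded$nt, lib$nt, ignore_attr = TRUE)
})

test_that("primer scheme validation enforces structure and prefix-freeness", {
  sc <- default_primer_scheme()
  expect_silent(validate_primer_scheme(sc))
  bad <- rbind(sc, data.frame(gene = "UBA", role = "forward", label = "UBA1x",
                              sequence = paste0(sc$sequence[1L], "AA")))
  expect_error(validate_primer_scheme(bad), "prefix")
  expect_error(validate_primer_scheme(sc[sc$role == "forward", ]),
               "reverse primer")
  sc2 <- sc; sc2$sequence[1L] <- "ACGU?"
  expect_error(validate_primer_scheme(sc2), "A/C/G/T")
  # fixture scheme on disk equals the built-in scheme
  disk <- read_primer_scheme(system.file("extdata", "primer_scheme.tsv",
                                         package = "mhctyper"))
  expect_equal(disk, sc, ignore_attr = TRUE)
})
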