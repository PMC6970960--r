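gt_row <- function(animal, gene, a1, a2 = NA_character_) {
  data.frame(animal = animal, gene = gene, allele_1 = a1, allele_2 = a2,
             stringsAsFactors = FALSE)
}

study_fixture <- function() {
  read_genotype_table(system.file("extdata", "study_genotypes.tsv",
                                  package = "mhctyper"))
}

test_that("a DAA-homozygous animal phases its single alpha with both betas, warning", {
  gt <- rbind(gt_row("AS5", "DAA", "DAA*06:01"),
              gt_row("AS5", "DAB", "DAB*06:01", "AS5DABs2"))
  hs <- phase_two_locus(gt)
  expect_setequal(paste(hs$haplotypes$daa, hs$haplotypes$dab),
                  c("DAA*06:01 DAB*06:01", "DAA*06:01 AS5DABs2"))
  expect_match(paste(hs$warnings, collapse = " "), "AS5")
})

test_that("an all-homozygous cohort is fully phase-known in the first step", {
  gt <- rbind(gt_row("A1", "DAA", "x"), gt_row("A1", "DAB", "y"),
              gt_row("A2", "DAA", "x"), gt_row("A2", "DAB", "z"))
  hs <- phase_two_locus(gt)
  expect_equal(nrow(hs$haplotypes), 2L)
  expect_equal(hs$haplotypes$support, c(1L, 1L))
  expect_equal(length(hs$unresolved_animals), 0L)
})

test_that("the study genotype table phases into the expected haplotype set", {
  gt <- study_fixture()
  hs <- phase_two_locus(gt[gt$gene %in% c("DAA", "DAB"), ])
  key <- paste(hs$haplotypes$daa, hs$haplotypes$dab, sep = "-")
  expect_setequal(key, c(
    "DAA*01:02-DAB*08:01", "DAA*02:01-DAB*02:01", "DAA*03:02-DAB*20:01",
    "DAA*04:01-DAB*09:01", "DAA*04:01-DAB*09:02", "DAA*06:01-AS5DABs2",
    "DAA*06:01-DAB*06:01", "DAA*09:01-DAB*07:01", "DAA*09:01-DAB*09:01"))
  h <- hs$haplotypes
  expect_equal(h$animals[key == "DAA*04:01-DAB*09:01"], "AS1,AS10")
  expect_equal(h$support[key == "DAA*06:01-DAB*06:01"], 4L)
  expect_equal(length(hs$unresolved_animals), 0L)
  # every supporting animal carries both constituent alleles
  for (i in seq_len(nrow(h))) {
    for (a in strsplit(h$animals[i], ",")[[1L]]) {
      daa <- unlist(gt[gt$animal == a & gt$gene == "DAA", c("allele_1", "allele_2")])
      dab <- unlist(gt[gt$animal == a & gt$gene == "DAB", c("allele_1", "allele_2")])
      expect_true(h$daa[i] %in% daa && h$dab[i] %in% dab,
                  label = paste(a, h$daa[i], h$dab[i]))
    }
  }
})

test_that("the exhaustive search agrees with the iterative resolution", {
  gt <- study_fixture()
  gt <- gt[gt$gene %in% c("DAA", "DAB"), ]
  h_auto <- phase_two_locus(gt)
  h_exh <- phase_two_locus(gt, method = "exhaustive")
  expect_setequal(paste(h_auto$haplotypes$daa, h_auto$haplotypes$dab),
                  paste(h_exh$haplotypes$daa, h_exh$haplotypes$dab))
})

test_that("cohorts drawn from a haplotype pool are recovered when anchored", {
  pool <- data.frame(daa = c("DAA*01", "DAA*02", "DAA*03", "DAA*04"),
                     dab = c("DAB*01", "DAB*02", "DAB*03", "DAB*04"),
                     stringsAsFactors = FALSE)
  set.seed(61)
  for (rep in 1:5) {
    # every haplotype appears in at least one homozygous (phase-known) animal
    rows <- list()
    for (i in seq_len(nrow(pool)))
      rows[[i]] <- c(i, i)
    for (j in 1:6)
      rows[[length(rows) + 1L]] <- sample(nrow(pool), 2L, replace = TRUE)
    gt <- do.call(rbind, lapply(seq_along(rows), function(k) {
      h <- rows[[k]]
      a <- sprintf("A%02d", k)
      daa <- unique(pool$daa[h]); dab <- unique(pool$dab[h])
      rbind(gt_row(a, "DAA", daa[1L], if (length(daa) > 1L) daa[2L] else NA),
            gt_row(a, "DAB", dab[1L], if (length(dab) > 1L) dab[2L] else NA))
    }))
    hs <- phase_two_locus(gt)
    expect_setequal(paste(hs$haplotypes$daa, hs$haplotypes$dab),
                    paste(pool$daa, pool$dab))
    expect_equal(length(hs$unresolved_animals), 0L)
  }
})

test_that("equal-parsimony phasings are surfaced as ambiguous, not broken silently", {
  gt <- rbind(gt_row("A1", "DAA", "a1", "a2"), gt_row("A1", "DAB", "b1", "b2"))
  hs <- phase_two_locus(gt)
  expect_equal(hs$unresolved_animals, "A1")
  expect_true(all(hs$haplotypes$status == "ambiguous"))
})

test_that("haplotype set comparison splits shared and novel", {
  inferred <- data.frame(daa = c("DAA*02:01", "DAA*04:01"),
                         dab = c("DAB*02:01", "DAB*09:01"))
  ref <- utils::read.delim(system.file("extdata", "known_haplotypes.tsv",
                                       package = "mhctyper"))
  cmp <- compare_haplotype_sets(inferred, ref)
  expect_equal(nrow(cmp$shared), 1L)
  expect_equal(cmp$novel$dab, "DAB*09:01")
  cmp2 <- compare_haplotype_sets(inferred, ref[0, ])
  expect_equal(nrow(cmp2$novel), 2L)
  cmp3 <- compare_haplotype_sets(inferred, inferred)
  expect_equal(nrow(cmp3$novel), 0L)
})

test_that("shared-allele haplotypes are annotated as possible crossover products", {
  gt <- study_fixture()
  hs <- phase_two_locus(gt[gt$gene %in% c("DAA", "DAB"), ])
  ref <- utils::read.delim(system.file("extdata", "known_haplotypes.tsv",
                                       package = "mhctyper"))
  haps <- annotate_recombinants(hs$haplotypes, ref)
  key <- paste(haps$daa, haps$dab, sep = "-")
  # DAA*04:01-DAB*09:01 shares DAA*04:01 with the known DAA*04:01-DAB*07:01
  # and DAB*09:01 with the inferred DAA*09:01-DAB*09:01
  expect_match(haps$annotation[key == "DAA*04:01-DAB*09:01"], "crossover")
})
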