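# Dereplication of merged amplicon reads: exact sequence identity defines a
# variant; variants are ranked by abundance (count descending, sequence
# lexicographic for determinism) and the top-ranked, sufficiently frequent
# variants become allele candidates.

#' Collapse merged reads into unique ranked variants
#'
#' @param merged a seqset of merged reads, or a character vector of sequences.
#' @return `data.frame(seq, count, rank, fraction)` ordered by rank; zero rows
#'   for empty input. Counts sum to the number of input reads and fractions
#'   to 1.
#' @export
collapse_reads <- function(merged) {
  seqs <- if (is.data.frame(merged)) merged$seq else as.character(merged)
  if (length(seqs) == 0L)
    return(data.frame(seq = character(), count = integer(), rank = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  tab <- table(seqs)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$fraction <- out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

#' Select allele candidates from ranked variants
#'
#' The top `top_n` variants with `fraction >= min_fraction` proceed to
#' classification. The default minimum fraction of 1% (the low end of the
#' observed top-variant share) keeps true alleles whose counts are depressed
#' by primer-efficiency differences.
#'
#' @param variants output of [collapse_reads()].
#' @param top_n maximum number of candidates (default 5).
#' @param min_fraction minimum read fraction (default 0.01).
#' @export
select_candidates <- function(variants, top_n = 5L, min_fraction = 0.01) {
  keep <- variants[variants$fraction >= min_fraction, , drop = FALSE]
  utils::head(keep, top_n)
}

#' Candidate FASTA-style identifiers
#'
#' Builds the `<animal>_<gene><primerLabel>_s<rank>_<count>` naming used in
#' reports (e.g. `AS1_DAA_s1_39861`).
#'
#' @param variants output of [collapse_reads()] / [select_candidates()].
#' @param animal,gene,label naming components; the forward-primer `label`
#'   (which already encodes the gene, e.g. `UBA1`) replaces the bare gene
#'   name when given.
#' @export
name_candidates <- function(variants, animal, gene, label = "") {
  label <- rep_len(as.character(label), nrow(variants))
  mid <- ifelse(nzchar(label) & !is.na(label), label, gene)
  sprintf("%s_%s_s%d_%d", animal, mid, variants$rank, variants$count)
}
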