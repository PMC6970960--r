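# Overlap merging of read pairs into full-length amplicon sequences. Mate 2
# is reverse-complemented, every admissible overlap placement is scored by
# substitution mismatch density (no indels, as in overlap-merging tools for
# short amplicons), and the lowest-density placement wins, ties going to the
# longest overlap. Both standard ("innie") and read-through ("outie")
# orientations are scanned; outie merges return the overlap region only so
# that adapter overhang never enters the merged sequence.

#' Merge one read pair
#'
#' @param r1,r2 single-row seqsets (or lists with `seq`/`qual`) for the two
#'   mates; `r2` is given in sequencing orientation and is
#'   reverse-complemented internally.
#' @param min_overlap minimum overlap length in bases (default 10).
#' @param max_mismatch_density maximum mismatches/overlap-length for a merge
#'   to succeed (default 0.25).
#' @return on success a list with `seq`, `qual`, `overlap_len`,
#'   `mismatches_in_overlap`, `source_pair_id`; on failure a list with
#'   `failed = TRUE` and `reason` (`"no_overlap"` or `"too_divergent"`).
#' @details Consensus at disagreeing overlap positions takes the base with the
#'   higher quality (quality = absolute difference, floored at 2); agreeing
#'   positions keep the maximum of the two qualities. `N` matches anything and
#'   defers to the other base. A best placement whose mismatch density
#'   exceeds 0.5 is indistinguishable from a random placement and is reported
#'   as `no_overlap`; densities between `max_mismatch_density` and 0.5 are
#'   reported as `too_divergent`.
#' @export
merge_pair <- function(r1, r2, min_overlap = 10L, max_mismatch_density = 0.25) {
  res <- merge_bucket(seqset(r1$id, r1$seq, qual = r1$qual),
                      seqset(r2$id, r2$seq, qual = r2$qual),
                      min_overlap, max_mismatch_density)
  if (res$stats$n_merged == 1L) {
    m <- res$merged
    list(seq = m$seq, qual = m$qual, overlap_len = m$overlap,
         mismatches_in_overlap = m$mismatches, source_pair_id = m$id)
  } else {
    list(failed = TRUE, reason = res$failed_reason[1L])
  }
}

#' Merge all read pairs of a bucket
#'
#' Vectorised over pairs (the scan runs in compiled code).
#'
#' @param r1,r2 seqsets (mates row-aligned); primers already stripped.
#' @inheritParams merge_pair
#' @return list with `merged` (seqset plus `overlap`/`mismatches` columns),
#'   `failed_reason` per input pair (NA where merged) and `stats`
#'   (`n_input`, `n_merged`, `n_no_overlap`, `n_too_divergent`).
#' @export
merge_bucket <- function(r1, r2, min_overlap = 10L, max_mismatch_density = 0.25) {
  stopifnot(nrow(r1) == nrow(r2))
  if (nrow(r1) == 0L) {
    empty <- cbind(seqset(character(), character()),
                   overlap = integer(), mismatches = integer())
    return(list(merged = empty, failed_reason = character(),
                stats = list(n_input = 0L, n_merged = 0L,
                             n_no_overlap = 0L, n_too_divergent = 0L)))
  }
  q1 <- ifelse(is.na(r1$qual), strrep("I", nchar(r1$seq)), r1$qual)
  q2 <- ifelse(is.na(r2$qual), strrep("I", nchar(r2$seq)), r2$qual)
  r2rc <- reverse_complement(r2$seq)
  q2rc <- vapply(strsplit(q2, ""), function(x) paste(rev(x), collapse = ""), "")
  res <- merge_pairs_cpp(r1$seq, q1, r2rc, q2rc,
                         as.integer(min_overlap),
                         as.numeric(max_mismatch_density))
  ok <- res$status == 0L
  merged <- seqset(r1$id[ok], unlist(res$seq[ok], use.names = FALSE),
                   qual = unlist(res$qual[ok], use.names = FALSE))
  merged$overlap <- res$overlap[ok]
  merged$mismatches <- res$mismatches[ok]
  reason <- rep(NA_character_, nrow(r1))
  reason[res$status == 1L] <- "no_overlap"
  reason[res$status == 2L] <- "too_divergent"
  list(merged = merged, failed_reason = reason,
       stats = list(n_input = nrow(r1), n_merged = sum(ok),
                    n_no_overlap = sum(res$status == 1L),
                    n_too_divergent = sum(res$status == 2L)))
}
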