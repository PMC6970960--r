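# Read-pair preprocessing: 3' quality trimming with adapter suffix removal,
# and exact-match primer demultiplexing into per-gene, per-forward-primer
# buckets (the first-PCR primers sit at position 0 of each mate by
# construction, so matching is anchored, with zero mismatches allowed).

#' Quality-trim read pairs
#'
#' Each mate is trimmed at the 3' end at the first position where the running
#' mean quality over a 4-base window drops below `q_threshold`; afterwards any
#' read suffix exactly matching a prefix (>= 8 nt) of a configured adapter is
#' removed. A pair is rejected when either trimmed mate is shorter than
#' `min_len`.
#'
#' @param r1,r2 seqsets of equal length (mates row-aligned).
#' @param q_threshold sliding-mean Phred threshold (default 20).
#' @param min_len minimum mate length after trimming (default 100).
#' @param adapters character vector of adapter sequences (may be empty).
#' @param window sliding window size (default 4).
#' @return list with trimmed seqsets `r1`, `r2` (rejected pairs dropped) and
#'   counts `n_input`, `n_kept`, `n_rejected`.
#' @export
quality_trim <- function(r1, r2, q_threshold = 20, min_len = 100L,
                         adapters = character(), window = 4L) {
  stopifnot(nrow(r1) == nrow(r2))
  if (nrow(r1) == 0L)
    return(list(r1 = r1, r2 = r2, n_input = 0L, n_kept = 0L, n_rejected = 0L))
  if (any(is.na(r1$qual)) || any(is.na(r2$qual)))
    stop("quality trimming requires FASTQ qualities")
  trim_one <- function(rec) {
    keep <- trim_cut_cpp(rec$qual, as.integer(window), as.numeric(q_threshold))
    rec$seq <- substr(rec$seq, 1L, keep)
    rec$qual <- substr(rec$qual, 1L, keep)
    for (ad in adapters) rec <- strip_adapter_suffix(rec, ad)
    rec
  }
  r1 <- trim_one(r1); r2 <- trim_one(r2)
  ok <- nchar(r1$seq) >= min_len & nchar(r2$seq) >= min_len
  list(r1 = r1[ok, , drop = FALSE], r2 = r2[ok, , drop = FALSE],
       n_input = length(ok), n_kept = sum(ok), n_rejected = sum(!ok))
}

# remove the longest read suffix (>= 8 nt) equal to a prefix of `adapter`
strip_adapter_suffix <- function(rec, adapter, min_match = 8L) {
  L <- nchar(rec$seq)
  kmax <- pmin(L, nchar(adapter))
  cut <- rep.int(0L, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    for (k in seq.int(kmax[i], min_match)) {
      if (k < min_match) break
      if (substr(rec$seq[i], L[i] - k + 1L, L[i]) == substr(adapter, 1L, k)) {
        cut[i] <- k; break
      }
    }
  }
  rec$seq <- substr(rec$seq, 1L, L - cut)
  rec$qual <- substr(rec$qual, 1L, L - cut)
  rec
}

#' Demultiplex read pairs by first-PCR primer
#'
#' A pair is assigned to bucket (gene, forward label) iff R1 begins exactly
#' with that forward primer and R2 begins exactly with the gene's reverse
#' primer (zero mismatches). Assigned primers are stripped from both mates.
#' Scheme validation guarantees no primer is a prefix of another, so every
#' pair lands in at most one bucket.
#'
#' @param r1,r2 seqsets (mates row-aligned).
#' @param scheme a validated primer scheme (see [read_primer_scheme()]).
#' @return list with `buckets` (named `gene/label` list of
#'   `list(gene, forward_label, r1, r2, n)`), `unassigned` seqset indices,
#'   and a `counts` data.frame.
#' @export
demultiplex_by_primer <- function(r1, r2, scheme) {
  scheme <- validate_primer_scheme(scheme)
  stopifnot(nrow(r1) == nrow(r2))
  fwd <- scheme[scheme$role == "forward", , drop = FALSE]
  assigned <- rep.int(FALSE, nrow(r1))
  buckets <- list()
  for (i in seq_len(nrow(fwd))) {
    gene <- fwd$gene[i]; flab <- fwd$label[i]; fp <- fwd$sequence[i]
    rp <- scheme$sequence[scheme$gene == gene & scheme$role == "reverse"]
    sel <- !assigned & startsWith(r1$seq, fp) & startsWith(r2$seq, rp)
    assigned <- assigned | sel
    b1 <- r1[sel, , drop = FALSE]; b2 <- r2[sel, , drop = FALSE]
    b1$seq <- substring(b1$seq, nchar(fp) + 1L)
    b1$qual <- ifelse(is.na(b1$qual), b1$qual, substring(b1$qual, nchar(fp) + 1L))
    b2$seq <- substring(b2$seq, nchar(rp) + 1L)
    b2$qual <- ifelse(is.na(b2$qual), b2$qual, substring(b2$qual, nchar(rp) + 1L))
    buckets[[paste(gene, flab, sep = "/")]] <-
      list(gene = gene, forward_label = flab, r1 = b1, r2 = b2, n = nrow(b1))
  }
  counts <- data.frame(
    bucket = names(buckets),
    gene = vapply(buckets, `[[`, "", "gene"),
    forward_label = vapply(buckets, `[[`, "", "forward_label"),
    n_assigned = vapply(buckets, `[[`, 0L, "n"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(buckets = buckets, unassigned = which(!assigned),
       n_input = nrow(r1), n_assigned = sum(assigned),
       n_unassigned = sum(!assigned), counts = counts)
}
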