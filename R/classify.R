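# Candidate classification: reading-frame adjustment and translation, local
# (Smith-Waterman) alignment against the reference allele library, closest
# allele search with a neighbour-joining cross-check, and assembly of a
# per-candidate report feeding the nomenclature proposal.

#' Frame-adjust a candidate nucleotide sequence
#'
#' Removes 0-2 bases from either end so that the remaining length is a
#' multiple of 3 and the translation has as few internal stop codons as
#' possible (ties broken by the smallest left trim, then the smallest right
#' trim). When every frame contains an internal stop the candidate is flagged
#' (`clean = FALSE`) but still reported, as such sequences are usually
#' artefacts.
#'
#' @param nt nucleotide sequence (length >= 30).
#' @return list with `left`, `right`, `aa`, `internal_stops`, `clean`.
#' @export
adjust_frame <- function(nt) {
  if (nchar(nt) < 30L) stop("sequence too short to frame-adjust (< 30 nt)")
  best <- NULL
  for (l in 0:2) {
    r <- (nchar(nt) - l) %% 3L
    aa <- translate_dna(substr(nt, l + 1L, nchar(nt) - r))
    stops <- sum(strsplit(substr(aa, 1L, nchar(aa) - 1L), "")[[1L]] == "*")
    if (is.null(best) || stops < best$internal_stops)
      best <- list(left = l, right = r, aa = aa, internal_stops = stops)
  }
  best$clean <- best$internal_stops == 0L
  best
}

# substitution matrix for nucleotide local alignment: match +5 / mismatch -4,
# with N scoring -2 against bases and -1 against itself (EDNAFULL values)
nt_submat <- function() {
  m <- matrix(-4, 5L, 5L,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m) <- 5
  m["N", ] <- -2; m[, "N"] <- -2; m["N", "N"] <- -1
  m
}

aa_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Local (Smith-Waterman) pairwise alignment with identity and similarity
#'
#' Nucleotide scoring is match +5 / mismatch -4; amino-acid scoring is
#' BLOSUM62; gap opening 10 and gap extension 0.5 (a gap of length L costs
#' 10 + 0.5 L). Identity is the percentage of alignment columns with
#' identical residues; similarity additionally counts positive-scoring
#' substitutions. A pair with no positive-scoring alignment (e.g. disjoint
#' alphabets) yields identity 0 over an empty alignment.
#'
#' @param a,b sequences to align (pattern, subject).
#' @param type `"nt"` or `"aa"`.
#' @return list with `identity`, `similarity` (percent), `score`, aligned
#'   strings `aligned_a`/`aligned_b`, and 1-based subject coordinates
#'   `start_b`/`end_b` of the aligned region.
#' @export
align_pair <- function(a, b, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  sub <- if (type == "nt") nt_submat() else aa_submat()
  mk <- if (type == "nt") Biostrings::DNAString else Biostrings::AAString
  pa <- Biostrings::pairwiseAlignment(
    mk(a), mk(b), type = "local", substitutionMatrix = sub,
    gapOpening = 10, gapExtension = 0.5)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  if (Biostrings::score(pa) <= 0 || nchar(al_a) == 0L)
    return(list(identity = 0, similarity = 0, score = 0,
                aligned_a = "", aligned_b = "",
                start_b = NA_integer_, end_b = NA_integer_))
  ca <- strsplit(al_a, "")[[1L]]
  cb <- strsplit(al_b, "")[[1L]]
  len <- length(ca)
  ident <- sum(ca == cb)
  both <- ca != "-" & cb != "-"
  pos <- sum(vapply(which(both), function(i) sub[ca[i], cb[i]] > 0, TRUE))
  list(identity = 100 * ident / len,
       similarity = 100 * pos / len,
       score = Biostrings::score(pa),
       aligned_a = al_a, aligned_b = al_b,
       start_b = Biostrings::start(Biostrings::subject(pa)),
       end_b = Biostrings::end(Biostrings::subject(pa)))
}

#' Slice the amplified region out of a reference allele sequence
#'
#' Locates the gene's forward primer site and the reverse-primer site
#' (reverse complement of the reverse primer) in the reference, by exact
#' match or, failing that, best local alignment, and returns the region
#' between them (primers excluded, matching demultiplexed reads whose primers
#' are stripped).
#'
#' @param ref_nt reference nucleotide sequence.
#' @param gene gene name in the scheme.
#' @param scheme validated primer scheme.
#' @return list with `seq`, `start`, `end` (1-based, primer-exclusive) and
#'   `forward_label` of the matching forward primer.
#' @export
slice_amplicon <- function(ref_nt, gene, scheme) {
  scheme <- validate_primer_scheme(scheme)
  fwd <- scheme[scheme$gene == gene & scheme$role == "forward", , drop = FALSE]
  rev_p <- scheme$sequence[scheme$gene == gene & scheme$role == "reverse"]
  if (nrow(fwd) == 0L || length(rev_p) != 1L)
    stop("gene ", gene, " not in scheme")
  start <- NA_integer_; flab <- NA_character_
  for (i in seq_len(nrow(fwd))) {
    hit <- regexpr(fwd$sequence[i], ref_nt, fixed = TRUE)
    if (hit > 0L) {
      start <- hit + nchar(fwd$sequence[i]); flab <- fwd$label[i]; break
    }
  }
  if (is.na(start)) {  # fall back to best local alignment across primers
    best <- NULL
    for (i in seq_len(nrow(fwd))) {
      al <- align_pair(fwd$sequence[i], ref_nt, type = "nt")
      if (is.null(best) || al$score > best$score) {
        best <- al; flab <- fwd$label[i]
      }
    }
    if (is.na(best$start_b)) stop("no forward primer site found for ", gene)
    start <- best$end_b + 1L
  }
  rc <- reverse_complement(rev_p)
  hit <- regexpr(rc, ref_nt, fixed = TRUE)
  if (hit > 0L) {
    end <- as.integer(hit) - 1L
  } else {
    al <- align_pair(rc, ref_nt, type = "nt")
    if (is.na(al$start_b)) stop("no reverse primer site found for ", gene)
    end <- al$start_b - 1L
  }
  if (end < start) stop("primer sites out of order in reference for ", gene)
  list(seq = substr(ref_nt, start, end), start = start, end = end,
       forward_label = flab)
}

#' Restrict a reference library to the amplified regions
#'
#' @param library output of [load_reference_library()] (or a compatible
#'   `data.frame(name, locus, nt)`).
#' @param scheme validated primer scheme; genes must be named after loci.
#' @return the library with `nt`/`aa` replaced by their amplified-region
#'   slices (columns `full_nt` retain the originals).
#' @export
prepare_reference <- function(library, scheme) {
  library$full_nt <- library$nt
  for (i in seq_len(nrow(library))) {
    sl <- slice_amplicon(library$nt[i], library$locus[i], scheme)
    library$nt[i] <- sl$seq
    library$aa[i] <- adjust_frame(sl$seq)$aa
  }
  library
}

#' Find the closest reference allele
#'
#' The primary criterion is the best nucleotide identity from [align_pair()]
#' against every library allele (over the amplified region). A
#' neighbour-joining guide tree built from pairwise alignment distances
#' (1 - identity/100) of candidate plus library provides an independent
#' sibling estimate; discordance between the two is flagged.
#'
#' @param candidate_nt candidate sequence (amplified region).
#' @param library `data.frame(name, nt)` for the locus (>= 2 alleles),
#'   sliced to the amplified region.
#' @return list with `closest` (`data.frame(name, nt_identity,
#'   nt_similarity)`, identity-descending; co-closest rows first),
#'   `closest_names` (all tied at the top identity), `nj_sibling`,
#'   `discordant`.
#' @export
find_closest <- function(candidate_nt, library) {
  if (nrow(library) < 2L)
    stop("configuration error: closest-allele search needs >= 2 library alleles")
  aln <- lapply(library$nt, function(s) align_pair(candidate_nt, s, type = "nt"))
  tab <- data.frame(name = library$name,
                    nt_identity = vapply(aln, `[[`, 0, "identity"),
                    nt_similarity = vapply(aln, `[[`, 0, "similarity"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$nt_identity, tab$name), , drop = FALSE]
  rownames(tab) <- NULL
  top <- tab$nt_identity >= tab$nt_identity[1L] - 1e-9
  closest_names <- tab$name[top]

  # NJ guide tree over candidate + library; the library-internal block is
  # independent of the candidate and cached across calls
  labels <- c("candidate", library$name)
  n <- length(labels)
  dm <- matrix(0, n, n, dimnames = list(labels, labels))
  dm[2:n, 2:n] <- library_distmat(library)
  cand_d <- 1 - vapply(aln, `[[`, 0, "identity") / 100  # library order
  dm[1L, 2:n] <- dm[2:n, 1L] <- cand_d
  tree <- ape::nj(stats::as.dist(dm))
  nj_sibling <- nj_sister_leaf(tree, "candidate", dm)
  list(closest = tab, closest_names = closest_names,
       nj_sibling = nj_sibling,
       discordant = !(nj_sibling %in% closest_names))
}

# cache of library-internal pairwise alignment distances (1 - identity/100),
# keyed by the allele names and sequences of the (sliced) library
.distmat_cache <- new.env(parent = emptyenv())

library_distmat <- function(library) {
  key <- paste(c(library$name, substr(library$nt, 1L, 25L),
                 nchar(library$nt)), collapse = "\r")
  hit <- .distmat_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- nrow(library)
  dm <- matrix(0, n, n, dimnames = list(library$name, library$name))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    id <- align_pair(library$nt[i], library$nt[j], type = "nt")$identity
    dm[i, j] <- dm[j, i] <- 1 - id / 100
  }
  .distmat_cache[[key]] <- dm
  dm
}

# sibling of `tip` on the guide tree: the leaf nearest by tree-path
# (cophenetic) distance, negative NJ branch lengths truncated at zero; ties
# are broken toward the topological sister clade, then by name. Plain
# parent-clade extraction misplaces zero-distance duplicates, which NJ
# resolves arbitrarily.
nj_sister_leaf <- function(tree, tip, dm) {
  tree$edge.length <- pmax(tree$edge.length, 0)
  coph <- ape::cophenetic.phylo(tree)
  others <- setdiff(tree$tip.label, tip)
  tipi <- match(tip, tree$tip.label)
  parent <- tree$edge[tree$edge[, 2L] == tipi, 1L]
  kids <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], tipi)
  clade <- unlist(lapply(kids, function(k) {
    if (k <= length(tree$tip.label)) tree$tip.label[k]
    else ape::extract.clade(tree, k)$tip.label
  }))
  ord <- order(coph[tip, others], !(others %in% clade), others)
  others[ord[1L]]
}

#' Classify a candidate allele sequence
#'
#' Composes [adjust_frame()], [find_closest()], amino-acid [align_pair()]
#' against the closest allele, and [propose_name()] into a per-candidate
#' report. UBA (class I) proposals carry a note that official submission
#' requires the three extracellular domains and the transmembrane domain,
#' which this amplicon cannot provide.
#'
#' @param candidate_id identifier (see [name_candidates()]).
#' @param candidate_nt merged candidate sequence (primers stripped).
#' @param library locus-restricted reference library sliced to the amplified
#'   region (see [prepare_reference()]).
#' @param locus UBA, DAA or DAB.
#' @return an object of class `classification_report`.
#' @export
classify_candidate <- function(candidate_id, candidate_nt, library, locus) {
  fr <- adjust_frame(candidate_nt)
  fc <- find_closest(candidate_nt, library)
  best_name <- fc$closest$name[1L]
  best_aa <- library$aa[match(best_name, library$name)]
  aa_al <- align_pair(fr$aa, best_aa, type = "aa")
  prop <- propose_name(candidate_nt, locus, library, candidate_aa = fr$aa)
  closest <- fc$closest
  closest$aa_identity <- NA_real_; closest$aa_similarity <- NA_real_
  closest$aa_identity[1L] <- aa_al$identity
  closest$aa_similarity[1L] <- aa_al$similarity
  notes <- character()
  if (!fr$clean)
    notes <- c(notes, "no clean frame: internal stop codons in all frames (likely artefact)")
  if (fc$discordant)
    notes <- c(notes, sprintf("NJ sibling (%s) disagrees with identity-closest (%s)",
                              fc$nj_sibling, best_name))
  if (locus == "UBA")
    notes <- c(notes, paste("class I submission requires the three extracellular",
                            "domains and the transmembrane domain; this amplicon",
                            "must be extended by Sanger sequencing"))
  structure(list(candidate_id = candidate_id,
                 locus = locus,
                 frame_trim = c(left = fr$left, right = fr$right),
                 aa_seq = fr$aa,
                 clean_frame = fr$clean,
                 closest = closest,
                 closest_names = fc$closest_names,
                 nj_sibling = fc$nj_sibling,
                 proposal = prop,
                 notes = notes), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("candidate:", x$candidate_id, sprintf("(locus %s)\n", x$locus))
  cat(sprintf("  frame trim: left %d right %d%s\n", x$frame_trim["left"],
              x$frame_trim["right"], if (x$clean_frame) "" else " [no clean frame]"))
  top <- x$closest[1L, ]
  cat(sprintf("  closest: %s (nt id %.1f%%, nt sim %.1f%%, aa id %.1f%%, aa sim %.1f%%)\n",
              top$name, top$nt_identity, top$nt_similarity,
              top$aa_identity, top$aa_similarity))
  cat("  NJ sibling:", x$nj_sibling, "\n")
  cat("  proposal:", x$proposal$status,
      if (!is.null(x$proposal$proposed))
        paste0("-> ", format_allele_name(x$proposal$proposed)) else "", "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
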