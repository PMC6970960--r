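# Per-animal, per-gene genotype calling with jumping-PCR chimera exclusion.
# A jumping-PCR artefact arises when a partially extended strand re-anneals
# to the other allele: at every site where the two parental alleles differ,
# the artefact carries one parent's base or the other's, in a mixed pattern,
# and carries nothing novel elsewhere. Detection operates on nucleotide
# sequences (strictly more informative than the amino-acid pattern).

# project `x` onto the coordinate frame of `ref` using a global alignment:
# returns the characters of x at each ref position ('-' for deletions);
# insertions relative to ref are dropped. With equal-length substitution-only
# sequences this is the identity.
project_onto <- function(x, ref) {
  if (nchar(x) == nchar(ref)) return(x)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(x), Biostrings::BString(ref), type = "global",
    substitutionMatrix = NULL, gapOpening = 10, gapExtension = 0.5)
  ax <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  ar <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  paste(ax[ar != "-"], collapse = "")
}

#' Variable sites between two aligned parent sequences
#'
#' @param p1,p2 aligned sequences of equal length (gaps allowed; a gap
#'   opposite a residue is a differing state).
#' @return integer vector of 1-based differing positions.
#' @export
variable_sites <- function(p1, p2) {
  if (nchar(p1) != nchar(p2)) stop("parents must be aligned (equal length)")
  a <- strsplit(p1, "")[[1L]]
  b <- strsplit(p2, "")[[1L]]
  which(a != b)
}

#' Test a candidate for a jumping-PCR chimera pattern
#'
#' The candidate is a chimera of `p1` and `p2` iff it differs from both
#' parents, at every variable site carries the base of one parent or the
#' other, uses both parents at least once, and mismatches the shared parental
#' consensus at no more than `allowed_novel` invariant positions (default 0:
#' a single novel base rescues the candidate, since the jumping-PCR pattern
#' is defined by the parents' bases alone).
#'
#' @param candidate candidate sequence (aligned to the parents' frame; when
#'   lengths differ a global alignment projection is applied).
#' @param p1,p2 the two provisional parent sequences.
#' @param allowed_novel maximum novel bases at invariant positions.
#' @return an object of class `chimera_verdict`: `is_chimera`,
#'   `parent_pattern` (per variable site, 1/2/NA), `n_variable_sites`,
#'   `n_novel_positions`, `warning`.
#' @export
chimera_check <- function(candidate, p1, p2, allowed_novel = 0L) {
  p2 <- project_onto(p2, p1)
  cand <- project_onto(candidate, p1)
  warn <- NULL
  vs <- variable_sites(p1, p2)
  if (length(vs) == 0L) {
    return(structure(list(is_chimera = FALSE, parent_pattern = integer(),
                          n_variable_sites = 0L, n_novel_positions = 0L,
                          warning = "parents are identical (no variable sites)"),
                     class = "chimera_verdict"))
  }
  a <- strsplit(p1, "")[[1L]]; b <- strsplit(p2, "")[[1L]]
  cc <- strsplit(cand, "")[[1L]]
  pattern <- rep(NA_integer_, length(vs))
  pattern[cc[vs] == a[vs]] <- 1L
  pattern[cc[vs] == b[vs]] <- 2L
  inv <- setdiff(seq_along(a), vs)
  n_novel <- sum(cc[inv] != a[inv])
  is_chim <- cand != p1 && cand != p2 &&
    !anyNA(pattern) && all(c(1L, 2L) %in% pattern) &&
    n_novel <= allowed_novel
  structure(list(is_chimera = is_chim, parent_pattern = pattern,
                 n_variable_sites = length(vs),
                 n_novel_positions = n_novel, warning = warn),
            class = "chimera_verdict")
}

#' @export
print.chimera_verdict <- function(x, ...) {
  cat(if (x$is_chimera) "chimera" else "not a chimera",
      sprintf("(%d variable sites, %d novel positions)\n",
              x$n_variable_sites, x$n_novel_positions))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Call a per-animal, per-gene genotype
#'
#' The two most abundant distinct variants are the provisional parents.
#' Every lower-ranked candidate is chimera-checked against them and excluded
#' when chimeric; remaining candidates below `min_fraction` are excluded as
#' sub-threshold. Two survivors give a heterozygous call, one a homozygous
#' call (no statistical test of allele balance is applied); more than two
#' survivors call the top two with a possible extra-locus/duplication
#' warning.
#'
#' @param candidates ranked variants (output of [collapse_reads()] /
#'   [select_candidates()]), optionally with a `candidate_id` column.
#' @param animal,gene identifiers recorded in the call.
#' @param min_fraction minimum read fraction for an allele (default 0.01).
#' @param allowed_novel passed to [chimera_check()].
#' @return an object of class `genotype_call`: `animal`, `gene`, `alleles`
#'   (data.frame seq/count/fraction/rank), `zygosity`, `excluded`
#'   (data.frame rank/seq/reason), `warnings`; or a no-call (`zygosity =
#'   "no_call"`) for empty input.
#' @export
call_genotype <- function(candidates, animal = "", gene = "",
                          min_fraction = 0.01, allowed_novel = 0L) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(structure(list(animal = animal, gene = gene,
                          alleles = NULL, zygosity = "no_call",
                          excluded = NULL,
                          warnings = "no candidates (empty input)"),
                     class = "genotype_call"))
  }
  cand <- candidates[order(candidates$rank), , drop = FALSE]
  p1 <- cand$seq[1L]
  p2 <- if (nrow(cand) >= 2L) cand$seq[2L] else NULL
  keep <- rep(TRUE, nrow(cand))
  reason <- rep(NA_character_, nrow(cand))
  verdicts <- vector("list", nrow(cand))
  if (nrow(cand) >= 3L && !is.null(p2)) {
    for (i in seq.int(3L, nrow(cand))) {
      v <- chimera_check(cand$seq[i], p1, p2, allowed_novel)
      verdicts[[i]] <- v
      if (v$is_chimera) { keep[i] <- FALSE; reason[i] <- "chimera" }
    }
  }
  sub <- keep & cand$fraction < min_fraction
  keep[sub] <- FALSE; reason[sub] <- "sub_threshold"
  warnings <- character()
  idx <- which(keep)
  if (length(idx) > 2L) {
    warnings <- c(warnings, "possible extra locus/duplication: >2 supported variants")
    extra <- idx[-(1:2)]
    keep[extra] <- FALSE
    reason[extra] <- "beyond_two_alleles"
  }
  surv <- cand[keep, , drop = FALSE]
  excluded <- cand[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  zyg <- if (nrow(surv) >= 2L) "heterozygous" else "homozygous"
  structure(list(animal = animal, gene = gene, alleles = surv,
                 zygosity = zyg, excluded = excluded,
                 chimera_verdicts = verdicts, warnings = warnings),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("%s %s: %s\n", x$animal, x$gene, x$zygosity))
  if (!is.null(x$alleles))
    for (i in seq_len(nrow(x$alleles)))
      cat(sprintf("  allele %d: %d reads (%.1f%%)\n", i, x$alleles$count[i],
                  100 * x$alleles$fraction[i]))
  if (!is.null(x$excluded) && nrow(x$excluded))
    cat("  excluded:", paste(sprintf("rank %d (%s)", x$excluded$rank,
                                     x$excluded$reason), collapse = ", "), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
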