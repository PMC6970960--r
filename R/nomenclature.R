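# Fish MHC allele nomenclature: parsing of old concatenated-digit and new
# colon-delimited names, amino-acid distance between aligned sequences, and
# naming proposals for candidate sequences. Group-level name changes require
# >= 4 amino-acid differences for class I and >= 3 for class II; smaller
# non-synonymous differences yield a new protein number, nucleotide-only
# differences a new synonymous number.

#' Class-level amino-acid difference thresholds for a new allele group
#' @param mhc_class "I" or "II".
#' @return integer threshold (4 for class I, 3 for class II).
#' @export
group_threshold <- function(mhc_class) {
  switch(match.arg(mhc_class, c("I", "II")), I = 4L, II = 3L)
}

#' Parse an MHC allele name
#'
#' Accepts the new colon-delimited style (`Sasa-UBA*01:01:01:01`) and the old
#' concatenated style (`Sasa-DAA*0101`, `Sasa-DAA*010102`), with an optional
#' `MHC-` prefix; the species prefix itself is optional (`UBA*07:01`). Old
#' names convert as first two digits = group, next two = protein, trailing
#' two or three = synonymous.
#'
#' @param text the allele name.
#' @return an object of class `allele_name` with fields `species`, `locus`,
#'   `group`, `protein`, `synonymous`, `noncoding` (later fields `NA` when
#'   absent).
#' @export
parse_allele_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- trimws(text)
  x <- sub("^MHC-", "", x)
  m <- regmatches(x, regexec("^(?:([A-Za-z]{4})-)?([A-Za-z][A-Za-z0-9]*)\\*(.+)$", x))[[1L]]
  if (length(m) == 0L)
    stop("parse error: '", text, "' is not an allele name")
  species <- if (nzchar(m[2L])) m[2L] else NA_character_
  locus <- toupper(m[3L])
  fields_txt <- m[4L]
  if (grepl(":", fields_txt, fixed = TRUE)) {
    parts <- strsplit(fields_txt, ":", fixed = TRUE)[[1L]]
    if (length(parts) < 1L || length(parts) > 4L || any(!grepl("^[0-9]+$", parts)))
      stop("parse error: bad colon fields in '", text, "'")
    widths <- nchar(parts)
    ok <- widths[1L] == 2L &&
      (length(parts) < 2L || widths[2L] == 2L) &&
      (length(parts) < 3L || widths[3L] %in% 2:3) &&
      (length(parts) < 4L || widths[4L] == 2L)
    if (!ok) stop("parse error: bad field width in '", text, "'")
    f <- as.integer(parts)
    f <- c(f, rep(NA_integer_, 4L - length(f)))
  } else {
    if (!grepl("^[0-9]+$", fields_txt))
      stop("parse error: unknown separator in '", text, "'")
    n <- nchar(fields_txt)
    if (!n %in% c(2L, 4L, 6L, 7L))
      stop("parse error: old-style name '", text, "' has ", n,
           " digits (expected 2, 4, 6 or 7)")
    grp <- as.integer(substr(fields_txt, 1L, 2L))
    prot <- if (n >= 4L) as.integer(substr(fields_txt, 3L, 4L)) else NA_integer_
    syn <- if (n >= 6L) as.integer(substr(fields_txt, 5L, n)) else NA_integer_
    f <- c(grp, prot, syn, NA_integer_)
  }
  if (any(diff(is.na(f)) < 0L))
    stop("parse error: '", text, "' has a later field without earlier fields")
  structure(list(species = species, locus = locus, group = f[1L],
                 protein = f[2L], synonymous = f[3L], noncoding = f[4L]),
            class = "allele_name")
}

#' Format an allele name in the canonical colon-delimited style
#' @param x an `allele_name` (or a string, which is parsed first).
#' @param species include the species prefix when known (default `TRUE`).
#' @export
format_allele_name <- function(x, species = TRUE) {
  if (is.character(x)) x <- parse_allele_name(x)
  fields <- c(x$group, x$protein, x$synonymous, x$noncoding)
  fields <- fields[!is.na(fields)]
  num <- paste(sprintf("%02d", fields), collapse = ":")
  pre <- if (species && !is.na(x$species)) paste0(x$species, "-") else ""
  paste0(pre, x$locus, "*", num)
}

#' @export
print.allele_name <- function(x, ...) {
  cat(format_allele_name(x), "\n")
  invisible(x)
}

#' Count amino-acid differences between two aligned sequences
#'
#' The sequences must already be aligned over their shared (amplicon) region,
#' i.e. have equal length, possibly containing `-` gap characters. A gap
#' opposite a residue counts as one difference; a gap opposite a gap counts
#' as none.
#'
#' @param aa1,aa2 aligned amino-acid strings of equal length.
#' @return integer difference count.
#' @export
aa_difference <- function(aa1, aa2) {
  if (nchar(aa1) != nchar(aa2))
    stop("sequences must be pre-aligned (equal length)")
  if (nchar(aa1) == 0L)
    stop("undefined comparison: zero-length overlap")
  a <- strsplit(aa1, "")[[1L]]
  b <- strsplit(aa2, "")[[1L]]
  sum(a != b & !(a == "-" & b == "-"))
}

#' Propose a name for a candidate allele sequence
#'
#' Compares the candidate with every library allele over the amplified
#' region (the caller supplies library sequences already restricted to that
#' region) and derives a nomenclature status:
#' \describe{
#'   \item{known}{zero aa differences and nucleotide-identical to exactly one
#'     library allele.}
#'   \item{ambiguous_within_amplicon}{nucleotide-identical to more than one
#'     allele over the amplified region.}
#'   \item{new_synonymous}{identical protein but a distinct nucleotide
#'     sequence.}
#'   \item{new_protein}{0 < d < class threshold; proposed protein number is
#'     max existing in the closest allele's group + 1.}
#'   \item{new_group}{d >= threshold against every library allele; proposed
#'     group is max existing group + 1, protein 01.}
#' }
#' Because only the amplified fragment is observed, every proposal carries
#' `needs_full_length = TRUE`: full-length Sanger verification is required
#' before official naming.
#'
#' Ties for the closest allele (equal d) are broken by higher nucleotide
#' identity, then by lexicographically smallest name; all co-closest names
#' are reported.
#'
#' @param candidate_nt candidate nucleotide sequence (amplified region).
#' @param locus locus name (UBA/DAA/DAB).
#' @param library `data.frame(name, nt, aa)` restricted to `locus` and sliced
#'   to the amplified region.
#' @param candidate_aa optional translated candidate (computed with
#'   [adjust_frame()] when omitted).
#' @param mhc_class "I" or "II"; derived from `locus` when omitted.
#' @param aligner alignment provider, a function with the contract of
#'   [align_pair()].
#' @return an object of class `name_proposal`.
#' @export
propose_name <- function(candidate_nt, locus, library, candidate_aa = NULL,
                         mhc_class = NULL, aligner = align_pair) {
  if (is.null(library) || nrow(library) == 0L)
    stop("configuration error: empty reference library for locus ", locus)
  if (is.null(mhc_class)) mhc_class <- locus_class(locus)
  thr <- group_threshold(mhc_class)
  if (is.null(candidate_aa)) candidate_aa <- adjust_frame(candidate_nt)$aa

  n <- nrow(library)
  d <- integer(n); nt_id <- numeric(n); nt_same <- logical(n)
  for (i in seq_len(n)) {
    aln_aa <- aligner(candidate_aa, library$aa[i], type = "aa")
    d[i] <- if (nchar(aln_aa$aligned_a) == 0L) nchar(candidate_aa)
            else aa_difference(aln_aa$aligned_a, aln_aa$aligned_b)
    aln_nt <- aligner(candidate_nt, library$nt[i], type = "nt")
    nt_id[i] <- aln_nt$identity
    nt_same[i] <- candidate_nt == library$nt[i] ||
      (aln_nt$identity == 100 &&
         nchar(gsub("-", "", aln_nt$aligned_a)) == nchar(candidate_nt))
  }
  dmin <- min(d)
  co <- which(d == dmin)
  co <- co[order(-nt_id[co], library$name[co])]
  closest <- library$name[co[1L]]
  parsed <- lapply(library$name, parse_allele_name)
  groups <- vapply(parsed, `[[`, 1L, "group")
  proteins <- vapply(parsed, `[[`, 1L, "protein")

  base <- parse_allele_name(closest)
  if (dmin == 0L && any(nt_same)) {
    idx <- which(nt_same)
    if (length(idx) == 1L) {
      status <- "known"; proposed <- parse_allele_name(library$name[idx])
      base <- proposed
      co <- idx
    } else {
      status <- "ambiguous_within_amplicon"; proposed <- NULL
      co <- idx
    }
  } else if (dmin == 0L) {
    status <- "new_synonymous"
    syn <- vapply(parsed, function(p) {
      if (p$group == base$group && identical(p$protein, base$protein))
        ifelse(is.na(p$synonymous), 1L, p$synonymous) else NA_integer_
    }, 1L)
    proposed <- base
    proposed$synonymous <- max(syn, na.rm = TRUE) + 1L
    proposed$noncoding <- NA_integer_
  } else if (dmin < thr) {
    status <- "new_protein"
    in_group <- groups == base$group
    proposed <- base
    proposed$protein <- max(proteins[in_group], 1L, na.rm = TRUE) + 1L
    proposed$synonymous <- NA_integer_; proposed$noncoding <- NA_integer_
  } else {
    status <- "new_group"
    proposed <- base
    proposed$group <- max(groups) + 1L
    proposed$protein <- 1L
    proposed$synonymous <- NA_integer_; proposed$noncoding <- NA_integer_
  }
  structure(list(
    status = status,
    base_allele = base,
    proposed = proposed,
    aa_diff_to_closest = dmin,
    nt_identical = any(nt_same),
    co_closest = library$name[co],
    threshold = thr,
    needs_full_length = TRUE), class = "name_proposal")
}

#' @export
print.name_proposal <- function(x, ...) {
  cat("name proposal:", x$status, "\n")
  if (!is.null(x$proposed))
    cat("  proposed:", format_allele_name(x$proposed), "\n")
  cat("  closest:", paste(x$co_closest, collapse = ", "),
      sprintf("(aa diff %d, class threshold %d)\n",
              x$aa_diff_to_closest, x$threshold))
  if (x$status != "known")
    cat("  note: based on the amplified region only;",
        "full-length Sanger verification required before official naming\n")
  invisible(x)
}
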