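# Sequence I/O: FASTA/FASTQ reading and writing, reference allele libraries,
# primer schemes, and basic nucleotide utilities. Records travel through the
# pipeline as plain data frames ("seqset") with columns id, desc, seq, qual;
# qual is a Phred+33 string (NA for FASTA records).

#' Construct a sequence record set
#'
#' A seqset is the package's light-weight container for named sequences: a
#' `data.frame` with columns `id`, `desc`, `seq` and `qual` (Phred+33 encoded
#' quality string, `NA` when absent). All per-read pipeline stages accept and
#' return seqsets.
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of residues (uppercase; nucleotide records are
#'   restricted to A, C, G, T, N).
#' @param desc optional description (the FASTA header after the first space).
#' @param qual optional Phred+33 quality strings, same nchar as `seq`.
#' @return a `data.frame` with one row per record.
#' @export
seqset <- function(id, seq, desc = "", qual = NA_character_) {
  stopifnot(length(id) == length(seq))
  if (any(!is.na(seq) & nchar(seq) == 0L))
    stop("empty sequence for record ", id[which(nchar(seq) == 0L)[1L]])
  bad <- !is.na(qual) & nchar(qual) != nchar(seq)
  if (any(bad))
    stop("quality length differs from sequence length for record ",
         id[which(bad)[1L]])
  data.frame(id = as.character(id), desc = rep_len(as.character(desc), length(id)),
             seq = as.character(seq),
             qual = rep_len(as.character(qual), length(id)),
             stringsAsFactors = FALSE)
}

# uppercase and map RNA U to T (cDNA context)
canonical_nt <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Read a FASTA file
#'
#' Headers are split at the first whitespace into `id` and `desc`. Sequences
#' are uppercased and `U` is mapped to `T`.
#'
#' @param path path to a FASTA file.
#' @param nucleotide if `TRUE` (default) validate the A/C/G/T/N alphabet.
#' @return a seqset (see [seqset()]); zero rows for an empty file.
#' @export
read_fasta <- function(path, nucleotide = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (all(!nzchar(trimws(lines)))) return(seqset(character(), character()))
  first <- which(nzchar(trimws(lines)))[1L]
  if (!startsWith(lines[first], ">"))
    stop("FASTA format error at line ", first, ": expected '>' header")
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  if (any(!nzchar(headers))) {
    at <- grep("^>\\s*$", lines)[1L]
    stop("FASTA format error at line ", if (is.na(at)) "?" else at,
         ": empty header")
  }
  if (any(Biostrings::width(set) == 0L)) {
    bad <- headers[Biostrings::width(set) == 0L][1L]
    at <- grep(paste0("^>", bad), lines, fixed = FALSE)[1L]
    stop("FASTA format error at line ", if (is.na(at)) "?" else at,
         ": empty sequence for '", bad, "'")
  }
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq <- canonical_nt(as.character(set))
  if (nucleotide) check_nt_alphabet(seq, id)
  seqset(id, unname(seq), desc)
}

check_nt_alphabet <- function(seq, id) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("non-nucleotide symbol in record ", id[which(bad)[1L]])
  invisible(TRUE)
}

#' Write a seqset as FASTA
#'
#' @param records a seqset.
#' @param path output path.
#' @param width line-wrap width (fixed policy: 60 columns).
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Phred+64 input is rejected: a file whose quality characters never go below
#' `';'` but average above `'K'` can only be +64-scaled.
#'
#' @param path path to a FASTQ file.
#' @return a seqset with `qual` filled.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) stop("FASTQ format error in ", path, ": ",
                               conditionMessage(e))),
    warning = function(w) {  # harmless internal metadata-column notice
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (length(set) == 0L) return(seqset(character(), character()))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  qual <- as.character(Biostrings::quality(set))
  qc <- utf8ToInt(paste(qual, collapse = ""))
  if (length(qc) && min(qc) >= utf8ToInt(";") && mean(qc) > utf8ToInt("K"))
    stop("quality scores look Phred+64 encoded; only Phred+33 is supported")
  seqset(id, canonical_nt(as.character(set)), desc, qual)
}

#' Write a seqset as FASTQ (Phred+33)
#' @param records a seqset with `qual` present.
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
  if (any(is.na(records$qual))) stop("records lack qualities")
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(records$qual))
  invisible(path)
}

#' Read a read pair (R1/R2 FASTQ files)
#'
#' Both files must contain the same number of records and matching ids in
#' file order; a trailing `/1` or `/2` mate suffix is ignored when comparing.
#'
#' @param path_r1,path_r2 FASTQ paths for read 1 and read 2.
#' @return list with seqsets `r1` and `r2`, row i of each forming a pair.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq(path_r1)
  r2 <- read_fastq(path_r2)
  if (nrow(r1) != nrow(r2))
    stop("pairing error: ", nrow(r1), " records in R1 vs ", nrow(r2),
         " in R2")
  strip <- function(x) sub("/[12]$", "", x)
  mism <- strip(r1$id) != strip(r2$id)
  if (any(mism))
    stop("pairing error: id mismatch at record ", which(mism)[1L], " ('",
         r1$id[which(mism)[1L]], "' vs '", r2$id[which(mism)[1L]], "')")
  list(r1 = r1, r2 = r2)
}

#' Decode a Phred+33 quality string to integer scores
#' @param qual character vector of quality strings.
#' @return list of integer vectors.
#' @export
qual_to_int <- function(qual) {
  lapply(qual, function(q) if (is.na(q)) integer() else utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores as a +33 string
#' @param scores integer vector.
#' @export
int_to_qual <- function(scores) intToUtf8(pmax(0L, scores) + 33L)

#' Reverse complement
#'
#' `N` maps to `N`. Vectorised; an involution.
#'
#' @param nt character vector of nucleotide sequences.
#' @export
reverse_complement <- function(nt) {
  nt <- canonical_nt(nt)
  check_nt_alphabet(nt, seq_along(nt))
  out <- character(length(nt))
  nz <- nchar(nt) > 0L
  if (any(nz))
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(nt[nz])))
  out
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; stop codons emit `*`; codons containing `N` (or any
#' ambiguity) emit `X`; a trailing partial codon is dropped.
#'
#' @param nt nucleotide string.
#' @param frame_offset 0, 1 or 2: number of leading bases to skip.
#' @return amino-acid string.
#' @export
translate_dna <- function(nt, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  nt <- canonical_nt(nt)
  body <- substr(nt, frame_offset + 1L, nchar(nt))
  n_codon <- nchar(body) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(body, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# locus -> MHC class map used throughout
locus_class <- function(locus) {
  cls <- c(UBA = "I", DAA = "II", DAB = "II")
  out <- cls[locus]
  if (any(is.na(out)))
    stop("unknown locus: ", paste(unique(locus[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Load a reference allele library from FASTA
#'
#' Headers must parse as IPD-MHC-style allele names (old concatenated or new
#' colon-delimited style, see [parse_allele_name()]). Names are normalised to
#' the canonical colon style. The translated sequence is obtained with the
#' frame-adjustment rule of [adjust_frame()].
#'
#' @param fasta_path path to the library FASTA snapshot.
#' @return a `data.frame` with columns `name`, `locus`, `mhc_class`, `nt`,
#'   `aa`, one row per allele.
#' @export
load_reference_library <- function(fasta_path) {
  recs <- read_fasta(fasta_path)
  if (nrow(recs) == 0L) stop("empty reference library: ", fasta_path)
  parsed <- lapply(recs$id, function(h) {
    tryCatch(parse_allele_name(h),
             error = function(e) stop("name-format error for header '", h,
                                      "': ", conditionMessage(e)))
  })
  name <- vapply(parsed, format_allele_name, "")
  if (anyDuplicated(name))
    stop("duplicate allele name in library: ", name[duplicated(name)][1L])
  locus <- vapply(parsed, `[[`, "", "locus")
  aa <- vapply(recs$seq, function(s) adjust_frame(s)$aa, "", USE.NAMES = FALSE)
  out <- data.frame(name = name, locus = locus,
                    mhc_class = locus_class(locus),
                    nt = recs$seq, aa = aa, stringsAsFactors = FALSE)
  out[order(out$locus, out$name), , drop = FALSE]
}

#' Read a primer scheme
#'
#' Tab-separated columns `gene`, `role` (`forward`/`reverse`), `label`,
#' `sequence`. Each gene needs at least one forward primer and exactly one
#' reverse primer. Validation rejects primers that are prefixes of one
#' another (within a role), since exact-prefix demultiplexing would then
#' depend on scan order.
#'
#' @param path scheme TSV path.
#' @return `data.frame(gene, role, label, sequence)`.
#' @export
read_primer_scheme <- function(path) {
  sc <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_primer_scheme(sc)
}

#' @rdname read_primer_scheme
#' @param scheme a scheme `data.frame` to validate.
#' @export
validate_primer_scheme <- function(scheme) {
  need <- c("gene", "role", "label", "sequence")
  if (!all(need %in% names(scheme)))
    stop("scheme must have columns ", paste(need, collapse = ", "))
  scheme$sequence <- canonical_nt(scheme$sequence)
  if (any(!nzchar(scheme$sequence)) || any(grepl("[^ACGT]", scheme$sequence)))
    stop("primer sequences must be nonempty and A/C/G/T only")
  if (!all(scheme$role %in% c("forward", "reverse")))
    stop("role must be 'forward' or 'reverse'")
  for (g in unique(scheme$gene)) {
    sub <- scheme[scheme$gene == g, ]
    if (sum(sub$role == "forward") < 1L)
      stop("gene ", g, " has no forward primer")
    if (sum(sub$role == "reverse") != 1L)
      stop("gene ", g, " must have exactly one reverse primer")
  }
  for (role in c("forward", "reverse")) {
    p <- scheme$sequence[scheme$role == role]
    lab <- scheme$label[scheme$role == role]
    if (length(p) > 1L) {
      for (i in seq_along(p)) for (j in seq_along(p)) {
        if (i != j && startsWith(p[j], p[i]))
          stop("scheme-validation error: ", role, " primer ", lab[i],
               " is a prefix of ", lab[j])
      }
    }
  }
  scheme
}
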