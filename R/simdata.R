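# Synthetic data: a deterministic synthetic reference allele library (a
# stand-in for an IPD-MHC snapshot, engineered so the documented amino-acid
# distance relations between groups, proteins and novel alleles hold) and a
# seeded paired-end read simulator with per-read truth labels, so that every
# pipeline stage is testable offline.

# run expr under a fixed RNG state without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' The study primer scheme
#'
#' First-PCR primers for the UBA, DAA and DAB genes (two alternative forward
#' primers for UBA, one of which covers leader-sequence variants; two for
#' DAB; one for DAA).
#'
#' @return a validated scheme `data.frame(gene, role, label, sequence)`.
#' @export
default_primer_scheme <- function() {
  validate_primer_scheme(data.frame(
    gene = c("UBA", "UBA", "UBA", "DAA", "DAA", "DAB", "DAB", "DAB"),
    role = c("forward", "forward", "reverse", "forward", "reverse",
             "forward", "forward", "reverse"),
    label = c("UBA1", "UBA4", "UBA_R", "DAA", "DAA_R", "DAB1", "DAB2", "DAB_R"),
    sequence = c("CTGGGAATAGGCCTTCTACAT", "GGCATCTGCAGTAACCCACT",
                 "TCCAGATACTTCTTCAGCCAC",
                 "TGCTGGCAGGTGTATGCAGAA", "GGTGAAATCAGCGTTGGGGT",
                 "ATGTCGATGTCTATCTTCTG", "TTCTGCGTTTCCCTGACCC",
                 "GTACCAGTCCCCGTTAGCCAG"),
    stringsAsFactors = FALSE))
}

# stop-free codons used for random region backbones
safe_codons <- c("GCT", "GCA", "GCC", "TGC", "GAT", "GAA", "TTC", "GGT",
                 "CAT", "ATC", "AAA", "CTG", "ATG", "AAC", "CCT", "CAG",
                 "CGT", "TCT", "ACC", "GTT", "TGG", "TAC")

REGION_CODONS <- 150L              # codons between the primer sites
BASE_SLOT <- "GCT"                 # alanine backbone at reserved slots
GROUP_MARKER <- "ACT"              # threonine: one aa change per slot
PROTEIN_MARKER <- "TCT"            # serine: protein-level change

# reserved codon slots (1-based, within the region): per locus, per group /
# protein / novel allele. Disjoint slot sets make pairwise aa distances the
# sum of slot counts: class I groups get 6 slots (>= the 4-aa threshold),
# class II groups 4 slots (>= the 3-aa threshold).
uba_group_slots <- list(`02` = 11:16, `06` = 17:22, `07` = 23:28,
                        `13` = 29:34, `20` = 35:40, `34` = 41:46,
                        `35` = 47:52)
daa_group_slots <- list(`01` = integer(), `02` = 11:14, `03` = 15:18,
                        `04` = 19:22, `06` = 23:26, `09` = 27:30)
dab_group_slots <- list(`02` = 11:14, `06` = 15:18, `07` = 19:22,
                        `08` = 23:26, `09` = 27:30, `20` = 31:34)
uba_novel_slots <- list(AS2UBAs1 = 60:65, AS2UBAs2 = 66:71,
                        AS5UBAs1 = 72:77, AS5UBAs2 = 78:83,
                        AS9UBAs2 = 84:89)

locus_tail <- "GCTGCAGCCGCTGCAGCCGCTGCAGCCGCT"  # untranslated-side padding

# deterministic per-locus codon backbones with all reserved slots set to the
# alanine base codon
synthetic_bases <- function() {
  bases <- with_seed(632001L, list(
    UBA = sample(safe_codons, REGION_CODONS, replace = TRUE),
    DAA = sample(safe_codons, REGION_CODONS, replace = TRUE),
    DAB = sample(safe_codons, REGION_CODONS, replace = TRUE)))
  all_slots <- unlist(c(uba_group_slots, daa_group_slots, dab_group_slots,
                        uba_novel_slots, list(95:96, 40L, 60:63)))
  for (loc in names(bases)) bases[[loc]][all_slots] <- BASE_SLOT
  bases
}

region_with_markers <- function(base_codons, slots, marker = GROUP_MARKER) {
  cod <- base_codons
  cod[slots] <- marker
  paste(cod, collapse = "")
}

# assemble a full synthetic reference: forward primer site + region +
# reverse-primer site (+ 3' tail outside the amplicon)
assemble_ref <- function(fwd, region, rev_primer, tail = locus_tail) {
  paste0(fwd, region, reverse_complement(rev_primer), tail)
}

#' Synthetic reference allele library
#'
#' A deterministic, fully synthetic stand-in for an IPD-MHC snapshot of the
#' alleles discussed in the package (no real salmon sequence is included).
#' Engineered relations: allele groups differ by 6 (class I) or 4 (class II)
#' amino acids over the amplified region; `DAA*01:01` and `DAA*01:02` are
#' identical over the amplified region and differ only 3' of it;
#' `DAB*09:02` differs from `DAB*09:01` by one amino acid.
#'
#' @return `data.frame(name, locus, mhc_class, nt, aa)` as from
#'   [load_reference_library()].
#' @export
synthetic_reference_library <- function() {
  sc <- default_primer_scheme()
  p <- function(g, r, l = NULL) {
    rows <- sc[sc$gene == g & sc$role == r, , drop = FALSE]
    if (!is.null(l)) rows <- rows[rows$label == l, , drop = FALSE]
    rows$sequence[1L]
  }
  bases <- synthetic_bases()
  alleles <- list()
  add <- function(name, locus, region, tail = locus_tail) {
    fwd <- if (locus == "UBA") p("UBA", "forward", "UBA1")
           else if (locus == "DAA") p("DAA", "forward")
           else p("DAB", "forward", "DAB1")
    nt <- assemble_ref(fwd, region, p(locus, "reverse"), tail)
    alleles[[length(alleles) + 1L]] <<-
      list(name = name, locus = locus, nt = nt)
  }
  for (g in names(uba_group_slots))
    add(sprintf("Sasa-UBA*%s:01", g), "UBA",
        region_with_markers(bases$UBA, uba_group_slots[[g]]))
  tail_0102 <- paste0(substr(locus_tail, 1L, 1L), "A",
                      substr(locus_tail, 3L, nchar(locus_tail)))
  for (g in names(daa_group_slots)) {
    reg <- region_with_markers(bases$DAA, daa_group_slots[[g]])
    if (g == "01") {
      add("Sasa-DAA*01:01", "DAA", reg, tail = locus_tail)
      add("Sasa-DAA*01:02", "DAA", reg, tail = tail_0102)
    } else if (g == "03") {
      add("Sasa-DAA*03:02", "DAA", reg)
    } else {
      add(sprintf("Sasa-DAA*%s:01", g), "DAA", reg)
    }
  }
  for (g in names(dab_group_slots)) {
    reg <- region_with_markers(bases$DAB, dab_group_slots[[g]])
    add(sprintf("Sasa-DAB*%s:01", g), "DAB", reg)
    if (g == "09") {
      cod <- bases$DAB
      cod[dab_group_slots[[g]]] <- GROUP_MARKER
      cod[40L] <- PROTEIN_MARKER
      add("Sasa-DAB*09:02", "DAB", paste(cod, collapse = ""))
    }
  }
  nt <- vapply(alleles, `[[`, "", "nt")
  name <- vapply(alleles, `[[`, "", "name")
  locus <- vapply(alleles, `[[`, "", "locus")
  data.frame(name = name, locus = locus, mhc_class = locus_class(locus),
             nt = nt,
             aa = vapply(nt, function(s) adjust_frame(s)$aa, "",
                         USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Synthetic novel alleles (absent from the library)
#'
#' Sequences used by the simulator for the study's novel alleles: five UBA
#' sequences differing from every library allele by well over the class I
#' group threshold, one UBA sequence (`AS7UBAs1`) exactly two amino acids
#' from `UBA*35:01`, and one DAB sequence (`AS5DABs2`) four amino acids from
#' `DAB*06:01`. The two `AS5UBA` alleles carry the alternative UBA4 forward
#' primer site (leader-sequence variation).
#'
#' @return `data.frame(name, locus, nt)`.
#' @export
synthetic_novel_alleles <- function() {
  sc <- default_primer_scheme()
  bases <- synthetic_bases()
  uba_r <- sc$sequence[sc$gene == "UBA" & sc$role == "reverse"]
  dab_r <- sc$sequence[sc$gene == "DAB" & sc$role == "reverse"]
  uba1 <- sc$sequence[sc$label == "UBA1"]
  uba4 <- sc$sequence[sc$label == "UBA4"]
  dab1 <- sc$sequence[sc$label == "DAB1"]
  out <- list()
  for (nm in names(uba_novel_slots)) {
    fwd <- if (nm %in% c("AS5UBAs1", "AS5UBAs2")) uba4 else uba1
    out[[nm]] <- assemble_ref(
      fwd, region_with_markers(bases$UBA, uba_novel_slots[[nm]]), uba_r)
  }
  cod <- bases$UBA
  cod[uba_group_slots[["35"]]] <- GROUP_MARKER
  cod[95:96] <- GROUP_MARKER
  out[["AS7UBAs1"]] <- assemble_ref(uba1, paste(cod, collapse = ""), uba_r)
  cod <- bases$DAB
  cod[dab_group_slots[["06"]]] <- GROUP_MARKER
  cod[60:63] <- GROUP_MARKER
  out[["AS5DABs2"]] <- assemble_ref(dab1, paste(cod, collapse = ""), dab_r)
  data.frame(name = names(out),
             locus = ifelse(grepl("DAB", names(out)), "DAB", "UBA"),
             nt = unlist(out, use.names = FALSE), stringsAsFactors = FALSE)
}

# short display name (no species prefix) for matching fixture tables
short_allele_name <- function(name) {
  vapply(name, function(n) {
    p <- tryCatch(parse_allele_name(n), error = function(e) NULL)
    if (is.null(p)) n else format_allele_name(p, species = FALSE)
  }, "", USE.NAMES = FALSE)
}

# resolve an allele label (short official name or novel label) to a sequence
resolve_allele_seq <- function(label, library, novel) {
  i <- match(label, short_allele_name(library$name))
  if (!is.na(i)) return(library$nt[i])
  j <- match(label, novel$name)
  if (!is.na(j)) return(novel$nt[j])
  stop("allele '", label, "' is neither in the library nor a novel allele")
}

#' Build a simulation specification
#'
#' @param animals `data.frame(animal, gene, allele_1, allele_2, balance)`;
#'   `allele_2 = NA` for homozygotes, `balance` = expected read fraction of
#'   `allele_1` among non-chimeric pairs (ignored for homozygotes).
#' @param library reference library (`data.frame(name, locus, nt)`); defaults
#'   to [synthetic_reference_library()].
#' @param novel novel-allele table, defaults to [synthetic_novel_alleles()].
#' @param scheme primer scheme, defaults to [default_primer_scheme()].
#' @param reads_per_gene read pairs per animal x gene cell (default 2000).
#' @param read_len read length (default 300, MiSeq v3 paired-end).
#' @param error_rate per-base substitution probability (default 0.001).
#' @param chimera_rate probability that a pair derives from a jumping-PCR
#'   recombinant template (default 0.05; heterozygotes only).
#' @param quality `list(model = "constant", q = 35)` or
#'   `list(model = "decline", q5 = 37, q3 = 25)`.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @export
simulation_spec <- function(animals,
                            library = synthetic_reference_library(),
                            novel = synthetic_novel_alleles(),
                            scheme = default_primer_scheme(),
                            reads_per_gene = 2000L, read_len = 300L,
                            error_rate = 0.001, chimera_rate = 0.05,
                            quality = list(model = "constant", q = 35L),
                            seed = 1L) {
  stopifnot(all(c("animal", "gene", "allele_1") %in% names(animals)))
  if (is.null(animals$allele_2)) animals$allele_2 <- NA_character_
  if (is.null(animals$balance)) animals$balance <- 0.5
  stopifnot(error_rate >= 0, error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  for (k in seq_len(nrow(animals))) {  # fail early on unknown alleles
    resolve_allele_seq(animals$allele_1[k], library, novel)
    if (!is.na(animals$allele_2[k]))
      resolve_allele_seq(animals$allele_2[k], library, novel)
  }
  structure(list(animals = animals, library = library, novel = novel,
                 scheme = scheme, reads_per_gene = as.integer(reads_per_gene),
                 read_len = as.integer(read_len), error_rate = error_rate,
                 chimera_rate = chimera_rate, quality = quality,
                 seed = as.integer(seed)), class = "simulation_spec")
}

# amplicon (primer-inclusive top strand) of an allele, with forward label
allele_amplicon <- function(nt, gene, scheme) {
  sl <- slice_amplicon(nt, gene, scheme)
  fwd <- scheme[scheme$gene == gene & scheme$role == "forward" &
                  scheme$label == sl$forward_label, , drop = FALSE]
  rev_p <- scheme$sequence[scheme$gene == gene & scheme$role == "reverse"]
  list(seq = substr(nt, sl$start - nchar(fwd$sequence[1L]),
                    sl$end + nchar(rev_p)),
       forward_label = sl$forward_label)
}

quality_string <- function(quality, read_len) {
  if (quality$model == "constant") {
    int_to_qual(rep.int(as.integer(quality$q), read_len))
  } else {
    int_to_qual(as.integer(round(seq(quality$q5, quality$q3,
                                     length.out = read_len))))
  }
}

inject_errors <- function(seqs, error_rate, read_len) {
  n <- length(seqs)
  pos_list <- vector("list", n)
  k <- stats::rbinom(n, read_len, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(k > 0L)) {
    pos <- sort(sample.int(read_len, k[i]))
    s <- strsplit(seqs[i], "")[[1L]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
    pos_list[[i]] <- pos
  }
  list(seqs = seqs, positions = pos_list)
}

#' Simulate paired-end amplicon reads with a truth table
#'
#' For each animal x gene cell, templates are drawn from the genotype's
#' allele amplicons (forward primer + amplified region + reverse-primer
#' site): heterozygote pairs pick allele 1 with probability `balance`, and
#' with probability `chimera_rate` the template is instead a single-breakpoint
#' recombinant of the two alleles with the breakpoint uniform between their
#' first and last variable sites (outside that interval a recombinant is
#' indistinguishable from a parent). R1 is the first `read_len` bases of the
#' top strand, R2 the first `read_len` bases of the bottom strand;
#' substitution errors are i.i.d. per base. A homozygous cell cannot produce
#' detectable chimeras; a positive `chimera_rate` is coerced to 0 there, with
#' a warning.
#'
#' @param spec a [simulation_spec()].
#' @return list with `pairs` (per animal: seqsets `r1`, `r2`), `truth`
#'   (per-pair data.frame) and the `spec` (with the resolved seed).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    an <- spec$animals
    qstr <- quality_string(spec$quality, spec$read_len)
    pairs <- list(); truth <- list()
    for (k in seq_len(nrow(an))) {
      animal <- an$animal[k]; gene <- an$gene[k]
      a1 <- an$allele_1[k]; a2 <- an$allele_2[k]
      amp1 <- allele_amplicon(resolve_allele_seq(a1, spec$library, spec$novel),
                              gene, spec$scheme)
      het <- !is.na(a2)
      ch_rate <- spec$chimera_rate
      if (het) {
        amp2 <- allele_amplicon(resolve_allele_seq(a2, spec$library, spec$novel),
                                gene, spec$scheme)
        vs <- if (nchar(amp1$seq) == nchar(amp2$seq))
          variable_sites(amp1$seq, amp2$seq) else integer()
        if (length(vs) < 2L && ch_rate > 0) {
          warning(animal, " ", gene,
                  ": alleles lack a variable-site interval; chimera rate coerced to 0")
          ch_rate <- 0
        }
      } else if (ch_rate > 0) {
        warning(animal, " ", gene,
                ": homozygous cell cannot produce chimeras; rate coerced to 0")
        ch_rate <- 0
      }
      n <- spec$reads_per_gene
      if (n == 0L) next
      is_chim <- het & stats::rbinom(n, 1L, ch_rate) == 1L
      from1 <- if (het) stats::rbinom(n, 1L, an$balance[k]) == 1L
               else rep(TRUE, n)
      bp <- rep(NA_integer_, n); swap <- rep(NA, n)
      templates <- character(n)
      for (i in seq_len(n)) {
        if (is_chim[i]) {
          bp[i] <- if (length(vs) == 2L) vs[1L]
                   else sample(seq.int(vs[1L], vs[length(vs)] - 1L), 1L)
          swap[i] <- stats::runif(1L) < 0.5
          pa <- if (swap[i]) amp2$seq else amp1$seq
          pb <- if (swap[i]) amp1$seq else amp2$seq
          templates[i] <- paste0(substr(pa, 1L, bp[i]),
                                 substr(pb, bp[i] + 1L, nchar(pb)))
        } else {
          templates[i] <- if (from1[i]) amp1$seq else amp2$seq
        }
      }
      r1 <- substr(templates, 1L, spec$read_len)
      r2 <- substr(reverse_complement(templates), 1L, spec$read_len)
      e1 <- inject_errors(r1, spec$error_rate, spec$read_len)
      e2 <- inject_errors(r2, spec$error_rate, spec$read_len)
      ids <- sprintf("%s_%s_%06d", animal, gene, seq_len(n))
      cell_truth <- data.frame(
        read_id = ids, animal = animal, gene = gene,
        template_allele = ifelse(is_chim, "chimera",
                                 ifelse(from1, a1, a2)),
        parent_1 = ifelse(is_chim, ifelse(swap, a2, a1), NA_character_),
        parent_2 = ifelse(is_chim, ifelse(swap, a1, a2), NA_character_),
        is_chimera = is_chim, breakpoint = bp,
        errors_r1 = vapply(e1$positions, function(p)
          paste(p, collapse = ","), ""),
        errors_r2 = vapply(e2$positions, function(p)
          paste(p, collapse = ","), ""),
        stringsAsFactors = FALSE)
      if (is.null(pairs[[animal]]))
        pairs[[animal]] <- list(r1 = NULL, r2 = NULL)
      pairs[[animal]]$r1 <- rbind(pairs[[animal]]$r1,
                                  seqset(ids, e1$seqs, qual = qstr))
      pairs[[animal]]$r2 <- rbind(pairs[[animal]]$r2,
                                  seqset(ids, e2$seqs, qual = qstr))
      truth[[length(truth) + 1L]] <- cell_truth
    }
    list(pairs = pairs, truth = do.call(rbind, truth), spec = spec)
  })
}

#' Write simulated reads, truth table and spec echo to a directory
#'
#' @param sim output of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in names(sim$pairs)) {
    write_fastq(sim$pairs[[a]]$r1, file.path(dir, paste0(a, "_R1.fastq")))
    write_fastq(sim$pairs[[a]]$r2, file.path(dir, paste0(a, "_R2.fastq")))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  echo <- sim$spec[c("reads_per_gene", "read_len", "error_rate",
                     "chimera_rate", "seed")]
  echo$quality <- sim$spec$quality
  jsonlite::write_json(echo, file.path(dir, "spec.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Compare called genotypes with simulation truth
#'
#' A cell matches when the set of called allele sequences equals the set of
#' amplified-region sequences of the simulated genotype (comparison is at the
#' sequence level, so novel alleles and within-amplicon ambiguities are
#' handled naturally).
#'
#' @param result an `mhc_typing` object from [run_pipeline()].
#' @param sim the [simulate_reads()] output the pipeline was run on.
#' @return `data.frame(animal, gene, match)` with one row per simulated cell.
#' @export
genotype_recovery <- function(result, sim) {
  spec <- sim$spec
  an <- spec$animals
  region <- function(label) {
    nt <- resolve_allele_seq(label, spec$library, spec$novel)
    slice_amplicon(nt, an$gene[k], spec$scheme)$seq
  }
  out <- an[, c("animal", "gene")]
  out$match <- FALSE
  for (k in seq_len(nrow(an))) {
    truth <- region(an$allele_1[k])
    if (!is.na(an$allele_2[k])) truth <- c(truth, region(an$allele_2[k]))
    call <- result$genotypes[[paste(an$animal[k], an$gene[k], sep = "/")]]
    called <- if (is.null(call$alleles)) character() else call$alleles$seq
    out$match[k] <- setequal(unique(truth), unique(called))
  }
  out
}

#' The study cohort as a simulation input
#'
#' The nine-animal genotype table shipped with the package (see
#' `system.file("extdata", "study_genotypes.tsv", package = "mhctyper")`)
#' expressed as a simulation `animals` table over the synthetic library and
#' novel alleles.
#'
#' @param balance allelic balance for heterozygotes: a single value, or a
#'   two-element range from which per-cell balances are drawn (requires a
#'   seeded caller).
#' @export
study_cohort <- function(balance = 0.5) {
  path <- system.file("extdata", "study_genotypes.tsv", package = "mhctyper")
  gt <- utils::read.delim(path, stringsAsFactors = FALSE)
  an <- gt[, c("animal", "gene", "allele_1", "allele_2")]
  an$allele_2[!is.na(an$allele_2) & !nzchar(an$allele_2)] <- NA_character_
  if (length(balance) == 2L) {
    an$balance <- stats::runif(nrow(an), balance[1L], balance[2L])
  } else {
    an$balance <- balance
  }
  an
}
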