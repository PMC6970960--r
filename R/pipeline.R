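# Pipeline orchestration: per animal x gene, preprocess -> merge -> collapse
# -> classify -> genotype; then haplotype phasing across animals. Stage read
# counts are tracked and conservation-checked (retained <= input; assigned +
# unassigned = retained; merged <= assigned; variant counts sum to merged).

#' Pipeline configuration
#'
#' @param q_threshold,min_len,adapters,window quality trimming, see
#'   [quality_trim()].
#' @param min_overlap,max_mismatch_density merging, see [merge_pair()].
#' @param top_n,min_fraction candidate selection, see [select_candidates()].
#' @param allowed_novel chimera detection, see [chimera_check()].
#' @export
pipeline_config <- function(q_threshold = 20, min_len = 100L,
                            adapters = character(), window = 4L,
                            min_overlap = 10L, max_mismatch_density = 0.25,
                            top_n = 5L, min_fraction = 0.01,
                            allowed_novel = 0L) {
  stopifnot(q_threshold >= 0, min_len >= 1L, min_overlap >= 1L,
            max_mismatch_density >= 0, max_mismatch_density <= 1,
            top_n >= 1L, min_fraction >= 0, min_fraction <= 1,
            allowed_novel >= 0L)
  list(q_threshold = q_threshold, min_len = min_len, adapters = adapters,
       window = window, min_overlap = min_overlap,
       max_mismatch_density = max_mismatch_density, top_n = top_n,
       min_fraction = min_fraction, allowed_novel = allowed_novel)
}

#' Run the full typing pipeline
#'
#' @param pairs named list (per animal) of `list(r1, r2)` seqsets, e.g. the
#'   `pairs` element of [simulate_reads()], or read from FASTQ with
#'   [read_fastq_pairs()].
#' @param scheme validated primer scheme.
#' @param library reference allele library (see [load_reference_library()] /
#'   [synthetic_reference_library()]); sliced internally to the amplified
#'   regions.
#' @param config a [pipeline_config()].
#' @return an object of class `mhc_typing`: `genotypes` (list of
#'   `genotype_call`s), `genotype_table` (one row per animal x gene),
#'   `reports` (classification reports keyed by candidate id), `haplotypes`
#'   (a `haplotype_set`, when both DAA and DAB were typed), `stage_counts`.
#'   Stage failures abort only the affected animal x gene cell, recording a
#'   reason.
#' @export
run_pipeline <- function(pairs, scheme, library, config = pipeline_config()) {
  scheme <- validate_primer_scheme(scheme)
  ref <- prepare_reference(library, scheme)
  genotypes <- list(); reports <- list(); stage_counts <- list()
  for (animal in names(pairs)) {
    r1 <- pairs[[animal]]$r1; r2 <- pairs[[animal]]$r2
    tr <- quality_trim(r1, r2, config$q_threshold, config$min_len,
                       config$adapters, config$window)
    dm <- demultiplex_by_primer(tr$r1, tr$r2, scheme)
    counts <- list(input_pairs = tr$n_input, retained_after_trim = tr$n_kept,
                   assigned = dm$n_assigned, unassigned = dm$n_unassigned,
                   buckets = list())
    stopifnot(tr$n_kept <= tr$n_input,
              dm$n_assigned + dm$n_unassigned == tr$n_kept)
    per_gene <- list()
    for (bk in dm$buckets) {
      mg <- merge_bucket(bk$r1, bk$r2, config$min_overlap,
                         config$max_mismatch_density)
      stopifnot(mg$stats$n_merged <= bk$n)
      counts$buckets[[paste(bk$gene, bk$forward_label, sep = "/")]] <-
        list(assigned = bk$n, merged = mg$stats$n_merged,
             failed_no_overlap = mg$stats$n_no_overlap,
             failed_too_divergent = mg$stats$n_too_divergent)
      if (mg$stats$n_merged == 0L) next
      cv <- collapse_reads(mg$merged)
      cv$forward_label <- bk$forward_label
      stopifnot(sum(cv$count) == mg$stats$n_merged)
      per_gene[[bk$gene]] <- rbind(per_gene[[bk$gene]], cv)
    }
    for (gene in unique(scheme$gene)) {
      cell <- tryCatch({
        cv <- per_gene[[gene]]
        cell_reports <- list()
        if (is.null(cv) || nrow(cv) == 0L) {
          call <- call_genotype(NULL, animal, gene)
        } else {
          # pool buckets of the gene: identical sequences merge, counts add
          agg <- stats::aggregate(count ~ seq, data = cv, FUN = sum)
          lab <- vapply(agg$seq, function(s) {
            rows <- cv[cv$seq == s, , drop = FALSE]
            rows$forward_label[which.max(rows$count)]
          }, "")
          pooled <- data.frame(seq = agg$seq, count = agg$count,
                               forward_label = lab, stringsAsFactors = FALSE)
          pooled <- pooled[order(-pooled$count, pooled$seq), , drop = FALSE]
          pooled$rank <- seq_len(nrow(pooled))
          pooled$fraction <- pooled$count / sum(pooled$count)
          cand <- select_candidates(pooled, config$top_n, config$min_fraction)
          cand$candidate_id <- name_candidates(cand, animal, gene,
                                               cand$forward_label)
          cell_reports <- lapply(seq_len(nrow(cand)), function(i)
            classify_candidate(cand$candidate_id[i], cand$seq[i],
                               ref[ref$locus == gene, , drop = FALSE], gene))
          names(cell_reports) <- cand$candidate_id
          call <- call_genotype(cand, animal, gene, config$min_fraction,
                                config$allowed_novel)
          call$alleles$name <- vapply(call$alleles$candidate_id, function(id) {
            classification_label(cell_reports[[id]])
          }, "")
        }
        list(call = call, reports = cell_reports)
      }, error = function(e) {
        list(call = structure(
          list(animal = animal, gene = gene, alleles = NULL,
               zygosity = "no_call", excluded = NULL,
               warnings = paste("stage error:", conditionMessage(e))),
          class = "genotype_call"), reports = list())
      })
      reports <- c(reports, cell$reports)
      genotypes[[paste(animal, gene, sep = "/")]] <- cell$call
    }
    stage_counts[[animal]] <- counts
  }
  gt <- genotype_table(genotypes)
  haps <- NULL
  if (all(c("DAA", "DAB") %in% gt$gene)) {
    both <- intersect(gt$animal[gt$gene == "DAA" & gt$zygosity != "no_call"],
                      gt$animal[gt$gene == "DAB" & gt$zygosity != "no_call"])
    if (length(both) > 0L)
      haps <- phase_two_locus(gt[gt$animal %in% both &
                                   gt$gene %in% c("DAA", "DAB"), , drop = FALSE])
  }
  structure(list(genotypes = genotypes, genotype_table = gt,
                 reports = reports, haplotypes = haps,
                 stage_counts = stage_counts),
            class = "mhc_typing")
}

# display label for a classified candidate: the official name when known,
# the proposal otherwise, the ambiguity set when indistinguishable
classification_label <- function(report) {
  pr <- report$proposal
  if (pr$status == "known")
    return(format_allele_name(pr$proposed, species = FALSE))
  if (pr$status == "ambiguous_within_amplicon")
    return(paste(short_allele_name(pr$co_closest), collapse = "/"))
  paste0("novel(", pr$status, ":",
         format_allele_name(pr$proposed, species = FALSE), ")")
}

#' Flatten genotype calls into a table
#'
#' One row per animal x gene with `allele_1`/`allele_2` labels (classified
#' names when reports were attached, sequence digests otherwise), counts,
#' zygosity, number of excluded candidates and warnings. The layout mirrors
#' a per-animal genotype table.
#'
#' @param genotypes list of `genotype_call` objects.
#' @export
genotype_table <- function(genotypes) {
  rows <- lapply(genotypes, function(g) {
    lab <- function(i) {
      if (is.null(g$alleles) || nrow(g$alleles) < i) return(NA_character_)
      if (!is.null(g$alleles$name)) g$alleles$name[i]
      else paste0("seq:", substr(g$alleles$seq[i], 1L, 12L))
    }
    cnt <- function(i) {
      if (is.null(g$alleles) || nrow(g$alleles) < i) NA_integer_
      else g$alleles$count[i]
    }
    data.frame(animal = g$animal, gene = g$gene,
               allele_1 = lab(1L), count_1 = cnt(1L),
               allele_2 = lab(2L), count_2 = cnt(2L),
               zygosity = g$zygosity,
               n_excluded = if (is.null(g$excluded)) 0L else nrow(g$excluded),
               warnings = paste(g$warnings, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mhc_typing <- function(x, ...) {
  cat("MHC typing of", length(unique(x$genotype_table$animal)), "animal(s)\n\n")
  print(x$genotype_table, row.names = FALSE)
  if (!is.null(x$haplotypes)) { cat("\n"); print(x$haplotypes) }
  invisible(x)
}

#' Summarise a genotype table
#'
#' Per-gene heterozygous/homozygous animal counts and the number of distinct
#' alleles.
#'
#' @param gt a genotype table (`animal`, `gene`, `allele_1`, `allele_2`,
#'   optionally `zygosity`).
#' @export
summarize_genotypes <- function(gt) {
  gt$allele_2[!is.na(gt$allele_2) & !nzchar(gt$allele_2)] <- NA_character_
  if (is.null(gt$zygosity))
    gt$zygosity <- ifelse(is.na(gt$allele_2), "homozygous", "heterozygous")
  out <- lapply(split(gt, gt$gene), function(sub) {
    data.frame(gene = sub$gene[1L],
               n_animals = nrow(sub),
               n_heterozygous = sum(sub$zygosity == "heterozygous"),
               n_homozygous = sum(sub$zygosity == "homozygous"),
               n_unique_alleles = length(unique(stats::na.omit(
                 c(sub$allele_1, sub$allele_2)))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read a genotype table from TSV
#'
#' Expected columns `animal`, `gene`, `allele_1`, `count_1`, `allele_2`,
#' `count_2` (counts optional; empty `allele_2` = homozygous).
#'
#' @param path TSV path.
#' @export
read_genotype_table <- function(path) {
  gt <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("animal", "gene", "allele_1")
  if (!all(need %in% names(gt)))
    stop("genotype table must have columns ", paste(need, collapse = ", "))
  if (is.null(gt$allele_2)) gt$allele_2 <- NA_character_
  gt$allele_2[!is.na(gt$allele_2) & !nzchar(gt$allele_2)] <- NA_character_
  gt$zygosity <- ifelse(is.na(gt$allele_2), "homozygous", "heterozygous")
  gt
}

#' Write pipeline outputs to a directory
#'
#' Genotype TSV (one row per animal x gene), classification report TSV plus a
#' human-readable text block per candidate, haplotype TSV and the per-stage
#' read-count JSON.
#'
#' @param result an `mhc_typing` object.
#' @param dir output directory.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$genotype_table, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(result$reports)) {
    rep_tab <- do.call(rbind, lapply(result$reports, function(r) {
      top <- r$closest[1L, ]
      data.frame(candidate_id = r$candidate_id, locus = r$locus,
                 left_trim = r$frame_trim[["left"]],
                 right_trim = r$frame_trim[["right"]],
                 clean_frame = r$clean_frame,
                 closest = top$name,
                 nt_identity = round(top$nt_identity, 2),
                 nt_similarity = round(top$nt_similarity, 2),
                 aa_identity = round(top$aa_identity, 2),
                 aa_similarity = round(top$aa_similarity, 2),
                 nj_sibling = r$nj_sibling,
                 proposal = r$proposal$status,
                 proposed_name = if (is.null(r$proposal$proposed)) ""
                                 else format_allele_name(r$proposal$proposed),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rep_tab, file.path(dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    txt <- utils::capture.output(for (r in result$reports) { print(r); cat("\n") })
    writeLines(txt, file.path(dir, "classification_report.txt"))
  }
  if (!is.null(result$haplotypes))
    utils::write.table(result$haplotypes$haplotypes,
                       file.path(dir, "haplotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$stage_counts, file.path(dir, "stage_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
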