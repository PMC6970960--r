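# Cross-animal DAA-DAB haplotype inference. The two class II genes sit ~3 kb
# apart on chromosome 12 and segregate together, so each animal's DAA and DAB
# alleles pair into two haplotypes. Phasing is Clark-style parsimony:
# animals homozygous at a locus are phase-known; double heterozygotes are
# resolved against already-known haplotypes; anything left is settled by
# exhaustive search minimising the number of distinct haplotypes, with
# equal-parsimony alternatives surfaced as ambiguous rather than broken.

#' Phase DAA-DAB haplotypes across animals
#'
#' @param genotype_table `data.frame` with columns `animal`, `gene`
#'   (`"DAA"`/`"DAB"`), `allele_1`, `allele_2` (`NA` or `""` for a homozygous
#'   call). Every animal needs one DAA and one DAB row.
#' @param max_exhaustive maximum number of unresolved double-heterozygous
#'   animals for the exhaustive fallback (default 30).
#' @param method `"auto"` (homozygote anchoring, then iterative known-
#'   haplotype resolution, then exhaustive search for the remainder) or
#'   `"exhaustive"` (skip the iterative step; every double heterozygote goes
#'   to the global minimum-distinct-haplotypes search — used as a
#'   cross-check of the iterative procedure).
#' @return an object of class `haplotype_set`: `haplotypes`
#'   (`data.frame(daa, dab, support, animals, status, annotation)`),
#'   `per_animal` (phases as `daa|dab` strings), `unresolved_animals`,
#'   `warnings`.
#' @export
phase_two_locus <- function(genotype_table, max_exhaustive = 30L,
                            method = c("auto", "exhaustive")) {
  method <- match.arg(method)
  gt <- genotype_table
  gt$allele_2[!is.na(gt$allele_2) & !nzchar(gt$allele_2)] <- NA_character_
  animals <- unique(gt$animal)
  geno <- lapply(animals, function(a) {
    g <- list()
    for (loc in c("DAA", "DAB")) {
      row <- gt[gt$animal == a & gt$gene == loc, , drop = FALSE]
      if (nrow(row) != 1L)
        stop("animal ", a, " needs exactly one ", loc, " call")
      al <- stats::na.omit(c(row$allele_1, row$allele_2))
      if (length(al) < 1L) stop("animal ", a, " has no ", loc, " alleles")
      g[[loc]] <- unique(al)
    }
    g
  })
  names(geno) <- animals

  hap_key <- function(daa, dab) paste(daa, dab, sep = "|")
  warnings <- character()
  phases <- stats::setNames(vector("list", length(animals)), animals)
  known <- character()

  # step (i): animals homozygous at >= 1 locus phase unambiguously
  for (a in animals) {
    daa <- geno[[a]]$DAA; dab <- geno[[a]]$DAB
    if (length(daa) == 1L || length(dab) == 1L) {
      # pair the single allele with each allele of the other locus
      if (length(daa) == 1L) {
        ph <- hap_key(daa, if (length(dab) == 2L) dab else c(dab, dab))
        if (length(dab) == 2L)
          warnings <- c(warnings, paste0(
            a, ": single DAA allele paired with two different DAB alleles",
            " (possible extra locus or shared-allele haplotypes)"))
      } else {
        ph <- hap_key(if (length(daa) == 2L) daa else c(daa, daa), dab)
      }
      phases[[a]] <- ph
      known <- union(known, ph)
    }
  }

  # step (ii): iterate known-haplotype resolution of double heterozygotes
  if (method == "auto") repeat {
    progress <- FALSE
    for (a in animals) {
      if (!is.null(phases[[a]])) next
      daa <- geno[[a]]$DAA; dab <- geno[[a]]$DAB
      opt1 <- c(hap_key(daa[1L], dab[1L]), hap_key(daa[2L], dab[2L]))
      opt2 <- c(hap_key(daa[1L], dab[2L]), hap_key(daa[2L], dab[1L]))
      u1 <- any(opt1 %in% known); u2 <- any(opt2 %in% known)
      if (u1 && !u2) { phases[[a]] <- opt1; known <- union(known, opt1); progress <- TRUE }
      else if (u2 && !u1) { phases[[a]] <- opt2; known <- union(known, opt2); progress <- TRUE }
    }
    if (!progress) break
  }

  # step (iii): exhaustive minimum-distinct-haplotypes search for the rest
  open <- animals[vapply(phases, is.null, TRUE)]
  ambiguous <- character()
  if (length(open) > 0L) {
    if (length(open) > max_exhaustive)
      stop(length(open), " unresolved animals exceed the exhaustive-search cap")
    opts <- lapply(open, function(a) {
      daa <- geno[[a]]$DAA; dab <- geno[[a]]$DAB
      list(c(hap_key(daa[1L], dab[1L]), hap_key(daa[2L], dab[2L])),
           c(hap_key(daa[1L], dab[2L]), hap_key(daa[2L], dab[1L])))
    })
    grid <- as.matrix(expand.grid(rep(list(1:2), length(open))))
    sizes <- apply(grid, 1L, function(choice) {
      hs <- known
      for (k in seq_along(open)) hs <- union(hs, opts[[k]][[choice[k]]])
      length(hs)
    })
    best <- which(sizes == min(sizes))
    for (k in seq_along(open)) {
      picks <- unique(grid[best, k])
      if (length(picks) == 1L) {
        phases[[open[k]]] <- opts[[k]][[picks]]
      } else {
        ambiguous <- c(ambiguous, open[k])
        phases[[open[k]]] <- opts[[k]][[grid[best[1L], k]]]
        warnings <- c(warnings, paste0(
          open[k], ": equal-parsimony phasings ",
          paste(opts[[k]][[1L]], collapse = " + "), "  vs  ",
          paste(opts[[k]][[2L]], collapse = " + ")))
      }
    }
  }

  support <- lapply(phases, unique)
  all_keys <- sort(unique(unlist(support)))
  haps <- data.frame(
    daa = sub("\\|.*$", "", all_keys),
    dab = sub("^.*\\|", "", all_keys),
    support = vapply(all_keys, function(k)
      sum(vapply(support, function(p) k %in% p, TRUE)), 0L),
    animals = vapply(all_keys, function(k)
      paste(animals[vapply(support, function(p) k %in% p, TRUE)],
            collapse = ","), ""),
    status = ifelse(vapply(all_keys, function(k)
      any(vapply(support[ambiguous], function(p) k %in% p, TRUE)),
      FALSE), "ambiguous", "resolved"),
    row.names = NULL, stringsAsFactors = FALSE)
  haps <- annotate_recombinants(haps)
  per_animal <- data.frame(
    animal = animals,
    hap1 = vapply(phases, `[`, "", 1L),
    hap2 = vapply(phases, `[`, "", 2L),
    status = ifelse(animals %in% ambiguous, "ambiguous", "resolved"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(haplotypes = haps, per_animal = per_animal,
                 unresolved_animals = ambiguous, warnings = warnings),
            class = "haplotype_set")
}

#' Annotate possible crossover products
#'
#' A haplotype sharing its DAA allele with one other haplotype and its DAB
#' allele with another is annotated as a possible crossover product of those
#' two (annotation only; no inference).
#'
#' @param haps `data.frame(daa, dab, ...)` of inferred haplotypes.
#' @param reference optional `data.frame(daa, dab)` of additional (known)
#'   haplotypes to consider as possible parents.
#' @export
annotate_recombinants <- function(haps, reference = NULL) {
  pool <- haps[, c("daa", "dab")]
  if (!is.null(reference)) pool <- unique(rbind(pool, reference[, c("daa", "dab")]))
  haps$annotation <- ""
  for (i in seq_len(nrow(haps))) {
    same_daa <- pool$daa == haps$daa[i] & pool$dab != haps$dab[i]
    same_dab <- pool$dab == haps$dab[i] & pool$daa != haps$daa[i]
    if (any(same_daa) && any(same_dab))
      haps$annotation[i] <- sprintf(
        "possible crossover product of %s|%s and %s|%s",
        pool$daa[which(same_daa)[1L]], pool$dab[which(same_daa)[1L]],
        pool$daa[which(same_dab)[1L]], pool$dab[which(same_dab)[1L]])
  }
  haps
}

#' Compare inferred haplotypes with a reference list
#'
#' @param inferred,reference `data.frame(daa, dab)` (extra columns ignored).
#' @return list with `shared` and `novel` subsets of `inferred`.
#' @export
compare_haplotype_sets <- function(inferred, reference) {
  key <- function(x) paste(x$daa, x$dab, sep = "|")
  ref_keys <- if (is.null(reference) || nrow(reference) == 0L) character()
              else key(reference)
  in_ref <- key(inferred) %in% ref_keys
  list(shared = inferred[in_ref, , drop = FALSE],
       novel = inferred[!in_ref, , drop = FALSE])
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("inferred DAA-DAB haplotypes:\n")
  print(x$haplotypes, row.names = FALSE)
  if (length(x$unresolved_animals))
    cat("ambiguous animals:", paste(x$unresolved_animals, collapse = ", "), "\n")
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
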