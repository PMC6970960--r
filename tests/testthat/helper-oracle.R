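# Independent oracles used by several test files.
#
# Local-alignment oracle: the optimal local alignment score equals the
# maximum, over all pairs of (possibly empty) substrings, of the optimal
# *global* alignment score of those substrings. The global score is computed
# with a three-state affine-gap recursion written here, independent of the
# package's alignment route. Scoring convention (shared definition, not
# copied code): substitution matrix lookup per aligned pair; a gap of length
# L costs open + L * ext.

oracle_global_affine <- function(a, b, submat, open = 10, ext = 0.5) {
  m <- nchar(a); n <- nchar(b)
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  neg <- -1e9
  # M[i,j]: best score of aligning a[1..i], b[1..j] ending in a match state;
  # X: ending in a gap in b (a residue over '-'); Y: gap in a
  M <- matrix(neg, m + 1L, n + 1L)
  X <- matrix(neg, m + 1L, n + 1L)
  Y <- matrix(neg, m + 1L, n + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(m)) X[i + 1L, 1L] <- -(open + ext * i)
  for (j in seq_len(n)) Y[1L, j + 1L] <- -(open + ext * j)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- submat[av[i], bv[j]]
    M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext, X[i, j + 1L] - ext)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext, Y[i + 1L, j] - ext)
  }
  max(M[m + 1L, n + 1L], X[m + 1L, n + 1L], Y[m + 1L, n + 1L])
}

oracle_local_score <- function(a, b, submat, open = 10, ext = 0.5) {
  best <- 0
  m <- nchar(a); n <- nchar(b)
  for (i1 in seq_len(m)) for (i2 in seq.int(i1, m)) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(n)) for (j2 in seq.int(j1, n)) {
      sc <- oracle_global_affine(sa, substr(b, j1, j2), submat, open, ext)
      if (sc > best) best <- sc
    }
  }
  best
}

# score an alignment (two gapped strings) under the same convention; used to
# verify that align_pair's returned alignment achieves its reported score and
# identity
score_alignment <- function(al_a, al_b, submat, open = 10, ext = 0.5) {
  a <- strsplit(al_a, "")[[1L]]; b <- strsplit(al_b, "")[[1L]]
  stopifnot(length(a) == length(b))
  sc <- 0; gap_a <- 0L; gap_b <- 0L
  for (k in seq_along(a)) {
    if (a[k] == "-") {
      gap_a <- gap_a + 1L
      if (gap_b > 0L) { sc <- sc - open - ext * gap_b; gap_b <- 0L }
    } else if (b[k] == "-") {
      gap_b <- gap_b + 1L
      if (gap_a > 0L) { sc <- sc - open - ext * gap_a; gap_a <- 0L }
    } else {
      if (gap_a > 0L) { sc <- sc - open - ext * gap_a; gap_a <- 0L }
      if (gap_b > 0L) { sc <- sc - open - ext * gap_b; gap_b <- 0L }
      sc <- sc + submat[a[k], b[k]]
    }
  }
  if (gap_a > 0L) sc <- sc - open - ext * gap_a
  if (gap_b > 0L) sc <- sc - open - ext * gap_b
  sc
}

test_nt_submat <- function() {
  m <- matrix(-4, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  diag(m) <- 5
  m["N", ] <- -2; m[, "N"] <- -2; m["N", "N"] <- -1
  m
}

# enumerate every parent-site combination sequence for the chimera oracle:
# all 2^k assignments of variable sites to parent 1 or 2
enumerate_site_combinations <- function(p1, p2) {
  vs <- variable_sites(p1, p2)
  k <- length(vs)
  a <- strsplit(p1, "")[[1L]]; b <- strsplit(p2, "")[[1L]]
  grid <- expand.grid(rep(list(1:2), k))
  apply(grid, 1L, function(choice) {
    s <- a
    s[vs[choice == 2L]] <- b[vs[choice == 2L]]
    paste(s, collapse = "")
  })
}

random_nt <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
}

# mutate the given codons of an in-frame region to a codon with a different
# amino acid (non-synonymous by construction)
mutate_codons <- function(region, codon_idx) {
  starts <- 3L * (codon_idx - 1L) + 1L
  for (s in starts) {
    cod <- substr(region, s, s + 2L)
    repl <- if (cod == "TGG") "CAT" else "TGG"   # His <-> Trp, never equal
    substr(region, s, s + 2L) <- repl
  }
  region
}

# synonymous single-codon change: find an alanine-family codon and swap it
syn_mutate <- function(region) {
  n_codon <- nchar(region) %/% 3L
  for (ci in seq_len(n_codon)) {
    s <- 3L * (ci - 1L) + 1L
    cod <- substr(region, s, s + 2L)
    if (cod %in% c("GCT", "GCA", "GCC")) {
      substr(region, s, s + 2L) <- setdiff(c("GCT", "GCA", "GCC"), cod)[1L]
      return(region)
    }
  }
  stop("no alanine codon found")
}

get_slice <- function(name, ref) ref$nt[ref$name == name]

fixture_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- prepare_reference(synthetic_reference_library(),
                                  default_primer_scheme())
    cache
  }
})
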