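# mhctyper

Genotyping the classical MHC genes of Atlantic salmon (*Salmo salar*) from
Illumina amplicon sequencing — for immunogenetics groups typing the class I
**UBA** and class II **DAA**/**DAB** loci from cDNA amplicons, and for anyone
building or auditing an amplicon-based allele-typing workflow for a species
with one classical locus per gene.

## What it does

Per animal and per gene, starting from index-demultiplexed paired-end FASTQ
(300 bp reads over a ~450–500 bp amplicon):

1. **Quality trim** — sliding-window (4-base, Q20) 3' trimming, adapter
   suffix removal, pair rejection under a length floor.
2. **Primer demultiplex** — exact, zero-mismatch anchored match of the
   first-PCR forward primer on R1 and the gene's reverse primer on R2;
   primers stripped.
3. **Merge** — overlap-based pair merging: mate 2 is reverse-complemented and
   every placement with overlap ≥ 10 is scored by mismatch density
   (mismatches/overlap); the lowest-density placement wins, consensus takes
   the higher-quality base.
4. **Collapse** — exact dereplication; variants ranked by abundance; the top
   5 variants with ≥ 1% of merged reads become allele candidates.
5. **Classify** — frame adjustment (0–2 nt per end, minimising internal
   stops), translation, Smith–Waterman alignment (nt: +5/−4, aa: BLOSUM62,
   gap 10/0.5) against a reference allele library restricted to the
   amplified region, closest allele by nucleotide identity with a
   neighbour-joining sibling cross-check, and a colon-delimited
   IPD-MHC-style name proposal: a new **group** needs ≥ 4 aa differences
   (class I) or ≥ 3 (class II); less is a new **protein**; nucleotide-only
   differences a new **synonymous** number.
6. **Genotype** — the top two distinct variants are provisional parents;
   lower ranks are excluded as **jumping-PCR chimeras** when every variable
   site carries one parent's base in a mixed pattern with nothing novel
   elsewhere; two survivors ⇒ heterozygous, one ⇒ homozygous.
7. **Haplotype** — Clark parsimony phasing of the ~3 kb-linked DAA–DAB pair
   across animals: homozygote anchoring, iterative reuse of known
   haplotypes, then exhaustive minimisation of distinct haplotypes, with
   equal-parsimony alternatives surfaced as ambiguous.

A seeded simulator (`simulate_reads()`) generates per-animal FASTQ with known
genotypes, allelic imbalance, substitution errors and single-breakpoint
chimeras plus a per-read truth table, so the whole pipeline is testable
offline. The bundled reference library is **synthetic** (no real salmon
sequence): engineered to reproduce the distance structure the nomenclature
rules act on.

## Worked example

```r
library(mhctyper)

an <- data.frame(
  animal   = c("F1","F1","F2","F2"),
  gene     = c("DAA","DAB","DAA","DAB"),
  allele_1 = c("DAA*06:01","DAB*06:01","DAA*04:01","DAB*09:01"),
  allele_2 = c("DAA*04:01","DAB*09:01",NA,NA),
  balance  = 0.5)

spec <- simulation_spec(an, reads_per_gene = 1000, seed = 2024)
sim  <- simulate_reads(spec)          # 0.1% error, 5% chimeras by default
res  <- run_pipeline(sim$pairs, spec$scheme, spec$library)
print(res)
#> MHC typing of 2 animal(s)
#>
#>  animal gene  allele_1 count_1  allele_2 count_2     zygosity n_excluded
#>      F1  DAA DAA*04:01     286 DAA*06:01     271 heterozygous          0
#>      F1  DAB DAB*09:01     299 DAB*06:01     296 heterozygous          1
#>      F2  DAA DAA*04:01     616      <NA>      NA   homozygous          0
#>      F2  DAB DAB*09:01     609      <NA>      NA   homozygous          0
#>
#> inferred DAA-DAB haplotypes:
#>        daa       dab support animals   status
#>  DAA*04:01 DAB*09:01       2   F1,F2 resolved
#>  DAA*06:01 DAB*06:01       1      F1 resolved
```

(UBA rows, not simulated here, come back as explicit no-calls and are omitted
above.) Reading it: both F1 genes are heterozygous with near-balanced read
counts; one rank-3 DAB variant was excluded as a jumping-PCR chimera
(`n_excluded`); homozygous F2 anchors the phase, so the cohort resolves into
two haplotypes, with `DAA*04:01–DAB*09:01` supported by both animals.
`res$reports` holds the per-candidate classification (closest allele,
identities, NJ sibling, name proposal); `write_pipeline_outputs(res, dir)`
writes the genotype/classification/haplotype TSVs and a per-stage read-count
JSON.

The same stages are available from a shell via the thin CLI:

```sh
exec/mhctyper simulate --reads 1000 --seed 7 --out-dir simdata
exec/mhctyper run --input-dir simdata --out-dir typed
exec/mhctyper haplotype --genotypes typed/genotypes.tsv \
    --reference inst/extdata/known_haplotypes.tsv --out haplotypes.tsv
```

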