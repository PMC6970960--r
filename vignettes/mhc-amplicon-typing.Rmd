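---
title: "Amplicon-based MHC typing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon-based MHC typing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhctyper)
```

## The typing problem

Atlantic salmon carries single classical MHC loci per class: the class I gene
UBA and the physically linked (~3 kb apart, chromosome 12) class II alpha and
beta genes DAA and DAB. Each animal therefore carries at most two alleles per
gene, and the DAA/DAB alleles of one chromosome travel together as a
haplotype. Typing from cDNA amplicons proceeds per animal and per gene:
overlapping 300 bp paired-end reads spanning a 450-500 bp amplicon are
cleaned, demultiplexed by the gene-specific first-PCR primer, merged through
their 3' overlap, dereplicated, and the few top-ranked unique sequences are
classified against a reference allele library. The two most supported
surviving variants are the genotype; everything below them must be explained
as a jumping-PCR artefact, a sequencing-error shadow of a real allele, or a
sign of an extra locus.

This vignette records the models and the genuinely open design choices. The
empirical statements below are all recomputed by the test suite or by
`scripts/acceptance.R`; nothing here is a claim the package does not itself
check.

## Stage models and tunable parameters

### Quality trimming (`quality_trim`)

Reads are 3'-trimmed with a sliding mean over a 4-base window (default
threshold Q20): at the first window whose mean drops below the threshold, the
read is cut at the first sub-threshold base inside that window, so a good
base leading a collapsing window survives. Suffixes of at least 8 nt exactly
matching an adapter prefix are then removed, and a pair is rejected when
either mate falls under `min_len` (default 100 nt). The defaults are
deliberately mild - modern MiSeq v3 data rarely loses more than a small
fraction of pairs here - and all are configurable through
`pipeline_config()`.

### Primer demultiplexing (`demultiplex_by_primer`)

Assignment requires an exact, zero-mismatch match of the forward primer at
position 0 of R1 and of the gene's reverse primer at position 0 of R2;
primers sit at the fragment termini by construction of a two-stage PCR
library, so no offset scan is performed. Exactness makes assignment a
partition: scheme validation rejects primers that are prefixes of one
another, so no pair can match two buckets. The cost of exactness is that a
sequencing error inside a primer sends the pair to the unassigned pile
(about 4% of pairs at 0.1%/base error with ~20 nt primers), which only
shrinks per-gene depth.

### Overlap merging (`merge_pair`)

Mate 2 is reverse-complemented and every placement against mate 1 with an
overlap of at least `min_overlap` (default 10) is scored by substitution
mismatch density (mismatches / overlap length, `N` matching anything).
The lowest density wins; ties go to the longest overlap, then to the
standard "innie" orientation. Indels are not modelled - the overlap scan is
substitution-only, which is the right trade-off for Illumina amplicons.
Placements where mate 2 starts left of mate 1 ("outie", adapter
read-through on short amplicons) are scanned too; their merge returns the
overlap region only, so adapter overhang never enters the merged sequence.

A merge fails when the best density exceeds `max_mismatch_density` (default
0.25). Failure is reported as `too_divergent` when the best density is still
below 0.5, and as `no_overlap` when even the best placement is
indistinguishable from random (> 0.5, the expected density of unrelated
sequences being 0.75) or when no admissible overlap length exists. The 0.5
boundary only affects how a failure is labelled, never whether it occurs.

Consensus: agreeing positions keep the higher of the two Phred scores;
disagreeing positions take the base with the higher score and a quality of
the absolute score difference, floored at 2. This is the standard
overlap-merge convention; nothing downstream consumes merged qualities
quantitatively.

### Dereplication and candidate selection (`collapse_reads`, `select_candidates`)

Identity is exact string equality of merged sequences; variants are ranked
by count with a lexicographic tie-break so output is deterministic. The top
5 variants with at least 1% of the gene's merged reads become candidates.
The 1% floor is the low end of the observed per-allele share in this kind of
data and deliberately keeps true alleles whose counts are depressed by
primer-efficiency differences, which can leave a real allele severalfold
below its partner; abundance is the only signal used - no error-model
denoising.

### Classification (`classify_candidate`)

Candidates are frame-adjusted (0-2 nt off each end, choosing the trim that
minimises internal stop codons, ties toward the smallest left then right
trim), translated, and locally aligned (Smith-Waterman) against every
library allele restricted to the amplified region. Scoring: nucleotide
match +5 / mismatch -4 (N: -2 against bases), BLOSUM62 for amino acids, gap
opening 10, gap extension 0.5, a gap of length L costing 10 + 0.5L.
Identity is identical columns over alignment length; similarity additionally
counts positive-scoring substitutions.

The closest allele is the best nucleotide identity - an objective,
order-independent criterion. A neighbour-joining guide tree over the
candidate plus the library (distances 1 - identity/100) is retained as a
cross-check: the candidate's nearest leaf by tree-path distance (negative
NJ branches truncated at zero, ties resolved toward the topological sister
clade) is reported, and discordance with the identity criterion is flagged
rather than resolved. Guide-tree siblings depend on tie-breaking in tree
construction, which is exactly why they are not the primary criterion.

Like-for-like comparison matters: reference alleles are sliced to the
amplified region by locating the primer sites (exact match, else best local
alignment), because candidates have their primers stripped during
demultiplexing.

### Nomenclature (`propose_name`)

Names are colon-delimited: group, protein, synonymous, non-coding
(`Sasa-UBA*01:01:01:01`), with old concatenated names (`Sasa-DAA*010102`)
converted on input. A new group requires at least 4 amino-acid differences
for class I and 3 for class II; any smaller non-synonymous difference is a
new protein in the closest allele's group; a nucleotide-only difference is a
new synonymous number. A candidate nucleotide-identical to more than one
library allele over the amplified region is reported as ambiguous rather
than arbitrarily resolved - with this amplicon that genuinely happens
(alleles can differ only outside the amplified fragment), and resolving it
requires extending the sequence by Sanger.

Two decisions here were open. First, whether the difference thresholds apply
to the full coding sequence or the amplified fragment is unstated in the
nomenclature convention; this package computes them over the amplified
region only, and therefore marks every proposal as requiring full-length
verification before official naming. Second, ties for the closest allele are
broken by higher nucleotide identity and then by name, with all co-closest
alleles reported - there is no established rule, so the package surfaces the
tie instead of hiding it. Non-coding (fourth-field) assignment is out of
reach of cDNA data and never proposed.

### Chimera exclusion and genotype calls (`chimera_check`, `call_genotype`)

Jumping PCR produces a sequence whose variable sites each carry one of the
two parental bases, in a mixed pattern, with nothing novel elsewhere.
`chimera_check` tests exactly that, on nucleotides (strictly more
informative than the amino-acid pattern): the candidate must differ from
both parents, match a parent at every variable site, use both parents at
least once, and mismatch the parental consensus at no more than
`allowed_novel` invariant positions. The default `allowed_novel = 0` is the
strict reading of the pattern - one genuinely novel base rescues a candidate
from chimera status, because a chimera of two templates cannot contain bases
found in neither.

Genotypes take the two most abundant distinct variants as provisional
parents; every lower rank is chimera-tested against them (all ranks, not
just the third), then the sub-threshold filter applies. Two survivors are a
heterozygote; one is a homozygote - no statistical test of allelic balance
is applied, because abundance ratios here are dominated by primer
efficiency, not by sampling. More than two survivors are called as the top
two with an explicit possible-extra-locus warning.

### Haplotype phasing (`phase_two_locus`)

Clark-style parsimony over the two linked class II loci: (i) animals
homozygous at either locus are phase-known; (ii) a double heterozygote is
resolved when exactly one of its two phasings reuses an already-known
haplotype; (iii) anything left goes to an exhaustive search minimising the
number of distinct haplotypes (at most 2^k configurations for k unresolved
animals; the cap is 30 animals). The parsimony objective is this package's
choice - phasing "by inspection" has no stated rule - and equal-parsimony
alternatives are reported as ambiguous for the affected animals rather than
broken by any tie rule. An animal with one DAA allele but two DAB alleles is
phased as that DAA paired with both DABs, with a warning: the data cannot
distinguish a shared-allele haplotype pair from an unrecognised duplication.
A haplotype sharing its DAA with one other haplotype and its DAB with
another is annotated as a possible crossover product; this is annotation
only, never inference.

## The synthetic data

Real reference alleles cannot be bundled, so the package constructs a fully
synthetic stand-in library (`synthetic_reference_library()`, also shipped as
`inst/extdata/synthetic_reference_alleles.fasta`): per locus, a random
stop-free codon backbone between the real primer sites, with reserved codon
slots whose substitutions realise the documented distance structure - allele
groups 6 (class I) or 4 (class II) amino acids apart, protein variants 1-2
amino acids within a group, `DAA*01:01`/`DAA*01:02` identical over the
amplified region and separated only 3' of it, `DAB*09:02` one amino acid
from `DAB*09:01`, one novel UBA sequence exactly two amino acids from
`UBA*35:01`, and the remaining novel alleles beyond every class threshold.
Two of the novel UBA alleles carry the alternative UBA4 forward-primer site,
exercising per-primer demultiplexing the way leader-sequence variation does
in real data.

The simulator (`simulate_reads`) draws, per read pair, a parental template
(heterozygotes: allele 1 with probability `balance`) or, with probability
`chimera_rate`, a single-breakpoint recombinant with the breakpoint uniform
between the first and last variable sites - outside that interval a
recombinant is indistinguishable from a parent, so restricting breakpoints
keeps the truth labels meaningful. Single breakpoints only: one
re-association event per artefact molecule is the dominant mode.
Substitution errors are i.i.d. per base; qualities follow a constant or
linearly declining model; a fixed seed gives byte-identical output.

Default study conditions: nine animals x three genes with the bundled
genotype table as truth, 2,000 read pairs per cell, 300 bp reads, 0.1%/base
substitution error, 5% chimera rate, per-cell allelic balance drawn from
[0.2, 0.8]. These are desk-scale stand-ins for production MiSeq runs, which
yield orders of magnitude more pairs per animal: large enough that every
variant class (true alleles, chimeras, error shadows) appears at realistic
relative abundances, small enough that the full cohort types in about a
minute.

What the simulator does **not** model - indels, PCR-cycle-resolved
amplification bias, index hopping, quality-correlated error bursts,
contamination - bounds what passing tests show: they demonstrate the
pipeline's logic (assignment, merging, ranking, chimera exclusion, phasing)
under the stated error model, not robustness to every artefact of a real
flow cell. Real-data throughput figures (retention, merge rates, top-allele
shares) are reported by the same stage-count machinery but are not
reproducible at desk scale and are not asserted against.

## Numerical and degenerate-input choices

* Phred+33 only; apparent +64 encodings are rejected outright.
* `U` maps to `T` and sequences are uppercased on input (cDNA context).
* An empty local alignment (no positive-scoring pair, e.g. disjoint
  alphabets) is identity 0, not an error.
* Candidates with internal stop codons in all three frames are flagged
  ("no clean frame") but still reported - they are usually artefacts and the
  user should see them.
* Variant ordering, closest-allele ties and haplotype ambiguity all have
  deterministic, documented tie-breaks; no result depends on input order
  (library permutation invariance is tested).
* Empty FASTQ input yields no-calls with reasons, never errors; a stage
  failure aborts only its animal x gene cell.

## Known limitations

* Chimera detection considers only the two provisional parents, as the
  genotype model implies; three-allele chimeras from contamination would
  need an abundance-weighted multi-parent model, deliberately out of scope.
* Within-amplicon ambiguity (`DAA*01:01` vs `DAA*01:02`) is surfaced, not
  resolved; resolution requires different primers and Sanger sequencing.
* The identity/similarity computation is local-alignment based; for
  candidates much shorter than the reference slice, identity is relative to
  the aligned region, which mildly favours truncated candidates. At this
  amplicon geometry (full-length merges) the effect is nil.
* The exhaustive phasing fallback is exponential in the number of unresolved
  double heterozygotes; it is capped and errors beyond the cap rather than
  silently degrading.
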