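---
title: "Coverage-based MHC class I typing from RNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based MHC class I typing from RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhctyper)
```

## The problem

MHC class I genotyping in cattle (BoLA) and other non-model species is hard
for two reasons: haplotypes carry a *variable number* of class I genes
(duplications included), and the public allele catalogue is small, so an
individual routinely expresses alleles that no database records.
White-blood-cell RNA-seq offers a way out: class I genes are highly
expressed, so an untargeted transcriptome carries every expressed allele at
deep coverage, without the allele preselection that PCR-based typing
suffers from.

`mhctyper` implements the full typing workflow on top of that idea:

1. **Strict calling.** Short reads are aligned end-to-end, ungapped, to a
   catalogue of known allele cDNA sequences with **zero mismatches**; an
   allele is called *present* only when **every base** of its sequence is
   covered by at least one such read. Multi-mapping reads support every
   allele they match (policy `"all"`), which is deterministic and
   conservative for a coverage criterion.
2. **Relaxed discovery.** A second alignment allows up to **3 mismatches**
   per read and keeps only each read's best stratum. Alleles fully covered
   in this pass — or covered except a *single* region shorter than 5 bp —
   become *parent* candidates for novel alleles. Called alleles are also
   inspected for recurrent pileup variants (a mutation recurring against
   every identified allele betrays a novel allele even when its parent
   looks present).
3. **Novel-allele reconstruction.** Against each parent, a pileup collects
   consistent variant bases; variants are phased into haplotypes with read
   and mate-pair co-occurrence evidence; each phased set applied to the
   parent yields a candidate sequence. Separately, reads carrying recurrent
   k-mers absent from the catalogue seed a greedy overlap assembly (the de
   novo path for alleles with no close parent). Every candidate must pass
   validation: distinct sequence, **complete zero-mismatch re-coverage** by
   the individual's reads, and protein-level plausibility (an open reading
   frame, or — for non-classical alleles — an early stop codon or a
   VPI/IPI/VLIK transmembrane motif).
4. **Iteration to closure.** Accepted alleles enter the catalogue and the
   whole procedure repeats until an iteration adds nothing. Classical genes
   are processed to closure before non-classical genes.
5. **Quantification.** A final zero-mismatch alignment against *only* the
   individual's called alleles yields per-allele read counts, reported as
   proportions normalised separately within the classical and the
   non-classical class.
6. **Validation by inheritance.** In families, multi-allele genotypes are
   checked against Mendelian transmission; founder haplotypes are derived
   by exhaustive 2-partition search, and SNP flank haplotypes in the class
   I region provide an independent transmission track.

## The aligner

The aligner re-implements the contract of an ungapped, bounded-mismatch
short-read mapper (end-to-end, `v` mismatches, best stratum) so that the
pipeline is hermetic and deterministic. It uses a 2-bit k-mer index over
the forward strand of the catalogue (reads are reverse-complemented
instead) and pigeonhole seeding: for a mismatch bound `v`, `v + 1`
non-overlapping seeds of length `k` guarantee that any valid placement has
at least one exact seed. Candidates are verified by full-length Hamming
comparison with early exit. Reads shorter than `(v + 1) k` fall back to an
exhaustive scan. `N` counts as a mismatch on either side; k-mers containing
`N` are simply not indexed, which cannot lose a valid placement because a
seed overlapping an `N` is never exact.

Coordinates are 0-based and half-open throughout; orientation is recorded
on the read and the catalogue stays forward. The test suite holds the
aligner to an *independent* brute-force Hamming scan over every allele,
offset and orientation (property-based, and at scale in the acceptance
tests).

Default `k = 15`: long enough that random 15-mers essentially never
collide in a ~50-kb catalogue, short enough that `(v+1)k = 60 ≤ 61` nt
still admits pigeonhole seeding at `v = 3` for the 61-nt reads the
sequencing design produces.

## Calling and the gap rule

"Completely covered" is implemented as depth ≥ `min_depth` at every base.
The underlying criterion is *presence* of zero-mismatch coverage, with no
stated depth threshold; we make the threshold explicit and default it to
**2 independent reads per base**. The reason is an error mode that only
exists at finite depth: a novel allele differs from its parent at a
handful of bases, and a single read carrying a sequencing error that
happens to revert such a base to the reference creates zero-mismatch
coverage of the parent at exactly the discriminating position. At 0.3 %
per-base error and ~25× depth this occurs for a few percent of novel
alleles, falsely calling the parent (which then blocks discovery) or
validating a partially reconstructed candidate. Requiring two independent
zero-mismatch reads per base removes the artefact (two such error reads
essentially never co-occur), while at the deep coverage the method is
designed for — thousands-fold for class I transcripts in blood — the two
settings coincide everywhere except at artefact positions.
`min_depth = 1` restores the literal presence criterion.

The candidate rule for novel-allele parents reads
the "single region < 5 bp" tolerance literally: exactly one maximal
uncovered interval, of length ≤ 4 bases. Two 2-base gaps disqualify; one
5-base gap disqualifies. Candidates are processed classical-first, then by
descending mean depth (the class order is fixed by the workflow; the
within-class order is a tie-break we declare).

## Variant thresholds and phasing

Manual inspection of alignments is replaced by explicit thresholds: a
pileup variant needs `min_support = 3` reads and `min_fraction = 0.2` of
the local pileup. The fraction rationale: a true variant on a co-dominantly
expressed allele approaches ~0.5 of the parent's pileup (or ~1.0 when the
parent itself is absent), so 0.2 tolerates multi-mapping dilution while
sequencing error at ≤ 0.5 % per base stays far below it.

Phasing builds a co-occurrence graph: an edge between two variants requires
`min_link = 2` fragments (reads or concordant mate pairs) carrying both
alternative bases; fragments carrying one alternative and one reference
base contribute *anti-edges* (repulsion). Connected components under edges
become phased sets; a component containing repulsion evidence is flagged
ambiguous and excluded rather than silently merged — repulsion dominates,
because two variants seen in repulsion belong to sibling alleles.

Variants of one parent that are never co-observed (too far apart for a
fragment) end up in separate components. Candidate sequences are therefore
generated from **anti-edge-free unions of components, smallest first**:
singletons are validated first, and only components not already explained
by an accepted allele are combined. Validation by complete re-coverage
settles which combination is real — a candidate missing a true variant has
an uncovered base at exactly that position and is rejected. This parsimony
order prevents a spurious "merged" allele when two sibling alleles each
validate on their own.

## De novo assembly

Alleles too far from any catalogue entry (beyond 3 mismatches per read
everywhere) are reached by a greedy overlap walk, mirroring reading the
sequence directly off assembled reads: seed on a k-mer absent from the
catalogue but present in ≥ `min_support` unexplained reads, then extend
base by base, requiring ≥ 25 nt of exact overlap for a read to vote, in
both directions (the reverse strand is handled by extending the reverse
complement). The walk uses **all** reads of the individual, not only
unaligned ones — stretches where the novel allele locally resembles a
catalogue allele are sequenced by reads that align there, yet still belong
to the contig. A second extension branch with ≥ 2 reads and ≥ 25 % of the
votes aborts the assembly as ambiguous; contigs under 200 nt are
fragmentary. The contig's strand is arbitrary, so both orientations are
offered to protein validation. This is deliberately not a de Bruijn
assembler: the intended regime is one highly expressed transcript at deep
coverage, where a transparent overlap walk is robust and auditable.

Indel alleles are reachable only through this path: the aligner is
ungapped by design (mirroring the `-v` alignment mode the workflow is
built on), so a substitution-only novel allele is the only kind the
variant path can produce.

## Quantification

Counts are raw mate counts (no length normalisation by default — class I
cDNAs within a class are nearly equal in length, and the published tables
are read-count ratios; a length-normalised mode exists behind a flag).
Multi-mapping ties are split fractionally by default, which conserves read
mass exactly and is deterministic; a seeded random single-assignment mode
emulates mappers that report one best hit. Proportions are normalised
within classical and within non-classical alleles separately; a class with
zero counts reports `NA`, not 0/0. Reports render 3 decimal places.

## Pedigree validation

SNP quality control retains markers inside the target region with call
rate > 0.98, minor allele frequency > 0.05 and Hardy-Weinberg exact-test
p > 0.001. The HWE test is the conditional exact test (enumeration of
heterozygote counts given allele counts), evaluated on founders only —
chi-square approximations are unreliable at family-panel sizes, and
offspring would distort the test through family structure.

Haplotype derivation searches all 2-partitions of each parent's called
allele set (canonicalised so the first allele anchors haplotype 1, i.e.
solutions are unique up to within-parent label swap) for assignments under
which every full sib's allele set is the union of one paternal and one
maternal haplotype. Sets are small — haplotypes carry 2–3 classical and
2–5 non-classical gene copies — so the 2^(n−1) search is cheap; it is
refused above 20 alleles per parent. Duplicated genes are supported (a
haplotype may carry several alleles of one gene) and per-haplotype gene
copy counts are reported. Alleles shared between the parents make an
offspring allele explainable from either side; all co-optimal assignments
are then reported as `"unresolvable"` rather than resolved arbitrarily.
Note that when both parents are genotyped and carry disjoint allele sets,
even genotypically identical sibs leave a unique partition (each offspring
set intersected with a parent's set *is* the transmitted haplotype, and
the other haplotype is the complement); ambiguity requires allele sharing
or missing parent genotypes. Recombination inside the class I region is
assumed absent; an inconsistency that could be a recombinant is reported
as a violation with that caveat in the message.

SNP flank tracking infers, at every SNP where a parent is heterozygous,
which parental allele each offspring received (using the other parent to
resolve heterozygous offspring), and partitions the offspring into
transmission classes as the connected components of the pairwise-agreement
graph — at parent-heterozygous SNPs the two parental chromosomes always
differ, so any overlapping informative SNP decides whether two offspring
share a chromosome. Sparse informativeness can leave more than two
classes (flagged with a warning); concordance with the MHC haplotype
classes is the validation criterion.

## The synthetic test bed

The generator produces the structures the method assumes, not real
transcriptomes:

* **Catalogue.** Per gene (classical 1–6, non-classical NC1–NC5 by
  default) an ancestral open reading frame of ~1.1 kb (the class I cDNA
  scale), from which alleles derive by seeded substitutions at 2 % per
  base. Classical alleles always retain a full ORF; non-classical alleles
  carry an early stop codon or a VPI/IPI/VLIK motif (probability 1 by
  default), so they always exhibit the features the validator checks.
* **Novel alleles.** A catalogue parent plus `k` substitutions (1–3 for
  the variant path; tens of substitutions to exercise the de novo path),
  withheld from the public catalogue and recorded in the truth set.
  Substitutions avoid start/stop codons and feature motifs so class
  features survive.
* **Families.** Founder haplotypes drawn with 2–3 classical and 2–5
  non-classical gene copies, allele-disjoint across founders so that
  haplotype derivation is identifiable; offspring inherit one haplotype
  per parent uniformly; a 7-SNP biallelic flank panel is phased with the
  founder chromosomes (positions in the class I region of bovine
  chromosome 23).
* **Reads.** 61-nt paired-end reads (the sequencing design's cycle
  count) from fragments of mean 200 ± 30 nt drawn with probability
  proportional to per-allele expression weights (symmetric Dirichlet with
  concentration 5, optionally shared between individuals with identical
  genotype, emulating the observed cross-individual consistency of
  allele-level expression). Substitution errors at a configurable rate
  (0.3 % default); constant qualities; fully deterministic under a seed.
  Fragment raw starts may overhang the molecule termini and are truncated,
  so terminal bases are covered at near-interior depth — with
  interior-uniform fragment starts the terminal base of a transcript is
  covered only by fragments starting exactly on it, which at desk-scale
  depth (hundreds of fragments per allele, versus the orders-of-magnitude
  deeper real libraries) would break the complete-coverage criterion for
  reasons that have nothing to do with the method.

What the generator does **not** emulate: transcriptome-wide background
(only an optional fraction of random decoy pairs, to exercise the
"unaligned reads are ignored" contract), splice variation, coverage bias
along transcripts, indel sequencing errors (excluded by default because
the aligner is ungapped; available behind a flag to probe de novo failure
modes), and base-quality structure. Passing tests therefore demonstrate
the method's *logic* — calling, discovery, phasing, quantification,
inheritance — under its stated assumptions, not its robustness to every
artefact of real libraries.

## Problem sizes in the test suite

The suite runs everything at desk scale, chosen once: unit tests use
3 + 2 genes × 3 alleles of 600 nt; the end-to-end properties use the full
default catalogue (11 genes × 4 alleles of 1.1 kb) with 900–1,400 read
pairs per individual (≈ 20–40× per-allele depth), 20 individuals × 20,000
error-free pairs for exact-recovery, 50 seeded novel-allele
reconstructions at 0.3 % error, 100 seeded sibling-phasing runs, and
50,000 pairs for quantification recovery. `scripts/acceptance.R` repeats
the same computations from scratch at comparable sizes and writes the
resulting rates as JSON.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
sim <- simulate_catalogue(cfg)
nov <- spawn_novel_alleles(sim$catalogue, 1, substitutions_range = 1:3,
                           seed = 8)
g <- c(setdiff(sim$catalogue$alleles$allele_id,
               nov$novel$parent_id)[c(1, 12, 30)], nov$novel$novel_id)
w <- setNames(rep(0.25, 4), g)
rr <- simulate_reads(w, c(sim$catalogue$sequences, nov$sequences), cfg,
                     seed = 9, n_pairs = 1000)
run <- run_pipeline(list(cow1 = rr$reads), sim$catalogue)
run$calls$cow1
run$manifest$novel_alleles
```

## Known limitations

* The complete-coverage criterion can genuinely call an unexpressed
  allele whose every window is matched by some expressed relative (a
  mosaic of a novel allele's reads plus conserved windows of a same-gene
  allele, for example). Variant inspection of called alleles recovers the
  hidden novel allele in such cases, but the mosaic parent itself remains
  "present" by the criterion's own logic; family-based validation is the
  backstop.
* Ungapped alignment means indel alleles surface only via de novo
  assembly.
* The phasing graph needs fragments that bridge variant pairs; variants
  farther apart than a fragment on a parent with no linking evidence are
  resolved by the validation-driven union enumeration, which assumes the
  accepted-allele set explains every recurrent variant.
* Haplotype derivation assumes no recombination within the region and
  parents genotyped with the same completeness as offspring.
* When a novel allele carries several variants pairwise farther apart
  than a fragment, and co-expressed same-gene relatives mosaic-cover the
  single-variant branch candidates, the reads cannot distinguish one
  multi-variant allele from two sibling branch alleles — both
  interpretations satisfy complete coverage. Reconstruction then reports
  the branch alleles. Longer fragments (or mates) that bridge the
  variants resolve the ambiguity.
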