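---
title: "Methods: homozygosity filtering and cohort validation for recessive disease-gene discovery"
author: "pxdscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homozygosity filtering and cohort validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pxdscout)
```

## The discovery model

pxdscout implements the classical whole-genome strategy for a fully
penetrant autosomal-recessive trait in a closed breeding population such
as a dog breed. The assumptions are explicit:

* the causal variant is **homozygous** for the alternate allele in every
  affected individual (recessive inheritance, no locus heterogeneity
  between the sequenced cases);
* it **alters the gene product** — missense, nonsense, stop-loss,
  frameshift, in-frame indel, or disruption of an exon-splicing signal
  (purely regulatory causes are outside the model);
* it is **absent from control genomes**, at any zygosity. Heterozygous
  carriers certainly exist in the breed, but a panel of unrelated control
  genomes is unlikely to contain the rare causal allele at all, whereas
  shared ancestral polymorphism will appear in at least one control.
  Treating any control observation as disqualifying is the strictest
  reading and is what makes the candidate count shrink monotonically as
  controls accumulate.

For a case genome the filter retains exactly the calls satisfying all
three criteria (`filterCandidates()`); with several cases the candidate
sets are intersected on the variant identity key
(contig, position, ref, alt) after decomposition of multi-allelic records
and left-normalisation (`intersectCases()`). `candidateTrajectory()`
recomputes the candidate count after each control genome is indexed; the
sequence is non-increasing because indexing never removes store entries.

The control store is an embedded in-memory index (variant key → set of
observing genomes) rather than a database server; its query semantics —
"has any control genome observed this variant?" — are all the filter
needs.

## Consequence annotation

Gene models are single-transcript: ordered exons on a contig plus genomic
CDS bounds, read from BED12 (blocks + thick range) or minimal GFF3
(gene/exon/CDS). Internally exons are held as `IRanges` (1-based, closed,
the Bioconductor convention); all file I/O keeps each format's native
convention (VCF 1-based, BED 0-based half-open).

A substitution inside the CDS is mapped to its coding position `c` along
the coding strand; codon index and offset follow from
`⌊(c−1)/3⌋+1` and `((c−1) mod 3)+1`, and the reference and alternate
codons are translated with the standard genetic code
(`Biostrings::GENETIC_CODE`). Minus-strand genes are handled by reverse
complement; no special start-codon category is used — a variant in the
initiator codon is classified by its codon effect like any other.
Length-changing coding variants are frameshift unless the length
difference is a multiple of 3 (in-frame indel). Protein HGVS uses
one-letter codes by default (`p.T133I`); three-letter output is a flag.
HGVS for indels is rendered in a simplified `c.start_enddel` /
`c.pos_pos+1insSEQ` form — sufficient for reporting, not a full HGVS
realignment engine.

**Splice window.** The extent of an "exon-splicing signal" is not sharply
defined; the default window is the 2 canonical intronic bases at each
boundary (the GT/AG dinucleotides), configurable via `spliceWindow` for
users who want to include the extended donor/acceptor context. Donor and
acceptor sides are assigned in transcription order, so they mirror
correctly on minus-strand genes.

## Genotype calling from endpoint fluorescence

Allelic-discrimination assays yield one endpoint intensity per
allele-specific probe. The caller works in polar coordinates of the
(reference-channel, variant-channel) plane: genotype information is
carried by the **angle** (0° pure reference, 45° heterozygote, 90° pure
variant), while the radius reflects amplification strength. A k-means
style iteration on angles, seeded at the canonical 0°/45°/90° and with
empty clusters pinned to their seeds, assigns each amplified sample to a
genotype; this makes calls invariant to uniform rescaling of both
channels (gain settings, plate effects).

Two no-call rules, both configurable: samples whose magnitude falls below
`minSignalFrac` (default 0.05) of the cohort's median magnitude are
failed amplifications; samples farther than `maxAngleDeg` (default 20°)
from every converged centre are ambiguous. At the generator's noise
levels (5% of signal by default) the caller reproduces planted genotypes
essentially perfectly; the test suite measures ≥99% accuracy at 10%
noise and exact recovery at zero noise.

`segregationCheck()` tabulates genotype × phenotype within each breed
stratum. Recessive consistency requires every called affected sample to
be hom-alt and no called unaffected sample to be hom-alt; no-calls and
unknown phenotypes are excluded from the criterion but reported. Control
allele frequency is `(2·hom_alt + het) / (2·n_called_controls)`, overall
and per breed. Association uses a recessive coding — hom-alt versus the
rest, affected versus unaffected — in a two-sided Fisher exact test
computed by enumerating the hypergeometric distribution over all tables
with the observed margins and summing probabilities no greater than the
observed table's (relative tie tolerance 1e−7, the standard convention);
degenerate margins return p = 1. A single pre-specified site is tested,
so no multiple-testing correction is applied. Breed labels are free
text; crossbred samples (e.g. SCWT × Poodle) are ordinary rows and no
pedigree inference is attempted.

## Conservation analysis

The input is a precomputed ortholog residue alignment and a focal column
(alignment construction is out of scope). `columnComposition()` counts
residues at the column, case-insensitively, with gaps excluded and
reported separately; `toleratedStates()` returns the residues observed at
least `minCount` times (monotone non-increasing in the threshold) and can
flag whether a variant amino acid lies outside the observed set — the
reasoning used to argue that isoleucine at a position occupied only by
threonine or serine across 148 vertebrate species is likely deleterious.
No phylogenetic weighting or substitution-matrix scoring is applied: the
statement made is purely observational ("never seen"), which is also its
limitation — shallow or biased species panels weaken it.

## The synthetic-data generator

`syntheticScenario()` / `generateScenario()` produce every input the
pipeline consumes, from one integer seed, with a truth manifest. Defaults
encode the study conditions: **2 case genomes**, **20 controls**, a
planted causal substitution at coding position **398** (codon 133) whose
reference codon is forced to ACC so the change is the canonical Thr→Ile,
and the published genotyping cohort (25 affected hom-alt — 22 SCWT and 3
Whoodles — 682 control SCWT of which 15 het and 667 hom-ref, 388 Poodles
and 132 other-breed dogs, all hom-ref). Where the study does not pin a
value we chose once what is realistic at desk scale and kept it: 2
contigs of 50 kb, 20 three-exon genes with 600 nt CDS and 30 nt UTRs,
Poisson background rates of 25 het-coding / 20 hom-coding / 25
hom-non-coding variants per genome (≈1,500 background variants per
scenario), fluorescence signal 1000 units with 5% Gaussian noise, and an
alignment column of 146 threonines + 2 serines.

The sharing model controls identifiability. Each case background
homozygous coding variant is, with probability `pControlShare` (default
0.7), also placed in 1–3 control genomes; with probability `pCaseShared`
(default 0) it is instead planted in **all** cases and kept out of
controls; otherwise it is private to its case. With the default
(`pCaseShared = 0`) every confounder is removed either by the control
store or by the cross-case intersection, so recovery of exactly the
planted variant is guaranteed — this is the regime the recovery tests
use. Raising `pCaseShared` makes recovery deliberately ambiguous, and the
tests verify that the pipeline's output then matches a replay of the
generator's own manifest through the filter criteria.

Cohort genotype counts are assigned by exact partition of each stratum,
not Bernoulli draws, so printed counts are reproduced exactly on every
seed. A single RNG stream derives from the scenario seed; identical seeds
give byte-identical output files (the determinism test hashes them).

What the generator does **not** emulate: sequencing error and
variant-calling artifacts (calls are taken as given; the optional quality
gate of real pipelines is not modelled), linkage disequilibrium and
haplotype structure, population stratification within breeds, indel-rich
background (background variants are substitutions; indel handling is
exercised by dedicated unit tests), and read-level data. Passing the
synthetic suites therefore demonstrates the correctness of the filtering
logic and calling algorithms under the stated model, not robustness to
noisy real-world call sets.

## Numerical and design choices

* Variant identity is exact-match on the normalised
  (contig, pos, ref, alt) key; no fuzzy indel matching.
* Missing genotypes in input VCFs are excluded (not homozygous) and
  counted in a message.
* Ref alleles of every variant are validated against the assembly;
  mismatch is an error rather than a warning, since it indicates
  inconsistent inputs.
* Ties in the Fisher two-sided sum use the `(1 + 1e-7)` relative
  tolerance; the test suite checks equality with an exhaustive
  `lchoose`-based enumeration to 1e−12 over all 2×2 tables with n ≤ 60.
* Reports print floats with 6 significant digits in a stable key order,
  so reruns diff cleanly.
* Problem sizes in the test and acceptance suites — 50 replicate
  scenarios for recovery, 200 small scenarios for trajectory
  monotonicity, 500–1000 cohorts of 200 samples for caller accuracy —
  were chosen as the smallest sizes that make the corresponding claims
  statistically meaningful at desk scale.

## Known limitations

One transcript per gene (no isoform resolution); no compound-heterozygous
mode (the model is strictly homozygous-recessive); no population
frequency annotation from external databases; no protein-impact scores;
the splice model is positional only (no motif scoring). The published
candidate lists accompanying the original study are distributed as a
supplementary file, and their exact counts are therefore exercised
against synthetically constructed candidate tables of the same shape
rather than the original file.
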