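# pxdscout

Candidate-variant discovery for autosomal-recessive Mendelian disease from
whole-genome variant calls, built around the strategy that mapped canine
paroxysmal dyskinesia (cPxD) in Soft-Coated Wheaten Terriers to a
hypomorphic missense allele of *PIGN* (`PIGN:c.398C>T`, p.T133I). The
package is aimed at researchers doing disease-gene discovery in companion
animals or other small pedigreed populations: it provides the filtering
and validation machinery as tested, reusable functions, together with a
seeded synthetic-data generator so every stage can be exercised and
benchmarked without any external data.

## What it computes

**Three-criteria homozygosity filter.** For an affected genome *A* with
variant calls `V(A)` and a store of control genomes `C₁…Cₙ`, the candidate
set is

```
K(A) = { v ∈ V(A) :  altering(v)  ∧  gt_A(v) = alt/alt  ∧  v ∉ ⋃ᵢ V(Cᵢ) }
```

where `altering(v)` means the predicted consequence changes the protein
(missense, nonsense, stop-loss, frameshift, in-frame indel) or disrupts a
splice signal (±2 intronic bases by default). Any control observation —
heterozygous or homozygous — disqualifies a variant: under a recessive
model unaffected carriers are expected, but the causal variant must be
homozygous in cases and was absent from all control genomes. With two or
more cases the final candidates are the intersection of the per-case sets,
keyed by (contig, pos, ref, alt) after biallelic decomposition and
left-normalisation. `candidateTrajectory()` reproduces the study's
observation that `|K(A)|` is non-increasing as controls accumulate.

**Consequence annotation.** Variants are classified against single-
transcript gene models by translating the spliced CDS with the standard
genetic code (strand-aware), and rendered in HGVS c./p. notation; coding
position 398 lies at offset 2 of codon 133, so an ACC→ATC change is
reported as `c.398C>T` / `p.T133I`.

**Cohort validation.** Endpoint allelic-discrimination fluorescence is
genotyped by angle-based clustering of the two probe channels (seeds at
0°/45°/90°, scale-invariant, no-call radius). `segregationCheck()`
tabulates genotype × phenotype per breed, flags recessive consistency
(all affected hom-alt, no unaffected hom-alt), reports control allele
frequencies, and tests association with a two-sided Fisher exact test
(hom-alt vs rest × affected vs unaffected) computed by hypergeometric
enumeration.

**Conservation.** `columnComposition()` and `toleratedStates()` summarise
an ortholog alignment column at the focal codon and flag a variant residue
that has never been observed across species.

## Worked example

```r
library(pxdscout)

# a full synthetic study: 2 affected genomes sharing a planted recessive
# missense variant, 20 control genomes, shared + private background variants
real <- generateScenario(syntheticScenario(seed = 42))
res  <- analyzeScenario(real)
res$intersection
#> CandidateSet [case01&case02]: 1 variant(s) in 1 gene(s), 20 control genome(s) used
candidateVariants(res$intersection)[, c("geneId", "category", "hgvsC", "hgvsP")]
#>    geneId category    hgvsC   hgvsP
#> 1 gene007 missense c.398C>T p.T133I
```

The filter + intersection recovered exactly the planted causal variant:
one missense change at coding position 398 (codon 133, Thr→Ile), the
synthetic analogue of the *PIGN* discovery.

```r
# the published genotyping cohort (1227 dogs), called from fluorescence
cohort <- generateStudyCohort(seed = 1)
cohort$genotype <- callGenotypes(cohort)$genotype
segregationCheck(cohort)
#> SegregationReport
#>   consistent with recessive inheritance: TRUE
#>   Fisher exact p (hom-alt vs rest): 1.19242e-52
#>   control alt-allele frequency: 0.0062396
#>       breed   n nAffectedHomAlt nAffectedOther nControlHomAlt nControlHet ...
#>  OtherBreed 132               0              0              0           0
#>      Poodle 388               0              0              0           0
#>        SCWT 704              22              0              0          15
#>     Whoodle   3               3              0              0           0
```

All 25 affected dogs are variant-allele homozygotes, no unaffected dog
is, and the 15 heterozygous carriers among 682 control SCWT give a
control allele frequency of 15/1364 ≈ 0.011 in that breed.

```r
aln <- generateAlignment(c(T = 146L, S = 2L))
toleratedStates(aln, 1, variantAA = "I")
#> [1] "T" "S"
#> attr(,"variantObserved")
#> [1] FALSE
```

Across a 148-species ortholog panel only threonine and serine occur at
the focal position; the variant isoleucine is unobserved.

A file-based workflow (FASTA + GFF3/BED12 + per-genome VCFs + cohort TSV
+ aligned FASTA, driven by a YAML config) is available through
`writeScenario()` / `runPipeline()`, and a thin command-line wrapper lives
in `inst/cli/pxdscout.R` (`simulate` and `run` subcommands).

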