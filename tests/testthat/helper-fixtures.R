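# Hand-built fixtures shared across test files. All sequences are built in
# code; nothing is read from disk except files the tests write themselves.

# Single-exon plus-strand gene: CDS covers genomic 101..700 (600 nt) of a
# 1000 bp contig; codon 133 (c.397-399, genomic 497-499) is forced to ACC
# so that c.398C>T is the canonical threonine-to-isoleucine change.
toyAssemblyPlus <- function(seed = 11) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    substr(s, 497, 499) <- "ACC"
    Biostrings::DNAStringSet(c(chr1 = s))
  })
}

toyGenePlus <- function() geneModel("g1", "chr1", "+", 101, 700, 101, 700)

# Two-exon minus-strand gene on its own contig: exons 201-500 and 801-1100,
# CDS spanning both exons (genomic 251..1050; spliced CDS length 500+... )
# laid out so the spliced CDS length is a multiple of 3.
toyAssemblyMinus <- function(seed = 12) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
               collapse = "")
    Biostrings::DNAStringSet(c(chr2 = s))
  })
}

# exon1 201-500 (300 nt), exon2 801-1100 (300 nt); CDS 251..1050:
# 250 nt in exon1 + 250 nt in exon2 = 500 -> not %3; use 252..1049:
# 249 + 249 = 498 nt = 166 codons.
toyGeneMinus <- function() {
  geneModel("g2", "chr2", "-", c(201, 801), c(500, 1100), 252, 1049)
}

# a genome observation built from a bare variant table
obs <- function(id, role, contig, pos, ref, alt, zygosity) {
  genomeObservation(id, role,
    data.frame(contig = contig, pos = as.integer(pos), ref = ref,
               alt = alt, zygosity = zygosity, stringsAsFactors = FALSE))
}

# minimal annotation rows for filter tests that do not need real sequence
fakeAnnotation <- function(vt, category, geneId = "gX") {
  data.frame(contig = vt$contig, pos = vt$pos, ref = vt$ref, alt = vt$alt,
             geneId = geneId, category = category,
             cdsPos = NA_integer_, codonIndex = NA_integer_,
             codonOffset = NA_integer_, refAA = NA_character_,
             altAA = NA_character_, hgvsC = NA_character_,
             hgvsP = NA_character_, stringsAsFactors = FALSE)
}

# small scenario used by property tests (fast to generate)
smallScenario <- function(seed, ...) {
  syntheticScenario(seed = seed, nContigs = 1L, contigLength = 20000L,
                    nGenes = 6L, nControls = 5L, meanHetCoding = 6,
                    meanHomCoding = 10, meanHomNoncoding = 6, ...)
}

# naive reimplementation of the three-criteria filter: explicit loops over
# case variants, criteria and control genomes (oracle for filterCandidates)
naiveFilter <- function(case, controls, annotations) {
  vt <- calls(case)
  annKeys <- variantKey(annotations)
  keep <- logical(nrow(vt))
  for (i in seq_len(nrow(vt))) {
    ann <- annotations[annKeys == variantKey(vt[i, ]), , drop = FALSE]
    crit1 <- ann$category %in% c("missense", "nonsense", "stop_loss",
                                 "frameshift", "inframe_indel",
                                 "splice_donor", "splice_acceptor")
    crit2 <- vt$zygosity[i] == "hom_alt"
    crit3 <- TRUE
    for (ctl in controls) {
      cc <- calls(ctl)
      for (j in seq_len(nrow(cc))) {
        if (cc$contig[j] == vt$contig[i] && cc$pos[j] == vt$pos[i] &&
            cc$ref[j] == vt$ref[i] && cc$alt[j] == vt$alt[i])
          crit3 <- FALSE
      }
    }
    keep[i] <- crit1 && crit2 && crit3
  }
  sort(variantKey(vt)[keep])
}
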