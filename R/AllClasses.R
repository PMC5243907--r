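#' @importClassesFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
NULL

setOldClass("data.frame")

#' GeneModel: a single-transcript gene model
#'
#' Represents one gene as an ordered set of exons on a contig with genomic
#' CDS bounds. One model per gene (no isoform resolution). Exons are stored
#' as an [IRanges::IRanges] (1-based, closed, the Bioconductor convention);
#' all user-facing genomic coordinates are 1-based as in VCF.
#'
#' @slot geneId single gene identifier.
#' @slot contig contig name.
#' @slot strand "+" or "-".
#' @slot exons [IRanges::IRanges] of exons, sorted, non-overlapping.
#' @slot cdsStart,cdsEnd genomic bounds (min/max, strand-independent) of the
#'   coding region; both must fall inside exons and the resulting spliced
#'   CDS length must be divisible by 3.
#' @export
setClass("GeneModel",
  representation(geneId = "character", contig = "character",
                 strand = "character", exons = "IRanges",
                 cdsStart = "integer", cdsEnd = "integer"))

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be length 1")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  ex <- object@exons
  if (length(ex) == 0L) msg <- c(msg, "at least one exon required")
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  if (is.unsorted(st, strictly = TRUE) ||
      any(st[-1] <= en[-length(en)]))
    msg <- c(msg, "exons must be sorted and non-overlapping")
  covered <- function(p) any(p >= st & p <= en)
  if (!covered(object@cdsStart) || !covered(object@cdsEnd))
    msg <- c(msg, "cds bounds must fall within exons")
  if (object@cdsStart > object@cdsEnd)
    msg <- c(msg, "cdsStart must be <= cdsEnd")
  if (length(msg) == 0L) {
    cdsLen <- sum(pmax(0L, pmin(en, object@cdsEnd) -
                         pmax(st, object@cdsStart) + 1L))
    if (cdsLen %% 3L != 0L)
      msg <- c(msg, sprintf("CDS length %d not divisible by 3", cdsLen))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param contig contig name.
#' @param strand "+" or "-".
#' @param exonStarts,exonEnds 1-based inclusive exon coordinates.
#' @param cdsStart,cdsEnd genomic CDS bounds (1-based inclusive).
#' @return a [GeneModel-class] object.
#' @examples
#' geneModel("g1", "chr1", "+", 101, 700, 101, 700)
#' @export
geneModel <- function(geneId, contig, strand, exonStarts, exonEnds,
                      cdsStart, cdsEnd) {
  new("GeneModel", geneId = as.character(geneId),
      contig = as.character(contig), strand = strand,
      exons = IRanges::IRanges(as.integer(exonStarts), as.integer(exonEnds)),
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd))
}

#' @describeIn GeneModel-class gene identifier accessor
#' @param object,x a GeneModel.
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s%s) %d exon(s), CDS %d-%d (%d nt)\n",
              object@geneId, object@contig, object@strand,
              length(object@exons), object@cdsStart, object@cdsEnd,
              cdsLength(object)))
})

#' Spliced CDS length of a gene model
#' @param model a [GeneModel-class].
#' @return integer number of coding bases.
#' @export
cdsLength <- function(model) {
  st <- IRanges::start(model@exons); en <- IRanges::end(model@exons)
  sum(pmax(0L, pmin(en, model@cdsEnd) - pmax(st, model@cdsStart) + 1L))
}

#' GenomeObservation: variant calls from one whole-genome sequence
#'
#' One record per genome: a role (case or control) and the genome's
#' non-reference calls as a variant table with a zygosity column
#' (`het` or `hom_alt`). Hom-ref sites are absent by construction.
#'
#' @slot genomeId unique genome identifier.
#' @slot role "case" or "control".
#' @slot calls data.frame with columns contig, pos, ref, alt, zygosity.
#' @export
setClass("GenomeObservation",
  representation(genomeId = "character", role = "character",
                 calls = "data.frame"))

setValidity("GenomeObservation", function(object) {
  msg <- character(0)
  if (!object@role %in% c("case", "control"))
    msg <- c(msg, "role must be 'case' or 'control'")
  need <- c("contig", "pos", "ref", "alt", "zygosity")
  if (!all(need %in% names(object@calls)))
    msg <- c(msg, paste("calls must have columns",
                        paste(need, collapse = ", ")))
  else {
    if (!all(object@calls$zygosity %in% c("het", "hom_alt")))
      msg <- c(msg, "zygosity must be het or hom_alt")
    if (anyDuplicated(variantKey(object@calls)))
      msg <- c(msg, "duplicate variant keys in calls")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeObservation
#' @param genomeId genome identifier.
#' @param role "case" or "control".
#' @param calls data.frame with contig, pos, ref, alt, zygosity columns.
#' @return a [GenomeObservation-class].
#' @export
genomeObservation <- function(genomeId, role, calls) {
  rownames(calls) <- NULL
  new("GenomeObservation", genomeId = as.character(genomeId),
      role = role, calls = calls)
}

#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @describeIn GenomeObservation-class genome identifier accessor
#' @param x a GenomeObservation.
#' @export
setMethod("genomeId", "GenomeObservation", function(x) x@genomeId)

#' @export
setGeneric("calls", function(x) standardGeneric("calls"))
#' @describeIn GenomeObservation-class calls accessor
#' @export
setMethod("calls", "GenomeObservation", function(x) x@calls)

setMethod("show", "GenomeObservation", function(object) {
  zy <- table(object@calls$zygosity)
  cat(sprintf("GenomeObservation %s [%s]: %d call(s) (%s)\n",
              object@genomeId, object@role, nrow(object@calls),
              paste(names(zy), as.integer(zy), sep = "=", collapse = ", ")))
})

#' ControlVariantStore: multi-genome variant observation index
#'
#' An embedded store of variant observations from control genomes,
#' supporting the "absent from controls" query of the three-criteria
#' filter: any observation, het or hom, disqualifies a case variant.
#'
#' @slot genomeIds ids of the genomes indexed so far.
#' @slot index named list mapping [variantKey()] to the character vector of
#'   genome ids observing that variant at any zygosity.
#' @export
setClass("ControlVariantStore",
  representation(genomeIds = "character", index = "list"))

#' Create an empty or pre-populated control variant store
#' @param observations optional list of [GenomeObservation-class] with role
#'   "control" to index immediately.
#' @return a [ControlVariantStore-class].
#' @export
controlVariantStore <- function(observations = list()) {
  store <- new("ControlVariantStore", genomeIds = character(0),
               index = list())
  for (obs in observations) store <- addGenome(store, obs)
  store
}

#' @export
setGeneric("addGenome", function(store, obs) standardGeneric("addGenome"))

#' Index one control genome into the store
#'
#' Idempotent: re-adding a genome id already present is a no-op. Adding a
#' genome never removes index entries.
#'
#' @param store a [ControlVariantStore-class].
#' @param obs a [GenomeObservation-class] with role "control".
#' @return the updated store.
#' @export
setMethod("addGenome", c("ControlVariantStore", "GenomeObservation"),
  function(store, obs) {
    if (obs@role != "control")
      stop("only control genomes can be added to the store")
    if (obs@genomeId %in% store@genomeIds) return(store)
    keys <- variantKey(obs@calls)
    idx <- store@index
    for (k in keys) idx[[k]] <- c(idx[[k]], obs@genomeId)
    store@index <- idx
    store@genomeIds <- c(store@genomeIds, obs@genomeId)
    store
  })

#' Which store genomes observe each variant?
#' @param store a [ControlVariantStore-class].
#' @param keys character vector of variant keys (see [variantKey()]).
#' @return integer vector: number of control genomes observing each key.
#' @export
countObservations <- function(store, keys) {
  vapply(keys, function(k) length(store@index[[k]]), integer(1),
         USE.NAMES = FALSE)
}

#' @export
setGeneric("nGenomes", function(x) standardGeneric("nGenomes"))
#' @describeIn ControlVariantStore-class number of indexed genomes
#' @param x a ControlVariantStore.
#' @export
setMethod("nGenomes", "ControlVariantStore", function(x) length(x@genomeIds))

setMethod("show", "ControlVariantStore", function(object) {
  cat(sprintf("ControlVariantStore: %d genome(s), %d distinct variant(s)\n",
              length(object@genomeIds), length(object@index)))
})

#' CandidateSet: variants surviving the three-criteria filter
#'
#' Holds, for one case genome (or an intersection of cases), the variants
#' that are amino-acid-altering, homozygous-alternate in the case, and
#' absent from all indexed control genomes, together with their
#' consequence annotation.
#'
#' @slot caseId case genome id (or joined ids for intersections).
#' @slot variants data.frame of variants with annotation columns
#'   (category, geneId, hgvsC, hgvsP, ...).
#' @slot nControlsUsed number of control genomes the filter was run against.
#' @export
setClass("CandidateSet",
  representation(caseId = "character", variants = "data.frame",
                 nControlsUsed = "integer"))

#' @export
setGeneric("candidateVariants", function(x) standardGeneric("candidateVariants"))
#' @describeIn CandidateSet-class candidate variant table accessor
#' @param x a CandidateSet.
#' @export
setMethod("candidateVariants", "CandidateSet", function(x) x@variants)

#' @export
setGeneric("candidateGenes", function(x) standardGeneric("candidateGenes"))
#' @describeIn CandidateSet-class distinct gene ids harbouring candidates
#' @export
setMethod("candidateGenes", "CandidateSet", function(x) {
  g <- unique(x@variants$geneId)
  sort(g[!is.na(g) & g != ""])
})

setMethod("show", "CandidateSet", function(object) {
  s <- summarizeCandidates(object)
  cat(sprintf(
    "CandidateSet [%s]: %d variant(s) in %d gene(s), %d control genome(s) used\n",
    object@caseId, s[["nVariants"]], s[["nGenes"]], object@nControlsUsed))
})

#' SegregationReport: genotype-phenotype tabulation for a cohort
#'
#' Per-breed genotype-by-phenotype counts with an overall recessive
#' consistency flag, a Fisher exact association p-value (homozygous-alt vs
#' rest, affected vs unaffected) and control allele frequencies.
#'
#' @slot perBreed data.frame, one row per breed stratum.
#' @slot consistentRecessive TRUE iff no affected dog carries a non-hom-alt
#'   genotype and no unaffected dog is hom-alt.
#' @slot fisherP two-sided Fisher exact p for the recessive 2x2 table.
#' @slot alleleFreqControls overall alt-allele frequency in unaffected dogs
#'   with called genotypes.
#' @export
setClass("SegregationReport",
  representation(perBreed = "data.frame", consistentRecessive = "logical",
                 fisherP = "numeric", alleleFreqControls = "numeric"))

#' @export
setGeneric("consistentRecessive",
           function(x) standardGeneric("consistentRecessive"))
#' @describeIn SegregationReport-class recessive-consistency flag
#' @param x a SegregationReport.
#' @export
setMethod("consistentRecessive", "SegregationReport",
          function(x) x@consistentRecessive)

#' @export
setGeneric("perBreed", function(x) standardGeneric("perBreed"))
#' @describeIn SegregationReport-class per-breed count table
#' @export
setMethod("perBreed", "SegregationReport", function(x) x@perBreed)

#' @export
setGeneric("fisherP", function(x) standardGeneric("fisherP"))
#' @describeIn SegregationReport-class Fisher exact p-value
#' @export
setMethod("fisherP", "SegregationReport", function(x) x@fisherP)

#' @export
setGeneric("alleleFreqControls",
           function(x) standardGeneric("alleleFreqControls"))
#' @describeIn SegregationReport-class overall control alt-allele frequency
#' @export
setMethod("alleleFreqControls", "SegregationReport",
          function(x) x@alleleFreqControls)

setMethod("show", "SegregationReport", function(object) {
  cat("SegregationReport\n")
  cat(sprintf("  consistent with recessive inheritance: %s\n",
              object@consistentRecessive))
  cat(sprintf("  Fisher exact p (hom-alt vs rest): %s\n",
              fmtNum(object@fisherP)))
  cat(sprintf("  control alt-allele frequency: %s\n",
              fmtNum(object@alleleFreqControls)))
  print(object@perBreed, row.names = FALSE)
})

#' OrthologAlignment: residue alignment with a focal column
#'
#' A protein multiple alignment of ortholog sequences together with the
#' 1-based alignment column mapped to the focal codon of interest.
#'
#' @slot aln an [Biostrings::AAStringSet]; all rows equal width.
#' @slot focalColumn 1-based column index within the alignment.
#' @export
setClass("OrthologAlignment",
  representation(aln = "AAStringSet", focalColumn = "integer"))

setValidity("OrthologAlignment", function(object) {
  msg <- character(0)
  w <- Biostrings::width(object@aln)
  if (length(w) > 0 && length(unique(w)) != 1L)
    msg <- c(msg, "ragged alignment: rows differ in length")
  if (length(w) > 0 &&
      (object@focalColumn < 1L || object@focalColumn > w[1]))
    msg <- c(msg, "focalColumn out of alignment bounds")
  if (length(msg)) msg else TRUE
})

#' Construct an OrthologAlignment
#' @param aln [Biostrings::AAStringSet] (or named character vector) of
#'   aligned residues, one row per species.
#' @param focalColumn 1-based alignment column of the focal codon.
#' @return an [OrthologAlignment-class].
#' @export
orthologAlignment <- function(aln, focalColumn) {
  if (is.character(aln)) aln <- Biostrings::AAStringSet(aln)
  new("OrthologAlignment", aln = aln, focalColumn = as.integer(focalColumn))
}

setMethod("show", "OrthologAlignment", function(object) {
  cat(sprintf("OrthologAlignment: %d species, width %d, focal column %d\n",
              length(object@aln),
              if (length(object@aln)) Biostrings::width(object@aln)[1] else 0L,
              object@focalColumn))
})
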