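#' Apply the three-criteria candidate filter to one case genome
#'
#' Retains a case variant if and only if it (1) is predicted to alter the
#' amino-acid sequence of the gene product, including splice-signal
#' disruption ([isAminoAcidAltering()]); (2) is homozygous for the
#' alternate allele in the case genome; and (3) has never been observed,
#' at any zygosity, in any control genome indexed in the store. Any
#' control observation disqualifies, het or hom: under a recessive model
#' unaffected carriers are expected, but the causal variant must be
#' homozygous in cases and was absent from all control genomes.
#'
#' @param case a [GenomeObservation-class] with role "case".
#' @param store a [ControlVariantStore-class].
#' @param annotations annotation data.frame covering every case variant
#'   (see [annotateVariants()]); an unannotated case variant is an error.
#' @return a [CandidateSet-class].
#' @export
filterCandidates <- function(case, store, annotations) {
  if (case@role != "case") stop("filterCandidates requires a case genome")
  vt <- case@calls
  keys <- variantKey(vt)
  annKeys <- variantKey(annotations)
  missing <- setdiff(keys, annKeys)
  if (length(missing))
    stop("unannotated case variant(s): ", paste(missing, collapse = ", "))
  ann <- annotations[match(keys, annKeys), , drop = FALSE]
  keep <- isAminoAcidAltering(ann) &
          vt$zygosity == "hom_alt" &
          countObservations(store, keys) == 0L
  variants <- cbind(ann[keep, , drop = FALSE],
                    zygosity = vt$zygosity[keep])
  rownames(variants) <- NULL
  new("CandidateSet", caseId = case@genomeId, variants = variants,
      nControlsUsed = nGenomes(store))
}

#' Candidate counts as control genomes accumulate
#'
#' Re-runs the three-criteria filter after indexing each control genome in
#' turn, reproducing the study's observation that the number of candidate
#' variants unique to the affected genome decreases as control genomes are
#' added. The sequence is non-increasing because indexing a genome never
#' removes store entries.
#'
#' @param case a [GenomeObservation-class] with role "case".
#' @param controls ordered list of [GenomeObservation-class] (role control).
#' @param annotations annotation data.frame covering every case variant.
#' @return integer vector: candidate count after each control is added
#'   (empty for zero controls).
#' @export
candidateTrajectory <- function(case, controls, annotations) {
  store <- controlVariantStore()
  out <- integer(0)
  for (obs in controls) {
    store <- addGenome(store, obs)
    cs <- filterCandidates(case, store, annotations)
    out <- c(out, nrow(cs@variants))
  }
  out
}

#' Intersect candidate sets across cases
#'
#' The causal variant of a recessive disease shared by the cases must
#' survive the filter in every case; variants are matched by their
#' (contig, pos, ref, alt) identity key. An empty intersection yields a
#' warning (no shared candidate under the model's assumptions).
#'
#' @param sets list of at least two [CandidateSet-class] objects.
#' @return a [CandidateSet-class] with the shared variants (annotation
#'   columns taken from the first set).
#' @export
intersectCases <- function(sets) {
  if (length(sets) < 2L)
    stop("intersectCases requires at least two candidate sets")
  keyList <- lapply(sets, function(s) variantKey(s@variants))
  shared <- Reduce(intersect, keyList)
  first <- sets[[1L]]@variants
  variants <- first[variantKey(first) %in% shared, , drop = FALSE]
  rownames(variants) <- NULL
  if (nrow(variants) == 0L)
    warning("candidate intersection is empty: no variant shared by all cases")
  new("CandidateSet",
      caseId = paste(vapply(sets, function(s) s@caseId, character(1)),
                     collapse = "&"),
      variants = variants,
      nControlsUsed = max(vapply(sets, function(s) s@nControlsUsed,
                                 integer(1))))
}

#' Count distinct candidate variants and genes
#'
#' @param x a [CandidateSet-class] or a candidate table (data.frame with a
#'   `geneId` column and variant identity columns).
#' @return named integer vector `c(nVariants = ..., nGenes = ...)`.
#' @export
summarizeCandidates <- function(x) {
  vt <- if (is(x, "CandidateSet")) x@variants else x
  g <- unique(vt$geneId)
  g <- g[!is.na(g) & g != ""]
  c(nVariants = length(unique(variantKey(vt))), nGenes = length(g))
}

#' Read a candidate-variant table from TSV
#'
#' Parses a tab-separated candidate list (one variant per row) with at
#' least contig/pos/ref/alt and a gene column, for parse-and-count checks
#' against published candidate lists. Column names are matched
#' case-insensitively against common synonyms (chrom/chr/contig,
#' pos/position, gene/geneId/gene_id).
#'
#' @param path TSV file path.
#' @return data.frame with columns contig, pos, ref, alt, geneId (plus any
#'   extra columns preserved).
#' @export
readCandidateTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lut <- c(chrom = "contig", chr = "contig", contig = "contig",
           pos = "pos", position = "pos", ref = "ref", alt = "alt",
           gene = "geneId", geneid = "geneId", gene_id = "geneId")
  nm <- tolower(names(df))
  hit <- nm %in% names(lut)
  names(df)[hit] <- lut[nm[hit]]
  need <- c("contig", "pos", "ref", "alt", "geneId")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("candidate table lacks column(s): ", paste(missing, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df
}

#' Write a candidate set to TSV
#' @param x a [CandidateSet-class].
#' @param path output TSV path.
#' @return invisibly `path`.
#' @export
writeCandidateTable <- function(x, path) {
  write.table(x@variants, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
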