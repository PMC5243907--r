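#' Coding positions of a gene model, in transcription order
#'
#' Genomic positions of the spliced CDS, ordered along the coding strand
#' (descending genomic coordinate for minus-strand genes). Position k of
#' the returned vector is coding position k (c.k in HGVS terms).
#'
#' @param model a [GeneModel-class].
#' @return integer vector of genomic positions, length [cdsLength()].
#' @export
cdsPositions <- function(model) {
  st <- IRanges::start(model@exons); en <- IRanges::end(model@exons)
  pos <- unlist(lapply(seq_along(st), function(i) {
    a <- max(st[i], model@cdsStart); b <- min(en[i], model@cdsEnd)
    if (a > b) integer(0) else seq.int(a, b)
  }))
  if (model@strand == "-") rev(pos) else pos
}

#' Map a genomic position to a coding (c.) position
#'
#' Strand-aware: coding positions count along the coding strand from the
#' first base of the start codon. Returns `NA` for positions outside the
#' CDS (introns, UTRs, intergenic).
#'
#' @param model a [GeneModel-class].
#' @param pos 1-based genomic position(s).
#' @return integer vector of 1-based coding positions, `NA` where not coding.
#' @examples
#' gm <- geneModel("g", "chr1", "+", 101, 700, 101, 700)
#' genomicToCds(gm, 498)  # 398
#' @export
genomicToCds <- function(model, pos) {
  match(as.integer(pos), cdsPositions(model))
}

#' Map a coding (c.) position back to its genomic position
#'
#' Inverse of [genomicToCds()]; round-trips exactly for every coding base.
#'
#' @param model a [GeneModel-class].
#' @param cdsPos 1-based coding position(s).
#' @return integer genomic position(s); errors if out of CDS range.
#' @export
cdsToGenomic <- function(model, cdsPos) {
  cp <- cdsPositions(model)
  cdsPos <- as.integer(cdsPos)
  if (any(cdsPos < 1L | cdsPos > length(cp)))
    stop("cdsPos out of range 1..", length(cp))
  cp[cdsPos]
}

#' Codon index and offset of a coding position
#'
#' Coding position k falls in codon `(k - 1) %/% 3 + 1` at within-codon
#' offset `(k - 1) %% 3 + 1`; e.g. c.398 is base 2 of codon 133, the basis
#' of the p.T133I prediction for c.398C>T.
#'
#' @param cdsPos 1-based coding position(s).
#' @return data.frame with columns `codonIndex` and `codonOffset`.
#' @examples
#' codonCoordinates(398)  # codon 133, offset 2
#' @export
codonCoordinates <- function(cdsPos) {
  cdsPos <- as.integer(cdsPos)
  if (any(cdsPos < 1L)) stop("cdsPos must be >= 1")
  data.frame(codonIndex = (cdsPos - 1L) %/% 3L + 1L,
             codonOffset = (cdsPos - 1L) %% 3L + 1L)
}

#' Spliced CDS sequence of a gene model
#'
#' @param assembly named [Biostrings::DNAStringSet].
#' @param model a [GeneModel-class].
#' @return a [Biostrings::DNAString] of the coding-strand CDS.
#' @export
cdsSequence <- function(assembly, model) {
  if (!model@contig %in% names(assembly))
    stop("unknown contig: ", model@contig)
  st <- IRanges::start(model@exons); en <- IRanges::end(model@exons)
  parts <- lapply(seq_along(st), function(i) {
    a <- max(st[i], model@cdsStart); b <- min(en[i], model@cdsEnd)
    if (a > b) Biostrings::DNAString("") else
      Biostrings::subseq(assembly[[model@contig]], a, b)
  })
  s <- do.call(Biostrings::xscat, parts)
  if (model@strand == "-") Biostrings::reverseComplement(s) else s
}
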