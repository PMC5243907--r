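#' Consequence categories considered amino-acid-altering
#'
#' The candidate filter's first criterion retains variants predicted to
#' alter the amino-acid sequence of the gene product, including those that
#' disrupt exon-splicing signals.
#' @export
ALTERING_CATEGORIES <- c("missense", "nonsense", "stop_loss", "frameshift",
                         "inframe_indel", "splice_donor", "splice_acceptor")

#' All consequence categories emitted by the annotator
#' @export
CONSEQUENCE_CATEGORIES <- c(ALTERING_CATEGORIES,
                            "synonymous", "intronic", "utr", "intergenic")

.aa1to3 <- function(aa) {
  out <- ifelse(aa == "*", "Ter",
                unname(Biostrings::AMINO_ACID_CODE[aa]))
  ifelse(is.na(out), aa, out)
}

.renderAA <- function(aa, threeLetter) {
  if (threeLetter) .aa1to3(aa) else aa
}

.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# Precomputed per-model context so batch annotation does not re-splice the
# CDS for every variant.
.modelContext <- function(assembly, model) {
  cp <- cdsPositions(model)
  list(model = model,
       cp = cp,
       cdsStr = as.character(cdsSequence(assembly, model)),
       exSt = IRanges::start(model@exons),
       exEn = IRanges::end(model@exons),
       spanSt = min(IRanges::start(model@exons)),
       spanEn = max(IRanges::end(model@exons)))
}

.emptyCall <- function(v, category, geneId = NA_character_) {
  data.frame(contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
             geneId = geneId, category = category,
             cdsPos = NA_integer_, codonIndex = NA_integer_,
             codonOffset = NA_integer_,
             refAA = NA_character_, altAA = NA_character_,
             hgvsC = NA_character_, hgvsP = NA_character_,
             stringsAsFactors = FALSE)
}

# HGVS c. string for an intronic position relative to its nearest exonic
# coding base, e.g. c.397+1G>A. Falls back to NA when the flanking exonic
# base is untranslated.
.intronicHgvs <- function(ctx, pos, refC, altC) {
  m <- ctx$model
  i <- which(ctx$exEn < pos)
  i <- if (length(i)) max(i) else return(NA_character_)
  if (i >= length(ctx$exSt)) return(NA_character_)
  upEnd <- ctx$exEn[i]; downSt <- ctx$exSt[i + 1L]
  if (m@strand == "+") {
    dPlus <- pos - upEnd          # distance past donor-side exon base
    dMinus <- downSt - pos        # distance before acceptor-side exon base
    if (dPlus <= dMinus) {
      c0 <- genomicToCds(m, upEnd)
      if (is.na(c0)) return(NA_character_)
      sprintf("c.%d+%d%s>%s", c0, dPlus, refC, altC)
    } else {
      c0 <- genomicToCds(m, downSt)
      if (is.na(c0)) return(NA_character_)
      sprintf("c.%d-%d%s>%s", c0, dMinus, refC, altC)
    }
  } else {
    dPlus <- downSt - pos         # transcription runs right to left
    dMinus <- pos - upEnd
    if (dPlus <= dMinus) {
      c0 <- genomicToCds(m, downSt)
      if (is.na(c0)) return(NA_character_)
      sprintf("c.%d+%d%s>%s", c0, dPlus, refC, altC)
    } else {
      c0 <- genomicToCds(m, upEnd)
      if (is.na(c0)) return(NA_character_)
      sprintf("c.%d-%d%s>%s", c0, dMinus, refC, altC)
    }
  }
}

.classifySubstitution <- function(ctx, v, spliceWindow, threeLetterAA) {
  m <- ctx$model
  minus <- m@strand == "-"
  refC <- if (minus) revComp(v$ref) else v$ref
  altC <- if (minus) revComp(v$alt) else v$alt
  cdsPos <- match(v$pos, ctx$cp)
  if (!is.na(cdsPos)) {
    cc <- codonCoordinates(cdsPos)
    ci <- cc$codonIndex; off <- cc$codonOffset
    codon <- substr(ctx$cdsStr, 3L * (ci - 1L) + 1L, 3L * ci)
    stopifnot(substr(codon, off, off) == refC)
    altCodon <- codon
    substr(altCodon, off, off) <- altC
    refAA <- .translateCodon(codon)
    altAA <- .translateCodon(altCodon)
    category <- if (refAA == altAA) "synonymous"
      else if (altAA == "*") "nonsense"
      else if (refAA == "*") "stop_loss"
      else "missense"
    out <- .emptyCall(v, category, m@geneId)
    out$cdsPos <- cdsPos; out$codonIndex <- ci; out$codonOffset <- off
    out$refAA <- refAA; out$altAA <- altAA
    out$hgvsC <- sprintf("c.%d%s>%s", cdsPos, refC, altC)
    out$hgvsP <- sprintf("p.%s%d%s", .renderAA(refAA, threeLetterAA), ci,
                         .renderAA(altAA, threeLetterAA))
    return(out)
  }
  inExon <- any(v$pos >= ctx$exSt & v$pos <= ctx$exEn)
  if (inExon) return(.emptyCall(v, "utr", m@geneId))
  # intronic: splice signal if within spliceWindow of an exon boundary
  i <- max(which(ctx$exEn < v$pos))
  upEnd <- ctx$exEn[i]; downSt <- ctx$exSt[i + 1L]
  dLeft <- v$pos - upEnd; dRight <- downSt - v$pos
  category <- "intronic"
  if (min(dLeft, dRight) <= spliceWindow) {
    donorSide <- if (dLeft <= dRight) !minus else minus
    category <- if (donorSide) "splice_donor" else "splice_acceptor"
  }
  out <- .emptyCall(v, category, m@geneId)
  out$hgvsC <- .intronicHgvs(ctx, v$pos, refC, altC)
  out
}

.classifyIndel <- function(ctx, v, spliceWindow, threeLetterAA) {
  m <- ctx$model
  lenDiff <- nchar(v$alt) - nchar(v$ref)
  # changed region past the anchor base (VCF left-anchored representation)
  regSt <- v$pos + 1L
  regEn <- max(v$pos + nchar(v$ref) - 1L, regSt)
  hit <- intersect(seq.int(regSt, regEn), ctx$cp)
  if (length(hit) == 0L && lenDiff > 0L) {
    # pure insertion between pos and pos+1: coding if both flanks coding
    if ((v$pos %in% ctx$cp) && ((v$pos + 1L) %in% ctx$cp)) hit <- v$pos
  }
  if (length(hit) > 0L) {
    category <- if (lenDiff %% 3L == 0L) "inframe_indel" else "frameshift"
    cdsHit <- sort(match(hit, ctx$cp))
    cdsPos <- cdsHit[1L]
    cc <- codonCoordinates(cdsPos)
    codon <- substr(ctx$cdsStr, 3L * (cc$codonIndex - 1L) + 1L,
                    3L * cc$codonIndex)
    refAA <- .translateCodon(codon)
    out <- .emptyCall(v, category, m@geneId)
    out$cdsPos <- cdsPos
    out$codonIndex <- cc$codonIndex; out$codonOffset <- cc$codonOffset
    out$refAA <- refAA
    out$hgvsC <- if (lenDiff < 0L) {
      sprintf("c.%d_%ddel", cdsHit[1L], cdsHit[length(cdsHit)])
    } else if (nchar(v$ref) == 1L) {
      ins <- substr(v$alt, 2L, nchar(v$alt))
      if (m@strand == "-") ins <- revComp(ins)
      sprintf("c.%d_%dins%s", cdsPos, cdsPos + 1L, ins)
    } else {
      sprintf("c.%d_%ddelins", cdsHit[1L], cdsHit[length(cdsHit)])
    }
    out$hgvsP <- if (category == "frameshift")
      sprintf("p.%s%dfs", .renderAA(refAA, threeLetterAA), cc$codonIndex)
      else "p.?"
    return(out)
  }
  inExon <- any(regSt >= ctx$exSt & regSt <= ctx$exEn) ||
            any(v$pos >= ctx$exSt & v$pos <= ctx$exEn)
  if (inExon) return(.emptyCall(v, "utr", m@geneId))
  i <- which(ctx$exEn < regSt)
  if (length(i) == 0L) return(.emptyCall(v, "utr", m@geneId))
  i <- max(i)
  if (i >= length(ctx$exSt)) return(.emptyCall(v, "intronic", m@geneId))
  dLeft <- regSt - ctx$exEn[i]; dRight <- ctx$exSt[i + 1L] - regEn
  category <- "intronic"
  if (min(dLeft, dRight) <= spliceWindow) {
    donorSide <- if (dLeft <= dRight) m@strand == "+" else m@strand == "-"
    category <- if (donorSide) "splice_donor" else "splice_acceptor"
  }
  .emptyCall(v, category, m@geneId)
}

.classifyOne <- function(ctx, v, spliceWindow, threeLetterAA) {
  if (nchar(v$ref) == 1L && nchar(v$alt) == 1L)
    .classifySubstitution(ctx, v, spliceWindow, threeLetterAA)
  else
    .classifyIndel(ctx, v, spliceWindow, threeLetterAA)
}

#' Classify one variant against one gene model
#'
#' Predicts the coding consequence of a variant: substitutions inside the
#' CDS are translated with the standard genetic code on the coding strand
#' (minus-strand genes are handled by reverse complement); intronic
#' substitutions within `spliceWindow` bases of an exon boundary are
#' classified as splice-donor or splice-acceptor by boundary side;
#' length-changing coding variants are frameshift unless the length
#' difference is a multiple of 3 (inframe indel). HGVS c. and p. strings
#' are rendered, one-letter amino-acid codes by default (p.T133I).
#'
#' @param assembly named [Biostrings::DNAStringSet] reference.
#' @param model a [GeneModel-class].
#' @param v one-row variant table (see [variantTable()]).
#' @param spliceWindow number of intronic bases at each exon boundary
#'   treated as splice signal (default 2, the canonical GT/AG dinucleotide).
#' @param threeLetterAA render protein HGVS with three-letter codes.
#' @return one-row data.frame: contig, pos, ref, alt, geneId, category,
#'   cdsPos, codonIndex, codonOffset, refAA, altAA, hgvsC, hgvsP.
#' @export
classifyVariant <- function(assembly, model, v, spliceWindow = 2L,
                            threeLetterAA = FALSE) {
  checkRefAlleles(v, assembly)
  ctx <- .modelContext(assembly, model)
  if (v$contig != model@contig || v$pos < ctx$spanSt || v$pos > ctx$spanEn)
    return(.emptyCall(v, "intergenic"))
  .classifyOne(ctx, v, spliceWindow, threeLetterAA)
}

#' Annotate a variant table against a set of gene models
#'
#' Each variant is classified against the gene model whose span contains
#' it (gene models are assumed non-overlapping, one model per gene);
#' variants outside every gene span are intergenic.
#'
#' @param assembly named [Biostrings::DNAStringSet] reference.
#' @param models list of [GeneModel-class] objects.
#' @param vt variant table.
#' @inheritParams classifyVariant
#' @return data.frame with one annotation row per variant, in input order.
#' @export
annotateVariants <- function(assembly, models, vt, spliceWindow = 2L,
                             threeLetterAA = FALSE) {
  checkRefAlleles(vt, assembly)
  ctxs <- lapply(models, .modelContext, assembly = assembly)
  rows <- lapply(seq_len(nrow(vt)), function(i) {
    v <- vt[i, , drop = FALSE]
    for (ctx in ctxs) {
      if (v$contig == ctx$model@contig &&
          v$pos >= ctx$spanSt && v$pos <= ctx$spanEn)
        return(.classifyOne(ctx, v, spliceWindow, threeLetterAA))
    }
    .emptyCall(v, "intergenic")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Does a consequence alter the protein (or splicing)?
#'
#' TRUE exactly for missense, nonsense, stop-loss, frameshift, inframe
#' indel and splice-donor/acceptor calls; synonymous, intronic, UTR and
#' intergenic variants are not amino-acid-altering.
#'
#' @param x an annotation data.frame (from [annotateVariants()]) or a
#'   character vector of categories.
#' @return logical vector.
#' @export
isAminoAcidAltering <- function(x) {
  category <- if (is.data.frame(x)) x$category else x
  bad <- setdiff(unique(category), CONSEQUENCE_CATEGORIES)
  if (length(bad))
    stop("unknown consequence category: ", paste(bad, collapse = ", "))
  category %in% ALTERING_CATEGORIES
}
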