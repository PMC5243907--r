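#' Read a reference assembly from FASTA
#'
#' Sequence names are truncated at the first whitespace; sequences are
#' upper-cased and checked against the A/C/G/T/N alphabet.
#'
#' @param path FASTA path.
#' @return named [Biostrings::DNAStringSet].
#' @export
readReference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate contig names in ", path)
  if (any(Biostrings::width(x) == 0)) stop("empty contig in ", path)
  x <- Biostrings::DNAStringSet(toupper(x))
  freq <- Biostrings::alphabetFrequency(x, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  used <- colnames(freq)[colSums(freq) > 0]
  if (length(setdiff(used, allowed)))
    stop("assembly alphabet outside A,C,G,T,N: ",
         paste(setdiff(used, allowed), collapse = ","))
  x
}

#' Write a reference assembly to FASTA
#' @param assembly named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return invisibly `path`.
#' @export
writeReference <- function(assembly, path) {
  Biostrings::writeXStringSet(assembly, path)
  invisible(path)
}

.modelFromBedRow <- function(gr, blocks) {
  geneModel(gr$name, as.character(GenomicRanges::seqnames(gr)),
            as.character(GenomicRanges::strand(gr)),
            IRanges::start(blocks), IRanges::end(blocks),
            IRanges::start(gr$thick)[1], IRanges::end(gr$thick)[1])
}

#' Read gene models from BED12 or GFF3
#'
#' BED12: one transcript per line; blocks become exons, the thick range
#' becomes the CDS. GFF3: minimal gene/exon/CDS feature model, exons and
#' CDS grouped under their gene by Parent (or ID). One model per gene.
#'
#' @param path file path; format inferred from the extension (.bed vs
#'   .gff/.gff3) unless given.
#' @param format "bed" or "gff3" (optional).
#' @return named list of [GeneModel-class] objects.
#' @export
readGeneModels <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "gff3"
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    bl <- rtracklayer::blocks(gr)
    models <- lapply(seq_along(gr), function(i)
      .modelFromBedRow(gr[i], bl[[i]]))
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[gr$type == "gene"]
    models <- lapply(seq_along(genes), function(i) {
      gid <- genes$ID[i]
      isChild <- vapply(gr$Parent, function(p)
        length(p) > 0 && p[1] == gid, logical(1))
      kids <- gr[isChild]
      ex <- kids[kids$type == "exon"]
      cds <- kids[kids$type == "CDS"]
      if (length(ex) == 0L || length(cds) == 0L)
        stop("gene ", gid, " lacks exon or CDS features")
      o <- order(GenomicRanges::start(ex))
      geneModel(gid, as.character(GenomicRanges::seqnames(genes[i])),
                as.character(GenomicRanges::strand(genes[i])),
                GenomicRanges::start(ex)[o], GenomicRanges::end(ex)[o],
                min(GenomicRanges::start(cds)),
                max(GenomicRanges::end(cds)))
    })
  }
  names(models) <- vapply(models, geneId, character(1))
  models
}

#' Write gene models as GFF3 (gene/exon/CDS features)
#' @param models list of [GeneModel-class].
#' @param path output .gff3 path.
#' @return invisibly `path`.
#' @export
writeGeneModels <- function(models, path) {
  allContigs <- unique(vapply(models, function(m) m@contig, character(1)))
  grs <- lapply(models, function(m) {
    contigF <- factor(m@contig, levels = allContigs)
    st <- IRanges::start(m@exons); en <- IRanges::end(m@exons)
    cSt <- pmax(st, m@cdsStart); cEn <- pmin(en, m@cdsEnd)
    hasCds <- cSt <= cEn
    gene <- GenomicRanges::GRanges(contigF,
      IRanges::IRanges(min(st), max(en)), strand = m@strand,
      type = "gene", ID = m@geneId, Parent = IRanges::CharacterList(list(character(0))))
    ex <- GenomicRanges::GRanges(contigF, IRanges::IRanges(st, en),
      strand = m@strand, type = "exon",
      ID = paste0(m@geneId, ".exon", seq_along(st)),
      Parent = IRanges::CharacterList(as.list(rep(m@geneId, length(st)))))
    # phase: coding bases preceding each CDS piece, in transcription order
    lens <- (cEn - cSt + 1L)[hasCds]
    if (m@strand == "-") lens <- rev(lens)
    phase <- (3L - cumsum(c(0L, lens[-length(lens)])) %% 3L) %% 3L
    if (m@strand == "-") phase <- rev(phase)
    cds <- GenomicRanges::GRanges(contigF,
      IRanges::IRanges(cSt[hasCds], cEn[hasCds]), strand = m@strand,
      type = "CDS", ID = paste0(m@geneId, ".cds", seq_len(sum(hasCds))),
      phase = phase,
      Parent = IRanges::CharacterList(as.list(rep(m@geneId, sum(hasCds)))))
    c(gene, ex, cds)
  })
  gr <- do.call(c, unname(grs))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

.decomposeGenotypes <- function(fix, gtvec, source) {
  out <- list()
  nMissing <- 0L
  for (i in seq_along(gtvec)) {
    gtRaw <- gtvec[i]
    gtField <- if (is.na(gtRaw)) "." else strsplit(gtRaw, ":", fixed = TRUE)[[1]][1]
    alleles <- strsplit(gtField, "[/|]")[[1]]
    if (any(alleles == ".") || gtField == ".") {
      nMissing <- nMissing + 1L
      next
    }
    alleles <- as.integer(alleles)
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      cnt <- sum(alleles == k)
      if (cnt == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        contig = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = toupper(fix[i, "REF"]), alt = toupper(alts[k]),
        zygosity = if (cnt >= 2L) "hom_alt" else "het",
        stringsAsFactors = FALSE)
    }
  }
  if (nMissing > 0L)
    message(source, ": ", nMissing,
            " record(s) with missing genotype excluded")
  if (length(out) == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      zygosity = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read one genome's variant calls from a VCF
#'
#' Reads a single-sample VCF (v4.2; plain or gzipped), decomposes
#' multi-allelic records into biallelic variants, left-normalises alleles
#' and derives zygosity from the GT field (0/1 -> het, 1/1 -> hom_alt).
#' Records with missing genotypes are excluded (treated as not
#' homozygous) and counted in a message.
#'
#' @param path VCF path.
#' @param genomeId identifier for the genome (defaults to the VCF sample
#'   name).
#' @param role "case" or "control".
#' @return a [GenomeObservation-class].
#' @export
readGenomeVcf <- function(path, genomeId = NULL, role = "control") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (length(samples) != 1L)
    stop(path, " must contain exactly one sample, found ", length(samples))
  if (is.null(genomeId)) genomeId <- samples[1]
  gtvec <- as.vector(vcfR::extract.gt(v, element = "GT"))
  callsDf <- .decomposeGenotypes(v@fix, gtvec, path)
  callsDf <- normalizeVariants(callsDf)
  callsDf <- callsDf[!duplicated(variantKey(callsDf)), , drop = FALSE]
  genomeObservation(genomeId, role, callsDf)
}

.vcfMeta <- function(assembly = NULL, info = FALSE) {
  meta <- c("##fileformat=VCFv4.2",
            "##source=pxdscout",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (info)
    meta <- c(meta,
      '##INFO=<ID=CSQCAT,Number=1,Type=String,Description="Consequence category">',
      '##INFO=<ID=HGVSC,Number=1,Type=String,Description="HGVS coding-DNA notation">',
      '##INFO=<ID=HGVSP,Number=1,Type=String,Description="HGVS protein notation">')
  if (!is.null(assembly))
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>", names(assembly),
                            Biostrings::width(assembly)))
  meta
}

#' Write one genome's calls as a single-sample VCF
#'
#' Output is gzip-compressed (use a `.vcf.gz` path); readable back with
#' [readGenomeVcf()].
#'
#' @param obs a [GenomeObservation-class].
#' @param path output `.vcf.gz` path.
#' @param assembly optional assembly for contig header lines.
#' @param annotations optional annotation data.frame (from
#'   [annotateVariants()]); when given, consequence category and HGVS
#'   strings are written to the INFO keys CSQCAT, HGVSC and HGVSP.
#' @return invisibly `path`.
#' @export
writeGenomeVcf <- function(obs, path, assembly = NULL, annotations = NULL) {
  vt <- obs@calls
  o <- order(vt$contig, vt$pos, vt$ref, vt$alt)
  vt <- vt[o, , drop = FALSE]
  info <- rep(".", nrow(vt))
  if (!is.null(annotations)) {
    ann <- annotations[match(variantKey(vt), variantKey(annotations)), ,
                       drop = FALSE]
    info <- sprintf("CSQCAT=%s;HGVSC=%s;HGVSP=%s", ann$category,
                    ifelse(is.na(ann$hgvsC), ".", ann$hgvsC),
                    ifelse(is.na(ann$hgvsP), ".", ann$hgvsP))
    info[is.na(ann$category)] <- "."
  }
  fix <- cbind(CHROM = vt$contig, POS = as.character(vt$pos), ID = ".",
               REF = vt$ref, ALT = vt$alt, QUAL = ".", FILTER = "PASS",
               INFO = info)
  gtcol <- ifelse(vt$zygosity == "hom_alt", "1/1", "0/1")
  gt <- cbind(FORMAT = "GT", gtcol)
  colnames(gt) <- c("FORMAT", obs@genomeId)
  v <- new("vcfR", meta = .vcfMeta(assembly, info = !is.null(annotations)),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}

#' Write a cohort or fluorescence table to TSV
#' @param df data.frame.
#' @param path output TSV path.
#' @return invisibly `path`.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
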