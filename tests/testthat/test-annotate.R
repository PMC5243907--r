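test_that("the canonical missense call is rendered as p.T133I", {
  asm <- toyAssemblyPlus()
  gm <- toyGenePlus()
  v <- variantTable("chr1", 498, "C", "T", asm)
  cc <- classifyVariant(asm, gm, v)
  expect_equal(cc$category, "missense")
  expect_equal(cc$cdsPos, 398L)
  expect_equal(cc$codonIndex, 133L)
  expect_equal(cc$codonOffset, 2L)
  expect_equal(cc$refAA, "T")
  expect_equal(cc$altAA, "I")
  expect_equal(cc$hgvsC, "c.398C>T")
  expect_equal(cc$hgvsP, "p.T133I")
  cc3 <- classifyVariant(asm, gm, v, threeLetterAA = TRUE)
  expect_equal(cc3$hgvsP, "p.Thr133Ile")
})

test_that("wobble-position change in the same codon is synonymous", {
  asm <- toyAssemblyPlus()
  gm <- toyGenePlus()
  v <- variantTable("chr1", 499, "C", "T", asm)   # ACC -> ACT, both Thr
  cc <- classifyVariant(asm, gm, v)
  expect_equal(cc$category, "synonymous")
  expect_equal(cc$refAA, "T")
  expect_equal(cc$altAA, "T")
  expect_false(isAminoAcidAltering(cc))
})

test_that("ref-mismatch against the assembly is an error", {
  asm <- toyAssemblyPlus()
  gm <- toyGenePlus()
  wrongRef <- setdiff(c("A", "C", "G", "T"),
                      substr(as.character(asm[["chr1"]]), 498, 498))[1]
  expect_error(
    classifyVariant(asm, gm, variantTable("chr1", 498, wrongRef, "G")),
    "ref mismatch")
  expect_error(
    classifyVariant(asm, gm, variantTable("chrZ", 10, "A", "G")),
    "unknown contig")
})

test_that("splice-window classification respects boundary side and strand", {
  asm <- toyAssemblyMinus()
  gm <- toyGeneMinus()  # exons 201-500, 801-1100; minus strand
  classifyAt <- function(pos, window = 2L) {
    ref <- substr(as.character(asm[["chr2"]]), pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    classifyVariant(asm, gm, variantTable("chr2", pos, ref, alt), window)
  }
  # minus strand: transcription right-to-left, so the intron bases just
  # left of exon2 (genomic 799-800) are the donor side and the bases just
  # right of exon1 (genomic 501-502) are the acceptor side
  expect_equal(classifyAt(800)$category, "splice_donor")
  expect_equal(classifyAt(799)$category, "splice_donor")
  expect_equal(classifyAt(501)$category, "splice_acceptor")
  expect_equal(classifyAt(502)$category, "splice_acceptor")
  expect_equal(classifyAt(650)$category, "intronic")
  # widening the window recruits deeper intronic bases
  expect_equal(classifyAt(650, window = 200L)$category, "splice_acceptor")
  # shrinking it to zero abolishes splice calls
  expect_equal(classifyAt(800, window = 0L)$category, "intronic")
  # plus strand mirror image
  asmP <- toyAssemblyPlus()
  gmP <- geneModel("gp", "chr1", "+", c(101, 401), c(300, 700), 151, 652)
  classifyAtP <- function(pos) {
    ref <- substr(as.character(asmP[["chr1"]]), pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    classifyVariant(asmP, gmP, variantTable("chr1", pos, ref, alt))
  }
  expect_equal(classifyAtP(301)$category, "splice_donor")
  expect_equal(classifyAtP(400)$category, "splice_acceptor")
})

test_that("UTR and intergenic positions are classified and not altering", {
  asm <- toyAssemblyPlus()
  gmUtr <- geneModel("gu", "chr1", "+", 101, 700, 161, 640)
  at <- function(pos) {
    ref <- substr(as.character(asm[["chr1"]]), pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    classifyVariant(asm, gmUtr, variantTable("chr1", pos, ref, alt))
  }
  expect_equal(at(120)$category, "utr")
  expect_equal(at(680)$category, "utr")
  outside <- at(900)
  expect_equal(outside$category, "intergenic")
  expect_false(any(isAminoAcidAltering(rbind(at(120), outside))))
})

test_that("translation agrees with the Biostrings translate oracle", {
  for (fix in list(list(asm = toyAssemblyPlus(), gm = toyGenePlus()),
                   list(asm = toyAssemblyMinus(), gm = toyGeneMinus()))) {
    cds <- cdsSequence(fix$asm, fix$gm)
    oracle <- strsplit(as.character(
      Biostrings::translate(cds, if.fuzzy.codon = "X")), "")[[1]]
    # classify a substitution at offset 1 of every 10th codon and compare
    # the annotator's refAA with the whole-CDS translation
    for (ci in seq(1, cdsLength(fix$gm) %/% 3L, by = 10)) {
      gpos <- cdsToGenomic(fix$gm, 3L * (ci - 1L) + 1L)
      ctg <- fix$gm@contig
      ref <- substr(as.character(fix$asm[[ctg]]), gpos, gpos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      cc <- classifyVariant(fix$asm, fix$gm,
                            variantTable(ctg, gpos, ref, alt))
      expect_equal(cc$refAA, oracle[ci])
    }
  }
})

test_that("strand symmetry: mirrored construction classifies identically", {
  # classify variants against the minus-strand gene, then rebuild the
  # same gene as a plus-strand construction on the reverse-complemented
  # contig with mirrored coordinates; categories and amino acids match
  asm <- toyAssemblyMinus()
  gm <- toyGeneMinus()
  L <- Biostrings::width(asm)[1]
  rcAsm <- Biostrings::DNAStringSet(
    setNames(list(Biostrings::reverseComplement(asm[["chr2"]])), "chr2"))
  mirror <- function(x) L - x + 1L
  gmMirror <- geneModel("g2", "chr2", "+",
                        rev(mirror(IRanges::end(gm@exons))),
                        rev(mirror(IRanges::start(gm@exons))),
                        mirror(gm@cdsEnd), mirror(gm@cdsStart))
  set.seed(99)
  testPos <- sample(cdsToGenomic(gm, seq_len(cdsLength(gm))), 40)
  for (pos in testPos) {
    ref <- substr(as.character(asm[["chr2"]]), pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    a <- classifyVariant(asm, gm, variantTable("chr2", pos, ref, alt))
    b <- classifyVariant(rcAsm, gmMirror,
                         variantTable("chr2", mirror(pos),
                                      chartr("ACGT", "TGCA", ref),
                                      chartr("ACGT", "TGCA", alt)))
    expect_equal(a$category, b$category)
    expect_equal(a$cdsPos, b$cdsPos)
    expect_equal(a$refAA, b$refAA)
    expect_equal(a$altAA, b$altAA)
    expect_equal(a$hgvsC, b$hgvsC)
  }
})

test_that("length-changing coding variants split into frameshift/in-frame", {
  asm <- toyAssemblyPlus()
  gm <- toyGenePlus()
  s <- as.character(asm[["chr1"]])
  # 1 bp deletion inside the CDS: frameshift
  del1 <- variantTable("chr1", 300, substr(s, 300, 301),
                       substr(s, 300, 300), asm)
  ccDel <- classifyVariant(asm, gm, del1)
  expect_equal(ccDel$category, "frameshift")
  expect_match(ccDel$hgvsP, "fs$")
  # 3 bp deletion: in-frame
  del3 <- variantTable("chr1", 300, substr(s, 300, 303),
                       substr(s, 300, 300), asm)
  expect_equal(classifyVariant(asm, gm, del3)$category, "inframe_indel")
  # 2 bp insertion: frameshift
  ins2 <- variantTable("chr1", 300, substr(s, 300, 300),
                       paste0(substr(s, 300, 300), "AT"), asm)
  expect_equal(classifyVariant(asm, gm, ins2)$category, "frameshift")
  expect_true(all(isAminoAcidAltering(
    rbind(ccDel, classifyVariant(asm, gm, del3)))))
})

test_that("altering flag is a deterministic function of the category", {
  altering <- c("missense", "nonsense", "stop_loss", "frameshift",
                "inframe_indel", "splice_donor", "splice_acceptor")
  silent <- c("synonymous", "intronic", "utr", "intergenic")
  expect_true(all(isAminoAcidAltering(altering)))
  expect_false(any(isAminoAcidAltering(silent)))
  expect_error(isAminoAcidAltering("exotic"), "unknown consequence")
})

test_that("nonsense and stop-loss substitutions are recognised", {
  # build a tiny dedicated assembly where codon 2 is TAC (Tyr) and the
  # final codon is TAA (stop)
  cdsStr <- paste0("ATG", "TAC", "GGG", "TAA")
  s <- paste0(strrep("A", 100), cdsStr, strrep("G", 100))
  asm <- Biostrings::DNAStringSet(c(c1 = s))
  gm <- geneModel("gs", "c1", "+", 101, 112, 101, 112)
  # TAC -> TAA: nonsense
  cc <- classifyVariant(asm, gm, variantTable("c1", 106, "C", "A", asm))
  expect_equal(cc$category, "nonsense")
  expect_equal(cc$altAA, "*")
  # TAA -> CAA: stop lost
  cc2 <- classifyVariant(asm, gm, variantTable("c1", 110, "T", "C", asm))
  expect_equal(cc2$category, "stop_loss")
  expect_true(all(isAminoAcidAltering(rbind(cc, cc2))))
})

test_that("annotateVariants assigns each variant to its harbouring gene", {
  asm <- toyAssemblyPlus()
  gms <- list(geneModel("gA", "chr1", "+", 101, 400, 101, 400),
              geneModel("gB", "chr1", "+", 501, 800, 501, 800))
  s <- as.character(asm[["chr1"]])
  vt <- do.call(rbind, lapply(c(150, 600, 950), function(pos) {
    ref <- substr(s, pos, pos)
    variantTable("chr1", pos, ref, setdiff(c("A", "C", "G", "T"), ref)[1])
  }))
  ann <- annotateVariants(asm, gms, vt)
  expect_equal(ann$geneId, c("gA", "gB", NA))
  expect_equal(ann$category[3], "intergenic")
})
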