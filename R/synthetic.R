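#' SyntheticScenario: seeded specification of a full study
#'
#' Declares every input the pipeline consumes: a reference assembly, gene
#' models, a planted homozygous-recessive causal variant shared by all
#' case genomes and absent from all controls, background variants with a
#' controlled sharing structure, a breed-stratified genotyping cohort with
#' endpoint-fluorescence signal, and an ortholog alignment column with a
#' controlled residue composition. [generateScenario()] realises it
#' deterministically from the seed.
#'
#' @slot params named list of generator parameters; see
#'   [syntheticScenario()].
#' @export
setClass("SyntheticScenario", representation(params = "list"))

#' The study's genotyping cohort as a specification table
#'
#' 25 affected variant-allele homozygotes (22 SCWT, 3 Whoodles), 682
#' unaffected SCWT (15 heterozygous carriers, 667 reference homozygotes),
#' 388 Poodles and 132 dogs of other breeds, all reference homozygotes.
#'
#' @return data.frame with columns breed, phenotype, genotype, n.
#' @export
studyCohortSpec <- function() {
  data.frame(
    breed = c("SCWT", "Whoodle", "SCWT", "SCWT", "Poodle", "OtherBreed"),
    phenotype = c("affected", "affected", "unaffected", "unaffected",
                  "unaffected", "unaffected"),
    genotype = c("hom_alt", "hom_alt", "het", "hom_ref", "hom_ref",
                 "hom_ref"),
    n = c(22L, 3L, 15L, 667L, 388L, 132L),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic scenario
#'
#' Defaults emulate the study design: two affected case genomes sharing
#' one planted homozygous missense variant (coding position 398, codon
#' 133, threonine to isoleucine), a panel of 20 control genomes, private
#' and shared background variants, the published genotyping cohort, 5%
#' fluorescence noise and an alignment column of 146 threonines and 2
#' serines.
#'
#' @param seed integer RNG seed; identical seeds give identical outputs.
#' @param nContigs,contigLength synthetic assembly shape.
#' @param nGenes,exonsPerGene,cdsLength,utrLength,intronLength gene-model
#'   shape; `cdsLength` must be a multiple of 3 and at least
#'   `plantedCdsPos`.
#' @param plantedGene gene id to carry the causal variant (default: chosen
#'   at random).
#' @param plantedCdsPos 1-based coding position of the planted
#'   substitution (default 398; the reference codon is set so the change
#'   is missense, T>I at the default offset).
#' @param nCases,nControls genome counts.
#' @param meanHetCoding,meanHomCoding,meanHomNoncoding expected per-genome
#'   background variant counts by class (Poisson).
#' @param pControlShare probability that a case background homozygous
#'   coding variant is also present in at least one control genome
#'   (otherwise it is private to that case); with `pCaseShared = 0` this
#'   guarantees exact recovery of the planted variant by the filter +
#'   intersection pipeline.
#' @param pCaseShared probability that a case background homozygous coding
#'   variant is instead planted in every case and kept out of controls,
#'   making recovery ambiguous (default 0).
#' @param cohortSpec data.frame(breed, phenotype, genotype, n); default
#'   [studyCohortSpec()].
#' @param fluorSignal endpoint fluorescence signal magnitude (arbitrary
#'   units).
#' @param fluorNoiseSd per-channel Gaussian noise, as a fraction of
#'   `fluorSignal`.
#' @param alignmentComposition named integer vector residue -> species
#'   count at the focal alignment column.
#' @param alignmentWidth,focalColumn alignment shape.
#' @return a [SyntheticScenario-class].
#' @export
syntheticScenario <- function(seed = 42L, nContigs = 2L,
    contigLength = 50000L, nGenes = 20L, exonsPerGene = 3L,
    cdsLength = 600L, utrLength = 30L, intronLength = 200L,
    plantedGene = NULL, plantedCdsPos = 398L, nCases = 2L,
    nControls = 20L, meanHetCoding = 25, meanHomCoding = 20,
    meanHomNoncoding = 25, pControlShare = 0.7, pCaseShared = 0,
    cohortSpec = studyCohortSpec(), fluorSignal = 1000,
    fluorNoiseSd = 0.05, alignmentComposition = c(T = 146L, S = 2L),
    alignmentWidth = 21L, focalColumn = 11L) {
  params <- as.list(environment())
  if (cdsLength %% 3L != 0L) stop("cdsLength must be a multiple of 3")
  if (cdsLength < plantedCdsPos)
    stop("cds too short for planted codon: cdsLength ", cdsLength,
         " < plantedCdsPos ", plantedCdsPos)
  if (pControlShare + pCaseShared > 1)
    stop("pControlShare + pCaseShared must be <= 1")
  span <- utrLength * 2L + cdsLength +
    (exonsPerGene - 1L) * (intronLength + 100L) + 500L
  need <- ceiling(nGenes / nContigs) * span + 1000L
  if (need > contigLength)
    stop("contigLength too small for ", nGenes, " genes (need ~", need, ")")
  new("SyntheticScenario", params = params)
}

setMethod("show", "SyntheticScenario", function(object) {
  p <- object@params
  cat(sprintf(
    "SyntheticScenario: seed %d, %d case(s) + %d control(s), %d gene(s), planted c.%d\n",
    p$seed, p$nCases, p$nControls, p$nGenes, p$plantedCdsPos))
})

#' ScenarioRealization: the generated study inputs plus truth
#'
#' Output of [generateScenario()]: in-memory assembly, gene models, case
#' and control genome observations, cohort with fluorescence, ortholog
#' alignment, and a truth manifest recording every planted variant,
#' genotype and label.
#'
#' @slot scenario the generating [SyntheticScenario-class].
#' @slot assembly named [Biostrings::DNAStringSet].
#' @slot models named list of [GeneModel-class].
#' @slot genomes list of [GenomeObservation-class], cases first.
#' @slot truth list: `planted` (one-row variant data.frame with hgvsC /
#'   hgvsP / geneId), `manifest` (per-genome variant table with class
#'   labels), `proteins` (named character, translated reference CDS per
#'   gene).
#' @slot cohort data.frame sampleId, breed, phenotype, genotype (truth),
#'   channelRef, channelAlt.
#' @slot alignment an [OrthologAlignment-class].
#' @export
setClass("ScenarioRealization",
  representation(scenario = "SyntheticScenario", assembly = "DNAStringSet",
                 models = "list", genomes = "list", truth = "list",
                 cohort = "data.frame", alignment = "OrthologAlignment"))

setMethod("show", "ScenarioRealization", function(object) {
  pl <- object@truth$planted
  cat(sprintf(
    "ScenarioRealization: %d genome(s), %d gene(s); planted %s (%s %s in %s)\n",
    length(object@genomes), length(object@models),
    variantKey(pl), pl$hgvsC, pl$hgvsP, pl$geneId))
})

#' @export
setGeneric("caseObservations", function(x) standardGeneric("caseObservations"))
#' @describeIn ScenarioRealization-class case genomes
#' @param x a ScenarioRealization.
#' @export
setMethod("caseObservations", "ScenarioRealization", function(x)
  Filter(function(g) g@role == "case", x@genomes))

#' @export
setGeneric("controlObservations",
           function(x) standardGeneric("controlObservations"))
#' @describeIn ScenarioRealization-class control genomes
#' @export
setMethod("controlObservations", "ScenarioRealization", function(x)
  Filter(function(g) g@role == "control", x@genomes))

#' @export
setGeneric("scenarioTruth", function(x) standardGeneric("scenarioTruth"))
#' @describeIn ScenarioRealization-class truth manifest accessor
#' @export
setMethod("scenarioTruth", "ScenarioRealization", function(x) x@truth)

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exon/CDS layout for one gene starting at `cursor`; returns the model
.layoutGene <- function(gid, contig, cursor, p) {
  totalExonic <- 2L * p$utrLength + p$cdsLength
  base <- totalExonic %/% p$exonsPerGene
  lens <- rep(base, p$exonsPerGene)
  extra <- totalExonic - sum(lens)
  if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  starts <- integer(p$exonsPerGene); ends <- integer(p$exonsPerGene)
  at <- cursor
  for (i in seq_len(p$exonsPerGene)) {
    starts[i] <- at
    ends[i] <- at + lens[i] - 1L
    at <- ends[i] + p$intronLength + sample.int(100L, 1L)
  }
  strand <- sample(c("+", "-"), 1L)
  exonic <- unlist(lapply(seq_len(p$exonsPerGene),
                          function(i) seq.int(starts[i], ends[i])))
  cdsStart <- exonic[p$utrLength + 1L]
  cdsEnd <- exonic[p$utrLength + p$cdsLength]
  list(model = geneModel(gid, contig, strand, starts, ends,
                         cdsStart, cdsEnd),
       nextCursor = max(ends) + 500L)
}

# codon content and substitution guaranteeing a missense change at the
# planted offset: T>A for offset 1, T>I (the study's change) for offset 2,
# M>I for offset 3
.plantedCodonPlan <- function(offset) {
  switch(offset,
         list(codon = "ACC", refC = "A", altC = "G"),
         list(codon = "ACC", refC = "C", altC = "T"),
         list(codon = "ATG", refC = "G", altC = "A"))
}

# draw helpers work on a plain-character copy of the assembly and
# precomputed per-model CDS position vectors; each returns
# list(contig, pos, ref, alt) and marks the key used
.drawCodingVariant <- function(seqChars, modelCds, forbiddenKey, used) {
  repeat {
    i <- sample.int(length(modelCds), 1L)
    cds <- modelCds[[i]]
    gpos <- cds$pos[sample.int(length(cds$pos), 1L)]
    ref <- substr(seqChars[[cds$contig]], gpos, gpos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    k <- paste(cds$contig, gpos, ref, alt, sep = ":")
    if (gpos %in% forbiddenKey[[cds$contig]] || !is.null(used[[k]])) next
    used[[k]] <- TRUE
    return(list(contig = cds$contig, pos = gpos, ref = ref, alt = alt))
  }
}

.drawNoncodingVariant <- function(seqChars, codingPos, used) {
  contigs <- names(seqChars)
  repeat {
    ctg <- contigs[sample.int(length(contigs), 1L)]
    gpos <- sample.int(nchar(seqChars[[ctg]]), 1L)
    if (gpos %in% codingPos[[ctg]]) next
    ref <- substr(seqChars[[ctg]], gpos, gpos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    k <- paste(ctg, gpos, ref, alt, sep = ":")
    if (!is.null(used[[k]])) next
    used[[k]] <- TRUE
    return(list(contig = ctg, pos = gpos, ref = ref, alt = alt))
  }
}

#' Endpoint fluorescence for known genotypes
#'
#' Two-channel signal drawn around the canonical cluster centres: hom_ref
#' at (signal, 0), het at 45 degrees, hom_alt at (0, signal); no_call
#' genotypes get residual low-level signal. Gaussian per-channel noise
#' with sd `noiseSd * signal`, truncated at zero.
#'
#' @param genotypes character vector of planted genotypes.
#' @param signal signal magnitude.
#' @param noiseSd noise sd as a fraction of `signal`.
#' @return data.frame channelRef, channelAlt.
#' @export
simulateFluorescence <- function(genotypes, signal = 1000, noiseSd = 0.05) {
  centers <- list(hom_ref = c(1, 0), het = c(cos(pi / 4), sin(pi / 4)),
                  hom_alt = c(0, 1), no_call = c(0.02, 0.02))
  mu <- t(vapply(genotypes, function(g) centers[[g]], numeric(2))) * signal
  n <- length(genotypes)
  data.frame(
    channelRef = pmax(0, mu[, 1] + rnorm(n, 0, noiseSd * signal)),
    channelAlt = pmax(0, mu[, 2] + rnorm(n, 0, noiseSd * signal)))
}

#' Generate the study's genotyping cohort with fluorescence
#'
#' Genotype counts are assigned by exact partition of each breed/phenotype
#' stratum (not by Bernoulli draws), so the specified counts are
#' reproduced exactly; row order is shuffled. Defaults reproduce the
#' published cohort: 25 affected homozygotes, 682 unaffected SCWT (15
#' het / 667 hom-ref), 388 Poodles and 132 other-breed dogs, 1227 rows.
#'
#' @param seed RNG seed.
#' @param cohortSpec data.frame(breed, phenotype, genotype, n).
#' @param signal,noiseSd passed to [simulateFluorescence()].
#' @return data.frame sampleId, breed, phenotype, genotype (truth),
#'   channelRef, channelAlt.
#' @export
generateStudyCohort <- function(seed = 1L,
                                    cohortSpec = studyCohortSpec(),
                                    signal = 1000, noiseSd = 0.05) {
  set.seed(seed)
  rows <- cohortSpec[rep(seq_len(nrow(cohortSpec)), cohortSpec$n),
                     c("breed", "phenotype", "genotype")]
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  rownames(rows) <- NULL
  rows <- cbind(sampleId = sprintf("s%04d", seq_len(nrow(rows))), rows)
  cbind(rows, simulateFluorescence(rows$genotype, signal, noiseSd))
}

#' Generate an ortholog alignment with a controlled focal column
#'
#' Non-focal columns are fully conserved (one residue per column across
#' all species); the focal column carries exactly the requested residue
#' composition, shuffled over species.
#'
#' @param composition named vector residue -> species count ("-" allowed
#'   for gap rows).
#' @param width,focalColumn alignment shape.
#' @return an [OrthologAlignment-class] with species_NNN row names.
#' @export
generateAlignment <- function(composition = c(T = 146L, S = 2L),
                              width = 21L, focalColumn = 11L) {
  n <- sum(composition)
  backbone <- sample(setdiff(names(Biostrings::AMINO_ACID_CODE), "U"),
                     width, replace = TRUE)
  focal <- sample(rep(names(composition), composition))
  rows <- vapply(seq_len(n), function(i) {
    r <- backbone
    r[focalColumn] <- focal[i]
    paste(r, collapse = "")
  }, character(1))
  names(rows) <- sprintf("species_%03d", seq_len(n))
  orthologAlignment(rows, focalColumn)
}

#' Realise a synthetic scenario
#'
#' Deterministic for a fixed seed. The planted causal variant is
#' homozygous-alternate in every case genome, absent from every control,
#' and missense under the generated gene model (verified by running the
#' annotator). Each case background homozygous coding variant is, per the
#' scenario's sharing model, present in at least one control
#' (`pControlShare`), shared by all cases and absent from controls
#' (`pCaseShared`, ambiguity dial, default 0), or private to its case —
#' so with the default sharing model the filter + intersection pipeline
#' is guaranteed to recover exactly the planted variant.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return a [ScenarioRealization-class].
#' @export
generateScenario <- function(scenario) {
  p <- scenario@params
  set.seed(p$seed)

  # --- assembly and gene models
  contigNames <- sprintf("contig%02d", seq_len(p$nContigs))
  seqs <- vapply(seq_len(p$nContigs), function(i) .randomDna(p$contigLength),
                 character(1))
  names(seqs) <- contigNames
  cursors <- setNames(rep(500L, p$nContigs), contigNames)
  models <- list()
  for (g in seq_len(p$nGenes)) {
    ctg <- contigNames[(g - 1L) %% p$nContigs + 1L]
    lay <- .layoutGene(sprintf("gene%03d", g), ctg, cursors[[ctg]], p)
    cursors[[ctg]] <- lay$nextCursor
    models[[lay$model@geneId]] <- lay$model
  }

  # --- plant the causal codon and variant
  plantedGene <- if (is.null(p$plantedGene))
    names(models)[sample.int(length(models), 1L)] else p$plantedGene
  pm <- models[[plantedGene]]
  cc <- codonCoordinates(p$plantedCdsPos)
  plan <- .plantedCodonPlan(cc$codonOffset)
  codonChars <- strsplit(plan$codon, "")[[1]]
  for (k in 1:3) {
    cpos <- 3L * (cc$codonIndex - 1L) + k
    gpos <- cdsToGenomic(pm, cpos)
    b <- if (pm@strand == "-") COMPLEMENT[[codonChars[k]]] else codonChars[k]
    substr(seqs[[pm@contig]], gpos, gpos) <- b
  }
  assembly <- Biostrings::DNAStringSet(seqs)
  plantedPos <- cdsToGenomic(pm, p$plantedCdsPos)
  refG <- if (pm@strand == "-") COMPLEMENT[[plan$refC]] else plan$refC
  altG <- if (pm@strand == "-") COMPLEMENT[[plan$altC]] else plan$altC
  plantedVt <- variantTable(pm@contig, plantedPos, refG, altG, assembly)
  plantedAnn <- classifyVariant(assembly, pm, plantedVt)
  stopifnot(plantedAnn$category == "missense")

  # --- background variant structure
  seqChars <- as.character(assembly)
  modelCds <- lapply(models, function(m)
    list(contig = m@contig, pos = cdsPositions(m)))
  codingPos <- lapply(setNames(contigNames, contigNames), function(ctg) {
    unlist(lapply(modelCds, function(mc)
      if (mc$contig == ctg) mc$pos else integer(0)), use.names = FALSE)
  })
  forbidden <- lapply(setNames(contigNames, contigNames), function(ctg)
    if (ctg == pm@contig) plantedPos else integer(0))
  used <- new.env(parent = emptyenv())
  used[[variantKey(plantedVt)]] <- TRUE

  caseIds <- sprintf("case%02d", seq_len(p$nCases))
  controlIds <- sprintf("control%02d", seq_len(p$nControls))
  # flat accumulators; one data.frame built at the end
  acc <- list(genomeId = character(0), contig = character(0),
              pos = integer(0), ref = character(0), alt = character(0),
              zygosity = character(0), class = character(0))
  addCall <- function(gid, v, zyg, class) {
    n <- length(acc$genomeId) + 1L
    acc$genomeId[n] <<- gid; acc$contig[n] <<- v$contig
    acc$pos[n] <<- v$pos; acc$ref[n] <<- v$ref; acc$alt[n] <<- v$alt
    acc$zygosity[n] <<- zyg; acc$class[n] <<- class
  }
  plantedV <- list(contig = plantedVt$contig, pos = plantedVt$pos,
                   ref = plantedVt$ref, alt = plantedVt$alt)
  for (ci in seq_len(p$nCases))
    addCall(caseIds[ci], plantedV, "hom_alt", "planted")

  for (ci in seq_len(p$nCases)) {
    for (j in seq_len(rpois(1L, p$meanHomCoding))) {
      v <- .drawCodingVariant(seqChars, modelCds, forbidden, used)
      u <- runif(1L)
      if (u < p$pCaseShared && p$nCases >= 2L) {
        for (ck in seq_len(p$nCases))
          addCall(caseIds[ck], v, "hom_alt", "background_case_shared")
      } else if (u < p$pCaseShared + p$pControlShare) {
        addCall(caseIds[ci], v, "hom_alt", "background_control_shared")
        carriers <- sample(controlIds, sample.int(min(3L, p$nControls), 1L))
        for (ct in carriers)
          addCall(ct, v, sample(c("het", "hom_alt"), 1L),
                  "background_control_shared")
      } else {
        addCall(caseIds[ci], v, "hom_alt", "background_private")
      }
    }
    for (j in seq_len(rpois(1L, p$meanHetCoding)))
      addCall(caseIds[ci],
              .drawCodingVariant(seqChars, modelCds, forbidden, used),
              "het", "background_het_coding")
    for (j in seq_len(rpois(1L, p$meanHomNoncoding)))
      addCall(caseIds[ci],
              .drawNoncodingVariant(seqChars, codingPos, used),
              "hom_alt", "background_noncoding")
  }
  for (ct in controlIds) {
    for (j in seq_len(rpois(1L, p$meanHomCoding)))
      addCall(ct, .drawCodingVariant(seqChars, modelCds, forbidden, used),
              "hom_alt", "background_private")
    for (j in seq_len(rpois(1L, p$meanHetCoding)))
      addCall(ct, .drawCodingVariant(seqChars, modelCds, forbidden, used),
              "het", "background_het_coding")
    for (j in seq_len(rpois(1L, p$meanHomNoncoding)))
      addCall(ct, .drawNoncodingVariant(seqChars, codingPos, used),
              "hom_alt", "background_noncoding")
  }

  manifest <- data.frame(acc, stringsAsFactors = FALSE)
  o <- order(manifest$genomeId, manifest$contig, manifest$pos,
             manifest$ref, manifest$alt)
  manifest <- manifest[o, , drop = FALSE]
  rownames(manifest) <- NULL
  genomes <- lapply(c(caseIds, controlIds), function(gid) {
    df <- manifest[manifest$genomeId == gid,
                   c("contig", "pos", "ref", "alt", "zygosity"),
                   drop = FALSE]
    genomeObservation(gid, if (gid %in% caseIds) "case" else "control", df)
  })
  names(genomes) <- c(caseIds, controlIds)

  proteins <- vapply(models, function(m)
    as.character(Biostrings::translate(cdsSequence(assembly, m))),
    character(1))

  cohort <- generateStudyCohortInternal(p)
  alignment <- generateAlignment(p$alignmentComposition, p$alignmentWidth,
                                 p$focalColumn)

  new("ScenarioRealization", scenario = scenario, assembly = assembly,
      models = models, genomes = genomes,
      truth = list(planted = cbind(plantedAnn[, c("contig", "pos", "ref",
                                                  "alt", "geneId", "category",
                                                  "hgvsC", "hgvsP")],
                                   codonIndex = plantedAnn$codonIndex),
                   manifest = manifest, proteins = proteins),
      cohort = cohort, alignment = alignment)
}

# cohort built inside generateScenario's RNG stream (no re-seeding)
generateStudyCohortInternal <- function(p) {
  rows <- p$cohortSpec[rep(seq_len(nrow(p$cohortSpec)), p$cohortSpec$n),
                       c("breed", "phenotype", "genotype")]
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  rownames(rows) <- NULL
  rows <- cbind(sampleId = sprintf("s%04d", seq_len(nrow(rows))), rows)
  cbind(rows, simulateFluorescence(rows$genotype, p$fluorSignal,
                                   p$fluorNoiseSd))
}

#' Write a realised scenario to disk
#'
#' Emits every pipeline input plus the truth manifest and a ready-to-run
#' pipeline config: `reference.fasta`, `genes.gff3`, one
#' `<genomeId>.vcf.gz` per genome, `cohort.tsv` (breed, phenotype and the
#' two fluorescence channels; genotypes withheld), `alignment.fasta`,
#' `truth_manifest.tsv`, `config.yaml`.
#'
#' @param real a [ScenarioRealization-class].
#' @param dir output directory (created if needed).
#' @return invisibly the named list of paths.
#' @export
writeScenario <- function(real, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(reference = file.path(dir, "reference.fasta"),
                geneModels = file.path(dir, "genes.gff3"),
                cohort = file.path(dir, "cohort.tsv"),
                alignment = file.path(dir, "alignment.fasta"),
                manifest = file.path(dir, "truth_manifest.tsv"),
                config = file.path(dir, "config.yaml"))
  writeReference(real@assembly, paths$reference)
  writeGeneModels(real@models, paths$geneModels)
  vcfs <- lapply(real@genomes, function(g) {
    f <- file.path(dir, paste0(g@genomeId, ".vcf.gz"))
    writeGenomeVcf(g, f, assembly = real@assembly)
    f
  })
  paths$caseVcfs <- unlist(vcfs[vapply(real@genomes, function(g)
    g@role == "case", logical(1))], use.names = FALSE)
  paths$controlVcfs <- unlist(vcfs[vapply(real@genomes, function(g)
    g@role == "control", logical(1))], use.names = FALSE)
  writeTsv(real@cohort[, c("sampleId", "breed", "phenotype",
                           "channelRef", "channelAlt")], paths$cohort)
  aln <- real@alignment
  Biostrings::writeXStringSet(aln@aln, paths$alignment)
  writeTsv(real@truth$manifest, paths$manifest)
  cfg <- list(reference = paths$reference, geneModels = paths$geneModels,
              caseVcfs = as.list(paths$caseVcfs),
              controlVcfs = as.list(paths$controlVcfs),
              cohort = paths$cohort, alignment = paths$alignment,
              focalColumn = aln@focalColumn,
              variantAA = "I", spliceWindow = 2L,
              seed = real@scenario@params$seed)
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
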