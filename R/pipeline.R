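#' Run the candidate-discovery analysis on an in-memory scenario
#'
#' Convenience driver used by tests and simulations: annotates every case
#' genome's variants, indexes the controls, applies the three-criteria
#' filter per case and intersects the candidate sets.
#'
#' @param real a [ScenarioRealization-class].
#' @param spliceWindow passed to [annotateVariants()].
#' @param trajectory also compute per-case [candidateTrajectory()]
#'   (default FALSE; quadratic in control count).
#' @return list: `candidateSets` (per case), `intersection`
#'   ([CandidateSet-class]), `annotations` (per case), `trajectories`
#'   (per case, if requested).
#' @export
analyzeScenario <- function(real, spliceWindow = 2L, trajectory = FALSE) {
  cases <- caseObservations(real)
  controls <- controlObservations(real)
  store <- controlVariantStore(controls)
  annotations <- lapply(cases, function(cs)
    annotateVariants(real@assembly, real@models, cs@calls, spliceWindow))
  names(annotations) <- vapply(cases, genomeId, character(1))
  sets <- lapply(seq_along(cases), function(i)
    filterCandidates(cases[[i]], store, annotations[[i]]))
  names(sets) <- names(annotations)
  intersection <- if (length(sets) >= 2L)
    suppressWarnings(intersectCases(sets)) else sets[[1L]]
  out <- list(candidateSets = sets, intersection = intersection,
              annotations = annotations)
  if (trajectory)
    out$trajectories <- lapply(seq_along(cases), function(i)
      candidateTrajectory(cases[[i]], controls, annotations[[i]]))
  out
}

.readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("reference", "geneModels", "caseVcfs")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config lacks field(s): ", paste(missing, collapse = ", "))
  if (is.null(config$controlVcfs) || length(config$controlVcfs) == 0L) {
    warning("no control VCFs configured: the absence criterion is vacuous ",
            "and all homozygous amino-acid-altering variants are retained")
    config$controlVcfs <- list()
  }
  files <- c(config$reference, config$geneModels,
             unlist(config$caseVcfs), unlist(config$controlVcfs),
             config$cohort, config$alignment)
  absent <- files[!file.exists(files)]
  if (length(absent))
    stop("config references missing file(s): ",
         paste(absent, collapse = ", "))
  if (is.null(config$spliceWindow)) config$spliceWindow <- 2L
  if (is.null(config$strict)) config$strict <- FALSE
  config
}

#' Run the full file-based discovery pipeline
#'
#' Orchestrates annotate -> filter (per case) -> intersect, plus cohort
#' segregation/association and conservation analysis when the config
#' provides a cohort table and an ortholog alignment. Inputs are files
#' (FASTA reference, BED12/GFF3 gene models, one VCF per genome, cohort
#' TSV, aligned FASTA) referenced from a YAML config or an equivalent
#' named list; [writeScenario()] emits a ready-made config.
#'
#' @param config YAML path or named list with fields `reference`,
#'   `geneModels`, `caseVcfs`, `controlVcfs`, and optionally `cohort`,
#'   `alignment`, `focalColumn`, `variantAA`, `spliceWindow`, `outDir`,
#'   `strict`.
#' @return report list with elements `perCase` (data.frame: caseId,
#'   nVariantsTotal, nCandidates, nGenes), `trajectories`, `intersection`
#'   ([CandidateSet-class]), `segregation` ([SegregationReport-class] or
#'   NULL), `conservation` (list or NULL). When `outDir` is set, TSV/text
#'   reports are written there.
#' @export
runPipeline <- function(config) {
  config <- .readRunConfig(config)
  assembly <- readReference(config$reference)
  models <- readGeneModels(config$geneModels)
  cases <- lapply(unlist(config$caseVcfs), readGenomeVcf, role = "case")
  controls <- lapply(unlist(config$controlVcfs), readGenomeVcf,
                     role = "control")
  if (length(cases) < 1L) stop("at least one case VCF required")
  store <- controlVariantStore(controls)
  annotations <- lapply(cases, function(cs)
    annotateVariants(assembly, models, cs@calls, config$spliceWindow))
  sets <- lapply(seq_along(cases), function(i)
    filterCandidates(cases[[i]], store, annotations[[i]]))
  names(sets) <- vapply(cases, genomeId, character(1))
  trajectories <- lapply(seq_along(cases), function(i)
    candidateTrajectory(cases[[i]], controls, annotations[[i]]))
  names(trajectories) <- names(sets)
  intersection <- if (length(sets) >= 2L) intersectCases(sets) else
    sets[[1L]]
  if (config$strict && nrow(intersection@variants) == 0L)
    stop("strict mode: candidate intersection is empty")
  perCase <- do.call(rbind, lapply(seq_along(cases), function(i) {
    s <- summarizeCandidates(sets[[i]])
    data.frame(caseId = genomeId(cases[[i]]),
               nVariantsTotal = nrow(cases[[i]]@calls),
               nCandidates = s[["nVariants"]], nGenes = s[["nGenes"]],
               stringsAsFactors = FALSE)
  }))
  segregation <- NULL
  if (!is.null(config$cohort)) {
    cohort <- readCohortTable(config$cohort)
    segregation <- segregationCheck(cohort)
  }
  conservation <- NULL
  if (!is.null(config$alignment)) {
    if (is.null(config$focalColumn))
      stop("config needs focalColumn with alignment")
    aln <- readOrthologAlignment(config$alignment, config$focalColumn)
    comp <- columnComposition(aln)
    tol <- toleratedStates(aln, 1L, variantAA = config$variantAA)
    conservation <- list(composition = comp$counts, nGaps = comp$nGaps,
                         tolerated = as.character(tol),
                         variantAA = config$variantAA,
                         variantObserved = attr(tol, "variantObserved"))
  }
  report <- list(perCase = perCase, trajectories = trajectories,
                 intersection = intersection, segregation = segregation,
                 conservation = conservation)
  if (!is.null(config$outDir))
    writePipelineReport(report, config$outDir, sets, annotations, cases,
                        assembly)
  report
}

#' Write pipeline outputs to a directory
#'
#' Per-case candidate TSV + annotated VCF, intersection TSV, trajectory
#' CSV, segregation TSV, and both machine-readable (JSON) and
#' human-readable (text) summaries. Numbers are emitted in a stable key
#' order with 6 significant digits.
#'
#' @param report report list from [runPipeline()].
#' @param outDir output directory.
#' @param sets,annotations,cases,assembly pipeline internals (optional;
#'   enable per-case candidate VCF output).
#' @return invisibly `outDir`.
#' @export
writePipelineReport <- function(report, outDir, sets = NULL,
                                annotations = NULL, cases = NULL,
                                assembly = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sets)) {
    for (i in seq_along(sets)) {
      id <- sets[[i]]@caseId
      writeCandidateTable(sets[[i]],
                          file.path(outDir, paste0(id, ".candidates.tsv")))
      if (!is.null(cases))
        writeGenomeVcf(cases[[i]],
                       file.path(outDir, paste0(id, ".annotated.vcf.gz")),
                       assembly = assembly,
                       annotations = annotations[[i]])
    }
  }
  writeCandidateTable(report$intersection,
                      file.path(outDir, "intersection.tsv"))
  traj <- do.call(rbind, lapply(names(report$trajectories), function(id)
    data.frame(caseId = id,
               nControls = seq_along(report$trajectories[[id]]),
               nCandidates = report$trajectories[[id]])))
  if (!is.null(traj))
    write.table(traj, file.path(outDir, "trajectory.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$segregation))
    writeTsv(perBreed(report$segregation),
             file.path(outDir, "segregation.tsv"))
  json <- list(perCase = report$perCase,
               intersection = list(
                 n = nrow(report$intersection@variants),
                 variants = report$intersection@variants))
  if (!is.null(report$segregation))
    json$segregation <- list(
      consistentRecessive = consistentRecessive(report$segregation),
      fisherP = fisherP(report$segregation),
      alleleFreqControls = alleleFreqControls(report$segregation))
  if (!is.null(report$conservation))
    json$conservation <- report$conservation[c("composition", "nGaps",
                                               "tolerated",
                                               "variantObserved")]
  jsonlite::write_json(json, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(formatPipelineReport(report), file.path(outDir, "report.txt"))
  invisible(outDir)
}

#' Render a human-readable pipeline summary
#' @param report report list from [runPipeline()].
#' @return character vector of report lines.
#' @export
formatPipelineReport <- function(report) {
  lines <- c("candidate-variant discovery report", "")
  for (i in seq_len(nrow(report$perCase))) {
    r <- report$perCase[i, ]
    lines <- c(lines, sprintf(
      "case %s: %d variant(s) total, %d candidate(s) in %d gene(s)",
      r$caseId, r$nVariantsTotal, r$nCandidates, r$nGenes))
  }
  iv <- report$intersection@variants
  lines <- c(lines, "", sprintf("intersection: %d shared candidate(s)",
                                nrow(iv)))
  for (i in seq_len(nrow(iv)))
    lines <- c(lines, sprintf("  %s %s %s (%s, %s)", iv$geneId[i],
                              iv$hgvsC[i], iv$hgvsP[i], iv$category[i],
                              variantKey(iv[i, ])))
  if (!is.null(report$segregation)) {
    s <- report$segregation
    lines <- c(lines, "",
               sprintf("segregation: consistent with recessive = %s",
                       consistentRecessive(s)),
               sprintf("  Fisher exact p = %s", fmtNum(fisherP(s))),
               sprintf("  control alt-allele frequency = %s",
                       fmtNum(alleleFreqControls(s))))
  }
  if (!is.null(report$conservation)) {
    comp <- report$conservation$composition
    lines <- c(lines, "",
               sprintf("conservation at focal column: %s",
                       paste(names(comp), comp, sep = "=",
                             collapse = ", ")),
               sprintf("  tolerated residues: %s",
                       paste(report$conservation$tolerated,
                             collapse = ", ")))
    if (!is.null(report$conservation$variantAA))
      lines <- c(lines, sprintf("  variant residue %s observed: %s",
                                report$conservation$variantAA,
                                report$conservation$variantObserved))
  }
  lines
}
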