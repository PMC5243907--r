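test_that("the three criteria are each enforced", {
  # v1 het missense, v2 hom missense absent from controls, v3 hom missense
  # seen het in one control, v4 hom synonymous -> only v2 survives
  vt <- data.frame(contig = "c1", pos = c(10L, 20L, 30L, 40L),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  case <- obs("case1", "case", "c1", vt$pos, "A", "G",
              c("het", "hom_alt", "hom_alt", "hom_alt"))
  ann <- fakeAnnotation(vt, c("missense", "missense", "missense",
                              "synonymous"))
  ctl <- obs("ctl1", "control", "c1", 30, "A", "G", "het")
  store <- controlVariantStore(list(ctl))
  cs <- filterCandidates(case, store, ann)
  expect_equal(variantKey(candidateVariants(cs)), "c1:20:A:G")
  expect_equal(cs@nControlsUsed, 1L)

  # empty store: absence criterion vacuous, all hom missense retained
  cs0 <- filterCandidates(case, controlVariantStore(), ann)
  expect_setequal(variantKey(candidateVariants(cs0)),
                  c("c1:20:A:G", "c1:30:A:G"))

  # no hom_alt calls: empty set
  caseHet <- obs("case2", "case", "c1", vt$pos, "A", "G", rep("het", 4))
  expect_equal(nrow(candidateVariants(
    filterCandidates(caseHet, store, ann))), 0L)

  # unannotated case variant is an error naming the offender
  expect_error(filterCandidates(case, store, ann[-2, ]), "c1:20:A:G")

  # control-role enforcement both ways
  expect_error(filterCandidates(ctl, store, ann), "case genome")
  expect_error(addGenome(store, case), "control genomes")
})

test_that("any control zygosity disqualifies, and re-adding is idempotent", {
  vt <- data.frame(contig = "c1", pos = c(1L, 2L, 3L), ref = "A",
                   alt = "T", stringsAsFactors = FALSE)
  case <- obs("case1", "case", "c1", vt$pos, "A", "T", rep("hom_alt", 3))
  ann <- fakeAnnotation(vt, rep("missense", 3))
  ctlHet <- obs("c_het", "control", "c1", 1, "A", "T", "het")
  ctlHom <- obs("c_hom", "control", "c1", 2, "A", "T", "hom_alt")
  store <- controlVariantStore(list(ctlHet, ctlHom))
  expect_equal(variantKey(candidateVariants(
    filterCandidates(case, store, ann))), "c1:3:A:T")
  # duplicate genome id changes nothing
  store2 <- addGenome(store, ctlHet)
  expect_equal(nGenomes(store2), 2L)
  expect_equal(countObservations(store2, "c1:1:A:T"), 1L)
})

test_that("trajectory is non-increasing and empty for zero controls", {
  real <- generateScenario(smallScenario(101))
  cases <- caseObservations(real)
  controls <- controlObservations(real)
  ann <- annotateVariants(real@assembly, real@models, calls(cases[[1]]))
  expect_length(candidateTrajectory(cases[[1]], list(), ann), 0)
  traj <- candidateTrajectory(cases[[1]], controls, ann)
  expect_length(traj, length(controls))
  expect_true(all(diff(traj) <= 0))
})

test_that("final candidate set is invariant to control insertion order", {
  real <- generateScenario(smallScenario(202))
  cases <- caseObservations(real)
  controls <- controlObservations(real)
  ann <- annotateVariants(real@assembly, real@models, calls(cases[[1]]))
  ref <- filterCandidates(cases[[1]], controlVariantStore(controls), ann)
  for (perm in list(rev(seq_along(controls)),
                    sample(seq_along(controls)))) {
    cs <- filterCandidates(cases[[1]],
                           controlVariantStore(controls[perm]), ann)
    expect_setequal(variantKey(candidateVariants(cs)),
                    variantKey(candidateVariants(ref)))
  }
})

test_that("filterCandidates agrees with the naive triple-loop oracle", {
  for (seed in c(7, 8, 9)) {
    real <- generateScenario(smallScenario(seed, pCaseShared = 0.2))
    cases <- caseObservations(real)
    controls <- controlObservations(real)
    store <- controlVariantStore(controls)
    for (cs in cases) {
      ann <- annotateVariants(real@assembly, real@models, calls(cs))
      got <- sort(variantKey(candidateVariants(
        filterCandidates(cs, store, ann))))
      expect_equal(got, naiveFilter(cs, controls, ann))
    }
  }
})

test_that("intersection behaves as set intersection keyed by identity", {
  mkSet <- function(id, pos) {
    vt <- data.frame(contig = "c1", pos = pos, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
    new("CandidateSet", caseId = id,
        variants = fakeAnnotation(vt, rep("missense", length(pos))),
        nControlsUsed = 0L)
  }
  shared <- intersectCases(list(mkSet("A", c(2L, 5L)),
                                mkSet("B", c(2L, 6L))))
  expect_equal(variantKey(candidateVariants(shared)), "c1:2:A:G")
  expect_equal(shared@caseId, "A&B")
  # intersection is a subset of every input
  expect_true(all(variantKey(candidateVariants(shared)) %in%
                    variantKey(candidateVariants(mkSet("A", c(2L, 5L))))))
  expect_warning(intersectCases(list(mkSet("A", 1L), mkSet("B", 2L))),
                 "empty")
  expect_error(intersectCases(list(mkSet("A", 1L))), "at least two")
})

test_that("candidate summaries count distinct variants and genes", {
  vt <- data.frame(contig = "c1", pos = 1:4, ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  ann <- fakeAnnotation(vt, rep("missense", 4))
  ann$geneId <- c("g1", "g1", "g2", "g3")
  cs <- new("CandidateSet", caseId = "x", variants = ann,
            nControlsUsed = 0L)
  expect_equal(summarizeCandidates(cs),
               c(nVariants = 4L, nGenes = 3L))
  expect_equal(candidateGenes(cs), c("g1", "g2", "g3"))
  empty <- new("CandidateSet", caseId = "x", variants = ann[0, ],
               nControlsUsed = 0L)
  expect_equal(summarizeCandidates(empty),
               c(nVariants = 0L, nGenes = 0L))
})

test_that("candidate tables round-trip through TSV with synonym headers", {
  dir <- withr::local_tempdir()
  vt <- data.frame(contig = "c1", pos = c(5L, 9L), ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  ann <- fakeAnnotation(vt, c("missense", "nonsense"))
  ann$geneId <- c("gA", "gB")
  cs <- new("CandidateSet", caseId = "case1", variants = ann,
            nControlsUsed = 3L)
  f <- file.path(dir, "cand.tsv")
  writeCandidateTable(cs, f)
  back <- readCandidateTable(f)
  expect_equal(summarizeCandidates(back), c(nVariants = 2L, nGenes = 2L))
  # external-style headers (CHROM/POSITION/GENE) are recognised too
  df <- data.frame(CHROM = "c1", POSITION = 1:3, REF = "A", ALT = "T",
                   GENE = c("g1", "g2", "g2"))
  f2 <- file.path(dir, "ext.tsv")
  write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(summarizeCandidates(readCandidateTable(f2)),
               c(nVariants = 3L, nGenes = 2L))
})
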