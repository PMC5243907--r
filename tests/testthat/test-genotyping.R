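test_that("pure-channel samples get the expected calls", {
  expect_equal(callGenotypes(data.frame(sampleId = "s1",
                                        channelRef = 1000,
                                        channelAlt = 0))$genotype,
               "hom_ref")
  expect_warning(
    out <- callGenotypes(data.frame(sampleId = c("a", "b"),
                                    channelRef = 0, channelAlt = 0)),
    "zero intensity")
  expect_equal(out$genotype, c("no_call", "no_call"))
  expect_error(callGenotypes(data.frame(sampleId = "s",
                                        channelRef = -1,
                                        channelAlt = 0)),
               "non-negative")
})

test_that("caller recovers well-separated clusters and is scale-invariant", {
  set.seed(5)
  truth <- sample(c("hom_ref", "het", "hom_alt"), 300, replace = TRUE)
  fl <- simulateFluorescence(truth, signal = 1000, noiseSd = 0.05)
  rec <- cbind(sampleId = sprintf("s%03d", 1:300), fl)
  called <- callGenotypes(rec)
  expect_equal(called$genotype, truth)
  # uniform scaling of both channels leaves every call unchanged
  for (k in c(0.01, 7, 1e4)) {
    recK <- rec
    recK$channelRef <- recK$channelRef * k
    recK$channelAlt <- recK$channelAlt * k
    expect_equal(callGenotypes(recK)$genotype, called$genotype)
  }
})

test_that("zero-amplification samples inside a cohort become no-calls", {
  set.seed(6)
  truth <- c(rep("hom_ref", 50), rep("het", 50), rep("hom_alt", 50))
  fl <- simulateFluorescence(truth, 1000, 0.03)
  fl <- rbind(fl, data.frame(channelRef = c(0, 3), channelAlt = c(0, 2)))
  rec <- cbind(sampleId = sprintf("s%03d", seq_len(nrow(fl))), fl)
  called <- callGenotypes(rec)
  expect_equal(called$genotype[151:152], c("no_call", "no_call"))
  expect_equal(called$genotype[1:150], truth)
})

test_that("Fisher exact matches the exhaustive fixed-margins oracle", {
  # oracle: enumerate every table with the observed margins, computing
  # each probability from binomial coefficients directly
  oracleP <- function(m) {
    a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
    support <- max(0, r1 + c1 - n):min(r1, c1)
    logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) -
      lchoose(n, r1)
    probs <- exp(logp)
    pObs <- probs[support == a]
    sum(probs[probs <= pObs * (1 + 1e-7)])
  }
  m <- rbind(c(8, 2), c(1, 5))
  expect_equal(fisherExactRecessive(m), oracleP(m), tolerance = 1e-12)
  expect_equal(fisherExactRecessive(m),
               stats::fisher.test(m)$p.value, tolerance = 1e-9)
  expect_equal(fisherExactRecessive(rbind(c(0, 10), c(0, 10))), 1.0)
  # sweep of random tables up to n = 60
  set.seed(13)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c <- sample(0:(n - a - b), 1); d <- n - a - b - c
    m <- rbind(c(a, b), c(c, d))
    expect_equal(fisherExactRecessive(m), oracleP(m), tolerance = 1e-12)
  }
})

test_that("the published cohort segregates as an autosomal recessive", {
  cohort <- generateStudyCohort(seed = 21, noiseSd = 0)
  rep <- segregationCheck(cohort)
  expect_true(consistentRecessive(rep))
  pb <- perBreed(rep)
  scwt <- pb[pb$breed == "SCWT", ]
  expect_equal(scwt$nAffectedHomAlt, 22L)
  expect_equal(scwt$nControlHet, 15L)
  expect_equal(scwt$nControlHomRef, 667L)
  expect_equal(scwt$alleleFreqControls, 15 / 1364)
  expect_equal(sum(pb$n), 1227L)
  # stratum counts are conserved: affected + control + no-call = stratum n
  # (phenotype "unknown" does not occur in this cohort)
  expect_equal(pb$nAffectedHomAlt + pb$nAffectedOther + pb$nControlHomAlt +
                 pb$nControlHet + pb$nControlHomRef + pb$nNoCall, pb$n)
  expect_lt(fisherP(rep), 1e-10)
  # one affected heterozygote breaks recessive consistency
  broken <- cohort
  i <- which(broken$phenotype == "affected")[1]
  broken$genotype[i] <- "het"
  expect_false(consistentRecessive(segregationCheck(broken)))
  # one unaffected hom-alt breaks it too
  broken2 <- cohort
  j <- which(broken2$phenotype == "unaffected")[1]
  broken2$genotype[j] <- "hom_alt"
  expect_false(consistentRecessive(segregationCheck(broken2)))
})

test_that("segregation input validation catches malformed cohorts", {
  cohort <- generateStudyCohort(seed = 3)
  dup <- rbind(cohort, cohort[1, ])
  expect_error(segregationCheck(dup), "duplicate sampleId")
  bad <- cohort
  bad$genotype[1] <- "homozygote"
  expect_error(segregationCheck(bad), "unknown genotype")
})
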