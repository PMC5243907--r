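#' Call biallelic genotypes from two-channel endpoint fluorescence
#'
#' Endpoint allelic-discrimination data place each sample in the plane of
#' (reference-probe, variant-probe) intensities: pure reference signal
#' lies along the x-axis (hom-ref), pure variant signal along the y-axis
#' (hom-alt), heterozygotes along the diagonal. The caller clusters the
#' polar angle of each amplified sample with a k-means-style iteration
#' seeded at the canonical angles 0, 45 and 90 degrees (k <= 3; empty
#' clusters stay at their seed), which makes calls invariant to uniform
#' scaling of both channels. Samples with total intensity below
#' `minSignalFrac` of the cohort median magnitude (no amplification), or
#' farther than `maxAngleDeg` from every cluster centre, are no-calls.
#'
#' @param records data.frame with columns `sampleId`, `channelRef`
#'   (reference-allele probe intensity, e.g. VIC) and `channelAlt`
#'   (variant-allele probe intensity, e.g. FAM); intensities finite, >= 0.
#' @param minSignalFrac fraction of the median signal magnitude below
#'   which a sample is a no-call (default 0.05).
#' @param maxAngleDeg maximum angular distance (degrees) from the assigned
#'   cluster centre (default 20).
#' @param maxIter k-means iteration cap (default 50).
#' @return data.frame `sampleId`, `genotype` in
#'   hom_ref / het / hom_alt / no_call.
#' @examples
#' callGenotypes(data.frame(sampleId = "s1", channelRef = 1000,
#'                          channelAlt = 10))
#' @export
callGenotypes <- function(records, minSignalFrac = 0.05,
                          maxAngleDeg = 20, maxIter = 50L) {
  stopifnot(nrow(records) >= 1L,
            all(c("sampleId", "channelRef", "channelAlt") %in%
                  names(records)))
  r <- as.numeric(records$channelRef)
  a <- as.numeric(records$channelAlt)
  if (any(!is.finite(r)) || any(!is.finite(a)) || any(r < 0) || any(a < 0))
    stop("intensities must be finite and non-negative")
  mag <- sqrt(r^2 + a^2)
  out <- data.frame(sampleId = records$sampleId,
                    genotype = "no_call", stringsAsFactors = FALSE)
  if (all(mag == 0)) {
    warning("all samples have zero intensity; calling everything no_call")
    return(out)
  }
  ok <- mag > minSignalFrac * median(mag)
  theta <- rep(NA_real_, length(mag))
  theta[ok] <- atan2(a[ok], r[ok]) * 180 / pi
  centers <- c(hom_ref = 0, het = 45, hom_alt = 90)
  seeds <- centers
  assign <- rep(NA_integer_, length(theta))
  for (it in seq_len(maxIter)) {
    d <- abs(outer(theta[ok], centers, "-"))
    newAssign <- max.col(-d, ties.method = "first")
    if (identical(newAssign, assign[ok])) break
    assign[ok] <- newAssign
    for (k in 1:3) {
      members <- theta[ok][assign[ok] == k]
      centers[k] <- if (length(members)) mean(members) else seeds[k]
    }
  }
  gt <- names(seeds)[assign[ok]]
  dist <- abs(theta[ok] - centers[assign[ok]])
  gt[dist > maxAngleDeg] <- "no_call"
  out$genotype[ok] <- gt
  out
}

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "no_call")

#' Tabulate genotypes against phenotypes and check recessive segregation
#'
#' Cross-tabulates genotype by phenotype within each breed stratum and
#' evaluates consistency with autosomal-recessive inheritance: every
#' affected dog homozygous for the variant allele and no unaffected dog
#' homozygous for it. Samples with phenotype "unknown" or genotype
#' "no_call" are excluded from the consistency check and allele
#' frequencies but reported in the stratum table. Control alt-allele
#' frequency is (2 x hom_alt + het) / (2 x called controls), overall and
#' per breed.
#'
#' @param table cohort data.frame with columns `sampleId`, `breed`,
#'   `phenotype` (affected/unaffected/unknown) and `genotype`
#'   (hom_ref/het/hom_alt/no_call).
#' @return a [SegregationReport-class].
#' @export
segregationCheck <- function(table) {
  stopifnot(nrow(table) >= 1L,
            all(c("sampleId", "breed", "phenotype", "genotype") %in%
                  names(table)))
  if (anyDuplicated(table$sampleId))
    stop("duplicate sampleId(s) in cohort table")
  bad <- setdiff(unique(table$genotype), GT_LEVELS)
  if (length(bad)) stop("unknown genotype value(s): ",
                        paste(bad, collapse = ", "))
  breeds <- sort(unique(table$breed))
  rows <- lapply(breeds, function(b) {
    sub <- table[table$breed == b, , drop = FALSE]
    aff <- sub[sub$phenotype == "affected", , drop = FALSE]
    ctl <- sub[sub$phenotype == "unaffected", , drop = FALSE]
    affCalled <- aff[aff$genotype != "no_call", , drop = FALSE]
    ctlCalled <- ctl[ctl$genotype != "no_call", , drop = FALSE]
    nCtlCalled <- nrow(ctlCalled)
    ctlHomAlt <- sum(ctlCalled$genotype == "hom_alt")
    ctlHet <- sum(ctlCalled$genotype == "het")
    data.frame(
      breed = b,
      n = nrow(sub),
      nAffectedHomAlt = sum(affCalled$genotype == "hom_alt"),
      nAffectedOther = sum(affCalled$genotype != "hom_alt"),
      nControlHomAlt = ctlHomAlt,
      nControlHet = ctlHet,
      nControlHomRef = sum(ctlCalled$genotype == "hom_ref"),
      nNoCall = sum(sub$genotype == "no_call"),
      alleleFreqControls = if (nCtlCalled > 0)
        (2 * ctlHomAlt + ctlHet) / (2 * nCtlCalled) else NA_real_,
      stringsAsFactors = FALSE)
  })
  pb <- do.call(rbind, rows)
  consistent <- sum(pb$nAffectedOther) == 0L && sum(pb$nControlHomAlt) == 0L
  ctlAll <- table[table$phenotype == "unaffected" &
                    table$genotype != "no_call", , drop = FALSE]
  afc <- if (nrow(ctlAll) > 0)
    (2 * sum(ctlAll$genotype == "hom_alt") +
       sum(ctlAll$genotype == "het")) / (2 * nrow(ctlAll)) else NA_real_
  p <- tryCatch(fisherExactRecessive(table), error = function(e) NA_real_)
  new("SegregationReport", perBreed = pb,
      consistentRecessive = consistent, fisherP = p,
      alleleFreqControls = afc)
}

#' Two-sided Fisher exact test for recessive association
#'
#' Tests association between affection status and homozygosity for the
#' variant allele: the 2x2 table is (hom_alt vs not hom_alt) x (affected
#' vs unaffected), over samples with called genotypes. The two-sided
#' p-value is computed by enumerating the hypergeometric distribution over
#' all tables with the observed margins and summing the probabilities of
#' tables no more probable than the observed one.
#'
#' @param table either a cohort data.frame (see [segregationCheck()]) or a
#'   2x2 integer matrix `rbind(c(affected hom_alt, affected other),
#'   c(control hom_alt, control other))`.
#' @return two-sided p-value; degenerate margins give 1.
#' @export
fisherExactRecessive <- function(table) {
  if (is.matrix(table)) {
    m <- table
    stopifnot(identical(dim(m), c(2L, 2L)))
  } else {
    called <- table[table$genotype != "no_call" &
                      table$phenotype %in% c("affected", "unaffected"), ,
                    drop = FALSE]
    if (!any(called$phenotype == "affected") ||
        !any(called$phenotype == "unaffected"))
      stop("need at least one called affected and one called control")
    m <- rbind(
      c(sum(called$phenotype == "affected" & called$genotype == "hom_alt"),
        sum(called$phenotype == "affected" & called$genotype != "hom_alt")),
      c(sum(called$phenotype == "unaffected" & called$genotype == "hom_alt"),
        sum(called$phenotype == "unaffected" & called$genotype != "hom_alt")))
  }
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0L || c1 == 0L || r1 == n || c1 == n) return(1)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, n - c1, r1)
  pObs <- dhyper(a, c1, n - c1, r1)
  # standard tolerance for ties in the two-sided sum
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Read a cohort table (genotypes or fluorescence) from TSV
#'
#' Accepts either a `genotype` column or the two fluorescence channel
#' columns `channelRef`/`channelAlt`; in the latter case genotypes are
#' called with [callGenotypes()].
#'
#' @param path TSV path with columns sampleId, breed, phenotype, and
#'   genotype or channelRef + channelAlt.
#' @param ... passed to [callGenotypes()] when calling from fluorescence.
#' @return cohort data.frame with a genotype column.
#' @export
readCohortTable <- function(path, ...) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sampleId", "breed", "phenotype")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  if (!"genotype" %in% names(df)) {
    if (!all(c("channelRef", "channelAlt") %in% names(df)))
      stop("cohort table needs a genotype column or channelRef/channelAlt")
    df$genotype <- callGenotypes(df, ...)$genotype
  }
  df
}
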