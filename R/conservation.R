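#' Residue composition of the focal alignment column
#'
#' Counts residues across species at the focal column of an ortholog
#' alignment; gap characters ("-" or ".") are excluded from the
#' composition and reported separately. Residues are upper-cased;
#' ambiguous residues (e.g. X) count under their own key.
#'
#' @param a an [OrthologAlignment-class].
#' @return list with `counts` (named integer vector, residue -> species
#'   count, decreasing) and `nGaps` (number of gap rows at the column).
#' @examples
#' a <- orthologAlignment(c(sp1 = "MTT", sp2 = "MST"), focalColumn = 2)
#' columnComposition(a)
#' @export
columnComposition <- function(a) {
  n <- length(a@aln)
  if (n == 0L) return(list(counts = integer(0), nGaps = 0L))
  col <- toupper(vapply(seq_len(n), function(i) {
    as.character(Biostrings::subseq(a@aln[[i]], a@focalColumn,
                                    a@focalColumn))
  }, character(1)))
  isGap <- col %in% c("-", ".")
  counts <- table(col[!isGap])
  counts <- sort(setNames(as.integer(counts), names(counts)),
                 decreasing = TRUE)
  list(counts = counts, nGaps = sum(isGap))
}

#' Residues tolerated at the focal position across species
#'
#' Residues observed at least `minCount` times at the focal column are the
#' empirically tolerated states; a variant amino acid outside this set has
#' never been observed in the ortholog panel, evidence that it may impair
#' function (the reasoning that flagged isoleucine at a position where
#' only threonine and serine occur across vertebrates).
#'
#' @param a an [OrthologAlignment-class].
#' @param minCount minimum species count for a residue to qualify
#'   (default 1); the set is monotone non-increasing in `minCount`.
#' @param variantAA optional one-letter variant residue; when given, the
#'   result carries an attribute `variantObserved` (logical).
#' @return character vector of tolerated residues (decreasing count).
#' @export
toleratedStates <- function(a, minCount = 1L, variantAA = NULL) {
  if (minCount < 1L) stop("minCount must be >= 1")
  comp <- columnComposition(a)
  states <- names(comp$counts)[comp$counts >= minCount]
  if (!is.null(variantAA))
    attr(states, "variantObserved") <- toupper(variantAA) %in% states
  states
}

#' Read an aligned residue FASTA as an OrthologAlignment
#' @param path aligned protein FASTA path.
#' @param focalColumn 1-based focal alignment column.
#' @return an [OrthologAlignment-class].
#' @export
readOrthologAlignment <- function(path, focalColumn) {
  orthologAlignment(Biostrings::readAAStringSet(path), focalColumn)
}
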