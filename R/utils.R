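#' @import methods
#' @importFrom stats rnorm rpois runif setNames dhyper median
#' @importFrom utils read.delim write.table head
NULL

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#'
#' Thin wrapper used on plain character alleles; full sequences go through
#' [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revComp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical identity key for a variant
#'
#' Variants are keyed by (contig, pos, ref, alt) after decomposition and
#' left-normalisation; the key is the join of the four fields. Two variants
#' are the same observation if and only if their keys are equal.
#'
#' @param contig contig name(s), or a variant table (data.frame with columns
#'   `contig`, `pos`, `ref`, `alt`) in which case the other arguments are
#'   ignored.
#' @param pos 1-based genomic position(s).
#' @param ref,alt allele strings.
#' @return character vector of keys.
#' @export
variantKey <- function(contig, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(contig)) {
    vt <- contig
    return(paste(vt$contig, vt$pos, vt$ref, vt$alt, sep = ":"))
  }
  paste(contig, pos, ref, alt, sep = ":")
}

#' Construct a variant table
#'
#' The package represents variants as plain data.frames with columns
#' `contig`, `pos` (1-based), `ref` and `alt`; this constructor validates
#' and (optionally) checks ref alleles against a reference assembly.
#'
#' @param contig,pos,ref,alt vectors of equal length (recycled per base R).
#' @param assembly optional [Biostrings::DNAStringSet] reference; when given,
#'   every ref allele is checked against the assembly sequence at its
#'   position and a mismatch is an error.
#' @return data.frame with columns contig, pos, ref, alt.
#' @examples
#' variantTable("chr1", 498, "C", "T")
#' @export
variantTable <- function(contig, pos, ref, alt, assembly = NULL) {
  vt <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   stringsAsFactors = FALSE)
  bad <- vt$ref == vt$alt
  if (any(bad))
    stop("ref equals alt for variant(s): ",
         paste(variantKey(vt)[bad], collapse = ", "))
  if (any(!grepl("^[ACGTN]+$", vt$ref)) || any(!grepl("^[ACGTN]+$", vt$alt)))
    stop("alleles must be non-empty strings over A,C,G,T,N")
  if (!is.null(assembly)) checkRefAlleles(vt, assembly)
  vt
}

#' Check variant ref alleles against an assembly
#' @param vt variant table.
#' @param assembly named [Biostrings::DNAStringSet].
#' @return invisibly TRUE; errors on any mismatch or unknown contig.
#' @keywords internal
checkRefAlleles <- function(vt, assembly) {
  if (nrow(vt) == 0) return(invisible(TRUE))
  unknown <- setdiff(unique(vt$contig), names(assembly))
  if (length(unknown))
    stop("unknown contig(s): ", paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(vt))) {
    len <- nchar(vt$ref[i])
    seqlen <- Biostrings::width(assembly[vt$contig[i]])
    if (vt$pos[i] < 1L || vt$pos[i] + len - 1L > seqlen)
      stop("variant ", variantKey(vt[i, ]), " out of contig bounds")
    obs <- as.character(Biostrings::subseq(assembly[[vt$contig[i]]],
                                           vt$pos[i], vt$pos[i] + len - 1L))
    if (obs != vt$ref[i])
      stop("ref mismatch at ", variantKey(vt[i, ]),
           ": assembly has ", obs)
  }
  invisible(TRUE)
}

#' Left-normalise variants
#'
#' Trims shared trailing bases, then shared leading bases, keeping one
#' anchor base for indels (VCF convention). Substitutions with equal-length
#' alleles are trimmed to their minimal differing core.
#'
#' @param vt variant table.
#' @return variant table with normalised pos/ref/alt.
#' @examples
#' normalizeVariants(data.frame(contig = "c", pos = 10,
#'                              ref = "CAG", alt = "CG"))  # -> pos 10, CA > C
#' @export
normalizeVariants <- function(vt) {
  for (i in seq_len(nrow(vt))) {
    ref <- strsplit(vt$ref[i], "", fixed = TRUE)[[1]]
    alt <- strsplit(vt$alt[i], "", fixed = TRUE)[[1]]
    # trim common suffix, keeping at least one base each
    while (length(ref) > 1L && length(alt) > 1L &&
           ref[length(ref)] == alt[length(alt)]) {
      ref <- ref[-length(ref)]
      alt <- alt[-length(alt)]
    }
    # trim common prefix; keep an anchor base when lengths differ
    minKeep <- if (length(ref) == length(alt)) 1L else 2L
    while (length(ref) >= minKeep && length(alt) >= minKeep &&
           length(ref) > 1L && length(alt) > 1L && ref[1L] == alt[1L]) {
      ref <- ref[-1L]; alt <- alt[-1L]
      vt$pos[i] <- vt$pos[i] + 1L
    }
    # pure substitution: drop a remaining shared leading base
    if (length(ref) == length(alt) && length(ref) > 1L && ref[1L] == alt[1L]) {
      ref <- ref[-1L]; alt <- alt[-1L]
      vt$pos[i] <- vt$pos[i] + 1L
    }
    vt$ref[i] <- paste(ref, collapse = "")
    vt$alt[i] <- paste(alt, collapse = "")
  }
  vt
}

#' Format numbers for reports with stable precision
#' @keywords internal
fmtNum <- function(x) formatC(x, digits = 6, format = "g")
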