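# Pairwise alignment and percent identity. Needleman-Wunsch / Smith-Waterman
# are delegated to Biostrings::pairwiseAlignment; identity is always
# matches / alignment columns (gaps count as columns).

alignScores <- function(match = 1, mismatch = -1, gapOpening = 2, gapExtension = 1) {
  list(match = match, mismatch = mismatch,
       gapOpening = gapOpening, gapExtension = gapExtension)
}

# One pairwise alignment with the package's default DNA scoring.
alignPair <- function(a, b, type = c("global", "local"),
                      scores = alignScores(), protein = FALSE,
                      substitutionMatrix = NULL) {
  type <- match.arg(type)
  if (is.null(substitutionMatrix)) {
    substitutionMatrix <- if (protein) {
      m <- outer(names(KYTE_DOOLITTLE), names(KYTE_DOOLITTLE),
                 function(x, y) ifelse(x == y, scores$match, scores$mismatch))
      dimnames(m) <- list(names(KYTE_DOOLITTLE), names(KYTE_DOOLITTLE))
      m
    } else {
      nucleotideSubstitutionMatrix(match = scores$match,
                                   mismatch = scores$mismatch, baseOnly = FALSE)
    }
  }
  if (protein) {
    a <- AAString(a); b <- AAString(b)
  } else {
    a <- DNAString(a); b <- DNAString(b)
  }
  pairwiseAlignment(a, b, type = type,
                    substitutionMatrix = substitutionMatrix,
                    gapOpening = scores$gapOpening,
                    gapExtension = scores$gapExtension)
}

# Identity as matches / alignment columns, with terminal gap columns
# counted (pid()/nchar() on PairwiseAlignments exclude them).
alnIdentity <- function(aln) {
  p <- chars(as.character(alignedPattern(aln)))
  s <- chars(as.character(alignedSubject(aln)))
  matches <- sum(p == s & p != "-")
  list(identity = 100 * matches / length(p), columns = length(p))
}

#' Percent identity between two sequences
#'
#' Aligns two sequences by Needleman-Wunsch (\code{mode = "global"}) or
#' Smith-Waterman (\code{mode = "local"}) with match +1, mismatch -1, gap
#' open -2, gap extend -1 by default, and reports identity as
#' matches / alignment columns x 100 (gap columns count).
#'
#' @param seqA,seqB non-empty sequences (character or \code{XString}).
#' @param mode \code{"global"} or \code{"local"}.
#' @param scores list from \code{alignScores()}; override to change the
#'   scoring scheme.
#' @param protein logical; align as amino-acid sequences.
#' @return List with \code{identity} (percent), \code{alignedLength}
#'   (columns) and \code{score}.
#' @examples
#' regionIdentity("ACGT", "ACGA")$identity  # 75
#' @export
regionIdentity <- function(seqA, seqB, mode = c("global", "local"),
                           scores = alignScores(), protein = FALSE) {
  mode <- match.arg(mode)
  seqA <- asSeqChar(seqA); seqB <- asSeqChar(seqB)
  stopifnotScalarSeq(seqA, "seqA"); stopifnotScalarSeq(seqB, "seqB")
  aln <- alignPair(seqA, seqB, type = mode, scores = scores, protein = protein)
  ai <- alnIdentity(aln)
  list(identity = ai$identity,
       alignedLength = ai$columns,
       score = as.numeric(BiocGenerics::score(aln)))
}
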