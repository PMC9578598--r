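# Tandem-repeat analysis of PTS/VNTR exons: dot-plot self comparison,
# autocorrelation period detection, decomposition into period-length units
# with perfect/imperfect classification, and consensus/PFM summaries.

#' Exact word-match dot plot
#'
#' All positions (i, j) where the length-\code{word} substrings of the two
#' sequences agree exactly (word hashing, GEPARD-style). For nucleotide
#' sequences the reverse-complement orientation can be added.
#'
#' @param seqA,seqB sequences (character or \code{XString}).
#' @param word word length (>= 3, at most the shorter sequence length).
#' @param revcompToo also report matches of \code{seqA} words against the
#'   reverse complement of \code{seqB} (nucleotide only); these carry
#'   \code{orientation = "-"}.
#' @return List of class \code{"DotPlot"}: \code{word}, \code{lenA},
#'   \code{lenB} and \code{matches}, a data.frame of 1-based word start
#'   positions \code{i} (in A), \code{j} (in B) and \code{orientation}.
#' @examples
#' dotPlot("ABCABC", "ABCABC", word = 3)$matches
#' @export
dotPlot <- function(seqA, seqB, word, revcompToo = FALSE) {
  seqA <- asSeqChar(seqA); seqB <- asSeqChar(seqB)
  word <- as.integer(word)
  if (word < 3L) stop("word must be >= 3")
  if (word > min(nchar(seqA), nchar(seqB)))
    stop("word exceeds a sequence length")
  matchWords <- function(b, orient) {
    kb <- kmersOf(b, word)
    idx <- split(seq_along(kb), kb)
    ka <- kmersOf(seqA, word)
    hit <- ka %in% names(idx)
    if (!any(hit)) return(NULL)
    js <- idx[ka[hit]]
    data.frame(i = rep(which(hit), lengths(js)),
               j = unlist(js, use.names = FALSE),
               orientation = orient)
  }
  m <- matchWords(seqB, "+")
  if (revcompToo) m <- rbind(m, matchWords(revComp(seqB), "-"))
  if (is.null(m)) m <- data.frame(i = integer(0), j = integer(0),
                                  orientation = character(0))
  structure(list(word = word, lenA = nchar(seqA), lenB = nchar(seqB),
                 matches = m[order(m$i, m$j), , drop = FALSE]),
            class = "DotPlot")
}

#' Detect the repeat period of a sequence by autocorrelation
#'
#' Scores each lag \code{p} by \code{A(p)}, the fraction of positions
#' \code{i} with \code{seq[i] == seq[i + p]}. Among lags scoring at least
#' 95\% of the maximum, the smallest is returned, which suppresses the
#' harmonics at 2p, 3p, ... Returns \code{NA} when even the best lag scores
#' below 0.5 (no tandem structure).
#'
#' @param seq protein or nucleotide string.
#' @param minP,maxP lag range; \code{2 <= minP <= maxP <= nchar(seq) / 2}.
#' @return Integer period, or \code{NA_integer_}.
#' @examples
#' detectPeriod(strrep("ITTTETTSHSTPSFTSS", 10))  # 17
#' @export
detectPeriod <- function(seq, minP = 2L, maxP = nchar(asSeqChar(seq)) %/% 2L) {
  seq <- asSeqChar(seq)
  stopifnotScalarSeq(seq)
  n <- nchar(seq)
  minP <- as.integer(minP); maxP <- as.integer(maxP)
  if (minP < 2L || minP > maxP || maxP > n %/% 2L)
    stop("need 2 <= minP <= maxP <= floor(length / 2)")
  x <- chars(seq)
  lags <- minP:maxP
  A <- vapply(lags, function(p) mean(x[seq_len(n - p)] == x[(p + 1L):n]),
              numeric(1))
  if (max(A) < 0.5) return(NA_integer_)
  lags[which(A >= 0.95 * max(A))][1L]
}

majorityConsensus <- function(charMat) {
  # rows = positions, cols = units; ties -> lexicographically smallest
  apply(charMat, 1L, function(r) names(which.max(table(r))))
}

#' Decompose a tandem array into period-length units
#'
#' Cuts the sequence into consecutive non-overlapping windows of length
#' \code{period}, choosing the cutting phase that maximizes the number of
#' units matching a provisional consensus (majority consensus of the phase-0
#' cut) at \code{perfectMinIdentity}; the array is then re-cut at that phase.
#' A unit is \emph{perfect} iff it has exact unit length and at least
#' \code{perfectMinIdentity}\% positional identity to the consensus,
#' \emph{imperfect} otherwise. The final consensus and position-frequency
#' matrix are computed over the perfect units (over all units when none is
#' perfect). Sequence outside complete units is returned in the flanks, so
#' the decomposition reconstructs its input exactly.
#'
#' @param seq the array (protein or nucleotide string).
#' @param period unit length; when \code{NULL} it is detected with
#'   \code{\link{detectPeriod}}.
#' @param perfectMinIdentity percent identity to the consensus at or above
#'   which an exact-length unit is called perfect (default 70).
#' @param minP,maxP period search range, passed to \code{\link{detectPeriod}}
#'   when \code{period} is \code{NULL}.
#' @return A \code{\linkS4class{RepeatDecomposition}}.
#' @examples
#' d <- decomposeArray(strrep("ITTTETTSHSTPSFTSS", 8), period = 17)
#' nPerfect(d)
#' @export
decomposeArray <- function(seq, period = NULL, perfectMinIdentity = 70,
                           minP = 2L, maxP = nchar(asSeqChar(seq)) %/% 2L) {
  seq <- asSeqChar(seq)
  stopifnotScalarSeq(seq)
  if (is.null(period)) {
    period <- detectPeriod(seq, minP, maxP)
    if (is.na(period)) stop("not a tandem array: no period detected")
  }
  period <- as.integer(period)
  n <- nchar(seq)
  if (n < 2L * period) stop("not a tandem array: fewer than 2 complete units")
  cutAt <- function(phase) {
    starts <- seq.int(phase + 1L, n - period + 1L, by = period)
    substring(seq, starts, starts + period - 1L)
  }
  unitMat <- function(units) {
    matrix(unlist(strsplit(units, "", fixed = TRUE)), nrow = period)
  }
  identityTo <- function(units, consensus) {
    100 * colMeans(unitMat(units) == consensus)
  }
  provisional <- majorityConsensus(unitMat(cutAt(0L)))
  nGood <- vapply(0:(period - 1L), function(ph) {
    u <- cutAt(ph)
    if (length(u) < 2L) return(-1L)
    sum(identityTo(u, provisional) >= perfectMinIdentity)
  }, numeric(1))
  phase <- which.max(nGood) - 1L
  units <- cutAt(phase)
  starts <- seq.int(phase + 1L, n - period + 1L, by = period)
  # classify against the consensus of this cut, then finalize the consensus
  # over the perfect units and report identities against it
  consAll <- majorityConsensus(unitMat(units))
  perfect <- identityTo(units, consAll) >= perfectMinIdentity
  base <- if (any(perfect)) units[perfect] else units
  consFinal <- majorityConsensus(unitMat(base))
  ident <- identityTo(units, consFinal)
  perfect <- ident >= perfectMinIdentity
  pfmBase <- unitMat(if (any(perfect)) units[perfect] else units)
  alphabet <- sort(unique(as.vector(pfmBase)))
  pfm <- vapply(seq_len(period), function(p) {
    tab <- table(factor(pfmBase[p, ], levels = alphabet))
    as.numeric(tab) / sum(tab)
  }, numeric(length(alphabet)))
  rownames(pfm) <- alphabet
  colnames(pfm) <- seq_len(period)
  new("RepeatDecomposition",
      period = period,
      units = data.frame(start = starts, end = starts + period - 1L,
                         seq = units, identity = ident, perfect = perfect),
      consensus = collapse0(consFinal),
      pfm = pfm,
      leadingFlank = substr(seq, 1L, phase),
      trailingFlank = substr(seq, starts[length(starts)] + period, n))
}

#' Compare two repeat decompositions (expansion report)
#'
#' @param decompA,decompB \code{\linkS4class{RepeatDecomposition}} objects
#'   sharing one period.
#' @return List with \code{unitCountDelta}, \code{perfectCountDelta} and
#'   \code{imperfectLengthDelta} (residues), each as B minus A.
#' @export
compareRepeatExpansion <- function(decompA, decompB) {
  if (repeatPeriod(decompA) != repeatPeriod(decompB))
    stop("decompositions have different periods")
  impLen <- function(d) sum(nchar(repeatUnits(d)$seq[!repeatUnits(d)$perfect]))
  list(unitCountDelta = nrow(repeatUnits(decompB)) - nrow(repeatUnits(decompA)),
       perfectCountDelta = nPerfect(decompB) - nPerfect(decompA),
       imperfectLengthDelta = impLen(decompB) - impLen(decompA))
}
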