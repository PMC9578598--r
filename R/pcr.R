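# In-silico PCR: primer-site scanning with IUPAC-aware mismatch counting,
# amplicon prediction, restriction digestion and fragment-pattern
# discrimination of near-identical transcripts.

#' PstI restriction enzyme definition
#'
#' Recognition site CTGCAG, top-strand cut after position 5 (CTGCA^G).
#' @format List with \code{name}, \code{site}, \code{cutOffset}.
#' @export
pstI <- list(name = "PstI", site = "CTGCAG", cutOffset = 5L)

#' Published MUC3A/MUC3B-specific RT-qPCR primers
#'
#' The gene-specific primer pairs targeting exons 3 and 8 of the human
#' MUC3A and MUC3B transcripts (5' to 3'; the reverse primers are the
#' minus-strand sequences, bench convention).
#'
#' @return Nested list \code{$MUC3A$fwd/rev}, \code{$MUC3B$fwd/rev}.
#' @export
muc3Primers <- function() {
  list(MUC3A = list(fwd = "TGGGGGTCAGTGGGATGGCCTCAAA",
                    rev = "CACGTGGGACCGCTCGTCTCC"),
       MUC3B = list(fwd = "CGGGGGCCAGTGGGATGGCCTCAAG",
                    rev = "CACGCGGGACCGCTCGTCTCT"))
}

#' Percent mismatch between two equal-length primers
#'
#' Position-wise mismatch count divided by length, in percent (1 decimal).
#'
#' @param primerA,primerB primer sequences of equal length.
#' @return Numeric percent mismatch.
#' @examples
#' p <- muc3Primers()
#' primerPairMismatch(p$MUC3A$fwd, p$MUC3B$fwd)  # 12.0
#' @export
primerPairMismatch <- function(primerA, primerB) {
  primerA <- asSeqChar(primerA); primerB <- asSeqChar(primerB)
  if (nchar(primerA) != nchar(primerB)) stop("primers differ in length")
  mm <- sum(chars(primerA) != chars(primerB))
  round(100 * mm / nchar(primerA), 1)
}

# Mismatch count of `primer` (IUPAC allowed) against every template offset.
# Template bases outside {A,C,G,T} (e.g. assembly N) never match.
primerMismatchProfile <- function(template, primer) {
  p <- nchar(primer)
  n <- nchar(template)
  if (n < p) return(integer(0))
  tcode <- match(chars(template), c("A", "C", "G", "T"))
  tcode[is.na(tcode)] <- 5L
  pc <- chars(primer)
  if (!all(pc %in% names(IUPAC_SETS))) stop("primer contains non-IUPAC characters")
  allowed <- matrix(FALSE, nrow = p, ncol = 5L)
  for (i in seq_len(p))
    allowed[i, match(IUPAC_SETS[[pc[i]]], c("A", "C", "G", "T"))] <- TRUE
  nOff <- n - p + 1L
  mm <- integer(nOff)
  for (i in seq_len(p))
    mm <- mm + !allowed[i, tcode[i:(i + nOff - 1L)]]
  mm
}

#' Find primer binding sites on a template
#'
#' Scans every offset on both strands (the reverse strand is scanned with
#' the reverse complement of the primer), counting mismatches with IUPAC
#' classes in the primer matching their base sets. With
#' \code{require3primeMatch} (default), the primer's 3'-terminal base must
#' match exactly, reflecting polymerase extension chemistry.
#'
#' @param template template sequence.
#' @param primer primer (5' to 3'; IUPAC allowed, >= 15 nt).
#' @param maxMm maximum mismatches (default 3).
#' @param require3primeMatch logical (default \code{TRUE}).
#' @return data.frame with \code{start}, \code{end} (1-based closed
#'   template interval), \code{strand}, \code{mismatches}, sorted by
#'   \code{start}.
#' @export
findPrimerSites <- function(template, primer, maxMm = 3L,
                            require3primeMatch = TRUE) {
  template <- asSeqChar(template); primer <- asSeqChar(primer)
  if (nchar(primer) < 15L) stop("primer must be >= 15 nt")
  if (nchar(template) < nchar(primer)) stop("template shorter than primer")
  p <- nchar(primer)
  out <- list()
  for (str in c("+", "-")) {
    q <- if (str == "+") primer else revComp(primer)
    mm <- primerMismatchProfile(template, q)
    hit <- which(mm <= maxMm)
    if (require3primeMatch && length(hit)) {
      # 3'-terminal primer base: last position on '+', first on '-'
      i3 <- if (str == "+") p else 1L
      exact3 <- vapply(hit, function(o) {
        base <- substr(template, o + i3 - 1L, o + i3 - 1L)
        base %in% IUPAC_SETS[[substr(q, i3, i3)]]
      }, logical(1))
      hit <- hit[exact3]
    }
    if (length(hit))
      out[[str]] <- data.frame(start = hit, end = hit + p - 1L,
                               strand = str, mismatches = mm[hit])
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict the PCR amplicon of a primer pair on a template
#'
#' Takes the leftmost forward-strand site of the forward primer and the
#' nearest downstream minus-strand site of the reverse primer whose end
#' yields an amplicon of at most \code{maxLen} bp. The amplicon spans from
#' the forward-site start to the reverse-site end, both primers included.
#' When \code{enzyme} is given, the amplicon is digested and the fragment
#' lengths recorded.
#'
#' @param template template sequence.
#' @param fwd,rev forward and reverse primers (5' to 3').
#' @param maxMm maximum mismatches per site (default 3).
#' @param maxLen maximum amplicon length (default 5000).
#' @param enzyme optional enzyme definition (e.g. \code{pstI}).
#' @param templateId label for the template.
#' @param require3primeMatch passed to \code{\link{findPrimerSites}}.
#' @return An \code{\linkS4class{AmpliconPrediction}}, or \code{NULL} when
#'   no compatible site pair exists.
#' @export
predictAmplicon <- function(template, fwd, rev, maxMm = 3L, maxLen = 5000L,
                            enzyme = NULL, templateId = "template",
                            require3primeMatch = TRUE) {
  template <- asSeqChar(template)
  fs <- findPrimerSites(template, fwd, maxMm, require3primeMatch)
  fs <- fs[fs$strand == "+", , drop = FALSE]
  if (nrow(fs) == 0L) return(NULL)
  f <- fs[1L, ]  # leftmost
  rs <- findPrimerSites(template, rev, maxMm, require3primeMatch)
  rs <- rs[rs$strand == "-" & rs$start > f$end &
             rs$end - f$start + 1L <= maxLen, , drop = FALSE]
  if (nrow(rs) == 0L) return(NULL)
  r <- rs[1L, ]  # nearest downstream
  len <- r$end - f$start + 1L
  frags <- if (is.null(enzyme)) len else
    digestSequence(substring(template, f$start, r$end), enzyme)
  new("AmpliconPrediction", templateId = templateId,
      fwdSite = as.integer(c(f$start, f$end, f$mismatches)),
      revSite = as.integer(c(r$start, r$end, r$mismatches)),
      amplicon = as.integer(c(f$start, r$end)),
      length = as.integer(len), fragments = as.integer(frags))
}

#' Digest a linear sequence with a restriction enzyme
#'
#' Cuts after \code{cutOffset} bases within each occurrence of the
#' IUPAC-expanded recognition site, scanning leftmost-first and skipping
#' overlapping occurrences. A sequence without sites yields one fragment.
#'
#' @param seq linear sequence.
#' @param enzyme list with \code{site} and \code{cutOffset} (e.g.
#'   \code{pstI}).
#' @return Integer vector of fragment lengths in template order (sums to
#'   \code{nchar(seq)}).
#' @examples
#' digestSequence("AAACTGCAGTT", pstI)  # 8 3
#' @export
digestSequence <- function(seq, enzyme) {
  seq <- asSeqChar(seq)
  site <- asSeqChar(enzyme$site)
  co <- as.integer(enzyme$cutOffset)
  if (co <= 0L || co >= nchar(site)) stop("cutOffset must lie inside the site")
  n <- nchar(seq)
  if (n < nchar(site)) return(n)
  mm <- primerMismatchProfile(seq, site)
  pos <- which(mm == 0L)
  if (length(pos) > 1L) {  # leftmost-first, non-overlapping
    kept <- pos[1L]
    for (q in pos[-1L]) if (q >= kept[length(kept)] + nchar(site)) kept <- c(kept, q)
    pos <- kept
  }
  if (!length(pos)) return(n)
  cuts <- pos + co - 1L
  diff(c(0L, cuts, n))
}

#' Discriminate templates by restriction fragment pattern
#'
#' Compares an observed fragment multiset against labelled expected
#' patterns; fragments match within \code{tolBp} each (after sorting).
#' Exactly one matching signature gives its label; zero or several give
#' \code{"inconclusive"}.
#'
#' @param fragments observed fragment lengths.
#' @param signatures named list of expected fragment-length vectors.
#' @param tolBp per-fragment tolerance in bp (default 5).
#' @return A signature label or \code{"inconclusive"}.
#' @examples
#' discriminateFragments(c(380, 266),
#'                       list(cut = c(380, 266), uncut = 646))  # "cut"
#' @export
discriminateFragments <- function(fragments, signatures, tolBp = 5L) {
  if (length(signatures) == 0L) stop("empty signature set")
  obs <- sort(as.numeric(fragments))
  hits <- vapply(signatures, function(sig) {
    sig <- sort(as.numeric(sig))
    length(sig) == length(obs) && all(abs(sig - obs) <= tolBp)
  }, logical(1))
  if (sum(hits) == 1L) names(signatures)[hits] else "inconclusive"
}
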