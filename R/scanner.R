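# Criteria-based mucin gene detection in a marker-anchored genomic interval:
# (1) an ATG start codon, (2) a long PTS-encoding segment, (3) a SEA-domain
# hit downstream of it, (4) unique (non-duplicate) flanking sequence.
# TM/PDZ C-terminal features are annotated but do not gate.

#' Locate a marker gene on a contig
#'
#' Seeds with exact 15-mers (via \code{matchPDict}), estimates the placement
#' from the modal seed diagonal, and refines with a bounded Smith-Waterman
#' alignment of the marker against the candidate window. Ties are broken
#' toward the lower start coordinate.
#'
#' @param contig contig sequence (character or \code{DNAString}).
#' @param markerSeq marker gene sequence (>= 30 nt).
#' @param minIdentity minimum percent identity for a successful placement
#'   (default 80).
#' @param k seed word size (default 15).
#' @return List of class \code{"MarkerAnchor"}: \code{start}, \code{end}
#'   (1-based, closed), \code{identity}.
#' @export
locateMarker <- function(contig, markerSeq, minIdentity = 80, k = 15L) {
  contig <- asSeqChar(contig); markerSeq <- asSeqChar(markerSeq)
  if (nchar(markerSeq) < 30L) stop("markerSeq must be >= 30 nt")
  seeds <- kmersOf(markerSeq, k)
  hits <- Biostrings::matchPDict(Biostrings::PDict(DNAStringSet(seeds)),
                                 DNAString(contig))
  qidx <- rep(seq_along(hits), lengths(hits))
  sstart <- unlist(lapply(hits, start), use.names = FALSE)
  if (length(sstart) == 0L) stop("marker not found: no seed hit")
  diagOffset <- sstart - qidx  # contig start of a perfectly placed marker - 1
  tab <- table(diagOffset)
  best <- as.integer(names(tab)[tab == max(tab)])
  d <- min(best)
  L <- nchar(markerSeq)
  lo <- max(1L, d + 1L - ceiling(0.2 * L))
  hi <- min(nchar(contig), d + L + ceiling(0.2 * L))
  aln <- alignPair(markerSeq, substring(contig, lo, hi), type = "local")
  identity <- alnIdentity(aln)$identity
  if (identity < minIdentity)
    stop(sprintf("marker not found: best identity %.1f below %.1f",
                 identity, minIdentity))
  sub <- aln@subject@range
  structure(list(start = lo + start(sub) - 1L, end = lo + end(sub) - 1L,
                 identity = identity), class = "MarkerAnchor")
}

#' Find ATG-initiated open reading frames
#'
#' Reports every ORF that starts at an ATG and ends at the first in-frame
#' stop codon (the stop is part of the ORF), on both strands, with length
#' at least \code{minLenNt}. Coordinates are 1-based closed positions on the
#' input sequence; minus-strand ORFs are reported in input coordinates with
#' \code{strand == "-"}.
#'
#' @param seq nucleotide string.
#' @param minLenNt minimum ORF length in nt (>= 30, multiple of 3).
#' @return data.frame with \code{start}, \code{end}, \code{frame} (0-2 on
#'   the scanned strand) and \code{strand}, sorted by \code{start}.
#' @examples
#' findOrfs("ATGAAATAG", minLenNt = 9)
#' @export
findOrfs <- function(seq, minLenNt = 300L) {
  seq <- asSeqChar(seq)
  minLenNt <- as.integer(minLenNt)
  if (minLenNt < 30L || minLenNt %% 3L != 0L)
    stop("minLenNt must be >= 30 and a multiple of 3")
  scanStrand <- function(s, strandLab) {
    n <- nchar(s)
    out <- list()
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 2L) next
      starts <- f + 3L * (seq_len(ncod) - 1L) + 1L
      cod <- substring(s, starts, starts + 2L)
      atg <- which(cod == "ATG")
      stp <- which(cod %in% STOP_CODONS)
      if (!length(atg) || !length(stp)) next
      nxt <- stp[findInterval(atg, stp) + 1L]
      keep <- !is.na(nxt)
      atg <- atg[keep]; nxt <- nxt[keep]
      lenNt <- 3L * (nxt - atg + 1L)
      keep <- lenNt >= minLenNt
      if (!any(keep)) next
      a <- starts[atg[keep]]
      b <- starts[nxt[keep]] + 2L
      if (strandLab == "-") {
        tmp <- n - b + 1L
        b <- n - a + 1L
        a <- tmp
      }
      out[[length(out) + 1L]] <- data.frame(start = a, end = b, frame = f,
                                            strand = strandLab)
    }
    out
  }
  res <- c(scanStrand(seq, "+"), scanStrand(revComp(seq), "-"))
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), strand = character(0)))
  res <- do.call(rbind, res)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a protein for PTS-rich segments
#'
#' Slides a window over the protein, computes the proline/threonine/serine
#' fraction, and merges maximal runs of windows at or above \code{minFrac}
#' into segments (a run of windows starting at i1..i2 covers residues i1 to
#' i2 + window - 1).
#'
#' @param protein protein string.
#' @param window window size in residues (>= 10; default 100).
#' @param minFrac minimum windowed P/T/S fraction (default 0.4).
#' @return data.frame with \code{start}, \code{end} (residues, 1-based
#'   closed) and \code{fraction} (overall P/T/S fraction of the segment).
#'   Empty when the protein is shorter than the window.
#' @export
ptsScan <- function(protein, window = 100L, minFrac = 0.4) {
  protein <- asSeqChar(protein)
  window <- as.integer(window)
  if (window < 10L) stop("window must be >= 10")
  if (minFrac <= 0 || minFrac > 1) stop("minFrac must lie in (0, 1]")
  empty <- data.frame(start = integer(0), end = integer(0), fraction = numeric(0))
  n <- nchar(protein)
  if (n < window) return(empty)
  ind <- as.integer(chars(protein) %in% c("P", "T", "S"))
  cs <- c(0L, cumsum(ind))
  frac <- (cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]) / window
  good <- frac >= minFrac
  if (!any(good)) return(empty)
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i1 <- starts[r$values]; i2 <- ends[r$values]
  segEnd <- i2 + window - 1L
  data.frame(start = i1, end = segEnd,
             fraction = (cs[segEnd + 1L] - cs[i1]) / (segEnd - i1 + 1L))
}

#' Detect a SEA-domain-like segment by local protein alignment
#'
#' Aligns each reference SEA sequence against the protein with
#' Smith-Waterman under BLOSUM62 (gap open 10, extend 1) and reports the
#' best-scoring hit, provided it reaches \code{minIdentity}\% over at least
#' \code{minLen} alignment columns.
#'
#' @param protein protein string.
#' @param seaRefs character vector of reference SEA domain sequences.
#' @param minIdentity minimum percent identity (default 30).
#' @param minLen minimum alignment columns (default 80).
#' @param gapOpening,gapExtension gap penalties for the local alignment.
#' @return List with \code{ref} (index), \code{identity},
#'   \code{alignedLength}, \code{start}, \code{end} (on the protein) and
#'   \code{score}, or \code{NULL} when nothing passes.
#' @export
detectSea <- function(protein, seaRefs = SEA_REF_SYNTHETIC, minIdentity = 30,
                      minLen = 80L, gapOpening = 10, gapExtension = 1) {
  protein <- asSeqChar(protein)
  if (length(seaRefs) == 0L) stop("empty SEA reference set")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  best <- NULL
  for (i in seq_along(seaRefs)) {
    aln <- pairwiseAlignment(AAString(asSeqChar(seaRefs[[i]])), AAString(protein),
                             type = "local", substitutionMatrix = BLOSUM62,
                             gapOpening = gapOpening, gapExtension = gapExtension)
    sc <- as.numeric(BiocGenerics::score(aln))
    if (is.null(best) || sc > best$score) {
      sub <- aln@subject@range
      ai <- alnIdentity(aln)
      best <- list(ref = i, identity = ai$identity,
                   alignedLength = ai$columns,
                   start = start(sub), end = end(sub), score = sc)
    }
  }
  if (best$identity >= minIdentity && best$alignedLength >= minLen) best else NULL
}

#' Detect C-terminal membrane-mucin features (TM segment, PDZ motif)
#'
#' The transmembrane segment is the best (leftmost on ties) 19-residue
#' window with mean Kyte-Doolittle hydropathy >= 1.6. The Class I
#' PDZ-binding motif is the C-terminal tripeptide [S/T]-X-Phi with
#' Phi in {L, I, V, F, M}.
#'
#' @param protein protein string (>= 25 residues).
#' @param tmWindow TM window size (default 19).
#' @param tmThreshold mean hydropathy threshold (default 1.6).
#' @return List with \code{tm} (c(start, end) or \code{NULL}),
#'   \code{tmHydropathy} (mean score of that window, or \code{NA}) and
#'   \code{pdz} (logical).
#' @export
detectCtermFeatures <- function(protein, tmWindow = 19L, tmThreshold = 1.6) {
  protein <- asSeqChar(protein)
  n <- nchar(protein)
  if (n < 25L) stop("protein must be >= 25 residues")
  h <- KYTE_DOOLITTLE[chars(protein)]
  h[is.na(h)] <- -4.5  # unknown residues / stops treated maximally hydrophilic
  cs <- c(0, cumsum(h))
  m <- (cs[(tmWindow + 1L):(n + 1L)] - cs[seq_len(n - tmWindow + 1L)]) / tmWindow
  tm <- NULL; tmH <- NA_real_
  if (max(m) >= tmThreshold) {
    i <- which(m == max(m))[1L]
    tm <- c(start = i, end = i + tmWindow - 1L)
    tmH <- m[i]
  }
  pdz <- grepl("[ST].[LIVFM]$", protein)
  list(tm = tm, tmHydropathy = tmH, pdz = pdz)
}

defaultScanParams <- function() {
  list(minPtsNt = 1000L, ptsWindow = 100L, ptsMinFrac = 0.4,
       ptsRefineFrac = 0.7, ptsMaxPeriod = 100L,
       seaRefs = SEA_REF_SYNTHETIC, seaMinIdentity = 30, seaMinLen = 80L,
       maxUpstreamNt = 9000L, startStopPenalty = 150L,
       ctermWindowNt = 9000L, mergeIdentity = 95)
}

# Snap density-refined bounds onto the tandem structure: detect the repeat
# period of the segment, then move each boundary (within one period of the
# density bound) to where the periodic self-agreement x[i] == x[i + p]
# breaks down. Residue-exact on clean arrays; bounded drift under noise.
polishPtsBounds <- function(x, s, e, maxPeriod = 100L) {
  len <- e - s + 1L
  p <- tryCatch(detectPeriod(collapse0(x[s:e]), minP = 2L,
                             maxP = min(maxPeriod, len %/% 2L)),
                error = function(e) NA_integer_)
  if (is.na(p) || len < 5L * p) return(c(s, e))
  i <- s + 2L * p - 1L
  lo <- max(1L, s - p)
  while (i >= lo && x[i] == x[i + p]) i <- i - 1L
  sStar <- i + 1L
  j <- e - 2L * p + 1L
  hi <- min(length(x), e + p)
  while (j <= hi && x[j] == x[j - p]) j <- j + 1L
  c(sStar, j - 1L)
}

# Sharpen a windowed PTS segment to residue precision: the maximum-sum
# subinterval of (indicator - refineFrac) inside the segment span, so the
# boundary sits where local P/T/S density crosses refineFrac.
refineSegmentBounds <- function(ind, from, to, refineFrac) {
  x <- ind[from:to] - refineFrac
  S <- cumsum(x)
  pre <- c(0, S[-length(S)])        # prefix sum before each position
  M <- cummin(pre)
  e <- which.max(S - M)
  s <- which(pre == M[e])[1L]
  c(from + s - 1L, from + e - 1L)
}

#' Call candidate membrane-mucin genes between two marker anchors
#'
#' Within the inter-anchor interval (forward strand), candidate genes are
#' called where (1) an in-frame ATG lies upstream of (2) a PTS-rich segment
#' of at least \code{minPtsNt} nt and (3) a SEA-domain hit falls downstream
#' of the PTS segment. TM/PDZ features are annotated but not required.
#' Criterion (4), unique flanking sequence, is enforced by merging adjacent
#' candidates whose non-PTS portions align at or above
#' \code{mergeIdentity}\% global identity (assembly-duplicate behaviour).
#'
#' @param contig contig sequence.
#' @param anchors list with elements \code{marker5} and \code{marker3}, each
#'   a \code{"MarkerAnchor"} from \code{\link{locateMarker}}.
#' @param params list of thresholds; see \code{defaultScanParams()} in the
#'   package sources. Any element can be overridden.
#' @return List of candidates, each with \code{model}
#'   (\code{\linkS4class{GeneModel}} in contig coordinates),
#'   \code{ptsFraction}, \code{sea}, \code{tm}, \code{pdz},
#'   \code{startCodonPos} and \code{mergedFrom}.
#' @export
callMucinGenes <- function(contig, anchors, params = list()) {
  contig <- asSeqChar(contig)
  if (is.null(anchors$marker5) || is.null(anchors$marker3))
    stop("both flanking anchors are required")
  p <- utils::modifyList(defaultScanParams(), params)
  offset <- anchors$marker5$end
  region <- substring(contig, offset + 1L, anchors$marker3$start - 1L)
  n <- nchar(region)
  frames <- lapply(0:2, function(f) {
    ncod <- (n - f) %/% 3L
    starts <- f + 3L * (seq_len(ncod) - 1L) + 1L
    substring(region, starts, starts + 2L)
  })
  segs <- list()
  ptsInd <- vector("list", 3L)
  protChars <- vector("list", 3L)
  for (f in 0:2) {
    cod <- frames[[f + 1L]]
    prot <- translateCds(collapse0(cod))
    protChars[[f + 1L]] <- chars(prot)
    ptsInd[[f + 1L]] <- as.integer(protChars[[f + 1L]] %in% c("P", "T", "S"))
    s <- ptsScan(prot, window = p$ptsWindow, minFrac = p$ptsMinFrac)
    if (nrow(s) == 0L) next
    s$ntStart <- f + 3L * (s$start - 1L) + 1L
    s$ntEnd <- f + 3L * s$end
    s$frame <- f
    s <- s[s$ntEnd - s$ntStart + 1L >= p$minPtsNt, , drop = FALSE]
    if (nrow(s)) segs[[length(segs) + 1L]] <- s
  }
  if (!length(segs)) return(list())
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs$ntStart, -segs$fraction), , drop = FALSE]
  # merge overlapping segments across frames: keep the densest
  keep <- segs[1L, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1L]) {
    last <- nrow(keep)
    if (segs$ntStart[i] <= keep$ntEnd[last]) {
      if (segs$fraction[i] > keep$fraction[last]) keep[last, ] <- segs[i, ]
    } else keep <- rbind(keep, segs[i, ])
  }
  candidates <- list()
  for (i in seq_len(nrow(keep))) {
    seg <- keep[i, ]
    f <- seg$frame
    cod <- frames[[f + 1L]]
    ind <- ptsInd[[f + 1L]]
    b <- refineSegmentBounds(ind, seg$start, seg$end, p$ptsRefineFrac)
    b <- polishPtsBounds(protChars[[f + 1L]], b[1L], b[2L], p$ptsMaxPeriod)
    seg$start <- b[1L]; seg$end <- b[2L]
    seg$ntStart <- f + 3L * (seg$start - 1L) + 1L
    seg$ntEnd <- f + 3L * seg$end
    if (seg$ntEnd - seg$ntStart + 1L < p$minPtsNt) next
    seg$fraction <- mean(ind[seg$start:seg$end])
    codStart <- (seg$ntStart - 1L - f) %/% 3L + 1L
    codEnd <- (seg$ntEnd - f) %/% 3L
    stops <- which(cod %in% STOP_CODONS)
    atgs <- which(cod == "ATG")
    # criterion 1: choose the upstream in-frame ATG maximizing ORF openness,
    # (codons covered) - penalty x (in-frame stops spanned). Robust to rare
    # noise-created stops while rejecting ATGs out in the stop-dense spacer.
    cands <- atgs[atgs <= codStart & codStart - atgs <= p$maxUpstreamNt %/% 3L]
    if (!length(cands)) next                          # criterion 1 fails
    nStops <- findInterval(codStart - 1L, stops) - findInterval(cands - 1L, stops)
    openness <- (codStart - cands) - p$startStopPenalty * nStops
    startAtg <- cands[which.max(openness)]
    startNt <- f + 3L * (startAtg - 1L) + 1L
    downStop <- stops[stops > codEnd]
    endCod <- if (length(downStop)) min(downStop) else length(cod)
    endNt <- f + 3L * endCod
    # criterion 3: SEA scan reads through premature (noise) stops
    ctermScanEnd <- min(length(cod), codEnd + p$ctermWindowNt %/% 3L)
    if (ctermScanEnd <= codEnd) next                  # no C-terminal block
    seaProt <- translateCds(collapse0(cod[(codEnd + 1L):ctermScanEnd]))
    sea <- detectSea(seaProt, p$seaRefs,
                     minIdentity = p$seaMinIdentity, minLen = p$seaMinLen)
    if (is.null(sea)) next                            # criterion 3 fails
    annotEnd <- min(if (length(downStop)) endCod - 1L else endCod, ctermScanEnd)
    ctermProt <- if (annotEnd > codEnd)
      translateCds(collapse0(cod[(codEnd + 1L):annotEnd])) else ""
    feat <- if (nchar(ctermProt) >= 25L) detectCtermFeatures(ctermProt)
            else list(tm = NULL, tmHydropathy = NA_real_, pdz = FALSE)
    ex <- GRanges("contig",
                  IRanges(offset + c(startNt, seg$ntStart, seg$ntEnd + 1L),
                          offset + c(seg$ntStart - 1L, seg$ntEnd, endNt)),
                  strand = "+")
    gid <- sprintf("candidate%d", length(candidates) + 1L)
    candidates[[gid]] <- list(
      model = GeneModel(gid, ex, roles = c("N-term", "PTS", "C-term")),
      ptsFraction = seg$fraction, sea = sea, tm = feat$tm, pdz = feat$pdz,
      startCodonPos = offset + startNt, mergedFrom = character(0))
  }
  if (length(candidates) > 1L) {
    # one candidate per start codon (a noise-split PTS exon would otherwise
    # surface twice); keep the longer PTS segment
    startPos <- vapply(candidates, `[[`, numeric(1), "startCodonPos")
    ptsLen <- vapply(candidates, function(cand) {
      ex <- modelExons(cand$model)
      width(ex)[exonRoles(cand$model) == "PTS"]
    }, numeric(1))
    keepIdx <- vapply(split(seq_along(candidates), startPos),
                      function(i) i[which.max(ptsLen[i])], integer(1))
    candidates <- candidates[sort(keepIdx)]
  }
  if (length(candidates) < 2L) return(candidates)
  # criterion 4: adjacent candidates with near-identical non-PTS sequence
  # are treated as one locus
  nonPts <- vapply(candidates, function(cand) {
    ex <- modelExons(cand$model)
    role <- exonRoles(cand$model)
    collapse0(substring(contig, start(ex)[role != "PTS"], end(ex)[role != "PTS"]))
  }, character(1))
  merged <- candidates[1L]
  keptIdx <- 1L
  for (i in seq_along(candidates)[-1L]) {
    idn <- regionIdentity(nonPts[[i]], nonPts[[keptIdx[length(keptIdx)]]],
                          mode = "global")$identity
    if (idn >= p$mergeIdentity) {
      lastIdx <- length(merged)
      merged[[lastIdx]]$mergedFrom <- c(merged[[lastIdx]]$mergedFrom,
                                        geneId(candidates[[i]]$model))
    } else {
      merged[[length(merged) + 1L]] <- candidates[[i]]
      names(merged)[length(merged)] <- names(candidates)[i]
      keptIdx <- c(keptIdx, i)
    }
  }
  merged
}

#' Cluster span and intergenic metrics
#'
#' @param candidates non-empty list of candidates from
#'   \code{\link{callMucinGenes}} (or of \code{GeneModel}s).
#' @return List with \code{spanKbp} (first gene start to last gene end,
#'   kbp, 1 decimal), \code{intergenicBp} (between consecutive models) and
#'   \code{geneOrder}.
#' @export
clusterMetrics <- function(candidates) {
  if (length(candidates) == 0L) stop("empty candidate list")
  models <- lapply(candidates, function(x) if (is(x, "GeneModel")) x else x$model)
  starts <- vapply(models, function(m) min(start(modelExons(m))), numeric(1))
  ends <- vapply(models, function(m) max(end(modelExons(m))), numeric(1))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ids <- vapply(models, geneId, character(1))[o]
  list(spanKbp = unname(round((ends[length(ends)] - starts[1L] + 1) / 1000, 1)),
       intergenicBp = if (length(models) > 1L)
         setNames(starts[-1L] - ends[-length(ends)] - 1,
                  paste(ids[-length(ids)], ids[-1L], sep = "-"))
       else numeric(0),
       geneOrder = unname(ids))
}

#' Region identity versus divergence time
#'
#' Computes global percent identity for each species-pair/region sequence
#' pair and regresses identity on divergence time per region (ordinary least
#' squares), giving the evolutionary decay slope in percent per Mya.
#'
#' @param pairs data.frame with columns \code{speciesPair}, \code{region},
#'   \code{seqA}, \code{seqB}.
#' @param times named numeric vector: divergence time (Mya) per species pair.
#' @param protein logical; align as proteins.
#' @return List with \code{points} (data.frame sorted by time: speciesPair,
#'   region, time, identity) and \code{slopes} (named numeric per region;
#'   \code{NA} with fewer than 2 points).
#' @export
conservationVsTime <- function(pairs, times, protein = FALSE) {
  missing <- setdiff(unique(pairs$speciesPair), names(times))
  if (length(missing))
    stop("missing divergence time for: ", paste(missing, collapse = ", "))
  idn <- mapply(function(a, b) regionIdentity(a, b, "global",
                                              protein = protein)$identity,
                pairs$seqA, pairs$seqB)
  pts <- data.frame(speciesPair = pairs$speciesPair, region = pairs$region,
                    time = as.numeric(times[pairs$speciesPair]),
                    identity = as.numeric(idn))
  pts <- pts[order(pts$time), , drop = FALSE]
  rownames(pts) <- NULL
  slopes <- vapply(split(pts, pts$region), function(d) {
    if (nrow(d) < 2L || stats::var(d$time) == 0) return(NA_real_)
    stats::cov(d$time, d$identity) / stats::var(d$time)
  }, numeric(1))
  list(points = pts, slopes = slopes)
}
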