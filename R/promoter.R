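# Promoter extraction, reference-anchored cross-species alignment, JASPAR
# PFM parsing, PWM scanning and conserved-TFBS calling.

#' Extract the upstream (promoter) region of a gene
#'
#' Returns the \code{nBp} bases 5' of the gene's transcription start (the
#' 5'-most exon boundary on the gene strand); minus-strand genes yield the
#' reverse complement, so the promoter always reads toward the gene.
#' Truncated with a warning at the contig edge.
#'
#' @param contig contig sequence.
#' @param geneModel a \code{\linkS4class{GeneModel}}.
#' @param nBp promoter length (default 1000).
#' @return Promoter sequence (character).
#' @export
extractUpstream <- function(contig, geneModel, nBp = 1000L) {
  contig <- asSeqChar(contig)
  nBp <- as.integer(nBp)
  if (nBp < 1L) stop("nBp must be >= 1")
  ex <- modelExons(geneModel)
  minus <- as.character(strand(ex))[1L] == "-"
  n <- nchar(contig)
  if (!minus) {
    tss <- min(start(ex))
    from <- tss - nBp
    if (from < 1L) {
      if (tss == 1L) stop("gene starts at the contig edge; no upstream sequence")
      warning("promoter truncated at contig start")
      from <- 1L
    }
    substring(contig, from, tss - 1L)
  } else {
    tss <- max(end(ex))
    to <- tss + nBp
    if (to > n) {
      if (tss == n) stop("gene starts at the contig edge; no upstream sequence")
      warning("promoter truncated at contig end")
      to <- n
    }
    revComp(substring(contig, tss + 1L, to))
  }
}

#' Align promoters of several species to a reference
#'
#' Each species is aligned to the reference promoter by Needleman-Wunsch
#' (match +1, mismatch -1, gap open -2, extend -1); the identity and a
#' column map translating species coordinates to reference coordinates
#' (\code{NA} at reference gaps) are reported. The reference maps to itself.
#'
#' @param promoters named character vector (>= 2 species).
#' @param referenceSpecies name of the reference; must be present.
#' @return List with \code{reference} and \code{species}, a named list
#'   holding \code{identity} and integer \code{map} (length of that
#'   species' promoter) per species.
#' @export
alignToReference <- function(promoters, referenceSpecies) {
  if (length(promoters) < 2L) stop("need promoters from >= 2 species")
  if (!referenceSpecies %in% names(promoters))
    stop("reference species missing from promoters")
  ref <- asSeqChar(promoters[[referenceSpecies]])
  species <- lapply(names(promoters), function(sp) {
    s <- asSeqChar(promoters[[sp]])
    if (sp == referenceSpecies)
      return(list(identity = 100, map = seq_len(nchar(s))))
    aln <- alignPair(s, ref, type = "global")
    pa <- chars(as.character(alignedPattern(aln)))
    sa <- chars(as.character(alignedSubject(aln)))
    spPos <- cumsum(pa != "-")
    refPos <- cumsum(sa != "-")
    map <- rep(NA_integer_, nchar(s))
    keep <- pa != "-"
    map[spPos[keep]] <- ifelse(sa[keep] != "-", refPos[keep], NA_integer_)
    list(identity = alnIdentity(aln)$identity, map = map)
  })
  names(species) <- names(promoters)
  list(reference = referenceSpecies, species = species)
}

#' Parse JASPAR PFM text
#'
#' Reads the JASPAR (2020+) position-frequency-matrix flat format: a
#' \code{">ID name"} header followed by four labelled, bracketed count rows
#' in the order A, C, G, T.
#'
#' @param file path to a JASPAR PFM text file.
#' @return Named list of motifs, each a list with \code{id}, \code{name}
#'   and \code{matrix} (4 x width counts, rownames A/C/G/T).
#' @export
readJasparMatrices <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("no JASPAR records in ", file)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    last <- if (h < length(heads)) heads[h + 1L] - 1L else length(lines)
    body <- lines[(i + 1L):last]
    if (length(body) != 4L) stop("JASPAR record needs exactly 4 matrix rows")
    labels <- toupper(substr(body, 1L, 1L))
    if (!identical(labels, c("A", "C", "G", "T")))
      stop("matrix rows must be labelled A, C, G, T in order")
    rows <- lapply(body, function(l) {
      nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]$", "", l)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L) stop("ragged matrix rows")
    if (lengths(rows)[1L] < 4L) stop("motif must have >= 4 positions")
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(m < 0)) stop("negative matrix entries")
    hd <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1L]]
    id <- hd[1L]
    out[[id]] <- list(id = id, name = if (length(hd) > 1L) hd[2L] else "",
                      matrix = m)
  }
  out
}

# Log-odds weights from a count PFM: log2((f + 0.5*bg) / ((N + 0.5) * bg)),
# pseudocount 0.5 distributed by the background.
pwmWeights <- function(counts, background = rep(0.25, 4)) {
  N <- colSums(counts)
  w <- log2(sweep(counts + 0.5 * background, 2L, (N + 0.5), "/") / background)
  rownames(w) <- rownames(counts)
  w
}

#' Scan a sequence with a position-weight matrix
#'
#' Scores every window on both strands with the log-odds weights derived
#' from the count matrix (pseudocount 0.5, uniform background by default)
#' and reports windows whose relative score -- (score - min) / (max - min)
#' over the achievable range -- reaches \code{minRelScore}. Minus-strand
#' hits are reported at their footprint on the forward strand.
#'
#' @param seq nucleotide sequence.
#' @param pfm a motif from \code{\link{readJasparMatrices}} (or any list
#'   with \code{id} and 4 x width count \code{matrix}).
#' @param minRelScore minimum relative score in (0, 1] (default 0.8).
#' @param background base composition (A, C, G, T; default uniform).
#' @return data.frame with \code{motif}, \code{start}, \code{end},
#'   \code{strand}, \code{score}, \code{relScore}, sorted by start. Empty
#'   when the sequence is shorter than the motif.
#' @export
pwmScan <- function(seq, pfm, minRelScore = 0.8, background = rep(0.25, 4)) {
  seq <- asSeqChar(seq)
  if (minRelScore <= 0 || minRelScore > 1) stop("minRelScore must lie in (0, 1]")
  counts <- pfm$matrix
  L <- ncol(counts)
  n <- nchar(seq)
  empty <- data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), relScore = numeric(0))
  if (n < L) return(empty)
  w <- pwmWeights(counts, background)
  lo <- sum(apply(w, 2L, min)); hi <- sum(apply(w, 2L, max))
  code <- match(chars(seq), c("A", "C", "G", "T"))
  nOff <- n - L + 1L
  scoreStrand <- function(wm) {
    sc <- numeric(nOff)
    for (i in seq_len(L)) {
      col <- c(wm[, i], min(wm[, i]))  # 5th entry: non-ACGT scores worst
      ci <- code[i:(i + nOff - 1L)]
      ci[is.na(ci)] <- 5L
      sc <- sc + col[ci]
    }
    sc
  }
  hitsFor <- function(sc, strandLab) {
    rel <- (sc - lo) / (hi - lo)
    h <- which(rel >= minRelScore)
    if (!length(h)) return(NULL)
    data.frame(motif = pfm$id, start = h, end = h + L - 1L,
               strand = strandLab, score = sc[h], relScore = rel[h])
  }
  # minus strand: scoring the window's reverse complement equals scoring the
  # forward window with the reversed, base-complemented weight matrix
  wRc <- w[c("T", "G", "C", "A"), rev(seq_len(L)), drop = FALSE]
  rownames(wRc) <- c("A", "C", "G", "T")
  res <- rbind(hitsFor(scoreStrand(w), "+"), hitsFor(scoreStrand(wRc), "-"))
  if (is.null(res)) return(empty)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call cross-species conserved TFBS hits
#'
#' A reference-species hit is conserved iff every other species has a hit of
#' the same motif whose footprint, projected onto reference coordinates via
#' the alignment column maps, overlaps at least \code{minOverlap} of the
#' reference hit's footprint.
#'
#' @param perSpeciesHits named list (species -> hit data.frame from
#'   \code{\link{pwmScan}}, possibly several motifs row-bound).
#' @param alignments result of \code{\link{alignToReference}} covering every
#'   species in \code{perSpeciesHits}.
#' @param minOverlap minimum fractional footprint overlap (default 0.5).
#' @return data.frame of conserved reference hits (motif, start, end,
#'   strand, score, relScore).
#' @export
conservedSites <- function(perSpeciesHits, alignments, minOverlap = 0.5) {
  ref <- alignments$reference
  if (!ref %in% names(perSpeciesHits))
    stop("reference species has no hits table")
  missing <- setdiff(names(perSpeciesHits), names(alignments$species))
  if (length(missing))
    stop("species missing from alignments: ", paste(missing, collapse = ", "))
  others <- setdiff(names(perSpeciesHits), ref)
  refHits <- perSpeciesHits[[ref]]
  if (nrow(refHits) == 0L) return(refHits)
  supported <- vapply(seq_len(nrow(refHits)), function(i) {
    rh <- refHits[i, ]
    rlen <- rh$end - rh$start + 1L
    all(vapply(others, function(sp) {
      hs <- perSpeciesHits[[sp]]
      hs <- hs[hs$motif == rh$motif, , drop = FALSE]
      if (nrow(hs) == 0L) return(FALSE)
      map <- alignments$species[[sp]]$map
      any(vapply(seq_len(nrow(hs)), function(j) {
        mapped <- map[hs$start[j]:hs$end[j]]
        mapped <- mapped[!is.na(mapped)]
        if (!length(mapped)) return(FALSE)
        ov <- length(intersect(mapped, rh$start:rh$end))
        ov / rlen >= minOverlap
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  out <- refHits[supported, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import a BED-like signal track and average it over a region
#'
#' Minimal helper for externally produced accessibility/occupancy tracks
#' (chrom, start, end, score): imports the intervals and reports the
#' width-weighted mean score over a query region.
#'
#' @param file BED file with a score column.
#' @return \code{GRanges} with a \code{score} column.
#' @export
readSignalTrack <- function(file) {
  rtracklayer::import(file, format = "bed")
}

#' @rdname readSignalTrack
#' @param track \code{GRanges} from \code{readSignalTrack}.
#' @param region a \code{GRanges} of length 1 (the cCRE).
#' @return \code{meanSignalOver}: width-weighted mean score (\code{NA} when
#'   nothing overlaps).
#' @export
meanSignalOver <- function(track, region) {
  ov <- IRanges::findOverlapPairs(track, region)
  if (length(ov) == 0L) return(NA_real_)
  inter <- IRanges::pintersect(ov)
  sum(S4Vectors::first(ov)$score * width(inter)) / sum(width(inter))
}
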