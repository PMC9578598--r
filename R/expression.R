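# Paralog-aware expression quantification: unique k-mer masks, seed-and-verify
# read placement with unique/shared/unassigned classification, unique-read RPK
# and TPM with proportional apportionment of shared reads.

#' Unique k-mer masks over a transcript set
#'
#' A transcript position is masked unique iff it is covered by at least one
#' k-mer whose total multiplicity across all transcripts (all positions) is
#' exactly one. Identical paralog stretches therefore mask FALSE; only the
#' discriminating region masks TRUE.
#'
#' @param transcripts named character vector (>= 2 transcripts).
#' @param k k-mer length (default 31; small values give noisy masks).
#' @return Named list of logical vectors, one per transcript (its length).
#'   Transcripts shorter than \code{k} get an all-FALSE mask with a warning.
#' @export
uniqueKmerMask <- function(transcripts, k = 31L) {
  transcripts <- vapply(transcripts, asSeqChar, character(1))
  k <- as.integer(k)
  if (k < 3L) stop("k must be >= 3")
  if (length(transcripts) < 2L) stop("need >= 2 transcripts")
  if (is.null(names(transcripts)))
    names(transcripts) <- sprintf("tx%d", seq_along(transcripts))
  km <- lapply(transcripts, kmersOf, k = k)
  short <- names(transcripts)[lengths(km) == 0L & nchar(transcripts) > 0L]
  short <- union(short, names(transcripts)[nchar(transcripts) < k])
  if (length(short))
    warning("transcript(s) shorter than k: ", paste(short, collapse = ", "))
  all <- unlist(km, use.names = FALSE)
  dup <- duplicated(all) | duplicated(all, fromLast = TRUE)
  uniq <- !dup
  off <- c(0L, cumsum(lengths(km)))
  out <- vector("list", length(transcripts))
  names(out) <- names(transcripts)
  for (i in seq_along(transcripts)) {
    len <- nchar(transcripts[[i]])
    mask <- logical(len)
    if (lengths(km)[i] > 0L) {
      s <- which(uniq[(off[i] + 1L):off[i + 1L]])
      if (length(s)) {
        cov <- reduce(IRanges(s, s + k - 1L))
        for (j in seq_along(cov))
          mask[start(cov)[j]:end(cov)[j]] <- TRUE
      }
    }
    out[[i]] <- mask
  }
  out
}

# Shared classification logic: one row per read in `placements`
# (read, transcript, pos, mismatches); reads absent from `placements`
# (ids listed in `allReads`) are unassigned.
classifyPlacements <- function(placements, allReads, maxMm = 2L) {
  placements <- placements[placements$mismatches <= maxMm, , drop = FALSE]
  cls <- data.frame(read = allReads, class = "unassigned",
                    transcript = NA_character_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  if (nrow(placements)) {
    byRead <- split(placements, placements$read)
    ids <- names(byRead)
    best <- lapply(byRead, function(d) {
      m <- min(d$mismatches)
      unique(d$transcript[d$mismatches == m])
    })
    bm <- vapply(byRead, function(d) min(d$mismatches), numeric(1))
    i <- match(ids, cls$read)
    cls$mismatches[i] <- as.integer(bm)
    one <- lengths(best) == 1L
    cls$class[i] <- ifelse(one, "unique", "shared")
    cls$transcript[i[one]] <- unlist(best[one])
  }
  rownames(cls) <- NULL
  cls
}

#' Place reads on transcripts by seed-and-verify matching
#'
#' Candidate positions are found by exact matching of \code{maxMm + 1}
#' read segments (pigeonhole: a read with at most \code{maxMm} mismatches
#' has at least one error-free segment) against a k-mer index of the
#' transcripts, then verified by full-read Hamming comparison. Reads are
#' classified \code{unique} (one transcript attains the minimum mismatch
#' count), \code{shared} (>= 2 transcripts tie) or \code{unassigned}
#' (no placement with at most \code{maxMm} mismatches).
#'
#' @param reads named character vector of reads (all at least
#'   \code{kSeed} long).
#' @param transcripts named character vector of transcript sequences.
#' @param maxMm maximum mismatches for a valid placement (default 2).
#' @param kSeed seed length (default 21).
#' @return List with \code{placements} (data.frame read, transcript, pos,
#'   mismatches; all placements at or below \code{maxMm}) and \code{classes}
#'   (data.frame read, class, transcript, mismatches).
#' @export
placeReads <- function(reads, transcripts, maxMm = 2L, kSeed = 21L) {
  reads <- vapply(reads, asSeqChar, character(1))
  transcripts <- vapply(transcripts, asSeqChar, character(1))
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  if (is.null(names(transcripts)))
    names(transcripts) <- sprintf("tx%d", seq_along(transcripts))
  kSeed <- as.integer(kSeed)
  nSeg <- maxMm + 1L
  # disjoint segments (pigeonhole): the effective seed must fit nSeg times
  # into the shortest read
  kEff <- min(kSeed, min(nchar(reads)) %/% nSeg)
  if (kEff < 8L) stop("reads too short for maxMm = ", maxMm,
                      " (need length >= ", 8L * nSeg, ")")
  txLen <- nchar(transcripts)
  off <- c(0L, cumsum(txLen))  # global coordinate offsets per transcript
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_along(transcripts)) {
    ks <- kmersOf(transcripts[[t]], kEff)
    gpos <- off[t] + seq_along(ks)
    sp <- split(gpos, ks)
    for (key in names(sp)) {
      prev <- if (exists(key, envir = idx, inherits = FALSE))
        get(key, envir = idx) else integer(0)
      assign(key, c(prev, sp[[key]]), envir = idx)
    }
  }
  txRaw <- lapply(transcripts, charToRaw)
  nR <- length(reads)
  readLen <- nchar(reads)
  candList <- vector("list", nR)
  for (s in seq_len(nSeg)) {
    segOff <- 1L + (s - 1L) * (readLen %/% nSeg)
    keys <- substring(reads, segOff, segOff + kEff - 1L)
    hits <- mget(keys, envir = idx, ifnotfound = list(integer(0)))
    for (i in which(lengths(hits) > 0L))
      candList[[i]] <- c(candList[[i]], hits[[i]] - segOff[i] + 1L)
  }
  rows <- vector("list", nR)
  for (i in seq_len(nR)) {
    cands <- unique(candList[[i]])
    cands <- cands[cands >= 1L]
    if (!length(cands)) next
    rRaw <- charToRaw(reads[[i]])
    L <- readLen[i]
    t <- findInterval(cands - 1L, off[-length(off)])
    localPos <- cands - off[t]
    ok <- localPos >= 1L & localPos + L - 1L <= txLen[t]
    res <- NULL
    for (j in which(ok)) {
      mm <- sum(txRaw[[t[j]]][localPos[j]:(localPos[j] + L - 1L)] != rRaw)
      if (mm <= maxMm)
        res <- rbind(res, c(t[j], localPos[j], mm))
    }
    if (!is.null(res)) rows[[i]] <- res
  }
  found <- which(!vapply(rows, is.null, logical(1)))
  placements <- if (length(found)) {
    m <- do.call(rbind, rows[found])
    data.frame(read = rep(names(reads)[found],
                          vapply(rows[found], nrow, integer(1))),
               transcript = names(transcripts)[m[, 1L]],
               pos = m[, 2L], mismatches = m[, 3L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(read = character(0), transcript = character(0),
               pos = integer(0), mismatches = integer(0))
  }
  list(placements = placements,
       classes = classifyPlacements(placements, names(reads), maxMm))
}

#' Quantify paralog expression from read placements
#'
#' Unique-read counts per gene, reads-per-kilobase over the discriminating
#' (unique-maskable) region, and TPM from effective counts. Each shared read
#' is apportioned among its tied transcripts proportionally to their
#' unique-read rates (unique count / unique-maskable kb); when all tied
#' genes have zero unique reads the read is split equally.
#'
#' @param placed result of \code{\link{placeReads}} (or a list with
#'   \code{placements} and \code{classes} in the same shape, e.g. built from
#'   \code{\link{readSamPlacements}} + \code{classifyPlacements}).
#' @param transcripts named character vector of transcript sequences.
#' @param masks unique k-mer masks from \code{\link{uniqueKmerMask}}.
#' @param rpkDenominator \code{"unique"} (default: unique-maskable length)
#'   or \code{"full"} (transcript length).
#' @return data.frame per gene: \code{uniqueCount}, \code{sharedCount}
#'   (apportioned), \code{effectiveCount}, \code{uniqueLenBp}, \code{rpk},
#'   \code{tpm}. TPM sums to 1e6 (all-zero counts give all-zero TPM with a
#'   warning).
#' @export
quantifyParalogs <- function(placed, transcripts, masks,
                             rpkDenominator = c("unique", "full")) {
  rpkDenominator <- match.arg(rpkDenominator)
  transcripts <- vapply(transcripts, asSeqChar, character(1))
  genes <- names(transcripts)
  txLen <- nchar(transcripts)
  cls <- placed$classes
  uniqueCount <- vapply(genes, function(g)
    sum(cls$class == "unique" & cls$transcript == g, na.rm = TRUE), numeric(1))
  uniqueLen <- vapply(genes, function(g) sum(masks[[g]]), numeric(1))
  denom <- if (rpkDenominator == "unique") uniqueLen else txLen
  rpk <- ifelse(denom > 0, uniqueCount / (denom / 1000), 0)
  sharedCount <- setNames(numeric(length(genes)), genes)
  sharedReads <- cls$read[cls$class == "shared"]
  if (length(sharedReads)) {
    pl <- placed$placements
    pl <- pl[pl$read %in% sharedReads, , drop = FALSE]
    for (d in split(pl, pl$read)) {
      m <- min(d$mismatches)
      tied <- unique(d$transcript[d$mismatches == m])
      w <- rpk[tied]
      w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(tied), length(tied))
      sharedCount[tied] <- sharedCount[tied] + w
    }
  }
  effective <- uniqueCount + sharedCount
  dens <- effective / txLen
  if (sum(dens) == 0) {
    warning("all genes have zero counts; TPM set to 0")
    tpm <- dens
  } else tpm <- 1e6 * dens / sum(dens)
  data.frame(gene = genes, uniqueCount = uniqueCount,
             sharedCount = sharedCount, effectiveCount = effective,
             uniqueLenBp = uniqueLen, rpk = rpk, tpm = tpm,
             row.names = NULL)
}

#' Quality-filter FASTQ reads
#'
#' Drops reads whose mean Phred quality is below \code{minMeanQuality} or
#' whose fraction of N bases exceeds \code{maxNFrac}.
#'
#' @param reads named character vector of read sequences, or a
#'   \code{QualityScaledDNAStringSet} (then \code{qualities} is ignored).
#' @param qualities Phred+33 quality strings parallel to \code{reads}.
#' @param minMeanQuality mean Phred threshold (default 20).
#' @param maxNFrac maximum N fraction (default 0.1).
#' @return List with \code{reads}, \code{qualities} (the kept ones) and
#'   \code{report} (\code{nIn}, \code{nKept}, \code{nDroppedQuality},
#'   \code{nDroppedN}).
#' @export
qcFilterReads <- function(reads, qualities = NULL, minMeanQuality = 20,
                          maxNFrac = 0.1) {
  if (is(reads, "QualityScaledDNAStringSet")) {
    qualities <- as.character(quality(reads))
    reads <- setNames(as.character(reads), names(reads))
  }
  if (is.null(qualities)) stop("qualities are required")
  meanQ <- vapply(qualities, function(q) mean(utf8ToInt(q) - 33L), numeric(1))
  nFrac <- vapply(reads, function(r) {
    mean(chars(toupper(r)) == "N")
  }, numeric(1))
  lowQ <- meanQ < minMeanQuality
  manyN <- nFrac > maxNFrac
  keep <- !(lowQ | manyN)
  list(reads = reads[keep], qualities = qualities[keep],
       report = list(nIn = length(reads), nKept = sum(keep),
                     nDroppedQuality = sum(lowQ), nDroppedN = sum(manyN & !lowQ)))
}

#' Import read placements from a SAM text file
#'
#' Minimal reader of the mandatory SAM columns (plus the \code{NM:i:} tag
#' when present, else 0 mismatches), so that placements from an external
#' aligner can replace \code{\link{placeReads}}. Unmapped records (flag 0x4
#' or \code{RNAME == "*"}) are skipped.
#'
#' @param file path to a SAM file.
#' @return data.frame with \code{read}, \code{transcript}, \code{pos},
#'   \code{mismatches}; feed to \code{classifyPlacements} logic via
#'   \code{\link{placeReads}}-shaped lists.
#' @export
readSamPlacements <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(read = character(0), transcript = character(0),
                      pos = integer(0), mismatches = integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 11L
  if (any(bad)) stop("malformed SAM record (fewer than 11 fields)")
  flag <- vapply(fields, function(f) as.integer(f[[2L]]), integer(1))
  rname <- vapply(fields, `[[`, character(1), 3L)
  keep <- bitwAnd(flag, 4L) == 0L & rname != "*"
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[[1L]])) else 0L
  }, integer(1))
  data.frame(read = vapply(fields, `[[`, character(1), 1L)[keep],
             transcript = rname[keep],
             pos = vapply(fields, function(f) as.integer(f[[4L]]), integer(1))[keep],
             mismatches = nm[keep], stringsAsFactors = FALSE)
}

#' Summarize expression tables across samples
#'
#' @param tables named list of per-sample tables from
#'   \code{\link{quantifyParalogs}}.
#' @param groups optional factor/character of sample groups (defaults to one
#'   group).
#' @return data.frame with per-group, per-gene mean and SD of TPM and RPK.
#' @export
summarizeExpression <- function(tables, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(tables))
  long <- do.call(rbind, lapply(seq_along(tables), function(i) {
    cbind(tables[[i]][, c("gene", "rpk", "tpm")], group = groups[[i]])
  }))
  agg <- lapply(split(long, list(long$group, long$gene), drop = TRUE),
                function(d) data.frame(group = d$group[1L], gene = d$gene[1L],
                                       n = nrow(d),
                                       meanTpm = mean(d$tpm),
                                       sdTpm = stats::sd(d$tpm),
                                       meanRpk = mean(d$rpk),
                                       sdRpk = stats::sd(d$rpk)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$group, out$gene), , drop = FALSE]
}
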