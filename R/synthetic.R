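# Synthetic mucin-cluster generator. Builds toy genomic clusters with planted
# ground truth (gene models, repeat counts, paralog identity, read origins)
# so every pipeline stage can be exercised and scored without external data.

# A synthetic SEA-like reference segment (120 aa). This is NOT a biological
# SEA domain sequence: it is a fixed, arbitrary protein segment that plays
# the role of a conserved reference in simulations and tests.
SEA_REF_SYNTHETIC <- paste0(
  "GSVVDPNSELYQRLAKEFTDLMNVSPSQIRSLRVTKGSIIVDHEVILREPLSNNETLVKE",
  "LFRSALQNGSLGPYELDPSSVYINGALICRPEVMDTPFSWRDAQKTLEAGVNCPTMKDLG")

# 19-residue strongly hydrophobic stretch used as the planted TM segment.
TM_SEGMENT_SYNTHETIC <- "LIVLLIVALLIVFLIVLLA"

#' Specification of a synthetic mucin gene cluster
#'
#' Describes the cluster that \code{\link{buildClusterGenome}} materializes:
#' mucin-like genes between two flanking marker genes, each gene carrying an
#' ATG-initiated N-terminal block, a single PTS exon built by back-translating
#' \code{repeatUnit} \code{repeatCounts[i]} times, and a C-terminal block with
#' a planted SEA-like segment, a hydrophobic transmembrane stretch and a
#' Class I PDZ-binding C-terminus. One designated gene pair is generated as
#' paralogs whose non-PTS sequence diverges to \code{paralogIdentity}.
#'
#' Defaults mirror the human MUC3 cluster: three genes, the 17-residue unit
#' \code{ITTTETTSHSTPSFTSS}, perfect-repeat counts 166 and 549 for the
#' paralog pair, intergenic gaps of 10939 bp and 2469 bp, and 93\%
#' paralog identity.
#'
#' @param nGenes number of mucin-like genes (>= 1).
#' @param repeatUnit protein repeat unit (>= 2 residues).
#' @param repeatCounts integer vector of per-gene repeat counts.
#' @param paralogIdentity target global identity (fraction in [0.5, 1]) for
#'   the non-PTS parts of the designated paralog pair.
#' @param paralogPair indices of the two genes forming the paralog pair
#'   (ignored when \code{nGenes == 1}).
#' @param intergenicLengths bp of the \code{nGenes - 1} intergenic spacers.
#' @param markerLengths bp of the 5' and 3' marker genes.
#' @param flankLengths bp of spacer between each marker and the nearest gene.
#' @param ntermLength,ctermLength lengths (aa) of the N- and C-terminal
#'   protein blocks. Defaults echo the sizes reported for MUC3-type genes
#'   (about 2.2 kb and 6.3 kb of coding sequence).
#' @param seed integer seed making the build deterministic.
#' @return A validated object of class \code{ClusterSpec} (a list).
#' @export
clusterSpec <- function(nGenes = 3L,
                        repeatUnit = "ITTTETTSHSTPSFTSS",
                        repeatCounts = NULL,
                        paralogIdentity = 0.93,
                        paralogPair = c(1L, 2L),
                        intergenicLengths = NULL,
                        markerLengths = c(2000L, 2000L),
                        flankLengths = c(500L, 500L),
                        ntermLength = 728L,
                        ctermLength = 2020L,
                        seed = 1L) {
  nGenes <- as.integer(nGenes)
  if (is.null(repeatCounts))
    repeatCounts <- c(166L, 549L, 120L, 80L)[seq_len(nGenes)]
  if (is.null(intergenicLengths))
    intergenicLengths <- c(10939L, 2469L, 5000L)[seq_len(max(nGenes - 1L, 0L))]
  spec <- structure(list(
    nGenes = nGenes, repeatUnit = toupper(repeatUnit),
    repeatCounts = as.integer(repeatCounts),
    paralogIdentity = paralogIdentity, paralogPair = as.integer(paralogPair),
    intergenicLengths = as.integer(intergenicLengths),
    markerLengths = as.integer(markerLengths),
    flankLengths = as.integer(flankLengths),
    ntermLength = as.integer(ntermLength),
    ctermLength = as.integer(ctermLength),
    seed = as.integer(seed)), class = "ClusterSpec")
  validateClusterSpec(spec)
  spec
}

validateClusterSpec <- function(spec) {
  with(spec, {
    if (nGenes < 1L) stop("nGenes must be >= 1")
    if (nchar(repeatUnit) < 2L) stop("repeatUnit must have >= 2 residues")
    if (paralogIdentity < 0.5 || paralogIdentity > 1)
      stop("paralogIdentity must lie in [0.5, 1]")
    if (length(repeatCounts) != nGenes) stop("one repeatCount per gene required")
    if (any(repeatCounts < 2L)) stop("repeatCounts must be >= 2")
    if (length(intergenicLengths) != max(nGenes - 1L, 0L))
      stop("need nGenes - 1 intergenic lengths")
    if (any(c(intergenicLengths, markerLengths, flankLengths,
              ntermLength, ctermLength) <= 0L))
      stop("all lengths must be positive")
    if (any(c(intergenicLengths, flankLengths) < 10L))
      stop("spacer lengths must be >= 10 bp")
    if (ctermLength < 210L)
      stop("ctermLength must be >= 210 aa to fit the SEA/TM/PDZ features")
    if (nGenes > 1L && (length(paralogPair) != 2L ||
                        any(paralogPair < 1L | paralogPair > nGenes)))
      stop("paralogPair must index two genes")
  })
  invisible(spec)
}

# Substitute bases in a coding sequence at `rate`, then revert any codon the
# mutation turned into a stop, so the reading frame stays open.
mutateCodingKeepFrame <- function(cds, rate) {
  if (rate <= 0) return(cds)
  mut <- mutateSequence(cds, subRate = rate)
  n <- nchar(mut) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  cod <- substring(mut, starts, starts + 2L)
  # revert codons that became stops, and the initiator codon, so the frame
  # stays open and ATG-anchored
  bad <- union(which(cod %in% STOP_CODONS), 1L)
  orig <- substring(cds, starts, starts + 2L)
  cod[bad] <- orig[bad]
  collapse0(cod)
}

# One synthetic gene CDS (including its terminal stop codon) plus the
# protein-block boundaries needed for the truth gene model.
buildGeneCds <- function(spec, repeatCount,
                         ntermProt = NULL, ctermProt = NULL) {
  if (is.null(ntermProt))
    ntermProt <- paste0("M", randomProtein(spec$ntermLength - 1L))
  if (is.null(ctermProt)) {
    tailLen <- spec$ctermLength - nchar(SEA_REF_SYNTHETIC) -
      nchar(TM_SEGMENT_SYNTHETIC) - 64L
    linker <- randomProtein(tailLen %/% 2L)
    ct <- randomProtein(tailLen - nchar(linker))
    ctermProt <- paste0(linker, SEA_REF_SYNTHETIC, ct,
                        TM_SEGMENT_SYNTHETIC,
                        randomProtein(60L), "ETSL")
  }
  ptsProt <- strrep(spec$repeatUnit, repeatCount)
  list(ntermProt = ntermProt, ptsProt = ptsProt, ctermProt = ctermProt,
       ntermNt = backTranslate(ntermProt),
       ptsNt = backTranslate(ptsProt),
       ctermNt = paste0(backTranslate(ctermProt), "TAA"))
}

#' Build a synthetic cluster genome with planted truth
#'
#' Assembles \code{5' marker + flank + gene1 + gap + ... + geneN + flank +
#' 3' marker} on one contig. Every gene is a single open reading frame whose
#' N-terminal, PTS and C-terminal coding blocks are recorded as role-tagged
#' exons in the truth gene models; an in-frame TAA is planted immediately
#' upstream of each ATG so the ORF boundary is exact. The designated paralog
#' pair shares N-/C-terminal sequence diverged to the target identity by
#' substitutions only (reading frame preserved).
#'
#' @param spec a \code{\link{clusterSpec}}.
#' @return List with \code{contig} (named character, one cluster sequence)
#'   and \code{truth}: gene \code{models} (list of
#'   \code{\linkS4class{GeneModel}}), per-gene \code{cds} and
#'   \code{ptsProteins}, \code{markerSeqs} and \code{markerIntervals},
#'   \code{repeatCounts}, \code{intergenicLengths} and the spec itself.
#' @examples
#' res <- buildClusterGenome(clusterSpec(nGenes = 2, repeatCounts = c(5, 12),
#'                                       ntermLength = 60, ctermLength = 260,
#'                                       intergenicLengths = 300))
#' names(res$truth$models)
#' @export
buildClusterGenome <- function(spec) {
  validateClusterSpec(spec)
  withSeed(spec$seed, {
    markers <- list(marker5 = randomDna(spec$markerLengths[1L]),
                    marker3 = randomDna(spec$markerLengths[2L]))
    genes <- vector("list", spec$nGenes)
    for (i in seq_len(spec$nGenes)) genes[[i]] <- buildGeneCds(spec, spec$repeatCounts[i])
    if (spec$nGenes > 1L && spec$paralogIdentity < 1) {
      a <- spec$paralogPair[1L]; b <- spec$paralogPair[2L]
      rate <- 1 - spec$paralogIdentity
      genes[[b]]$ntermNt <- mutateCodingKeepFrame(genes[[a]]$ntermNt, rate)
      ctA <- genes[[a]]$ctermNt
      body <- substr(ctA, 1L, nchar(ctA) - 3L)
      genes[[b]]$ctermNt <- paste0(mutateCodingKeepFrame(body, rate), "TAA")
      genes[[b]]$ntermProt <- translateCds(genes[[b]]$ntermNt)
      genes[[b]]$ctermProt <- translateCds(substr(genes[[b]]$ctermNt, 1L,
                                                  nchar(genes[[b]]$ctermNt) - 3L))
    }
    pieces <- character(0)
    pos <- 0L
    addPiece <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      from <- pos + 1L
      pos <<- pos + nchar(s)
      c(from, pos)
    }
    mk5 <- addPiece(markers$marker5)
    addPiece(randomDna(spec$flankLengths[1L] - 3L))
    models <- list(); cds <- character(spec$nGenes); ptsProteins <- character(spec$nGenes)
    for (i in seq_len(spec$nGenes)) {
      addPiece("TAA")  # in-frame upstream stop, planted
      g <- genes[[i]]
      nt <- addPiece(g$ntermNt)
      pt <- addPiece(g$ptsNt)
      ct <- addPiece(g$ctermNt)
      gid <- sprintf("gene%d", i)
      ex <- GRanges("cluster", IRanges(c(nt[1L], pt[1L], ct[1L]),
                                       c(nt[2L], pt[2L], ct[2L])), strand = "+")
      models[[gid]] <- GeneModel(gid, ex, roles = c("N-term", "PTS", "C-term"))
      cds[i] <- paste0(g$ntermNt, g$ptsNt, g$ctermNt)
      ptsProteins[i] <- g$ptsProt
      if (i < spec$nGenes) addPiece(randomDna(spec$intergenicLengths[i] - 3L))
    }
    addPiece(randomDna(spec$flankLengths[2L]))
    mk3 <- addPiece(markers$marker3)
    contig <- setNames(collapse0(pieces), "cluster")
    names(cds) <- names(ptsProteins) <- names(models)
    list(contig = contig,
         truth = list(models = models, cds = cds, ptsProteins = ptsProteins,
                      markerSeqs = unlist(markers),
                      markerIntervals = list(marker5 = mk5, marker3 = mk3),
                      repeatCounts = setNames(spec$repeatCounts, names(models)),
                      intergenicLengths = spec$intergenicLengths,
                      spec = spec))
  })
}

#' Mutate a sequence with substitutions and 1-bp indels
#'
#' Each position is substituted with probability \code{subRate} (uniformly
#' over the three alternative bases) and hit by a 1-bp indel with probability
#' \code{indelRate} (insertion or deletion, 50/50). Deterministic under a
#' fixed \code{seed}; with \code{seed = NULL} the caller's RNG stream is used.
#'
#' @param seq nucleotide string.
#' @param subRate,indelRate per-position rates in [0, 1).
#' @param seed optional integer seed.
#' @return The mutated sequence.
#' @export
mutateSequence <- function(seq, subRate, indelRate = 0, seed = NULL) {
  seq <- asSeqChar(seq)
  stopifnotScalarSeq(seq)
  if (subRate < 0 || subRate >= 1 || indelRate < 0 || indelRate >= 1)
    stop("rates must lie in [0, 1)")
  withSeed(seed, {
    x <- chars(seq)
    bases <- c("A", "C", "G", "T")
    if (subRate > 0) {
      hit <- which(runif(length(x)) < subRate)
      if (length(hit)) {
        alt <- vapply(x[hit], function(b) sample(setdiff(bases, b), 1L), character(1))
        x[hit] <- alt
      }
    }
    if (indelRate > 0) {
      hit <- which(runif(length(x)) < indelRate)
      if (length(hit)) {
        ins <- runif(length(hit)) < 0.5
        x[hit[!ins]] <- ""
        x[hit[ins]] <- paste0(sample(bases, sum(ins), replace = TRUE), x[hit[ins]])
      }
    }
    collapse0(x)
  })
}

#' Simulate uniform-coverage error-bearing reads from transcripts
#'
#' Read origins are drawn with probability proportional to
#' \code{abundance x transcript length}; start positions are uniform; each
#' base is substituted with probability \code{errRate}. Constant Phred 37
#' qualities are attached.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param abundances per-transcript molar abundances summing to 1.
#' @param nReads number of reads.
#' @param readLen read length; must not exceed any transcript length.
#' @param errRate per-base substitution error rate.
#' @param seed optional integer seed.
#' @return List with \code{reads} (named character vector),
#'   \code{qualities} (Phred+33 strings) and \code{truth} (data.frame
#'   \code{read}, \code{transcript}, \code{start}).
#' @export
simulateReads <- function(transcripts, abundances, nReads, readLen,
                          errRate = 0, seed = NULL) {
  transcripts <- vapply(transcripts, asSeqChar, character(1))
  if (is.null(names(transcripts)))
    names(transcripts) <- sprintf("tx%d", seq_along(transcripts))
  if (abs(sum(abundances) - 1) > 1e-8) stop("abundances must sum to 1")
  len <- nchar(transcripts)
  if (any(readLen > len)) stop("readLen exceeds a transcript length")
  withSeed(seed, {
    w <- abundances * len
    origin <- sample(seq_along(transcripts), nReads, replace = TRUE, prob = w)
    startMax <- len[origin] - readLen + 1L
    starts <- 1L + floor(runif(nReads) * startMax)
    reads <- substring(transcripts[origin], starts, starts + readLen - 1L)
    if (errRate > 0) {
      nerr <- rbinom(nReads, readLen, errRate)
      for (i in which(nerr > 0L)) {
        p <- sample.int(readLen, nerr[i])
        x <- chars(reads[[i]])
        x[p] <- vapply(x[p], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                       character(1))
        reads[[i]] <- collapse0(x)
      }
    }
    ids <- sprintf("read%06d", seq_len(nReads))
    names(reads) <- ids
    list(reads = reads,
         qualities = setNames(rep(strrep("F", readLen), nReads), ids),
         truth = data.frame(read = ids,
                            transcript = names(transcripts)[origin],
                            start = starts))
  })
}
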