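#' Gene model: exon intervals, strand and per-exon roles
#'
#' A \code{GeneModel} holds the exon structure of one gene on one contig.
#' Exons are stored as a \code{\link[GenomicRanges]{GRanges}} in 5'-to-3'
#' order on the gene strand, each tagged with a role: \code{"N-term"},
#' \code{"PTS"} (the single long mucin-domain exon, when present),
#' \code{"C-term"} or \code{"other"}.
#'
#' Coordinates are 1-based closed intervals, the Bioconductor convention;
#' GFF3 I/O is therefore a direct mapping.
#'
#' @slot geneId single character gene identifier.
#' @slot exons \code{GRanges} of exons (metadata column \code{role}),
#'   ordered 5' to 3' on the gene strand.
#' @export
setClass("GeneModel", representation(geneId = "character", exons = "GRanges"))

validGeneModel <- function(object) {
  ex <- object@exons
  msg <- character(0)
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  if (length(ex) == 0L) msg <- c(msg, "gene model needs at least one exon")
  if (length(unique(as.character(seqnames(ex)))) > 1L)
    msg <- c(msg, "all exons must lie on one contig")
  st <- unique(as.character(strand(ex)))
  if (length(st) != 1L || !st %in% c("+", "-"))
    msg <- c(msg, "exons must share one strand, '+' or '-'")
  role <- mcols(ex)$role
  if (is.null(role) || !all(role %in% c("N-term", "PTS", "C-term", "other")))
    msg <- c(msg, "each exon needs a role in {N-term, PTS, C-term, other}")
  if (sum(role == "PTS") > 1L) msg <- c(msg, "at most one exon may be tagged PTS")
  if (length(ex) > 1L) {
    s <- start(ex); e <- end(ex)
    ordered <- if (identical(st, "-")) all(diff(s) < 0) else all(diff(s) > 0)
    if (!ordered) msg <- c(msg, "exons must be ordered 5' to 3' on the gene strand")
    gs <- sort(s); ge <- sort(e)
    if (any(gs[-1L] <= ge[-length(ge)])) msg <- c(msg, "exons must not overlap")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GeneModel", validGeneModel)

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param exons \code{GRanges} of exon intervals, all on one contig and
#'   strand. They are reordered 5' to 3' automatically.
#' @param roles character vector of per-exon roles, parallel to \code{exons};
#'   defaults to \code{"other"}.
#' @return A \code{\linkS4class{GeneModel}}.
#' @examples
#' ex <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(1, 101), c(50, 200)),
#'                              strand = "+")
#' GeneModel("g1", ex, roles = c("N-term", "C-term"))
#' @export
GeneModel <- function(geneId, exons, roles = rep("other", length(exons))) {
  mcols(exons)$role <- roles
  st <- as.character(strand(exons))[1L]
  o <- order(start(exons), decreasing = identical(st, "-"))
  new("GeneModel", geneId = as.character(geneId), exons = exons[o])
}

#' @describeIn GeneModel gene identifier.
#' @param object,x a \code{GeneModel}.
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @describeIn GeneModel exon \code{GRanges} (5' to 3').
#' @export
setGeneric("modelExons", function(x) standardGeneric("modelExons"))
#' @export
setMethod("modelExons", "GeneModel", function(x) x@exons)

#' @describeIn GeneModel per-exon roles.
#' @export
setGeneric("exonRoles", function(x) standardGeneric("exonRoles"))
#' @export
setMethod("exonRoles", "GeneModel", function(x) mcols(x@exons)$role)

#' @describeIn GeneModel summed exon length (spliced transcript length).
#' @export
setGeneric("transcriptLength", function(x) standardGeneric("transcriptLength"))
#' @export
setMethod("transcriptLength", "GeneModel", function(x) sum(width(x@exons)))

setMethod("show", "GeneModel", function(object) {
  ex <- object@exons
  cat("GeneModel", object@geneId, "on", as.character(seqnames(ex))[1L],
      paste0("(", as.character(strand(ex))[1L], ")"), "\n")
  cat(" ", length(ex), "exon(s), transcript length",
      transcriptLength(object), "nt\n")
  cat("  roles:", paste(mcols(ex)$role, collapse = ", "), "\n")
})

#' Tandem-repeat decomposition of a (PTS) sequence
#'
#' Result of \code{\link{decomposeArray}}: the array cut into consecutive
#' period-length units, each classified perfect (full length and at least
#' the identity threshold against the consensus) or imperfect, plus the
#' consensus unit and a position-frequency matrix over perfect units.
#' Leading/trailing sequence not covered by full units is kept in the flanks,
#' so that \code{leading flank + units + trailing flank} reconstructs the
#' input exactly.
#'
#' @slot period repeat unit length (residues or nt).
#' @slot units data.frame with columns \code{start}, \code{end} (1-based,
#'   closed), \code{seq}, \code{identity} (percent vs consensus),
#'   \code{perfect} (logical).
#' @slot consensus consensus unit string (column-wise majority over perfect
#'   units; ties broken by the lexicographically smallest residue).
#' @slot pfm position x residue frequency matrix from perfect units
#'   (columns sum to 1).
#' @slot leadingFlank,trailingFlank unassigned sequence before/after the
#'   unit array.
#' @export
setClass("RepeatDecomposition", representation(
  period = "integer", units = "data.frame", consensus = "character",
  pfm = "matrix", leadingFlank = "character", trailingFlank = "character"))

setValidity("RepeatDecomposition", function(object) {
  msg <- character(0)
  if (nrow(object@units) > 0 &&
      !all(c("start", "end", "seq", "identity", "perfect") %in%
           colnames(object@units)))
    msg <- c(msg, "units must have start/end/seq/identity/perfect columns")
  if (ncol(object@pfm) > 0 && any(abs(colSums(object@pfm) - 1) > 1e-9))
    msg <- c(msg, "pfm columns must each sum to 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn RepeatDecomposition the detected/used period.
#' @param x,object a \code{RepeatDecomposition}.
#' @export
setGeneric("repeatPeriod", function(x) standardGeneric("repeatPeriod"))
#' @export
setMethod("repeatPeriod", "RepeatDecomposition", function(x) x@period)

#' @describeIn RepeatDecomposition data.frame of units.
#' @export
setGeneric("repeatUnits", function(x) standardGeneric("repeatUnits"))
#' @export
setMethod("repeatUnits", "RepeatDecomposition", function(x) x@units)

#' @describeIn RepeatDecomposition number of perfect units.
#' @export
setGeneric("nPerfect", function(x) standardGeneric("nPerfect"))
#' @export
setMethod("nPerfect", "RepeatDecomposition", function(x) sum(x@units$perfect))

#' @describeIn RepeatDecomposition number of imperfect units.
#' @export
setGeneric("nImperfect", function(x) standardGeneric("nImperfect"))
#' @export
setMethod("nImperfect", "RepeatDecomposition", function(x) sum(!x@units$perfect))

#' @describeIn RepeatDecomposition the consensus unit.
#' @export
setGeneric("consensusUnit", function(x) standardGeneric("consensusUnit"))
#' @export
setMethod("consensusUnit", "RepeatDecomposition", function(x) x@consensus)

#' @describeIn RepeatDecomposition position-frequency matrix (position x residue).
#' @export
setGeneric("unitPFM", function(x) standardGeneric("unitPFM"))
#' @export
setMethod("unitPFM", "RepeatDecomposition", function(x) x@pfm)

#' @describeIn RepeatDecomposition reassemble the input sequence from
#'   flanks and units.
#' @export
setGeneric("reconstructSequence", function(x) standardGeneric("reconstructSequence"))
#' @export
setMethod("reconstructSequence", "RepeatDecomposition", function(x) {
  paste0(x@leadingFlank, paste0(x@units$seq, collapse = ""), x@trailingFlank)
})

setMethod("show", "RepeatDecomposition", function(object) {
  cat("RepeatDecomposition: period", object@period, "\n")
  cat(" ", nrow(object@units), "units:", nPerfect(object), "perfect,",
      nImperfect(object), "imperfect\n")
  cat("  consensus:", object@consensus, "\n")
  if (nzchar(object@leadingFlank) || nzchar(object@trailingFlank))
    cat("  flanks:", nchar(object@leadingFlank), "/",
        nchar(object@trailingFlank), "residues\n")
})

#' In-silico PCR amplicon prediction
#'
#' Result of \code{\link{predictAmplicon}}: the chosen forward and reverse
#' primer binding sites on a template, the amplicon they delimit, and the
#' ordered restriction fragment lengths once \code{\link{digestSequence}} has
#' been applied (a single fragment equal to the amplicon length when
#' undigested).
#'
#' @slot templateId template sequence identifier.
#' @slot fwdSite,revSite integer \code{c(start, end, mismatches)} of the
#'   primer binding sites (1-based, closed; reverse site is on the minus
#'   strand).
#' @slot amplicon integer \code{c(start, end)} on the template.
#' @slot length amplicon length in bp.
#' @slot fragments ordered integer fragment lengths (sum equals
#'   \code{length}).
#' @export
setClass("AmpliconPrediction", representation(
  templateId = "character", fwdSite = "integer", revSite = "integer",
  amplicon = "integer", length = "integer", fragments = "integer"))

setValidity("AmpliconPrediction", function(object) {
  msg <- character(0)
  if (length(object@fragments) && sum(object@fragments) != object@length)
    msg <- c(msg, "fragments must sum to the amplicon length")
  if (object@fwdSite[1L] > object@revSite[1L])
    msg <- c(msg, "forward site must precede the reverse site")
  if (length(msg)) msg else TRUE
})

#' @describeIn AmpliconPrediction amplicon length in bp.
#' @param x,object an \code{AmpliconPrediction}.
#' @export
setGeneric("ampliconLength", function(x) standardGeneric("ampliconLength"))
#' @export
setMethod("ampliconLength", "AmpliconPrediction", function(x) x@length)

#' @describeIn AmpliconPrediction ordered fragment lengths after digestion.
#' @export
setGeneric("fragmentLengths", function(x) standardGeneric("fragmentLengths"))
#' @export
setMethod("fragmentLengths", "AmpliconPrediction", function(x) x@fragments)

setMethod("show", "AmpliconPrediction", function(object) {
  cat("AmpliconPrediction on", object@templateId, "\n")
  cat("  fwd site [", object@fwdSite[1L], ",", object@fwdSite[2L], "] (",
      object@fwdSite[3L], " mm), rev site [", object@revSite[1L], ",",
      object@revSite[2L], "] (", object@revSite[3L], " mm)\n", sep = "")
  cat("  amplicon", object@length, "bp")
  if (length(object@fragments) > 1L)
    cat("; fragments:", paste(object@fragments, collapse = " + "), "bp")
  cat("\n")
})
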