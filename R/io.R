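# Sequence and annotation I/O. Parsing of the standard formats is delegated
# to Biostrings/rtracklayer; this layer enforces the package's conventions
# (upper-case sequences, 1-based closed coordinates, 5'->3' exon order).

#' Read contigs from a FASTA file
#'
#' Reads genomic/contig sequences, concatenating wrapped lines and
#' normalizing to upper case.
#'
#' @param file path to a FASTA file.
#' @return A named \code{DNAStringSet}, one element per record. Record names
#'   are truncated at the first whitespace.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ac", "gt"), fa)
#' readContigs(fa)
#' @export
readContigs <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA stream: ", file)
  if (!startsWith(lines[[1L]], ">"))
    stop("malformed FASTA: sequence line before any '>' header")
  x <- readDNAStringSet(file)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(x)))
  names(seqs) <- sub("\\s.*$", "", names(x))
  DNAStringSet(seqs)
}

#' Write contigs to FASTA
#'
#' @param contigs named \code{DNAStringSet} (or named character vector).
#' @param file output path. Sequences are wrapped at 60 columns.
#' @return Invisibly, \code{file}.
#' @export
writeContigs <- function(contigs, file) {
  if (is.character(contigs)) contigs <- DNAStringSet(contigs)
  writeXStringSet(contigs, file, width = 60L)
  invisible(file)
}

#' Reverse complement of a nucleotide sequence
#'
#' IUPAC ambiguity codes are complemented class-wise (R to Y, etc.);
#' the operation is an involution.
#'
#' @param seq a single nucleotide string (IUPAC alphabet) or \code{DNAString}.
#' @return The reverse complement as a character string.
#' @examples
#' revComp("AAACTGCAGTT")
#' @export
revComp <- function(seq) {
  seq <- asSeqChar(seq)
  stopifnotScalarSeq(seq)
  as.character(reverseComplement(DNAString(seq)))
}

#' Translate a coding sequence
#'
#' Standard genetic code; internal stop codons are rendered \code{"*"}.
#'
#' @param cds nucleotide string whose length is a multiple of 3.
#' @return Protein string of length \code{nchar(cds) / 3}.
#' @examples
#' translateCds("ATGGCC")
#' @export
translateCds <- function(cds) {
  cds <- asSeqChar(cds)
  stopifnotScalarSeq(cds, "cds")
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length (", nchar(cds), ") is not a multiple of 3")
  as.character(suppressWarnings(translate(DNAString(cds))))
}

#' Read gene models from GFF3
#'
#' Exon features are grouped into genes by their \code{Parent} attribute
#' (falling back to \code{ID}/\code{gene_id}); minus-strand genes get their
#' exons ordered 5' to 3'. An optional \code{role} attribute on exon lines
#' is carried through.
#'
#' @param file path to a GFF3 file.
#' @param contigs optional \code{DNAStringSet}; when given, exons are checked
#'   to lie inside their contig.
#' @return A named list of \code{\linkS4class{GeneModel}}.
#' @export
readGeneModels <- function(file, contigs = NULL) {
  gr <- rtracklayer::import(file, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", file)
  md <- mcols(gr)
  gid <- if (!is.null(md$Parent) && any(lengths(md$Parent) > 0)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p[[1L]]) else NA_character_,
           character(1))
  } else NULL
  if (is.null(gid) || anyNA(gid))
    gid <- if (!is.null(md$gene_id)) as.character(md$gene_id) else as.character(md$ID)
  if (is.null(gid) || anyNA(gid))
    stop("exon features must carry Parent, gene_id or ID attributes")
  role <- if (!is.null(md$role)) as.character(md$role) else rep("other", length(gr))
  if (!is.null(contigs)) {
    len <- setNames(nchar(as.character(contigs)), names(contigs))
    cid <- as.character(seqnames(gr))
    if (any(!cid %in% names(len)))
      stop("exon on unknown contig: ", paste(unique(setdiff(cid, names(len))), collapse = ", "))
    if (any(start(gr) < 1L) || any(end(gr) > len[cid]))
      stop("exon outside contig bounds")
  }
  models <- lapply(split(seq_along(gr), gid), function(i) {
    ex <- GRanges(seqnames(gr)[i], IRanges(start(gr)[i], end(gr)[i]),
                  strand = strand(gr)[i])
    GeneModel(gid[i[1L]], ex, roles = role[i])
  })
  models[unique(gid)]
}

#' Write gene models to GFF3
#'
#' Emits a \code{gene} feature spanning each model plus one \code{exon}
#' feature per exon (with its \code{role} attribute), with the GFF3 version
#' pragma.
#'
#' @param models list of \code{\linkS4class{GeneModel}}.
#' @param file output path.
#' @return Invisibly, \code{file}.
#' @export
writeGeneModels <- function(models, file) {
  feats <- lapply(models, function(m) {
    ex <- modelExons(m)
    gene <- GRanges(seqnames(ex)[1L],
                    IRanges(min(start(ex)), max(end(ex))),
                    strand = strand(ex)[1L])
    mcols(gene)$type <- "gene"
    mcols(gene)$ID <- geneId(m)
    mcols(ex)$type <- "exon"
    mcols(ex)$Parent <- geneId(m)
    mcols(ex)$ID <- paste0(geneId(m), ".exon", seq_along(ex))
    suppressWarnings(c(gene, ex))
  })
  gr <- do.call(c, unname(feats))
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' Spliced, stranded transcript sequence of a gene model
#'
#' @param contig the contig sequence (character or \code{DNAString}) the
#'   model lives on.
#' @param model a \code{\linkS4class{GeneModel}}.
#' @return Character string: exon sequences concatenated 5' to 3'; for
#'   minus-strand genes each exon is reverse-complemented.
#' @export
transcriptSeq <- function(contig, model) {
  contig <- asSeqChar(contig)
  ex <- modelExons(model)
  minus <- as.character(strand(ex))[1L] == "-"
  pieces <- substring(contig, start(ex), end(ex))
  if (minus) pieces <- vapply(pieces, revComp, character(1))
  collapse0(pieces)
}

#' Read short reads from FASTQ
#'
#' Phred+33 qualities are parsed and kept alongside the sequences.
#'
#' @param file path to a FASTQ file.
#' @return A \code{QualityScaledDNAStringSet}.
#' @export
readReads <- function(file) {
  # the reader warns about dropping (empty) mcols on every file; silence it
  suppressWarnings(readQualityScaledDNAStringSet(file))
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a \code{QualityScaledDNAStringSet}, or named character vector
#'   (constant quality 'I' is then written).
#' @param file output path.
#' @return Invisibly, \code{file}.
#' @export
writeReads <- function(reads, file) {
  if (is.character(reads)) {
    q <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
    reads <- QualityScaledDNAStringSet(DNAStringSet(reads), PhredQuality(q))
  }
  writeXStringSet(reads, file, format = "fastq", qualities = quality(reads))
  invisible(file)
}
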