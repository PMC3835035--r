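# Standard-format I/O: FASTA via Biostrings, GFF3 via rtracklayer.

#' Read / write FASTA files
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] so that every module reads and writes
#' multi-record, line-wrapped FASTA the same way.
#'
#' @param path file path.
#' @return `readFastaDNA` returns a [Biostrings::DNAStringSet];
#'   `readFastaAA` an [Biostrings::AAStringSet].
#' @export
readFastaDNA <- function(path) readDNAStringSet(path)

#' @rdname readFastaDNA
#' @export
readFastaAA <- function(path) readAAStringSet(path)

#' @rdname readFastaDNA
#' @param seqs a [Biostrings::XStringSet] (or named character vector).
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- DNAStringSet(seqs)
  }
  writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write a gene model to GFF3 (and optionally its genome to FASTA)
#'
#' Exon features carry `ID` (the exon label), `Parent` (the gene) and the
#' custom attribute `splicing_class`.  GFF3 coordinates are 1-based closed,
#' which is also the internal convention, so no shifting occurs at this
#' boundary.
#'
#' @param model a [GeneModel-class].
#' @param path output GFF3 path.
#' @param fastaPath optional path for the genomic FASTA.
#' @return `path`, invisibly.
#' @export
writeGeneModel <- function(model, path, fastaPath = NULL) {
  ex <- model@exons
  gene <- GRanges(seqnames = geneId(model),
                  ranges = IRanges(min(start(ex)), max(end(ex))),
                  strand = "+",
                  type = "gene",
                  ID = geneId(model))
  exf <- GRanges(seqnames = geneId(model), ranges = IRanges(start(ex), end(ex)),
                 strand = "+",
                 type = "exon",
                 ID = mcols(ex)$label,
                 Parent = geneId(model),
                 splicing_class = mcols(ex)$splicing_class)
  rtracklayer::export(c(gene, exf), path, format = "gff3")
  if (!is.null(fastaPath)) {
    writeFasta(setNames(DNAStringSet(model@genome), geneId(model)), fastaPath)
  }
  invisible(path)
}

#' Read a gene model from GFF3
#'
#' Exon features (`type == "exon"`) belonging to `geneId` (or to the single
#' gene present) are collected into a [GeneModel-class].  Minus-strand models
#' are normalized to the coding strand at load time: the genome is
#' reverse-complemented and exon coordinates are flipped, so downstream code
#' always works on `"+"`.
#'
#' @param path GFF3 path.
#' @param genome genomic sequence ([Biostrings::DNAString], character, or a
#'   FASTA path).
#' @param geneId optional gene identifier to select; defaults to the single
#'   gene in the file.
#' @return a [GeneModel-class].
#' @export
readGeneModel <- function(path, genome, geneId = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      grepl("\\.(fa|fasta|fna)$", genome, ignore.case = TRUE)) {
    genome <- as.character(readFastaDNA(genome)[[1L]])
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e)))
  ex <- gr[!is.na(mcols(gr)$type) & mcols(gr)$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  if (is.null(geneId)) {
    parents <- unique(unlist(mcols(ex)$Parent))
    if (length(parents) > 1L) {
      stop("multiple genes in file; pass geneId explicitly")
    }
    geneId <- if (length(parents) == 1L) parents else "gene"
  } else {
    ex <- ex[vapply(mcols(ex)$Parent,
                    function(p) geneId %in% p, logical(1))]
  }
  minus <- as.character(strand(ex)) == "-"
  genome <- .asChar(genome)
  tab <- data.frame(label = mcols(ex)$ID,
                    start = start(ex), end = end(ex),
                    splicing_class = if (!is.null(mcols(ex)$splicing_class))
                      mcols(ex)$splicing_class else "constitutive",
                    stringsAsFactors = FALSE)
  if (all(minus) && length(minus) > 0L) {
    L <- nchar(genome)
    newStart <- L - tab$end + 1L
    newEnd <- L - tab$start + 1L
    tab$start <- newStart
    tab$end <- newEnd
    genome <- revComp(genome)
  } else if (any(minus)) {
    stop("exons on mixed strands are not supported")
  }
  newGeneModel(geneId, genome, tab)
}
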