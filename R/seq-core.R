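#' Translate a DNA sequence in one reading frame
#'
#' Uses the standard genetic code (translation table 1).  The trailing partial
#' codon is dropped; stop codons are rendered as `*`; any codon containing an
#' IUPAC ambiguity code is translated as `X`.
#'
#' @param dna a [Biostrings::DNAString] or character scalar.
#' @param frame integer 0, 1 or 2: number of nucleotides skipped at the 5'
#'   end before the first codon.
#' @return an [Biostrings::AAString] (possibly empty).
#' @examples
#' translateFrame("ATGAAA", 0)   # MK
#' translateFrame("ATGAAA", 1)   # TGA -> "*"
#' @export
translateFrame <- function(dna, frame = 0) {
  if (length(frame) != 1L || !frame %in% 0:2) {
    stop("frame must be 0, 1 or 2")
  }
  s <- .asChar(dna)
  .checkDna(s, "dna")
  n <- nchar(s)
  from <- frame + 1L
  len <- if (n >= from) (n - frame) %/% 3L * 3L else 0L
  if (len == 0L) return(AAString(""))
  sub <- substr(s, from, from + len - 1L)
  d <- DNAString(sub)
  # the fuzzy-codon path rebuilds a large lookup table per call; take it
  # only when ambiguity codes are actually present
  if (grepl("[^ACGT]", sub)) {
    translate(d, if.fuzzy.codon = "X")
  } else {
    translate(d)
  }
}

#' Reverse complement with IUPAC ambiguity support
#'
#' @param dna a [Biostrings::DNAString] or character scalar over the IUPAC
#'   DNA alphabet.
#' @return the reverse complement, in the same representation as the input.
#' @examples
#' revComp("ACGT")  # "ACGT"
#' revComp("AAAA")  # "TTTT"
#' @export
revComp <- function(dna) {
  asString <- is(dna, "DNAString")
  s <- .asChar(dna)
  .checkDna(s, "dna")
  out <- as.character(reverseComplement(DNAString(s)))
  if (asString) DNAString(out) else out
}

#' Construct a gene model
#'
#' Builds a validated [GeneModel-class] from an exon table.  Phases (codon
#' offset at each exon start, for the reading that includes every exon) are
#' computed automatically; alternative exons whose length is not a multiple
#' of three are flagged `frame_shifting`.
#'
#' @param geneId gene identifier.
#' @param genome genomic sequence ([Biostrings::DNAString] or character).
#' @param exons data.frame with columns `label`, `start`, `end` (1-based
#'   closed) and optionally `splicing_class` (default `"constitutive"`).
#' @return a [GeneModel-class].
#' @export
newGeneModel <- function(geneId, genome, exons) {
  s <- .asChar(genome)
  .checkDna(s, "genome")
  stopifnot(is.data.frame(exons),
            all(c("label", "start", "end") %in% colnames(exons)))
  if (is.null(exons$splicing_class)) exons$splicing_class <- "constitutive"
  exons <- exons[order(exons$start), , drop = FALSE]
  w <- exons$end - exons$start + 1L
  cum <- cumsum(c(0L, w[-length(w)]))
  phase <- as.integer(cum %% 3L)
  gr <- GRanges(seqnames = geneId,
                ranges = IRanges(start = as.integer(exons$start),
                                 end = as.integer(exons$end)),
                strand = "+",
                label = as.character(exons$label),
                splicing_class = as.character(exons$splicing_class),
                phase = phase,
                frame_shifting = exons$splicing_class == "alternative" &
                  w %% 3L != 0L)
  new("GeneModel", geneId = geneId, genome = DNAString(s), exons = gr)
}

.exonSeq <- function(model, label) {
  ex <- model@exons
  i <- match(label, mcols(ex)$label)
  substr(as.character(model@genome), start(ex)[i], end(ex)[i])
}

#' Splice a transcript from a gene model
#'
#' Concatenates the chosen exons in genomic order.  All constitutive exons
#' must be included; excluding one is a contract error (use alternative
#' exons for optional inclusion).
#'
#' @param model a [GeneModel-class].
#' @param included exon labels to include (default: all exons).
#' @param label isoform label for the resulting transcript.
#' @return a [Transcript-class].
#' @export
spliceTranscript <- function(model, included = exonLabels(model),
                             label = "transcript") {
  labs <- exonLabels(model)
  unknown <- setdiff(included, labs)
  if (length(unknown) > 0L) {
    stop("unknown exon label(s): ", paste(unknown, collapse = ", "))
  }
  cls <- mcols(model@exons)$splicing_class
  missingConst <- setdiff(labs[cls == "constitutive"], included)
  if (length(missingConst) > 0L) {
    stop("constitutive exon(s) excluded: ",
         paste(missingConst, collapse = ", "))
  }
  keep <- labs[labs %in% included]        # genomic order
  seqs <- vapply(keep, function(l) .exonSeq(model, l), character(1))
  new("Transcript", isoformLabel = label, includedExons = keep,
      seq = DNAString(paste(seqs, collapse = "")))
}

#' Translate a transcript (frame 0)
#'
#' @param transcript a [Transcript-class].
#' @return an [Biostrings::AAString].
#' @export
translateTranscript <- function(transcript) {
  translateFrame(transcript@seq, 0)
}
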