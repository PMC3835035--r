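#' @import methods
#' @importFrom Biostrings DNAString AAString DNAStringSet AAStringSet
#'   readDNAStringSet readAAStringSet writeXStringSet reverseComplement
#'   translate subseq matchPattern mismatch GENETIC_CODE
#' @importFrom GenomicRanges GRanges start end width strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom stats setNames
#' @importFrom utils write.table read.table head tail combn
NULL

#' Gene model on a genomic sequence
#'
#' A `GeneModel` holds a genomic (coding-strand) sequence together with an
#' ordered, non-overlapping set of exons.  Exons carry a `label`, a
#' `splicing_class` (`"constitutive"` or `"alternative"`), a `phase` (codon
#' offset at exon start, computed for the all-exon reading) and a
#' `frame_shifting` flag for alternative exons whose length is not a multiple
#' of three.  Coordinates are 1-based closed intervals, the convention of
#' IRanges/GRanges and of GFF3 itself.  Minus-strand input is normalized to
#' the coding strand at load time ([readGeneModel()]), so downstream code only
#' ever sees `"+"`.
#'
#' @slot geneId single gene identifier.
#' @slot genome a [Biostrings::DNAString] with the genomic sequence.
#' @slot exons a [GenomicRanges::GRanges] of exon intervals with metadata
#'   columns `label`, `splicing_class`, `phase`, `frame_shifting`.
#'
#' @seealso [newGeneModel()], [spliceTranscript()], [readGeneModel()]
#' @export
setClass("GeneModel",
         representation(geneId = "character",
                        genome = "DNAString",
                        exons = "GRanges"))

setValidity("GeneModel", function(object) {
  msg <- character(0)
  ex <- object@exons
  mc <- mcols(ex)
  need <- c("label", "splicing_class", "phase", "frame_shifting")
  if (!all(need %in% colnames(mc))) {
    return(paste("exon metadata must contain:", paste(need, collapse = ", ")))
  }
  if (length(ex) == 0L) msg <- c(msg, "a GeneModel needs at least one exon")
  if (anyDuplicated(mc$label)) msg <- c(msg, "exon labels must be unique")
  if (!all(mc$splicing_class %in% c("constitutive", "alternative"))) {
    msg <- c(msg, "splicing_class must be constitutive or alternative")
  }
  if (length(ex) > 0L) {
    if (any(width(ex) < 1L)) msg <- c(msg, "exon length must be >= 1")
    if (is.unsorted(start(ex), strictly = TRUE)) {
      msg <- c(msg, "exons must be strictly ordered by start")
    }
    if (length(ex) > 1L) {
      gapLen <- start(ex)[-1L] - end(ex)[-length(ex)] - 1L
      if (any(gapLen < 4L)) {
        msg <- c(msg, "introns must be >= 4 nt (room for GT...AG)")
      }
    }
    if (max(end(ex)) > length(object@genome)) {
      msg <- c(msg, "exons extend beyond the genomic sequence")
    }
    shifty <- mc$splicing_class == "alternative" & width(ex) %% 3L != 0L
    if (any(shifty & !mc$frame_shifting)) {
      msg <- c(msg,
        "alternative exons with length not a multiple of 3 must be flagged frame_shifting")
    }
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Spliced transcript of a gene model
#'
#' @slot isoformLabel transcript / isoform label.
#' @slot includedExons labels of the included exons, in genomic order.
#' @slot seq the spliced [Biostrings::DNAString].
#'
#' @seealso [spliceTranscript()], [enumerateIsoforms()]
#' @export
setClass("Transcript",
         representation(isoformLabel = "character",
                        includedExons = "character",
                        seq = "DNAString"))

#' Splice graph: constitutive plus optional exons of a gene model
#'
#' @slot model the underlying [GeneModel-class].
#' @slot optionalExons labels of the alternatively spliced exons.
#'
#' @seealso [spliceGraph()], [enumerateIsoforms()]
#' @export
setClass("SpliceGraph",
         representation(model = "GeneModel",
                        optionalExons = "character"))

setValidity("SpliceGraph", function(object) {
  labs <- exonLabels(object@model)
  if (!all(object@optionalExons %in% labs)) {
    return("optional exons must be labels of the gene model")
  }
  TRUE
})

#' Primer pair for in silico RT-PCR
#'
#' Both primers are given 5'->3'; the reverse primer anneals to the sense
#' strand as its reverse complement.  IUPAC ambiguity codes are allowed
#' (degenerate primers).
#'
#' @slot name primer pair name, e.g. `"Ms1-6R"`.
#' @slot forward,reverse [Biostrings::DNAString] primers, 15-35 nt.
#'
#' @seealso [primerPair()], [inSilicoPcr()]
#' @export
setClass("PrimerPair",
         representation(name = "character",
                        forward = "DNAString",
                        reverse = "DNAString"))

setValidity("PrimerPair", function(object) {
  lf <- length(object@forward); lr <- length(object@reverse)
  if (lf < 15L || lf > 35L || lr < 15L || lr > 35L) {
    return("primers must be 15-35 nt long")
  }
  TRUE
})

#' Assembly report: scaffolds, placements, conflicts, gaps
#'
#' Produced by [assembleFragments()] and updated by [bridgeGaps()].
#'
#' @slot scaffolds a [Biostrings::DNAStringSet] of merged scaffolds, ordered
#'   by decreasing length (ties broken lexicographically).
#' @slot placements data.frame with one row per input fragment: `fragment`,
#'   `scaffold`, `offset` (1-based within the scaffold), `strand`, `placed`,
#'   `note`.
#' @slot conflicts data.frame `fragment_a`, `fragment_b`, `kind` with kinds
#'   `strand_inversion`, `order_inversion`, `internal_deletion`.
#' @slot gaps data.frame `junction`, `left_scaffold`, `right_scaffold`,
#'   `bridged`, `bridged_by`.
#'
#' @export
setClass("AssemblyReport",
         representation(scaffolds = "DNAStringSet",
                        placements = "data.frame",
                        conflicts = "data.frame",
                        gaps = "data.frame"))

#' Architecture report for a projectin-like protein
#'
#' Result of [classifyArchitecture()]: the observed domain layout measured
#' against the canonical projectin template (two N-terminal Ig tracts
#' separated by the PEVK/NTCS-1 unique region, a core of tandem
#' \[Fn-Fn-Ig\] repeats, and a C-terminal kinase domain).
#'
#' @slot tractSizes integer(2): Ig counts before/after the unique region.
#' @slot coreRepeats observed number of consecutive \[Fn-Fn-Ig\] repeats.
#' @slot kinasePresent logical.
#' @slot uniqueRegion,pevkRegion,ntcs1Region integer(2) amino-acid intervals
#'   (1-based closed) or `NA` when empty.
#' @slot yerpCount,yerpPositions count and start offsets of YERP motifs in
#'   the unique region.
#' @slot linkers observed inter-domain linker lengths (aa).
#' @slot deviations character codes for departures from the template.
#' @slot calls the domain-call data.frame the report was built from.
#'
#' @export
setClass("ArchitectureReport",
         representation(tractSizes = "integer",
                        coreRepeats = "integer",
                        kinasePresent = "logical",
                        uniqueRegion = "integer",
                        pevkRegion = "integer",
                        ntcs1Region = "integer",
                        yerpCount = "integer",
                        yerpPositions = "integer",
                        linkers = "integer",
                        deviations = "character",
                        calls = "data.frame"))

#' Ground truth bundle emitted by the synthetic-data generator
#'
#' @slot model the true [GeneModel-class].
#' @slot protein the full-length translated protein ([Biostrings::AAString]).
#' @slot domainMap data.frame `kind`, `start`, `end` (aa, 1-based closed) of
#'   every planted Ig/Fn/Kinase domain.
#' @slot uniqueRegion integer(2) aa interval between the two Ig tracts.
#' @slot pevkBoundary last aa of the planted PEVK block (the NTCS-1 segment
#'   starts at `pevkBoundary + 1`).
#' @slot isoformPools named list: sample label -> isoform labels present.
#' @slot references per-exon clean (unmutated) peptides
#'   ([Biostrings::AAStringSet] named by exon label), the homology input for
#'   exon prediction.
#' @slot config the echoed generator configuration.
#'
#' @seealso [generateGene()]
#' @export
setClass("SyntheticTruth",
         representation(model = "GeneModel",
                        protein = "AAString",
                        domainMap = "data.frame",
                        uniqueRegion = "integer",
                        pevkBoundary = "integer",
                        isoformPools = "list",
                        references = "AAStringSet",
                        config = "list"))
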