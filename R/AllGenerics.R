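# Generics, accessors and show() methods.

#' @describeIn GeneModel gene identifier
#' @param object,x an object of the documented class
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))
#' @export
setMethod("geneId", "GeneModel", function(object) object@geneId)

#' @describeIn GeneModel the genomic [Biostrings::DNAString]
#' @export
setGeneric("genomeSeq", function(object) standardGeneric("genomeSeq"))
#' @export
setMethod("genomeSeq", "GeneModel", function(object) object@genome)

#' @describeIn GeneModel exon [GenomicRanges::GRanges] with metadata
#' @export
setGeneric("exonRanges", function(object) standardGeneric("exonRanges"))
#' @export
setMethod("exonRanges", "GeneModel", function(object) object@exons)

#' @describeIn GeneModel exon labels in genomic order
#' @export
setGeneric("exonLabels", function(object) standardGeneric("exonLabels"))
#' @export
setMethod("exonLabels", "GeneModel", function(object) mcols(object@exons)$label)

#' @describeIn GeneModel exon table as a plain data.frame (label, start, end,
#'   width, splicing_class, phase, frame_shifting)
#' @export
setGeneric("exonTable", function(object) standardGeneric("exonTable"))
#' @export
setMethod("exonTable", "GeneModel", function(object) {
  ex <- object@exons
  data.frame(label = mcols(ex)$label,
             start = start(ex), end = end(ex), width = width(ex),
             splicing_class = mcols(ex)$splicing_class,
             phase = mcols(ex)$phase,
             frame_shifting = mcols(ex)$frame_shifting,
             stringsAsFactors = FALSE)
})

#' @export
setMethod("show", "GeneModel", function(object) {
  ex <- object@exons
  nAlt <- sum(mcols(ex)$splicing_class == "alternative")
  cat(sprintf("GeneModel '%s': %d nt genomic sequence, %d exons (%d alternative)\n",
              object@geneId, length(object@genome), length(ex), nAlt))
  cat(sprintf("  coding span %d-%d; exon labels: %s\n",
              min(start(ex)), max(end(ex)),
              paste(head(mcols(ex)$label, 6L), collapse = ", ")))
})

#' @describeIn Transcript isoform label
#' @export
setGeneric("isoformLabel", function(object) standardGeneric("isoformLabel"))
#' @export
setMethod("isoformLabel", "Transcript", function(object) object@isoformLabel)

#' @describeIn Transcript labels of included exons
#' @export
setGeneric("includedExons", function(object) standardGeneric("includedExons"))
#' @export
setMethod("includedExons", "Transcript", function(object) object@includedExons)

#' @describeIn Transcript spliced sequence as a [Biostrings::DNAString]
#' @export
setGeneric("transcriptSeq", function(object) standardGeneric("transcriptSeq"))
#' @export
setMethod("transcriptSeq", "Transcript", function(object) object@seq)

#' @export
setMethod("length", "Transcript", function(x) length(x@seq))

#' @export
setMethod("show", "Transcript", function(object) {
  cat(sprintf("Transcript '%s': %d nt from %d exons (%s)\n",
              object@isoformLabel, length(object@seq),
              length(object@includedExons),
              paste(head(object@includedExons, 8L), collapse = ",")))
})

#' @describeIn SpliceGraph labels of the optional (alternative) exons
#' @export
setGeneric("optionalExons", function(object) standardGeneric("optionalExons"))
#' @export
setMethod("optionalExons", "SpliceGraph", function(object) object@optionalExons)

#' @describeIn SpliceGraph labels of the constitutive exons
#' @export
setGeneric("constitutiveExons",
           function(object) standardGeneric("constitutiveExons"))
#' @export
setMethod("constitutiveExons", "SpliceGraph", function(object) {
  setdiff(exonLabels(object@model), object@optionalExons)
})

#' @export
setMethod("show", "SpliceGraph", function(object) {
  cat(sprintf("SpliceGraph on '%s': %d exons, %d optional -> %d isoforms\n",
              geneId(object@model), length(exonLabels(object@model)),
              length(object@optionalExons),
              2^length(object@optionalExons)))
})

#' @export
setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair '%s'\n  F: %s\n  R: %s\n", object@name,
              as.character(object@forward), as.character(object@reverse)))
})

#' @describeIn AssemblyReport scaffold sequences
#' @export
setGeneric("scaffolds", function(object) standardGeneric("scaffolds"))
#' @export
setMethod("scaffolds", "AssemblyReport", function(object) object@scaffolds)

#' @describeIn AssemblyReport conflict table
#' @export
setGeneric("conflicts", function(object) standardGeneric("conflicts"))
#' @export
setMethod("conflicts", "AssemblyReport", function(object) object@conflicts)

#' @describeIn AssemblyReport gap table (method on the [IRanges::gaps()]
#'   generic)
#' @importFrom IRanges gaps
#' @export gaps
#' @aliases gaps
#' @export
setMethod("gaps", "AssemblyReport", function(x, start = NA, end = NA) x@gaps)

#' @describeIn AssemblyReport per-fragment placement table
#' @export
setGeneric("placements", function(object) standardGeneric("placements"))
#' @export
setMethod("placements", "AssemblyReport", function(object) object@placements)

#' @export
setMethod("show", "AssemblyReport", function(object) {
  cat(sprintf("AssemblyReport: %d scaffold(s) (%s nt), %d conflict(s), %d gap(s)\n",
              length(object@scaffolds),
              paste(width(object@scaffolds), collapse = "+"),
              nrow(object@conflicts), nrow(object@gaps)))
})

#' @describeIn ArchitectureReport observed Ig tract sizes, integer(2)
#' @export
setGeneric("tractSizes", function(object) standardGeneric("tractSizes"))
#' @export
setMethod("tractSizes", "ArchitectureReport", function(object) object@tractSizes)

#' @describeIn ArchitectureReport observed number of \[Fn-Fn-Ig\] core repeats
#' @export
setGeneric("coreRepeats", function(object) standardGeneric("coreRepeats"))
#' @export
setMethod("coreRepeats", "ArchitectureReport",
          function(object) object@coreRepeats)

#' @describeIn ArchitectureReport template deviation codes
#' @export
setGeneric("deviations", function(object) standardGeneric("deviations"))
#' @export
setMethod("deviations", "ArchitectureReport", function(object) object@deviations)

#' @describeIn ArchitectureReport PEVK sub-region (aa interval) of the unique
#'   region
#' @export
setGeneric("pevkRegion", function(object) standardGeneric("pevkRegion"))
#' @export
setMethod("pevkRegion", "ArchitectureReport", function(object) object@pevkRegion)

#' @describeIn ArchitectureReport NTCS-1 sub-region (aa interval)
#' @export
setGeneric("ntcs1Region", function(object) standardGeneric("ntcs1Region"))
#' @export
setMethod("ntcs1Region", "ArchitectureReport",
          function(object) object@ntcs1Region)

#' @describeIn ArchitectureReport YERP motif count in the unique region
#' @export
setGeneric("yerpCount", function(object) standardGeneric("yerpCount"))
#' @export
setMethod("yerpCount", "ArchitectureReport", function(object) object@yerpCount)

#' @export
setMethod("show", "ArchitectureReport", function(object) {
  cat(sprintf("ArchitectureReport: Ig tracts (%s), %d [Fn-Fn-Ig] core repeats, kinase %s\n",
              paste(object@tractSizes, collapse = ","), object@coreRepeats,
              if (object@kinasePresent) "present" else "absent"))
  pr <- object@pevkRegion; nr <- object@ntcs1Region
  cat(sprintf("  PEVK %s, NTCS-1 %s, %d YERP motif(s)\n",
              if (anyNA(pr)) "empty" else paste(pr, collapse = "-"),
              if (anyNA(nr)) "empty" else paste(nr, collapse = "-"),
              object@yerpCount))
  if (length(object@deviations) == 0L) {
    cat("  conforms to template (no deviations)\n")
  } else {
    cat("  deviations:", paste(object@deviations, collapse = "; "), "\n")
  }
})

#' @describeIn SyntheticTruth the true gene model
#' @export
setGeneric("truthModel", function(object) standardGeneric("truthModel"))
#' @export
setMethod("truthModel", "SyntheticTruth", function(object) object@model)

#' @describeIn SyntheticTruth the full translated protein
#' @export
setGeneric("truthProtein", function(object) standardGeneric("truthProtein"))
#' @export
setMethod("truthProtein", "SyntheticTruth", function(object) object@protein)

#' @describeIn SyntheticTruth planted domain map (aa coordinates)
#' @export
setGeneric("domainMap", function(object) standardGeneric("domainMap"))
#' @export
setMethod("domainMap", "SyntheticTruth", function(object) object@domainMap)

#' @describeIn SyntheticTruth per-sample isoform pools
#' @export
setGeneric("isoformPools", function(object) standardGeneric("isoformPools"))
#' @export
setMethod("isoformPools", "SyntheticTruth", function(object) object@isoformPools)

#' @describeIn SyntheticTruth clean per-exon reference peptides
#' @export
setGeneric("exonReferences", function(object) standardGeneric("exonReferences"))
#' @export
setMethod("exonReferences", "SyntheticTruth", function(object) object@references)

#' @export
setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth (seed %s): gene '%s', %d exons, %d planted domains\n",
              object@config$seed, geneId(object@model),
              length(exonLabels(object@model)), nrow(object@domainMap)))
  cat(sprintf("  unique region %d-%d aa, PEVK/NTCS-1 boundary at %d\n",
              object@uniqueRegion[1], object@uniqueRegion[2],
              object@pevkBoundary))
})
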