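# End-to-end orchestration: generate -> assemble -> predict-exons ->
# scan-pevk -> annotate -> isoforms -> compare, with plain-file handoff
# between stages and a checksum manifest for reproducibility.

#' Pipeline configuration
#'
#' @param outDir output directory (created if missing).
#' @param seed seed propagated to every stochastic stage.
#' @param generator a [generatorConfig()]; its seed is overridden by `seed`.
#' @param stages character subset of the seven stage names, in any order;
#'   they always execute in dependency order.
#' @param minOverlap assembly overlap floor, nt.
#' @param anchorMinIdentity minimum anchoring identity for exon prediction.
#' @param scanMinLength,scanMinFraction PEVK scanner settings.
#' @return a named list.
#' @export
pipelineConfig <- function(outDir, seed = 1L,
                           generator = generatorConfig(),
                           stages = c("generate", "assemble", "predict-exons",
                                      "scan-pevk", "annotate", "isoforms",
                                      "compare"),
                           minOverlap = 20L, anchorMinIdentity = 0.7,
                           scanMinLength = 10L, scanMinFraction = 0.6) {
  known <- c("generate", "assemble", "predict-exons", "scan-pevk",
             "annotate", "isoforms", "compare")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  generator$seed <- as.integer(seed)
  list(outDir = outDir, seed = as.integer(seed), generator = generator,
       stages = known[known %in% stages], minOverlap = as.integer(minOverlap),
       anchorMinIdentity = anchorMinIdentity,
       scanMinLength = as.integer(scanMinLength),
       scanMinFraction = scanMinFraction)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order with plain-file
#' handoff (FASTA/GFF3/TSV/JSON) so any stage's inputs and outputs can be
#' inspected or re-used.  A manifest with the md5 checksum of every output
#' is written to `manifest.json`; identical configuration and seed yield
#' identical checksums.  On stage failure a `<stage>.partial` marker is
#' left in the output directory and the run aborts naming the stage.
#'
#' @param config a [pipelineConfig()].
#' @return the manifest data.frame (`stage`, `file`, `md5`), invisibly
#'   written to `manifest.json`.
#' @export
runPipeline <- function(config) {
  outDir <- config$outDir
  if (is.null(outDir) || !nzchar(outDir)) stop("pre-flight: outDir not set")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("pre-flight: cannot create ", outDir)

  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  note <- function(stage, paths) {
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, file = basename(paths),
                                  md5 = unname(tools::md5sum(paths)),
                                  stringsAsFactors = FALSE))
  }
  runStage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    marker <- file.path(outDir, paste0(stage, ".partial"))
    file.create(marker)
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    file.remove(marker)
    res
  }

  truth <- NULL; frags <- NULL; asmRep <- NULL
  genomePath <- file.path(outDir, "genome.fasta")

  truth <- runStage("generate", function() {
    tr <- generateGene(config$generator)
    writeGeneModel(truthModel(tr), file.path(outDir, "truth_model.gff3"),
                   fastaPath = genomePath)
    .writeTsv(domainMap(tr), file.path(outDir, "domain_map.tsv"))
    poolsDf <- do.call(rbind, lapply(names(isoformPools(tr)), function(s) {
      data.frame(sample = s,
                 isoforms = paste(isoformPools(tr)[[s]], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    .writeTsv(poolsDf, file.path(outDir, "isoform_pools.tsv"))
    note("generate", file.path(outDir, c("genome.fasta", "truth_model.gff3",
                                         "domain_map.tsv",
                                         "isoform_pools.tsv")))
    tr
  })
  if (is.null(truth)) stop("pre-flight: the generate stage is required")

  runStage("assemble", function() {
    fr <- generateFragments(truth)
    writeFasta(fr$fragments, file.path(outDir, "fragments.fasta"))
    rep <- assembleFragments(fr$fragments, config$minOverlap)
    writeFasta(scaffolds(rep), file.path(outDir, "scaffolds.fasta"))
    .writeTsv(conflicts(rep), file.path(outDir, "assembly_conflicts.tsv"))
    .writeTsv(gaps(rep), file.path(outDir, "assembly_gaps.tsv"))
    note("assemble", file.path(outDir, c("fragments.fasta", "scaffolds.fasta",
                                         "assembly_conflicts.tsv",
                                         "assembly_gaps.tsv")))
  })

  runStage("predict-exons", function() {
    anchors <- anchorDomains(genomeSeq(truthModel(truth)),
                             exonReferences(truth),
                             config$anchorMinIdentity)
    pred <- refineBoundaries(anchors, genomeSeq(truthModel(truth)),
                             references = exonReferences(truth))
    writeGeneModel(pred$model, file.path(outDir, "predicted_model.gff3"))
    .writeTsv(pred$sites, file.path(outDir, "splice_sites.tsv"))
    cd <- generateCdnaPools(truth)
    ver <- verifyWithCdna(pred$model, cd$flight, sites = pred$sites)
    .writeTsv(ver$report, file.path(outDir, "cdna_verification.tsv"))
    note("predict-exons",
         file.path(outDir, c("predicted_model.gff3", "splice_sites.tsv",
                             "cdna_verification.tsv")))
  })

  runStage("scan-pevk", function() {
    segs <- threeFrameScan(genomeSeq(truthModel(truth)),
                           config$scanMinLength, config$scanMinFraction)
    .writeTsv(segs, file.path(outDir, "pevk_segments.tsv"))
    note("scan-pevk", file.path(outDir, "pevk_segments.tsv"))
  })

  archReport <- runStage("annotate", function() {
    prot <- truthProtein(truth)
    calls <- findDomains(prot, consensusDomains())
    rep <- classifyArchitecture(calls, prot,
                                template = truth@config$template,
                                minLength = config$scanMinLength,
                                minFraction = config$scanMinFraction)
    .writeTsv(rep@calls, file.path(outDir, "domain_calls.tsv"))
    jsonlite::write_json(
      list(tract_sizes = tractSizes(rep), core_repeats = coreRepeats(rep),
           kinase_present = rep@kinasePresent,
           pevk_region = pevkRegion(rep), ntcs1_region = ntcs1Region(rep),
           yerp_count = yerpCount(rep), deviations = deviations(rep)),
      file.path(outDir, "architecture.json"), auto_unbox = TRUE)
    note("annotate", file.path(outDir, c("domain_calls.tsv",
                                         "architecture.json")))
    rep
  })

  isoTab <- runStage("isoforms", function() {
    isofs <- enumerateIsoforms(spliceGraph(truthModel(truth)))
    tab <- isoformTable(isofs, truthModel(truth))
    .writeTsv(tab, file.path(outDir, "isoforms.tsv"))
    primers <- generateDegeneratePrimers(truth)
    ladder <- ampliconLadder(isoformPools(truth), isofs, primers)
    .writeTsv(ladder, file.path(outDir, "amplicon_ladder.tsv"))
    note("isoforms", file.path(outDir, c("isoforms.tsv",
                                         "amplicon_ladder.tsv")))
    tab
  })

  runStage("compare", function() {
    prof <- lepidopteraProfiles()
    if (!is.null(isoTab)) {
      synth <- data.frame(
        species_id = "synthetic",
        shortest_pevk_aa = min(isoTab$pevk_length_aa),
        longest_pevk_aa = max(isoTab$pevk_length_aa),
        pevk_content_long = isoTab$pevk_content[which.max(isoTab$pevk_length_aa)],
        pevk_content_short = isoTab$pevk_content[which.min(isoTab$pevk_length_aa)],
        n_alternative_exons = length(optionalExons(spliceGraph(truthModel(truth)))),
        n_isoforms_detected = nrow(isoTab),
        yerp_count = if (!is.null(archReport)) yerpCount(archReport) else NA_integer_,
        ntcs1_length_aa = truth@config$ntcs1Length,
        stringsAsFactors = FALSE)
      prof <- rbind(prof, synth)
    }
    .writeTsv(summarizeProfiles(prof), file.path(outDir, "comparison.tsv"))
    note("compare", file.path(outDir, "comparison.tsv"))
  })

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"))
  invisible(manifest)
}
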