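# Seeded generator of projectin-like genes, fragmented contig sets, cDNA
# pools and degenerate primer pairs, with full ground truth.  All random
# choices are drawn through R's integer sampler under the configured seed,
# so output is byte-identical across runs and platforms.

# fixed synthetic stand-in consensus domains, shared with the architecture
# module's library; these are NOT real Pfam consensi
.IG_CONSENSUS <- "TFQYTTIRDLCTGILNCFQIQGGRCCANTSGQRWSSFITMLWICMHNTLFMQAIRQRLQMACNRTTRTWFIMHCIFCYDRNTDAHRAITN"
.FN_CONSENSUS <- "THTYRLQRQRAFDRNYSGHFFSYALNQFICWMLSMLMDIGYAHYWTYTGRQWLQRGMNQDSNRMYYACLTDLFSTNSLTFSTMFLMQAFGRHDMTDGHQC"
.KINASE_CONSENSUS <- "AYGQIMSLMHSCGHAFFHMCWQYARDLQIYQSQAYFNSTSNCLWWYWNWDLMCCWWTGLCQFYIYAFQSFNTANWYSHGYHGTNQCNLWTRQAIWINMRCCRNMCGSMSRHRRNIDFDLDIRWCLARGYRWYTNSFSCYDWAFCANIWTWLWSANAWAMRCTNDNCMNMLYGLAAAMMDYQRWNIMSMGRNNLSYGCGRSHNGLMAWMFADCNFINFYHYQQYTILRDDRYGMRYNHGMCSMNIICTLCQ"
.NTCS1_CONSENSUS <- "RQDWIFHHIDCDSSGRNAQSYLWNGCLNHRIWQLAFGQGTGFGMIIWHALSMITDDTQLLYIWTFDTNNFMMWLCMMAAFLCRYFQMMGDHQLRNHTSWCIDHDMQQIDIMSQDLW"

# residues used for linkers and NTCS-1 filler: none of P, E, V, K
.LINKER_AA <- c("A", "C", "D", "F", "G", "H", "I", "L",
                "M", "N", "Q", "R", "S", "T", "W", "Y")
.PEVK_FILLER_AA <- c("G", "A", "S", "T", "N")

#' Synthetic stand-in consensus domain library
#'
#' Fixed synthetic peptides (~90 aa Ig-like, ~100 aa Fn-like, ~250 aa
#' kinase-like) shared between the generator and [findDomains()].  They are
#' synthetic stand-ins, not real Pfam consensus sequences.
#'
#' @return a named [Biostrings::AAStringSet] with entries `Ig`, `Fn`,
#'   `Kinase`.
#' @export
consensusDomains <- function() {
  AAStringSet(c(Ig = .IG_CONSENSUS, Fn = .FN_CONSENSUS,
                Kinase = .KINASE_CONSENSUS))
}

#' Generator configuration
#'
#' Defaults describe the canonical projectin-like gene: Ig tracts of 8 and
#' 6 domains, 14 \[Fn-Fn-Ig\] core repeats, a kinase domain, linkers of
#' 5-46 aa, a PEVK region of 7 exons of which #3 and #6 are alternatively
#' spliced, PEVK exon composition drawn from 42-100 percent, a 120 aa
#' NTCS-1 segment, two planted YERP motifs (one mid-PEVK, one starting
#' NTCS-1), decoy-free GT-AG introns of 70-150 nt, and 5 percent domain
#' mutation.
#'
#' @param seed integer RNG seed.
#' @param template an [architectureTemplate()].
#' @param pevkExonCount number of PEVK exons (>= 1).
#' @param pevkExonLengthRange PEVK exon lengths, aa (min >= 10).
#' @param pevkContentRange PEVK composition bounds of planted exons.
#' @param alternativeExons indices of the alternatively spliced PEVK exons.
#' @param intronLengthRange intron lengths, nt (min >= 8).
#' @param domainMutationRate per-residue substitution rate applied to
#'   Ig/Fn/kinase domain copies.
#' @param ntcs1Length NTCS-1 segment length, aa (includes the leading YERP).
#' @param yerpMotifs number of planted YERP motifs (2 = one mid-PEVK, one
#'   starting NTCS-1).
#' @param decoySpliceSites plant extra GT/AG dinucleotides inside introns to
#'   stress-test boundary refinement.
#' @param fragmentLengthRange,fragmentOverlapRange fragmentation settings
#'   for [generateFragments()], nt.
#' @param minOverlap assembly overlap floor carried in the config.
#' @return a named list.
#' @export
generatorConfig <- function(seed = 1L,
                            template = architectureTemplate(),
                            pevkExonCount = 7L,
                            pevkExonLengthRange = c(15L, 120L),
                            pevkContentRange = c(0.42, 1.0),
                            alternativeExons = c(3L, 6L),
                            intronLengthRange = c(70L, 150L),
                            domainMutationRate = 0.05,
                            ntcs1Length = 120L,
                            yerpMotifs = 2L,
                            decoySpliceSites = FALSE,
                            fragmentLengthRange = c(800L, 1500L),
                            fragmentOverlapRange = c(30L, 80L),
                            minOverlap = 20L) {
  if (pevkExonLengthRange[1L] < 10L) {
    stop("config error: PEVK exons must be at least 10 aa (the scanner's minimum)")
  }
  if (pevkContentRange[1L] > pevkContentRange[2L] ||
      pevkContentRange[1L] < 0 || pevkContentRange[2L] > 1) {
    stop("config error: invalid pevkContentRange")
  }
  if (length(alternativeExons) > 0L &&
      max(alternativeExons) > pevkExonCount) {
    stop("config error: alternative exon index exceeds pevkExonCount")
  }
  if (intronLengthRange[1L] < 8L) stop("config error: introns must be >= 8 nt")
  if (domainMutationRate < 0 || domainMutationRate > 1) {
    stop("config error: mutation rate must be in [0, 1]")
  }
  if (fragmentOverlapRange[2L] >= fragmentLengthRange[1L]) {
    stop("config error: overlap must be smaller than fragment length")
  }
  list(seed = as.integer(seed), template = template,
       pevkExonCount = as.integer(pevkExonCount),
       pevkExonLengthRange = as.integer(pevkExonLengthRange),
       pevkContentRange = pevkContentRange,
       alternativeExons = as.integer(alternativeExons),
       intronLengthRange = as.integer(intronLengthRange),
       domainMutationRate = domainMutationRate,
       ntcs1Length = as.integer(ntcs1Length),
       yerpMotifs = as.integer(yerpMotifs),
       decoySpliceSites = isTRUE(decoySpliceSites),
       fragmentLengthRange = as.integer(fragmentLengthRange),
       fragmentOverlapRange = as.integer(fragmentOverlapRange),
       minOverlap = as.integer(minOverlap))
}

.mutatePeptide <- function(pep, rate) {
  if (rate <= 0) return(pep)
  ch <- .chars(pep)
  nMut <- as.integer(.roundHalfAway(rate * length(ch)))
  if (nMut == 0L) return(pep)
  pos <- sample.int(length(ch), nMut)
  for (p in pos) {
    ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# PEVK-biased peptide of naa residues with alphabet fraction ~= content;
# non-alphabet filler positions are spread evenly through the interior so
# every planted exon starts and ends on alphabet residues
.pevkPeptide <- function(naa, content) {
  nNon <- as.integer(.roundHalfAway((1 - content) * naa))
  nNon <- min(nNon, max(naa - 2L, 0L))
  ch <- sample(c("P", "E", "V", "K"), naa, replace = TRUE)
  if (nNon > 0L) {
    # keep a 3-residue alphabet margin at both ends so a maximal segment
    # always reaches the exon boundary
    lo <- min(4L, naa); hi <- max(naa - 3L, lo)
    at <- unique(as.integer(.roundHalfAway(seq(lo, hi, length.out = nNon))))
    extra <- nNon - length(at)
    if (extra > 0L) {
      pool <- setdiff(lo:hi, at)
      at <- c(at, pool[sample.int(length(pool), min(extra, length(pool)))])
    }
    ch[at] <- sample(.PEVK_FILLER_AA, length(at), replace = TRUE)
  }
  paste(ch, collapse = "")
}

.linkerPeptide <- function(range) {
  len <- .sampleRange(range[1L], range[2L])
  paste(sample(.LINKER_AA, len, replace = TRUE), collapse = "")
}

# uniform synonymous reverse translation (no codon-usage table)
.codonTable <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), gc)
    }
    tab
  }
})

.reverseTranslate <- function(pep) {
  ch <- .chars(pep)
  tab <- .codonTable()
  codons <- character(length(ch))
  for (aa in unique(ch)) {
    idx <- which(ch == aa)
    codons[idx] <- sample(tab[[aa]], length(idx), replace = TRUE)
  }
  paste(codons, collapse = "")
}

# decoy-free intron: GT + G-free body + AG (a G-free body can contain
# neither a GT nor an AG), so the boundary search windows see exactly one
# canonical pair
.intronSeq <- function(range, decoy = FALSE) {
  len <- .sampleRange(range[1L], range[2L])
  body <- sample(c("A", "C", "T"), len - 4L, replace = TRUE)
  if (decoy && len >= 40L) {
    mid <- (len - 4L) %/% 2L
    body[mid] <- "G"; body[mid + 1L] <- "T"
    body[mid + 6L] <- "A"; body[mid + 7L] <- "G"
  }
  paste0("GT", paste(body, collapse = ""), "AG")
}

#' Generate a projectin-like gene with ground truth
#'
#' Builds the protein architecture from the packaged consensus domains
#' (mutated at `domainMutationRate`), plants PEVK exons with the configured
#' composition and YERP motifs, reverse-translates with uniform synonymous
#' codon choice, and inserts decoy-free GT-AG introns.  Every exon is
#' codon-preserving (length a multiple of 3), so alternative splicing never
#' shifts frame.  The returned [SyntheticTruth-class] carries the gene
#' model, the protein, the planted domain map, the PEVK/NTCS-1 boundary,
#' per-muscle isoform pools and the per-exon clean reference peptides.
#'
#' @param config a [generatorConfig()].
#' @return a [SyntheticTruth-class].
#' @export
generateGene <- function(config = generatorConfig()) {
  .withSeed(config$seed, .generateGeneImpl(config))
}

.generateGeneImpl <- function(config) {
  tpl <- config$template
  rate <- config$domainMutationRate
  exLabel <- character(0); exPep <- character(0); exRef <- character(0)
  domKind <- character(0); domLenBefore <- integer(0); domLen <- integer(0)

  addDomainExon <- function(kind, label, trailingLinker) {
    cons <- switch(kind, Ig = .IG_CONSENSUS, Fn = .FN_CONSENSUS,
                   Kinase = .KINASE_CONSENSUS)
    mut <- .mutatePeptide(cons, rate)
    linker <- if (trailingLinker) .linkerPeptide(tpl$linkerRange) else ""
    exLabel <<- c(exLabel, label)
    exPep <<- c(exPep, paste0(mut, linker))
    exRef <<- c(exRef, paste0(cons, linker))
    domKind <<- c(domKind, kind)
    domLenBefore <<- c(domLenBefore,
                       sum(nchar(exPep)) - nchar(mut) - nchar(linker))
    domLen <<- c(domLen, nchar(cons))
  }

  for (d in seq_len(tpl$tract1)) {
    addDomainExon("Ig", sprintf("n8ig_%d", d), trailingLinker = d < tpl$tract1)
  }
  # PEVK exons (no linkers: the unique region starts right after the tract)
  contents <- .sampleRange(round(config$pevkContentRange[1L] * 100),
                           round(config$pevkContentRange[2L] * 100),
                           config$pevkExonCount) / 100
  # the block must end above the scanner threshold so the PEVK/NTCS-1
  # boundary is recoverable by composition
  contents[config$pevkExonCount] <- max(contents[config$pevkExonCount], 0.7)
  lens <- .sampleRange(config$pevkExonLengthRange[1L],
                       config$pevkExonLengthRange[2L],
                       config$pevkExonCount)
  pevkStartAA <- sum(nchar(exPep)) + 1L
  config$pevkExonTargets <- data.frame(
    label = sprintf("pevk_%d", seq_len(config$pevkExonCount)),
    length_aa = lens, target_content = contents, stringsAsFactors = FALSE)
  for (i in seq_len(config$pevkExonCount)) {
    pep <- .pevkPeptide(lens[i], contents[i])
    if (i == 1L && config$yerpMotifs >= 1L && lens[i] >= 14L) {
      mid <- lens[i] %/% 2L
      pep <- paste0(substr(pep, 1L, mid - 1L), "YERP",
                    substr(pep, mid + 4L, lens[i]))
    }
    exLabel <- c(exLabel, sprintf("pevk_%d", i))
    exPep <- c(exPep, pep)
    exRef <- c(exRef, pep)
  }
  pevkEndAA <- sum(nchar(exPep))
  ntcs1Core <- .NTCS1_CONSENSUS
  need <- config$ntcs1Length - 4L
  while (nchar(ntcs1Core) < need) ntcs1Core <- paste0(ntcs1Core, .NTCS1_CONSENSUS)
  ntcs1 <- paste0(if (config$yerpMotifs >= 2L) "YERP" else "",
                  substr(ntcs1Core, 1L, config$ntcs1Length -
                           (if (config$yerpMotifs >= 2L) 4L else 0L)))
  exLabel <- c(exLabel, "ntcs1"); exPep <- c(exPep, ntcs1)
  exRef <- c(exRef, ntcs1)
  for (d in seq_len(tpl$tract2)) {
    addDomainExon("Ig", sprintf("n6ig_%d", d), trailingLinker = TRUE)
  }
  for (r in seq_len(tpl$coreRepeats)) {
    addDomainExon("Fn", sprintf("core%02d_fn1", r), TRUE)
    addDomainExon("Fn", sprintf("core%02d_fn2", r), TRUE)
    addDomainExon("Ig", sprintf("core%02d_ig", r), TRUE)
  }
  if (tpl$kinase) addDomainExon("Kinase", "kinase", FALSE)

  protein <- paste(exPep, collapse = "")
  domainMapDf <- data.frame(kind = domKind,
                            start = domLenBefore + 1L,
                            end = domLenBefore + domLen,
                            stringsAsFactors = FALSE)

  # reverse-translate exon by exon, then interleave decoy-free introns
  exDna <- vapply(exPep, .reverseTranslate, character(1), USE.NAMES = FALSE)
  introns <- vapply(seq_len(length(exDna) - 1L),
                    function(i) .intronSeq(config$intronLengthRange,
                                           config$decoySpliceSites),
                    character(1))
  genomeParts <- character(0)
  starts <- integer(length(exDna)); ends <- integer(length(exDna))
  pos <- 0L
  for (i in seq_along(exDna)) {
    starts[i] <- pos + 1L
    pos <- pos + nchar(exDna[i])
    ends[i] <- pos
    genomeParts <- c(genomeParts, exDna[i])
    if (i < length(exDna)) {
      genomeParts <- c(genomeParts, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  genome <- paste(genomeParts, collapse = "")

  altLabels <- sprintf("pevk_%d", config$alternativeExons)
  model <- newGeneModel("synthetic_projectin", genome,
                        data.frame(label = exLabel, start = starts,
                                   end = ends,
                                   splicing_class = ifelse(exLabel %in% altLabels,
                                                           "alternative",
                                                           "constitutive"),
                                   stringsAsFactors = FALSE))

  # isoform pools: the shortest isoform (all optional exons excluded) is
  # restricted to thorax and flight, emulating a flight-enriched variant
  k <- length(altLabels)
  combos <- if (k == 0L) list(character(0)) else {
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    lapply(seq_len(nrow(grid)), function(r) altLabels[unlist(grid[r, ])])
  }
  altW <- setNames(nchar(exPep)[match(altLabels, exLabel)] * 3L, altLabels)
  constLen <- sum(nchar(exPep) * 3L) - sum(altW)
  lensNt <- vapply(combos, function(inc) constLen + sum(altW[inc]), numeric(1))
  keys <- vapply(combos, function(inc) paste(sort(inc), collapse = "+"),
                 character(1))
  ord <- order(-lensNt, keys)
  labels <- if (length(combos) <= 26L) LETTERS[seq_along(combos)] else
    sprintf("iso%03d", seq_along(combos))
  shortest <- labels[length(combos)]
  allLabs <- labels
  pools <- list(leg = setdiff(allLabs, shortest),
                thorax = allLabs,
                flight = allLabs,
                head = setdiff(allLabs, shortest))

  new("SyntheticTruth",
      model = model,
      protein = AAString(protein),
      domainMap = domainMapDf,
      uniqueRegion = c(pevkStartAA, pevkEndAA + nchar(ntcs1)),
      pevkBoundary = pevkEndAA,
      isoformPools = pools,
      references = AAStringSet(setNames(exRef, exLabel)),
      config = config)
}

#' Fragment a synthetic genome into an overlapping contig set
#'
#' Tiles the genome with fragments of the configured lengths and overlaps.
#' Optional planted events emulate curation hazards: `"gap"` drops coverage
#' over the interior of the intron nearest the genome midpoint (an
#' unsequenced region), `"inversion"` reverse-complements one interior
#' fragment (strand inversion), `"deletion"` removes a 100 nt interior
#' chunk from one fragment (internal deletion).  Fragment order is shuffled
#' so assembly cannot rely on input order.
#'
#' @param truth a [SyntheticTruth-class].
#' @param events character subset of `c("gap", "inversion", "deletion")`.
#' @param config generator configuration; defaults to the truth's.
#' @return list with `fragments` ([Biostrings::DNAStringSet]), `provenance`
#'   (data.frame: `fragment`, `start`, `end`, `strand`, `event`) and
#'   `planted` (data.frame of planted events).
#' @export
generateFragments <- function(truth, events = character(0),
                              config = truth@config) {
  stopifnot(all(events %in% c("gap", "inversion", "deletion")))
  .withSeed(config$seed + 1L, {
    genome <- as.character(genomeSeq(truth@model))
    L <- nchar(genome)
    lr <- config$fragmentLengthRange; ovr <- config$fragmentOverlapRange
    segs <- list(c(1L, L))
    planted <- data.frame(event = character(0), detail = character(0),
                          stringsAsFactors = FALSE)
    if ("gap" %in% events) {
      ex <- exonTable(truth@model)
      intronStart <- ex$end[-nrow(ex)] + 1L
      intronEnd <- ex$start[-1L] - 1L
      mid <- (intronStart + intronEnd) / 2
      pick <- which.min(abs(mid - L / 2))
      g1 <- intronStart[pick] + 10L
      g2 <- intronEnd[pick] - 10L
      segs <- list(c(1L, g1 - 1L), c(g2 + 1L, L))
      planted <- rbind(planted,
                       data.frame(event = "gap",
                                  detail = sprintf("%d-%d", g1, g2),
                                  stringsAsFactors = FALSE))
    }
    prov <- NULL
    seqs <- character(0)
    for (sg in segs) {
      s <- sg[1L]
      repeat {
        len <- .sampleRange(lr[1L], lr[2L])
        e <- min(s + len - 1L, sg[2L])
        if (sg[2L] - e < lr[1L] %/% 2L) e <- sg[2L]
        prov <- rbind(prov, data.frame(start = s, end = e, strand = "+",
                                       event = "", stringsAsFactors = FALSE))
        seqs <- c(seqs, substr(genome, s, e))
        if (e >= sg[2L]) break
        s <- e - .sampleRange(ovr[1L], ovr[2L]) + 1L
      }
    }
    n <- length(seqs)
    interior <- setdiff(seq_len(n), c(1L, n))
    if ("inversion" %in% events && length(interior) > 0L) {
      pick <- interior[(length(interior) + 1L) %/% 2L]
      seqs[pick] <- revComp(seqs[pick])
      prov$strand[pick] <- "-"
      prov$event[pick] <- "inversion"
      planted <- rbind(planted,
                       data.frame(event = "inversion",
                                  detail = sprintf("fragment_%03d", pick),
                                  stringsAsFactors = FALSE))
      interior <- setdiff(interior, pick)
    }
    if ("deletion" %in% events && length(interior) > 0L) {
      # remove a chunk that reaches into the overlap zone with the next
      # fragment: the damaged fragment keeps a short intact tail that then
      # recurs *inside* the neighbouring scaffold, which is what makes the
      # deletion detectable after assembly
      ok <- interior[interior < n & prov$event[interior] == "" &
                       prov$event[pmin(interior + 1L, n)] == ""]
      ok <- ok[prov$end[ok] - prov$start[ok + 1L] + 1L >= 26L]
      if (length(ok) > 0L) {
        b <- ok[1L]; cc <- b + 1L
        delFrom <- prov$start[cc] - 80L
        delTo <- prov$end[b] - 25L
        localFrom <- delFrom - prov$start[b] + 1L
        localTo <- delTo - prov$start[b] + 1L
        if (localFrom > 50L) {
          seqs[b] <- paste0(substr(seqs[b], 1L, localFrom - 1L),
                            substr(seqs[b], localTo + 1L, nchar(seqs[b])))
          prov$event[b] <- "deletion"
          planted <- rbind(planted,
                           data.frame(event = "deletion",
                                      detail = sprintf("fragment_%03d", b),
                                      stringsAsFactors = FALSE))
        }
      }
    }
    prov$fragment <- sprintf("fragment_%03d", seq_len(n))
    perm <- sample.int(n)
    list(fragments = setNames(DNAStringSet(seqs[perm]), prov$fragment[perm]),
         provenance = prov[, c("fragment", "start", "end", "strand", "event")],
         planted = planted)
  })
}

#' Generate per-sample cDNA pools from the truth's isoform pools
#'
#' Splices each pooled isoform's transcript; optionally truncates the
#' cDNAs to the region delimited by a primer pair, emulating RT-PCR
#' products rather than full-length transcripts.
#'
#' @param truth a [SyntheticTruth-class].
#' @param truncateTo optional [PrimerPair-class].
#' @return named list: sample label -> [Biostrings::DNAStringSet] named by
#'   isoform label.
#' @export
generateCdnaPools <- function(truth, truncateTo = NULL) {
  isofs <- enumerateIsoforms(spliceGraph(truth@model))
  pools <- truth@isoformPools
  unknown <- setdiff(unlist(pools), names(isofs))
  if (length(unknown) > 0L) {
    stop("config error: pool references unknown isoform(s): ",
         paste(unknown, collapse = ", "))
  }
  lapply(pools, function(labs) {
    seqs <- lapply(labs, function(l) {
      if (is.null(truncateTo)) {
        isofs[[l]]@seq
      } else {
        amp <- inSilicoPcr(isofs[[l]], truncateTo)
        subseq(isofs[[l]]@seq, amp$forward_start, amp$reverse_end)
      }
    })
    setNames(DNAStringSet(vapply(seqs, as.character, character(1))), labs)
  })
}

.degenerateCodeFor <- c(A = "RWM", C = "YSM", G = "RSK", T = "YWK")

#' Derive a (possibly degenerate) primer pair from the truth transcript
#'
#' Primers are copied from constitutive exons flanking the PEVK region (by
#' default the last Ig exon of the first tract, and the NTCS-1 exon) and a
#' configured number of positions is degenerated to IUPAC codes that cover
#' the true base.  Placing a primer inside an alternatively spliced exon is
#' a config error: such a primer could not bind all isoforms.
#'
#' @param truth a [SyntheticTruth-class].
#' @param forwardExon,reverseExon exon labels carrying the primer
#'   footprints.
#' @param primerLength primer length, nt (15-35).
#' @param nDegenerate number of degenerate positions per primer.
#' @param name primer pair name.
#' @return a [PrimerPair-class].
#' @export
generateDegeneratePrimers <- function(truth, forwardExon = NULL,
                                      reverseExon = "ntcs1",
                                      primerLength = 20L, nDegenerate = 0L,
                                      name = "synF-synR") {
  tab <- exonTable(truth@model)
  if (is.null(forwardExon)) {
    firstPevk <- which(grepl("^pevk_", tab$label))[1L]
    forwardExon <- tab$label[firstPevk - 1L]
  }
  for (lab in c(forwardExon, reverseExon)) {
    i <- match(lab, tab$label)
    if (is.na(i)) stop("config error: unknown exon ", lab)
    if (tab$splicing_class[i] == "alternative") {
      stop("config error: primer exon '", lab,
           "' is alternatively spliced; primers must bind all isoforms")
    }
  }
  .withSeed(truth@config$seed + 2L, {
    fSeqFull <- .exonSeq(truth@model, forwardExon)
    rSeqFull <- .exonSeq(truth@model, reverseExon)
    stopifnot(nchar(fSeqFull) >= primerLength,
              nchar(rSeqFull) >= primerLength + 100L)
    fwd <- substr(fSeqFull, nchar(fSeqFull) - primerLength + 1L,
                  nchar(fSeqFull))
    rev <- revComp(substr(rSeqFull, 101L, 100L + primerLength))
    degen <- function(p) {
      if (nDegenerate == 0L) return(p)
      ch <- .chars(p)
      pos <- sample.int(length(ch), min(nDegenerate, length(ch)))
      for (i in pos) {
        codes <- .chars(.degenerateCodeFor[[ch[i]]])
        ch[i] <- sample(codes, 1L)
      }
      paste(ch, collapse = "")
    }
    primerPair(name, degen(fwd), degen(rev))
  })
}
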