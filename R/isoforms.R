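# Splice-graph isoform enumeration, per-isoform PEVK statistics, and in
# silico RT-PCR amplicon prediction per muscle type.

#' Build the splice graph of a gene model
#'
#' @param model a [GeneModel-class].
#' @param optional labels of the optional exons; defaults to the model's
#'   `splicing_class == "alternative"` exons.
#' @return a [SpliceGraph-class].
#' @export
spliceGraph <- function(model, optional = NULL) {
  if (is.null(optional)) {
    tab <- exonTable(model)
    optional <- tab$label[tab$splicing_class == "alternative"]
  }
  new("SpliceGraph", model = model, optionalExons = as.character(optional))
}

#' Enumerate all splice isoforms of a splice graph
#'
#' All `2^k` inclusion combinations of the `k` optional exons are spliced.
#' Labels `A`, `B`, `C`, ... are assigned by descending spliced length, ties
#' broken lexicographically by the included-exon set, so the longest isoform
#' (all optional exons included) is always `A`.
#'
#' @param graph a [SpliceGraph-class].
#' @return named list of [Transcript-class] objects, ordered by label.
#' @export
enumerateIsoforms <- function(graph) {
  opt <- graph@optionalExons
  k <- length(opt)
  if (k > 20L) {
    stop(sprintf("refusing to enumerate 2^%d isoforms (more than 20 optional exons)", k))
  }
  combos <- if (k == 0L) list(character(0)) else {
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    lapply(seq_len(nrow(grid)), function(r) opt[unlist(grid[r, ])])
  }
  graphConst <- constitutiveExons(graph)
  trs <- lapply(combos, function(inc) {
    spliceTranscript(graph@model, included = c(graphConst, inc))
  })
  lens <- vapply(trs, function(tr) length(tr@seq), integer(1))
  keys <- vapply(trs, function(tr) paste(tr@includedExons, collapse = "+"),
                 character(1))
  ord <- order(-lens, keys)
  trs <- trs[ord]
  labels <- if (length(trs) <= 26L) LETTERS[seq_along(trs)] else
    sprintf("iso%03d", seq_along(trs))
  for (i in seq_along(trs)) trs[[i]]@isoformLabel <- labels[i]
  setNames(trs, labels)
}

#' PEVK length and content of one isoform
#'
#' The PEVK region of an isoform is the translation of its included
#' PEVK-region exons (by default, exons whose label starts with `"pevk"`).
#' The translation must be free of internal stops.
#'
#' @param isoform a [Transcript-class] from [enumerateIsoforms()].
#' @param model the underlying [GeneModel-class].
#' @param alphabet bias alphabet for the content computation.
#' @param pevkExons labels of the exons making up the PEVK region.
#' @return list with `length_aa` and `content`.
#' @export
pevkStats <- function(isoform, model, alphabet = biasAlphabet(),
                      pevkExons = grep("^pevk", exonLabels(model),
                                       value = TRUE)) {
  inc <- intersect(isoform@includedExons, pevkExons)
  if (length(inc) == 0L) return(list(length_aa = 0L, content = NA_real_))
  seqs <- vapply(inc, function(l) .exonSeq(model, l), character(1))
  aa <- as.character(translateFrame(paste(seqs, collapse = ""), 0))
  if (grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE)) {
    stop("internal stop codon in the PEVK region of isoform ",
         isoform@isoformLabel)
  }
  aa <- sub("\\*$", "", aa)
  list(length_aa = nchar(aa), content = pevkFraction(aa, alphabet))
}

#' Summary table over enumerated isoforms
#'
#' @param isoforms named list from [enumerateIsoforms()].
#' @param model the underlying [GeneModel-class].
#' @param alphabet bias alphabet.
#' @return data.frame: `isoform`, `n_exons`, `length_nt`, `pevk_length_aa`,
#'   `pevk_content`.
#' @export
isoformTable <- function(isoforms, model, alphabet = biasAlphabet()) {
  do.call(rbind, lapply(isoforms, function(iso) {
    st <- pevkStats(iso, model, alphabet)
    data.frame(isoform = iso@isoformLabel,
               n_exons = length(iso@includedExons),
               length_nt = length(iso@seq),
               pevk_length_aa = st$length_aa,
               pevk_content = st$content,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Ratio of two region lengths as an integer percentage
#'
#' Rounds half away from zero, so 205/377 gives 54 (not 54.4 truncated and
#' not banker's-rounded).
#'
#' @param shorter,longer positive lengths with `shorter <= longer`.
#' @return integer percent.
#' @examples
#' lengthRatioPercent(205, 377)  # 54
#' @export
lengthRatioPercent <- function(shorter, longer) {
  if (any(shorter <= 0) || any(longer <= 0)) {
    stop("lengths must be positive")
  }
  if (any(shorter > longer)) stop("shorter must not exceed longer")
  as.integer(.roundHalfAway(100 * shorter / longer))
}

#' Construct a primer pair
#'
#' @param name pair name, e.g. `"Ms1-6R"`.
#' @param forward,reverse primer sequences 5'->3' (IUPAC degeneracy
#'   allowed), 15-35 nt.
#' @return a [PrimerPair-class].
#' @export
primerPair <- function(name, forward, reverse) {
  f <- .asChar(forward); r <- .asChar(reverse)
  .checkDna(f, "forward primer"); .checkDna(r, "reverse primer")
  new("PrimerPair", name = name, forward = DNAString(f),
      reverse = DNAString(r))
}

#' Predict the RT-PCR product of a primer pair on a transcript
#'
#' The forward primer is matched on the transcript sense strand and the
#' reverse primer as its reverse complement; IUPAC ambiguity codes in the
#' primers match their expansion sets, and a full-length exact (degenerate)
#' match is required.  Each primer must bind exactly once: zero sites is a
#' no-amplification error, several sites an ambiguity error.  The product
#' size includes both primer footprints.
#'
#' @param transcript a [Transcript-class] (or [Biostrings::DNAString]).
#' @param primers a [PrimerPair-class].
#' @return data.frame row: `isoform`, `size_bp`, `forward_start`,
#'   `reverse_end` (transcript coordinates, 1-based).
#' @export
inSilicoPcr <- function(transcript, primers) {
  label <- if (is(transcript, "Transcript")) transcript@isoformLabel else "seq"
  seq <- if (is(transcript, "Transcript")) transcript@seq
         else DNAString(.asChar(transcript))
  fixedSpec <- c(pattern = FALSE, subject = TRUE)
  fHits <- matchPattern(primers@forward, seq, fixed = fixedSpec)
  rHits <- matchPattern(reverseComplement(primers@reverse), seq,
                        fixed = fixedSpec)
  if (length(fHits) == 0L) {
    stop(sprintf("no amplification: forward primer of '%s' has no site",
                 primers@name))
  }
  if (length(rHits) == 0L) {
    stop(sprintf("no amplification: reverse primer of '%s' has no site",
                 primers@name))
  }
  if (length(fHits) > 1L) {
    stop(sprintf("ambiguous amplification: forward primer of '%s' binds at %s",
                 primers@name, paste(start(fHits), collapse = ", ")))
  }
  if (length(rHits) > 1L) {
    stop(sprintf("ambiguous amplification: reverse primer of '%s' binds at %s",
                 primers@name, paste(start(rHits), collapse = ", ")))
  }
  fs <- start(fHits)[1L]; re <- end(rHits)[1L]
  if (re <= fs) {
    stop(sprintf("primer sites of '%s' are not in amplifiable orientation",
                 primers@name))
  }
  data.frame(isoform = label, size_bp = re - fs + 1L,
             forward_start = fs, reverse_end = re,
             stringsAsFactors = FALSE)
}

#' Predicted amplicon ladders per sample
#'
#' Runs [inSilicoPcr()] on every isoform of every sample pool and reports
#' the sorted product sizes per sample.  A size present in one sample but
#' absent from at least one other sample is flagged `sample_specific`: on a
#' gel this is the band that distinguishes, e.g., flight muscle from leg.
#'
#' @param pools named list: sample label -> character vector of isoform
#'   labels.
#' @param isoforms named list from [enumerateIsoforms()].
#' @param primers a [PrimerPair-class].
#' @return data.frame: `sample`, `isoform`, `size_bp`, `sample_specific`.
#' @export
ampliconLadder <- function(pools, isoforms, primers) {
  unknown <- setdiff(unlist(pools), names(isoforms))
  if (length(unknown) > 0L) {
    stop("unknown isoform label(s) in pools: ", paste(unknown, collapse = ", "))
  }
  rows <- NULL
  for (s in names(pools)) {
    for (lab in sort(unique(pools[[s]]))) {
      amp <- inSilicoPcr(isoforms[[lab]], primers)
      rows <- rbind(rows, data.frame(sample = s, isoform = lab,
                                     size_bp = amp$size_bp,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) {
    return(data.frame(sample = character(0), isoform = character(0),
                      size_bp = integer(0), sample_specific = logical(0),
                      stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$sample, rows$size_bp), , drop = FALSE]
  samples <- names(pools)
  rows$sample_specific <- vapply(seq_len(nrow(rows)), function(i) {
    sz <- rows$size_bp[i]
    any(vapply(samples, function(s) {
      !sz %in% rows$size_bp[rows$sample == s]
    }, logical(1)))
  }, logical(1))
  rownames(rows) <- NULL
  rows
}
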