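# Homology-guided exon-intron prediction: anchor reference peptides in the
# three frame translations of the genomic sequence, refine exon boundaries to
# canonical GT-AG splice sites preserving reading frame, and verify the
# resulting model against cDNA.
#
# Anchoring uses full-length ungapped windowed identity: the reference is
# slid over the frame translation and per-offset identity is computed.  The
# homology model is substitution-only (as in the packaged generator); indel
# homology is out of scope and stated as a limitation.

# identity of `ref` at every offset of `prot` (both character vectors of
# single residues); returns numeric(n - L + 1) or NULL when prot is shorter
.windowedIdentity <- function(prot, ref) {
  n <- length(prot); L <- length(ref)
  if (n < L) return(NULL)
  m <- integer(n - L + 1L)
  for (k in seq_len(L)) {
    m <- m + (prot[k:(n - L + k)] == ref[k])
  }
  m / L
}

#' Anchor reference peptides in a genomic sequence
#'
#' Each reference protein is scanned against the three forward-frame
#' translations of the genome by full-length windowed identity.  Offsets
#' with identity at least `minIdentity` become candidate anchors; anchors
#' are then resolved greedily by score (identity, then leftmost) so that the
#' returned anchors never overlap on the genome.  Reported scores use
#' match +2 / mismatch -1.
#'
#' @param genome a [Biostrings::DNAString] or character scalar.
#' @param referenceProteins a named [Biostrings::AAStringSet] (or named
#'   character vector) of reference peptides, each at least 8 aa.
#' @param minIdentity minimum identity in \[0, 1\]; default 0.7.
#' @return data.frame sorted by genomic position with columns
#'   `reference_id`, `start`, `end` (nt, 1-based closed), `frame`,
#'   `identity`, `score`.
#' @export
anchorDomains <- function(genome, referenceProteins, minIdentity = 0.7) {
  g <- .asChar(genome)
  .checkDna(g)
  refs <- .asChar(referenceProteins)
  if (is.null(names(refs))) names(refs) <- sprintf("ref_%02d", seq_along(refs))
  trans <- lapply(0:2, function(f) .chars(as.character(translateFrame(g, f))))
  cand <- list()
  for (ri in seq_along(refs)) {
    refCh <- .chars(refs[[ri]])
    L <- length(refCh)
    for (f in 0:2) {
      idv <- .windowedIdentity(trans[[f + 1L]], refCh)
      if (is.null(idv)) next
      hits <- which(idv >= minIdentity - FRACTION_EPS)
      for (o in hits) {
        ntStart <- f + 3L * (o - 1L) + 1L
        matches <- round(idv[o] * L)
        cand[[length(cand) + 1L]] <-
          data.frame(reference_id = names(refs)[ri],
                     start = ntStart, end = ntStart + 3L * L - 1L,
                     frame = f, identity = idv[o],
                     score = 2L * matches - (L - matches),
                     stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(reference_id = character(0), start = integer(0),
                      end = integer(0), frame = integer(0),
                      identity = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  # identity before raw score: references sharing a consensus differ at a
  # locus mainly through overhang mismatches, which dilute identity faster
  # than they dilute the match/mismatch score
  cand <- cand[order(-cand$identity, -cand$score, cand$start,
                     cand$reference_id), , drop = FALSE]
  keep <- logical(nrow(cand))
  covStart <- integer(0); covEnd <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= covEnd & cand$end[i] >= covStart)) {
      keep[i] <- TRUE
      covStart <- c(covStart, cand$start[i])
      covEnd <- c(covEnd, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# translate the spliced junction of two exon pieces and count matches
# against the expected reference residues around the junction; only the
# few codons flanking the junction are translated
.junctionMatches <- function(genome, exonStart, donorMinus1, acceptor,
                             nextEnd, phaseAtExon, refTail, refHead) {
  skip <- (3L - phaseAtExon) %% 3L
  leftLen <- donorMinus1 - exonStart + 1L
  aaLeftLen <- (leftLen - skip) %/% 3L
  if (aaLeftLen < 0L) return(-1L)
  want <- nchar(refTail)
  useAA <- min(want, aaLeftLen)
  dangling <- leftLen - skip - 3L * aaLeftLen
  tailStart <- exonStart + skip + 3L * (aaLeftLen - useAA)
  spliced <- paste0(substr(genome, tailStart, donorMinus1),
                    substr(genome, acceptor, nextEnd))
  aa <- as.character(translateFrame(spliced, 0))
  if (nchar(aa) == 0L) return(-1L)
  if (grepl("*", aa, fixed = TRUE)) return(-1L)
  expect <- paste0(substr(refTail, want - useAA + 1L, want),
                   if (dangling > 0L) "?" else "", refHead)
  got <- .chars(aa)
  exp <- .chars(expect)
  n <- min(length(got), length(exp))
  sum(got[seq_len(n)] == exp[seq_len(n)])
}

#' Refine anchor boundaries to canonical GT-AG splice sites
#'
#' Between consecutive anchors, a window around each anchor edge is searched
#' for a donor `GT` / acceptor `AG` pair such that (a) the spliced reading
#' frame is continuous across the junction and (b) the translated junction
#' best extends the reference alignment.  Junctions with no canonical pair,
#' or with several equally scoring pairs, are marked ambiguous.  Exons
#' inherit phases from the running coding length.
#'
#' @param anchors data.frame from [anchorDomains()] (ordered,
#'   non-overlapping).
#' @param genome a [Biostrings::DNAString] or character scalar.
#' @param references optional named peptides (as given to
#'   [anchorDomains()]); used for junction scoring.
#' @param window search window around each anchor edge, nt; default 60.
#' @param geneId identifier for the predicted model.
#' @return list with elements `model` (a [GeneModel-class] whose exon labels
#'   are the anchor reference ids) and `sites` (data.frame of splice-site
#'   calls: `intron`, `donor_pos`, `acceptor_pos`, `dinucleotides`,
#'   `canonical`, `ambiguous`).
#' @export
refineBoundaries <- function(anchors, genome, references = NULL,
                             window = 60L, geneId = "predicted_gene") {
  g <- .asChar(genome)
  if (nrow(anchors) == 0L) stop("no anchors to refine")
  if (is.unsorted(anchors$start)) anchors <- anchors[order(anchors$start), ]
  if (any(anchors$start[-1L] <= anchors$end[-nrow(anchors)])) {
    stop("anchors must be non-overlapping")
  }
  refs <- if (!is.null(references)) .asChar(references) else NULL
  nA <- nrow(anchors)
  exStart <- integer(nA); exEnd <- integer(nA)
  exStart[1L] <- anchors$start[1L]
  exEnd[nA] <- anchors$end[nA]
  sites <- NULL
  cumLen <- 0L
  junctionAA <- 4L
  for (i in seq_len(nA - 1L)) {
    expEnd <- anchors$end[i]
    expStart <- anchors$start[i + 1L]
    donorFrom <- max(exStart[i] + 1L, expEnd - 8L)
    donorTo <- min(expEnd + window, expStart - 1L)
    dCand <- donorFrom:donorTo
    dCand <- dCand[substring(g, dCand, dCand + 1L) == "GT"]
    accFrom <- max(expStart - window, exStart[i] + 2L)
    accTo <- min(expStart + 9L, nchar(g))
    aCand <- accFrom:accTo
    aCand <- aCand[aCand >= 3L &
                     substring(g, aCand - 2L, aCand - 1L) == "AG"]
    best <- NULL; bestScore <- -Inf; tie <- FALSE
    for (d in dCand) {
      exonLen <- d - exStart[i]
      if (exonLen < 1L) next
      phase <- as.integer((cumLen + exonLen) %% 3L)
      for (a in aCand) {
        if (a - d < 4L) next                       # room for GT...AG
        # frame continuity: anchor i+1 residues must stay in frame
        skip <- (3L - phase) %% 3L
        if ((expStart - (a + skip)) %% 3L != 0L) next
        sc <- 0
        if (!is.null(refs)) {
          ri <- anchors$reference_id[i]; rj <- anchors$reference_id[i + 1L]
          refTail <- if (ri %in% names(refs))
            substr(refs[[ri]], max(1L, nchar(refs[[ri]]) - junctionAA + 1L),
                   nchar(refs[[ri]])) else ""
          refHead <- if (rj %in% names(refs))
            substr(refs[[rj]], 1L, junctionAA) else ""
          sc <- .junctionMatches(g, exStart[i], d - 1L, a,
                                 min(a + 3L * junctionAA + 2L, nchar(g)),
                                 as.integer(cumLen %% 3L), refTail, refHead)
        }
        # prefer junctions at the anchor edges when scores tie
        sc <- sc - 1e-6 * (abs(d - (expEnd + 1L)) + abs(a - expStart))
        if (sc > bestScore + 1e-9) {
          best <- c(d, a); bestScore <- sc; tie <- FALSE
        } else if (sc > bestScore - 1e-9) {
          tie <- TRUE
        }
      }
    }
    if (is.null(best)) {
      exEnd[i] <- expEnd
      exStart[i + 1L] <- expStart
      sites <- rbind(sites, data.frame(
        intron = i, donor_pos = NA_integer_, acceptor_pos = NA_integer_,
        dinucleotides = NA_character_, canonical = FALSE, ambiguous = TRUE,
        stringsAsFactors = FALSE))
    } else {
      exEnd[i] <- best[1L] - 1L
      exStart[i + 1L] <- best[2L]
      sites <- rbind(sites, data.frame(
        intron = i, donor_pos = best[1L], acceptor_pos = best[2L] - 1L,
        dinucleotides = "GT..AG", canonical = TRUE, ambiguous = tie,
        stringsAsFactors = FALSE))
    }
    cumLen <- cumLen + (exEnd[i] - exStart[i] + 1L)
  }
  model <- newGeneModel(geneId, g,
                        data.frame(label = make.unique(anchors$reference_id),
                                   start = exStart, end = exEnd,
                                   stringsAsFactors = FALSE))
  if (is.null(sites)) {
    sites <- data.frame(intron = integer(0), donor_pos = integer(0),
                        acceptor_pos = integer(0),
                        dinucleotides = character(0), canonical = logical(0),
                        ambiguous = logical(0), stringsAsFactors = FALSE)
  }
  list(model = model, sites = sites)
}

#' Verify a gene model against cDNA sequences
#'
#' Each cDNA is tested for exact substring containment in the spliced
#' transcript of some isoform (all combinations of the model's alternative
#' exons are tried).  Non-matching cDNAs are reported with the positions of
#' their mismatches against the closest isoform.  Ambiguous splice-site
#' calls whose junction is covered by a confirming cDNA are upgraded to
#' resolved.
#'
#' @param model a [GeneModel-class].
#' @param cdnas a [Biostrings::DNAStringSet] or named character vector.
#' @param sites optional splice-site data.frame from [refineBoundaries()].
#' @param maxMismatch maximum mismatches tolerated when locating an
#'   unconfirmed cDNA; default 10.
#' @return list with `report` (data.frame: `cdna`, `status`, `isoform`,
#'   `position`, `mismatch_positions`) and `sites` (the updated splice-site
#'   table, or NULL).
#' @export
verifyWithCdna <- function(model, cdnas, sites = NULL, maxMismatch = 10L) {
  cd <- .asChar(cdnas)
  if (is.null(names(cd))) names(cd) <- sprintf("cdna_%02d", seq_along(cd))
  graph <- spliceGraph(model)
  isofs <- enumerateIsoforms(graph)
  report <- NULL
  for (ci in seq_along(cd)) {
    hit <- NULL
    for (iso in isofs) {
      p <- .allMatches(cd[[ci]], as.character(iso@seq))
      if (length(p) > 0L) {
        hit <- list(iso = iso, pos = p[1L])
        break
      }
    }
    if (!is.null(hit)) {
      report <- rbind(report, data.frame(
        cdna = names(cd)[ci], status = "confirmed",
        isoform = hit$iso@isoformLabel, position = hit$pos,
        mismatch_positions = "", stringsAsFactors = FALSE))
      if (!is.null(sites) && any(sites$ambiguous)) {
        # junction positions on this isoform's transcript
        ex <- exonTable(model)
        inc <- ex[ex$label %in% hit$iso@includedExons, , drop = FALSE]
        cumEnd <- cumsum(inc$width)
        span <- c(hit$pos, hit$pos + nchar(cd[[ci]]) - 1L)
        for (r in which(sites$ambiguous)) {
          iEx <- sites$intron[r]
          lab <- ex$label[iEx]
          k <- match(lab, inc$label)
          if (is.na(k) || k == nrow(inc)) next
          jpos <- cumEnd[k]
          if (span[1L] <= jpos - 2L && span[2L] >= jpos + 3L) {
            sites$ambiguous[r] <- FALSE
          }
        }
      }
    } else {
      bestMm <- Inf; bestIso <- NA_character_; bestPos <- NA_integer_
      bestSites <- integer(0)
      for (iso in isofs) {
        if (nchar(cd[[ci]]) > length(iso@seq)) next
        m <- matchPattern(DNAString(cd[[ci]]), iso@seq,
                          max.mismatch = maxMismatch, with.indels = FALSE)
        if (length(m) == 0L) next
        for (k in seq_len(length(m))) {
          mmpos <- mismatch(DNAString(cd[[ci]]), m[k])[[1L]]
          if (length(mmpos) < bestMm) {
            bestMm <- length(mmpos); bestIso <- iso@isoformLabel
            bestPos <- start(m)[k]; bestSites <- mmpos
          }
        }
      }
      report <- rbind(report, data.frame(
        cdna = names(cd)[ci],
        status = if (is.finite(bestMm)) "mismatch" else "unmatched",
        isoform = bestIso, position = bestPos,
        mismatch_positions = paste(bestSites, collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  list(report = report, sites = sites)
}
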