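# Greedy exact-overlap contig assembly with conflict and gap reporting.
# Mirrors hand curation of overlapping clone/contig sets: repeatedly merge the
# pair with the longest exact suffix-prefix overlap (either orientation),
# refuse to guess when a fragment overlaps two partners equally well, and
# report strand inversions, internal deletions and unbridged gaps.

.flipComponent <- function(comp) {
  n <- nchar(comp$seq)
  fr <- comp$frags
  fr$offset <- n - (fr$offset + fr$width - 1L) + 1L
  fr$strand <- ifelse(fr$strand == "+", "-", "+")
  list(seq = revComp(comp$seq), frags = fr[order(fr$offset), , drop = FALSE])
}

.orientComponent <- function(comp, orient) {
  if (orient == "+") comp else .flipComponent(comp)
}

# all candidate merges between active components; one row per distinct merge.
# A merge and its reverse complement are the same event; the representative
# kept is the one leaving the fewest fragments on the minus strand (then the
# lexicographically smaller merged sequence), which keeps assembly of
# unperturbed fragment sets in the input orientation and makes the result
# independent of input order.
.assemblyCandidates <- function(comps, active, minOverlap) {
  out <- list()
  ids <- which(active)
  for (i in ids) for (j in ids) {
    if (i == j) next
    for (oi in c("+", "-")) for (oj in c("+", "-")) {
      a <- if (oi == "+") comps[[i]]$seq else revComp(comps[[i]]$seq)
      b <- if (oj == "+") comps[[j]]$seq else revComp(comps[[j]]$seq)
      L <- .suffixPrefixOverlap(a, b, minOverlap)
      if (L == 0L) next
      merged <- paste0(a, substr(b, L + 1L, nchar(b)))
      nMinus <- function(k, o) {
        fr <- comps[[k]]$frags
        if (o == "+") sum(fr$strand == "-") else sum(fr$strand == "+")
      }
      minusCount <- nMinus(i, oi) + nMinus(j, oj)
      key <- paste(min(i, j), max(i, j),
                   min(merged, revComp(merged)), sep = "|")
      cand <- list(i = i, j = j, oi = oi, oj = oj, L = L, merged = merged,
                   minusCount = minusCount)
      prev <- out[[key]]
      if (is.null(prev) || minusCount < prev$minusCount ||
          (minusCount == prev$minusCount && merged < prev$merged)) {
        out[[key]] <- cand
      }
    }
  }
  unname(out)
}

#' Assemble genomic fragments by greedy exact overlap merging
#'
#' Repeatedly merges the pair of sequences sharing the longest exact
#' suffix-prefix overlap of at least `minOverlap` nucleotides, trying both
#' orientations.  Ties on overlap length are broken by the lexicographically
#' smallest merged sequence, which makes the result independent of input
#' order.  A fragment with equally long overlaps against two different
#' partners is never merged by guessing: it is left out and reported
#' `ambiguous_overlap` (repetitive-sequence hazard).  Fragments that were
#' reverse-complemented relative to their merge partner are reported as
#' `strand_inversion` conflicts; a scaffold whose terminal sequence reappears
#' inside another scaffold is reported as an `internal_deletion` conflict.
#' When more than one scaffold remains, the junctions between consecutive
#' scaffolds are reported as (unbridged) gaps; see [bridgeGaps()].
#'
#' @param fragments a [Biostrings::DNAStringSet] or named character vector.
#' @param minOverlap minimum exact overlap (nt), at least 8; default 20.
#' @return an [AssemblyReport-class].
#' @export
assembleFragments <- function(fragments, minOverlap = 20L) {
  frs <- .asChar(fragments)
  if (length(frs) == 0L) stop("at least one fragment is required")
  if (minOverlap < 8L) stop("minOverlap must be >= 8")
  if (is.null(names(frs)) || anyDuplicated(names(frs))) {
    names(frs) <- sprintf("frag_%03d", seq_along(frs))
  }
  for (i in seq_along(frs)) .checkDna(frs[[i]], names(frs)[i])

  comps <- lapply(seq_along(frs), function(i) {
    list(seq = unname(frs[[i]]),
         frags = data.frame(id = names(frs)[i], offset = 1L,
                            width = nchar(frs[[i]]), strand = "+",
                            stringsAsFactors = FALSE))
  })
  active <- rep(TRUE, length(comps))
  ambiguous <- rep(FALSE, length(comps))

  repeat {
    cands <- .assemblyCandidates(comps, active & !ambiguous, minOverlap)
    if (length(cands) == 0L) break
    Ls <- vapply(cands, `[[`, integer(1), "L")
    top <- cands[Ls == max(Ls)]
    # repetitive-sequence hazard: a component whose SAME end has max-length
    # overlaps against two different partners is flagged, not guessed at.
    # Equal-length overlaps on opposite ends (a left and a right neighbour)
    # are consistent and never ambiguous.
    ends <- lapply(top, function(cc) {
      # for the suffix side (i): the end used is oi's 3' end; for the
      # prefix side (j): oj's 5' end
      rbind(c(cc$i, if (cc$oi == "+") "right" else "left", cc$j),
            c(cc$j, if (cc$oj == "+") "left" else "right", cc$i))
    })
    ends <- do.call(rbind, ends)
    flagged <- integer(0)
    for (key in unique(paste(ends[, 1L], ends[, 2L]))) {
      rows <- ends[paste(ends[, 1L], ends[, 2L]) == key, , drop = FALSE]
      if (length(unique(rows[, 3L])) > 1L) {
        flagged <- c(flagged, as.integer(rows[1L, 1L]))
      }
    }
    flagged <- unique(flagged)
    if (length(flagged) > 0L) {
      ambiguous[flagged] <- TRUE
      next
    }
    ord <- order(vapply(top, `[[`, character(1), "merged"),
                 vapply(top, `[[`, integer(1), "i"),
                 vapply(top, `[[`, integer(1), "j"))
    pick <- top[[ord[1L]]]
    left <- .orientComponent(comps[[pick$i]], pick$oi)
    right <- .orientComponent(comps[[pick$j]], pick$oj)
    shift <- nchar(left$seq) - pick$L
    right$frags$offset <- right$frags$offset + shift
    comps[[pick$i]] <- list(seq = pick$merged,
                            frags = rbind(left$frags, right$frags))
    comps[[pick$i]]$frags <-
      comps[[pick$i]]$frags[order(comps[[pick$i]]$frags$offset), , drop = FALSE]
    active[pick$j] <- FALSE
  }

  comps <- comps[active]
  ambigFlag <- ambiguous[active]
  ord <- order(-vapply(comps, function(cc) nchar(cc$seq), integer(1)),
               vapply(comps, `[[`, character(1), "seq"))
  comps <- comps[ord]
  ambigFlag <- ambigFlag[ord]
  scafNames <- sprintf("scaffold_%02d", seq_along(comps))

  placements <- do.call(rbind, lapply(seq_along(comps), function(k) {
    fr <- comps[[k]]$frags
    data.frame(fragment = fr$id, scaffold = scafNames[k], offset = fr$offset,
               strand = fr$strand, placed = !ambigFlag[k],
               note = if (ambigFlag[k]) "ambiguous_overlap" else "",
               stringsAsFactors = FALSE)
  }))

  conflicts <- data.frame(fragment_a = character(0), fragment_b = character(0),
                          kind = character(0), stringsAsFactors = FALSE)
  # strand inversions: minority-strand fragments within a scaffold
  for (k in seq_along(comps)) {
    fr <- comps[[k]]$frags
    if (nrow(fr) < 2L) next
    nPlus <- sum(fr$strand == "+")
    minority <- if (nPlus >= nrow(fr) - nPlus) "-" else "+"
    for (r in which(fr$strand == minority)) {
      partner <- if (r > 1L) r - 1L else r + 1L
      conflicts <- rbind(conflicts,
                         data.frame(fragment_a = fr$id[r],
                                    fragment_b = fr$id[partner],
                                    kind = "strand_inversion",
                                    stringsAsFactors = FALSE))
    }
  }
  # internal deletions: a scaffold end recurring inside another scaffold
  if (length(comps) > 1L) {
    k <- minOverlap
    for (i in seq_along(comps)) for (j in seq_along(comps)) {
      if (i == j) next
      si <- comps[[i]]$seq; sj <- comps[[j]]$seq
      tailI <- substr(si, nchar(si) - k + 1L, nchar(si))
      for (p in .allMatches(tailI, sj)) {
        if (p == 1L) next
        fi <- comps[[i]]$frags
        fj <- comps[[j]]$frags
        fa <- fi$id[which(fi$offset + fi$width - 1L >= nchar(si))[1L]]
        fb <- fj$id[which(fj$offset <= p & fj$offset + fj$width - 1L >= p)[1L]]
        conflicts <- rbind(conflicts,
                           data.frame(fragment_a = fa, fragment_b = fb,
                                      kind = "internal_deletion",
                                      stringsAsFactors = FALSE))
      }
    }
    conflicts <- unique(conflicts)
  }

  gapsDf <- if (length(comps) > 1L) {
    data.frame(junction = seq_len(length(comps) - 1L),
               left_scaffold = scafNames[-length(comps)],
               right_scaffold = scafNames[-1L],
               bridged = FALSE, bridged_by = NA_character_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(junction = integer(0), left_scaffold = character(0),
               right_scaffold = character(0), bridged = logical(0),
               bridged_by = character(0), stringsAsFactors = FALSE)
  }

  new("AssemblyReport",
      scaffolds = setNames(DNAStringSet(vapply(comps, `[[`, character(1), "seq")),
                           scafNames),
      placements = placements, conflicts = conflicts, gaps = gapsDf)
}

# k-mer start positions of `qry` k-mers found in `sbj`, returned as positions
# within `qry`
.kmerHits <- function(qry, sbj, k) {
  n <- nchar(qry)
  if (n < k) return(integer(0))
  hits <- integer(0)
  # scan the subject's k-mers into a hash of the query instead of the other
  # way around when the query is long
  starts <- seq_len(n - k + 1L)
  kmers <- substring(qry, starts, starts + k - 1L)
  found <- vapply(kmers, function(km) length(.allMatches(km, sbj)) > 0L,
                  logical(1))
  starts[found]
}

#' Bridge assembly gaps with cDNA evidence
#'
#' A gap between two consecutive scaffolds is marked bridged when a single
#' cDNA contains exact matches of at least `minOverlap` nt to both flanking
#' scaffolds, in consistent orientation and order (left-scaffold match before
#' right-scaffold match, same strand).  A cDNA matching both flanks in
#' inverted order is not accepted as a bridge and is recorded as an
#' `order_inversion` conflict.
#'
#' @param report an [AssemblyReport-class].
#' @param cdnas a [Biostrings::DNAStringSet] or named character vector of
#'   spliced cDNA sequences.
#' @param scaffoldOrder optional character vector of scaffold names giving
#'   the reference-guided order; defaults to the report's current order.
#' @param minOverlap minimum exact match length (nt); default 20.
#' @return the updated [AssemblyReport-class].
#' @export
bridgeGaps <- function(report, cdnas, scaffoldOrder = NULL, minOverlap = 20L) {
  cd <- .asChar(cdnas)
  if (is.null(names(cd))) names(cd) <- sprintf("cdna_%02d", seq_along(cd))
  scafs <- as.character(report@scaffolds)
  if (!is.null(scaffoldOrder)) {
    stopifnot(setequal(scaffoldOrder, names(scafs)))
    scafs <- scafs[scaffoldOrder]
    n <- length(scafs)
    report@gaps <- if (n > 1L) {
      data.frame(junction = seq_len(n - 1L),
                 left_scaffold = names(scafs)[-n],
                 right_scaffold = names(scafs)[-1L],
                 bridged = FALSE, bridged_by = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      report@gaps[0L, ]
    }
  }
  g <- report@gaps
  if (nrow(g) == 0L || length(cd) == 0L) return(report)
  for (r in seq_len(nrow(g))) {
    left <- scafs[[g$left_scaffold[r]]]
    right <- scafs[[g$right_scaffold[r]]]
    for (ci in seq_along(cd)) {
      for (orient in c("+", "-")) {
        q <- if (orient == "+") cd[[ci]] else revComp(cd[[ci]])
        pl <- .kmerHits(q, left, minOverlap)
        pr <- .kmerHits(q, right, minOverlap)
        if (length(pl) == 0L || length(pr) == 0L) next
        forwardOk <- min(pl) + minOverlap <= max(pr)
        invertedOk <- min(pr) + minOverlap <= max(pl)
        if (forwardOk) {
          g$bridged[r] <- TRUE
          g$bridged_by[r] <- names(cd)[ci]
        } else if (invertedOk) {
          report@conflicts <- unique(rbind(report@conflicts,
            data.frame(fragment_a = names(cd)[ci],
                       fragment_b = paste(g$left_scaffold[r],
                                          g$right_scaffold[r], sep = "/"),
                       kind = "order_inversion", stringsAsFactors = FALSE)))
        }
      }
      if (g$bridged[r]) break
    }
  }
  report@gaps <- g
  report
}
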