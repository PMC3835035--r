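# Mapping located Ig/Fn/kinase domains onto the canonical projectin template:
# two N-terminal Ig tracts (canonically 8 and 6 domains) separated by the
# PEVK + NTCS-1 unique region, a core of tandem [Fn-Fn-Ig] modules
# (canonically 14) and a C-terminal kinase domain.

#' The canonical projectin architecture template
#'
#' @param tract1,tract2 expected Ig counts of the two N-terminal tracts.
#' @param coreUnit ordered kinds of the core repeat unit.
#' @param coreRepeats expected number of core repeats.
#' @param kinase whether a C-terminal kinase domain is expected.
#' @param linkerRange allowed inter-domain linker lengths, aa.
#' @param ntcs1Range expected NTCS-1 segment length range, aa.
#' @return a named list usable as `template` in [classifyArchitecture()].
#' @export
architectureTemplate <- function(tract1 = 8L, tract2 = 6L,
                                 coreUnit = c("Fn", "Fn", "Ig"),
                                 coreRepeats = 14L, kinase = TRUE,
                                 linkerRange = c(5L, 46L),
                                 ntcs1Range = c(112L, 138L)) {
  stopifnot(tract1 >= 1L, tract2 >= 1L, coreRepeats >= 1L,
            linkerRange[1L] > 0L, linkerRange[1L] <= linkerRange[2L])
  list(tract1 = as.integer(tract1), tract2 = as.integer(tract2),
       coreUnit = coreUnit, coreRepeats = as.integer(coreRepeats),
       kinase = isTRUE(kinase),
       linkerRange = as.integer(linkerRange),
       ntcs1Range = as.integer(ntcs1Range))
}

#' Locate consensus domains in a protein
#'
#' Each consensus sequence is scanned against the protein by full-length
#' windowed identity; positions with identity at least `minIdentity` become
#' candidate calls, and overlapping calls are resolved by score (then
#' leftmost).  The library names give the domain kinds (`Ig`, `Fn`,
#' `Kinase`, ...).
#'
#' @param protein an [Biostrings::AAString] or character scalar.
#' @param consensusLibrary named [Biostrings::AAStringSet] (or named
#'   character vector) of consensus peptides; see [consensusDomains()].
#' @param minIdentity minimum identity; default 0.7.
#' @return data.frame sorted by position: `kind`, `start`, `end` (aa,
#'   1-based closed), `identity`, `score`.
#' @export
findDomains <- function(protein, consensusLibrary, minIdentity = 0.7) {
  p <- .chars(.asChar(protein))
  lib <- .asChar(consensusLibrary)
  if (length(lib) == 0L) stop("empty consensus library")
  if (is.null(names(lib))) stop("consensus library must be named by kind")
  cand <- list()
  for (ki in seq_along(lib)) {
    refCh <- .chars(lib[[ki]])
    L <- length(refCh)
    idv <- .windowedIdentity(p, refCh)
    if (is.null(idv)) next
    for (o in which(idv >= minIdentity - FRACTION_EPS)) {
      matches <- round(idv[o] * L)
      cand[[length(cand) + 1L]] <-
        data.frame(kind = names(lib)[ki], start = o, end = o + L - 1L,
                   identity = idv[o], score = 2L * matches - (L - matches),
                   stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(kind = character(0), start = integer(0),
                      end = integer(0), identity = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  covS <- integer(0); covE <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= covE & cand$end[i] >= covS)) {
      keep[i] <- TRUE
      covS <- c(covS, cand$start[i]); covE <- c(covE, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# split ordered calls into tract1 / unique gap / tract2 / core / kinase
.parseArchitecture <- function(calls, maxLinker) {
  n <- nrow(calls)
  gapAfter <- if (n > 1L) calls$start[-1L] - calls$end[-n] - 1L else integer(0)
  i <- 1L
  tract1 <- integer(0)
  while (i <= n && calls$kind[i] == "Ig") {
    tract1 <- c(tract1, i)
    if (i < n && gapAfter[i] > maxLinker) { i <- i + 1L; break }
    i <- i + 1L
  }
  tract2 <- integer(0)
  while (i <= n && calls$kind[i] == "Ig") {
    tract2 <- c(tract2, i)
    if (i < n && gapAfter[i] > maxLinker) { i <- i + 1L; break }
    i <- i + 1L
  }
  core <- integer(0)
  while (i + 2L <= n &&
         all(calls$kind[i:(i + 2L)] == c("Fn", "Fn", "Ig")) &&
         all(gapAfter[i:(i + 1L)] <= maxLinker) &&
         (i == 1L || gapAfter[i - 1L] <= maxLinker)) {
    core <- c(core, i, i + 1L, i + 2L)
    i <- i + 3L
    if (i <= n && gapAfter[i - 1L] > maxLinker) break
  }
  kinase <- if (i <= n && calls$kind[i] == "Kinase") i else integer(0)
  leftover <- setdiff(seq_len(n), c(tract1, tract2, core, kinase))
  list(tract1 = tract1, tract2 = tract2, core = core, kinase = kinase,
       leftover = leftover, gapAfter = gapAfter)
}

#' Classify a domain-call sequence against the projectin template
#'
#' Segments the ordered calls into the leading Ig tract, the unique region,
#' the second Ig tract, the core (maximal run of consecutive \[Fn-Fn-Ig\]
#' triplets) and the kinase, counts repeats, measures inter-domain linkers,
#' and enumerates deviations from the template.  The PEVK / NTCS-1
#' delineation of the unique region is performed with
#' [delineateUniqueRegion()].
#'
#' @param calls data.frame from [findDomains()].
#' @param protein the protein the calls refer to.
#' @param template an [architectureTemplate()].
#' @param alphabet bias alphabet for the PEVK sub-region.
#' @param minLength,minFraction PEVK scanner settings.
#' @return an [ArchitectureReport-class].
#' @export
classifyArchitecture <- function(calls, protein,
                                 template = architectureTemplate(),
                                 alphabet = biasAlphabet(),
                                 minLength = 10L, minFraction = 0.6) {
  p <- .asChar(protein)
  if (nrow(calls) == 0L || !any(calls$kind == "Ig")) {
    stop("classification requires at least one Ig call")
  }
  if (is.unsorted(calls$start)) calls <- calls[order(calls$start), ]
  maxLinker <- template$linkerRange[2L]
  parsed <- .parseArchitecture(calls, maxLinker)
  dev <- character(0)
  t1 <- length(parsed$tract1); t2 <- length(parsed$tract2)
  nCore <- length(parsed$core) %/% 3L
  if (t1 != template$tract1) {
    dev <- c(dev, sprintf("tract1_size_%d_expected_%d", t1, template$tract1))
  }
  if (t2 != template$tract2) {
    dev <- c(dev, sprintf("tract2_size_%d_expected_%d", t2, template$tract2))
  }
  if (nCore != template$coreRepeats) {
    dev <- c(dev, sprintf("core_repeats_%d_expected_%d", nCore,
                          template$coreRepeats))
  }
  kinasePresent <- length(parsed$kinase) > 0L
  if (template$kinase && !kinasePresent) dev <- c(dev, "kinase_missing")
  for (idx in parsed$leftover) {
    dev <- c(dev, sprintf("unexpected_%s_at_%d", calls$kind[idx],
                          calls$start[idx]))
  }
  # linkers: gaps between consecutive calls inside tracts and core
  inside <- c(parsed$tract1, parsed$tract2, parsed$core, parsed$kinase)
  linkers <- integer(0)
  for (blk in list(parsed$tract1, parsed$tract2,
                   c(parsed$core, parsed$kinase))) {
    if (length(blk) > 1L) {
      linkers <- c(linkers, parsed$gapAfter[blk[-length(blk)]])
    }
  }
  bad <- linkers[linkers > 0L & (linkers < template$linkerRange[1L] |
                                 linkers > template$linkerRange[2L])]
  if (length(bad) > 0L) {
    dev <- c(dev, sprintf("linker_out_of_range_%daa", bad))
  }

  uniq <- c(NA_integer_, NA_integer_)
  pevk <- c(NA_integer_, NA_integer_)
  ntcs1 <- c(NA_integer_, NA_integer_)
  yerpPos <- integer(0)
  if (t1 > 0L && t2 > 0L) {
    uniq <- c(calls$end[parsed$tract1[t1]] + 1L,
              calls$start[parsed$tract2[1L]] - 1L)
    dl <- delineateUniqueRegion(p, calls, alphabet = alphabet,
                                minLength = minLength,
                                minFraction = minFraction,
                                maxLinker = maxLinker, quiet = TRUE)
    if (!is.null(dl$pevk)) pevk <- dl$pevk
    if (!is.null(dl$ntcs1)) ntcs1 <- dl$ntcs1
    yerpPos <- uniq[1L] - 1L +
      motifPositions(substr(p, uniq[1L], uniq[2L]))
    if (!anyNA(ntcs1)) {
      nLen <- ntcs1[2L] - ntcs1[1L] + 1L
      if (nLen < template$ntcs1Range[1L] || nLen > template$ntcs1Range[2L]) {
        dev <- c(dev, sprintf("ntcs1_length_%daa_outside_%d_%d", nLen,
                              template$ntcs1Range[1L], template$ntcs1Range[2L]))
      }
    }
  }
  new("ArchitectureReport",
      tractSizes = c(t1, t2), coreRepeats = nCore,
      kinasePresent = kinasePresent,
      uniqueRegion = as.integer(uniq), pevkRegion = as.integer(pevk),
      ntcs1Region = as.integer(ntcs1),
      yerpCount = length(yerpPos), yerpPositions = as.integer(yerpPos),
      linkers = as.integer(linkers), deviations = dev, calls = calls)
}

#' Delineate the PEVK and NTCS-1 sub-regions of the unique region
#'
#' The unique region is the span between the last Ig of the first tract and
#' the first Ig of the second tract.  Its PEVK sub-region runs from the
#' start of the unique region to the end of the last maximal elevated-PEVK
#' segment found by [scanSegments()]; the NTCS-1 sub-region is the remainder
#' abutting the second tract.  When both are non-empty they partition the
#' unique region exactly.
#'
#' @param protein protein sequence.
#' @param calls ordered domain-call data.frame ([findDomains()]).
#' @param alphabet bias alphabet.
#' @param minLength,minFraction scanner settings.
#' @param maxLinker maximum within-tract linker, aa (tract splitting).
#' @param quiet suppress warnings for empty regions.
#' @return list with `pevk` and `ntcs1`, each an integer(2) aa interval
#'   (1-based closed) or NULL when empty.
#' @export
delineateUniqueRegion <- function(protein, calls, alphabet = biasAlphabet(),
                                  minLength = 10L, minFraction = 0.6,
                                  maxLinker = 46L, quiet = FALSE) {
  p <- .asChar(protein)
  if (is.unsorted(calls$start)) calls <- calls[order(calls$start), ]
  parsed <- .parseArchitecture(calls, maxLinker)
  if (length(parsed$tract1) == 0L || length(parsed$tract2) == 0L) {
    stop("both Ig tracts must be identified to delineate the unique region")
  }
  u1 <- calls$end[parsed$tract1[length(parsed$tract1)]] + 1L
  u2 <- calls$start[parsed$tract2[1L]] - 1L
  if (u2 - u1 + 1L < minLength) {
    if (!quiet) warning("unique region shorter than minLength; both regions empty")
    return(list(pevk = NULL, ntcs1 = NULL))
  }
  segs <- scanSegments(substr(p, u1, u2), minLength, minFraction, alphabet)
  if (nrow(segs) == 0L) {
    if (!quiet) warning("no elevated-PEVK segment in the unique region")
    return(list(pevk = NULL, ntcs1 = NULL))
  }
  boundary <- u1 - 1L + max(segs$end_aa)
  pevk <- c(u1, boundary)
  if (boundary >= u2) {
    if (!quiet) warning("unique region entirely PEVK-rich; NTCS-1 empty")
    return(list(pevk = c(u1, u2), ntcs1 = NULL))
  }
  list(pevk = pevk, ntcs1 = c(boundary + 1L, u2))
}
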