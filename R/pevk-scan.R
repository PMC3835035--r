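# Detection of maximal compositional-bias (PEVK) segments in proteins and in
# three-frame translations of genomic DNA.
#
# "Elevated PEVK content" is scored per residue: +(1 - t) for a residue in
# the bias alphabet, -t otherwise, where t is the fraction threshold.  A
# window's score is >= 0 exactly when its alphabet fraction is >= t, so the
# maximal-scoring-segment decomposition (recursive extraction of the top
# scoring window, then recursion into the flanks) yields disjoint, maximal
# "open stretches" of elevated content.  Segments never cross a stop marker.

#' The default PEVK bias alphabet
#'
#' @param residues amino-acid one-letter codes; default P, E, V, K.
#' @param name alphabet name.
#' @return a list with elements `residues` and `name`.
#' @export
biasAlphabet <- function(residues = c("P", "E", "V", "K"), name = "PEVK") {
  residues <- toupper(residues)
  if (length(residues) == 0L || !all(residues %in% AA20)) {
    stop("alphabet must be a non-empty subset of the 20 amino-acid codes")
  }
  list(residues = unique(residues), name = name)
}

#' Fraction of residues belonging to a bias alphabet
#'
#' @param protein an [Biostrings::AAString] or character scalar without stop
#'   markers.
#' @param alphabet a [biasAlphabet()].
#' @return proportion in \[0, 1\].
#' @examples
#' pevkFraction("PEVK")      # 1
#' pevkFraction("PPEGVKAA")  # 0.625
#' @export
pevkFraction <- function(protein, alphabet = biasAlphabet()) {
  p <- .asChar(protein)
  if (nchar(p) == 0L) stop("empty sequence")
  if (grepl("*", p, fixed = TRUE)) stop("sequence contains stop markers")
  .checkProtein(p, allowStop = FALSE)
  ch <- .chars(p)
  sum(ch %in% alphabet$residues) / length(ch)
}

# top-scoring window within positions [from, to] of logical vector `isAlpha`
# (TRUE = alphabet residue); returns c(start, end) or NULL.
# Selection: max score; ties -> smallest start; ties -> longest window.
.topWindow <- function(isAlpha, from, to, minLength, t) {
  n <- to - from + 1L
  if (n < minLength) return(NULL)
  x <- as.integer(isAlpha[from:to])
  cs <- cumsum(c(0L, x))
  bestScore <- -Inf; bestStart <- NA_integer_; bestLen <- NA_integer_
  for (L in minLength:n) {
    cnt <- cs[(L + 1L):(n + 1L)] - cs[1L:(n - L + 1L)]
    sc <- cnt - t * L
    mx <- max(sc)
    if (mx < -FRACTION_EPS) next
    if (mx > bestScore + FRACTION_EPS) {
      bestScore <- mx
      bestStart <- which(sc >= mx - FRACTION_EPS)[1L]
      bestLen <- L
    } else if (mx > bestScore - FRACTION_EPS) {
      st <- which(sc >= mx - FRACTION_EPS)[1L]
      if (st < bestStart || (st == bestStart && L > bestLen)) {
        bestStart <- st
        bestLen <- L
      }
    }
  }
  if (!is.finite(bestScore)) return(NULL)
  c(from + bestStart - 1L, from + bestStart + bestLen - 2L)
}

.extractSegments <- function(isAlpha, from, to, minLength, t) {
  win <- .topWindow(isAlpha, from, to, minLength, t)
  if (is.null(win)) return(NULL)
  rbind(.extractSegments(isAlpha, from, win[1L] - 1L, minLength, t),
        matrix(win, nrow = 1L),
        .extractSegments(isAlpha, win[2L] + 1L, to, minLength, t))
}

#' Scan a protein for maximal segments of elevated bias content
#'
#' Returns all maximal disjoint segments of length at least `minLength`
#' whose alphabet fraction is at least `minFraction`, reported N- to
#' C-terminal.  Segments never cross a stop marker (`*`); adjacent
#' qualifying windows separated by a sub-threshold stretch are reported
#' separately, not merged.
#'
#' @param protein an [Biostrings::AAString] or character scalar (may contain
#'   `*` stop markers, which split the search space).
#' @param minLength minimum segment length in aa; default 10.
#' @param minFraction minimum alphabet fraction in (0, 1\]; default 0.6.
#' @param alphabet a [biasAlphabet()].
#' @return data.frame with columns `start_aa`, `end_aa` (1-based closed),
#'   `length`, `fraction`, `sequence`; zero rows when nothing qualifies.
#' @export
scanSegments <- function(protein, minLength = 10L, minFraction = 0.6,
                         alphabet = biasAlphabet()) {
  if (minLength < 1L) stop("minLength must be >= 1")
  if (minFraction <= 0 || minFraction > 1) stop("minFraction must be in (0, 1]")
  p <- .asChar(protein)
  .checkProtein(p)
  ch <- .chars(p)
  isAlpha <- ch %in% alphabet$residues
  isStop <- ch == "*"
  segs <- NULL
  # open stretches between stop markers
  bounds <- c(0L, which(isStop), length(ch) + 1L)
  for (b in seq_len(length(bounds) - 1L)) {
    from <- bounds[b] + 1L; to <- bounds[b + 1L] - 1L
    if (to - from + 1L < minLength) next
    segs <- rbind(segs, .extractSegments(isAlpha, from, to, minLength,
                                         minFraction))
  }
  if (is.null(segs)) {
    return(data.frame(start_aa = integer(0), end_aa = integer(0),
                      length = integer(0), fraction = numeric(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  segs <- segs[order(segs[, 1L]), , drop = FALSE]
  len <- segs[, 2L] - segs[, 1L] + 1L
  frac <- vapply(seq_len(nrow(segs)), function(i) {
    sum(isAlpha[segs[i, 1L]:segs[i, 2L]]) / len[i]
  }, numeric(1))
  data.frame(start_aa = segs[, 1L], end_aa = segs[, 2L], length = len,
             fraction = frac,
             sequence = substring(p, segs[, 1L], segs[, 2L]),
             stringsAsFactors = FALSE)
}

#' Scan three forward-frame translations of genomic DNA for PEVK segments
#'
#' Translates frames 0-2 of the forward strand, splits at stop codons, runs
#' [scanSegments()] on each open stretch and maps segment coordinates back
#' to nucleotide space.  The reverse strand can be scanned by passing
#' [revComp()] of the sequence explicitly.
#'
#' @inheritParams scanSegments
#' @param dna a [Biostrings::DNAString] or character scalar.
#' @return data.frame with columns `frame`, `start_aa`, `end_aa` (positions
#'   in that frame's translation), `nt_start`, `nt_end` (genomic, 1-based
#'   closed), `length`, `fraction`, `sequence`.
#' @export
threeFrameScan <- function(dna, minLength = 10L, minFraction = 0.6,
                           alphabet = biasAlphabet()) {
  s <- .asChar(dna)
  .checkDna(s)
  out <- NULL
  for (frame in 0:2) {
    aa <- as.character(translateFrame(s, frame))
    if (nchar(aa) == 0L) next
    segs <- scanSegments(aa, minLength, minFraction, alphabet)
    if (nrow(segs) == 0L) next
    segs$frame <- frame
    segs$nt_start <- frame + 3L * (segs$start_aa - 1L) + 1L
    segs$nt_end <- frame + 3L * segs$end_aa
    out <- rbind(out, segs)
  }
  if (is.null(out)) {
    return(data.frame(frame = integer(0), start_aa = integer(0),
                      end_aa = integer(0), nt_start = integer(0),
                      nt_end = integer(0), length = integer(0),
                      fraction = numeric(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$nt_start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("frame", "start_aa", "end_aa", "nt_start", "nt_end",
          "length", "fraction", "sequence")]
}

#' Count non-overlapping exact occurrences of a motif
#'
#' @param protein an [Biostrings::AAString] or character scalar.
#' @param motif exact residue motif; default `"YERP"`.
#' @return integer count (leftmost-first, non-overlapping).
#' @examples
#' countMotif("AYERPA")    # 1
#' countMotif("YERPYERP")  # 2
#' @export
countMotif <- function(protein, motif = "YERP") {
  if (nchar(motif) == 0L) stop("motif must be non-empty")
  length(.allMatches(toupper(motif), .asChar(protein)))
}

#' Positions of non-overlapping exact occurrences of a motif
#'
#' @inheritParams countMotif
#' @return integer vector of 1-based start offsets.
#' @export
motifPositions <- function(protein, motif = "YERP") {
  if (nchar(motif) == 0L) stop("motif must be non-empty")
  .allMatches(toupper(motif), .asChar(protein))
}
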