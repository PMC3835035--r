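# Cross-species PEVK/NTCS-1 summaries and pairwise global identity.
#
# Global identity is computed by Needleman-Wunsch with a linear gap penalty.
# Among equal-score alignments the one with the most matched columns, then
# the most aligned (residue-residue) columns, is chosen; this makes
# identity = matches / columns a deterministic, well-defined quantity
# (co-optimal alignments can otherwise disagree on it).

.nwAlign <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  A <- .chars(a); B <- .chars(b)
  n <- length(A); m <- length(B)
  sc <- matrix(0, n + 1L, m + 1L)   # best score
  mt <- matrix(0L, n + 1L, m + 1L)  # matches under best
  pr <- matrix(0L, n + 1L, m + 1L)  # aligned pairs under best
  pt <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 up, 3 left
  sc[1L, ] <- gap * (0:m); pt[1L, -1L] <- 3L
  sc[, 1L] <- gap * (0:n); pt[-1L, 1L] <- 2L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      hit <- A[i] == B[j]
      d <- sc[i, j] + if (hit) match else mismatch
      u <- sc[i, j + 1L] + gap
      l <- sc[i + 1L, j] + gap
      cand <- c(d, u, l)
      candM <- c(mt[i, j] + hit, mt[i, j + 1L], mt[i + 1L, j])
      candP <- c(pr[i, j] + 1L, pr[i, j + 1L], pr[i + 1L, j])
      best <- 1L
      for (k in 2:3) {
        if (cand[k] > cand[best] + 1e-12 ||
            (abs(cand[k] - cand[best]) <= 1e-12 &&
             (candM[k] > candM[best] ||
              (candM[k] == candM[best] && candP[k] > candP[best])))) {
          best <- k
        }
      }
      sc[i + 1L, j + 1L] <- cand[best]
      mt[i + 1L, j + 1L] <- candM[best]
      pr[i + 1L, j + 1L] <- candP[best]
      pt[i + 1L, j + 1L] <- best
    }
  }
  # traceback
  i <- n + 1L; j <- m + 1L
  alnA <- character(0); alnB <- character(0)
  while (i > 1L || j > 1L) {
    mv <- pt[i, j]
    if (mv == 1L) {
      alnA <- c(A[i - 1L], alnA); alnB <- c(B[j - 1L], alnB)
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      alnA <- c(A[i - 1L], alnA); alnB <- c("-", alnB)
      i <- i - 1L
    } else {
      alnA <- c("-", alnA); alnB <- c(B[j - 1L], alnB)
      j <- j - 1L
    }
  }
  list(score = sc[n + 1L, m + 1L], matches = mt[n + 1L, m + 1L],
       pairs = pr[n + 1L, m + 1L], columns = n + m - pr[n + 1L, m + 1L],
       alignedA = paste(alnA, collapse = ""),
       alignedB = paste(alnB, collapse = ""))
}

#' Pairwise global identity of two protein sequences
#'
#' Needleman-Wunsch global alignment with configurable linear scoring
#' (defaults: match +1, mismatch 0, gap -1 per residue).  Identity is the
#' number of matched columns divided by the total number of alignment
#' columns (aligned pairs plus gap columns).
#'
#' @param a,b [Biostrings::AAString] or character sequences (non-empty).
#' @param match,mismatch,gap scoring parameters.
#' @return data.frame row: `seq_a_id`, `seq_b_id`, `identity`,
#'   `aligned_length`, `matches`, `score`.
#' @examples
#' globalIdentity("PEVK", "PAVK")$identity  # 0.75
#' @export
globalIdentity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  aid <- if (!is.null(names(a))) names(a)[1L] else "seq_a"
  bid <- if (!is.null(names(b))) names(b)[1L] else "seq_b"
  a <- .asChar(a); b <- .asChar(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  al <- .nwAlign(a, b, match, mismatch, gap)
  data.frame(seq_a_id = aid, seq_b_id = bid,
             identity = al$matches / al$columns,
             aligned_length = al$columns, matches = al$matches,
             score = al$score, stringsAsFactors = FALSE)
}

#' Per-column conservation track against an anchor sequence
#'
#' Each sequence is globally aligned to the anchor; for every anchor column
#' the proportion of sequences carrying the identical residue is reported.
#' This is a lightweight stand-in for shaded multiple-alignment figures.
#'
#' @param anchor anchor protein sequence.
#' @param seqs named list/vector of protein sequences.
#' @inheritParams globalIdentity
#' @return data.frame: `position`, `residue`, `agreement`.
#' @export
conservationTrack <- function(anchor, seqs, match = 1, mismatch = 0,
                              gap = -1) {
  anchor <- .asChar(anchor)
  seqs <- .asChar(seqs)
  n <- nchar(anchor)
  agree <- matrix(FALSE, nrow = length(seqs), ncol = n)
  for (si in seq_along(seqs)) {
    al <- .nwAlign(anchor, seqs[[si]], match, mismatch, gap)
    ca <- .chars(al$alignedA); cb <- .chars(al$alignedB)
    pos <- cumsum(ca != "-")
    hit <- ca != "-" & ca == cb
    agree[si, pos[hit]] <- TRUE
  }
  data.frame(position = seq_len(n), residue = .chars(anchor),
             agreement = colMeans(agree), stringsAsFactors = FALSE)
}

#' Summarize species PEVK/NTCS-1 profiles
#'
#' Adds the derived columns `ratio_percent` (shortest/longest PEVK length as
#' an integer percentage, [lengthRatioPercent()]) and `length_difference_aa`
#' and sorts by species.
#'
#' @param profiles data.frame with at least `species_id`,
#'   `shortest_pevk_aa`, `longest_pevk_aa`; other profile columns
#'   (`pevk_content_long`, `pevk_content_short`, `n_alternative_exons`,
#'   `n_isoforms_detected`, `yerp_count`, `ntcs1_length_aa`) are carried
#'   through.
#' @return the augmented, sorted data.frame.
#' @export
summarizeProfiles <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L,
            all(c("species_id", "shortest_pevk_aa", "longest_pevk_aa") %in%
                  colnames(profiles)))
  bad <- profiles$shortest_pevk_aa > profiles$longest_pevk_aa
  if (any(bad)) {
    stop("inconsistent profile(s): shortest > longest for ",
         paste(profiles$species_id[bad], collapse = ", "))
  }
  for (cc in c("pevk_content_long", "pevk_content_short")) {
    if (cc %in% colnames(profiles) &&
        any(profiles[[cc]] < 0 | profiles[[cc]] > 1, na.rm = TRUE)) {
      stop("contents must lie in [0, 1]")
    }
  }
  profiles$ratio_percent <- lengthRatioPercent(profiles$shortest_pevk_aa,
                                               profiles$longest_pevk_aa)
  profiles$length_difference_aa <-
    profiles$longest_pevk_aa - profiles$shortest_pevk_aa
  profiles <- profiles[order(profiles$species_id), , drop = FALSE]
  rownames(profiles) <- NULL
  profiles
}
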