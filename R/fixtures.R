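# Packaged M. sexta-like PEVK fixture.
#
# The fixture encodes only the printed constraints of the M. sexta PEVK
# splice system: seven PEVK exons of which #3 and #6 are alternatively
# spliced, exon 5 of 24 nt, exon 6 of 33 nt, a longest PEVK region of 377 aa
# and a shortest of 205 aa, two YERP motifs present in every variant (one
# mid-PEVK, one starting the NTCS-1 segment), and Ms1-6R amplicons of 926
# and 893 bp for the C and D isoforms.  Exon lengths not fixed by those
# constraints are synthetic.  Construction is fully deterministic (cyclic
# codon choice, no RNG).

# deterministic reverse translation: per-amino-acid cyclic codon choice
.cyclicRevTranslator <- function() {
  tab <- .codonTable()
  counters <- new.env(parent = emptyenv())
  function(pep) {
    ch <- .chars(pep)
    out <- character(length(ch))
    for (i in seq_along(ch)) {
      aa <- ch[i]
      k <- if (is.null(counters[[aa]])) 0L else counters[[aa]]
      cods <- sort(tab[[aa]])
      out[i] <- cods[(k %% length(cods)) + 1L]
      counters[[aa]] <- k + 1L
    }
    paste(out, collapse = "")
  }
}

# deterministic PEVK-biased peptide: alphabet residues cycle P,E,V,K and
# filler residues (cycling G,A,S,T) are spread evenly through the interior
.pevkPeptideDet <- function(naa, content) {
  nNon <- as.integer(.roundHalfAway((1 - content) * naa))
  nNon <- min(nNon, max(naa - 2L, 0L))
  alpha <- c("P", "E", "V", "K"); fill <- c("G", "A", "S", "T")
  ch <- alpha[(seq_len(naa) - 1L) %% 4L + 1L]
  if (nNon > 0L) {
    lo <- min(4L, naa); hi <- max(naa - 3L, lo)
    at <- unique(as.integer(.roundHalfAway(seq(lo, hi, length.out = nNon))))
    ch[at] <- fill[(seq_along(at) - 1L) %% 4L + 1L]
  }
  paste(ch, collapse = "")
}

.flankPeptide <- function(naa) {
  # aperiodic over its first 64 residues so primer footprints stay unique
  base <- .chars("AGAMNFCYWLIQSWTFNLDMFQGDWGMCRCAITQWHYLFNSNSIRCIDQHTGRDHRLHASYMYT")
  paste(base[(seq_len(naa) - 1L) %% length(base) + 1L], collapse = "")
}

#' The packaged M. sexta-like PEVK gene fixture
#'
#' A deterministic nine-exon gene model covering the PEVK neighborhood of a
#' M. sexta-like projectin gene: one flanking Ig-tract exon, seven PEVK
#' exons (`pevk_3` and `pevk_6` alternatively spliced; `pevk_5` is 24 nt,
#' `pevk_6` 33 nt) and one NTCS-1 flanking exon.  Enumerating its splice
#' graph yields four isoforms A-D whose PEVK regions are 377, 366, 216 and
#' 205 aa, and the packaged Ms1-6R primer pair amplifies 926 / 893 bp
#' products from isoforms C and D.
#'
#' @return a list with elements `model` ([GeneModel-class]), `primers`
#'   ([PrimerPair-class] Ms1-6R) and `pools` (named list of isoform labels
#'   per muscle type: leg, thorax, flight, head).
#' @export
msextaFixture <- function() {
  rt <- .cyclicRevTranslator()
  peps <- c(
    ig_flank_up = .flankPeptide(50L),
    pevk_1 = .pevkPeptideDet(50L, 0.72),
    pevk_2 = .pevkPeptideDet(50L, 0.72),
    pevk_3 = .pevkPeptideDet(161L, 0.94),
    pevk_4 = .pevkPeptideDet(47L, 0.70),
    pevk_5 = "PEVKPEVK",
    pevk_6 = .pevkPeptideDet(11L, 8 / 11),
    pevk_7 = .pevkPeptideDet(50L, 0.72),
    ntcs1_flank = paste0("YERP", .NTCS1_CONSENSUS, .flankPeptide(14L))
  )
  # one YERP motif inside the constitutive PEVK exon 2
  peps["pevk_2"] <- paste0(substr(peps["pevk_2"], 1L, 19L), "YERP",
                           substr(peps["pevk_2"], 24L, 50L))
  exDna <- vapply(peps, rt, character(1))
  intron <- function(len) {
    body <- .chars("CTACTTACCATTCAACCTTA")
    paste0("GT", paste(body[(seq_len(len - 4L) - 1L) %% 20L + 1L],
                       collapse = ""), "AG")
  }
  intronLens <- c(84L, 92L, 76L, 88L, 80L, 96L, 72L, 90L)
  parts <- character(0)
  starts <- integer(length(exDna)); ends <- integer(length(exDna))
  pos <- 0L
  for (i in seq_along(exDna)) {
    starts[i] <- pos + 1L
    pos <- pos + nchar(exDna[i]); ends[i] <- pos
    parts <- c(parts, exDna[i])
    if (i < length(exDna)) {
      parts <- c(parts, intron(intronLens[i]))
      pos <- pos + intronLens[i]
    }
  }
  model <- newGeneModel("msexta_pevk", paste(parts, collapse = ""),
                        data.frame(label = names(peps), start = starts,
                                   end = ends,
                                   splicing_class = ifelse(
                                     names(peps) %in% c("pevk_3", "pevk_6"),
                                     "alternative", "constitutive"),
                                   stringsAsFactors = FALSE))
  # Ms1: nt 31-50 of the upstream Ig flank exon; 6R: reverse complement of
  # nt 139-158 of the NTCS-1 flank exon
  fwd <- substr(exDna[["ig_flank_up"]], 31L, 50L)
  rev <- revComp(substr(exDna[["ntcs1_flank"]], 139L, 158L))
  primers <- primerPair("Ms1-6R", fwd, rev)
  pools <- list(leg = c("A", "B", "C"),
                thorax = c("A", "B", "C", "D"),
                flight = c("A", "B", "C", "D"),
                head = c("A", "B", "C"))
  list(model = model, primers = primers, pools = pools)
}

#' In-text species PEVK profiles
#'
#' The per-species PEVK/NTCS-1 characteristics that appear as numbers in
#' the running text: M. sexta (shortest/longest PEVK 205/377 aa, 2
#' alternative exons, 4 detected isoforms, 2 YERP motifs) and
#' D. melanogaster (75/530 aa, 11 alternative exons, 10 detected isoforms,
#' 2 YERP motifs).  Columns without an in-text value are `NA`.
#'
#' @return a data.frame usable with [summarizeProfiles()].
#' @export
lepidopteraProfiles <- function() {
  data.frame(
    species_id = c("D.melanogaster", "M.sexta"),
    shortest_pevk_aa = c(75L, 205L),
    longest_pevk_aa = c(530L, 377L),
    pevk_content_long = c(NA_real_, NA_real_),
    pevk_content_short = c(NA_real_, NA_real_),
    n_alternative_exons = c(11L, 2L),
    n_isoforms_detected = c(10L, 4L),
    yerp_count = c(2L, 2L),
    ntcs1_length_aa = c(NA_integer_, 120L),
    stringsAsFactors = FALSE
  )
}
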