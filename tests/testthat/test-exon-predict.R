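test_that("an identical reference anchors with identity 1 at exact coordinates", {
  tr <- generateGene(scaledConfig(seed = 31, domainMutationRate = 0))
  g <- genomeSeq(truthModel(tr))
  refs <- exonReferences(tr)
  anc <- anchorDomains(g, refs["pevk_1"], minIdentity = 0.9)
  te <- exonTable(truthModel(tr))
  expect_equal(nrow(anc), 1L)
  expect_equal(anc$identity, 1.0)
  expect_equal(anc$start, te$start[te$label == "pevk_1"])
  expect_equal(anc$end, te$end[te$label == "pevk_1"])
})

test_that("unrelated references produce no anchors", {
  set.seed(5)
  g <- randomDna(3000)
  ref <- c(decoy = randomProtein(30, pevkPatch = FALSE))
  expect_equal(nrow(anchorDomains(g, ref, minIdentity = 0.8)), 0L)
})

test_that("mutated domains still anchor at identity 0.7", {
  tr <- generateGene(scaledConfig(seed = 32, domainMutationRate = 0.10))
  anc <- anchorDomains(genomeSeq(truthModel(tr)), exonReferences(tr), 0.7)
  expect_setequal(unique(anc$reference_id), names(exonReferences(tr)))
  expect_true(all(anc$start[-1L] > anc$end[-nrow(anc)]))  # non-overlapping
})

test_that("boundary refinement recovers clean gene models exactly", {
  tr <- cachedScaledGene()
  g <- genomeSeq(truthModel(tr))
  anc <- anchorDomains(g, exonReferences(tr), 0.7)
  pred <- refineBoundaries(anc, g, references = exonReferences(tr))
  te <- exonTable(truthModel(tr)); pe <- exonTable(pred$model)
  expect_equal(pe$start, te$start)
  expect_equal(pe$end, te$end)
  expect_equal(pe$phase, te$phase)
  expect_false(any(pred$sites$ambiguous))
  expect_true(all(pred$sites$canonical))
  # frame continuity: the full predicted transcript translates without
  # internal stops
  aa <- as.character(translateTranscript(spliceTranscript(pred$model)))
  expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE))
})

test_that("equally scoring acceptor pairs are flagged ambiguous, not guessed", {
  e1pep <- "MAAAAAAA"
  e2pep <- "QARSTNDH"
  rt <- function(p) paste(vapply(strsplit(p, "")[[1]], function(a) {
    c(M = "ATG", A = "GCA", Q = "CAA", R = "CGA", S = "TCA", T = "ACA",
      N = "AAC", D = "GAC", H = "CAC")[[a]]
  }, character(1)), collapse = "")
  e1 <- rt(e1pep)
  e2 <- rt(e2pep)                       # starts CAA; nt 2-3 are "AA"
  # acceptors at S-3 and S+3, none at the true start S
  substrRep <- function(x, at, rep) {
    paste0(substr(x, 1, at - 1), rep, substr(x, at + nchar(rep), nchar(x)))
  }
  e2 <- substrRep(e2, 2, "AG")          # exon nt 2-3 = AG -> acceptor at S+3
  intron <- paste0("GT", strrep("CT", 25), "AG", "TTT")  # acceptor at S-3
  genome <- paste0(e1, intron, e2)
  S <- nchar(e1) + nchar(intron) + 1L
  anchors <- data.frame(reference_id = c("e1", "e2"),
                        start = c(1L, S), end = c(nchar(e1), S + nchar(e2) - 1L),
                        frame = c(0L, (S - 1L) %% 3L),
                        identity = c(1, 1), score = c(10, 10),
                        stringsAsFactors = FALSE)
  pred <- refineBoundaries(anchors, genome, references = NULL)
  expect_true(pred$sites$ambiguous[1])
})

test_that("a single anchor yields an intronless single-exon model", {
  set.seed(9)
  pep <- randomProtein(40, pevkPatch = FALSE)
  dna <- paste(vapply(strsplit(pep, "")[[1]], function(a) {
    sample(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a], 1)
  }, character(1)), collapse = "")
  anc <- anchorDomains(dna, c(ref = pep), 0.9)
  pred <- refineBoundaries(anc, dna)
  expect_equal(nrow(exonTable(pred$model)), 1L)
  expect_equal(nrow(pred$sites), 0L)
})

test_that("cDNA verification confirms isoforms and pinpoints mismatches", {
  tr <- cachedScaledGene()
  m <- truthModel(tr)
  isofs <- enumerateIsoforms(spliceGraph(m))
  full <- as.character(transcriptSeq(isofs$A))
  short <- as.character(transcriptSeq(isofs[[length(isofs)]]))
  # exact transcript and an alternative-exon-skipping cDNA both confirm
  ver <- verifyWithCdna(m, c(full_tr = full, skip_tr = short))
  expect_equal(ver$report$status, c("confirmed", "confirmed"))
  # an artificially ambiguous junction covered by a confirming cDNA resolves
  sites <- data.frame(intron = 2L, donor_pos = NA, acceptor_pos = NA,
                      dinucleotides = "GT..AG", canonical = TRUE,
                      ambiguous = TRUE)
  ver2 <- verifyWithCdna(m, c(tr = full), sites = sites)
  expect_false(ver2$sites$ambiguous[1])
  # one mismatched base is reported with its position
  mm <- full
  substr(mm, 500, 500) <- if (substr(mm, 500, 500) == "A") "C" else "A"
  ver3 <- verifyWithCdna(m, c(bad = substr(mm, 400, 700)))
  expect_equal(ver3$report$status, "mismatch")
  expect_equal(ver3$report$mismatch_positions, "101")
})
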