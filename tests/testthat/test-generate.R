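test_that("generation is byte-deterministic under a fixed seed", {
  a <- generateGene(scaledConfig(seed = 42))
  b <- generateGene(scaledConfig(seed = 42))
  expect_identical(as.character(genomeSeq(truthModel(a))),
                   as.character(genomeSeq(truthModel(b))))
  expect_identical(exonTable(truthModel(a)), exonTable(truthModel(b)))
  expect_identical(as.character(truthProtein(a)),
                   as.character(truthProtein(b)))
  c <- generateGene(scaledConfig(seed = 43))
  expect_false(identical(as.character(genomeSeq(truthModel(a))),
                         as.character(genomeSeq(truthModel(c)))))
})

test_that("the planted domain map matches the template", {
  tr <- cachedDefaultGene()
  dm <- domainMap(tr)
  expect_equal(sum(dm$kind == "Ig"), 8L + 6L + 14L)
  expect_equal(sum(dm$kind == "Fn"), 28L)
  expect_equal(sum(dm$kind == "Kinase"), 1L)
  # the core is 14 consecutive Fn,Fn,Ig triplets before the kinase
  coreKinds <- dm$kind[(nrow(dm) - 42L):(nrow(dm) - 1L)]
  expect_equal(coreKinds, rep(c("Fn", "Fn", "Ig"), 14L))
})

test_that("planted PEVK exons hit their target composition", {
  tr <- cachedScaledGene()
  targets <- tr@config$pevkExonTargets
  refs <- exonReferences(tr)
  for (r in seq_len(nrow(targets))) {
    pep <- as.character(refs[[targets$label[r]]])
    cnt <- sum(strsplit(pep, "")[[1]] %in% c("P", "E", "V", "K"))
    want <- round(targets$target_content[r] * targets$length_aa[r])
    tol <- if (r == 1L) 3L else 1L    # exon 1 carries the planted YERP
    expect_lte(abs(cnt - want), tol)
  }
  # boundary of the configured range: 100 percent composition
  pure <- generateGene(scaledConfig(seed = 3, pevkContentRange = c(1, 1)))
  for (lab in grep("^pevk", names(exonReferences(pure)), value = TRUE)) {
    pep <- as.character(exonReferences(pure)[[lab]])
    pep <- gsub("YERP", "", pep)      # the planted motif is exempt
    expect_equal(pevkFraction(pep), 1.0)
  }
})

test_that("every truth isoform translates without internal stops", {
  tr <- cachedScaledGene()
  isofs <- enumerateIsoforms(spliceGraph(truthModel(tr)))
  for (iso in isofs) {
    aa <- as.character(translateTranscript(iso))
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE))
  }
})

test_that("fragment provenance tiles the genome exactly", {
  tr <- cachedScaledGene()
  fr <- generateFragments(tr)
  g <- as.character(genomeSeq(truthModel(tr)))
  prov <- fr$provenance[order(fr$provenance$start), ]
  expect_equal(prov$start[1], 1L)
  expect_equal(prov$end[nrow(prov)], nchar(g))
  expect_true(all(prov$start[-1L] <= prov$end[-nrow(prov)] + 1L))
  for (r in seq_len(nrow(prov))) {
    expect_equal(as.character(fr$fragments[[prov$fragment[r]]]),
                 substr(g, prov$start[r], prov$end[r]))
  }
})

test_that("isoform pools restrict the shortest variant to thorax and flight", {
  tr <- cachedScaledGene()
  pools <- isoformPools(tr)
  flightOnly <- setdiff(pools$flight, pools$leg)
  expect_length(flightOnly, 1L)
  expect_equal(setdiff(pools$thorax, pools$head), flightOnly)
  # pool structure is seed-invariant even though sequences change
  pools2 <- isoformPools(generateGene(scaledConfig(seed = 99)))
  expect_identical(lapply(pools, sort), lapply(pools2, sort))
})

test_that("degenerate primers bind every truth isoform uniquely", {
  tr <- cachedScaledGene()
  isofs <- enumerateIsoforms(spliceGraph(truthModel(tr)))
  exact <- generateDegeneratePrimers(tr, nDegenerate = 0)
  deg <- generateDegeneratePrimers(tr, nDegenerate = 3)
  for (iso in isofs) {
    s0 <- inSilicoPcr(iso, exact)$size_bp
    s3 <- inSilicoPcr(iso, deg)$size_bp
    expect_equal(s3, s0)   # degeneracy covers the true bases
  }
  expect_error(generateDegeneratePrimers(tr, forwardExon = "pevk_2"),
               "alternatively spliced")
})

test_that("decoy splice sites are resolved by junction scoring", {
  tr <- generateGene(scaledConfig(seed = 12, decoySpliceSites = TRUE))
  g <- genomeSeq(truthModel(tr))
  anc <- anchorDomains(g, exonReferences(tr), 0.7)
  pred <- refineBoundaries(anc, g, references = exonReferences(tr))
  te <- exonTable(truthModel(tr)); pe <- exonTable(pred$model)
  expect_equal(pe$start, te$start)
  expect_equal(pe$end, te$end)
})

test_that("impossible generator constraints are rejected up front", {
  expect_error(generatorConfig(pevkExonLengthRange = c(5, 50)), "at least 10")
  expect_error(generatorConfig(alternativeExons = c(3, 9),
                               pevkExonCount = 7), "exceeds")
  expect_error(generatorConfig(fragmentLengthRange = c(100, 200),
                               fragmentOverlapRange = c(120, 150)),
               "overlap")
})
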