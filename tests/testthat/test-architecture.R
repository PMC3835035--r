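test_that("findDomains locates consensus copies in order", {
  lib <- consensusDomains()
  ig <- as.character(lib[["Ig"]]); fn <- as.character(lib[["Fn"]])
  calls <- findDomains(ig, lib)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "Ig")
  expect_equal(calls$start, 1L)
  expect_equal(calls$end, nchar(ig))
  two <- findDomains(paste0(ig, fn), lib)
  expect_equal(two$kind, c("Ig", "Fn"))
  expect_equal(two$start, c(1L, nchar(ig) + 1L))
  expect_error(findDomains(ig, Biostrings::AAStringSet()), "empty")
})

test_that("domain calls on the default synthetic projectin match the planted map", {
  tr <- cachedDefaultGene()
  calls <- findDomains(truthProtein(tr), consensusDomains())
  dm <- domainMap(tr)
  expect_equal(nrow(calls), nrow(dm))
  expect_equal(calls$kind, dm$kind)
  expect_equal(calls$start, dm$start)
  expect_equal(calls$end, dm$end)
})

test_that("the canonical synthetic projectin classifies with zero deviations", {
  tr <- cachedDefaultGene()
  calls <- findDomains(truthProtein(tr), consensusDomains())
  rep <- classifyArchitecture(calls, truthProtein(tr))
  expect_equal(tractSizes(rep), c(8L, 6L))
  expect_equal(coreRepeats(rep), 14L)
  expect_true(rep@kinasePresent)
  expect_length(deviations(rep), 0L)
  expect_equal(yerpCount(rep), 2L)
  # linkers observed within the template range
  expect_true(all(rep@linkers >= 5L & rep@linkers <= 46L))
})

test_that("a 7-domain leading tract is reported as a deviation", {
  cache <- .projCache()
  if (is.null(cache$sevenTract)) {
    cache$sevenTract <- generateGene(
      generatorConfig(seed = 4,
                      template = architectureTemplate(tract1 = 7L)))
  }
  tr <- cache$sevenTract
  calls <- findDomains(truthProtein(tr), consensusDomains())
  rep <- classifyArchitecture(calls, truthProtein(tr))
  expect_equal(tractSizes(rep)[1], 7L)
  expect_true(any(grepl("tract1_size_7", deviations(rep))))
})

test_that("shuffled domain order yields zero core repeats and deviations", {
  protein <- strrep("A", 1000)
  calls <- data.frame(kind = rep(c("Ig", "Fn"), 5),
                      start = seq(1, by = 100, length.out = 10),
                      end = seq(90, by = 100, length.out = 10),
                      identity = 1, score = 100)
  rep <- suppressWarnings(classifyArchitecture(calls, protein))
  expect_equal(coreRepeats(rep), 0L)
  expect_gt(length(deviations(rep)), 0L)
  expect_error(classifyArchitecture(calls[calls$kind == "Fn", ], protein),
               "Ig")
})

test_that("classification is invariant to uniform coordinate shifts", {
  tr <- cachedDefaultGene()
  prot <- as.character(truthProtein(tr))
  calls <- findDomains(prot, consensusDomains())
  shift <- 100L
  protShift <- paste0(strrep("A", shift), prot)
  callsShift <- transform(calls, start = start + shift, end = end + shift)
  a <- classifyArchitecture(calls, prot)
  b <- classifyArchitecture(callsShift, protShift)
  expect_equal(tractSizes(b), tractSizes(a))
  expect_equal(coreRepeats(b), coreRepeats(a))
  expect_equal(deviations(b), deviations(a))
  expect_equal(pevkRegion(b), pevkRegion(a) + shift)
})

test_that("the unique region splits at the planted PEVK/NTCS-1 boundary", {
  tr <- cachedDefaultGene()
  calls <- findDomains(truthProtein(tr), consensusDomains())
  dl <- delineateUniqueRegion(truthProtein(tr), calls)
  expect_equal(dl$pevk[1], tr@uniqueRegion[1])
  expect_equal(dl$pevk[2], tr@pevkBoundary)      # split at the boundary +- 0
  expect_equal(dl$ntcs1[1], tr@pevkBoundary + 1L)
  expect_equal(dl$ntcs1[2], tr@uniqueRegion[2])
  # partition: no gap, no overlap
  expect_equal(dl$ntcs1[1] - dl$pevk[2], 1L)
})

test_that("degenerate unique regions are reported empty with a warning", {
  lib <- consensusDomains()
  ig <- as.character(lib[["Ig"]])
  # unique region entirely PEVK-rich: NTCS-1 empty
  prot <- paste0(ig, strrep("PEVK", 50), ig)
  calls <- data.frame(kind = c("Ig", "Ig"),
                      start = c(1L, 91L + 200L), end = c(90L, 290L),
                      identity = 1, score = 100)
  calls$end <- c(90L, calls$start[2] + 89L)
  expect_warning(dl <- delineateUniqueRegion(prot, calls), "NTCS-1 empty")
  expect_null(dl$ntcs1)
  expect_equal(dl$pevk, c(91L, 290L))
  # unique region shorter than the minimum segment length: both empty
  # (a small maxLinker forces the 5 aa span to count as a unique region)
  prot2 <- paste0(ig, "PEVKP", ig)
  calls2 <- data.frame(kind = c("Ig", "Ig"), start = c(1L, 96L),
                       end = c(90L, 185L), identity = 1, score = 100)
  expect_warning(dl2 <- delineateUniqueRegion(prot2, calls2, maxLinker = 3L),
                 "shorter")
  expect_null(dl2$pevk)
  expect_null(dl2$ntcs1)
})
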