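# Independent oracles and shared scaled fixtures for the test suite.

# ---- shared cache (persists across test files within one session) ---------

.projCache <- function() {
  if (!exists(".projectin_test_cache", envir = globalenv())) {
    assign(".projectin_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  }
  get(".projectin_test_cache", envir = globalenv())
}

# reduced template used by property suites: same gene grammar, desk scale
scaledConfig <- function(seed = 7L, ...) {
  generatorConfig(seed = seed,
                  template = architectureTemplate(tract1 = 3L, tract2 = 2L,
                                                  coreRepeats = 2L),
                  pevkExonCount = 4L, alternativeExons = c(2L, 4L), ...)
}

cachedScaledGene <- function(seed = 7L) {
  cache <- .projCache()
  key <- paste0("scaled_", seed)
  if (is.null(cache[[key]])) cache[[key]] <- generateGene(scaledConfig(seed))
  cache[[key]]
}

cachedDefaultGene <- function(seed = 1L) {
  cache <- .projCache()
  key <- paste0("default_", seed)
  if (is.null(cache[[key]])) {
    cache[[key]] <- generateGene(generatorConfig(seed = seed))
  }
  cache[[key]]
}

cachedFixture <- function() {
  cache <- .projCache()
  if (is.null(cache$fixture)) {
    fx <- msextaFixture()
    fx$isoforms <- enumerateIsoforms(spliceGraph(fx$model))
    cache$fixture <- fx
  }
  cache$fixture
}

# ---- random sequence builders ---------------------------------------------

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(n, pevkPatch = TRUE, stops = FALSE) {
  ch <- sample(AA20_T, n, replace = TRUE)
  if (pevkPatch && n >= 20L) {
    w <- sample(8:min(40L, n - 2L), 1L)
    at <- sample.int(n - w, 1L)
    patch <- sample(c("P", "E", "V", "K", sample(AA20_T, 2L)), w,
                    replace = TRUE)
    ch[at:(at + w - 1L)] <- patch
  }
  if (stops && n >= 10L) {
    ch[sample.int(n, max(1L, n %/% 60L))] <- "*"
  }
  paste(ch, collapse = "")
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- brute-force maximal-bias-segment oracle ------------------------------
# Enumerates every window, keeps those with length >= minLength and
# fraction >= minFraction (score >= 0 under the +-(1-t)/-t scoring), then
# greedily selects disjoint windows by maximum score (ties: smallest start,
# then longest window) -- an exhaustive restatement of the scanner's
# maximal-scoring-segment semantics on an independent code path.

oracleScanSegments <- function(protein, minLength = 10L, minFraction = 0.6,
                               alphabet = c("P", "E", "V", "K")) {
  eps <- 1e-9
  ch <- strsplit(protein, "")[[1]]
  isA <- ch %in% alphabet
  stops <- c(0L, which(ch == "*"), length(ch) + 1L)
  winsList <- list()
  for (b in seq_len(length(stops) - 1L)) {
    from <- stops[b] + 1L; to <- stops[b + 1L] - 1L
    n <- to - from + 1L
    if (n < minLength) next
    cs <- cumsum(c(0L, as.integer(isA[from:to])))
    for (st in 1:(n - minLength + 1L)) {
      en <- (st + minLength - 1L):n
      sc <- (cs[en + 1L] - cs[st]) - minFraction * (en - st + 1L)
      q <- sc >= -eps
      if (any(q)) {
        winsList[[length(winsList) + 1L]] <-
          cbind(from + st - 1L, from + en[q] - 1L, sc[q])
      }
    }
  }
  wins <- if (length(winsList) > 0L) do.call(rbind, winsList) else NULL
  if (is.null(wins)) {
    return(data.frame(start_aa = integer(0), end_aa = integer(0)))
  }
  sel <- NULL
  repeat {
    free <- rep(TRUE, nrow(wins))
    if (!is.null(sel)) {
      for (r in seq_len(nrow(sel))) {
        free <- free & (wins[, 2L] < sel[r, 1L] | wins[, 1L] > sel[r, 2L])
      }
    }
    if (!any(free)) break
    cand <- wins[free, , drop = FALSE]
    mx <- max(cand[, 3L])
    cand <- cand[cand[, 3L] >= mx - eps, , drop = FALSE]
    cand <- cand[cand[, 1L] == min(cand[, 1L]), , drop = FALSE]
    pick <- cand[which.max(cand[, 2L]), , drop = FALSE]
    sel <- rbind(sel, pick)
  }
  sel <- sel[order(sel[, 1L]), , drop = FALSE]
  data.frame(start_aa = as.integer(sel[, 1L]), end_aa = as.integer(sel[, 2L]))
}

# ---- exhaustive global-alignment oracle -----------------------------------
# Memoized recursion over sequence suffixes maximizing the
# (score, matches, aligned-pairs) tuple lexicographically; identity is
# matches / (na + nb - pairs).  Independent of the package's iterative
# prefix DP.

oracleGlobalIdentity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  memo <- new.env(parent = emptyenv())
  better <- function(x, y) {
    if (is.null(y)) return(TRUE)
    if (x[1] != y[1]) return(x[1] > y[1])
    if (x[2] != y[2]) return(x[2] > y[2])
    x[3] > y[3]
  }
  rec <- function(i, j) {
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    if (i > na && j > nb) {
      res <- c(0, 0, 0)
    } else {
      best <- NULL
      if (i <= na && j <= nb) {
        sub <- rec(i + 1L, j + 1L)
        hit <- A[i] == B[j]
        cand <- sub + c(if (hit) match else mismatch, as.numeric(hit), 1)
        if (better(cand, best)) best <- cand
      }
      if (i <= na) {
        cand <- rec(i + 1L, j) + c(gap, 0, 0)
        if (better(cand, best)) best <- cand
      }
      if (j <= nb) {
        cand <- rec(i, j + 1L) + c(gap, 0, 0)
        if (better(cand, best)) best <- cand
      }
      res <- best
    }
    memo[[key]] <- res
    res
  }
  r <- rec(1L, 1L)
  list(score = r[1], matches = r[2],
       identity = r[2] / (na + nb - r[3]),
       aligned_length = na + nb - r[3])
}
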