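# Internal helpers shared across modules.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# numeric slop used when comparing a segment fraction against a threshold;
# keeps count/length ratios stable against binary rounding of the threshold
FRACTION_EPS <- 1e-9

.asChar <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x)) {
    stop("expected a character vector or a Biostrings sequence object")
  }
  toupper(x)
}

.checkDna <- function(x, what = "sequence", ambiguity = TRUE) {
  chars <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  ok <- if (ambiguity) IUPAC_DNA else c("A", "C", "G", "T")
  bad <- setdiff(chars, ok)
  if (length(bad) > 0L) {
    stop(sprintf("invalid DNA character(s) in %s: %s", what,
                 paste(bad, collapse = ", ")))
  }
  invisible(x)
}

.checkProtein <- function(x, what = "protein", allowStop = TRUE) {
  chars <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  ok <- c(AA20, "X", if (allowStop) "*")
  bad <- setdiff(chars, ok)
  if (length(bad) > 0L) {
    stop(sprintf("invalid amino-acid character(s) in %s: %s", what,
                 paste(bad, collapse = ", ")))
  }
  invisible(x)
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# uniform integer draw from lo:hi that is safe for degenerate ranges
# (sample(x, ...) on a scalar x would sample from 1:x)
.sampleRange <- function(lo, hi, n = 1L) {
  vec <- lo:hi
  vec[sample.int(length(vec), n, replace = TRUE)]
}

# round half away from zero to integer (base round() is banker's rounding)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# all start positions of fixed `pattern` in `subject` (character scalars)
.allMatches <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(integer(0))
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# longest L >= minLen with suffix(a, L) == prefix(b, L)
.suffixPrefixOverlap <- function(a, b, minLen) {
  na <- nchar(a); nb <- nchar(b)
  if (na < minLen || nb < minLen) return(0L)
  seedB <- substr(b, 1L, minLen)
  hits <- .allMatches(seedB, a)
  best <- 0L
  for (p in hits) {
    L <- na - p + 1L
    if (L < minLen || L > nb || L <= best) next
    if (substr(a, p, na) == substr(b, 1L, L)) best <- L
  }
  best
}
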