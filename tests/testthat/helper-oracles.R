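# Independent oracles and small shared fixtures.

# Maximum-score nested pairing, computed by a left-anchored memoised
# recursion (decide the fate of position i first), independent of the
# package's right-anchored dynamic program.
oracleFoldScore <- function(seq, minLoop = 3L) {
  pairScore <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1)
    0
  }
  ch <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  n <- length(ch)
  memo <- matrix(NA_real_, n, n)
  best <- function(i, j) {
    if (j - i < minLoop + 1L) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- best(i + 1L, j)   # i unpaired
    for (k in (i + minLoop + 1L):j) {
      s <- pairScore(ch[i], ch[k])
      if (s == 0) next
      inner <- if (k - 1L >= i + 1L) best(i + 1L, k - 1L) else 0
      outer <- if (k + 1L <= j) best(k + 1L, j) else 0
      v <- max(v, s + inner + outer)
    }
    memo[i, j] <<- v
    v
  }
  if (n < minLoop + 2L) 0 else best(1L, n)
}

# Exhaustive alignment scorer: every register, every <=1-bulge placement.
# Direct per-configuration scoring (one vectorised sum per configuration),
# structurally unlike the package's prefix/suffix decomposition.
oracleAlignments <- function(mir, tx, core = 2:13) {
  P <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  P["A", "T"] <- 0; P["T", "A"] <- 0; P["G", "C"] <- 0; P["C", "G"] <- 0
  P["G", "T"] <- 0.5; P["T", "G"] <- 0.5
  mi <- match(strsplit(mir, "")[[1]], c("A", "C", "G", "T"))
  ti <- match(strsplit(tx, "")[[1]], c("A", "C", "G", "T"))
  m <- length(mi); L <- length(ti)
  w <- ifelse(seq_len(m) %in% core, 2, 1)
  rows <- list()
  add <- function(start, end, s, bulge, b) {
    rows[[length(rows) + 1L]] <<- data.frame(
      targetStart = start, targetEnd = end, score = s,
      bulge = bulge, bulgePos = b, stringsAsFactors = FALSE)
  }
  i <- seq_len(m)
  if (L >= m) for (e in m:L) {
    s <- sum(w * P[cbind(mi, ti[e - i + 1])])
    add(e - m + 1L, e, s, "none", NA_integer_)
  }
  if (L >= m + 1) for (b in 2:m) for (e in (m + 1):L) {
    tpos <- ifelse(i < b, e - i + 1, e - i)
    s <- w[b] + sum(w * P[cbind(mi, ti[tpos])])
    add(e - m, e, s, "target", b)
  }
  if (L >= m - 1) for (b in 2:(m - 1)) for (e in (m - 1):L) {
    keep <- i != b
    tpos <- ifelse(i < b, e - i + 1, e - i + 2)
    s <- w[b] + sum(w[keep] * P[cbind(mi[keep], ti[tpos[keep]])])
    add(e - m + 2L, e, s, "mirna", b)
  }
  do.call(rbind, rows)
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# reverse complement for plain characters (mirrors the package helper)
rcSeq <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1)))
}

# one small reference bundle shared across tests (built once per run)
.sharedRef <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateReference(syntheticConfig(seed = 42L, nMirnas = 6L,
                                                  nTranscripts = 8L))
    cache
  }
})

table3Fixture <- function() {
  read.delim(system.file("extdata", "table3_de_profiles.tsv",
                         package = "degradomiR"),
             stringsAsFactors = FALSE)
}

table1Fixture <- function() {
  read.delim(system.file("extdata", "table1_read_distribution.tsv",
                         package = "degradomiR"),
             stringsAsFactors = FALSE)
}

table4Fixture <- function() {
  read.delim(system.file("extdata", "table4_novel_targets.tsv",
                         package = "degradomiR"),
             stringsAsFactors = FALSE)
}
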