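## Degradome (PARE) tag processing, target alignment scoring and
## category I-IV cleavage classification.

#' Extract degradome tags from raw reads
#'
#' The insert upstream of the first occurrence of the adaptor motif is the
#' degradome tag; reads lacking the motif (or with nothing upstream of it)
#' are dropped and counted. Distinct tags are collapsed with counts.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet].
#' @param adaptor Adaptor motif (default `"CAGCAG"`).
#' @return A list with `tags` (named integer vector, sequence -> count,
#'   sorted) and `dropped` (number of reads without a usable tag).
#' @export
processDegradomeReads <- function(reads, adaptor = "CAGCAG") {
  reads <- as.character(reads)
  pos <- as.integer(regexpr(adaptor, reads, fixed = TRUE))
  usable <- pos > 1L
  tags <- substr(reads[usable], 1L, pos[usable] - 1L)
  counts <- if (length(tags)) {
    tab <- table(tags)
    setNames(as.integer(tab), names(tab))
  } else setNames(integer(0), character(0))
  counts <- counts[order(names(counts), method = "radix")]
  list(tags = counts, dropped = sum(!usable))
}

#' Map degradome tags onto transcripts (T-plot profiles)
#'
#' Exact sense-strand placement of each tag; the profile records the
#' transcript position of the tag 5' end. A tag matching k transcripts
#' contributes count/k to each (fractional assignment); within a
#' transcript the leftmost occurrence is used.
#'
#' @param tags Named integer vector from [processDegradomeReads()].
#' @param transcriptome A [Biostrings::DNAStringSet].
#' @return A list with `profiles` (named list of
#'   [TranscriptProfile-class], transcripts with no tags omitted),
#'   `unmapped` (tag count not placed) and `totalMapped` (library-wide
#'   mapped tag count, the tpb denominator).
#' @export
mapTags <- function(tags, transcriptome) {
  txs <- as.character(transcriptome)
  abund <- lapply(txs, function(s) numeric(nchar(s)))
  unmapped <- 0
  for (i in seq_along(tags)) {
    tag <- names(tags)[i]
    cnt <- tags[[i]]
    pos <- vapply(txs, function(s)
      as.integer(regexpr(tag, s, fixed = TRUE)), integer(1))
    hit <- which(pos > 0L)
    if (!length(hit)) { unmapped <- unmapped + cnt; next }
    share <- cnt / length(hit)
    for (h in hit) abund[[h]][pos[h]] <- abund[[h]][pos[h]] + share
  }
  keep <- vapply(abund, function(a) sum(a) > 0, logical(1))
  profiles <- lapply(names(txs)[keep], function(id) {
    a <- abund[[id]]
    new("TranscriptProfile", transcriptId = id, abundance = a,
        totalTags = sum(a))
  })
  names(profiles) <- names(txs)[keep]
  list(profiles = profiles, unmapped = unmapped,
       totalMapped = sum(tags) - unmapped)
}

## penalty of miRNA base (row) against target base (col):
## 0 Watson-Crick, 0.5 G:U wobble, 1 mismatch
penaltyMatrix <- local({
  P <- matrix(1, 4, 4, dimnames = list(DNA <- c("A", "C", "G", "T"), DNA))
  P["A", "T"] <- 0; P["T", "A"] <- 0; P["G", "C"] <- 0; P["C", "G"] <- 0
  P["G", "T"] <- 0.5; P["T", "G"] <- 0.5
  P
})

encodeDNA <- function(x) {
  match(strsplit(x, "")[[1]], c("A", "C", "G", "T"))
}

#' Score miRNA:target alignments along a transcript
#'
#' Scans every register of the reverse-complement alignment of the miRNA
#' against the transcript, allowing at most one single-nucleotide bulge on
#' either strand. Penalties: mismatch or bulge 1, G:U wobble 0.5, doubled
#' within the core segment (miRNA positions 2-13 from the 5' end); lower
#' scores mean better complementarity. Alignments scoring above `maxScore`
#' are discarded; overlapping alignments are deduplicated keeping the
#' lowest score (leftmost on ties).
#'
#' The expected cleavage site is the transcript position paired with
#' miRNA position 10 (slicing occurs opposite positions 10-11); a bulge
#' that disrupts the 10-11 register leaves the site undefined and the
#' alignment is flagged.
#'
#' @param mirna miRNA sequence, 5' to 3' (15-26 nt).
#' @param transcript Transcript sequence, 5' to 3'.
#' @param maxScore Maximum penalty retained (default 4.5).
#' @param core miRNA positions whose penalties are doubled.
#' @return A data.frame with columns `targetStart`, `targetEnd`, `score`,
#'   `bulge` (`"none"`, `"target"`, `"mirna"`), `bulgePos`,
#'   `expectedSite`, `siteDefined`.
#' @export
alignMirnaTarget <- function(mirna, transcript, maxScore = 4.5,
                             core = 2:13) {
  mirna <- canonicalizeDNA(mirna)
  transcript <- canonicalizeDNA(transcript)
  m <- nchar(mirna)
  if (m < 15L || m > 26L) stop("miRNA must be 15-26 nt")
  L <- nchar(transcript)
  if (L < m) return(emptyAlignments())
  mi <- encodeDNA(mirna)
  ti <- encodeDNA(transcript)
  w <- ifelse(seq_len(m) %in% core, 2, 1)
  inCore <- function(b) b %in% core

  res <- list()
  addHits <- function(e, score, bulge, bulgePos, site, defined) {
    keep <- which(score <= maxScore)
    if (!length(keep)) return()
    spanLen <- m + (bulge == "target") - (bulge == "mirna")
    res[[length(res) + 1L]] <<- data.frame(
      targetStart = e[keep] - spanLen + 1L, targetEnd = e[keep],
      score = score[keep], bulge = bulge,
      bulgePos = if (is.na(bulgePos)) NA_integer_ else bulgePos,
      expectedSite = site[keep], siteDefined = defined,
      stringsAsFactors = FALSE
    )
  }

  ## no bulge: miRNA position i pairs target position e - i + 1
  e <- m:L
  sc <- numeric(length(e))
  for (i in seq_len(m))
    sc <- sc + w[i] * penaltyMatrix[cbind(mi[i], ti[e - i + 1L])]
  addHits(e, sc, "none", NA_integer_, e - 9L, TRUE)

  ## per-position penalty tables for the bulged variants
  ## A[i, ] : miRNA i vs target e - i + 1  (unshifted register)
  ## B[i, ] : miRNA i vs target e - i      (target bulge downstream shift)
  ## C[i, ] : miRNA i vs target e - i + 2  (miRNA bulge shift)
  eAll <- seq_len(L)
  A <- matrix(NA_real_, m, L); B <- A; C <- A
  for (i in seq_len(m)) {
    ok <- eAll - i + 1L >= 1L & eAll - i + 1L <= L
    A[i, ok] <- w[i] * penaltyMatrix[cbind(mi[i], ti[eAll[ok] - i + 1L])]
    ok <- eAll - i >= 1L & eAll - i <= L
    B[i, ok] <- w[i] * penaltyMatrix[cbind(mi[i], ti[eAll[ok] - i])]
    ok <- eAll - i + 2L >= 1L & eAll - i + 2L <= L
    C[i, ok] <- w[i] * penaltyMatrix[cbind(mi[i], ti[eAll[ok] - i + 2L])]
  }

  ## target-side bulge between miRNA positions b-1 and b (b in 2..m):
  ## miRNA i < b pairs target e - i + 1; i >= b pairs target e - i
  for (b in 2:m) {
    if (m + 1L > L) break
    e <- (m + 1L):L
    pen <- if (inCore(b)) 2 else 1
    scPre <- if (b > 2L) colSums(A[seq_len(b - 1L), e, drop = FALSE])
             else A[1L, e]
    scSuf <- colSums(B[b:m, e, drop = FALSE])
    sc <- scPre + scSuf + pen
    defined <- b != 11L   # bulge between positions 10 and 11 -> undefined
    site <- if (b <= 10L) e - 10L else e - 9L
    addHits(e, sc, "target", b, if (defined) site else NA_integer_, defined)
  }

  ## miRNA-side bulge: miRNA position b unpaired (b in 2..(m-1)):
  ## miRNA i < b pairs target e - i + 1; i > b pairs target e - i + 2
  for (b in 2:(m - 1L)) {
    e <- (m - 1L):L
    pen <- if (inCore(b)) 2 else 1
    scPre <- if (b > 2L) colSums(A[seq_len(b - 1L), e, drop = FALSE])
             else A[1L, e]
    scSuf <- colSums(C[(b + 1L):m, e, drop = FALSE])
    sc <- scPre + scSuf + pen
    defined <- !(b %in% c(10L, 11L))
    site <- if (b < 10L) e - 8L else e - 9L
    addHits(e, sc, "mirna", b, if (defined) site else NA_integer_, defined)
  }

  if (!length(res)) return(emptyAlignments())
  hits <- do.call(rbind, res)
  dedupOverlaps(hits)
}

emptyAlignments <- function() {
  data.frame(targetStart = integer(), targetEnd = integer(),
             score = numeric(), bulge = character(), bulgePos = integer(),
             expectedSite = integer(), siteDefined = logical(),
             stringsAsFactors = FALSE)
}

## keep the lowest-scoring alignment in each group of mutually
## overlapping target spans; ties go to the leftmost
dedupOverlaps <- function(hits) {
  hits <- hits[order(hits$score, hits$targetStart), , drop = FALSE]
  kept <- hits[0, ]
  for (r in seq_len(nrow(hits))) {
    h <- hits[r, ]
    overlaps <- nrow(kept) > 0 &&
      any(h$targetStart <= kept$targetEnd & h$targetEnd >= kept$targetStart)
    if (!overlaps) kept <- rbind(kept, h)
  }
  kept <- kept[order(kept$targetStart), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Expected cleavage site of an alignment
#'
#' The transcript position paired with miRNA position 10; `NA` when a
#' bulge disrupts the 10-11 register.
#'
#' @param alignment One row of the [alignMirnaTarget()] result.
#' @return Integer position or `NA`.
#' @export
expectedCleavageSite <- function(alignment) {
  if (!alignment$siteDefined) return(NA_integer_)
  as.integer(alignment$expectedSite)
}

#' Classify a cleavage site into category I-IV
#'
#' Maximum and median tag abundance are computed over occupied positions
#' only (positions carrying at least one tag). Category I: the site
#' abundance equals the transcript maximum and the maximum is unique;
#' II: equals a shared maximum; III: below the maximum but above the
#' median; IV: at or below the median (a site with zero abundance is IV).
#'
#' @param profile A [TranscriptProfile-class] with at least one tag.
#' @param site 1-based transcript position.
#' @return `"I"`, `"II"`, `"III"` or `"IV"`.
#' @export
classifyCategory <- function(profile, site) {
  a <- profileAbundance(profile)
  if (sum(a) <= 0) stop("profile has no tags")
  if (site < 1L || site > length(a)) stop("site outside transcript")
  occ <- a[a > 0]
  x <- a[site]
  if (x <= 0) return("IV")
  mx <- max(occ)
  med <- median(occ)
  eps <- 1e-9
  if (x >= mx - eps) {
    if (sum(occ >= mx - eps) == 1L) "I" else "II"
  } else if (x > med + eps) "III" else "IV"
}

#' Degradome score thresholds per category
#'
#' @return Named numeric vector of the per-category maximum alignment
#'   score: I 4.5, II 4.0, III 3.5, IV 3.0.
#' @export
categoryThresholds <- function() {
  c(I = 4.5, II = 4.0, III = 3.5, IV = 3.0)
}

#' Accept or reject a cleavage call by the per-category score threshold
#'
#' @param score Alignment score(s).
#' @param category Category label(s) (`"I"`..`"IV"`).
#' @param thresholds Named thresholds (default [categoryThresholds()]).
#' @return Logical: `score <= thresholds[category]`.
#' @export
applyScoreThresholds <- function(score, category,
                                 thresholds = categoryThresholds()) {
  score <= unname(thresholds[category])
}

#' Share and tpb of degradome tags at a site
#'
#' @param profile A [TranscriptProfile-class].
#' @param site 1-based transcript position.
#' @param libraryTotal Library-wide mapped tag count (tpb denominator).
#' @return A list with `percent` (100 * site tags / transcript tags) and
#'   `tpb` (site tags * 1e9 / `libraryTotal`).
#' @export
percentAtSite <- function(profile, site, libraryTotal) {
  tot <- totalTags(profile)
  if (tot <= 0) stop("empty profile")
  x <- profileAbundance(profile)[site]
  list(percent = 100 * x / tot, tpb = x * 1e9 / libraryTotal)
}

#' Identify sliced miRNA targets in one degradome library
#'
#' For every miRNA x transcript pair, finds alignments within the score
#' cap, maps the expected cleavage site, reads the observed peak within
#' `siteTolerance` nt of it, classifies the site into category I-IV and
#' applies the per-category score threshold.
#'
#' @param mirnas A data.frame with columns `name` and `sequence`.
#' @param mapping Output of [mapTags()] for the library.
#' @param transcriptome A [Biostrings::DNAStringSet].
#' @param maxScore Alignment score cap (default 4.5).
#' @param siteTolerance The observed peak may sit within this many nt of
#'   the expected site (default 1).
#' @param thresholds Per-category score thresholds.
#' @return A data.frame with one row per (miRNA, transcript, alignment):
#'   `mirna`, `transcript`, `score`, `cleavageSite` (tag 5'-end position
#'   used, within the tolerance window), `expectedSite`, `category`,
#'   `percentAtSite`, `tpb`, `accepted`.
#' @export
identifyTargets <- function(mirnas, mapping, transcriptome,
                            maxScore = 4.5, siteTolerance = 1L,
                            thresholds = categoryThresholds()) {
  txs <- as.character(transcriptome)
  rows <- list()
  for (r in seq_len(nrow(mirnas))) {
    for (txId in names(mapping$profiles)) {
      profile <- mapping$profiles[[txId]]
      aln <- alignMirnaTarget(mirnas$sequence[r], txs[[txId]],
                              maxScore = maxScore)
      for (a in seq_len(nrow(aln))) {
        if (!aln$siteDefined[a]) next
        site <- aln$expectedSite[a]
        abund <- profileAbundance(profile)
        lo <- max(1L, site - siteTolerance)
        hi <- min(length(abund), site + siteTolerance)
        if (lo > length(abund)) next
        obs <- lo:hi
        used <- obs[which.max(abund[obs])]
        cat <- classifyCategory(profile, used)
        ps <- percentAtSite(profile, used, mapping$totalMapped)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mirnas$name[r], transcript = txId,
          score = aln$score[a], cleavageSite = used,
          expectedSite = site, category = cat,
          percentAtSite = ps$percent, tpb = ps$tpb,
          accepted = applyScoreThresholds(aln$score[a], cat, thresholds),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows))
    return(data.frame(mirna = character(), transcript = character(),
                      score = numeric(), cleavageSite = integer(),
                      expectedSite = integer(), category = character(),
                      percentAtSite = numeric(), tpb = numeric(),
                      accepted = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Plot a transcript T-plot
#'
#' Degradome tag abundance against transcript position, with the expected
#' cleavage site marked.
#'
#' @param profile A [TranscriptProfile-class].
#' @param site Optional cleavage site to mark.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the profile.
#' @importFrom graphics abline segments plot
#' @export
plotTranscriptProfile <- function(profile, site = NULL, ...) {
  a <- profileAbundance(profile)
  plot(seq_along(a), a, type = "h", xlab = "Transcript position (nt)",
       ylab = "Degradome tags", main = transcriptId(profile), ...)
  if (!is.null(site)) {
    segments(site, 0, site, a[site], col = "red", lwd = 2)
    abline(v = site, col = "red", lty = 3)
  }
  invisible(profile)
}
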