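## Known-miRNA assignment, precursor evaluation and star-strand detection.

hammingDistance <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

## minimum Hamming distance of `query` over all equal-length windows of
## `subject`; Inf when subject is shorter than query
slideHamming <- function(query, subject) {
  m <- nchar(query)
  L <- nchar(subject)
  if (L < m) return(Inf)
  q <- utf8ToInt(query)
  s <- utf8ToInt(subject)
  best <- Inf
  for (off in 0:(L - m)) {
    d <- sum(q != s[(off + 1):(off + m)])
    if (d < best) best <- d
    if (best == 0) break
  }
  best
}

#' Assign sequences to known miRNAs by mismatch-tolerant matching
#'
#' Each query is compared ungapped against every known mature sequence at
#' equal length, and slid along every known precursor, counting
#' substitutions. Queries within `maxMismatch` substitutions of a
#' reference are assigned to it; ties are broken by fewest mismatches,
#' then lexicographic miRNA name. Unassigned sequences are the input to
#' novel-miRNA discovery.
#'
#' @param sequences Character vector of unique clean sequences.
#' @param reference A `data.frame` with columns `name`, `mature`,
#'   `precursor` (as in [knownMiRNAs()]).
#' @param maxMismatch Maximum substitutions allowed (default 2).
#' @return A data.frame with columns `sequence`, `name`, `mismatches` for
#'   assigned queries only.
#' @export
matchKnown <- function(sequences, reference, maxMismatch = 2L) {
  if (!nrow(reference)) stop("empty known-miRNA reference")
  sequences <- canonicalizeDNA(sequences)
  ref <- reference[order(reference$name, method = "radix"), , drop = FALSE]
  out <- lapply(sequences, function(q) {
    best <- Inf; bestName <- NA_character_
    for (r in seq_len(nrow(ref))) {
      d <- Inf
      if (nchar(q) == nchar(ref$mature[r]))
        d <- hammingDistance(q, canonicalizeDNA(ref$mature[r]))
      d <- min(d, slideHamming(q, canonicalizeDNA(ref$precursor[r])))
      if (d < best) { best <- d; bestName <- ref$name[r] }
    }
    if (best <= maxMismatch)
      data.frame(sequence = q, name = bestName, mismatches = as.integer(best),
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sequence = character(), name = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  out
}

#' Locate a sequence in the genome (both strands)
#'
#' @param genome A [Biostrings::DNAStringSet] of chromosomes.
#' @param sequence Query sequence.
#' @return A data.frame of hits: `chrom`, `start`, `end`, `strand`
#'   (plus-strand coordinates; a minus-strand hit is where the reverse
#'   complement of the query matches).
#' @export
locateInGenome <- function(genome, sequence) {
  sequence <- canonicalizeDNA(sequence)
  rc <- revComp(sequence)
  hits <- list()
  for (i in seq_along(genome)) {
    chromName <- names(genome)[i]
    chrom <- as.character(genome[[i]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sequence else rc
      m <- gregexpr(pat, chrom, fixed = TRUE)[[1]]
      if (m[1] > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chromName, start = as.integer(m),
          end = as.integer(m) + nchar(pat) - 1L, strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Extract candidate precursor windows around a genomic hit
#'
#' Returns two windows around the hit locus: an upstream-biased window
#' `[start - flank, end + pad]` and a downstream-biased window
#' `[start - pad, end + flank]`, both clamped to the chromosome. Together
#' they cover `hit +/- flank`, so whichever side of the hit the rest of
#' the hairpin lies on, one window contains the full precursor. For a
#' minus-strand hit the reverse complement of each window is returned, so
#' the mature sequence always reads sense in the window.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param hit One-row data.frame (or list) with `chrom`, `start`, `end`,
#'   `strand`.
#' @param flank Bases of context on the biased side (default 120).
#' @param pad Bases of context on the short side (default 10).
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `bias`, `sequence`.
#' @export
extractPrecursor <- function(genome, hit, flank = 120L, pad = 10L) {
  if (!hit$chrom %in% names(genome))
    stop("hit chromosome '", hit$chrom, "' not found in genome")
  chrom <- as.character(genome[[hit$chrom]])
  L <- nchar(chrom)
  wins <- data.frame(
    bias = c("upstream", "downstream"),
    start = pmax(1L, c(hit$start - flank, hit$start - pad)),
    end = pmin(L, c(hit$end + pad, hit$end + flank)),
    stringsAsFactors = FALSE
  )
  wins$chrom <- hit$chrom
  wins$strand <- hit$strand
  wins$sequence <- substr(rep(chrom, 2L), wins$start, wins$end)
  if (hit$strand == "-") wins$sequence <- revComp(wins$sequence)
  wins[, c("chrom", "start", "end", "strand", "bias", "sequence")]
}

#' Fold a precursor candidate and compute its descriptors
#'
#' Folds the sequence with [foldSequence()], computes GC% and MFEI, and
#' packages everything as a [PrecursorCandidate-class].
#'
#' @param sequence Precursor sequence.
#' @param matureSpan Integer (start, end) of the mature on the precursor.
#' @param starSpan Optional integer (start, end) of the star strand.
#' @param folder Folding function with the [foldSequence()] contract.
#' @return A [PrecursorCandidate-class].
#' @export
buildPrecursorCandidate <- function(sequence, matureSpan, starSpan = NULL,
                                    folder = foldSequence) {
  sequence <- canonicalizeDNA(sequence)
  fold <- folder(sequence)
  gc <- gcPercent(sequence)
  mfei <- if (gc > 0) computeMFEI(fold$dG, nchar(sequence), gc) else 0
  new("PrecursorCandidate",
      sequence = sequence, structure = fold$structure,
      dG = as.numeric(fold$dG), gcPercent = gc, mfei = mfei,
      matureSpan = as.integer(matureSpan),
      starSpan = if (is.null(starSpan)) NULL else as.integer(starSpan))
}

#' Default hairpin acceptance criteria
#'
#' @param minMaturePairedFraction Minimum fraction of mature bases paired.
#' @param maxLoopsInDuplexRegion Maximum terminal loops allowed in the
#'   region spanning mature and star.
#' @param minMfei Minimum MFEI (default 0.5, the low end observed for
#'   accepted plant pre-miRNA hairpins).
#' @return Named list of criteria.
#' @export
hairpinCriteria <- function(minMaturePairedFraction = 0.75,
                            maxLoopsInDuplexRegion = 1L,
                            minMfei = 0.5) {
  list(minMaturePairedFraction = minMaturePairedFraction,
       maxLoopsInDuplexRegion = maxLoopsInDuplexRegion,
       minMfei = minMfei)
}

#' Evaluate a precursor candidate against hairpin criteria
#'
#' A candidate passes when (i) the mature lies entirely on one arm (it
#' must not straddle the terminal loop), (ii) at least
#' `minMaturePairedFraction` of its bases are paired, (iii) the region
#' spanning mature and star contains at most `maxLoopsInDuplexRegion`
#' terminal loops, and (iv) MFEI >= `minMfei`.
#'
#' @param candidate A [PrecursorCandidate-class].
#' @param criteria A list from [hairpinCriteria()].
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   failed checks: `"spans loop"`, `"mature pairing"`, `"multiple loops"`,
#'   `"mfei"`).
#' @export
evaluateHairpin <- function(candidate, criteria = hairpinCriteria()) {
  span <- candidate@matureSpan
  n <- nchar(candidate@sequence)
  if (span[1] < 1 || span[2] > n) stop("matureSpan outside precursor")
  db <- strsplit(candidate@structure, "")[[1]]
  matureDb <- db[span[1]:span[2]]
  reasons <- character(0)
  # the mature must not straddle the terminal loop: no complete hairpin
  # loop ("(...)" innermost pair) may lie inside the mature span
  if (gregexpr("\\(\\.*\\)", paste(matureDb, collapse = ""))[[1]][1] > 0)
    reasons <- c(reasons, "spans loop")
  pairedFrac <- mean(matureDb != ".")
  if (pairedFrac < criteria$minMaturePairedFraction)
    reasons <- c(reasons, "mature pairing")
  partner <- pairTable(candidate@structure)
  region <- if (!is.null(candidate@starSpan)) {
    range(c(span, candidate@starSpan))
  } else {
    # the star arm is where the bulk of the mature's partners lie; stray
    # partners rerouted into flanking context are excluded by keeping the
    # largest positional cluster, so the mature-star region is not
    # inflated by context structure
    partners <- sort(partner[span[1]:span[2]])
    partners <- partners[!is.na(partners)]
    gaps <- which(diff(partners) > 8)
    bounds <- c(0, gaps, length(partners))
    sizes <- diff(bounds)
    pick <- which.max(sizes)
    cluster <- partners[(bounds[pick] + 1):bounds[pick + 1]]
    range(c(span, cluster))
  }
  sub <- paste(db[region[1]:region[2]], collapse = "")
  m <- gregexpr("\\(\\.*\\)", sub)[[1]]
  nLoops <- if (m[1] < 0) 0L else length(m)
  if (nLoops > criteria$maxLoopsInDuplexRegion)
    reasons <- c(reasons, "multiple loops")
  if (candidate@mfei < criteria$minMfei)
    reasons <- c(reasons, "mfei")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

## structure-predicted star span: each strand's 3' end overhangs the
## partner's paired region by 2 nt (Dicer geometry)
predictedStarSpan <- function(structure, matureSpan) {
  partner <- pairTable(structure)
  idx <- matureSpan[1]:matureSpan[2]
  # partner of (matureEnd - 2): walk inward until a paired base is found
  aft <- rev(idx[idx <= matureSpan[2] - 2L])
  starStart <- NA_integer_
  for (i in aft) if (!is.na(partner[i])) { starStart <- partner[i]; break }
  starEnd <- NA_integer_
  for (i in idx) if (!is.na(partner[i])) { starEnd <- partner[i] + 2L; break }
  if (is.na(starStart) || is.na(starEnd)) return(NULL)
  c(starStart, starEnd)
}

#' Detect star (p3/p5) strand reads for a catalogued miRNA
#'
#' Predicts the star span from the folded structure (the strand pairing
#' the mature, with the 2-nt 3' overhang offset) and aggregates counts of
#' unique sequences that place on the opposite arm within `tolerance` nt
#' of the predicted star start. The star is named `<name>-p5` or
#' `<name>-p3` by the arm it comes from. When star reads outnumber mature
#' reads the result is flagged, since such candidates may themselves be
#' the true mature strand.
#'
#' @param candidate A [PrecursorCandidate-class].
#' @param uniqueCountsVec Named integer vector (sequence -> count).
#' @param name miRNA name used for labelling.
#' @param tolerance Placement tolerance around the predicted star start.
#' @return A list with `starName`, `starSpan`, `starCount`, `matureCount`
#'   and `starExceedsMature`, or `NULL` when no star span is predictable.
#' @export
detectStarStrand <- function(candidate, uniqueCountsVec, name = "mir",
                             tolerance = 4L) {
  span <- candidate@matureSpan
  starSpan <- predictedStarSpan(candidate@structure, span)
  if (is.null(starSpan)) return(NULL)
  seq <- candidate@sequence
  mature <- substr(seq, span[1], span[2])
  matureCount <- sum(uniqueCountsVec[names(uniqueCountsVec) == mature])
  arm <- if (starSpan[1] < span[1]) "p5" else "p3"
  starCount <- 0
  seqs <- names(uniqueCountsVec)
  for (i in seq_along(seqs)) {
    q <- seqs[i]
    if (q == mature) next
    m <- regexpr(q, seq, fixed = TRUE)
    if (m < 0) next
    qs <- as.integer(m)
    qe <- qs + nchar(q) - 1L
    # must sit on the opposite arm, near the predicted star
    onOppositeArm <- (arm == "p5" && qe < span[1]) ||
                     (arm == "p3" && qs > span[2])
    if (onOppositeArm && abs(qs - starSpan[1]) <= tolerance)
      starCount <- starCount + uniqueCountsVec[i]
  }
  list(starName = paste0(name, "-", arm), starSpan = starSpan,
       starCount = as.numeric(starCount),
       matureCount = as.numeric(matureCount),
       starExceedsMature = starCount > matureCount)
}

#' Check a miRNA/miRNA* duplex for 2-nt 3' overhangs
#'
#' Under the folded structure, a canonical Dicer duplex has each strand's
#' 3' end extending exactly 2 nt beyond the base paired with the partner
#' strand's 5' end. With spans X = (x1, x2) and Y = (y1, y2) the check is
#' `partner(y1) == x2 - 2` and `partner(x1) == y2 - 2`, each within
#' `tolerance`.
#'
#' @param structure Dot-bracket string of the precursor.
#' @param matureSpan,starSpan Integer (start, end) spans on the precursor.
#' @param tolerance Allowed deviation from a 2-nt overhang (default 0).
#' @return A list with `mature`, `star` span echoes and `passesOverhang`.
#' @export
checkDuplexOverhang <- function(structure, matureSpan, starSpan,
                                tolerance = 0L) {
  matureSpan <- as.integer(matureSpan)
  starSpan <- as.integer(starSpan)
  if (max(matureSpan[1], starSpan[1]) <= min(matureSpan[2], starSpan[2]))
    stop("mature and star spans overlap")
  partner <- pairTable(structure)
  ok <- function(p, want) !is.na(p) && abs(p - want) <= tolerance
  passes <- ok(partner[starSpan[1]], matureSpan[2] - 2L) &&
            ok(partner[matureSpan[1]], starSpan[2] - 2L)
  list(mature = matureSpan, star = starSpan, passesOverhang = passes)
}

#' Discover novel miRNA candidates from unassigned genome-mapped sequences
#'
#' For every candidate sequence (genome-mapped, not assigned to a known
#' miRNA), locates its loci, extracts upstream- and downstream-biased
#' precursor windows, folds each and keeps the candidate when at least one
#' window passes the hairpin criteria. Candidates mapping to multiple loci
#' are reported with their locus count, not discarded.
#'
#' @param sequences Character vector of candidate mature sequences.
#' @param bundle A [ReferenceBundle-class].
#' @param criteria Hairpin criteria from [hairpinCriteria()].
#' @param flank Precursor window flank (nt).
#' @return A data.frame with one row per accepted candidate: `sequence`,
#'   `length`, `chrom`, `strand`, `arm`, `dG`, `gcPercent`, `mfei`,
#'   `locusCount`, `precursor`, `structure`, `matureStart`, `matureEnd`.
#' @export
discoverNovelMirnas <- function(sequences, bundle,
                                criteria = hairpinCriteria(),
                                flank = 120L) {
  genome <- refGenome(bundle)
  rows <- list()
  for (q in sequences) {
    hits <- locateInGenome(genome, q)
    if (!nrow(hits)) next
    hit <- hits[1L, ]
    wins <- extractPrecursor(genome, hit, flank = flank)
    best <- NULL
    for (w in seq_len(nrow(wins))) {
      wseq <- wins$sequence[w]
      mpos <- regexpr(q, wseq, fixed = TRUE)
      if (mpos < 0) next
      span <- c(as.integer(mpos), as.integer(mpos) + nchar(q) - 1L)
      cand <- buildPrecursorCandidate(wseq, span)
      ev <- evaluateHairpin(cand, criteria)
      if (ev$pass && (is.null(best) || cand@mfei > best$cand@mfei))
        best <- list(cand = cand, win = wins[w, ])
    }
    if (is.null(best)) next
    cand <- best$cand
    db <- strsplit(cand@structure, "")[[1]]
    matureDb <- db[cand@matureSpan[1]:cand@matureSpan[2]]
    arm <- if (sum(matureDb == "(") >= sum(matureDb == ")")) "5p" else "3p"
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = q, length = nchar(q), chrom = best$win$chrom,
      strand = best$win$strand, arm = arm, dG = cand@dG,
      gcPercent = cand@gcPercent, mfei = cand@mfei,
      locusCount = nrow(hits), precursor = cand@sequence,
      structure = cand@structure,
      matureStart = cand@matureSpan[1], matureEnd = cand@matureSpan[2],
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows))
    return(data.frame(sequence = character(), length = integer(),
                      chrom = character(), strand = character(),
                      arm = character(), dG = numeric(),
                      gcPercent = numeric(), mfei = numeric(),
                      locusCount = integer(), precursor = character(),
                      structure = character(), matureStart = integer(),
                      matureEnd = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$name <- sprintf("PC-%d-%s", seq_len(nrow(out)), out$arm)
  out[, c("name", setdiff(names(out), "name"))]
}
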