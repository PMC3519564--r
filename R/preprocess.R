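## Small-RNA read cleaning and annotation partitioning.

#' Trim the 3' adapter from raw small-RNA reads
#'
#' Cuts each read at the leftmost occurrence of the adapter prefix. The
#' match seed is the first `minMatch` bases of the adapter (the full
#' adapter when it is shorter), matched exactly. Inserts shorter than
#' `minLen` after the cut are rejected; note that an insert of exactly
#' `minLen` nt is retained (the removal rule is "fewer than `minLen`
#' bases", so the boundary length is kept).
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of raw reads.
#' @param adapter 3' adapter sequence (>= 6 nt).
#' @param minLen Minimum insert length retained after trimming.
#' @param minMatch Minimum adapter prefix length that must match.
#' @return A data.frame with columns `insert` (trimmed sequence, `NA` when
#'   rejected) and `status` (`"keep"`, `"adapter_not_found"`,
#'   `"too_short_after_trim"`).
#' @export
trimAdapter <- function(reads, adapter, minLen = 15L, minMatch = 8L) {
  reads <- as.character(reads)
  if (any(!nzchar(reads))) stop("empty read")
  if (nchar(adapter) < 6L) stop("adapter must be at least 6 nt")
  seedLen <- min(minMatch, nchar(adapter))
  seed <- substr(adapter, 1L, seedLen)
  pos <- as.integer(regexpr(seed, reads, fixed = TRUE))
  insert <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), NA_character_)
  status <- ifelse(pos < 0L, "adapter_not_found",
            ifelse(nchar(insert) < minLen, "too_short_after_trim", "keep"))
  insert[status != "keep"] <- NA_character_
  data.frame(insert = insert, status = status, stringsAsFactors = FALSE)
}

#' Flag junk sequences
#'
#' A trimmed insert is junk when more than `maxNFraction` of its bases are
#' N, when a single base makes up more than `maxHomopolymerFraction` of
#' the sequence, or when tandem repeats of one dinucleotide cover more
#' than `maxDinucleotideFraction` of it.
#'
#' @param sequences Character vector of trimmed inserts.
#' @param maxNFraction,maxHomopolymerFraction,maxDinucleotideFraction
#'   Junk thresholds (fractions of sequence length).
#' @return Logical vector, `TRUE` = keep, `FALSE` = junk.
#' @export
filterJunk <- function(sequences, maxNFraction = 0.10,
                       maxHomopolymerFraction = 0.8,
                       maxDinucleotideFraction = 0.9) {
  dimers <- outer(DNA_BASES, DNA_BASES, paste0)
  dimers <- dimers[as.vector(!diag(4) > 0)]
  vapply(sequences, function(s) {
    n <- nchar(s)
    if (n == 0L) return(FALSE)
    ch <- strsplit(s, "")[[1]]
    if (sum(ch == "N") / n > maxNFraction) return(FALSE)
    if (max(table(ch)) / n > maxHomopolymerFraction) return(FALSE)
    dinucCover <- max(vapply(dimers, function(d) {
      m <- gregexpr(sprintf("(%s){2,}", d), s)[[1]]
      if (m[1] < 0) 0L else sum(attr(m, "match.length"))
    }, integer(1)))
    if (dinucCover / n > maxDinucleotideFraction) return(FALSE)
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Collapse sequences to unique entries with redundant counts
#'
#' @param sequences Character vector of retained inserts (may repeat).
#' @param rejected Named integer vector of rejection counters to carry
#'   along (`adapter_not_found`, `too_short_after_trim`, `junk`).
#' @return A [CleanReadSet-class]; unique keys are sorted lexicographically
#'   so outputs are deterministic.
#' @export
collapseUnique <- function(sequences,
                           rejected = c(adapter_not_found = 0L,
                                        too_short_after_trim = 0L,
                                        junk = 0L)) {
  counts <- if (length(sequences)) {
    tab <- table(sequences)
    setNames(as.integer(tab), names(tab))
  } else {
    setNames(integer(0), character(0))
  }
  counts <- counts[order(names(counts), method = "radix")]
  new("CleanReadSet", uniqueCounts = counts,
      rejected = as.integer(rejected) |> setNames(names(rejected)))
}

#' Clean a raw small-RNA library end to end
#'
#' Adapter trimming, junk filtering and collapsing in one call, with full
#' read accounting: every input read ends up either in the unique-count
#' map or in exactly one rejection counter.
#'
#' @inheritParams trimAdapter
#' @param junkParams List of arguments passed to [filterJunk()].
#' @return A [CleanReadSet-class].
#' @export
cleanReads <- function(reads, adapter, minLen = 15L, minMatch = 8L,
                       junkParams = list()) {
  tr <- trimAdapter(reads, adapter, minLen = minLen, minMatch = minMatch)
  kept <- tr$insert[tr$status == "keep"]
  good <- if (length(kept)) do.call(filterJunk, c(list(kept), junkParams))
          else logical(0)
  rejected <- c(
    adapter_not_found = sum(tr$status == "adapter_not_found"),
    too_short_after_trim = sum(tr$status == "too_short_after_trim"),
    junk = sum(!good)
  )
  collapseUnique(kept[good], rejected = rejected)
}

matchesAnywhere <- function(queries, refSeqs) {
  if (!length(refSeqs)) return(rep(FALSE, length(queries)))
  hay <- paste(as.character(refSeqs), collapse = "\n")
  rc <- revComp(queries)
  vapply(seq_along(queries), function(i) {
    grepl(queries[i], hay, fixed = TRUE) || grepl(rc[i], hay, fixed = TRUE)
  }, logical(1))
}

#' Partition unique clean sequences into annotation classes
#'
#' Assigns every unique sequence to exactly one class with priority
#' mRNA > rfam > repeats > miRNA_candidate > no_hit. `mRNA`, `rfam` and
#' `repeats` are exact-substring matches (either strand) against the
#' transcriptome, ncRNA decoys and repeat decoys respectively;
#' `miRNA_candidate` collects genome-mapped sequences matching none of
#' those; `no_hit` everything else. Classes are pairwise disjoint and
#' exhaustive.
#'
#' @param cleanSet A [CleanReadSet-class].
#' @param bundle A [ReferenceBundle-class].
#' @return A list with `classes` (named list of sequence vectors for
#'   `mRNA`, `rfam`, `repeats`, `miRNA_candidate`, `no_hit`) and `counts`
#'   (data.frame of unique and redundant counts per class).
#' @export
partitionByAnnotation <- function(cleanSet, bundle) {
  seqs <- names(uniqueCounts(cleanSet))
  for (cls in c("transcriptome", "ncrnaDecoys", "repeatDecoys")) {
    if (!length(slot(bundle, cls)))
      warning("reference class '", cls, "' is empty; its partition class ",
              "will be empty")
  }
  inMrna <- matchesAnywhere(seqs, refTranscriptome(bundle))
  inRfam <- matchesAnywhere(seqs, ncrnaDecoys(bundle))
  inRepeat <- matchesAnywhere(seqs, repeatDecoys(bundle))
  inGenome <- matchesAnywhere(seqs, refGenome(bundle))
  cls <- ifelse(inMrna, "mRNA",
         ifelse(inRfam, "rfam",
         ifelse(inRepeat, "repeats",
         ifelse(inGenome, "miRNA_candidate", "no_hit"))))
  classes <- lapply(
    c(mRNA = "mRNA", rfam = "rfam", repeats = "repeats",
      miRNA_candidate = "miRNA_candidate", no_hit = "no_hit"),
    function(k) seqs[cls == k]
  )
  counts <- data.frame(
    class = names(classes),
    unique = vapply(classes, length, integer(1)),
    redundant = vapply(classes, function(s)
      sum(uniqueCounts(cleanSet)[s]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(classes = classes, counts = counts)
}

#' Read-length histogram of a clean read set
#'
#' @param cleanSet A [CleanReadSet-class].
#' @param mode `"unique"` counts each distinct sequence once;
#'   `"redundant"` weights by its read count.
#' @return A data.frame with columns `length` and `count`.
#' @export
lengthDistribution <- function(cleanSet, mode = c("unique", "redundant")) {
  mode <- match.arg(mode)
  counts <- uniqueCounts(cleanSet)
  if (!length(counts))
    return(data.frame(length = integer(0), count = integer(0)))
  lens <- nchar(names(counts))
  w <- if (mode == "redundant") as.integer(counts) else rep(1L, length(counts))
  agg <- tapply(w, lens, sum)
  data.frame(length = as.integer(names(agg)), count = as.integer(agg),
             row.names = NULL)
}
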