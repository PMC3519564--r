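#' @import methods
#' @importFrom Biostrings DNAStringSet reverseComplement DNAString
#'   writeXStringSet readDNAStringSet letterFrequency
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom stats rpois runif median setNames quantile
#' @importFrom utils read.delim write.table head
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' ReferenceBundle: genome, transcriptome and annotation references
#'
#' Container for the reference sequences a small-RNA / degradome analysis
#' needs: a genome, a transcriptome, a miRBase-style set of known mature
#' miRNAs with their precursors, and optional non-coding RNA and repeat
#' decoy sets used when partitioning clean reads into annotation classes.
#'
#' @slot genome A [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot transcriptome A [Biostrings::DNAStringSet] of transcript sequences.
#' @slot knownMiRNAs A `data.frame` with columns `name`, `mature`,
#'   `precursor`, `arm` (one of `"5p"`, `"3p"`); every mature sequence is a
#'   substring of its precursor.
#' @slot ncrnaDecoys A [Biostrings::DNAStringSet] of non-coding RNA decoys
#'   (tRNA/rRNA/snoRNA-like sequences standing in for an Rfam screen).
#' @slot repeatDecoys A [Biostrings::DNAStringSet] of repeat decoys.
#'
#' @seealso [generateReference()], [partitionByAnnotation()]
#' @export
setClass("ReferenceBundle",
  slots = c(
    genome        = "DNAStringSet",
    transcriptome = "DNAStringSet",
    knownMiRNAs   = "data.frame",
    ncrnaDecoys   = "DNAStringSet",
    repeatDecoys  = "DNAStringSet"
  )
)

setValidity("ReferenceBundle", function(object) {
  msg <- character()
  allseq <- c(
    as.character(object@genome), as.character(object@transcriptome),
    as.character(object@ncrnaDecoys), as.character(object@repeatDecoys)
  )
  if (length(allseq) && any(grepl("[^ACGT]", allseq)))
    msg <- c(msg, "all reference sequences must be uppercase A/C/G/T")
  km <- object@knownMiRNAs
  need <- c("name", "mature", "precursor", "arm")
  if (!all(need %in% names(km))) {
    msg <- c(msg, sprintf(
      "knownMiRNAs must have columns %s", paste(need, collapse = ", ")
    ))
  } else if (nrow(km)) {
    if (!all(km$arm %in% c("5p", "3p")))
      msg <- c(msg, "knownMiRNAs$arm must be '5p' or '3p'")
    inside <- mapply(grepl, km$mature, km$precursor, fixed = TRUE)
    if (!all(inside))
      msg <- c(msg, "every mature miRNA must be a substring of its precursor")
  }
  if (length(msg)) msg else TRUE
})

#' CleanReadSet: collapsed clean reads plus rejection counters
#'
#' Result of adapter trimming, junk filtering and collapsing of a raw
#' small-RNA library. Holds the unique (distinct) insert sequences with
#' their redundant counts, and counters for every rejected read keyed by
#' rejection reason, so that retained + rejected reconciles with the raw
#' input read count.
#'
#' @slot uniqueCounts Named integer vector: insert sequence -> redundant count.
#' @slot rejected Named integer vector with elements `adapter_not_found`,
#'   `too_short_after_trim` and `junk`.
#'
#' @seealso [cleanReads()], [collapseUnique()]
#' @export
setClass("CleanReadSet",
  slots = c(uniqueCounts = "integer", rejected = "integer")
)

setValidity("CleanReadSet", function(object) {
  msg <- character()
  if (length(object@uniqueCounts)) {
    if (is.null(names(object@uniqueCounts)))
      msg <- c(msg, "uniqueCounts must be named by sequence")
    if (any(object@uniqueCounts < 0))
      msg <- c(msg, "uniqueCounts must be non-negative")
  }
  need <- c("adapter_not_found", "too_short_after_trim", "junk")
  if (!all(need %in% names(object@rejected)))
    msg <- c(msg, sprintf(
      "rejected must contain counters %s", paste(need, collapse = ", ")
    ))
  if (length(msg)) msg else TRUE
})

#' PrecursorCandidate: a folded miRNA precursor candidate
#'
#' A candidate pre-miRNA hairpin: its sequence, predicted secondary
#' structure in dot-bracket notation, folding score, GC content and minimal
#' folding free energy index (MFEI), together with the location of the
#' mature miRNA (and, when known, the star strand) on the precursor.
#'
#' @slot sequence Precursor sequence (DNA alphabet).
#' @slot structure Dot-bracket string, same length as `sequence`.
#' @slot dG Folding score of the structure (kcal/mol-like, <= 0).
#' @slot gcPercent G+C content of the precursor, percent.
#' @slot mfei Minimal folding free energy index, `(100*|dG|/length)/GC%`,
#'   reported as a positive magnitude.
#' @slot matureSpan Integer of length 2: 1-based inclusive (start, end) of
#'   the mature miRNA on the precursor.
#' @slot starSpan Integer of length 2 or `NULL`: span of the star strand.
#'
#' @seealso [foldSequence()], [evaluateHairpin()], [computeMFEI()]
#' @export
setClass("PrecursorCandidate",
  slots = c(
    sequence   = "character",
    structure  = "character",
    dG         = "numeric",
    gcPercent  = "numeric",
    mfei       = "numeric",
    matureSpan = "integer",
    starSpan   = "integerOrNULL"
  )
)

setValidity("PrecursorCandidate", function(object) {
  msg <- character()
  if (nchar(object@structure) != nchar(object@sequence))
    msg <- c(msg, "structure and sequence must have equal length")
  db <- strsplit(object@structure, "")[[1]]
  depth <- cumsum((db == "(") - (db == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0))
    msg <- c(msg, "structure brackets must be balanced")
  if (object@dG > 0)
    msg <- c(msg, "dG must be <= 0")
  sp <- object@matureSpan
  if (length(sp) != 2 || sp[1] < 1 || sp[2] > nchar(object@sequence) ||
      sp[1] > sp[2])
    msg <- c(msg, "matureSpan must lie within the precursor")
  if (length(msg)) msg else TRUE
})

#' TranscriptProfile: per-position degradome tag abundance (the T-plot)
#'
#' For one transcript, the number of degradome tags whose 5' end maps to
#' each transcript position. This is the quantity plotted in a T-plot and
#' the basis of category I-IV cleavage classification.
#'
#' @slot transcriptId Transcript identifier.
#' @slot abundance Numeric vector indexed by 1-based transcript position;
#'   entry i is the (possibly fractional, for multi-mapping tags) count of
#'   tags whose 5' end maps to position i.
#' @slot totalTags Sum of `abundance`.
#'
#' @seealso [mapTags()], [classifyCategory()], [plotTranscriptProfile()]
#' @export
setClass("TranscriptProfile",
  slots = c(
    transcriptId = "character",
    abundance    = "numeric",
    totalTags    = "numeric"
  )
)

setValidity("TranscriptProfile", function(object) {
  msg <- character()
  if (any(object@abundance < 0))
    msg <- c(msg, "abundance must be non-negative")
  if (abs(sum(object@abundance) - object@totalTags) > 1e-6)
    msg <- c(msg, "totalTags must equal sum(abundance)")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn ReferenceBundle-accessors Genome sequences.
#' @export
refGenome <- function(x) x@genome

#' @describeIn ReferenceBundle-accessors Transcript sequences.
#' @export
refTranscriptome <- function(x) x@transcriptome

#' @describeIn ReferenceBundle-accessors Known miRNA table.
#' @export
knownMiRNAs <- function(x) x@knownMiRNAs

#' Accessors for ReferenceBundle
#'
#' @param x A [ReferenceBundle-class] object.
#' @name ReferenceBundle-accessors
#' @aliases refGenome refTranscriptome knownMiRNAs ncrnaDecoys repeatDecoys
NULL

#' @describeIn ReferenceBundle-accessors Non-coding RNA decoys.
#' @export
ncrnaDecoys <- function(x) x@ncrnaDecoys

#' @describeIn ReferenceBundle-accessors Repeat decoys.
#' @export
repeatDecoys <- function(x) x@repeatDecoys

#' Accessors for CleanReadSet
#'
#' @param x A [CleanReadSet-class] object.
#' @return `uniqueCounts()` the named count vector; `rejectedCounts()` the
#'   rejection counters; `totalReads()` retained + rejected read total.
#' @name CleanReadSet-accessors
NULL

#' @describeIn CleanReadSet-accessors Unique sequence counts.
#' @export
uniqueCounts <- function(x) x@uniqueCounts

#' @describeIn CleanReadSet-accessors Rejection counters.
#' @export
rejectedCounts <- function(x) x@rejected

#' @describeIn CleanReadSet-accessors Total input reads accounted for.
#' @export
totalReads <- function(x) sum(x@uniqueCounts) + sum(x@rejected)

#' Accessors for TranscriptProfile
#'
#' @param x A [TranscriptProfile-class] object.
#' @name TranscriptProfile-accessors
NULL

#' @describeIn TranscriptProfile-accessors Per-position tag abundance.
#' @export
profileAbundance <- function(x) x@abundance

#' @describeIn TranscriptProfile-accessors Transcript identifier.
#' @export
transcriptId <- function(x) x@transcriptId

#' @describeIn TranscriptProfile-accessors Total mapped tags on the transcript.
#' @export
totalTags <- function(x) x@totalTags

## ---- show methods ----

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle\n")
  cat(sprintf("  genome       : %d sequence(s), %s nt total\n",
              length(object@genome),
              format(sum(Biostrings::width(object@genome)), big.mark = ",")))
  cat(sprintf("  transcriptome: %d transcript(s)\n", length(object@transcriptome)))
  cat(sprintf("  known miRNAs : %d\n", nrow(object@knownMiRNAs)))
  cat(sprintf("  decoys       : %d ncRNA, %d repeat\n",
              length(object@ncrnaDecoys), length(object@repeatDecoys)))
})

setMethod("show", "CleanReadSet", function(object) {
  cat("CleanReadSet\n")
  cat(sprintf("  unique sequences: %d (redundant: %d)\n",
              length(object@uniqueCounts), sum(object@uniqueCounts)))
  rej <- object@rejected
  cat(sprintf("  rejected        : %s\n",
              paste(sprintf("%s=%d", names(rej), rej), collapse = ", ")))
})

setMethod("show", "PrecursorCandidate", function(object) {
  cat("PrecursorCandidate\n")
  cat(sprintf("  length %d nt | dG %.1f | GC %.1f%% | MFEI %.2f\n",
              nchar(object@sequence), object@dG, object@gcPercent, object@mfei))
  cat(sprintf("  mature span [%d, %d]%s\n", object@matureSpan[1],
              object@matureSpan[2],
              if (is.null(object@starSpan)) "" else
                sprintf(" | star span [%d, %d]",
                        object@starSpan[1], object@starSpan[2])))
  cat(" ", object@sequence, "\n")
  cat(" ", object@structure, "\n")
})

setMethod("show", "TranscriptProfile", function(object) {
  occ <- which(object@abundance > 0)
  cat(sprintf("TranscriptProfile for %s: %d nt, %.1f tags at %d position(s)\n",
              object@transcriptId, length(object@abundance),
              object@totalTags, length(occ)))
})
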