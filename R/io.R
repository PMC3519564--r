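## Readers and writers for the pipeline's file formats.

#' Write sequences as FASTQ with dummy qualities
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeFastq <- function(seqs, path) {
  seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", ids[i]), seqs[i], "+",
                 strrep("I", nchar(seqs[i]))), con)
  }
  invisible(path)
}

#' Read a FASTQ file as a DNAStringSet
#'
#' @param path FASTQ file.
#' @return A [Biostrings::DNAStringSet] (qualities discarded).
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write a FASTA file
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a miRBase-style mature + hairpin FASTA pair
#'
#' Mature and hairpin records are matched by shared name prefix: a mature
#' named `xxx-5p`/`xxx-3p` (or exactly `xxx`) belongs to hairpin `xxx`.
#'
#' @param maturePath FASTA of mature miRNA sequences.
#' @param hairpinPath FASTA of precursor (hairpin) sequences.
#' @return A data.frame with columns `name`, `mature`, `precursor`, `arm`
#'   suitable as a known-miRNA reference.
#' @export
readMirbaseFasta <- function(maturePath, hairpinPath) {
  mat <- Biostrings::readDNAStringSet(maturePath)
  hp <- Biostrings::readDNAStringSet(hairpinPath)
  matNames <- sub("\\s.*$", "", names(mat))
  hpNames <- sub("\\s.*$", "", names(hp))
  rows <- lapply(seq_along(mat), function(i) {
    name <- matNames[i]
    stem <- sub("-(5p|3p)$", "", name)
    j <- match(stem, hpNames)
    if (is.na(j)) j <- match(name, hpNames)
    if (is.na(j)) return(NULL)
    arm <- if (grepl("-5p$", name)) "5p"
           else if (grepl("-3p$", name)) "3p"
           else {
             pre <- canonicalizeDNA(as.character(hp[[j]]))
             m <- regexpr(canonicalizeDNA(as.character(mat[[i]])), pre,
                          fixed = TRUE)
             if (m > 0 && (m + nchar(as.character(mat[[i]])) / 2) <
                 nchar(pre) / 2) "5p" else "3p"
           }
    data.frame(name = name,
               mature = canonicalizeDNA(as.character(mat[[i]])),
               precursor = canonicalizeDNA(as.character(hp[[j]])),
               arm = arm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(name = character(), mature = character(),
                      precursor = character(), arm = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Write a collapsed read set as count-annotated FASTA
#'
#' Headers follow the `>seqN_xCOUNT` convention.
#'
#' @param cleanSet A [CleanReadSet-class].
#' @param path Output FASTA.
#' @return Invisibly, `path`.
#' @export
writeCollapsedFasta <- function(cleanSet, path) {
  counts <- uniqueCounts(cleanSet)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(counts)) {
    writeLines(c(sprintf(">seq%d_x%d", i, counts[[i]]), names(counts)[i]),
               con)
  }
  invisible(path)
}

#' Read a count-annotated collapsed FASTA
#'
#' @param path FASTA with `>seqN_xCOUNT` headers.
#' @return Named integer vector (sequence -> count).
#' @export
readCollapsedFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  counts <- as.integer(sub("^.*_x(\\d+)$", "\\1", names(seqs)))
  setNames(counts, as.character(seqs))
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
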