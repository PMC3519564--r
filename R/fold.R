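#' @useDynLib degradomiR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Canonicalise a nucleotide string to the uppercase DNA alphabet
#'
#' Uppercases and converts U to T so RNA and DNA input are treated alike.
#'
#' @param x Character vector of sequences.
#' @return Character vector over A/C/G/T(/N).
#' @export
canonicalizeDNA <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Fold a sequence into a hairpin-capable secondary structure
#'
#' Predicts a nested secondary structure by scored base-pair maximisation
#' (a Nussinov-style dynamic program): G:C pairs score 3, A:U pairs 2 and
#' G:U wobbles 1, with a minimum hairpin loop of `minLoop` unpaired bases.
#' The returned energy is minus the total pair score -- a deterministic
#' stand-in for a thermodynamic minimum free energy, suitable for ranking
#' hairpins and computing an MFEI. A thermodynamic folder can be swapped in
#' behind the same contract: any function returning a dot-bracket string
#' and an energy for a sequence.
#'
#' Traceback is deterministic; when several structures achieve the optimum
#' the leftmost pairing is preferred.
#'
#' @param sequence A single nucleotide string (A/C/G/T/U, case-insensitive).
#' @param minLoop Minimum number of unpaired bases in a hairpin loop.
#' @return A list with elements `structure` (dot-bracket string), `dG`
#'   (energy, <= 0) and `score` (total pair score, >= 0).
#' @examples
#' foldSequence("GGGAAAACCC")  # three G:C pairs, energy -9
#' @export
foldSequence <- function(sequence, minLoop = 3L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- canonicalizeDNA(sequence)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("[^ACGT]", seq))
    stop("sequence contains characters outside A/C/G/T/U")
  res <- nussinov_fold_cpp(seq, as.integer(minLoop))
  list(structure = res$structure, dG = res$energy, score = res$score)
}

#' Minimal folding free energy index (MFEI)
#'
#' `MFEI = AMFE / GC%` with `AMFE = 100 * dG / length`, reported as a
#' positive magnitude. True pre-miRNA hairpins typically have larger MFEI
#' than other non-coding RNA or random genomic folds, which makes the index
#' a cheap hairpin-quality filter.
#'
#' @param dG Folding energy (kcal/mol-like, <= 0 or 0).
#' @param length Sequence length in nt (> 0).
#' @param gcPercent G+C content in percent, in (0, 100].
#' @return The MFEI as a positive magnitude.
#' @examples
#' computeMFEI(-50, 100, 50)  # 1.0
#' @export
computeMFEI <- function(dG, length, gcPercent) {
  stopifnot(length > 0)
  if (any(gcPercent <= 0))
    stop("gcPercent must be > 0")
  abs(100 * dG / length) / gcPercent
}

#' G+C content of sequences, in percent
#'
#' @param x Character vector of sequences.
#' @return Numeric vector of G+C percentages.
#' @export
gcPercent <- function(x) {
  x <- canonicalizeDNA(x)
  vapply(strsplit(x, ""), function(ch) {
    100 * sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1))
}

#' Base-pair partner table from a dot-bracket string
#'
#' @param structure Dot-bracket string.
#' @return Integer vector; entry i is the partner of position i, or NA
#'   when unpaired.
#' @export
pairTable <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  partner
}
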