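## Cross-library normalisation and log2 fold-change calling.

#' Normalise per-miRNA counts across two libraries
#'
#' Geometric-mean library scaling: with library sizes `N_free` and
#' `N_treated`, each library is multiplied by
#' `scale_i = sqrt(N_free * N_treated) / N_i`, so the two scale factors
#' are reciprocal (`scale_free * scale_treated = 1`) and the common scale
#' is the geometric mean of the library sizes. Library sizes default to
#' the total miRNA-assigned reads in each library and can be overridden.
#'
#' @param table A data.frame with columns `name`, `rawFree`, `rawTreated`
#'   and `origin` (`"known"` or `"novel"`).
#' @param nFree,nTreated Library sizes; default `sum(rawFree)` /
#'   `sum(rawTreated)`.
#' @return The table with `normFree` and `normTreated` columns added, and
#'   the scaling as attribute `"scaling"` (list with `nFree`, `nTreated`,
#'   `scaleFree`, `scaleTreated`).
#' @export
normalizeCounts <- function(table, nFree = NULL, nTreated = NULL) {
  if (is.null(nFree)) nFree <- sum(table$rawFree)
  if (is.null(nTreated)) nTreated <- sum(table$rawTreated)
  if (nFree <= 0 || nTreated <= 0) stop("library size must be positive")
  g <- sqrt(nFree * nTreated)
  scaleFree <- g / nFree
  scaleTreated <- g / nTreated
  table$normFree <- table$rawFree * scaleFree
  table$normTreated <- table$rawTreated * scaleTreated
  attr(table, "scaling") <- list(nFree = nFree, nTreated = nTreated,
                                 scaleFree = scaleFree,
                                 scaleTreated = scaleTreated)
  table
}

#' Filter miRNAs below the abundance floor
#'
#' Rows whose maximum raw count across the two libraries falls below the
#' floor for their origin are marked `call = "filtered"`: fewer than
#' `knownMin` raw reads for known miRNAs, fewer than `novelMin` for novel
#' ones. A row passing in either library is retained, so e.g. a novel
#' miRNA with raw counts (4, 29) survives a floor of 20.
#'
#' @param table A normalised count table with an `origin` column.
#' @param knownMin,novelMin Raw-read floors (defaults 10 and 20).
#' @return The table with a `call` column (`"filtered"` or `NA` pending).
#' @export
filterLowAbundance <- function(table, knownMin = 10, novelMin = 20) {
  floorFor <- ifelse(table$origin == "novel", novelMin, knownMin)
  mx <- pmax(table$rawFree, table$rawTreated)
  table$call <- ifelse(mx < floorFor, "filtered", NA_character_)
  table
}

#' Call differentially expressed miRNAs by log2 fold change
#'
#' `log2fc = log2(normTreated / normFree)`; a miRNA is called `"up"` when
#' log2fc exceeds `upThreshold`, `"down"` when below `downThreshold`,
#' otherwise `"unchanged"`. Rows already marked `"filtered"` are skipped;
#' rows with a zero normalised count on either side are excluded from
#' calling and marked `"zero_norm"`.
#'
#' @param table Output of [filterLowAbundance()].
#' @param upThreshold,downThreshold log2 fold-change thresholds (+1/-1).
#' @return The table with `log2fc` and completed `call` columns.
#' @export
callDifferential <- function(table, upThreshold = 1, downThreshold = -1) {
  table$log2fc <- ifelse(table$normFree > 0 & table$normTreated > 0,
                         log2(table$normTreated / table$normFree), NA_real_)
  pending <- is.na(table$call)
  zero <- pending & (table$normFree == 0 | table$normTreated == 0)
  table$call[zero] <- "zero_norm"
  pending <- is.na(table$call)
  table$call[pending & table$log2fc > upThreshold] <- "up"
  pending <- is.na(table$call)
  table$call[pending & table$log2fc < downThreshold] <- "down"
  table$call[is.na(table$call)] <- "unchanged"
  table
}

#' Relative expression by the 2^-ddCt method
#'
#' `ratio = 2^-((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control))`, the standard qPCR relative
#' quantification against a reference gene.
#'
#' @param ctTargetTreated,ctTargetControl Target-gene Ct values.
#' @param ctRefTreated,ctRefControl Reference-gene Ct values.
#' @return Relative expression ratio (treated vs control).
#' @examples
#' ddctFoldChange(20, 22, 18, 18)  # ddCt = 2 -> 0.25
#' @export
ddctFoldChange <- function(ctTargetTreated, ctTargetControl,
                           ctRefTreated, ctRefControl) {
  stopifnot(ctTargetTreated > 0, ctTargetControl > 0,
            ctRefTreated > 0, ctRefControl > 0)
  ddct <- (ctTargetTreated - ctRefTreated) -
          (ctTargetControl - ctRefControl)
  2^(-ddct)
}
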