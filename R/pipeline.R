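## End-to-end orchestration: simulate -> preprocess -> catalog ->
## express -> degradome, from a single config with one seed.

PIPELINE_STAGES <- c("reference", "srna_free", "srna_treated",
                     "degradome_free", "degradome_treated")

#' Derive a per-stage child seed from the pipeline seed
#'
#' `child = (seed * 1013 + stageIndex) mod (2^31 - 1)`, so each stage can
#' be rerun standalone with a reproducible seed.
#'
#' @param seed Pipeline seed.
#' @param stage Stage name (one of the documented stages).
#' @return Integer child seed.
#' @export
childSeed <- function(seed, stage) {
  idx <- match(stage, PIPELINE_STAGES)
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1013 + idx) %% 2147483647)
}

#' Build a pipeline configuration
#'
#' @param outdir Output directory (created if needed).
#' @param seed Single pipeline seed; all stage randomness derives from it.
#' @param simulate `NULL`, or a [syntheticConfig()] list: when present,
#'   [stageSimulate()] generates the input files.
#' @param inputs Named list of input paths (`srna_free`, `srna_treated`,
#'   `degradome_free`, `degradome_treated`, `genome`, `transcriptome`,
#'   `mature`, `hairpin`, `ncrna`, `repeats`); filled by [stageSimulate()]
#'   when simulating.
#' @param parameters Stage parameters (adapter, minLen, maxMismatch,
#'   knownMin, novelMin, upThreshold, downThreshold, maxScore,
#'   siteTolerance, flank, mfeiMin).
#' @return Config list.
#' @export
pipelineConfig <- function(outdir, seed = 1L, simulate = NULL,
                           inputs = list(), parameters = list()) {
  defaults <- list(
    adapter = "TGGAATTCTCGGGTGCCAAGG", minLen = 15L, maxMismatch = 2L,
    knownMin = 10, novelMin = 20, upThreshold = 1, downThreshold = -1,
    maxScore = 4.5, siteTolerance = 1L, flank = 120L, mfeiMin = 0.5
  )
  parameters <- utils::modifyList(defaults, parameters)
  list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
       inputs = inputs, parameters = parameters)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML config file.
#' @return Config list (defaults filled in).
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  pipelineConfig(
    outdir = raw$outdir, seed = raw$seed %||% 1L,
    simulate = if (!is.null(raw$simulate)) do.call(syntheticConfig, raw$simulate),
    inputs = raw$inputs %||% list(),
    parameters = raw$parameters %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

REQUIRED_INPUTS <- c("srna_free", "srna_treated", "degradome_free",
                     "degradome_treated", "genome", "transcriptome",
                     "mature", "hairpin", "ncrna", "repeats")

#' Validate a pipeline configuration
#'
#' Checks that every required input path is present and exists (skipped
#' when a `simulate` block will generate them) and that thresholds are in
#' range. Errors name the offending field.
#'
#' @param config Config list.
#' @return Invisibly `TRUE`.
#' @export
validatePipelineConfig <- function(config) {
  if (is.null(config$outdir)) stop("config field missing: outdir")
  if (is.null(config$simulate)) {
    for (f in REQUIRED_INPUTS) {
      p <- config$inputs[[f]]
      if (is.null(p)) stop("config input missing: ", f)
      if (!file.exists(p)) stop("config input '", f, "' does not exist: ", p)
    }
  }
  p <- config$parameters
  if (p$maxScore < 0 || p$maxScore > 10)
    stop("config parameter out of range: maxScore")
  if (p$minLen < 1) stop("config parameter out of range: minLen")
  invisible(TRUE)
}

#' Generate synthetic input files for the pipeline
#'
#' Runs the synthetic-data generator under the pipeline's derived seeds
#' and writes genome/transcriptome/miRNA reference FASTAs, the four
#' FASTQ libraries, and ground-truth manifests under
#' `<outdir>/inputs/`.
#'
#' @param config Config list with a `simulate` block.
#' @return The config with `inputs` paths filled in; the generated ground
#'   truth is attached as attribute `"truth"`.
#' @export
stageSimulate <- function(config) {
  stopifnot(!is.null(config$simulate))
  dir.create(file.path(config$outdir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  simCfg <- config$simulate
  simCfg$seed <- childSeed(config$seed, "reference")
  ref <- generateReference(simCfg)
  ip <- function(f) file.path(config$outdir, "inputs", f)

  writeFasta(refGenome(ref$bundle), ip("genome.fa"))
  writeFasta(refTranscriptome(ref$bundle), ip("transcriptome.fa"))
  km <- knownMiRNAs(ref$bundle)
  writeFasta(setNames(km$mature, paste0(km$name, "-", km$arm)),
             ip("mature.fa"))
  writeFasta(setNames(km$precursor, km$name), ip("hairpin.fa"))
  writeFasta(ncrnaDecoys(ref$bundle), ip("ncrna.fa"))
  writeFasta(repeatDecoys(ref$bundle), ip("repeats.fa"))

  noise <- list(junkFraction = simCfg$junkFraction %||% 0.01,
                adapterlessFraction = simCfg$adapterlessFraction %||% 0.05)
  for (cond in c("free", "treated")) {
    lib <- simulateSrnaLibrary(ref, cond,
                               junkFraction = noise$junkFraction,
                               adapterlessFraction = noise$adapterlessFraction,
                               seed = childSeed(config$seed,
                                                paste0("srna_", cond)))
    writeFastq(lib, ip(sprintf("srna_%s.fastq", cond)))
    dg <- simulateDegradomeLibrary(ref,
            seed = childSeed(config$seed, paste0("degradome_", cond)))
    writeFastq(dg, ip(sprintf("degradome_%s.fastq", cond)))
  }
  writeTsv(ref$plantedMiRNAs, ip("planted_mirnas.tsv"))
  writeTsv(ref$plantedCleavages, ip("planted_cleavages.tsv"))

  config$inputs <- list(
    srna_free = ip("srna_free.fastq"), srna_treated = ip("srna_treated.fastq"),
    degradome_free = ip("degradome_free.fastq"),
    degradome_treated = ip("degradome_treated.fastq"),
    genome = ip("genome.fa"), transcriptome = ip("transcriptome.fa"),
    mature = ip("mature.fa"), hairpin = ip("hairpin.fa"),
    ncrna = ip("ncrna.fa"), repeats = ip("repeats.fa")
  )
  attr(config, "truth") <- ref
  config
}

loadBundle <- function(config) {
  new("ReferenceBundle",
      genome = Biostrings::readDNAStringSet(config$inputs$genome),
      transcriptome = Biostrings::readDNAStringSet(config$inputs$transcriptome),
      knownMiRNAs = readMirbaseFasta(config$inputs$mature,
                                     config$inputs$hairpin),
      ncrnaDecoys = Biostrings::readDNAStringSet(config$inputs$ncrna),
      repeatDecoys = Biostrings::readDNAStringSet(config$inputs$repeats))
}

## round half up, the convention used for the printed percentages
roundHalfUp <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Build a read-distribution summary table for one library
#'
#' Rows: raw reads, the three rejection reasons, mapped (clean) reads and
#' the five annotation classes. Percentages are reported against both
#' denominators -- total raw reads (`pctRaw`) and mapped reads
#' (`pctMapped`) -- rounded half-up to 2 decimals.
#'
#' @param rawCount Total raw reads in the library.
#' @param cleanSet A [CleanReadSet-class].
#' @param partition Output of [partitionByAnnotation()].
#' @return A data.frame with columns `class`, `count`, `pctRaw`,
#'   `pctMapped`.
#' @export
makeSummaryTable <- function(rawCount, cleanSet, partition) {
  if (rawCount <= 0) stop("zero raw reads")
  rej <- rejectedCounts(cleanSet)
  mapped <- sum(uniqueCounts(cleanSet))
  classCounts <- setNames(partition$counts$redundant,
                          partition$counts$class)
  rows <- data.frame(
    class = c("raw", "adapter_not_found", "too_short_after_trim", "junk",
              "mapped", "mRNA", "rfam", "repeats", "miRNA_candidate",
              "no_hit"),
    count = c(rawCount, rej[["adapter_not_found"]],
              rej[["too_short_after_trim"]], rej[["junk"]], mapped,
              classCounts[["mRNA"]], classCounts[["rfam"]],
              classCounts[["repeats"]], classCounts[["miRNA_candidate"]],
              classCounts[["no_hit"]]),
    stringsAsFactors = FALSE
  )
  rows$pctRaw <- roundHalfUp(100 * rows$count / rawCount)
  rows$pctMapped <- if (mapped > 0)
    roundHalfUp(100 * rows$count / mapped) else NA_real_
  rows
}

#' Preprocess both small-RNA libraries
#'
#' Cleans each library, partitions the unique sequences by annotation and
#' writes collapsed FASTA, partition, length-histogram and summary TSVs
#' under `<outdir>/preprocess/`.
#'
#' @param config Validated config with input paths.
#' @return A list per condition with the clean set, partition, raw count
#'   and summary table.
#' @export
stagePreprocess <- function(config) {
  dir.create(file.path(config$outdir, "preprocess"), recursive = TRUE,
             showWarnings = FALSE)
  bundle <- loadBundle(config)
  p <- config$parameters
  out <- list()
  for (cond in c("free", "treated")) {
    reads <- readFastq(config$inputs[[sprintf("srna_%s", cond)]])
    cs <- cleanReads(as.character(reads), p$adapter, minLen = p$minLen)
    part <- partitionByAnnotation(cs, bundle)
    op <- function(f) file.path(config$outdir, "preprocess",
                                sprintf(f, cond))
    writeCollapsedFasta(cs, op("collapsed_%s.fasta"))
    partDf <- do.call(rbind, lapply(names(part$classes), function(k) {
      s <- part$classes[[k]]
      if (!length(s)) return(NULL)
      data.frame(sequence = s, class = k, count = uniqueCounts(cs)[s],
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
    writeTsv(partDf, op("partition_%s.tsv"))
    writeTsv(lengthDistribution(cs, "unique"), op("lengths_unique_%s.tsv"))
    writeTsv(lengthDistribution(cs, "redundant"),
             op("lengths_redundant_%s.tsv"))
    summary <- makeSummaryTable(length(reads), cs, part)
    writeTsv(summary, op("summary_%s.tsv"))
    out[[cond]] <- list(cleanSet = cs, partition = part,
                        rawCount = length(reads), summary = summary)
  }
  out
}

#' Catalogue known and novel miRNAs
#'
#' Matches the genome-mapped candidate sequences of both libraries
#' against the known reference, detects star (p3/p5) strands on the known
#' precursors, and runs novel-miRNA discovery (hairpin + MFEI evaluation)
#' on the unassigned candidates. Writes `known_assignments.tsv`,
#' `known_counts.tsv`, `star_strands.tsv` and `novel_report.tsv` under
#' `<outdir>/catalog/`.
#'
#' @param config Validated config.
#' @param preprocess Output of [stagePreprocess()] (re-read from disk
#'   when omitted).
#' @return A list with the assignment, star, novel and count tables.
#' @export
stageCatalog <- function(config, preprocess = NULL) {
  dir.create(file.path(config$outdir, "catalog"), recursive = TRUE,
             showWarnings = FALSE)
  bundle <- loadBundle(config)
  p <- config$parameters
  counts <- list()
  candidates <- character(0)
  for (cond in c("free", "treated")) {
    if (is.null(preprocess)) {
      cnt <- readCollapsedFasta(file.path(config$outdir, "preprocess",
                                          sprintf("collapsed_%s.fasta", cond)))
      part <- readTsv(file.path(config$outdir, "preprocess",
                                sprintf("partition_%s.tsv", cond)))
      cand <- part$sequence[part$class == "miRNA_candidate"]
    } else {
      cnt <- uniqueCounts(preprocess[[cond]]$cleanSet)
      cand <- preprocess[[cond]]$partition$classes$miRNA_candidate
    }
    counts[[cond]] <- cnt
    candidates <- union(candidates, cand)
  }
  candidates <- sort(candidates, method = "radix")
  countOf <- function(seqs, cond) {
    v <- counts[[cond]][seqs]
    ifelse(is.na(v), 0L, as.integer(v))
  }

  km <- knownMiRNAs(bundle)
  assigned <- matchKnown(candidates, km, maxMismatch = p$maxMismatch)
  writeTsv(assigned, file.path(config$outdir, "catalog",
                               "known_assignments.tsv"))

  ## per-known-miRNA mature counts: assigned sequences of mature length
  ## within the mismatch cap of the mature itself
  knownCounts <- do.call(rbind, lapply(seq_len(nrow(km)), function(r) {
    seqs <- assigned$sequence[assigned$name == km$name[r]]
    isMature <- vapply(seqs, function(s) {
      nchar(s) == nchar(km$mature[r]) &&
        hammingDistance(s, km$mature[r]) <= p$maxMismatch
    }, logical(1))
    seqs <- seqs[isMature]
    data.frame(name = km$name[r], sequence = km$mature[r],
               origin = "known",
               rawFree = sum(countOf(seqs, "free")),
               rawTreated = sum(countOf(seqs, "treated")),
               stringsAsFactors = FALSE)
  }))
  if (is.null(knownCounts))
    knownCounts <- data.frame(name = character(), sequence = character(),
                              origin = character(), rawFree = integer(),
                              rawTreated = integer(), stringsAsFactors = FALSE)
  writeTsv(knownCounts, file.path(config$outdir, "catalog",
                                  "known_counts.tsv"))

  ## star strands of known miRNAs (union counts across both libraries
  ## for detection; per-library counts for expression)
  unionCounts <- counts$free
  for (s in names(counts$treated)) {
    unionCounts[s] <- (if (s %in% names(unionCounts)) unionCounts[s] else 0L) +
      counts$treated[s]
  }
  stars <- list()
  for (r in seq_len(nrow(km))) {
    mpos <- regexpr(km$mature[r], km$precursor[r], fixed = TRUE)
    if (mpos < 0) next
    span <- c(as.integer(mpos), as.integer(mpos) + nchar(km$mature[r]) - 1L)
    cand <- buildPrecursorCandidate(km$precursor[r], span)
    st <- detectStarStrand(cand, unionCounts, name = km$name[r])
    if (is.null(st) || st$starCount == 0) next
    starSeqs <- candidates[vapply(candidates, function(q) {
      mq <- regexpr(q, km$precursor[r], fixed = TRUE)
      mq > 0 && abs(as.integer(mq) - st$starSpan[1]) <= 4L &&
        q != km$mature[r]
    }, logical(1))]
    stars[[length(stars) + 1L]] <- data.frame(
      name = st$starName, sequence = starSeqs[1],
      origin = "known",
      rawFree = sum(countOf(starSeqs, "free")),
      rawTreated = sum(countOf(starSeqs, "treated")),
      starExceedsMature = st$starExceedsMature,
      stringsAsFactors = FALSE
    )
  }
  stars <- if (length(stars)) do.call(rbind, stars) else
    data.frame(name = character(), sequence = character(),
               origin = character(), rawFree = integer(),
               rawTreated = integer(), starExceedsMature = logical(),
               stringsAsFactors = FALSE)
  writeTsv(stars, file.path(config$outdir, "catalog", "star_strands.tsv"))

  ## novel discovery on candidates not assigned to a known precursor
  unassigned <- setdiff(candidates, assigned$sequence)
  criteria <- hairpinCriteria(minMfei = p$mfeiMin)
  novel <- discoverNovelMirnas(unassigned, bundle, criteria = criteria,
                               flank = p$flank)
  if (nrow(novel)) {
    novel$rawFree <- countOf(novel$sequence, "free")
    novel$rawTreated <- countOf(novel$sequence, "treated")
  } else {
    novel$rawFree <- integer(0); novel$rawTreated <- integer(0)
  }
  writeTsv(novel[, setdiff(names(novel), "structure")],
           file.path(config$outdir, "catalog", "novel_report.tsv"))
  list(assigned = assigned, knownCounts = knownCounts, stars = stars,
       novel = novel)
}

#' Call differentially expressed miRNAs across the two libraries
#'
#' Assembles the known (mature and star) and novel count rows, normalises
#' by geometric-mean library scaling, applies the abundance floors and
#' the +-1 log2 fold-change rule, and writes `de_table.tsv` under
#' `<outdir>/express/`.
#'
#' @param config Validated config.
#' @param catalog Output of [stageCatalog()] (re-read from disk if omitted).
#' @return The differential-expression table.
#' @export
stageExpress <- function(config, catalog = NULL) {
  dir.create(file.path(config$outdir, "express"), recursive = TRUE,
             showWarnings = FALSE)
  p <- config$parameters
  cp <- function(f) file.path(config$outdir, "catalog", f)
  knownCounts <- if (is.null(catalog)) readTsv(cp("known_counts.tsv"))
                 else catalog$knownCounts
  stars <- if (is.null(catalog)) readTsv(cp("star_strands.tsv"))
           else catalog$stars
  novel <- if (is.null(catalog)) readTsv(cp("novel_report.tsv"))
           else catalog$novel
  novelRows <- if (nrow(novel))
    data.frame(name = novel$name, sequence = novel$sequence,
               origin = "novel", rawFree = novel$rawFree,
               rawTreated = novel$rawTreated, stringsAsFactors = FALSE)
  else NULL
  starRows <- if (nrow(stars))
    stars[, c("name", "sequence", "origin", "rawFree", "rawTreated")]
  else NULL
  tab <- rbind(knownCounts, starRows, novelRows)
  tab <- tab[order(tab$name, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  tab <- normalizeCounts(tab)
  tab <- filterLowAbundance(tab, knownMin = p$knownMin,
                            novelMin = p$novelMin)
  tab <- callDifferential(tab, upThreshold = p$upThreshold,
                          downThreshold = p$downThreshold)
  report <- tab
  report$normFree <- roundHalfUp(report$normFree)
  report$normTreated <- roundHalfUp(report$normTreated)
  report$log2fc <- roundHalfUp(report$log2fc)
  writeTsv(report, file.path(config$outdir, "express", "de_table.tsv"))
  tab
}

#' Identify degradome-supported miRNA targets in both libraries
#'
#' Processes each degradome library (CAGCAG tag extraction), maps tags to
#' T-plot profiles, aligns every catalogued miRNA against every profiled
#' transcript and classifies cleavage sites. Writes per-library call
#' tables and a merged wide table (`targets.tsv`) under
#' `<outdir>/degradome/`.
#'
#' @param config Validated config.
#' @param catalog Output of [stageCatalog()] (re-read from disk if omitted).
#' @return A list with per-library calls and the merged table.
#' @export
stageDegradome <- function(config, catalog = NULL) {
  dir.create(file.path(config$outdir, "degradome"), recursive = TRUE,
             showWarnings = FALSE)
  bundle <- loadBundle(config)
  p <- config$parameters
  cp <- function(f) file.path(config$outdir, "catalog", f)
  knownCounts <- if (is.null(catalog)) readTsv(cp("known_counts.tsv"))
                 else catalog$knownCounts
  novel <- if (is.null(catalog)) readTsv(cp("novel_report.tsv"))
           else catalog$novel
  mirnas <- rbind(knownCounts[, c("name", "sequence")],
                  if (nrow(novel)) novel[, c("name", "sequence")])
  mirnas <- mirnas[nchar(mirnas$sequence) >= 15 &
                   nchar(mirnas$sequence) <= 26, , drop = FALSE]
  calls <- list()
  for (cond in c("free", "treated")) {
    reads <- readFastq(config$inputs[[sprintf("degradome_%s", cond)]])
    proc <- processDegradomeReads(as.character(reads))
    mapping <- mapTags(proc$tags, refTranscriptome(bundle))
    res <- identifyTargets(mirnas, mapping, refTranscriptome(bundle),
                           maxScore = p$maxScore,
                           siteTolerance = p$siteTolerance)
    writeTsv(res, file.path(config$outdir, "degradome",
                            sprintf("calls_%s.tsv", cond)))
    calls[[cond]] <- res
  }
  merged <- mergeTargetCalls(calls$treated, calls$free)
  writeTsv(merged, file.path(config$outdir, "degradome", "targets.tsv"))
  list(calls = calls, merged = merged)
}

## wide per-(miRNA, transcript) table with per-library category columns
mergeTargetCalls <- function(treated, free) {
  key <- function(df) paste(df$mirna, df$transcript, df$cleavageSite)
  keys <- union(key(treated), key(free))
  pick <- function(df, k, col) {
    i <- match(k, key(df))
    if (is.na(i)) NA else df[[col]][i]
  }
  rows <- lapply(keys, function(k) {
    src <- if (k %in% key(treated)) treated else free
    i <- match(k, key(src))
    data.frame(
      mirna = src$mirna[i], transcript = src$transcript[i],
      score = src$score[i], cleavageSite = src$cleavageSite[i],
      categoryTreated = pick(treated, k, "category"),
      percentTreated = pick(treated, k, "percentAtSite"),
      tpbTreated = pick(treated, k, "tpb"),
      acceptedTreated = pick(treated, k, "accepted"),
      categoryFree = pick(free, k, "category"),
      percentFree = pick(free, k, "percentAtSite"),
      tpbFree = pick(free, k, "tpb"),
      acceptedFree = pick(free, k, "accepted"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$transcript, out$cleavageSite,
                   method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full pipeline from one config
#'
#' Executes simulate (when configured) -> preprocess -> catalog ->
#' express -> degradome. All randomness flows from the single config
#' seed, so reruns produce byte-identical outputs. Counts are reconciled
#' across stage boundaries and the run report records per-stage record
#' counts, parameters and wall time.
#'
#' @param config Config from [pipelineConfig()] or [readPipelineConfig()].
#' @return A RunReport list (`stages`, `parameters`, `seed`, `timing`).
#' @export
runPipeline <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  if (!is.null(config$simulate)) {
    config <- stageSimulate(config)
    tick("simulate")
  }
  validatePipelineConfig(config)
  pre <- stagePreprocess(config)
  tick("preprocess")
  for (cond in c("free", "treated")) {
    stopifnot(totalReads(pre[[cond]]$cleanSet) == pre[[cond]]$rawCount)
    stopifnot(sum(pre[[cond]]$partition$counts$redundant) ==
              sum(uniqueCounts(pre[[cond]]$cleanSet)))
  }
  cat <- stageCatalog(config, pre)
  tick("catalog")
  de <- stageExpress(config, cat)
  stopifnot(nrow(de) == nrow(cat$knownCounts) + nrow(cat$stars) +
            nrow(cat$novel))
  tick("express")
  dg <- stageDegradome(config, cat)
  tick("degradome")
  report <- list(
    seed = config$seed,
    parameters = config$parameters,
    stages = list(
      preprocess = lapply(pre, function(x)
        list(raw = x$rawCount, clean = sum(uniqueCounts(x$cleanSet)),
             rejected = as.list(rejectedCounts(x$cleanSet)))),
      catalog = list(known = nrow(cat$knownCounts), stars = nrow(cat$stars),
                     novel = nrow(cat$novel)),
      express = list(rows = nrow(de),
                     up = sum(de$call == "up"),
                     down = sum(de$call == "down")),
      degradome = list(
        callsFree = nrow(dg$calls$free),
        callsTreated = nrow(dg$calls$treated),
        acceptedFree = sum(dg$calls$free$accepted),
        acceptedTreated = sum(dg$calls$treated$accepted))
    ),
    timing = as.list(timing)
  )
  yaml::write_yaml(report, file.path(config$outdir, "run_report.yaml"))
  invisible(report)
}
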