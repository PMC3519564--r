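## Seeded synthetic references and libraries with planted ground truth.
##
## The generator writes perfect Dicer-style hairpins into a random genome:
##   5'-[flank A]-[stem5]-[CC]-[loop A]-[rc(stem5)]-[CC]-[flank A]-3'
## The two CC dinucleotides are the 2-nt 3' overhangs of the miRNA/miRNA*
## duplex; flanks and loop are A-runs so that, under base-pair
## maximisation, the designed stem is the unique optimal structure and the
## overhangs stay unpaired (A cannot pair with A, C cannot pair with A).

DNA_BASES <- c("A", "C", "G", "T")

#' Default configuration for the synthetic-data generator
#'
#' Returns the generation parameters as a named list. The defaults define
#' the simulated study: two small-RNA libraries (an untreated "free" and a
#' stress-"treated" condition) with planted four-fold up- and down-regulated
#' miRNAs at sequencing depths of several hundred reads, a ten percent star
#' strand fraction, and one planted category-I cleavage site per miRNA with
#' a 100-read peak over a 50-read uniform background on 500-nt transcripts.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param nChromosomes,chromosomeLength Genome shape.
#' @param nMirnas Number of planted miRNA hairpin loci.
#' @param knownFraction Fraction of planted miRNAs entered into the known
#'   (miRBase-style) reference; the rest are novel.
#' @param nTranscripts,transcriptLength Transcriptome shape.
#' @param nCleavages Number of planted cleavage sites (at most one per
#'   transcript, guided by the first `nCleavages` planted miRNAs).
#' @param baseAbundance Expected read count of an unchanged miRNA per library.
#' @param effectFold Fold change planted for up-/down-regulated miRNAs.
#' @param starFraction Expected star-strand reads as a fraction of mature.
#' @param matureLengths Candidate mature lengths (nt), sampled per locus.
#' @param loopLength,flankLength Hairpin loop and flank lengths (nt).
#' @param peakReads,backgroundReads Planted degradome peak and background.
#' @param nNcrnaDecoys,nRepeatDecoys,decoyLength Decoy reference shape.
#' @param adapter 3' adapter sequence ligated to small-RNA reads.
#' @param readLength Raw read length before trimming (nt).
#' @param tagLength Degradome tag length (nt).
#' @return Named list of parameters.
#' @export
syntheticConfig <- function(seed = 1L,
                            nChromosomes = 3L,
                            chromosomeLength = 20000L,
                            nMirnas = 12L,
                            knownFraction = 0.5,
                            nTranscripts = 16L,
                            transcriptLength = 500L,
                            nCleavages = nMirnas,
                            baseAbundance = 600,
                            effectFold = 4,
                            starFraction = 0.1,
                            matureLengths = 20:24,
                            loopLength = 8L,
                            flankLength = 6L,
                            peakReads = 100L,
                            backgroundReads = 50L,
                            nNcrnaDecoys = 5L,
                            nRepeatDecoys = 5L,
                            decoyLength = 80L,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            readLength = 36L,
                            tagLength = 20L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$nChromosomes > 0, cfg$chromosomeLength > 0, cfg$nMirnas >= 0,
    cfg$nTranscripts > 0, cfg$transcriptLength > 0,
    cfg$starFraction >= 0, cfg$starFraction <= 1
  )
  cfg
}

randomDNA <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## replace any CAGCAG occurrence so degradome tag extraction is unambiguous
scrubMotif <- function(seq, motif = "CAGCAG") {
  while ((pos <- regexpr(motif, seq, fixed = TRUE)) > 0) {
    base <- substr(seq, pos, pos)
    substr(seq, pos, pos) <- if (base == "C") "G" else "C"
  }
  seq
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## a base that neither Watson-Crick pairs nor G:U wobbles with miRNA base b
mismatchBase <- function(b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")[[b]]
  forbidden <- c(comp, if (b == "G") "T", if (b == "T") "G")
  setdiff(DNA_BASES, forbidden)[1]
}

buildHairpin <- function(matureLength, loopLength, flankLength) {
  p <- matureLength - 2L
  # Stem boundaries are an all-C block (5' arm) facing an all-G block
  # (3' arm) and the loop-proximal pair is G:C. Flanks, loop and the 2-nt
  # overhangs are A-runs, which pair with nothing outside the stems
  # (A:A is not a pair and every stem T is engaged at higher cost), so
  # every re-routing of a stem pair to an external base loses score and
  # the designed duplex is the unique base-pair-maximisation optimum.
  stem5 <- paste0("CCCCC", randomDNA(p - 6L), "G")
  stem3 <- revComp(stem5)
  flank <- strrep("A", flankLength)
  loop <- strrep("A", loopLength)
  precursor <- paste0(flank, stem5, "AA", loop, stem3, "AA", flank)
  span5 <- c(flankLength + 1L, flankLength + p + 2L)
  span3 <- c(flankLength + p + 2L + loopLength + 1L,
             flankLength + p + 2L + loopLength + p + 2L)
  list(precursor = precursor,
       seq5p = paste0(stem5, "AA"),
       seq3p = paste0(stem3, "AA"),
       span5p = as.integer(span5),
       span3p = as.integer(span3))
}

#' Generate a seeded synthetic reference bundle with planted ground truth
#'
#' Builds a random genome with planted miRNA hairpin loci, a transcriptome
#' carrying near-complementary target sites for the planted miRNAs, decoy
#' ncRNA/repeat references, and a known-miRNA reference covering a subset
#' of the planted loci. Every planted target site is complementary to its
#' miRNA except for two mismatches outside the core region (at miRNA
#' positions 16 and 19), so the alignment penalty is 2 and mature
#' sequences never match transcripts exactly on either strand.
#'
#' @param config A list from [syntheticConfig()].
#' @return A list with elements `bundle` ([ReferenceBundle-class]),
#'   `plantedMiRNAs` (data.frame: name, chrom, start, end, strand, arm,
#'   mature, precursor, abundanceFree, abundanceTreated, starFraction,
#'   origin, effect) and `plantedCleavages` (data.frame: mirnaName,
#'   transcriptId, site, targetStart, targetEnd, peakReads,
#'   backgroundReads, intendedCategory).
#' @examples
#' ref <- generateReference(syntheticConfig(seed = 1, nMirnas = 3))
#' ref$bundle
#' @export
generateReference <- function(config = syntheticConfig()) {
  cfg <- config
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(cfg$seed)

  maxPre <- 2L * (max(cfg$matureLengths)) + cfg$loopLength +
    2L * cfg$flankLength
  perChrom <- ceiling(cfg$nMirnas / cfg$nChromosomes)
  if (perChrom * (maxPre + 50L) + 100L > cfg$chromosomeLength)
    stop("infeasible packing: chromosomeLength too small for ",
         cfg$nMirnas, " precursors on ", cfg$nChromosomes, " chromosome(s)")

  chroms <- vapply(seq_len(cfg$nChromosomes),
                   function(i) randomDNA(cfg$chromosomeLength), character(1))
  names(chroms) <- sprintf("Chr%02d", seq_len(cfg$nChromosomes))

  effects <- c("up", "down", "unchanged")
  planted <- NULL
  if (cfg$nMirnas > 0) {
    rows <- vector("list", cfg$nMirnas)
    nKnown <- ceiling(cfg$nMirnas * cfg$knownFraction)
    for (i in seq_len(cfg$nMirnas)) {
      chromIdx <- ((i - 1L) %% cfg$nChromosomes) + 1L
      slot <- (i - 1L) %/% cfg$nChromosomes
      m <- sample(cfg$matureLengths, 1L)
      hp <- buildHairpin(m, cfg$loopLength, cfg$flankLength)
      arm <- if (i %% 2L == 1L) "5p" else "3p"
      preLen <- nchar(hp$precursor)
      start <- 50L + slot * (maxPre + 50L)
      end <- start + preLen - 1L
      substr(chroms[chromIdx], start, end) <- hp$precursor
      effect <- effects[((i - 1L) %% 3L) + 1L]
      abFree <- switch(effect, up = cfg$baseAbundance,
                       down = cfg$baseAbundance * cfg$effectFold,
                       unchanged = cfg$baseAbundance)
      abTreated <- switch(effect, up = cfg$baseAbundance * cfg$effectFold,
                          down = cfg$baseAbundance,
                          unchanged = cfg$baseAbundance)
      origin <- if (i <= nKnown) "known" else "novel"
      name <- if (origin == "known") sprintf("gso-miR%03d", i)
        else sprintf("PC-%d-%s", i, arm)
      rows[[i]] <- data.frame(
        name = name, chrom = names(chroms)[chromIdx],
        start = start, end = end, strand = "+", arm = arm,
        mature = if (arm == "5p") hp$seq5p else hp$seq3p,
        star = if (arm == "5p") hp$seq3p else hp$seq5p,
        precursor = hp$precursor,
        matureStart = if (arm == "5p") hp$span5p[1] else hp$span3p[1],
        matureEnd = if (arm == "5p") hp$span5p[2] else hp$span3p[2],
        starStart = if (arm == "5p") hp$span3p[1] else hp$span5p[1],
        starEnd = if (arm == "5p") hp$span3p[2] else hp$span5p[2],
        abundanceFree = abFree, abundanceTreated = abTreated,
        starFraction = cfg$starFraction, origin = origin, effect = effect,
        stringsAsFactors = FALSE
      )
    }
    planted <- do.call(rbind, rows)
  } else {
    planted <- data.frame(
      name = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), arm = character(),
      mature = character(), star = character(), precursor = character(),
      matureStart = integer(), matureEnd = integer(),
      starStart = integer(), starEnd = integer(),
      abundanceFree = numeric(), abundanceTreated = numeric(),
      starFraction = numeric(), origin = character(), effect = character(),
      stringsAsFactors = FALSE
    )
  }

  transcripts <- vapply(seq_len(cfg$nTranscripts),
                        function(i) scrubMotif(randomDNA(cfg$transcriptLength)),
                        character(1))
  names(transcripts) <- sprintf("TR%04d", seq_len(cfg$nTranscripts))

  nCl <- min(cfg$nCleavages, nrow(planted), cfg$nTranscripts)
  cleav <- data.frame(
    mirnaName = character(), transcriptId = character(), site = integer(),
    targetStart = integer(), targetEnd = integer(), peakReads = integer(),
    backgroundReads = integer(), intendedCategory = character(),
    stringsAsFactors = FALSE
  )
  if (nCl > 0) {
    rows <- vector("list", nCl)
    for (i in seq_len(nCl)) {
      mat <- planted$mature[i]
      m <- nchar(mat)
      site5p <- revComp(mat)      # perfect complement of the miRNA
      # two mismatches outside the core (miRNA positions 16 and 19):
      # miRNA position k pairs target-site offset m - k + 1
      for (k in c(16L, 19L)) {
        if (k <= m) {
          off <- m - k + 1L
          substr(site5p, off, off) <- mismatchBase(substr(mat, k, k))
        }
      }
      tstart <- 60L + (i * 13L) %% (cfg$transcriptLength - m - 100L)
      tend <- tstart + m - 1L
      substr(transcripts[i], tstart, tend) <- site5p
      transcripts[i] <- scrubMotif(transcripts[i])
      site <- tstart + m - 10L    # base paired with miRNA position 10
      rows[[i]] <- data.frame(
        mirnaName = planted$name[i], transcriptId = names(transcripts)[i],
        site = site, targetStart = tstart, targetEnd = tend,
        peakReads = cfg$peakReads, backgroundReads = cfg$backgroundReads,
        intendedCategory = "I", stringsAsFactors = FALSE
      )
    }
    cleav <- do.call(rbind, rows)
  }

  known <- planted[planted$origin == "known",
                   c("name", "mature", "precursor", "arm")]
  rownames(known) <- NULL
  decoys <- function(n) {
    Biostrings::DNAStringSet(vapply(seq_len(max(n, 0L)),
                                    function(i) randomDNA(cfg$decoyLength),
                                    character(1)))
  }
  bundle <- new("ReferenceBundle",
    genome = Biostrings::DNAStringSet(chroms),
    transcriptome = Biostrings::DNAStringSet(transcripts),
    knownMiRNAs = known,
    ncrnaDecoys = decoys(cfg$nNcrnaDecoys),
    repeatDecoys = decoys(cfg$nRepeatDecoys)
  )
  list(bundle = bundle, plantedMiRNAs = planted, plantedCleavages = cleav,
       config = cfg)
}

#' Simulate a small-RNA sequencing library
#'
#' Draws Poisson read counts around each planted miRNA's expected abundance
#' for the requested condition (and around `starFraction * abundance` for
#' the star strand), then emits fixed-length reads consisting of the mature
#' (or star) sequence followed by the 3' adapter, truncated to the read
#' length. A fraction of reads lacks the adapter (random filler instead)
#' and a fraction is junk (homopolymer or dinucleotide-repeat inserts that
#' still carry the adapter), drawn per read.
#'
#' RNG order for a fixed seed: (1) mature counts `rpois` in planted-table
#' order, (2) star counts `rpois` in the same order, (3) per-read noise
#' assignment and filler generation in read order.
#'
#' @param reference Output of [generateReference()].
#' @param condition `"free"` or `"treated"`.
#' @param junkFraction,adapterlessFraction Per-read noise probabilities.
#' @param seed Integer seed for this library.
#' @return A [Biostrings::DNAStringSet] of reads with metadata columns
#'   recording the seeded per-miRNA mature and star counts
#'   (`S4Vectors::metadata(x)$matureCounts`, `$starCounts`).
#' @export
simulateSrnaLibrary <- function(reference, condition = c("free", "treated"),
                                junkFraction = 0, adapterlessFraction = 0,
                                seed = 1L) {
  condition <- match.arg(condition)
  cfg <- reference$config
  planted <- reference$plantedMiRNAs
  stopifnot(junkFraction >= 0, adapterlessFraction >= 0,
            junkFraction + adapterlessFraction <= 1)
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)

  lambda <- if (condition == "free") planted$abundanceFree
            else planted$abundanceTreated
  matureCounts <- if (nrow(planted)) rpois(nrow(planted), lambda) else integer()
  starCounts <- if (nrow(planted))
    rpois(nrow(planted), planted$starFraction * lambda) else integer()

  inserts <- c(rep(planted$mature, matureCounts),
               rep(planted$star, starCounts))
  n <- length(inserts)
  reads <- character(n)
  noise <- junkFraction + adapterlessFraction
  for (i in seq_len(n)) {
    u <- if (noise > 0) runif(1) else 1
    if (u < junkFraction) {
      base <- sample(DNA_BASES, 2L)
      insert <- if (runif(1) < 0.5) strrep(base[1], 20L)
        else strrep(paste0(base[1], base[2]), 10L)
      read <- paste0(insert, cfg$adapter)
    } else if (u < noise) {
      read <- paste0(inserts[i], randomDNA(cfg$readLength))
    } else {
      read <- paste0(inserts[i], cfg$adapter, randomDNA(cfg$readLength))
    }
    reads[i] <- substr(read, 1L, cfg$readLength)
  }
  out <- Biostrings::DNAStringSet(reads)
  if (n) names(out) <- sprintf("sr_%s_%06d", condition, seq_len(n))
  S4Vectors::metadata(out) <- list(matureCounts = matureCounts,
                                   starCounts = starCounts,
                                   condition = condition)
  out
}

#' Simulate a degradome (PARE) sequencing library
#'
#' For every planted cleavage, emits `peakReads` tags whose 5' end is the
#' planted site and `backgroundReads` tags at uniform positions along the
#' same transcript. Each read is the transcript-derived tag followed by the
#' CAGCAG adaptor and random filler, truncated to the read length.
#'
#' @param reference Output of [generateReference()].
#' @param seed Integer seed.
#' @param adaptor Adaptor motif appended after the tag.
#' @return A [Biostrings::DNAStringSet] of degradome reads.
#' @export
simulateDegradomeLibrary <- function(reference, seed = 1L,
                                     adaptor = "CAGCAG") {
  cfg <- reference$config
  cleav <- reference$plantedCleavages
  txs <- as.character(refTranscriptome(reference$bundle))
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)

  tagLen <- cfg$tagLength
  reads <- character(0)
  for (i in seq_len(nrow(cleav))) {
    tx <- txs[[cleav$transcriptId[i]]]
    site <- cleav$site[i]
    if (site + tagLen - 1L > nchar(tx))
      stop("cleavage site + tag length exceeds transcript end for ",
           cleav$transcriptId[i])
    peakTag <- substr(tx, site, site + tagLen - 1L)
    reads <- c(reads, rep(peakTag, cleav$peakReads[i]))
    nb <- cleav$backgroundReads[i]
    if (nb > 0) {
      pos <- sample.int(nchar(tx) - tagLen + 1L, nb, replace = TRUE)
      reads <- c(reads, substring(tx, pos, pos + tagLen - 1L))
    }
  }
  full <- vapply(reads, function(tag) {
    substr(paste0(tag, adaptor, randomDNA(cfg$readLength)),
           1L, max(cfg$readLength, tagLen + nchar(adaptor)))
  }, character(1), USE.NAMES = FALSE)
  out <- Biostrings::DNAStringSet(full)
  if (length(out)) names(out) <- sprintf("dg_%06d", seq_along(out))
  out
}
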