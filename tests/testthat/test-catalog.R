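mutateAt <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

test_that("known-miRNA matching enforces the two-mismatch cap and tie rules", {
  ref <- .sharedRef()
  km <- knownMiRNAs(ref$bundle)
  mature <- km$mature[1]

  hit <- matchKnown(mature, km)
  expect_equal(hit$name, km$name[1])
  expect_equal(hit$mismatches, 0L)

  two <- mutateAt(mature, c(8, 12))
  hit <- matchKnown(two, km)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mismatches, 2L)

  three <- mutateAt(mature, c(8, 12, 16))
  expect_equal(nrow(matchKnown(three, km)), 0L)

  # tie: a sequence 0 mismatches from one reference and 2 from another
  # fabricated reference takes the 0-mismatch name
  km2 <- rbind(km[1, ], km[1, ])
  km2$name <- c("zzz-exact", "aaa-mutant")
  km2$mature[2] <- mutateAt(mature, c(3, 5))
  km2$precursor[2] <- gsub(mature, km2$mature[2], km2$precursor[2],
                           fixed = TRUE)
  hit <- matchKnown(mature, km2)
  expect_equal(hit$name, "zzz-exact")
  expect_equal(hit$mismatches, 0L)

  expect_error(matchKnown(mature, km[0, ]), "empty")
})

test_that("matching never assigns above the mismatch cap (fuzz)", {
  ref <- .sharedRef()
  km <- knownMiRNAs(ref$bundle)
  set.seed(31)
  nAssigned <- 0L
  for (rep in 1:40) {
    q <- if (rep %% 2 == 0) {
      # mutated copy of a real mature: 0-4 substitutions
      mutateAt(km$mature[sample(nrow(km), 1)],
               sample(16, sample(0:4, 1)))
    } else {
      randomSeq(sample(16:25, 1))   # random queries almost never match
    }
    res <- matchKnown(q, km, maxMismatch = 2)
    if (nrow(res)) {
      nAssigned <- nAssigned + 1L
      expect_lte(res$mismatches, 2L)
      # recount against the assigned reference directly
      r <- km[km$name == res$name, ]
      dPre <- min(vapply(
        seq_len(nchar(r$precursor) - nchar(q) + 1), function(off)
          sum(strsplit(q, "")[[1]] !=
              strsplit(substr(r$precursor, off, off + nchar(q) - 1),
                       "")[[1]]),
        numeric(1)))
      expect_equal(res$mismatches, as.integer(dPre))
    }
  }
  expect_gt(nAssigned, 5L)
})

test_that("precursor windows cover the flank and respect strand", {
  ref <- .sharedRef()
  genome <- refGenome(ref$bundle)
  hit <- data.frame(chrom = names(genome)[1], start = 500L, end = 521L,
                    strand = "+", stringsAsFactors = FALSE)
  wins <- extractPrecursor(genome, hit, flank = 120L, pad = 10L)
  expect_equal(min(wins$start), 380L)
  expect_equal(max(wins$end), 641L)        # 521 + 120
  expect_equal(wins$sequence[1],
               substr(as.character(genome[[1]]), wins$start[1], wins$end[1]))

  # clamped at the chromosome start
  hit2 <- transform(hit, start = 10L, end = 31L)
  wins2 <- extractPrecursor(genome, hit2, flank = 120L)
  expect_equal(min(wins2$start), 1L)

  # minus-strand windows come back reverse-complemented
  hit3 <- transform(hit, strand = "-")
  wins3 <- extractPrecursor(genome, hit3, flank = 120L)
  plus <- substr(as.character(genome[[1]]), wins3$start[1], wins3$end[1])
  expect_equal(wins3$sequence[1], unname(rcSeq(plus)))

  expect_error(extractPrecursor(genome, transform(hit, chrom = "nope")),
               "not found")
})

test_that("hairpin evaluation fails the right reasons", {
  ref <- .sharedRef()
  pm <- ref$plantedMiRNAs[1, ]
  cand <- buildPrecursorCandidate(pm$precursor,
                                  c(pm$matureStart, pm$matureEnd),
                                  c(pm$starStart, pm$starEnd))
  expect_true(evaluateHairpin(cand)$pass)

  # a mature straddling the terminal loop
  loopMid <- as.integer((pm$matureEnd + pm$starStart) / 2)
  straddle <- buildPrecursorCandidate(pm$precursor,
                                      c(loopMid - 10L, loopMid + 10L))
  ev <- evaluateHairpin(straddle)
  expect_false(ev$pass)
  expect_true("spans loop" %in% ev$reasons)

  # low MFEI fails with reason "mfei"
  weak <- new("PrecursorCandidate", sequence = cand@sequence,
              structure = cand@structure, dG = cand@dG,
              gcPercent = cand@gcPercent, mfei = 0.4,
              matureSpan = cand@matureSpan, starSpan = cand@starSpan)
  ev <- evaluateHairpin(weak)
  expect_false(ev$pass)
  expect_equal(ev$reasons, "mfei")

  expect_error(evaluateHairpin(
    buildPrecursorCandidate(pm$precursor, c(1L, 20L)) |>
      (\(x) { x@matureSpan <- c(1L, 10000L); x })()), "outside")
})

test_that("star strands are detected near the predicted star position", {
  ref <- .sharedRef()
  pm <- ref$plantedMiRNAs
  free <- simulateSrnaLibrary(ref, "free", seed = 77)
  cs <- cleanReads(as.character(free), ref$config$adapter)
  counts <- uniqueCounts(cs)
  i <- 1L
  cand <- buildPrecursorCandidate(pm$precursor[i],
                                  c(pm$matureStart[i], pm$matureEnd[i]))
  st <- detectStarStrand(cand, counts, name = pm$name[i])
  expect_false(is.null(st))
  expect_equal(st$starName,
               paste0(pm$name[i], "-", if (pm$arm[i] == "5p") "p3" else "p5"))
  # star reads within the binomial 99% CI of starFraction * mature draws
  lambda <- pm$starFraction[i] * pm$abundanceFree[i]
  expect_gt(st$starCount, lambda - 2.576 * sqrt(lambda) - 1)
  expect_lt(st$starCount, lambda + 2.576 * sqrt(lambda) + 1)
  expect_false(st$starExceedsMature)

  # no star reads -> zero count
  onlyMature <- counts[names(counts) == pm$mature[i]]
  st0 <- detectStarStrand(cand, onlyMature, name = pm$name[i])
  expect_equal(st0$starCount, 0)

  # star more abundant than mature raises the flag
  inflated <- counts
  inflated[names(inflated) == pm$star[i]] <- 10 * sum(counts)
  stF <- detectStarStrand(cand, inflated, name = pm$name[i])
  expect_true(stF$starExceedsMature)
})

test_that("duplex overhang check demands exact 2-nt 3' overhangs", {
  ref <- .sharedRef()
  pm <- ref$plantedMiRNAs[2, ]
  cand <- buildPrecursorCandidate(pm$precursor,
                                  c(pm$matureStart, pm$matureEnd),
                                  c(pm$starStart, pm$starEnd))
  expect_true(checkDuplexOverhang(cand@structure, cand@matureSpan,
                                  cand@starSpan)$passesOverhang)
  # star shifted by 1 nt fails at zero tolerance, passes at 1
  shifted <- cand@starSpan + 1L
  expect_false(checkDuplexOverhang(cand@structure, cand@matureSpan,
                                   shifted)$passesOverhang)
  expect_true(checkDuplexOverhang(cand@structure, cand@matureSpan,
                                  shifted, tolerance = 1L)$passesOverhang)
  # blunt-ended duplex (spans trimmed to the paired stem) fails
  blunt <- c(cand@matureSpan[1], cand@matureSpan[2] - 2L)
  bluntStar <- c(cand@starSpan[1], cand@starSpan[2] - 2L)
  expect_false(checkDuplexOverhang(cand@structure, blunt,
                                   bluntStar)$passesOverhang)
  expect_error(checkDuplexOverhang(cand@structure, c(10L, 40L),
                                   c(30L, 60L)), "overlap")
})

test_that("planted novel miRNAs are recovered by hairpin discovery", {
  ref <- .sharedRef()
  novel <- ref$plantedMiRNAs[ref$plantedMiRNAs$origin == "novel", ]
  disc <- discoverNovelMirnas(novel$mature, ref$bundle)
  expect_setequal(disc$sequence, novel$mature)
  expect_true(all(disc$mfei >= 0.5))
  expect_true(all(disc$locusCount == 1L))
  # reported arm matches the planted arm
  arm <- setNames(novel$arm, novel$mature)
  expect_identical(unname(arm[disc$sequence]), disc$arm)
})
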