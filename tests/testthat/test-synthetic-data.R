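test_that("reference generation is deterministic and respects ground-truth closure", {
  cfg <- syntheticConfig(seed = 1, nMirnas = 5)
  a <- generateReference(cfg)
  b <- generateReference(cfg)
  expect_identical(as.character(refGenome(a$bundle)),
                   as.character(refGenome(b$bundle)))
  expect_identical(a$plantedMiRNAs, b$plantedMiRNAs)
  expect_identical(a$plantedCleavages, b$plantedCleavages)

  pm <- a$plantedMiRNAs
  expect_equal(nrow(pm), 5)
  genome <- as.character(refGenome(a$bundle))
  for (i in seq_len(nrow(pm))) {
    expect_true(grepl(pm$mature[i], pm$precursor[i], fixed = TRUE))
    # precursor is an exact substring of exactly one chromosome
    hits <- vapply(genome, function(chr)
      length(gregexpr(pm$precursor[i], chr, fixed = TRUE)[[1]][
        gregexpr(pm$precursor[i], chr, fixed = TRUE)[[1]] > 0]),
      integer(1))
    expect_equal(sum(hits), 1L)
    # recorded locus matches
    expect_equal(substr(genome[[pm$chrom[i]]], pm$start[i], pm$end[i]),
                 pm$precursor[i])
  }
})

test_that("empty and infeasible generator configs are handled", {
  ref <- generateReference(syntheticConfig(seed = 1, nMirnas = 0))
  expect_equal(nrow(ref$plantedMiRNAs), 0)
  expect_gt(sum(Biostrings::width(refGenome(ref$bundle))), 0)
  expect_equal(nrow(ref$plantedCleavages), 0)

  expect_error(
    generateReference(syntheticConfig(seed = 1, nMirnas = 200,
                                      chromosomeLength = 1000,
                                      nChromosomes = 1)),
    "infeasible packing")
})

test_that("planted hairpins pass the default hairpin criteria", {
  ref <- .sharedRef()
  pm <- ref$plantedMiRNAs
  for (i in seq_len(nrow(pm))) {
    cand <- buildPrecursorCandidate(
      pm$precursor[i], c(pm$matureStart[i], pm$matureEnd[i]),
      c(pm$starStart[i], pm$starEnd[i]))
    ev <- evaluateHairpin(cand)
    expect_true(ev$pass, info = paste(pm$name[i], ":",
                                      paste(ev$reasons, collapse = ",")))
  }
})

test_that("simulated sRNA libraries reproduce the seeded Poisson draws", {
  ref <- .sharedRef()
  lib <- simulateSrnaLibrary(ref, "free", seed = 99)
  pm <- ref$plantedMiRNAs

  # independent re-draw with the documented RNG order
  set.seed(99)
  expCounts <- rpois(nrow(pm), pm$abundanceFree)
  expect_identical(S4Vectors::metadata(lib)$matureCounts, expCounts)

  # at zero noise, observed mature counts equal the draws exactly
  reads <- as.character(lib)
  for (i in seq_len(nrow(pm))) {
    obs <- sum(startsWith(reads, paste0(pm$mature[i],
                                        substr(ref$config$adapter, 1, 6))))
    expect_equal(obs, expCounts[i], info = pm$name[i])
  }

  # zero-noise reads all contain the adapter motif
  expect_true(all(grepl(substr(ref$config$adapter, 1, 8), reads,
                        fixed = TRUE)))

  # determinism
  lib2 <- simulateSrnaLibrary(ref, "free", seed = 99)
  expect_identical(as.character(lib), as.character(lib2))
})

test_that("planted four-fold effects survive Poisson sampling at depth", {
  ref <- .sharedRef()
  free <- simulateSrnaLibrary(ref, "free", seed = 5)
  treated <- simulateSrnaLibrary(ref, "treated", seed = 6)
  pm <- ref$plantedMiRNAs
  cf <- S4Vectors::metadata(free)$matureCounts
  ct <- S4Vectors::metadata(treated)$matureCounts
  up <- pm$effect == "up"
  lfc <- log2(ct[up] / cf[up])
  expect_true(all(lfc > 1.5 & lfc < 2.5))
  down <- pm$effect == "down"
  lfc <- log2(ct[down] / cf[down])
  expect_true(all(lfc > -2.5 & lfc < -1.5))
})

test_that("degradome simulation plants peaks at the recorded sites", {
  ref <- .sharedRef()

  # background-free library: single nonzero position per transcript
  ref0 <- ref
  ref0$plantedCleavages$backgroundReads <- 0L
  lib <- simulateDegradomeLibrary(ref0, seed = 3)
  proc <- processDegradomeReads(as.character(lib))
  expect_equal(proc$dropped, 0)
  mapping <- mapTags(proc$tags, refTranscriptome(ref$bundle))
  cl <- ref$plantedCleavages
  for (i in seq_len(nrow(cl))) {
    prof <- mapping$profiles[[cl$transcriptId[i]]]
    occupied <- which(profileAbundance(prof) > 0)
    expect_equal(occupied, cl$site[i])
    expect_equal(profileAbundance(prof)[cl$site[i]], cl$peakReads[i])
  }

  # with background, planted category-I geometry classifies as I
  lib2 <- simulateDegradomeLibrary(ref, seed = 3)
  proc2 <- processDegradomeReads(as.character(lib2))
  mapping2 <- mapTags(proc2$tags, refTranscriptome(ref$bundle))
  for (i in seq_len(nrow(cl))) {
    prof <- mapping2$profiles[[cl$transcriptId[i]]]
    expect_equal(classifyCategory(prof, cl$site[i]), "I",
                 info = cl$transcriptId[i])
  }

  # zero cleavages -> empty profile set
  refEmpty <- generateReference(syntheticConfig(seed = 2, nMirnas = 0))
  libE <- simulateDegradomeLibrary(refEmpty, seed = 1)
  expect_length(libE, 0)

  # site + tag length beyond transcript end is an error
  refBad <- ref
  refBad$plantedCleavages$site[1] <-
    nchar(as.character(refTranscriptome(ref$bundle))[[
      refBad$plantedCleavages$transcriptId[1]]]) - 5L
  expect_error(simulateDegradomeLibrary(refBad, seed = 1), "exceeds")
})
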