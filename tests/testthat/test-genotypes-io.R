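test_that("wide CSV parsing handles full, partial and missing cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "individual,population,LocA,LocB",
    "i1,p1,150/153/153/156,200/200/200/200",
    "i2,p1,150/156,",
    "i3,p2,153/153/153/153,204/208"
  ), f)
  gm <- readGenotypes(f, "wide")
  expect_s4_class(gm, "SsrGenotypes")
  expect_equal(genotypeAt(gm, "i1", "LocA"), c(150L, 153L, 153L, 156L))
  expect_true(dosageKnown(genotypeAt(gm, "i1", "LocA")))
  expect_equal(genotypeAt(gm, "i2", "LocA"), c(150L, 156L))
  expect_false(dosageKnown(genotypeAt(gm, "i2", "LocA")))
  expect_identical(genotypeAt(gm, "i2", "LocB"), integer(0))  # missing
  expect_equal(nInd(gm), 3L)
  expect_equal(nLoc(gm), 2L)
})

test_that("long CSV parsing accumulates allele copies with multiplicity", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "individual,population,locus,allele",
    "i1,p1,LocA,150", "i1,p1,LocA,153", "i1,p1,LocA,153", "i1,p1,LocA,156",
    "i2,p1,LocA,150"
  ), f)
  gm <- readGenotypes(f, "long")
  expect_equal(genotypeAt(gm, "i1", "LocA"), c(150L, 153L, 153L, 156L))
  expect_equal(genotypeAt(gm, "i2", "LocA"), 150L)
})

test_that("unparseable cells warn and become missing; duplicates are fatal", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,population,LocA",
               "i1,p1,150/xx", "i2,p1,150/150/150/150"), f)
  expect_warning(gm <- readGenotypes(f, "wide"), "unparseable")
  expect_identical(genotypeAt(gm, "i1", "LocA"), integer(0))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,population,LocA", "i1,p1,150", "i1,p1,153"), f2)
  expect_error(readGenotypes(f2, "wide"), "duplicate")
})

test_that("alleles outside the declared locus size range fail validation", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,population,LocA", "i1,p1,150", "i2,p1,500"), f)
  loci <- data.frame(name = "LocA", motifLength = 3, sizeMin = 140,
                     sizeMax = 200)
  expect_error(readGenotypes(f, "wide", loci = loci), "size range")
})

test_that("genotype wide CSV round-trips", {
  gm <- makeGenotypes(list(i1 = list(c(150, 153, 153, 156), c(200, 204)),
                           i2 = list(c(150, 150, 150, 150), integer(0))),
                      population = c("p1", "p2"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeGenotypes(gm, f)
  back <- readGenotypes(f, "wide")
  expect_identical(back@genotypes, gm@genotypes)
  expect_equal(as.character(populations(back)), as.character(populations(gm)))
})

test_that("dominant recoding follows band definitions", {
  gm <- makeGenotypes(list(i1 = list(c(150, 153)), i2 = list(c(153, 156))),
                      population = c("p1", "p1"))
  dm <- toDominant(gm)
  expect_equal(ncol(bandValues(dm)), 3L)
  expect_equal(unname(bandValues(dm)[1, ]), c(1L, 1L, 0L))
  expect_equal(unname(bandValues(dm)[2, ]), c(0L, 1L, 1L))
  expect_equal(bandInfo(dm)$size, c(150, 153, 156))
})

test_that("missing genotypes mask that locus' bands; monomorphic locus is one band", {
  gm <- makeGenotypes(list(i1 = list(c(150, 153), c(200, 200, 200, 200)),
                           i2 = list(integer(0), c(200, 200, 200, 200))),
                      population = c("p1", "p1"))
  dm <- toDominant(gm)
  l1 <- bandInfo(dm)$locus == "L1"
  expect_true(all(is.na(bandValues(dm)[2, l1])))
  expect_equal(sum(bandInfo(dm)$locus == "L2"), 1L)
  expect_equal(unname(bandValues(dm)[, !l1]), c(1L, 1L))
})

test_that("dominant recoding preserves the distinct allele sets (information idempotence)", {
  set.seed(5)
  sim <- simulateHierarchical(simulationConfig(ambiguityRate = 0.3), seed = 5)
  dm <- toDominant(sim$genotypes)
  g <- sim$genotypes@genotypes
  bi <- bandInfo(dm)
  for (i in sample(nInd(sim$genotypes), 10)) {
    for (l in colnames(g)) {
      sel <- bi$locus == l
      got <- bi$size[sel][which(bandValues(dm)[i, sel] == 1L)]
      expect_equal(sort(got), sort(unique(g[[i, l]])))
    }
  }
})

test_that("band count per locus equals the pooled allele count from the diversity module", {
  sim <- simulateHierarchical(simulationConfig(), seed = 9)
  dm <- toDominant(sim$genotypes)
  ft <- alleleFrequencies(sim$genotypes)
  pooled <- alleleCounts(ft)$pooledPerLocus
  bands <- table(bandInfo(dm)$locus)[names(pooled)]
  expect_equal(as.numeric(bands), as.numeric(pooled))
})

test_that("small-population filtering removes and reports, preserving genotypes", {
  cells <- c(
    lapply(1:7, function(i) list(c(150, 153, 153, 156))),
    lapply(1:2, function(i) list(c(159, 162)))
  )
  names(cells) <- paste0("i", 1:9)
  gm <- makeGenotypes(cells, population = c(rep("big", 7), rep("small", 2)))
  out <- filterSmallPopulations(gm, minN = 6)
  expect_equal(levels(populations(out)), "big")
  expect_equal(out@metadata$removedPopulations$population, "small")
  expect_identical(out@genotypes, gm@genotypes[1:7, , drop = FALSE])
  # identity and failure modes
  expect_identical(filterSmallPopulations(gm, 1L)@genotypes, gm@genotypes)
  expect_error(filterSmallPopulations(gm, 100L), "all populations")
})

test_that("STRUCTURE export round-trips including missing cells", {
  gm <- makeGenotypes(list(i1 = list(c(150, 153), c(200, 204)),
                           i2 = list(c(153, 156), integer(0))),
                      population = c("p1", "p2"))
  dm <- toDominant(gm)
  f <- withr::local_tempfile(fileext = ".str")
  writeStructureFile(dm, f)
  lines <- readLines(f)
  expect_length(lines, 3L)        # header + 2 individuals
  expect_match(lines[3], "-9")    # masked cell token
  back <- readStructureFile(f, populationLevels = levels(populations(dm)))
  expect_identical(bandValues(back), bandValues(dm))
  expect_equal(as.character(populations(back)), as.character(populations(dm)))
})

test_that("repeat-count conversion warns on off-lattice sizes", {
  expect_identical(sizesToRepeats(c(150, 156), 3, 150), c(0L, 2L))
  expect_warning(sizesToRepeats(c(150, 152), 3, 150), "lattice")
  expect_error(sizesToRepeats(150, NA, 150), "motifLength")
})
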