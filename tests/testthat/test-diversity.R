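test_that("allele frequencies follow the dosage policy", {
  gm <- makeGenotypes(list(i1 = list(c(150, 150, 153, 153))),
                      population = "p1")
  ft <- alleleFrequencies(gm)
  expect_equal(unname(freqVector <- ft$counts$p1$L1 / sum(ft$counts$p1$L1)),
               c(0.5, 0.5))
  expect_equal(ft$copies["p1", "L1"], 4)

  # ambiguous cell under equal-split: each allele gets 2 copies
  gm2 <- makeGenotypes(list(i1 = list(c(150, 153))), population = "p1")
  ft2 <- alleleFrequencies(gm2, "equal-split")
  expect_equal(unname(ft2$counts$p1$L1), c(2, 2))
  # known-only drops the ambiguous cell entirely
  ft3 <- alleleFrequencies(gm2, "known-only")
  expect_length(ft3$counts$p1$L1, 0)
  expect_equal(ft3$copies["p1", "L1"], 0)
  expect_match(attr(ft3, "empty"), "p1:L1")

  gm4 <- makeGenotypes(list(i1 = list(rep(150, 4)), i2 = list(rep(153, 4))),
                       population = c("p1", "p1"))
  ft4 <- alleleFrequencies(gm4)
  expect_equal(unname(ft4$counts$p1$L1) / 8, c(0.5, 0.5))
  expect_equal(ft4$copies["p1", "L1"], 8)
})

test_that("gene diversity matches the unbiased closed form", {
  # two alleles at 0.5 with 8 copies: (8/7) * 0.5
  gm <- makeGenotypes(list(i1 = list(rep(150, 4)), i2 = list(rep(153, 4))),
                      population = c("p1", "p1"))
  he <- geneDiversity(alleleFrequencies(gm))
  expect_equal(unname(he$perLocus["p1", "L1"]), 8 / 7 * 0.5, tolerance = 1e-12)
  # monomorphic locus
  gm2 <- makeGenotypes(list(i1 = list(rep(150, 4)), i2 = list(rep(150, 4))),
                       population = c("p1", "p1"))
  expect_equal(unname(geneDiversity(alleleFrequencies(gm2))$perLocus[1, 1]), 0)
})

test_that("rarefied allelic richness matches exhaustive subsample enumeration", {
  # counts {A:3, B:1}, N = 4 copies, g = 2:
  # enumerate all C(4,2) = 6 subsamples of the 4 copies -> mean allele count
  copies <- c("A", "A", "A", "B")
  pairs <- combn(4, 2)
  enum <- mean(apply(pairs, 2, function(ix) length(unique(copies[ix]))))
  gm <- makeGenotypes(list(i1 = list(c(150, 150, 150, 153))),
                      population = "p1")
  ar <- allelicRichness(alleleFrequencies(gm), g = 2)
  expect_equal(unname(ar$perLocus["p1", "L1"]), enum, tolerance = 1e-12)
  expect_equal(enum, 1.5)

  # g = N: no rarefaction, AR equals the observed allele count
  ar4 <- allelicRichness(alleleFrequencies(gm), g = 4)
  expect_equal(unname(ar4$perLocus["p1", "L1"]), 2)

  # monotone non-decreasing in g, and AR < NA when an allele is rare
  gm2 <- makeGenotypes(list(i1 = list(c(150, 150, 150, 150)),
                            i2 = list(c(150, 150, 150, 153))),
                       population = c("p1", "p1"))
  ft2 <- alleleFrequencies(gm2)
  ars <- vapply(2:8, function(g) allelicRichness(ft2, g)$perLocus[1, 1], 0)
  expect_true(all(diff(ars) >= -1e-12))
  expect_lt(ars[1], 2)
  expect_error(allelicRichness(ft2, g = 1), ">= 2")
})

test_that("total gene diversity behaves at the limit cases", {
  # identical frequencies in both populations: HT ~ mean He
  gm <- makeGenotypes(list(i1 = list(c(150, 150, 153, 153)),
                           i2 = list(c(150, 150, 153, 153)),
                           i3 = list(c(150, 150, 153, 153)),
                           i4 = list(c(150, 150, 153, 153))),
                      population = c("p1", "p1", "p2", "p2"))
  ft <- alleleFrequencies(gm)
  ht <- totalGeneDiversity(ft)$multilocus
  he <- mean(geneDiversity(ft)$perPopulation)
  # the small-sample correction term makes HT undershoot He by at most
  # He/(harmonic copies) when populations are identical
  expect_equal(ht, he, tolerance = 0.08)
  expect_gte(ht, he - he / 8)

  # two populations fixed for different alleles: 1 - sum(0.5^2) = 0.5 + correction
  gm2 <- makeGenotypes(list(i1 = list(rep(150, 4)), i2 = list(rep(150, 4)),
                            i3 = list(rep(153, 4)), i4 = list(rep(153, 4))),
                       population = c("p1", "p1", "p2", "p2"))
  ft2 <- alleleFrequencies(gm2)
  # He = 0 within, harmonic copies = 8: HT = 0.5 + 0/(8*2) = 0.5 exactly
  expect_equal(totalGeneDiversity(ft2)$multilocus, 0.5, tolerance = 1e-12)
})

test_that("private alleles count only single-population alleles and sum to the total", {
  gm <- makeGenotypes(
    list(i1 = list(c(150, 153)), i2 = list(c(150, 156)),
         i3 = list(c(150, 159))),
    population = c("p1", "p2", "p3"))
  pa <- privateAlleles(alleleFrequencies(gm))
  # 150 shared by all three: private for none; 153/156/159 private
  expect_equal(unname(pa$counts), c(1, 1, 1))
  expect_equal(unname(pa$perPopulation), rep(100 / 4, 3))
  expect_equal(pa$total, sum(pa$perPopulation))

  gm2 <- makeGenotypes(list(i1 = list(c(150, 153)), i2 = list(c(150, 153))),
                       population = c("solo", "other"))
  # both alleles in both populations: no private alleles anywhere
  expect_equal(sum(privateAlleles(alleleFrequencies(gm2))$counts), 0)
})

test_that("He and HT are invariant under allele and individual relabelling", {
  sim <- simulateHierarchical(simulationConfig(), seed = 3)
  gm <- sim$genotypes
  ft <- alleleFrequencies(gm)
  # shift all allele sizes at locus 1 by a constant (relabelling)
  g2 <- gm@genotypes
  for (i in seq_len(nrow(g2))) g2[[i, 1]] <- g2[[i, 1]] + 30L
  loci2 <- gm@loci
  loci2$sizeMin[1] <- loci2$sizeMin[1] + 30
  loci2$sizeMax[1] <- loci2$sizeMax[1] + 30
  perm <- sample(nrow(g2))
  gm2 <- SsrGenotypes(g2[perm, , drop = FALSE], loci2, gm@population[perm])
  ft2 <- alleleFrequencies(gm2)
  expect_equal(geneDiversity(ft2)$perPopulation, geneDiversity(ft)$perPopulation)
  expect_equal(totalGeneDiversity(ft2)$multilocus,
               totalGeneDiversity(ft)$multilocus)
})

test_that("inbreeding coefficient signs are forced by genotype composition", {
  # polymorphic population; i1 fully homozygous, i2 maximally heterozygous
  gm <- makeGenotypes(
    list(i1 = list(rep(150, 4)),
         i2 = list(c(150, 153, 156, 159)),
         i3 = list(c(150, 150, 153, 159)),
         i4 = list(c(153, 156, 159, 159))),
    population = rep("p1", 4))
  inb <- inbreedingCoefficients(gm, nPerm = 0)
  expect_gt(inb$fiIndividual[["i1"]], 0)
  expect_lt(inb$fiIndividual[["i2"]], 0)
})

test_that("estimated frequencies converge to the sampling frequencies", {
  set.seed(11)
  truth <- c(`100` = 0.4, `103` = 0.3, `106` = 0.2, `109` = 0.1)
  n <- 500
  cells <- lapply(seq_len(n), function(i)
    list(sort(sample(as.integer(names(truth)), 4, TRUE, truth))))
  names(cells) <- paste0("i", seq_len(n))
  gm <- makeGenotypes(cells, population = rep("p1", n))
  ft <- alleleFrequencies(gm)
  est <- ft$counts$p1$L1 / sum(ft$counts$p1$L1)
  expect_lt(mean(abs(est - truth[names(est)])), 0.02)
})

test_that("the permutation null for FIS is centred and calibrated", {
  # genotypes drawn under random union of gametes: FIS should be ~0 and the
  # permutation test should reject at about the nominal rate
  set.seed(21)
  rejections <- 0L
  nSim <- 40L
  for (s in seq_len(nSim)) {
    cells <- lapply(1:30, function(i)
      list(sort(sample(c(100L, 103L, 106L, 109L), 4, TRUE,
                       c(0.4, 0.3, 0.2, 0.1)))))
    names(cells) <- paste0("i", 1:30)
    gm <- makeGenotypes(cells, population = rep("p1", 30))
    inb <- inbreedingCoefficients(gm, nPerm = 99)
    if (inb$fisP <= 0.05) rejections <- rejections + 1L
  }
  # binomial(40, 0.05): P(X > 8) < 1e-4
  expect_lte(rejections, 8L)
})

test_that("diversity summary assembles a coherent per-population table", {
  sim <- simulateHierarchical(simulationConfig(), seed = 2)
  div <- diversitySummary(sim$genotypes, nPerm = 49)
  tab <- div$table
  expect_equal(sum(tab$N), 129L)
  expect_true(all(tab$He >= 0 & tab$He <= 1))
  expect_true(all(tab$AR <= tab$NA_ + 1e-9))
  expect_true(all(tab$Fi >= -1 & tab$Fi <= 1))
  expect_equal(sum(tab$Pa), div$totals$Pa_total, tolerance = 1e-9)
  expect_gte(div$totals$HT, mean(tab$He) - 1e-6)
})
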