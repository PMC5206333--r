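test_that("Bruvo pair distances match analytic values", {
  expect_equal(bruvoPair(c(150, 153, 153, 156), c(150, 153, 153, 156), 3), 0)
  # four copies one repeat apart: 1 - 2^-1 = 0.5
  expect_equal(bruvoPair(rep(150, 4), rep(153, 4), 3), 0.5)
  expect_true(is.na(bruvoPair(integer(0), rep(150, 4), 3)))
})

test_that("dosage-ambiguous Bruvo distances equal the completion average (brute force)", {
  cases <- list(
    list(g1 = c(150, 153), g2 = rep(150, 4)),
    list(g1 = c(150, 153), g2 = c(153, 156)),
    list(g1 = 150, g2 = c(150, 153, 156)),
    list(g1 = c(150, 153, 159), g2 = c(153, 153, 156, 162)),
    list(g1 = c(141, 162), g2 = c(150, 153, 156, 159))
  )
  for (cs in cases) {
    expect_equal(bruvoPair(cs$g1, cs$g2, 3),
                 oracleBruvoLocus(cs$g1, cs$g2, 3), tolerance = 1e-12)
  }
})

test_that("Bruvo matrix equals the exhaustive oracle on random small fixtures", {
  set.seed(31)
  for (rep in 1:3) {
    cells <- lapply(1:6, function(i) {
      lapply(1:3, function(l) {
        k <- sample(0:4, 1, prob = c(0.1, 0.15, 0.25, 0.25, 0.25))
        if (k == 0) integer(0) else
          sort(sample(seq(150, 177, by = 3), k, replace = (k == 4)))
      })
    })
    names(cells) <- paste0("i", 1:6)
    gm <- makeGenotypes(cells, population = rep("p1", 6))
    d <- bruvoMatrix(gm, allowMissing = TRUE)
    expect_equal(unclass(d)[1:6, 1:6], oracleBruvoMatrix(gm), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("Bruvo matrix is a bounded semimetric, invariant under reordering", {
  sim <- simulateHierarchical(simulationConfig(ambiguityRate = 0.2), seed = 6)
  keep <- sample(nInd(sim$genotypes), 20)
  gm <- SsrGenotypes(sim$genotypes@genotypes[keep, ], sim$genotypes@loci,
                     sim$genotypes@population[keep])
  d <- bruvoMatrix(gm)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d), ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 1))
  # clone pair (dosage-known: identical ambiguous cells average over
  # different completions and are legitimately > 0)
  simK <- simulateHierarchical(simulationConfig(), seed = 6)
  gK <- simK$genotypes@genotypes[1:5, , drop = FALSE]
  gK[1, ] <- gK[2, ]
  gmClone <- SsrGenotypes(gK, simK$genotypes@loci,
                          simK$genotypes@population[1:5])
  expect_equal(unname(bruvoMatrix(gmClone)[1, 2]), 0)
  # reordering permutes entries consistently
  perm <- sample(20)
  gmPerm <- SsrGenotypes(gm@genotypes[perm, ], gm@loci, gm@population[perm])
  expect_equal(unclass(bruvoMatrix(gmPerm)),
               unclass(d)[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Nei distance from band frequencies matches the closed form", {
  # identical frequency profiles -> 0
  v <- rbind(c(1L, 0L), c(1L, 1L), c(1L, 0L), c(1L, 1L))
  rownames(v) <- paste0("i", 1:4); colnames(v) <- c("L1.150", "L1.153")
  info <- data.frame(locus = "L1", size = c(150, 153))
  dm <- DominantMatrix(v, info, c("a", "a", "b", "b"))
  expect_equal(unname(neiDistance(dm)["a", "b"]), 0)

  # two-band toy: p1 = (1, 0.5), p2 = (0.5, 0.5); direct J-term evaluation
  v2 <- rbind(c(1L, 1L), c(1L, 0L), c(1L, 1L), c(0L, 0L))
  rownames(v2) <- paste0("i", 1:4); colnames(v2) <- c("L1.150", "L1.153")
  dm2 <- DominantMatrix(v2, info, c("a", "a", "b", "b"))
  p1 <- c(1, 0.5); p2 <- c(0.5, 0.5)
  j1 <- mean(p1^2 + (1 - p1)^2); j2 <- mean(p2^2 + (1 - p2)^2)
  j12 <- mean(p1 * p2 + (1 - p1) * (1 - p2))
  expect_equal(unname(neiDistance(dm2)["a", "b"]),
               -log(j12 / sqrt(j1 * j2)), tolerance = 1e-12)
})

test_that("disjoint single-band profiles hit the distance cap with a warning", {
  v <- rbind(1L, 1L, 0L, 0L)
  dim(v) <- c(4, 1); rownames(v) <- paste0("i", 1:4); colnames(v) <- "L1.150"
  # a lone all-zero band column is invalid; add a shared band
  v <- cbind(v, 1L)
  colnames(v) <- c("L1.150", "L1.153")
  info <- data.frame(locus = "L1", size = c(150, 153))
  dm <- DominantMatrix(v, info, c("a", "a", "b", "b"))
  # restrict to the disjoint band only by building a 1-band matrix where
  # population b carries a different band
  v3 <- rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 1L))
  rownames(v3) <- paste0("i", 1:4); colnames(v3) <- c("L1.150", "L1.153")
  dm3 <- DominantMatrix(v3, info, c("a", "a", "b", "b"))
  expect_warning(d <- neiDistance(dm3, cap = 10), "cap")
  expect_equal(unname(d["a", "b"]), 10)
})

test_that("Nei distance is invariant to band order and presence/absence flips", {
  set.seed(41)
  fx <- randomDominant(c(5, 6, 4), nBands = 10)
  d0 <- neiDistance(fx$dm)
  v <- bandValues(fx$dm)
  perm <- sample(ncol(v))
  dmPerm <- DominantMatrix(v[, perm], bandInfo(fx$dm)[perm, ],
                           populations(fx$dm))
  expect_equal(unclass(neiDistance(dmPerm)), unclass(d0), tolerance = 1e-12)
  vFlip <- v
  vFlip[, 3] <- 1L - vFlip[, 3]
  if (all(vFlip[, 3] == 0L)) vFlip[1, 3] <- 1L else {
    dmFlip <- DominantMatrix(vFlip, bandInfo(fx$dm), populations(fx$dm))
    expect_equal(unclass(neiDistance(dmFlip)), unclass(d0), tolerance = 1e-12)
  }
})

test_that("geographic distances follow the haversine closed form", {
  co <- data.frame(population = c("a", "b", "c", "d"),
                   lat = c(0, 0, 0, 10), lon = c(0, 1, 180, 20))
  d <- geographicMatrix(co)
  expect_equal(unname(d["a", "a"]), 0)
  # 1 degree of longitude on the equator
  expect_equal(unname(d["a", "b"]), 2 * pi * 6371000 / 360, tolerance = 1e-6)
  # antipodal points
  expect_equal(unname(d["a", "c"]), pi * 6371000, tolerance = 1e-6)
  co$lat[2] <- NA
  expect_error(geographicMatrix(co), "b")
})
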