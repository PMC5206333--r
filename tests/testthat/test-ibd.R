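symMat <- function(v, n, labels = paste0("p", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}

test_that("Mantel r is 1 for identical matrices and affine-invariant", {
  set.seed(91)
  a <- symMat(runif(45), 10)
  r <- mantelTest(a, a, nPerm = 99)
  expect_equal(r$r, 1)
  b <- 3.2 * a + 0.7
  diag(b) <- 0
  set.seed(1); r1 <- mantelTest(a, a, nPerm = 199)
  set.seed(1); r2 <- mantelTest(a, b, nPerm = 199)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p, r2$p)
  expect_error(mantelTest(a, symMat(rep(1, 45), 10)), "constant")
})

test_that("standard-scheme p-values match full enumeration for small n", {
  set.seed(92)
  a <- symMat(runif(15), 6)
  b <- symMat(runif(15), 6)
  exact <- mantelTest(a, b, exact = TRUE)
  expect_equal(exact$nPerm, factorial(6))
  # sampled p converges to the enumerated p
  set.seed(93)
  sampled <- mantelTest(a, b, nPerm = 9999)
  expect_lt(abs(sampled$p - exact$p), 0.03)
})

test_that("Mantel r agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(94)
  a <- symMat(runif(36), 9)
  b <- symMat(runif(36), 9)
  ours <- mantelTest(a, b, nPerm = 99)
  veg <- vegan::mantel(as.dist(a), as.dist(b), permutations = 99)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
})

test_that("stratified permutations stay within strata", {
  # strata structure: between-stratum pairs keep their ranks under any
  # within-stratum permutation, so a matrix that only separates strata has
  # a stratified p of 1
  n <- 8
  strata <- factor(rep(c("A", "B"), each = 4))
  a <- outer(strata, strata, `!=`) * 1 + 0
  diag(a) <- 0
  dimnames(a) <- list(paste0("p", 1:n), paste0("p", 1:n))
  set.seed(95)
  b <- a + symMat(runif(28, 0, 0.01), n)
  diag(b) <- 0
  res <- mantelTest(a, b, scheme = "stratified", nPerm = 199, strata = strata)
  expect_equal(res$p, 1)
})

test_that("type-I error is nominal and power high for planted IBD", {
  set.seed(96)
  nSim <- 120
  pvals <- replicate(nSim, {
    a <- symMat(runif(45), 10)
    b <- symMat(runif(45), 10)
    mantelTest(a, b, nPerm = 99)$p
  })
  rate <- mean(pvals <= 0.05)
  expect_lt(rate, 0.11)  # binomial(120, 0.05) upper tail
  powerHits <- replicate(40, {
    x <- runif(10)
    a <- as.matrix(dist(x)); dimnames(a) <- list(paste0("p", 1:10), paste0("p", 1:10))
    noise <- symMat(runif(45, 0, 0.25), 10)
    b <- a + noise
    mantelTest(a, b, nPerm = 99)$p <= 0.05
  })
  expect_gte(mean(powerHits), 0.95)
})

test_that("partial Mantel removes a confounding covariate", {
  set.seed(97)
  cv <- symMat(runif(45), 10)
  a <- 2 * cv + symMat(runif(45, 0, 0.05), 10)
  b <- -1.5 * cv + symMat(runif(45, 0, 0.05), 10)
  diag(a) <- diag(b) <- 0
  plain <- mantelTest(a, b, nPerm = 199)
  part <- mantelTest(a, b, scheme = "partial", nPerm = 199, covariate = cv)
  expect_lt(plain$r, -0.9)            # confounded correlation
  expect_lt(abs(part$r), 0.4)         # mostly gone after partialling
})

test_that("HIM/SSM protocol recovers the planted regime", {
  set.seed(98)
  # pure hierarchical: distances driven only by cluster membership
  clusters <- setNames(rep(c("c1", "c2", "c3"), each = 3), paste0("p", 1:9))
  ci <- clusterIndicatorMatrix(clusters)
  gen <- ci * 0.5 + symMat(runif(36, 0, 0.02), 9)
  diag(gen) <- 0
  geo <- symMat(runif(36, 10, 500), 9)
  him <- himSsmProtocol(gen, geo, clusters, nPerm = 499)
  expect_gt(him$p[2], 0.05)                       # stratified n.s.
  expect_lte(him$p[4], 0.05)                      # genetic ~ clusters | geo
  expect_equal(him$supports[2], "HIM")
  expect_equal(him$supports[4], "HIM")

  # pure stepping stone: distances driven only by geography
  x <- sort(runif(9))
  geo2 <- as.matrix(dist(x)) * 500
  dimnames(geo2) <- dimnames(gen)
  gen2 <- geo2 / 1000 + symMat(runif(36, 0, 0.05), 9)
  diag(gen2) <- 0
  ssm <- himSsmProtocol(gen2, geo2, clusters, nPerm = 499)
  expect_lte(ssm$p[3], 0.05)                      # genetic ~ geo | clusters
  expect_gt(ssm$r[3], 0.5)
  expect_equal(ssm$supports[3], "SSM")

  # degenerate single cluster: stratified equals the standard test and the
  # cluster-based test is undefined
  one <- setNames(rep("c1", 9), paste0("p", 1:9))
  deg <- himSsmProtocol(gen2, geo2, one, nPerm = 199)
  expect_equal(deg$r[1], deg$r[2])
  expect_true(is.na(deg$r[4]))
  expect_equal(deg$supports[4], "undefined")
})

test_that("beta regression recovers known coefficients", {
  set.seed(99)
  n <- 500
  x <- runif(n, -2, 2)
  mu <- plogis(-1 + 0.5 * x)
  y <- rbeta(n, mu * 30, (1 - mu) * 30)
  y <- pmin(pmax(y, 1e-6), 1 - 1e-6)
  fit <- fitBetaRegression(y, data.frame(x = x))
  est <- fit$coefficients$estimate
  se <- fit$coefficients$se
  expect_lt(abs(est[1] - (-1)) / se[1], 3)
  expect_lt(abs(est[2] - 0.5) / se[2], 3)
  expect_lt(abs(fit$phi - 30) / 30, 0.25)
  expect_lt(fit$gradientNorm, 1e-4)
  expect_equal(fit$aic, -2 * fit$logLik + 2 * fit$npar)
})

test_that("intercept-only fit on symmetric response centres at zero", {
  set.seed(100)
  y <- pmin(pmax(rbeta(200, 8, 8), 1e-6), 1 - 1e-6)
  fit <- fitBetaRegression(y)
  expect_lt(abs(fit$coefficients$estimate[1]), 0.1)
  expect_error(fitBetaRegression(c(0.5, 1.2)), "inside")
})

test_that("a pure-noise covariate rarely improves AIC by much", {
  set.seed(101)
  worse <- replicate(30, {
    n <- 80
    x <- runif(n)
    mu <- plogis(-0.5 + x)
    y <- pmin(pmax(rbeta(n, mu * 20, (1 - mu) * 20), 1e-6), 1 - 1e-6)
    f1 <- fitBetaRegression(y, data.frame(x = x))
    f2 <- fitBetaRegression(y, data.frame(x = x, junk = rnorm(n)))
    f2$aic - f1$aic
  })
  # adding one useless parameter costs ~2 AIC; improvements beyond 2 are rare
  expect_gte(mean(worse > -2), 0.9)
})

test_that("the response transformation lands strictly inside (0,1)", {
  d <- c(0, 0.2, 0.9, 3.7)
  y <- squeezeUnit(d)
  expect_true(all(y > 0 & y < 1))
  expect_equal(order(y), order(d))
  expect_equal(attr(y, "transform")$method, "minmax + Smithson-Verkuilen")
})

test_that("model ladders rank a real barrier effect above distance alone", {
  set.seed(102)
  co <- simulationConfig()$coords
  geo <- geographicMatrix(co)
  clusters <- setNames(rep(c("F", "P1", "P2", "T", "S"), c(1, 2, 2, 2, 2)),
                       co$population)
  straddle <- clusterIndicatorMatrix(clusters)
  hits <- replicate(20, {
    mu <- plogis(-1.5 + 0.002 * geo / 1000 + 1.2 * straddle)
    y <- matrix(0, 9, 9, dimnames = dimnames(geo))
    y[lower.tri(y)] <- rbeta(36, mu[lower.tri(mu)] * 40,
                             (1 - mu[lower.tri(mu)]) * 40)
    y <- y + t(y)
    lad <- buildModelLadder(y, geo, "structure-clusters", clusters)
    lad$best != 1
  })
  expect_gte(mean(hits), 0.9)
  # AIC ordering is invariant to the shared rescaling: refitting with a
  # linearly rescaled response keeps the same best model
  mu <- plogis(-1.5 + 0.002 * geo / 1000 + 1.2 * straddle)
  y <- matrix(0, 9, 9, dimnames = dimnames(geo))
  y[lower.tri(y)] <- rbeta(36, mu[lower.tri(mu)] * 40,
                           (1 - mu[lower.tri(mu)]) * 40)
  y <- y + t(y)
  l1 <- buildModelLadder(y, geo, "structure-clusters", clusters)
  l2 <- buildModelLadder(2 + 5 * y, geo, "structure-clusters", clusters)
  expect_equal(l1$best, l2$best)
  expect_equal(order(l1$aic), order(l2$aic))
})
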