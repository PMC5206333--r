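## synthetic tetraploid SSR datasets with known truth

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulation configuration
#'
#' Defaults emulate the study shape this package targets: 9 populations in
#' 5 island clusters (sizes 11, 13, 17, 13, 21, 13, 16, 19, 6; 129
#' individuals), 8 microsatellite loci with 10--31 alleles each on their
#' published motif lattices, hierarchical drift calibrated for a global
#' dominant-matrix Phi_ST near 0.45, and a heterozygote excess targeting a
#' multilocus FIS of about -0.19. Coordinates place the island clusters on
#' an Azores-like layout with sea gaps between islands.
#'
#' @param nLoci number of loci
#' @param allelesPerLocus alleles per locus (recycled)
#' @param motifLengths bp per repeat unit (recycled)
#' @param sizeMin minimum allele size per locus (recycled)
#' @param clusters named list cluster -> character vector of population
#'   names
#' @param individualsPerPopulation named or positional sizes
#' @param fCT cluster-level drift (Balding-Nichols F among clusters)
#' @param fSC population-level drift within clusters
#' @param fisTarget target multilocus inbreeding coefficient (negative =
#'   heterozygote excess)
#' @param ibdStrength stepping-stone spatial-divergence scale (0 = none)
#' @param barrierEffect extra effective distance (km) added across each
#'   planted barrier (stepping-stone model)
#' @param barrierGroups list of population sets; each set defines a planted
#'   barrier separating it from the rest
#' @param ambiguityRate fraction of cells reduced to their distinct allele
#'   set (dosage-ambiguous), default 0
#' @param coords population coordinates (data.frame population/lat/lon)
#' @export
simulationConfig <- function(
    nLoci = 8L,
    allelesPerLocus = c(18L, 15L, 31L, 15L, 15L, 18L, 10L, 17L),
    motifLengths = c(3L, 3L, 3L, 4L, 4L, 3L, 3L, 4L),
    sizeMin = c(150L, 230L, 230L, 230L, 160L, 240L, 140L, 300L),
    clusters = list(F = "FA1", P1 = c("PW1", "PW2"), P2 = c("PE1", "PE2"),
                    T = c("TE1", "TE2"), S = c("SM1", "SM2")),
    individualsPerPopulation = c(FA1 = 11L, PW1 = 13L, PW2 = 17L,
                                 PE1 = 13L, PE2 = 21L, TE1 = 13L,
                                 TE2 = 16L, SM1 = 19L, SM2 = 6L),
    fCT = 0.13, fSC = 0.02, fisTarget = -0.19,
    ibdStrength = 1, barrierEffect = 150,
    barrierGroups = list(c("SM1", "SM2")),
    ambiguityRate = 0,
    coords = data.frame(
      population = c("FA1", "PW1", "PW2", "PE1", "PE2", "TE1", "TE2",
                     "SM1", "SM2"),
      lat = c(38.58, 38.47, 38.45, 38.45, 38.43, 38.73, 38.70, 37.78, 37.76),
      lon = c(-28.72, -28.45, -28.40, -28.25, -28.18, -27.25, -27.20,
              -25.50, -25.45))) {
  pops <- unlist(clusters, use.names = FALSE)
  stopifnot(fCT >= 0, fCT < 1, fSC >= 0, fSC < 1,
            all(pops %in% names(individualsPerPopulation)),
            all(pops %in% coords$population))
  list(nLoci = nLoci,
       allelesPerLocus = rep_len(allelesPerLocus, nLoci),
       motifLengths = rep_len(motifLengths, nLoci),
       sizeMin = rep_len(sizeMin, nLoci),
       clusters = clusters,
       individualsPerPopulation = individualsPerPopulation,
       fCT = fCT, fSC = fSC, fisTarget = fisTarget,
       ibdStrength = ibdStrength, barrierEffect = barrierEffect,
       barrierGroups = barrierGroups, ambiguityRate = ambiguityRate,
       coords = coords)
}

clusterOfPop <- function(config) {
  cl <- config$clusters
  setNames(rep(names(cl), lengths(cl)), unlist(cl, use.names = FALSE))
}

drawGenotype <- function(sizes, freq, rho = 0) {
  counts <- drop(rmultinom(1L, 4L, freq))
  sort(rep(sizes, counts))
}

# heterozygote excess by copy swapping: genotypes at one population-locus
# are post-processed by exchanging duplicate gene copies between
# individuals until the mean within-individual identity Q_ind reaches
# Q_pop + fisTarget * (1 - Q_pop). Swaps permute copies of the fixed gene
# pool, so population allele frequencies are preserved exactly.
induceHeterozygoteExcess <- function(cells, fisTarget, maxSwaps = 10000L) {
  if (fisTarget >= 0) return(cells)
  n <- length(cells)
  if (n < 2) return(cells)
  stats <- function() {
    alleles <- sort(unique(unlist(cells)))
    w <- t(vapply(cells, function(a)
      as.numeric(table(factor(a, levels = alleles))), numeric(length(alleles))))
    C <- colSums(w)
    qp <- (sum(C^2) - sum(w^2)) / (16 * n * (n - 1))
    qi <- vapply(cells, function(a) { m <- table(a); sum(m * (m - 1)) / 12 }, 0)
    list(w = w, alleles = alleles, qp = qp, qi = qi)
  }
  for (it in seq_len(maxSwaps)) {
    s <- stats()
    if (s$qp >= 1 - 1e-12) break  # monomorphic
    target <- s$qp + fisTarget * (1 - s$qp)
    if (mean(s$qi) <= target + 1e-9) break
    i <- which.max(s$qi)
    if (s$qi[i] <= 0) break  # nobody has duplicates left
    mi <- table(cells[[i]])
    A <- as.numeric(names(mi)[which.max(mi)])
    lack <- setdiff(s$alleles, unique(cells[[i]]))
    if (!length(lack)) break
    # prefer partners that do not yet carry A (no duplicate created there)
    noA <- which(s$w[, match(A, s$alleles)] == 0)
    found <- FALSE
    for (j in sample(c(setdiff(noA, i), setdiff(seq_len(n), c(noA, i))))) {
      Bs <- intersect(unique(cells[[j]]), lack)
      if (!length(Bs)) next
      # favour taking a duplicated copy from the partner
      mj <- table(cells[[j]])
      Bs <- Bs[order(-as.numeric(mj[as.character(Bs)]))]
      B <- Bs[1]
      ci <- cells[[i]]; ci[match(A, ci)] <- as.integer(B)
      cj <- cells[[j]]; cj[match(B, cj)] <- as.integer(A)
      qiNew <- sum(table(ci) * (table(ci) - 1)) / 12 +
        sum(table(cj) * (table(cj) - 1)) / 12
      if (qiNew < s$qi[i] + s$qi[j]) {
        cells[[i]] <- sort(ci); cells[[j]] <- sort(cj)
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  cells
}

buildGenotypes <- function(config, popFreqs, lociSizes) {
  pops <- unlist(config$clusters, use.names = FALSE)
  nPer <- config$individualsPerPopulation[pops]
  inds <- unlist(lapply(pops, function(p) sprintf("%s_%02d", p, seq_len(nPer[[p]]))))
  popOf <- rep(pops, nPer[pops])
  L <- config$nLoci
  g <- matrix(list(), length(inds), L,
              dimnames = list(inds, paste0("L", seq_len(L))))
  for (p in pops) {
    rows <- which(popOf == p)
    for (l in seq_len(L)) {
      f <- popFreqs[[p]][[l]]
      cells <- lapply(rows, function(i)
        as.integer(drawGenotype(lociSizes[[l]], f)))
      cells <- induceHeterozygoteExcess(cells, config$fisTarget)
      for (k in seq_along(rows)) {
        cell <- cells[[k]]
        if (config$ambiguityRate > 0 && runif(1) < config$ambiguityRate)
          cell <- unique(cell)
        g[[rows[k], l]] <- cell
      }
    }
  }
  loci <- data.frame(
    name = paste0("L", seq_len(L)),
    motifLength = config$motifLengths,
    sizeMin = config$sizeMin,
    sizeMax = config$sizeMin + config$motifLengths *
      (config$allelesPerLocus - 1L))
  SsrGenotypes(g, loci, popOf,
               coords = config$coords[config$coords$population %in% pops, ,
                                      drop = FALSE])
}

#' Simulate a hierarchical-island tetraploid SSR dataset
#'
#' Ancestral allele frequencies per locus are drawn uniformly on the
#' simplex over a motif lattice of allele sizes; cluster frequencies drift
#' from them via the multi-allele Balding-Nichols Dirichlet
#' (concentration `p (1 - F)/F`); each cluster's drift is `fCT` scaled
#' inversely by its sample size (small island populations drift more; the
#' size-weighted mean equals `fCT`), and population frequencies
#' drift further with `fSC`. Tetraploid genotypes are 4 gene copies drawn
#' from the population frequencies; heterozygote excess is induced by
#' swapping duplicate gene copies between individuals (a permutation of the
#' realised gene pool, so allele frequencies are untouched) until the mean
#' within-individual identity reaches the `fisTarget` level. Fully
#' reproducible given `seed`.
#'
#' @param config from [simulationConfig()]
#' @param seed integer seed
#' @return list with `genotypes` (an [SsrGenotypes-class]) and `truth`
#'   (cluster labels, ancestral/cluster/population frequencies, config)
#' @export
simulateHierarchical <- function(config = simulationConfig(), seed = 1L) {
  set.seed(seed)
  L <- config$nLoci
  lociSizes <- lapply(seq_len(L), function(l)
    config$sizeMin[l] + config$motifLengths[l] *
      (0:(config$allelesPerLocus[l] - 1L)))
  ancestral <- lapply(seq_len(L), function(l)
    rdirichlet1(rep(1, config$allelesPerLocus[l])))
  drift <- function(p, F) if (F <= 0) p else rdirichlet1(p * (1 - F) / F)
  # per-cluster drift scales inversely with cluster sample size (smaller
  # island populations drift more); the size-weighted mean equals fCT, so
  # the global differentiation target is preserved
  clSize <- vapply(config$clusters, function(ps)
    sum(config$individualsPerPopulation[ps]), 0)
  fClust <- pmin(config$fCT * mean(clSize) / clSize, 0.6)
  clusterFreqs <- lapply(names(config$clusters), function(cl)
    lapply(seq_len(L), function(l) drift(ancestral[[l]], fClust[[cl]])))
  names(clusterFreqs) <- names(config$clusters)
  popFreqs <- list()
  for (cl in names(config$clusters)) for (p in config$clusters[[cl]])
    popFreqs[[p]] <- lapply(seq_len(L), function(l)
      drift(clusterFreqs[[cl]][[l]], config$fSC))
  gm <- buildGenotypes(config, popFreqs, lociSizes)
  truth <- list(model = "hierarchical", clusters = clusterOfPop(config),
                ancestral = ancestral, clusterFreqs = clusterFreqs,
                popFreqs = popFreqs, config = config, seed = seed)
  list(genotypes = gm, truth = truth)
}

#' Simulate a stepping-stone tetraploid SSR dataset
#'
#' Populations sit on their coordinates; allele frequencies diverge with
#' effective distance (geographic distance in km plus `barrierEffect` km
#' across each planted barrier) through a latent Gaussian field:
#' per allele, log-weights are `log(p0) + ibdStrength * z` with
#' `z ~ MVN(0, Sigma)`, `Sigma_ij = exp(-d_eff/range)`, then softmax. This
#' yields a monotone expected genetic-vs-geographic distance relation;
#' `ibdStrength = 0` gives identical expected frequencies everywhere.
#'
#' @inheritParams simulateHierarchical
#' @export
simulateSteppingStone <- function(config = simulationConfig(), seed = 1L) {
  set.seed(seed)
  L <- config$nLoci
  pops <- unlist(config$clusters, use.names = FALSE)
  lociSizes <- lapply(seq_len(L), function(l)
    config$sizeMin[l] + config$motifLengths[l] *
      (0:(config$allelesPerLocus[l] - 1L)))
  ancestral <- lapply(seq_len(L), function(l)
    rdirichlet1(rep(1, config$allelesPerLocus[l])))
  co <- config$coords[match(pops, config$coords$population), ]
  geo <- geographicMatrix(co) / 1000
  deff <- geo
  for (grp in config$barrierGroups) {
    straddle <- outer(pops %in% grp, pops %in% grp, FUN = `!=`)
    deff <- deff + straddle * config$barrierEffect
  }
  # correlation range from the geographic scale only (barrier penalties
  # must sharpen the contrast, not inflate the global scale), wide enough
  # that within-group divergence stays smooth over the archipelago span
  range <- 2 * stats::median(geo[lower.tri(geo)])
  Sigma <- exp(-deff / max(range, 1e-6))
  popFreqs <- setNames(lapply(pops, function(p) vector("list", L)), pops)
  for (l in seq_len(L)) {
    m <- config$allelesPerLocus[l]
    z <- MASS::mvrnorm(m, mu = rep(0, length(pops)), Sigma = Sigma)
    for (pi in seq_along(pops)) {
      w <- log(ancestral[[l]]) + config$ibdStrength * z[, pi]
      w <- exp(w - max(w))
      popFreqs[[pops[pi]]][[l]] <- w / sum(w)
    }
  }
  gm <- buildGenotypes(config, popFreqs, lociSizes)
  truth <- list(model = "stepping-stone", clusters = clusterOfPop(config),
                ancestral = ancestral, popFreqs = popFreqs,
                effectiveDistance = deff, config = config, seed = seed)
  list(genotypes = gm, truth = truth)
}

#' Study-shape preset
#'
#' Convenience wrapper: the hierarchical simulation at the default
#' (study-shape) configuration, optionally with an extra strongly diverged
#' outgroup population (for ordination tests with congener-like samples).
#'
#' @param seed integer seed
#' @param outgroup add an `OUT` population of `outgroupN` individuals drawn
#'   at large drift distance (F = 0.8) from the ancestral pool
#' @param outgroupN outgroup sample size
#' @export
simulatePaperShape <- function(seed = 1L, outgroup = FALSE, outgroupN = 5L) {
  sim <- simulateHierarchical(simulationConfig(), seed)
  if (!outgroup) return(sim)
  config <- sim$truth$config
  L <- config$nLoci
  lociSizes <- lapply(seq_len(L), function(l)
    config$sizeMin[l] + config$motifLengths[l] *
      (0:(config$allelesPerLocus[l] - 1L)))
  of <- lapply(seq_len(L), function(l)
    rdirichlet1(sim$truth$ancestral[[l]] * 0.25))  # F = 0.8 drift
  g <- sim$genotypes@genotypes
  extra <- matrix(list(), outgroupN, ncol(g),
                  dimnames = list(sprintf("OUT_%02d", seq_len(outgroupN)),
                                  colnames(g)))
  for (l in seq_len(L)) for (i in seq_len(outgroupN))
    extra[[i, l]] <- as.integer(drawGenotype(lociSizes[[l]], of[[l]], 0))
  gm <- SsrGenotypes(rbind(g, extra), sim$genotypes@loci,
                     c(as.character(sim$genotypes@population),
                       rep("OUT", outgroupN)),
                     coords = sim$genotypes@coords)
  sim$genotypes <- gm
  sim$truth$outgroupFreqs <- of
  sim
}
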